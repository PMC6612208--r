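,Technical aspects,Organizational aspects,Economic aspects,Clinical aspects,Social ethical and legal aspects
Technical aspects,1,1/3,1/7,1/5,1/5
Organizational aspects,3,1,1/5,1/3,1/3
Economic aspects,7,5,1,3,5
Clinical aspects,5,3,1/3,1,3
Social ethical and legal aspects,5,3,1/5,1/3,1
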