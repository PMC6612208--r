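# ahpgap

Multi-criteria health technology assessment (HTA) combining the **analytic
hierarchy process (AHP)** with **Likert-scale satisfaction surveys**, and
joining the two in an **importance–satisfaction gap analysis**.

The package is written for assessment teams who survey an expert panel
twice about the same service: once with pairwise comparisons ("which
matters more, and how much?") and once with agreement items ("how
satisfied are you with it today?"). AHP turns the comparisons into
priority weights; Likert scoring turns the agreement items into
satisfaction indices; the gap analysis flags the sub-criteria that are
heavily weighted but poorly rated — the "hierarchy of needs" a decision
maker should act on first.

## The model in brief

For each node of a goal / criteria / sub-criteria hierarchy, respondents
judge every child pair on Saaty's 1–9 scale (reciprocals for the mirrored
direction). Per pair, the N judgments are aggregated by the weighted
geometric mean **Π aₖ^βₖ** (βₖ = 1/N), rounded to the nearest scale value
on the ≥ 1 side and mirrored, so the group matrix **A** is a positive
reciprocal matrix. Its priority vector **w** is the principal eigenvector
(**Aw** = λ_max **w**, normalized to unit sum), screened by the
consistency ratio

    CI = (λ_max − n) / (n − 1),   CR = CI / RI(n),   acceptable if CR ≤ 0.1.

Local weights multiply down the tree into unit-sum global sub-criterion
weights; per-alternative local weights (from operational indicator models
or any other source) then synthesize into final alternative priorities.
Likert items — including reverse-coded ones — score into per-item
satisfaction indices in [0, 1], mapped onto the same sub-criteria, and
the gap table ranks improvement priority by importance × (1 −
satisfaction).

A synthetic study generator (`paper_scenario()`, `generate_judgments()`,
`generate_likert()`, `generate_timesteps()`) produces complete surveys
with known ground truth, so the whole pipeline is testable without any
external data.

## Worked example

The built-in example assesses a thyroglobulin-assay technology: five
criteria, fourteen sub-criteria, and three alternatives (cytological
analysis vs the LOF and LPG fibre-optic biosensors). The group comparison
matrix of the five criteria ships as a CSV fixture:

```r
library(ahpgap)
M <- read_pairwise_csv(system.file("extdata", "criteria_matrix.csv",
                                   package = "ahpgap"))
consistency(M)
#> lambda_max = 5.3185 (n = 5)  CI = 0.0796  RI = 1.12  CR = 0.0711 (7.11%) -> acceptable
```

CR = 7.11% is below the 10% cutoff, so the panel's judgments are
consistent enough to use. The unit-sum principal eigenvector gives the
criteria weights:

```r
normalize_weights(principal_eigen(M)$vector)
#> Priority weights (unit sum):
#>                Technical aspects           Organizational aspects
#>                           0.0404                           0.0807
#>                 Economic aspects                 Clinical aspects
#>                           0.4935                           0.2412
#> Social ethical and legal aspects
#>                           0.1443
```

Economic aspects dominate (49%), followed by clinical aspects (24%).
Summing each alternative's per-leaf contributions (global leaf weight ×
local alternative weight) ranks the alternatives:

```r
synthesize_priorities(contribs)  # contribs: named list of contribution vectors
#> Alternative priorities:
#>   1. Biosensor LPG  0.4195
#>   2. Biosensor LOF  0.3607
#>   3. Cytological Analysis  0.3430
#>   (totals sum to 1.1231, not renormalized)
```

— a preference for the LPG biosensor. `run_full_assessment()` chains all
stages (aggregate → consistency → propagate → indicators → synthesis →
Likert → gap) from a hierarchy config plus CSV inputs and writes
`report.json`, `weights.csv` and `gap.csv`; `inst/scripts/ahpgap` exposes
the same stages as CLI subcommands (`aggregate`, `consistency`,
`priorities`, `likert`, `gap`, `simulate`).

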