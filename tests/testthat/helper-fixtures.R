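# Fixtures built in code from the printed tables of the worked example.

`%||%` <- function(x, y) if (is.null(x)) y else x

# 5x5 criteria comparison matrix (rows/cols: technical, organizational,
# economic, clinical, social-ethical-legal)
table2_matrix <- function() {
  pairwise_matrix(matrix(c(
    1,   1/3, 1/7, 1/5, 1/5,
    3,   1,   1/5, 1/3, 1/3,
    7,   5,   1,   3,   5,
    5,   3,   1/3, 1,   3,
    5,   3,   1/5, 1/3, 1), 5, 5, byrow = TRUE),
    labels = c("Technical aspects", "Organizational aspects",
               "Economic aspects", "Clinical aspects",
               "Social, ethical and legal aspects"))
}

# sub-criterion comparison matrices and their printed local weights
table5_fixtures <- function() {
  list(
    technical = list(
      M = pairwise_matrix(matrix(c(1, 1, 3, 1, 1, 3, 1/3, 1/3, 1),
                                 3, 3, byrow = TRUE),
                          labels = c("Reliability", "Technological Efficiency",
                                     "Technological Safety")),
      weights = c(3, 3, 1) / 7),
    organizational = list(
      M = pairwise_matrix(matrix(c(1, 5, 1/5, 1), 2, 2, byrow = TRUE),
                          labels = c("Procedural Complexity",
                                     "Human Resources")),
      weights = c(5, 1) / 6),
    economic = list(
      M = pairwise_matrix(matrix(c(1, 1/3, 1/5, 3, 1, 1, 5, 1, 1),
                                 3, 3, byrow = TRUE),
                          labels = c("Investments", "Usefulness", "ROS")),
      weights = c(0.1140, 0.4054, 0.4806)),
    clinical = list(
      M = pairwise_matrix(matrix(c(1, 1, 3, 1, 1, 3, 1/3, 1/3, 1),
                                 3, 3, byrow = TRUE),
                          labels = c("Clinical Efficiency", "Effectiveness",
                                     "Side Effects")),
      weights = c(3, 3, 1) / 7),
    social = list(
      M = pairwise_matrix(matrix(c(1, 3, 1/5, 1/3, 1, 1/7, 5, 7, 1),
                                 3, 3, byrow = TRUE),
                          labels = c("Respect for social aspects",
                                     "Respect for legal issues",
                                     "Respect for ethical principles")),
      weights = c(0.1884, 0.0810, 0.7306))
  )
}

# printed per-alternative contribution lists of the final synthesis
printed_contributions <- function() {
  list(
    "Cytological Analysis" = c(0.0114, 0.00042, 0.00960, 0.0105, 0.00512,
                               0.0228, 0.0270, 0.0080, 0.0114, 0.0258,
                               0.01632, 0.0077, 0.00954, 0.1774),
    "Biosensor LOF" = c(0.00320, 0.00320, 0.00162, 0.0288, 0.00149, 0.0256,
                        0.0961, 0.0961, 0.0450, 0.0046, 0.00544, 0.0018,
                        0.0477),
    "Biosensor LPG" = c(0.00270, 0.00270, 0.00376, 0.0288, 0.00149, 0.0256,
                        0.0811, 0.1139, 0.0041, 0.00544, 0.0022, 0.0477,
                        0.0503, 0.0497)
  )
}

# goal-level normalized eigenvector weights of the worked example
eq21_weights <- function() c(0.0404, 0.0807, 0.4935, 0.2412, 0.1443)

# random valid reciprocal matrix with entries on the Saaty ratio grid
random_reciprocal <- function(n) {
  M <- diag(n)
  vals <- c(1 / (9:2), 1:9)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- sample(vals, 1)
      M[j, i] <- 1 / M[i, j]
    }
  }
  pairwise_matrix(M)
}

# brute-force largest root of det(M - lambda I): grid scan + uniroot,
# independent of eigen()
charpoly_lambda_max <- function(M, upper = 2 * nrow(M)) {
  f <- function(l) det(unclass(M) - l * diag(nrow(M)))
  grid <- seq(upper, nrow(M) - 1, length.out = 4000)
  fv <- vapply(grid, f, numeric(1))
  sc <- which(diff(sign(fv)) != 0)
  if (length(sc) == 0) stop("no sign change found in scan")
  i <- sc[1]  # grid descends, so the first sign change is the largest root
  stats::uniroot(f, c(grid[i + 1], grid[i]), tol = 1e-12)$root
}

# one-timestep record row for indicator unit tests
tiny_record <- function(...) {
  base <- data.frame(
    timestep = 1, executed_exams = 8, queued_exams_for_faults = 1,
    exams_no_additional_withdrawals = 6, exams_no_further_investigation = 1,
    exams_requiring_further_withdrawals = 1, effective_tests = 7,
    effective_exams_with_error = 1, exams_with_side_effects = 0,
    incoming_requests = 10, refused_exams_surgeon = 0,
    refused_exams_patient = 1, net_profit = 50, mon = 20,
    net_revenues = 100, medical_specialists = 2, biologists = 1,
    planned_daily_exams = 10, executed_daily_exams = 8)
  utils::modifyList(base, list(...))
}

default_scores <- function() score_panel(rep(8, 5), rep(2, 6), 1e4, 5e4)

# config written to a temp YAML for io tests
write_tiny_config <- function(path = tempfile(fileext = ".yaml")) {
  yaml::write_yaml(list(
    goal = "pick",
    criteria = list(A = c("a1", "a2"), B = c("b1")),
    alternatives = c("x", "y")), path)
  path
}
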