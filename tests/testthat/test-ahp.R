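test_that("principal_eigen recovers the worked-example eigen pair", {
  pe <- principal_eigen(table2_matrix())
  expect_equal(pe$lambda_max, 5.3185, tolerance = 1e-4)
  expect_equal(unname(pe$vector),
               c(0.0703, 0.1403, 0.8582, 0.4194, 0.2509), tolerance = 1e-3)
  expect_equal(sqrt(sum(pe$vector^2)), 1)  # unit Euclidean norm
  expect_true(all(pe$vector > 0))
})

test_that("consistent matrices have lambda_max = n and weights equal ratios", {
  M <- pairwise_matrix(matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1),
                              3, 3, byrow = TRUE))
  pe <- principal_eigen(M)
  expect_equal(pe$lambda_max, 3, tolerance = 1e-10)
  expect_equal(unname(pe$vector / pe$vector[3]), c(4, 2, 1),
               tolerance = 1e-10)
})

test_that("eigen solver agrees with independent oracles on random matrices", {
  set.seed(7)
  for (n in c(4, 5, 7)) {
    M <- random_reciprocal(n)
    pe <- principal_eigen(M)
    # oracle 1: brute-force largest root of the characteristic polynomial
    expect_equal(pe$lambda_max, charpoly_lambda_max(M), tolerance = 1e-8)
    # oracle 2: long power iteration
    pi <- ahpgap:::.power_iteration(unclass(M), tol = 1e-13)
    expect_equal(pe$lambda_max, pi$lambda, tolerance = 1e-9)
    expect_equal(unname(pe$vector), unname(pi$vector), tolerance = 1e-9)
    # reciprocal matrices always satisfy lambda_max >= n
    expect_gte(pe$lambda_max, n - 1e-10)
  }
})

test_that("normalize_weights is unit-sum and scale-invariant", {
  w <- normalize_weights(principal_eigen(table2_matrix())$vector)
  expect_equal(unname(w$weights), eq21_weights(), tolerance = 1e-3)
  expect_equal(sum(w$weights), 1)
  expect_equal(unname(normalize_weights(c(1, 1, 1, 1))$weights), rep(0.25, 4))
  set.seed(3)
  for (i in 1:20) {
    v <- runif(sample(2:8, 1), 0.01, 5)
    c_ <- runif(1, 0.01, 100)
    expect_equal(normalize_weights(c_ * v)$weights,
                 normalize_weights(v)$weights, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(normalize_weights(c(0, 0)), "all-zero")
  expect_error(normalize_weights(c(1, -1)), "positive")
})

test_that("consistency reproduces CI/CR of the worked example", {
  rep <- consistency(table2_matrix())
  expect_equal(rep$CI, 0.0796, tolerance = 5e-4)
  expect_equal(rep$RI, 1.12)
  expect_equal(rep$CR, 0.0711, tolerance = 5e-4)
  expect_true(rep$acceptable)
})

test_that("consistency is zero for consistent matrices and matches the formula", {
  # fully consistent: a_ij = w_i / w_j
  w <- c(5, 2, 1, 0.5)
  M <- pairwise_matrix(outer(w, w, "/"))
  rep <- consistency(M)
  expect_equal(rep$CI, 0, tolerance = 1e-10)
  expect_equal(rep$CR, 0, tolerance = 1e-10)
  # n = 2 reciprocal matrices are consistent by construction
  rep2 <- consistency(pairwise_matrix(matrix(c(1, 7, 1/7, 1), 2, 2,
                                             byrow = TRUE)))
  expect_equal(rep2$CR, 0)
  # perturbed 3x3 matches the hand formula (lambda_max - 3) / 2 / 0.58
  M3 <- pairwise_matrix(matrix(c(1, 2, 4, 1/2, 1, 3, 1/4, 1/3, 1),
                               3, 3, byrow = TRUE))
  lam <- charpoly_lambda_max(M3)
  rep3 <- consistency(M3)
  expect_equal(rep3$CR, (lam - 3) / 2 / 0.58, tolerance = 1e-8)
  expect_error(random_index(11), "tabled")
})

test_that("assess_node screens consistency and writes eigen weights", {
  h <- paper_hierarchy()
  h <- assess_node(h, "goal", table2_matrix())
  expect_equal(h$local$goal, eq21_weights(), tolerance = 1e-3)
  expect_equal(h$consistency$goal$CR, 0.0711, tolerance = 5e-4)
  # an inconsistent matrix warns by default, errors in strict mode
  bad <- pairwise_matrix(matrix(c(1, 9, 1/9, 1/9, 1, 9, 9, 1/9, 1),
                                3, 3, byrow = TRUE))
  expect_warning(assess_node(h, "Economic aspects", bad), "CR")
  expect_error(assess_node(h, "Economic aspects", bad, strict = TRUE), "CR")
  expect_error(assess_node(h, "goal", bad), "dimension")
})

test_that("propagate_weights reproduces the printed overall weights", {
  t5 <- table5_fixtures()
  h <- paper_hierarchy()
  h <- set_local_weights(h, "goal",
                         c(0.0404, 0.08065, 0.4933, 0.2413, 0.1439) /
                           sum(c(0.0404, 0.08065, 0.4933, 0.2413, 0.1439)))
  h <- set_local_weights(h, "Technical aspects", t5$technical$weights)
  h <- set_local_weights(h, "Organizational aspects", t5$organizational$weights)
  h <- set_local_weights(h, "Economic aspects",
                         t5$economic$weights / sum(t5$economic$weights))
  h <- set_local_weights(h, "Clinical aspects", t5$clinical$weights)
  h <- set_local_weights(h, "Social, ethical and legal aspects",
                         t5$social$weights / sum(t5$social$weights))
  g <- propagate_weights(h)$global
  expect_equal(unname(g["Clinical Efficiency"]), 0.1034, tolerance = 1e-3)
  expect_equal(unname(g["ROS"]), 0.237, tolerance = 1e-3)
  expect_equal(unname(g["Usefulness"]), 0.200, tolerance = 1e-3)
  expect_equal(unname(g["Human Resources"]), 0.01345, tolerance = 1e-3)
  expect_equal(sum(g), 1, tolerance = 1e-9)
  # one-leaf criterion passes its parent weight through
  h1 <- build_hierarchy(list(goal = "g", criteria = list(A = "a", B = "b"),
                             alternatives = c("x", "y")))
  h1 <- set_local_weights(h1, "goal", c(0.3, 0.7))
  h1 <- set_local_weights(h1, "A", 1)
  h1 <- set_local_weights(h1, "B", 1)
  expect_equal(unname(propagate_weights(h1)$global["a"]), 0.3)
})

test_that("synthesize_priorities sums printed contributions and ranks them", {
  pri <- synthesize_priorities(printed_contributions())
  expect_equal(unname(pri$totals["Biosensor LOF"]), 0.36065)
  expect_lt(abs(pri$totals[["Biosensor LPG"]] - 0.419), 5e-4)
  expect_equal(pri$ranking[1], "Biosensor LPG")
  expect_equal(pri$ranking[2], "Biosensor LOF")
  expect_equal(pri$ranking[3], "Cytological Analysis")
  expect_false(pri$unit_sum)  # the raw totals sum to ~1.11, reported honestly
  # permutation invariance in contribution order
  set.seed(2)
  shuffled <- lapply(printed_contributions(), sample)
  expect_equal(synthesize_priorities(shuffled)$totals, pri$totals)
  # ties keep input order
  tied <- synthesize_priorities(list(A = c(0.2, 0.1), B = c(0.15, 0.15)))
  expect_equal(tied$ranking, c("A", "B"))
  # normalized view is unit-sum
  expect_equal(sum(synthesize_priorities(printed_contributions(),
                                         normalize = TRUE)$totals), 1)
  expect_error(synthesize_priorities(list(A = c(0.1, -0.2), B = 0.1)),
               "negative")
})
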