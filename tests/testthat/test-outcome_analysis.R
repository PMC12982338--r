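test_that("top-five mean matches brute force with deterministic tie-breaks", {
  expect_equal(top5_mean(c(a = 0.5, b = 0.4, c = 0.3, d = 0.2, e = 0.1,
                           f = 0.01)), 0.30)
  expect_equal(top5_mean(c(a = 1, b = 2, c = 3, d = 4, e = 5)), 3)
  expect_error(top5_mean(c(a = 1, b = 2)), "fewer than 5")
  expect_equal(top5_mean(c(a = 1, b = 2), lenient = TRUE), 1.5)
  expect_error(top5_mean(numeric(0)), "empty")
  set.seed(71)
  for (i in 1:20) {
    v <- stats::setNames(runif(sample(5:30, 1)), NULL)
    names(v) <- paste0("T", seq_along(v))
    expect_equal(top5_mean(v), mean(sort(v, decreasing = TRUE)[1:5]),
                 tolerance = 1e-14)
  }
  # ties at rank five resolved lexicographically
  v <- c(z = 0.5, y = 0.5, a = 0.9, b = 0.9, c = 0.9, d = 0.9)
  # top five: a,b,c,d then the lexicographically first of the tied {y, z}
  expect_equal(top5_mean(v), mean(c(0.9, 0.9, 0.9, 0.9, 0.5)))
})

test_that("rank correlations are exact on monotone data and flag constants", {
  rc <- rank_correlation(c(0, 1, 2), c(1, 2, 3))
  expect_equal(rc$rho, 1)
  expect_equal(rc$tau, 1)
  rc2 <- rank_correlation(c(0, 1, 2), c(3, 2, 1))
  expect_equal(rc2$rho, -1)
  rc3 <- rank_correlation(c(0, 0, 0), c(1, 2, 3))
  expect_true(is.na(rc3$rho))
  expect_match(rc3$reason, "constant")
  expect_error(rank_correlation(c(0, 1), c(1, 2)), "at least 3")
  expect_error(rank_correlation(c(0, 1, 2), c(1, 2)), "equal length")
})

test_that("exact permutation p-values agree with an independent enumeration", {
  # tie-free n = 6 keeps the independent full enumeration cheap (720 perms)
  set.seed(72)
  outcomes <- c(0, 1, 2, 2, 1, 0) + c(0.1, 0, 0, 0.2, 0.3, 0.15)  # untied
  values <- runif(6)
  rc <- rank_correlation(outcomes, values)
  expect_identical(rc$p_method, "exact_permutation")
  # oracle: loop over all 720 permutations, Spearman via stats::cor
  perm_all <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perm_all(values),
                 function(p) stats::cor(outcomes, p, method = "spearman"),
                 numeric(1))
  p_oracle <- mean(abs(rhos) >= abs(rc$rho) - 1e-12)
  expect_equal(rc$p_value, p_oracle, tolerance = 1e-12)
  # with ties in the outcome (ordinal codes), average ranks are used
  oc <- c(0, 1, 2, 2, 1, 0)
  rc_t <- rank_correlation(oc, values)
  expect_equal(rc_t$rho, stats::cor(oc, values, method = "spearman"),
               tolerance = 1e-12)
  rhos_t <- vapply(perm_all(values),
                   function(p) stats::cor(oc, p, method = "spearman"),
                   numeric(1))
  expect_equal(rc_t$p_value, mean(abs(rhos_t) >= abs(rc_t$rho) - 1e-12),
               tolerance = 1e-12)
})

test_that("exact p-values match the closed-form null for tie-free small n", {
  # under H0 with n = 4 and untied data the attainable |rho| values and
  # probabilities are known from the 24 permutations
  rc <- rank_correlation(c(1.3, 2.1, 3.2, 4.4), c(10, 30, 20, 40))
  expect_identical(rc$p_method, "exact_permutation")
  # rho = 0.8 here; P(|rho| >= 0.8) over 24 permutations = 4/24... computed
  # independently below
  perms <- rbind(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
                 c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
                 c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
                 c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                 c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  rhos <- apply(perms, 1L, function(p) stats::cor(1:4, p))
  expect_equal(rc$p_value, mean(abs(rhos) >= abs(rc$rho) - 1e-12),
               tolerance = 1e-12)
  # tau and rho agree in sign on monotone data
  expect_true(sign(rc$rho) == sign(rc$tau))
})

test_that("axis contributions recover a constructed single-axis dependence", {
  set.seed(73)
  n_cases <- 8L
  peaks <- cbind(x = runif(n_cases, 1000, 9000),
                 y = runif(n_cases, 1000, 9000),
                 z = runif(n_cases, 1000, 9000))
  metrics <- cbind(
    TR_P_R = 0.3 + 2e-5 * peaks[, "x"],   # exact linear in the X peak
    CC_B = runif(n_cases),
    ICP_R = rep(0, n_cases))              # constant: missing row
  out <- axis_contribution(metrics, peaks)
  row1 <- out[out$tract == "TR_P_R", ]
  # the x-axis Pearson correlation is exactly 1 for a linear dependence
  expect_gt(row1$x, max(row1$y, row1$z))
  expect_equal(row1$x + row1$y + row1$z, 1, tolerance = 1e-12)
  expect_true(out[out$tract == "ICP_R", "missing"])
  present <- out[!out$missing, ]
  expect_equal(present$x + present$y + present$z, rep(1, nrow(present)),
               tolerance = 1e-12)
  # scale invariance of the metric
  out2 <- axis_contribution(metrics * 17, peaks)
  expect_equal(out2$x, out$x, tolerance = 1e-12)
  # perfectly linear single-axis metric: x dominates under Spearman too
  m_exact <- cbind(T1 = peaks[, "x"])
  o_sp <- axis_contribution(m_exact, peaks, method = "spearman")
  expect_identical(which.max(c(o_sp$x, o_sp$y, o_sp$z)), 1L)
  expect_error(axis_contribution(metrics[1:2, ], peaks[1:2, ]), "at least 3")
})

test_that("the bundled case manifest loads with the documented coding", {
  path <- system.file("extdata", "case_outcomes.csv", package = "axtract")
  cases <- read_case_manifest(path)
  expect_identical(nrow(cases), 8L)
  expect_setequal(cases$outcome, c(0, 1, 2))
  expect_identical(cases$outcome[cases$case_id == 8], 0L)
  expect_identical(sort(cases$case_id[cases$outcome == 1]), c(1L, 3L))
  expect_identical(sort(cases$case_id[cases$outcome == 2]),
                   c(2L, 4L, 5L, 6L, 7L))
  # a monotone synthetic metric across cases gives rho = 1 by construction
  metric <- cases$outcome * 0.1 + seq(0.001, 0.008, 0.001)
  rc <- rank_correlation(cases$outcome, metric)
  expect_lt(abs(rc$rho - stats::cor(rank(cases$outcome), rank(metric))),
            1e-12)
})
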