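test_that("multinomial pmf handles the categorical, factorial and edge cases", {
  expect_equal(multinomial_log_pmf(5, 1), 0)
  expect_equal(exp(multinomial_log_pmf(c(1, 0), c(0.3, 0.7))), 0.3)
  expect_equal(exp(multinomial_log_pmf(c(2, 1), c(0.5, 0.5))), 0.375)
  expect_equal(multinomial_log_pmf(c(1, 1), c(0, 1)), -Inf)
  expect_error(multinomial_log_pmf(c(1, 2), c(1, 0, 0)), "length")
  # sums to one over all outcomes (exhaustive enumeration)
  for (n in 2:4) {
    theta <- seq_len(n) / sum(seq_len(n))
    for (k in c(3, 6)) {
      dd <- compositions(k, n)
      tot <- sum(apply(dd, 1, function(d) exp(multinomial_log_pmf(d, theta))))
      expect_lt(abs(tot - 1), 1e-12)
    }
  }
})

test_that("chi-square pattern test matches hand arithmetic and calibrates", {
  r <- suppressWarnings(chisq_pattern_test(c(10, 20, 30), c(1, 2, 3) / 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- chisq_pattern_test(c(70, 30), c(0.5, 0.5))
  expect_equal(r2$statistic, 16)
  expect_equal(r2$df, 1)
  expect_equal(r2$p_value, pchisq(16, 1, lower.tail = FALSE))
  expect_error(chisq_pattern_test(c(0, 0), c(0.5, 0.5)), "k = 0")
  expect_warning(chisq_pattern_test(c(3, 1), c(0.5, 0.5)), "below 5")
  # null calibration: rejection rate at alpha = 0.05
  set.seed(3)
  a <- c(0.2, 0.3, 0.5)
  p <- replicate(10000, {
    d <- as.vector(rmultinom(1, 200, a))
    chisq_pattern_test(d, a)$p_value
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 10000) + 0.005)
})

test_that("binomial small-volume p-value is the inclusive upper tail", {
  expect_equal(binomial_svc_pvalue(0, 10, 0.3), 1)
  expect_equal(binomial_svc_pvalue(3, 3, 0.5), 0.125)
  expect_equal(binomial_svc_pvalue(8, 10, 0.5), 56 / 1024)
  # exact enumeration oracle
  enum <- sum(dbinom(8:10, 10, 0.37))
  expect_equal(binomial_svc_pvalue(8, 10, 0.37), enum, tolerance = 1e-14)
  # deficit test mirrors the lower tail
  expect_equal(binomial_svc_pvalue(2, 10, 0.5, tail = "deficit"),
               sum(dbinom(0:2, 10, 0.5)))
  expect_error(binomial_svc_pvalue(5, 3, 0.5), "exceed")
})

test_that("predictive variance identity matches the beta-binomial and its
           Monte-Carlo estimate, and shrinks with concentration", {
  expect_equal(dirmult_predictive_variance(1, 0.3, 5), 0.3 * 0.7)
  expect_equal(dirmult_predictive_variance(10, 0.5, Inf), 2.5)
  expect_equal(dirmult_predictive_variance(10, 0.5, 4), 7)
  # beta-binomial closed form: k a (1-a) (c + k) / (c + 1)
  k <- 10; a <- 0.5; cc <- 4
  expect_equal(dirmult_predictive_variance(k, a, cc),
               k * a * (1 - a) * (cc + k) / (cc + 1))
  set.seed(4)
  draws <- rbinom(1e6, k, rbeta(1e6, cc * a, cc * (1 - a)))
  mc <- stats::var(draws)
  se <- sqrt(2) * 7 / sqrt(1e6 - 1)   # rough SE of a variance estimate
  expect_lt(abs(mc - 7), 6 * se + 0.05)
  # strictly decreasing in c (Occam's razor)
  cs <- c(0.5, 1, 2, 5, 10, 100, 1e4)
  vs <- vapply(cs, function(ci) dirmult_predictive_variance(20, 0.3, ci),
               numeric(1))
  expect_true(all(diff(vs) < 0))
})

test_that("independent Poisson counts conditioned on their total are
           multinomial over regions", {
  set.seed(5)
  g <- volume_grid(c(6, 6, 6))
  lab <- array(rep(1:3, times = c(43, 65, 108)), c(6, 6, 6))
  part <- isotropic_rel_volume(lab, g)
  a <- part$table$rel_volume
  draws <- t(replicate(1e5, simulate_poisson_counts(4 / 216 * 10, part)$d))
  # law of large numbers on the marginal means
  lam <- 4 / 216 * 10 * part$table$resels
  expect_lt(max(abs(colMeans(draws) / lam - 1)), 0.02)
  # condition on the modal total and compare with the multinomial pmf
  k <- as.integer(names(which.max(table(rowSums(draws)))))
  sel <- draws[rowSums(draws) == k, , drop = FALSE]
  cells <- compositions(k, 3)
  probs <- apply(cells, 1, function(d) exp(multinomial_log_pmf(d, a)))
  obs <- apply(cells, 1, function(d) {
    sum(sel[, 1] == d[1] & sel[, 2] == d[2] & sel[, 3] == d[3])
  })
  keep <- probs * nrow(sel) >= 5
  oo <- obs[keep]; pp <- probs[keep]
  if (any(!keep)) { oo <- c(oo, sum(obs[!keep])); pp <- c(pp, sum(probs[!keep])) }
  gof <- suppressWarnings(stats::chisq.test(oo, p = pp / sum(pp)))
  expect_gt(gof$p.value, 0.001)
})
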