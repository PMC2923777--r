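test_that("pooling sums counts and resels over subjects", {
  one <- tibble::tibble(region = 1:2, d = c(3, 4), resels = c(10, 20))
  expect_equal(pool_counts(one)$d, c(3, 4))
  two <- tibble::tibble(subject = rep(1:2, each = 2), region = rep(1:2, 2),
                        d = c(1, 2, 3, 4), resels = c(10, 30, 10, 30))
  p <- pool_counts(two)
  expect_equal(p$d, c(4, 6))
  expect_equal(p$resels, c(20, 60))
  expect_equal(p$rel_volume, c(0.25, 0.75))  # equal per-subject a unchanged
  bad <- tibble::tibble(subject = c(1, 1, 2), region = c(1, 2, 1),
                        d = 1, resels = 1)
  expect_error(pool_counts(bad), "region set")
})

test_that("evidences match the closed forms and the quadrature oracle", {
  expect_equal(log_evidence_null(c(1, 1), c(0.5, 0.5)), log(0.5))
  expect_equal(log_evidence_alt(3, prior_alpha = 0.5), 0)  # single region
  expect_equal(exp(log_evidence_alt(c(1, 1))), 0.25)
  # numerical integration of the likelihood against the Jeffreys prior
  for (d in list(c(1, 1), c(5, 2), c(0, 9))) {
    expect_equal(exp(log_evidence_alt(d)), evidence_alt_quad_n2(d),
                 tolerance = 1e-8)
  }
  # permutation symmetry
  d <- c(4, 0, 7); al <- c(0.5, 1, 2)
  pm <- c(3, 1, 2)
  expect_equal(log_evidence_alt(d, al), log_evidence_alt(d[pm], al[pm]))
  # normalisation by exhaustive enumeration
  for (n in 2:4) {
    for (k in c(3, 6)) {
      dd <- compositions(k, n)
      tot <- sum(apply(dd, 1, function(d) exp(log_evidence_alt(d))))
      expect_lt(abs(tot - 1), 1e-10)
    }
  }
})

test_that("model posterior is a softmax with the BF >= 20 convention", {
  mp <- model_posterior(-3, -3)
  expect_equal(c(mp$p_M0, mp$p_M1), c(0.5, 0.5))
  expect_equal(mp$p_M0 + mp$p_M1, 1)
  mp20 <- model_posterior(0, log(20))
  expect_true(mp20$accept_alt)   # boundary case counts as a decision
  expect_false(model_posterior(0, log(19.99))$accept_alt)
  # non-equal priors shift the posterior but not the Bayes factor
  mp2 <- model_posterior(-1, -2, prior = c(0.9, 0.1))
  expect_equal(mp2$bf_10, exp(-1))
  expect_equal(mp2$p_M1 / mp2$p_M0, exp(-2 + log(0.1) - (-1 + log(0.9))))
})

test_that("penalised intervals use Beta marginals, the (1-x)/(n-1) penalty,
           and a grid-search quantile oracle", {
  d <- c(12, 3, 5)
  a <- c(0.5, 0.25, 0.25)
  iv <- posterior_intervals(d, a, x = 0.99)
  n <- 3; k <- sum(d)
  eps <- (1 - 0.99) / (n - 1)
  expect_equal(credible_spec(0.99, 2)$epsilon, 0.01)
  # interval contains the posterior mean
  expect_true(all(iv$lo < iv$post_mean & iv$post_mean < iv$hi))
  expect_equal(iv$post_mean, (d + 0.5) / (k + n / 2))
  # brute-force inverse-CDF grid search on the Beta CDF
  for (j in 1:n) {
    s1 <- d[j] + 0.5; s2 <- k - d[j] + (n - 1) / 2
    for (p in c(eps / 2, 1 - eps / 2)) {
      lohi <- c(0, 1)
      for (it in 1:60) {
        mid <- mean(lohi)
        if (pbeta(mid, s1, s2) < p) lohi[1] <- mid else lohi[2] <- mid
      }
      q <- if (p < 0.5) iv$lo[j] else iv$hi[j]
      expect_lt(abs(q - mean(lohi)), 1e-8)
    }
  }
  # flags compare a against the interval with strict exclusion
  iv2 <- posterior_intervals(c(40, 0, 5), c(0.5, 0.38, 0.12))
  expect_equal(as.character(iv2$flag), c("rich", "sparse", "null"))
  expect_error(posterior_intervals(5, 1), "at least 2")
})

test_that("Occam's razor: the null wins whenever counts sit exactly at the
           null proportions", {
  for (n in 2:10) {
    for (mult in c(5, 20)) {
      k <- n * mult   # needs k a_j integral; uniform a
      d <- rep(mult, n)
      a <- rep(1 / n, n)
      expect_gt(log_evidence_null(d, a), log_evidence_alt(d),
                label = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("the Bayes factor for a true alternative grows without bound in k", {
  theta <- c(0.7, 0.3); a <- c(0.5, 0.5)
  lbf <- vapply(c(100, 1000, 10000), function(k) {
    d <- round(k * theta)
    log_evidence_alt(d) - log_evidence_null(d, a)
  }, numeric(1))
  expect_true(all(diff(lbf) > 0))
  expect_gt(lbf[3], 100)
})

test_that("informed model comparison is a ratio of multinomial pmfs", {
  expect_equal(informed_ffx_comparison(c(3, 7), c(0.4, 0.6), c(0.4, 0.6))$bf, 1)
  bf <- informed_ffx_comparison(c(10, 0), c(0.5, 0.5), c(0.9, 0.1))$bf
  expect_equal(bf, 0.9^10 / 0.5^10, tolerance = 1e-12)
  expect_equal(bf, 357.05, tolerance = 1e-3)
  # reciprocity
  f <- informed_ffx_comparison(c(4, 6), c(0.3, 0.7), c(0.6, 0.4))$bf
  b <- informed_ffx_comparison(c(4, 6), c(0.6, 0.4), c(0.3, 0.7))$bf
  expect_equal(f * b, 1, tolerance = 1e-12)
  # impossible informed pattern gives BF 0, not an error
  expect_equal(informed_ffx_comparison(c(1, 1), c(0.5, 0.5), c(1, 0))$bf, 0)
})

test_that("ffx_fit ties the pieces together with tidy/glance methods", {
  counts <- tibble::tibble(subject = rep(1:2, each = 2),
                           region = rep(1:2, 2), d = c(20, 2, 18, 4),
                           resels = rep(c(50, 50), 2))
  fit <- ffx_fit(counts)
  expect_s3_class(fit, "ffx_fit")
  expect_equal(fit$k, 44)
  g <- glance(fit)
  expect_equal(g$log_bf_10, fit$logE1 - fit$logE0)
  expect_true(g$accept_alt)   # 38 vs 6 in equal volumes is decisive
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_equal(as.character(td$flag), c("rich", "sparse"))
  expect_s3_class(autoplot(fit), "ggplot")
})
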