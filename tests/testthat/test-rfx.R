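test_that("the collapsed log posterior matches a quadrature oracle and is
           permutation symmetric", {
  set.seed(61)
  data <- make_counts(I = 4, k_i = 30, theta = c(0.4, 0.6), seed = 61)
  d <- matrix(data$d, nrow = 4, byrow = TRUE)
  m <- c(0.35, 0.65); cc <- 12
  # per-subject: integrate the multinomial against the Beta(c m) density
  ll <- sum(vapply(seq_len(4), function(i) {
    di <- d[i, ]
    f <- function(th) {
      exp(lgamma(sum(di) + 1) - sum(lgamma(di + 1)) +
            di[1] * log(th) + di[2] * log(1 - th)) *
        stats::dbeta(th, cc * m[1], cc * m[2])
    }
    log(stats::integrate(f, 0, 1, rel.tol = 1e-12)$value)
  }, numeric(1)))
  oracle <- ll - log(cc)   # flat simplex prior, 1/c from the log-uniform
  expect_equal(rfx_log_posterior(m, cc, data), oracle, tolerance = 1e-6)
  # outside the support
  expect_equal(rfx_log_posterior(m, 1e9, data), -Inf)
  # single subject reduces to the Dirichlet-multinomial marginal + const
  one <- dplyr::filter(data, subject == 1)
  l1 <- rfx_log_posterior(m, cc, one)
  l2 <- rfx_log_posterior(rev(m), cc, dplyr::mutate(one, region = 3 - region))
  expect_equal(l1, l2)
  # three-region permutation symmetry
  d3 <- make_counts(I = 3, k_i = 20, theta = c(0.2, 0.3, 0.5), seed = 7)
  pm <- c(2, 3, 1)
  m3 <- c(0.25, 0.35, 0.4)
  d3p <- dplyr::mutate(d3, region = match(region, pm))
  expect_equal(rfx_log_posterior(m3, 5, d3),
               rfx_log_posterior(m3[pm], 5, d3p), tolerance = 1e-10)
})

test_that("the sampler is deterministic under a fixed seed and reports
           split R-hat", {
  data <- make_counts(I = 6, k_i = 40, theta = c(0.3, 0.7), seed = 3)
  p1 <- rfx_sample(data, chains = 2, iter = 1500, burn_in = 500, seed = 42)
  p2 <- rfx_sample(data, chains = 2, iter = 1500, burn_in = 500, seed = 42)
  expect_identical(p1$samples, p2$samples)
  expect_named(p1$rhat, c("m_1", "m_2", "c"))
  expect_true(all(rowSums(p1$samples[, 1:2]) - 1 < 1e-12))
  expect_true(all(p1$samples[, "c"] > 0))
})

test_that("the sampler recovers population means from synthetic subjects", {
  set.seed(8)
  I <- 50; m_true <- c(0.3, 0.7); c_true <- 50
  rows <- purrr::map_dfr(seq_len(I), function(i) {
    th <- rbeta(1, c_true * m_true[1], c_true * m_true[2])
    tibble::tibble(subject = i, region = 1:2,
                   d = as.vector(rmultinom(1, 200, c(th, 1 - th))),
                   resels = c(30, 70))
  })
  post <- rfx_sample(rows, chains = 2, iter = 4000, burn_in = 1000, seed = 9)
  expect_lt(abs(mean(post$samples[, "m_1"]) - 0.3), 0.05)
  expect_true(post$converged)
})

test_that("marginal interval quantiles equal a sort-based oracle and widen
           with the region penalty", {
  data <- make_counts(I = 5, k_i = 50, theta = c(0.5, 0.5), seed = 12)
  post <- rfx_sample(data, chains = 2, iter = 3000, burn_in = 1000, seed = 5)
  iv <- rfx_intervals(post, a = c(0.5, 0.5), x = 0.95)
  s <- sort(post$samples[, "m_1"])
  S <- length(s)
  eps <- (1 - 0.95) / (2 - 1)
  expect_equal(iv$lo[1], s[ceiling(eps / 2 * S)])
  expect_equal(iv$hi[1], s[ceiling((1 - eps / 2) * S)])
  # a fiercer penalty (larger n) cannot narrow the interval
  iv19 <- posterior_intervals(c(10, 40), c(0.5, 0.5), x = 0.99)
  w2 <- iv19$hi - iv19$lo
  eps19 <- credible_spec(0.99, 19)$epsilon
  lo19 <- qbeta(eps19 / 2, 10.5, 40 + 0.5)
  hi19 <- qbeta(1 - eps19 / 2, 10.5, 40 + 0.5)
  expect_gte(hi19 - lo19, w2[1])
  # degenerate samples equal to a yield no flags
  post0 <- post
  post0$samples[, 1] <- 0.5 + rnorm(nrow(post0$samples), 0, 1e-6)
  post0$samples[, 2] <- 1 - post0$samples[, 1]
  expect_true(all(rfx_intervals(post0, a = c(0.5, 0.5))$flag == "null"))
  expect_error(rfx_intervals(structure(list(samples = post$samples[1:10, ],
                                            n = 2), class = "rfx_posterior"),
                             a = c(0.5, 0.5)), "1000")
})

test_that("informed evidence matches trapezoidal integration and the
           large-concentration limit", {
  data <- make_counts(I = 3, k_i = 25, theta = c(0.45, 0.55), seed = 21)
  d <- matrix(data$d, nrow = 3, byrow = TRUE)
  m <- c(0.5, 0.5)
  le <- informed_rfx_evidence(d, m)
  # trapezoid on a fine fixed grid in log c
  u <- seq(log(0.1), log(1e4), length.out = 4001)
  ll <- vapply(u, function(ui) {
    cc <- exp(ui)
    sum(vapply(1:3, function(i) {
      di <- d[i, ]
      lgamma(sum(di) + 1) - sum(lgamma(di + 1)) +
        lgamma(cc) - lgamma(cc + sum(di)) +
        sum(lgamma(cc * m + di)) - sum(lgamma(cc * m))
    }, numeric(1)))
  }, numeric(1))
  mx <- max(ll)
  trap <- mx + log(sum(diff(u) * (exp(ll[-1] - mx) + exp(ll[-4001] - mx)) / 2)) -
    log(log(1e4) - log(0.1))
  expect_equal(le, trap, tolerance = 1e-6)
  # BF of a pattern against itself is exactly 1
  expect_equal(informed_rfx_evidence(d, m) - informed_rfx_evidence(d, m), 0)
  # concentration pinned very high: subjects share m exactly, so the
  # evidence approaches the product of multinomial pmfs at m
  le_hi <- informed_rfx_evidence(d[1, , drop = FALSE], m,
                                 prior = rfx_prior(c_range = c(1e8, 1.01e8)))
  expect_equal(le_hi, multinomial_log_pmf(d[1, ], m), tolerance = 1e-4)
})

test_that("fixed effects is the low-heterogeneity limit of random effects", {
  set.seed(14)
  I <- 12
  rows <- purrr::map_dfr(seq_len(I), function(i) {
    tibble::tibble(subject = i, region = 1:2,
                   d = as.vector(rmultinom(1, 150, c(0.4, 0.6))),
                   resels = c(40, 60))
  })
  rfx <- rfx_fit(rows, chains = 2, iter = 4000, burn_in = 1000, seed = 31)
  ffx <- ffx_fit(rows)
  mid_r <- (rfx$intervals$lo + rfx$intervals$hi) / 2
  mid_f <- (ffx$intervals$lo + ffx$intervals$hi) / 2
  expect_lt(max(abs(mid_r - mid_f)), 0.05)
  # the pattern coordinates must mix even though c drifts in its flat tail
  # (the data carry no heterogeneity information in this limit)
  expect_lt(max(rfx$posterior$rhat[1:2]), 1.1)
  expect_s3_class(autoplot(rfx), "ggplot")
  expect_equal(nrow(tidy(rfx)), 2)
})

test_that("stochastic entry points insist on a seed", {
  data <- make_counts(I = 3, k_i = 10, theta = c(0.5, 0.5))
  expect_error(rfx_sample(data), "seed")
  expect_error(rfx_fit(data), "seed")
  cfg <- null_sim_config("desk")
  expect_error(run_fwer_experiment(cfg), "seed")
})
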