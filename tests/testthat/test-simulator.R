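test_that("voronoi parcellation assigns every voxel to its nearest seed", {
  lab1 <- voronoi_parcellation(c(5, 5, 5), 1, seed = 1)
  expect_true(all(lab1 == 1L))
  # partition property
  lab <- voronoi_parcellation(c(9, 9, 9), 7, seed = 2)
  expect_equal(sum(tabulate(lab, 7)), 9^3)
  expect_true(all(tabulate(lab, 7) > 0))
  # brute-force distance oracle on a fresh draw
  set.seed(3)
  dm <- c(8, 8, 8)
  lab2 <- voronoi_parcellation(dm, 4, seed = 33)
  set.seed(33)
  seeds <- sample.int(prod(dm), 4)
  sc <- arrayInd(seeds, dm)
  for (lin in sample.int(prod(dm), 60)) {
    v <- arrayInd(lin, dm)
    d2 <- rowSums(sweep(sc, 2, as.numeric(v))^2)
    expect_equal(lab2[lin], which.min(d2))  # which.min = lowest index on ties
  }
  # two seeds at opposite corners split along the perpendicular bisector
  labs <- voronoi_oracle_corners(c(6, 6, 6))
  expect_true(all(labs$lab == labs$expected))
})

test_that("null subjects reproduce the Student-t marginal and honour the
           configured lattice", {
  cfg <- null_sim_config("desk", lattice = c(10L, 10L, 10L), n_scans = 24L,
                         n_voronoi = 4L)
  sim <- simulate_null_subject(cfg, seed = 5)
  expect_equal(dim(sim$t), c(10, 10, 10))
  expect_equal(sim$df, 23L)
  tv <- vapply(1:300, function(i) {
    simulate_null_subject(cfg, seed = 1000 + i)$t[5, 5, 5]
  }, numeric(1))
  ks <- stats::ks.test(tv, stats::pt, df = 23)
  expect_gt(ks$p.value, 0.01)
})

test_that("a collapsed smoothness range gives a stationary field whose
           resel count matches the closed form", {
  cfg <- null_sim_config("desk", lattice = c(24L, 24L, 24L), n_scans = 30L,
                         n_voronoi = 2L, fwhm_range = c(5, 5), global_fwhm = 0)
  sim <- simulate_null_subject(cfg, seed = 17, keep_scans = TRUE)
  g <- volume_grid(cfg$lattice)
  rpv <- estimate_rpv(sim$residuals, g, df = sim$df)
  expect_lt(abs(sum(rpv$rpv) / (24^3 / 5^3) - 1), 0.10)
})

test_that("simulator outputs are reproducible given the seed", {
  cfg <- null_sim_config("desk", lattice = c(8L, 8L, 8L), n_scans = 6L,
                         n_voronoi = 3L)
  s1 <- simulate_null_subject(cfg, seed = 99)
  s2 <- simulate_null_subject(cfg, seed = 99)
  expect_identical(s1$t, s2$t)
  expect_identical(voronoi_parcellation(c(7, 7, 7), 5, seed = 4),
                   voronoi_parcellation(c(7, 7, 7), 5, seed = 4))
})

test_that("the null sanity check calibrates and detects concentration", {
  set.seed(23)
  g <- volume_grid(c(6, 6, 6))
  lab <- voronoi_parcellation(c(6, 6, 6), 4, seed = 6)
  part <- isotropic_rel_volume(lab, g)
  a <- part$table$rel_volume
  # counts drawn exactly from the null pattern: BF rarely reaches 20
  rejections <- vapply(1:200, function(i) {
    d <- as.vector(rmultinom(1, 150, a))
    lb <- log_evidence_alt(d) - log_evidence_null(d, a)
    exp(lb) >= 20
  }, logical(1))
  expect_lt(mean(rejections), 0.05)
  # concentrated counts are detected
  n <- length(a)
  theta <- rep(0.1 / (n - 1), n)
  theta[1] <- 0.9
  d_conc <- as.vector(rmultinom(1, 200, theta))
  lb <- log_evidence_alt(d_conc) - log_evidence_null(d_conc, a)
  expect_gte(exp(lb), 20)
  # end-to-end on fields: spiked SPMs reject, empty SPMs report "no test"
  f0 <- array(0, c(6, 6, 6))
  expect_equal(null_spm_sanity(f0, part)$status, "no test")
})

test_that("fwer experiments on a miniature corpus produce bookkeeping that
           matches their flag logs, and x -> 1 disarms all flags", {
  cfg <- null_sim_config("desk", lattice = c(12L, 12L, 12L), n_scans = 8L,
                         n_voronoi = 4L, corpus_size = 12L, group_size = 4L,
                         n_experiments = 6L, n_anat_regions = 6L,
                         threshold = 2, fwhm_range = c(2, 4), global_fwhm = 1)
  corpus <- simulate_null_corpus(cfg, seed = 71)
  expect_length(corpus$subjects, 12)
  rep1 <- run_fwer_experiment(cfg, seed = 72, corpus = corpus, mode = "ffx",
                              n_select = c(3L), x = 0.99)
  expect_true(all(rep1$fwer >= 0 & rep1$fwer <= 1))
  expect_equal(rep1$n_flagged, as.integer(rep1$fwer * rep1$L))
  # intervals forced essentially infinitely wide: no flags possible
  rep_wide <- run_fwer_experiment(cfg, seed = 72, corpus = corpus,
                                  mode = "ffx", n_select = c(3L),
                                  x = 1 - 1e-9)
  expect_equal(rep_wide$fwer, 0)
  expect_s3_class(autoplot(rep1), "ggplot")
})
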