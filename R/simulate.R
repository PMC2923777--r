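#' Null-simulation configuration
#'
#' Settings for the non-stationary null corpus: per scan, iid standard
#' Gaussian noise on a regular lattice is made non-stationary by piecewise
#' constant smoothing over a random Voronoi layout (each cell with its own
#' FWHM drawn uniformly from `fwhm_range`), then the whole image is smoothed
#' again at `global_fwhm` to preclude sharp transitions at cell boundaries;
#' a mean-effect GLM over the scans yields the subject's t-field.
#'
#' The `"full"` profile matches the reference simulation study (64^3
#' lattice, 84 scans, corpus of 1000 subjects, 150 groups of 20, 116
#' anatomical-style regions); the `"desk"` profile is the scaled-down
#' counterpart used by the package's own validation runs (32^3 lattice, 24
#' scans, corpus of 300, 100 groups of 10, 60 regions).
#'
#' @param profile `"full"` or `"desk"`.
#' @param ... named overrides of any field below.
#' @return list of class `null_sim_config` with fields `lattice`, `n_scans`,
#'   `n_voronoi`, `fwhm_range`, `global_fwhm`, `corpus_size`, `group_size`,
#'   `n_experiments`, `n_partition_regions`, `n_anat_regions`, `threshold`,
#'   `connectivity`, `edge`.
#' @export
null_sim_config <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(lattice = c(64L, 64L, 64L), n_scans = 84L, n_voronoi = 20L,
         fwhm_range = c(4, 10), global_fwhm = 2, corpus_size = 1000L,
         group_size = 20L, n_experiments = 150L,
         n_partition_regions = c(5L, 10L, 15L, 20L), n_anat_regions = 116L,
         threshold = 3, connectivity = 26L, edge = "wrap")
  } else {
    list(lattice = c(32L, 32L, 32L), n_scans = 24L, n_voronoi = 20L,
         fwhm_range = c(4, 10), global_fwhm = 2, corpus_size = 300L,
         group_size = 10L, n_experiments = 100L,
         n_partition_regions = c(5L, 10L, 15L, 20L), n_anat_regions = 60L,
         threshold = 3, connectivity = 26L, edge = "wrap")
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$fwhm_range[1] >= 1, cfg$group_size <= cfg$corpus_size,
            all(unlist(cfg[c("n_scans", "n_voronoi", "corpus_size",
                             "group_size", "n_experiments")]) > 0))
  cfg$profile <- profile
  structure(cfg, class = "null_sim_config")
}

#' Voronoi parcellation of a lattice
#'
#' Labels every voxel by its nearest of `n_regions` uniformly drawn seed
#' voxels (Euclidean distance in voxel units, ties to the lowest seed
#' index).  Seeds are drawn without replacement, so every region contains at
#' least its own seed voxel.
#'
#' @param shape integer(3) lattice dimensions.
#' @param n_regions number of cells.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param seed_voxels optional matrix of seed voxel coordinates (rows of
#'   `x, y, z`), bypassing the random draw.
#' @return integer 3D array of labels `1..n_regions`.
#' @export
voronoi_parcellation <- function(shape, n_regions, seed = NULL,
                                 seed_voxels = NULL) {
  shape <- as.integer(shape)
  V <- prod(shape)
  if (n_regions > V) stop("more regions than voxels")
  if (is.null(seed_voxels)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    seeds <- sample.int(V, n_regions)
    sc <- arrayInd(seeds, shape)
  } else {
    sc <- as.matrix(seed_voxels)
    stopifnot(nrow(sc) == n_regions, ncol(sc) == 3)
  }
  crd <- arrayInd(seq_len(V), shape)
  lab <- integer(V)
  best <- rep(Inf, V)
  for (r in seq_len(n_regions)) {
    d2 <- (crd[, 1] - sc[r, 1])^2 + (crd[, 2] - sc[r, 2])^2 +
      (crd[, 3] - sc[r, 3])^2
    upd <- d2 < best       # strict: ties stay with the lowest seed index
    lab[upd] <- r
    best[upd] <- d2[upd]
  }
  array(lab, dim = shape)
}

#' Simulate one null subject's t-field
#'
#' Draws `n_scans` iid standard-normal volumes, applies the subject's fixed
#' piecewise smoothing (one FWHM per Voronoi cell) plus the global kernel to
#' each scan, and computes the one-sample t-field
#' `t = mean / (sd / sqrt(n_scans))` with `n_scans - 1` degrees of freedom.
#' The Voronoi layout and cell FWHMs are drawn once per subject and shared
#' by all of its scans.
#'
#' @param cfg a [null_sim_config()].
#' @param seed integer seed for this subject.
#' @param keep_scans also return the centred residual volumes (needed for
#'   resel estimation).
#' @return list with `t` (3D array), `df`, and when `keep_scans = TRUE`
#'   `residuals` (4D array) plus the smoothness `layout` (labels, fwhms).
#' @export
simulate_null_subject <- function(cfg, seed, keep_scans = FALSE) {
  stopifnot(inherits(cfg, "null_sim_config"))
  set.seed(as.integer(seed))
  dm <- cfg$lattice
  V <- prod(dm)
  labels <- voronoi_parcellation(dm, cfg$n_voronoi)
  fwhms <- runif(cfg$n_voronoi, cfg$fwhm_range[1], cfg$fwhm_range[2])
  lab_vec <- as.vector(labels)
  scans <- matrix(NA_real_, V, cfg$n_scans)
  for (s in seq_len(cfg$n_scans)) {
    noise <- array(rnorm(V), dim = dm)
    comp <- numeric(V)
    for (r in seq_len(cfg$n_voronoi)) {
      sm <- gauss_smooth(noise, fwhms[r], edge = cfg$edge)
      sel <- lab_vec == r
      comp[sel] <- sm[sel]
    }
    comp <- gauss_smooth(array(comp, dim = dm), cfg$global_fwhm,
                         edge = cfg$edge)
    scans[, s] <- comp
  }
  mu <- rowMeans(scans)
  res <- scans - mu
  s2 <- rowSums(res^2) / (cfg$n_scans - 1)
  tval <- mu / sqrt(s2 / cfg$n_scans)
  out <- list(t = array(tval, dim = dm), df = cfg$n_scans - 1L)
  if (keep_scans) {
    out$residuals <- array(res, dim = c(dm, cfg$n_scans))
    out$layout <- list(labels = labels, fwhms = fwhms)
  }
  out
}

#' Build a corpus of null subjects
#'
#' Simulates `cfg$corpus_size` independent null subjects and reduces each to
#' what pattern inference needs: the supra-threshold peak table and the
#' resels-per-voxel image estimated from that subject's own standardized GLM
#' residuals.
#'
#' @inheritParams simulate_null_subject
#' @param seed integer master seed; subject seeds are derived from it.
#' @param progress print a note every 50 subjects.
#' @return list of class `null_corpus`: `cfg`, `grid`, and `subjects`, a
#'   list with per-subject `peaks` (tibble `x,y,z,height`) and `rpv` (3D
#'   array).
#' @export
simulate_null_corpus <- function(cfg, seed, progress = FALSE) {
  stopifnot(inherits(cfg, "null_sim_config"))
  grid <- volume_grid(cfg$lattice)
  subjects <- vector("list", cfg$corpus_size)
  for (i in seq_len(cfg$corpus_size)) {
    sub_seed <- (as.numeric(seed) * 7 + 7919 * i) %% 2147483647
    sim <- simulate_null_subject(cfg, sub_seed, keep_scans = TRUE)
    rpv <- estimate_rpv(sim$residuals, grid, df = sim$df)
    ev <- find_peaks(sim$t, grid, threshold = cfg$threshold,
                     connectivity = cfg$connectivity)
    subjects[[i]] <- list(peaks = tibble::as_tibble(ev), rpv = rpv$rpv)
    if (progress && i %% 50 == 0) {
      message(sprintf("  simulated %d / %d subjects", i, cfg$corpus_size))
    }
  }
  structure(list(cfg = cfg, grid = grid, subjects = subjects, seed = seed),
            class = "null_corpus")
}

#' @export
print.null_corpus <- function(x, ...) {
  ks <- vapply(x$subjects, function(s) nrow(s$peaks), integer(1))
  cat("<null_corpus> ", length(x$subjects), " subjects on ",
      paste(x$cfg$lattice, collapse = "x"), "; events/subject: median ",
      stats::median(ks), " [", min(ks), ", ", max(ks), "]\n", sep = "")
  invisible(x)
}

# per-subject regional summaries against a label volume:
# resels[i, j] = sum of subject i's rpv over region j
# counts[i, j] = subject i's peak count in region j
corpus_regional_summaries <- function(corpus, labels) {
  lab_vec <- as.integer(labels)
  n <- max(lab_vec)
  f <- factor(lab_vec, levels = seq_len(n))
  I <- length(corpus$subjects)
  R <- matrix(0, I, n)
  Cm <- matrix(0L, I, n)
  dm <- corpus$grid$dim
  for (i in seq_len(I)) {
    s <- corpus$subjects[[i]]
    R[i, ] <- as.vector(tapply(as.vector(s$rpv), f, sum, default = 0))
    if (nrow(s$peaks) > 0) {
      lin <- s$peaks$x + (s$peaks$y - 1L) * dm[1] +
        (s$peaks$z - 1L) * dm[1] * dm[2]
      Cm[i, ] <- tabulate(lab_vec[lin], nbins = n)
    }
  }
  list(resels = R, counts = Cm)
}

#' Independent Poisson counts under the homogeneous model
#'
#' Draws `d_j ~ Poisson(lambda |A_j|)` independently per region — the point
#' process that, conditioned on the total count, reduces to the multinomial
#' null.  Used for property checks of that reduction, independently of any
#' simulated field.
#'
#' @param lambda event rate per resel (> 0).
#' @param partition a `region_partition`.
#' @return An `event_counts` tibble (`region`, `name`, `d`) with attribute
#'   `k`.
#' @export
simulate_poisson_counts <- function(lambda, partition) {
  stopifnot(lambda > 0, inherits(partition, "region_partition"))
  tbl <- partition$table
  d <- rpois(nrow(tbl), lambda * tbl$resels)
  structure(
    tibble::tibble(region = tbl$region, name = tbl$name, d = as.integer(d)),
    k = sum(d), class = c("event_counts", "tbl_df", "tbl", "data.frame")
  )
}

#' Goodness-of-fit of the uniform-per-resel null on observed maps
#'
#' Pools supra-threshold peak counts over one or more statistic maps and
#' compares the regional event fractions with the relative resel counts:
#' Pearson chi-square test plus the fixed-effects Bayes factor, with the
#' null "rejected" when the Bayes factor reaches `bf_threshold`.  With no
#' events the report carries `status = "no test"`.
#'
#' @param spms a 3D array or list of 3D arrays of statistic values.
#' @param partition a `region_partition` (provides grid, labels, resels).
#' @param threshold peak height threshold (default 3).
#' @param bf_threshold Bayes-factor decision threshold (default 20).
#' @return list with `counts` (pooled per-region tibble), `k`, `chisq`
#'   (tibble or `NULL`), `log_bf`, `bf`, `null_rejected`, `status`.
#' @export
null_spm_sanity <- function(spms, partition, threshold = 3,
                            bf_threshold = 20) {
  stopifnot(inherits(partition, "region_partition"))
  if (is.array(spms)) spms <- list(spms)
  d <- integer(nrow(partition$table))
  for (s in spms) {
    ev <- find_peaks(s, partition$grid, threshold = threshold)
    d <- d + count_events(ev, partition)$d
  }
  a <- partition$table$rel_volume
  k <- sum(d)
  if (k == 0) {
    return(list(counts = NULL, k = 0L, chisq = NULL, log_bf = NA_real_,
                bf = NA_real_, null_rejected = NA, status = "no test"))
  }
  counts <- tibble::tibble(region = partition$table$region,
                           name = partition$table$name, d = d, a = a,
                           fraction = d / k)
  chisq <- tryCatch(suppressWarnings(chisq_pattern_test(d, a)),
                    error = function(e) NULL)
  lb <- log_evidence_alt(d) - log_evidence_null(d, a)
  list(counts = counts, k = k, chisq = chisq, log_bf = lb, bf = exp(lb),
       null_rejected = exp(lb) >= bf_threshold, status = "ok")
}
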