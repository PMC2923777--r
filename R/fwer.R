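#' Frequentist operating characteristics of pattern inference under the null
#'
#' Runs the full validation loop: over `cfg$n_experiments` simulated null
#' "experiments", draws a group of subjects from the corpus, selects `N`
#' regions of an anatomical-style parcellation (a seeded Voronoi stand-in
#' for an atlas) plus the rest-of-volume union as the final region, pools
#' regional resel and event counts, and applies fixed-effects (and
#' optionally random-effects) inference with penalised credible intervals.
#' Reported per configuration are the family-wise error rate — the fraction
#' of experiments with at least one interval excluding its null relative
#' volume — and, for fixed effects, the rate of Bayes factors at or above
#' the decision threshold.
#'
#' @param cfg a [null_sim_config()].
#' @param seed integer master seed (required): drives corpus simulation (if
#'   no corpus is supplied), the anatomical parcellation, group draws and
#'   MCMC.
#' @param corpus optional pre-built [simulate_null_corpus()] output (saves
#'   the dominant cost when several calls share one corpus).
#' @param mode `"ffx"` or `"rfx"`.
#' @param n_select partition sizes `N` to assess; each experiment uses `N`
#'   randomly chosen atlas regions plus the rest-of-volume region.  Use
#'   `"all"` for the exploratory design: the full parcellation with no rest
#'   region.
#' @param n_experiments number of experiments `L` per partition size;
#'   defaults to `cfg$n_experiments`.
#' @param x credible level (default 0.99).
#' @param bf_threshold Bayes-factor decision threshold (default 20).
#' @param rfx_mcmc list of MCMC settings for `mode = "rfx"`:
#'   `chains`, `iter`, `burn_in`.
#' @param resel_floor minimum pooled resel count per selected region; a
#'   draw containing a thinner region is re-drawn (logged via `message()`).
#' @return A `fwer_report`: tibble with one row per partition size and
#'   columns `mode`, `N`, `L`, `group_size`, `n_flagged`, `fwer`,
#'   `max_bf` / `n_bf_exceed` / `bf_exceed_rate` (fixed effects), and for
#'   random effects `n_nonconverged`.
#' @export
run_fwer_experiment <- function(cfg, seed, corpus = NULL,
                                mode = c("ffx", "rfx"),
                                n_select = cfg$n_partition_regions,
                                n_experiments = cfg$n_experiments,
                                x = 0.99, bf_threshold = 20,
                                rfx_mcmc = list(chains = 2, iter = 8000,
                                                burn_in = 2000),
                                resel_floor = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "null_sim_config"))
  if (missing(seed)) stop("run_fwer_experiment() requires an explicit seed")
  if (is.null(corpus)) {
    corpus <- simulate_null_corpus(cfg, seed = seed)
  }
  n_anat <- cfg$n_anat_regions
  anat <- voronoi_parcellation(cfg$lattice, n_anat,
                               seed = (as.numeric(seed) + 17) %% 2147483647)
  summ <- corpus_regional_summaries(corpus, anat)
  I_corpus <- nrow(summ$resels)

  exploratory <- identical(n_select, "all")
  sizes <- if (exploratory) n_anat else as.integer(n_select)

  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    N <- sizes[si]
    flagged <- logical(n_experiments)
    nonconv <- logical(n_experiments)
    bfs <- rep(NA_real_, n_experiments)
    for (l in seq_len(n_experiments)) {
      exp_seed <- (as.numeric(seed) + 7919 * l + 104729 * si) %% 2147483647
      set.seed(as.integer(exp_seed))
      group <- sample.int(I_corpus, cfg$group_size)
      repeat {
        if (exploratory) {
          d_i <- summ$counts[group, , drop = FALSE]
          r_i <- summ$resels[group, , drop = FALSE]
        } else {
          sel <- sample.int(n_anat, N)
          rest <- setdiff(seq_len(n_anat), sel)
          d_i <- cbind(summ$counts[group, sel, drop = FALSE],
                       rowSums(summ$counts[group, rest, drop = FALSE]))
          r_i <- cbind(summ$resels[group, sel, drop = FALSE],
                       rowSums(summ$resels[group, rest, drop = FALSE]))
        }
        if (all(colSums(r_i) >= resel_floor)) break
        message(sprintf("experiment %d: region below resel floor, re-drawn", l))
      }
      d_pool <- colSums(d_i)
      a_pool <- colSums(r_i) / sum(r_i)
      if (mode == "ffx") {
        lb <- log_evidence_alt(d_pool) - log_evidence_null(d_pool, a_pool)
        bfs[l] <- exp(lb)
        iv <- posterior_intervals(d_pool, a_pool, x = x)
        flagged[l] <- any(iv$flag != "null")
      } else {
        post <- rfx_sample(d_i,
                           prior = null_centred_prior(a_pool),
                           chains = rfx_mcmc$chains,
                           iter = rfx_mcmc$iter, burn_in = rfx_mcmc$burn_in,
                           seed = exp_seed)
        nonconv[l] <- !post$converged
        iv <- rfx_intervals(post, a = a_pool, x = x)
        flagged[l] <- any(iv$flag != "null")
      }
    }
    rows[[si]] <- tibble::tibble(
      mode = mode, N = N, L = n_experiments, group_size = cfg$group_size,
      n_flagged = sum(flagged), fwer = mean(flagged),
      max_bf = if (mode == "ffx") max(bfs) else NA_real_,
      n_bf_exceed = if (mode == "ffx") sum(bfs >= bf_threshold) else NA_integer_,
      bf_exceed_rate = if (mode == "ffx") mean(bfs >= bf_threshold) else NA_real_,
      n_nonconverged = if (mode == "rfx") sum(nonconv) else NA_integer_
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(out, seed = seed, x = x,
            class = c("fwer_report", class(out)))
}
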