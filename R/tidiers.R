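#' Tidy a fixed-effects pattern fit
#'
#' One row per region: pooled count, null relative volume, posterior mean,
#' the penalised credible interval and the `sparse`/`null`/`rich` flag.
#'
#' @param x an `ffx_fit`.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.ffx_fit <- function(x, ...) {
  if (is.null(x$intervals)) {
    return(tibble::tibble(region = x$pooled$region, name = x$pooled$name,
                          d = x$pooled$d, a = x$pooled$rel_volume))
  }
  dplyr::relocate(x$intervals, "name", .after = "region")
}

#' Model-level summary of a fixed-effects pattern fit
#'
#' @param x an `ffx_fit`.
#' @param ... unused.
#' @return one-row tibble with the log evidences, Bayes factor, posterior
#'   model probability, decision, counts and flag totals.
#' @export
glance.ffx_fit <- function(x, ...) {
  nf <- if (is.null(x$intervals)) 0L else sum(x$intervals$flag != "null")
  tibble::tibble(
    n_regions = x$n, k = x$k,
    log_evidence_null = x$logE0, log_evidence_alt = x$logE1,
    log_bf_10 = x$model$log_bf_10, bf_10 = x$model$bf_10,
    p_M1 = x$model$p_M1, accept_alt = x$model$accept_alt,
    x = x$x, n_flagged = nf
  )
}

#' Tidy a random-effects pattern fit
#'
#' One row per region: null relative volume, posterior mean of the
#' population parameter `m_j`, penalised interval and flag.
#'
#' @param x an `rfx_fit`.
#' @param ... unused.
#' @return tibble.
#' @export
tidy.rfx_fit <- function(x, ...) {
  iv <- x$intervals
  if (!is.null(iv$name)) iv <- dplyr::relocate(iv, "name", .after = "region")
  iv
}

#' Sampler-level summary of a random-effects pattern fit
#'
#' @param x an `rfx_fit`.
#' @param ... unused.
#' @return one-row tibble with dimensions, draw counts, acceptance,
#'   convergence and flag totals.
#' @export
glance.rfx_fit <- function(x, ...) {
  p <- x$posterior
  nf <- sum(x$intervals$flag != "null")
  lev <- x$x
  tibble::tibble(
    n_regions = x$n, n_subjects = x$I,
    chains = p$chains, draws = nrow(p$samples),
    mean_accept = mean(p$accept_rate),
    max_rhat = max(p$rhat, na.rm = TRUE), converged = p$converged,
    post_mean_c = mean(p$samples[, "c"]),
    x = lev, n_flagged = nf
  )
}
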