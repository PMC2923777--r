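neighbour_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(18, 26))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  off
}

# pad a 3D array with one layer of `fill`
pad1 <- function(x, fill) {
  dp <- dim(x) + 2L
  out <- array(fill, dim = dp)
  out[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1)] <- x
  out
}

# flood fill over a voxel subset: `member` is a logical vector over padded
# linear indices; returns an integer component id per TRUE entry
flood_components <- function(member, dp, offsets) {
  off_lin <- offsets[, 1] + offsets[, 2] * dp[1] + offsets[, 3] * dp[1] * dp[2]
  idx <- which(member)
  comp <- integer(length(member))
  cur <- 0L
  for (s in idx) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- as.vector(outer(frontier, off_lin, `+`))
      nb <- nb[member[nb] & comp[nb] == 0L]
      nb <- unique(nb)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Detect supra-threshold local maxima ("events") in a statistic map
#'
#' A voxel is a peak when it lies inside the mask, exceeds the height
#' threshold, and is strictly higher than every in-mask neighbour
#' (out-of-mask neighbours count as `-Inf`).  Exact-tie plateaus above the
#' threshold yield a single peak at the lexicographically smallest coordinate
#' (ordering on `(x, y, z)`), provided no plateau member touches a strictly
#' higher voxel.  With `one_per_excursion = TRUE` only the global maximum of
#' each supra-threshold connected component is kept — the "one event per
#' blob" convention useful at higher thresholds.
#'
#' @param spm 3D numeric array, the statistic map.
#' @param grid a [volume_grid()] whose mask defines the search volume.
#' @param threshold height threshold in statistic units (default 3).
#' @param connectivity neighbourhood definition, 18 or 26 (default 26).
#' @param one_per_excursion keep only the highest peak of each
#'   supra-threshold connected component (default `FALSE`).
#' @return An `event_set`: tibble with columns `x`, `y`, `z` (1-based voxel
#'   coordinates) and `height`, ordered lexicographically; the grid is
#'   attached as attribute `grid`.
#' @examples
#' g <- volume_grid(c(8, 8, 8))
#' f <- array(0, c(8, 8, 8)); f[4, 5, 2] <- 5
#' find_peaks(f, g)
#' @export
find_peaks <- function(spm, grid, threshold = 3, connectivity = 26,
                       one_per_excursion = FALSE) {
  stopifnot(is.array(spm), length(dim(spm)) == 3)
  check_same_grid(spm, grid, "spm")
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (any(!is.finite(spm[grid$mask]))) {
    stop("non-finite values inside the mask")
  }
  dm <- grid$dim
  A <- spm
  A[!grid$mask] <- -Inf
  Ap <- pad1(A, -Inf)
  dp <- dim(Ap)
  offsets <- neighbour_offsets(connectivity)

  core <- list(2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1))
  nbr_max <- array(-Inf, dim = dm)
  for (r in seq_len(nrow(offsets))) {
    sh <- Ap[core[[1]] + offsets[r, 1],
             core[[2]] + offsets[r, 2],
             core[[3]] + offsets[r, 3]]
    nbr_max <- pmax(nbr_max, sh)
  }
  above <- grid$mask & A > threshold
  strict <- above & A > nbr_max
  flat <- above & A == nbr_max   # candidate plateau members

  peak_lin <- which(strict)
  if (any(flat)) {
    # resolve equal-valued plateaus: a plateau is a peak only if none of its
    # members touches a strictly higher in-mask voxel
    memb <- pad1(flat, FALSE)
    comp <- flood_components_equal(as.vector(memb), as.vector(Ap), dp, offsets)
    # a flat member is "safe" if its highest neighbour equals its own value;
    # members adjacent to higher ground have A < nbr_max and are not in flat,
    # but an equal-valued neighbour of a flat voxel may itself be such a
    # voxel: then the component is invalidated inside the flood helper
    for (cid in unique(comp$id[comp$id > 0])) {
      mem <- comp$lin[comp$id == cid]
      if (comp$valid[cid]) {
        crd <- arrayInd(mem, dp) - 1L   # back to unpadded coordinates
        o <- order(crd[, 1], crd[, 2], crd[, 3])
        keep <- crd[o[1], , drop = FALSE]
        peak_lin <- c(peak_lin,
                      keep[1] + (keep[2] - 1L) * dm[1] +
                        (keep[3] - 1L) * dm[1] * dm[2])
      }
    }
  }

  crd <- arrayInd(peak_lin, dm)
  ev <- tibble::tibble(
    x = crd[, 1], y = crd[, 2], z = crd[, 3],
    height = A[peak_lin]
  )
  ev <- ev[order(ev$x, ev$y, ev$z), ]

  if (one_per_excursion && nrow(ev) > 0) {
    supra <- pad1(above, FALSE)
    comp <- flood_components(as.vector(supra), dp, offsets)
    lin_p <- (ev$x + 1L) + ev$y * dp[1] + ev$z * dp[1] * dp[2]
    cid <- comp[lin_p]
    keep <- unlist(lapply(split(seq_len(nrow(ev)), cid), function(ii) {
      hh <- ev$height[ii]
      ii[which.max(hh)]   # rows are already in lexicographic order
    }), use.names = FALSE)
    ev <- ev[sort(keep), ]
  }

  structure(ev, grid = grid, class = c("event_set", class(ev)))
}

# flood over equal-valued connected plateau members; invalidate a component
# when the plateau extends to a voxel that touches strictly higher ground
# (such voxels have equal value but are not members)
flood_components_equal <- function(member, vals, dp, offsets) {
  off_lin <- offsets[, 1] + offsets[, 2] * dp[1] + offsets[, 3] * dp[1] * dp[2]
  idx <- which(member)
  comp <- integer(length(member))
  valid <- logical(0)
  cur <- 0L
  for (s in idx) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    ok <- TRUE
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- unique(as.vector(outer(frontier, off_lin, `+`)))
      eq <- nb[is.finite(vals[nb]) & vals[nb] == vals[s]]
      if (any(!member[eq])) ok <- FALSE
      nxt <- eq[member[eq] & comp[eq] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
    valid[cur] <- ok
  }
  list(lin = which(comp > 0), id = comp[comp > 0], valid = valid)
}

#' Count events per region of a partition
#'
#' Tallies the peaks of an [find_peaks()] event set over the regions of a
#' [region_resels()]/[isotropic_rel_volume()] partition.  Peaks falling on
#' label 0 (outside the partition) are excluded with a warning reporting how
#' many were dropped; supply a partition with an explicit rest region if they
#' should be modelled.
#'
#' @param events an `event_set`.
#' @param partition a `region_partition` on the same grid.
#' @param subject_id optional identifier copied into the output.
#' @return An `event_counts` tibble with columns `region`, `name`, `d` (and
#'   `subject` if `subject_id` is given); the total count `k` is attached as
#'   attribute `k`.
#' @export
count_events <- function(events, partition, subject_id = NULL) {
  stopifnot(inherits(events, "event_set"),
            inherits(partition, "region_partition"))
  g <- attr(events, "grid")
  if (!all(g$dim == partition$grid$dim)) {
    stop("events and partition are on different grids")
  }
  n <- nrow(partition$table)
  if (nrow(events) > 0) {
    lin <- events$x + (events$y - 1L) * g$dim[1] +
      (events$z - 1L) * g$dim[1] * g$dim[2]
    lab <- as.vector(partition$labels)[lin]
    n_out <- sum(lab == 0L)
    if (n_out > 0) {
      warning(sprintf(
        "%d peak(s) fall outside the partition (label 0) and are excluded",
        n_out))
    }
    d <- tabulate(lab[lab > 0L], nbins = n)
  } else {
    d <- integer(n)
  }
  out <- tibble::tibble(
    region = partition$table$region,
    name = partition$table$name,
    d = as.integer(d)
  )
  if (!is.null(subject_id)) out$subject <- subject_id
  structure(out, k = sum(d), class = c("event_counts", class(out)))
}
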