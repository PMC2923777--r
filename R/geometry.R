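#' Estimate a resels-per-voxel (RPV) image from residual fields
#'
#' The statistical volume of a region is its resel count: physical volume
#' normalised by the local smoothness of the component noise fields.  The
#' estimator follows the conventional approach for statistic maps: residual
#' volumes are standardized to unit sum of squares at each voxel, spatial
#' derivatives are formed by forward differences along each axis (a voxel
#' contributes on an axis only when its +1 neighbour is inside the mask), the
#' 3x3 matrix `Lambda` of derivative covariances across volumes is assembled
#' per voxel, and
#' \deqn{rpv = (4 \log 2)^{-3/2} |\Lambda|^{1/2}.}
#' Summing the RPV image over a region gives the region's resel count, which
#' under the null is proportional to the expected number of high local maxima
#' it emits.
#'
#' Voxels where `Lambda` cannot be assembled on all three axes (mask boundary,
#' or an all-zero residual vector) are imputed with the mean RPV of the
#' computable in-mask voxels, so regional sums are not biased by holes.
#'
#' @param residuals 4D numeric array (x, y, z, volume) of residual fields, or
#'   a list of 3D arrays on one grid.  At least 4 volumes are required.
#' @param grid a [volume_grid()]; its mask defines the analysis volume.
#' @param df residual degrees of freedom (positive integer); recorded in the
#'   result for reporting.
#' @return An object of class `rpv_image`: list with `grid`, `rpv` (3D array,
#'   zero outside the mask), `df`, and `n_imputed`.
#' @examples
#' set.seed(1)
#' g <- volume_grid(c(12, 12, 12))
#' res <- array(rnorm(12^3 * 8), c(12, 12, 12, 8))
#' rpv <- estimate_rpv(res, g, df = 7)
#' sum(rpv$rpv) # total resels: close to the voxel count for white noise
#' @export
estimate_rpv <- function(residuals, grid, df) {
  if (is.list(residuals)) {
    residuals <- array(unlist(residuals, use.names = FALSE),
                       dim = c(dim(residuals[[1]]), length(residuals)))
  }
  stopifnot(is.array(residuals), length(dim(residuals)) == 4)
  d4 <- dim(residuals)
  if (d4[4] < 4) stop("estimate_rpv() needs at least 4 residual volumes")
  if (!(is.numeric(df) && length(df) == 1 && df >= 1)) {
    stop("df must be a positive integer")
  }
  check_same_grid(array(0, d4[1:3]), grid, "residual series")
  dm <- grid$dim
  V <- prod(dm)
  T <- d4[4]
  r <- matrix(residuals, nrow = V, ncol = T)
  mask <- as.vector(grid$mask)

  ss <- rowSums(r^2)
  ok_vox <- mask & ss > 0
  r[ok_vox, ] <- r[ok_vox, , drop = FALSE] / sqrt(ss[ok_vox])

  # linear-index strides for the +1 neighbour on each axis
  strides <- c(1L, dm[1], dm[1] * dm[2])
  coord <- arrayInd(seq_len(V), dm)
  diffs <- vector("list", 3)
  valid <- matrix(FALSE, V, 3)
  for (a in 1:3) {
    has_nbr <- coord[, a] < dm[a]
    nbr <- seq_len(V) + strides[a]
    ok <- has_nbr & ok_vox
    ok[ok] <- ok_vox[nbr[ok]]
    D <- matrix(0, V, T)
    D[ok, ] <- r[nbr[ok], , drop = FALSE] - r[ok, , drop = FALSE]
    diffs[[a]] <- D
    valid[, a] <- ok
  }
  computable <- mask & valid[, 1] & valid[, 2] & valid[, 3]

  # Lambda entries: sums of products of derivatives across volumes
  l11 <- rowSums(diffs[[1]]^2)
  l22 <- rowSums(diffs[[2]]^2)
  l33 <- rowSums(diffs[[3]]^2)
  l12 <- rowSums(diffs[[1]] * diffs[[2]])
  l13 <- rowSums(diffs[[1]] * diffs[[3]])
  l23 <- rowSums(diffs[[2]] * diffs[[3]])
  det3 <- l11 * (l22 * l33 - l23^2) -
    l12 * (l12 * l33 - l23 * l13) +
    l13 * (l12 * l23 - l22 * l13)
  det3[det3 < 0] <- 0

  rpv <- numeric(V)
  rpv[computable] <- (4 * log(2))^(-3 / 2) * sqrt(det3[computable])
  n_imputed <- sum(mask & !computable)
  if (n_imputed > 0) {
    if (!any(computable)) stop("no voxel has a computable Lambda")
    rpv[mask & !computable] <- mean(rpv[computable])
  }

  structure(
    list(grid = grid, rpv = array(rpv, dim = dm), df = df,
         n_imputed = n_imputed),
    class = "rpv_image"
  )
}

#' @export
print.rpv_image <- function(x, ...) {
  cat("<rpv_image> total resels ", signif(sum(x$rpv), 6), " over ",
      sum(x$grid$mask), " voxels (", x$n_imputed, " imputed), df = ",
      x$df, "\n", sep = "")
  invisible(x)
}

new_region_partition <- function(grid, labels, table) {
  structure(list(grid = grid, labels = labels, table = table),
            class = "region_partition")
}

#' Regional resel counts over a labelled parcellation
#'
#' Sums the RPV image over each region of an integer label volume, giving the
#' regional statistical volumes `|A_j|` and the relative volumes
#' `a_j = |A_j| / sum |A_j|` that define the null multinomial pattern.
#'
#' @param rpv an `rpv_image` from [estimate_rpv()].
#' @param labels integer 3D array aligned with `rpv`'s grid; 0 = outside the
#'   partition, 1..n = regions.
#' @param names optional character vector of region names (label order).
#' @param floor minimum admissible resel count per region; a region below it
#'   makes the null pattern degenerate (`a_j = 0`) and raises an error asking
#'   for that region to be merged or excluded.
#' @return A `region_partition`: the grid, the label volume, and a tibble
#'   `table` with columns `region`, `name`, `n_voxels`, `resels`,
#'   `rel_volume`.
#' @seealso [isotropic_rel_volume()] for the stationary shortcut.
#' @export
region_resels <- function(rpv, labels, names = NULL, floor = 1e-6) {
  stopifnot(inherits(rpv, "rpv_image"))
  check_same_grid(labels, rpv$grid, "label volume")
  lab <- as.integer(labels)
  n <- max(lab, 0L)
  if (n < 1) stop("label volume contains no regions")
  in_part <- lab > 0L
  resels <- as.vector(tapply(as.vector(rpv$rpv)[in_part],
                             factor(lab[in_part], levels = seq_len(n)), sum))
  resels[is.na(resels)] <- 0
  nvox <- tabulate(lab[in_part], nbins = n)
  if (any(resels < floor)) {
    bad <- which(resels < floor)
    stop(sprintf(paste0(
      "region(s) %s have resel counts below %g; the null pattern is ",
      "degenerate there - merge them with a neighbour or exclude them"),
      paste(bad, collapse = ", "), floor))
  }
  tbl <- tibble::tibble(
    region = seq_len(n),
    name = if (is.null(names)) sprintf("region_%02d", seq_len(n)) else names,
    n_voxels = nvox,
    resels = resels,
    rel_volume = resels / sum(resels)
  )
  if (length(tbl$name) != n) stop("names must have one entry per region")
  new_region_partition(rpv$grid, array(lab, dim = rpv$grid$dim), tbl)
}

#' Relative statistical volumes under isotropy
#'
#' For an isotropic, stationary statistic field the resel count of a region is
#' proportional to its physical volume, so relative volumes can be read off
#' the voxel counts without estimating smoothness.  The `resels` column then
#' holds voxel counts (an arbitrary common scale; only `rel_volume` enters the
#' inference).
#'
#' @param labels integer 3D array (0 = outside the partition).
#' @param grid optional [volume_grid()]; defaults to a unit grid of the label
#'   dimensions.
#' @inheritParams region_resels
#' @return A `region_partition`.
#' @export
isotropic_rel_volume <- function(labels, grid = NULL, names = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (is.null(grid)) grid <- volume_grid(dim(labels))
  check_same_grid(labels, grid, "label volume")
  lab <- as.integer(labels)
  n <- max(lab, 0L)
  if (n < 1) stop("label volume contains no regions")
  nvox <- tabulate(lab[lab > 0L], nbins = n)
  if (any(nvox == 0)) {
    stop(sprintf("region(s) %s are empty",
                 paste(which(nvox == 0), collapse = ", ")))
  }
  tbl <- tibble::tibble(
    region = seq_len(n),
    name = if (is.null(names)) sprintf("region_%02d", seq_len(n)) else names,
    n_voxels = nvox,
    resels = as.numeric(nvox),
    rel_volume = nvox / sum(nvox)
  )
  new_region_partition(grid, array(lab, dim = grid$dim), tbl)
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> ", nrow(x$table), " regions, ",
      signif(sum(x$table$resels), 6), " total resels\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @export
as_tibble.region_partition <- function(x, ...) x$table

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
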