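#' Read a NIfTI volume together with its grid
#'
#' @param path path to a NIfTI-1 file (3D, or 4D where a series is
#'   expected).
#' @param mask optional 3D binary array or `volume_grid` supplying the
#'   analysis mask.
#' @return list with `data` (3D or 4D array) and `grid` (a [volume_grid()]
#'   built from the header's voxel sizes and affine).
#' @export
read_volume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (!length(dm) %in% c(3, 4)) {
    stop(sprintf("%s: expected a 3D or 4D NIfTI volume, got %dD",
                 path, length(dm)))
  }
  vx <- RNifti::pixdim(img)[1:3]
  aff <- structure(RNifti::xform(img), class = NULL)
  m <- if (inherits(mask, "volume_grid")) mask$mask else mask
  grid <- volume_grid(dm[1:3], voxel_size = vx,
                      affine = matrix(aff, 4, 4), mask = m)
  list(data = array(as.numeric(img), dim = dm), grid = grid)
}

#' Write a 3D/4D array as NIfTI, carrying a grid's geometry
#'
#' @param data numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid a [volume_grid()] providing voxel sizes; defaults to unit
#'   voxels.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, grid = NULL) {
  pd <- if (is.null(grid)) c(1, 1, 1) else grid$voxel_size
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a mask volume, insisting it is binary
#'
#' @inheritParams read_volume
#' @return a [volume_grid()] whose mask is the volume.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1))) {
    stop(sprintf("%s: mask must contain only 0/1 values", path))
  }
  volume_grid(v$grid$dim, v$grid$voxel_size, v$grid$affine,
              mask = array(v$data == 1, dim = v$grid$dim))
}

#' Read a regional counts table
#'
#' Expects a TSV with a header and columns `region` (unique names), `resels`
#' (positive), and one or more integer count columns (one per subject).
#' Malformed cells are reported with their row number.
#'
#' @param path path to the TSV file.
#' @return long tibble with columns `subject`, `region` (integer index in
#'   file order), `name`, `d`, `resels` — the format the inference
#'   functions consume.
#' @export
read_counts_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("region", "resels") %in% names(tab))) {
    stop(sprintf("%s: need columns 'region' and 'resels'", path))
  }
  cnt_cols <- setdiff(names(tab), c("region", "resels"))
  if (length(cnt_cols) == 0) stop(sprintf("%s: no count columns", path))
  if (anyDuplicated(tab$region)) {
    stop(sprintf("%s: duplicate region name at row %d", path,
                 which(duplicated(tab$region))[1]))
  }
  bad <- which(!is.finite(tab$resels) | tab$resels <= 0)
  if (length(bad)) {
    stop(sprintf("%s: missing or non-positive resels at row %d", path, bad[1]))
  }
  for (cc in cnt_cols) {
    v <- tab[[cc]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("%s: column '%s' row %d is not a non-negative integer",
                   path, cc, bad[1]))
    }
  }
  long <- tidyr::pivot_longer(tab, dplyr::all_of(cnt_cols),
                              names_to = "subject", values_to = "d")
  tibble::tibble(
    subject = long$subject,
    region = match(long$region, tab$region),
    name = as.character(long$region),
    d = as.integer(long$d),
    resels = long$resels
  )
}

#' Write a region table for a partition
#'
#' TSV with columns `region, n_voxels, resels, rel_volume`.
#'
#' @param partition a `region_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(partition, path) {
  stopifnot(inherits(partition, "region_partition"))
  tbl <- partition$table
  readr::write_tsv(
    tibble::tibble(region = tbl$name, n_voxels = tbl$n_voxels,
                   resels = tbl$resels, rel_volume = tbl$rel_volume),
    path
  )
  invisible(path)
}

# md5 checksums of input files, for embedding in JSON reports
input_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(NULL)
  as.list(tools::md5sum(paths))
}

#' Write an inference report as JSON
#'
#' Serialises a fitted `ffx_fit` or `rfx_fit` (evidences, Bayes factor,
#' intervals, flags, convergence diagnostics) together with md5 checksums of
#' the input files it was computed from.
#'
#' @param fit an `ffx_fit` or `rfx_fit`.
#' @param path output path.
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(fit, path, inputs = character()) {
  rep <- if (inherits(fit, "ffx_fit")) {
    list(model = "ffx", glance = as.list(glance(fit)), intervals = tidy(fit))
  } else if (inherits(fit, "rfx_fit")) {
    list(model = "rfx", glance = as.list(glance(fit)), intervals = tidy(fit),
         rhat = as.list(fit$posterior$rhat))
  } else {
    stop("fit must be an ffx_fit or rfx_fit")
  }
  rep$inputs <- input_checksums(inputs)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
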