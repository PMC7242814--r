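#' Write and read event tables
#'
#' Events are exchanged as tab-separated tables (a BIDS-events-like dialect):
#' one row per trial, with at minimum `onset`, `duration`, `trial_type`,
#' `category`, `session`, plus any behavioral response columns present.
#'
#' @param events Event data frame.
#' @param path Output path (`.tsv`).
#' @return `write_events_tsv()`: the path, invisibly. `read_events_tsv()`:
#'   the event data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
}

#' Write a beta matrix as delimited text with a metadata sidecar
#'
#' The trials x voxels values go to `<stem>_betas.tsv` and the per-trial
#' metadata to `<stem>_meta.tsv`.
#'
#' @param betas A [beta_matrix()].
#' @param stem Path stem (no extension).
#' @return Character vector of the two paths, invisibly.
#' @export
write_beta_matrix <- function(betas, stem) {
  stopifnot(inherits(betas, "beta_matrix"))
  vp <- paste0(stem, "_betas.tsv")
  mp <- paste0(stem, "_meta.tsv")
  utils::write.table(betas$values, vp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(betas$meta, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values = vp, meta = mp))
}

#' Read a beta matrix written by [write_beta_matrix()]
#'
#' @param stem Path stem used when writing.
#' @param roi List or [roi_spec()] with `name` and `preferred`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(stem, roi) {
  vals <- as.matrix(utils::read.delim(paste0(stem, "_betas.tsv"),
                                      header = FALSE))
  meta <- utils::read.delim(paste0(stem, "_meta.tsv"),
                            stringsAsFactors = FALSE)
  dimnames(vals) <- list(meta$trial_id, NULL)
  beta_matrix(vals, meta, roi)
}

#' Export a beta matrix as NIfTI volumes
#'
#' Writes one 3-D volume per trial (voxels laid out along the first axis) and
#' a companion ROI mask volume. Requires the RNifti package.
#'
#' @param betas A [beta_matrix()].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_betas_nifti <- function(betas, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export", call. = FALSE)
  }
  stopifnot(inherits(betas, "beta_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nv <- ncol(betas$values)
  paths <- character(0)
  for (t in seq_len(nrow(betas$values))) {
    vol <- array(betas$values[t, ], dim = c(nv, 1, 1))
    p <- file.path(dir, sprintf("%s_trial%03d.nii.gz", betas$roi$name, t))
    RNifti::writeNifti(vol, p)
    paths <- c(paths, p)
  }
  mask <- array(1, dim = c(nv, 1, 1))
  mp <- file.path(dir, sprintf("%s_mask.nii.gz", betas$roi$name))
  RNifti::writeNifti(mask, mp)
  invisible(c(paths, mp))
}
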