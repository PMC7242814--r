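#' Trial-by-voxel response matrix for one ROI
#'
#' The substrate of both selectivity metrics: a trials x voxels matrix of
#' single-trial response amplitudes (beta units) together with per-trial
#' metadata (image category, scanning session, subsequent-memory status) and a
#' reference to the ROI it was extracted from.
#'
#' @param values Numeric trials x voxels matrix.
#' @param meta Data frame with one row per trial; must contain `category`
#'   (`"face"`/`"scene"`) and `session`; `memory_status`
#'   (`"source_correct"`/`"other"`) is optional.
#' @param roi List or [roi_spec()] with at least `name` and `preferred`.
#'
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, meta, roi) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) == nrow(meta),
            all(c("category", "session") %in% names(meta)),
            !is.null(roi$name), roi$preferred %in% c("face", "scene"))
  structure(list(values = values, meta = as.data.frame(meta), roi = roi),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf(
    "<beta_matrix> ROI %s (preferred: %s): %d trials x %d voxels\n",
    x$roi$name, x$roi$preferred, nrow(x$values), ncol(x$values)
  ))
  print(table(category = x$meta$category, session = x$meta$session))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' Subset a beta matrix by subsequent-memory status
#'
#' Restricts a [beta_matrix()] to trials with the given subsequent-memory
#' outcome (by default those later attracting a correct source judgment),
#' preserving all metadata.
#'
#' @param betas A [beta_matrix()] whose metadata includes `memory_status`.
#' @param status Memory status to keep (`"source_correct"` or `"other"`).
#' @return A [beta_matrix()] containing only the matching trials.
#' @export
condition_on_memory <- function(betas, status = "source_correct") {
  stopifnot(inherits(betas, "beta_matrix"))
  if (is.null(betas$meta$memory_status)) {
    stop("beta matrix carries no memory_status metadata", call. = FALSE)
  }
  keep <- which(betas$meta$memory_status == status)
  if (length(keep) == 0L) {
    stop(sprintf("no trials with memory status '%s'", status), call. = FALSE)
  }
  beta_matrix(betas$values[keep, , drop = FALSE],
              betas$meta[keep, , drop = FALSE], betas$roi)
}
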