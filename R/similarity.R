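#' Cross-session within- minus between-category pattern similarity
#'
#' For every unordered pair of trials from *different* scanning sessions
#' (same-session pairs are excluded to avoid carry-over bias), computes the
#' Pearson correlation of the two voxel patterns, Fisher-z transforms it
#' (`atanh`), and averages: `within_z` over same-category pairs, `between_z`
#' over cross-category pairs. The similarity index is
#' `within_z - between_z`; like the differentiation index it is insensitive
#' to per-trial additive shifts and positive rescaling (hemodynamic gain).
#'
#' @param betas A [beta_matrix()] with at least 2 voxels and trials in at
#'   least 2 sessions.
#' @param within_scope `"both_categories"` (default): same-category pairs of
#'   either category contribute to `within_z`. `"preferred_only"`: only pairs
#'   of the ROI's preferred category.
#' @param condition Label recorded in the output (`"all_trials"` by default).
#' @return One-row data frame: `roi`, `condition`, `within_scope`,
#'   `within_z`, `between_z`, `index`, `n_within_pairs`, `n_between_pairs`.
#' @export
within_between_similarity <- function(betas,
                                      within_scope = c("both_categories",
                                                       "preferred_only"),
                                      condition = "all_trials") {
  stopifnot(inherits(betas, "beta_matrix"))
  within_scope <- match.arg(within_scope)
  V <- betas$values
  if (ncol(V) < 2L) stop("need at least 2 voxels", call. = FALSE)
  sds <- apply(V, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance pattern in trial(s) %s",
                 paste(rownames(V)[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  sess <- betas$meta$session
  if (length(unique(sess)) < 2L) {
    stop(errorCondition(
      "all trials fall in a single session; no cross-session pairs",
      class = c("dediffr_no_cross_session_pairs", "error", "condition")
    ))
  }
  R <- stats::cor(t(V))
  n <- nrow(V)
  pair <- which(upper.tri(R), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  cross_sess <- sess[i] != sess[j]
  i <- i[cross_sess]; j <- j[cross_sess]
  r <- R[cbind(i, j)]
  if (any(abs(r) >= 1 - 1e-12)) {
    stop("a trial pair is perfectly correlated (infinite Fisher z); inject noise",
         call. = FALSE)
  }
  cat_i <- betas$meta$category[i]
  cat_j <- betas$meta$category[j]
  same <- cat_i == cat_j
  within_sel <- if (within_scope == "preferred_only") {
    same & cat_i == betas$roi$preferred
  } else {
    same
  }
  between_sel <- !same
  if (!any(within_sel) || !any(between_sel)) {
    stop(errorCondition(
      "no cross-session within- or between-category pairs available",
      class = c("dediffr_no_cross_session_pairs", "error", "condition")
    ))
  }
  z <- atanh(r)
  within_z <- mean(z[within_sel])
  between_z <- mean(z[between_sel])
  data.frame(
    roi = betas$roi$name, condition = condition, within_scope = within_scope,
    within_z = within_z, between_z = between_z,
    index = within_z - between_z,
    n_within_pairs = sum(within_sel), n_between_pairs = sum(between_sel),
    stringsAsFactors = FALSE
  )
}

#' Memory-conditioned pattern similarity
#'
#' Restricts the similarity computation to trials with the given
#' subsequent-memory status (source-correct by default) before applying
#' [within_between_similarity()].
#'
#' @param betas A [beta_matrix()] with `memory_status` metadata.
#' @param status Memory status to keep.
#' @param within_scope Passed to [within_between_similarity()].
#' @return One-row data frame as in [within_between_similarity()], with
#'   `condition` set to the status label.
#' @export
memory_conditioned_similarity <- function(betas, status = "source_correct",
                                          within_scope = c("both_categories",
                                                           "preferred_only")) {
  within_scope <- match.arg(within_scope)
  sub <- condition_on_memory(betas, status)
  within_between_similarity(sub, within_scope,
                            condition = paste0(status, "_only"))
}
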