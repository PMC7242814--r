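#' Mean beta per image category
#'
#' The beta parameters averaged across all voxels within the ROI and then
#' across trials of each category — the quantities underlying the
#' attenuation-versus-broadening decomposition of dedifferentiation (a
#' reduced preferred-category mean indicates attenuation, an elevated
#' non-preferred mean indicates broadening).
#'
#' @param betas A [beta_matrix()].
#' @return Named numeric `c(face=, scene=)`; `NA` for an empty category.
#' @export
mean_category_betas <- function(betas) {
  stopifnot(inherits(betas, "beta_matrix"))
  resp <- rowMeans(betas$values)
  vapply(c(face = "face", scene = "scene"), function(cat_lab) {
    idx <- betas$meta$category == cat_lab
    if (!any(idx)) NA_real_ else mean(resp[idx])
  }, numeric(1))
}

#' Univariate differentiation index
#'
#' Regional category selectivity as the standardized difference between mean
#' responses to the ROI's preferred and non-preferred categories:
#'
#'   `DI = (mu_pref - mu_nonpref) / sqrt((sd_pref^2 + sd_nonpref^2) / 2)`,
#'
#' where, for each category, mu and sd are the mean and sample SD across
#' trials of the per-trial ROI response. Because of the pooled-SD scaling the
#' index is insensitive to additive shifts and to positive rescaling of all
#' betas (differences in hemodynamic gain). A higher index indicates greater
#' selectivity.
#'
#' @param betas A [beta_matrix()].
#' @param condition `"all_trials"` or `"source_correct_only"` (restricts to
#'   trials that later attracted a correct source judgment).
#' @param estimator `"roi_mean"` (default): per-trial responses are the means
#'   of the beta values across the ROI's voxels. `"voxel_pooled"`: trial x
#'   voxel values are pooled as individual observations.
#' @return One-row data frame: `roi`, `condition`, `di`, `mu_pref`,
#'   `mu_nonpref`, `sd_pref`, `sd_nonpref`, `n_pref`, `n_nonpref`.
#' @export
differentiation_index <- function(betas,
                                  condition = c("all_trials",
                                                "source_correct_only"),
                                  estimator = c("roi_mean", "voxel_pooled")) {
  stopifnot(inherits(betas, "beta_matrix"))
  condition <- match.arg(condition)
  estimator <- match.arg(estimator)
  if (condition == "source_correct_only") {
    betas <- condition_on_memory(betas, "source_correct")
  }
  pref <- betas$roi$preferred
  nonpref <- setdiff(c("face", "scene"), pref)
  if (estimator == "roi_mean") {
    resp <- rowMeans(betas$values)
    x_pref <- resp[betas$meta$category == pref]
    x_non <- resp[betas$meta$category == nonpref]
  } else {
    x_pref <- as.vector(betas$values[betas$meta$category == pref, ,
                                     drop = FALSE])
    x_non <- as.vector(betas$values[betas$meta$category == nonpref, ,
                                    drop = FALSE])
  }
  n_pref <- sum(betas$meta$category == pref)
  n_non <- sum(betas$meta$category == nonpref)
  if (n_pref < 2L || n_non < 2L) {
    few <- if (n_pref < 2L) pref else nonpref
    stop(sprintf("fewer than 2 '%s' trials in ROI %s under condition %s",
                 few, betas$roi$name, condition), call. = FALSE)
  }
  mu_p <- mean(x_pref); mu_n <- mean(x_non)
  sd_p <- stats::sd(x_pref); sd_n <- stats::sd(x_non)
  pooled <- sqrt((sd_p^2 + sd_n^2) / 2)
  if (pooled == 0) {
    stop("pooled SD is zero; differentiation index undefined", call. = FALSE)
  }
  data.frame(
    roi = betas$roi$name, condition = condition,
    di = (mu_p - mu_n) / pooled,
    mu_pref = mu_p, mu_nonpref = mu_n,
    sd_pref = sd_p, sd_nonpref = sd_n,
    n_pref = n_pref, n_nonpref = n_non,
    stringsAsFactors = FALSE
  )
}
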