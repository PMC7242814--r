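#' Canonical double-gamma hemodynamic response function
#'
#' The SPM-convention canonical HRF: a double-gamma kernel (response gamma
#' with delay 6 s and dispersion 1 s; undershoot gamma with delay 16 s and
#' dispersion 1 s, weighted 1/6), sampled over 32 s and scaled to unit peak.
#'
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @param duration_s Kernel length in seconds (default 32).
#' @return Numeric vector of kernel values at `seq(0, duration_s, by = tr_s)`.
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  stopifnot(tr_s > 0, duration_s > 0)
  t <- seq(0, duration_s, by = tr_s)
  h <- hrf_shape(t)
  h / max(hrf_shape(seq(0, duration_s, by = 0.01)))
}

hrf_shape <- function(t) {
  stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
}

# Continuous-time convolution of a unit boxcar with the peak-normalized HRF,
# evaluated on a fine grid and sampled at scan times.
convolve_boxcar <- function(onset, duration, n_scans, tr_s, dt) {
  grid_n <- ceiling(n_scans * tr_s / dt) + 1L
  u <- numeric(grid_n)
  tt <- (seq_len(grid_n) - 1L) * dt
  u[tt >= onset & tt < onset + duration] <- 1
  h <- hrf_shape(seq(0, 32, by = dt))
  h <- h / max(h)
  p <- length(h)
  conv <- numeric(grid_n)
  for (i in which(u > 0)) {
    j <- i:min(grid_n, i + p - 1L)
    conv[j] <- conv[j] + h[seq_along(j)] * dt
  }
  scan_t <- (seq_len(n_scans) - 1L) * tr_s
  conv[round(scan_t / dt) + 1L]
}

#' Build a least-squares-all single-trial design matrix
#'
#' Constructs the concatenated-session design matrix for least-squares-all
#' estimation: every modeled trial receives its own regressor (a boxcar of the
#' trial's duration convolved with the canonical HRF), plus nuisance columns
#' for the six motion parameters (when supplied), one session-specific mean
#' per session, and an optional rest-block regressor. Trial regressors are
#' identically zero outside their own session's scan range.
#'
#' @param events Data frame of trials to model, with columns `session`,
#'   `onset` (s, session-local), `duration` (s), and optionally `trial_id`
#'   (generated when absent).
#' @param n_scans_per_session Integer vector of scan counts, one per session
#'   (in ascending session order).
#' @param tr_s Repetition time in seconds.
#' @param motion Optional scans x 6 numeric matrix/data frame (rows =
#'   concatenated scans) of motion parameters.
#' @param rest_blocks Optional list of global scan-index vectors covered by
#'   rest periods; modeled as a single box regressor.
#' @param microtime Oversampling factor of the convolution grid relative to
#'   the TR (default 16).
#'
#' @return An object of class `glm_design`: list with `matrix` (scans x
#'   regressors), `labels`, `trial_columns` (named map trial id -> column),
#'   `session_blocks` (list of global row ranges per session), and `tr_s`.
#' @export
build_lsa_design <- function(events, n_scans_per_session, tr_s = 2,
                             motion = NULL, rest_blocks = NULL,
                             microtime = 16L) {
  stopifnot(tr_s > 0, all(n_scans_per_session >= 1))
  ev <- as.data.frame(events)
  stopifnot(all(c("session", "onset", "duration") %in% names(ev)))
  sessions <- sort(unique(ev$session))
  if (length(n_scans_per_session) != length(sessions)) {
    stop("need one scan count per session", call. = FALSE)
  }
  if (is.null(ev$trial_id)) {
    ev$trial_id <- sprintf("trial%03d", seq_len(nrow(ev)))
  }
  if (anyDuplicated(ev$trial_id)) {
    stop("trial ids must be unique", call. = FALSE)
  }
  dt <- tr_s / microtime
  n_total <- sum(n_scans_per_session)
  offsets <- c(0L, cumsum(n_scans_per_session))
  session_blocks <- lapply(seq_along(sessions), function(i) {
    offsets[i] + seq_len(n_scans_per_session[i])
  })
  names(session_blocks) <- paste0("session", sessions)

  X_trials <- matrix(0, n_total, nrow(ev))
  for (j in seq_len(nrow(ev))) {
    si <- match(ev$session[j], sessions)
    ns <- n_scans_per_session[si]
    if (ev$onset[j] + ev$duration[j] > ns * tr_s || ev$onset[j] < 0) {
      stop(sprintf("trial %s (onset %.1f s) falls outside session %s",
                   ev$trial_id[j], ev$onset[j], ev$session[j]), call. = FALSE)
    }
    X_trials[session_blocks[[si]], j] <-
      convolve_boxcar(ev$onset[j], ev$duration[j], ns, tr_s, dt)
  }
  colnames(X_trials) <- ev$trial_id

  nuisance <- NULL
  labels_n <- character(0)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_total || ncol(motion) != 6L) {
      stop("motion must be a (total scans) x 6 table", call. = FALSE)
    }
    nuisance <- cbind(nuisance, motion)
    labels_n <- c(labels_n, paste0("motion", 1:6))
  }
  if (!is.null(rest_blocks)) {
    r <- numeric(n_total)
    r[unlist(rest_blocks)] <- 1
    nuisance <- cbind(nuisance, r)
    labels_n <- c(labels_n, "rest")
  }
  sess_means <- matrix(0, n_total, length(sessions))
  for (i in seq_along(sessions)) sess_means[session_blocks[[i]], i] <- 1
  nuisance <- cbind(nuisance, sess_means)
  labels_n <- c(labels_n, paste0("session_mean", sessions))

  X <- cbind(X_trials, nuisance)
  labels <- c(ev$trial_id, labels_n)
  colnames(X) <- labels
  structure(list(
    matrix = X, labels = labels,
    trial_columns = stats::setNames(seq_len(nrow(ev)), ev$trial_id),
    session_blocks = session_blocks, tr_s = tr_s
  ), class = "glm_design")
}

#' Estimate single-trial betas by ordinary least squares
#'
#' Fits the least-squares-all model to a concatenated time-series matrix and
#' returns the trial regressors' coefficient estimates; nuisance coefficients
#' are discarded.
#'
#' @param series Scans x voxels numeric matrix (sessions concatenated in the
#'   design's scan order).
#' @param design A `glm_design` from [build_lsa_design()].
#' @param max_condition Condition-number threshold above which the design is
#'   treated as rank-deficient.
#' @return Trials x voxels matrix of beta estimates, row names = trial ids.
#' @export
fit_lsa <- function(series, design, max_condition = 1e8) {
  stopifnot(inherits(design, "glm_design"))
  series <- as.matrix(series)
  X <- design$matrix
  if (nrow(series) != nrow(X)) {
    stop("series rows must match design scans", call. = FALSE)
  }
  cn <- kappa(X, exact = FALSE)
  if (!is.finite(cn) || cn > max_condition) {
    stop(paste(
      "design is ill-conditioned (condition number", format(cn, digits = 3),
      "); space events further apart or reduce the number of regressors"
    ), call. = FALSE)
  }
  fit <- stats::lm.fit(X, series)
  B <- as.matrix(fit$coefficients)
  tb <- B[design$trial_columns, , drop = FALSE]
  rownames(tb) <- names(design$trial_columns)
  tb
}

#' Flag trials contaminated by head motion
#'
#' A trial is flagged when any scan overlapping its modeled window exceeds the
#' translation threshold (in mm, columns 1-3 of `motion`) or the rotation
#' threshold (in degrees, columns 4-6) on any axis, with strict inequality.
#' The modeled window runs from stimulus onset to onset + duration +
#' `window_extra_s` (default: the canonical-HRF peak lag), a conservative
#' covering of the scans that carry the trial's response.
#'
#' @param motion Scans x 6 matrix of motion parameters (concatenated
#'   sessions).
#' @param events Trial table with `session`, `onset`, `duration`.
#' @param n_scans_per_session Scan counts per session.
#' @param tr_s Repetition time (s).
#' @param trans_mm Translation threshold (default 1.0 mm, strict `>`).
#' @param rot_deg Rotation threshold (default 1.0 degree, strict `>`).
#' @param window_extra_s Seconds added after stimulus offset (default: HRF
#'   peak lag).
#' @return Logical vector, one element per event row; `TRUE` = flagged for
#'   exclusion.
#' @export
flag_high_motion_trials <- function(motion, events, n_scans_per_session,
                                    tr_s = 2, trans_mm = 1.0, rot_deg = 1.0,
                                    window_extra_s = NULL) {
  motion <- as.matrix(motion)
  ev <- as.data.frame(events)
  n_total <- sum(n_scans_per_session)
  if (nrow(motion) != n_total || ncol(motion) != 6L) {
    stop("motion must have one row per scan and 6 columns", call. = FALSE)
  }
  if (is.null(window_extra_s)) {
    fine <- seq(0, 32, by = 0.01)
    window_extra_s <- fine[which.max(hrf_shape(fine))]
  }
  sessions <- sort(unique(ev$session))
  offsets <- c(0L, cumsum(n_scans_per_session))
  bad_scan <- apply(abs(motion[, 1:3, drop = FALSE]) > trans_mm, 1, any) |
    apply(abs(motion[, 4:6, drop = FALSE]) > rot_deg, 1, any)
  flagged <- logical(nrow(ev))
  for (j in seq_len(nrow(ev))) {
    si <- match(ev$session[j], sessions)
    ns <- n_scans_per_session[si]
    t0 <- ev$onset[j]
    t1 <- ev$onset[j] + ev$duration[j] + window_extra_s
    k <- seq_len(ns)
    overlap <- ((k - 1) * tr_s < t1) & (k * tr_s > t0)
    rows <- offsets[si] + k[overlap]
    flagged[j] <- any(bad_scan[rows])
  }
  flagged
}

#' ROI specification
#'
#' @param name ROI label.
#' @param preferred Preferred category (`"face"` or `"scene"`).
#' @param voxel_ids Vector of voxel identifiers (non-empty, duplicate-free).
#' @param source Free-text provenance note.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, preferred, voxel_ids, source = "") {
  if (length(voxel_ids) == 0L) {
    stop(errorCondition(sprintf("ROI '%s' is empty", name),
                        class = c("dediffr_empty_roi", "error", "condition")))
  }
  if (anyDuplicated(voxel_ids)) {
    stop("voxel ids must be duplicate-free", call. = FALSE)
  }
  structure(list(name = name,
                 preferred = match.arg(preferred, c("face", "scene")),
                 voxel_ids = voxel_ids, source = source),
            class = "roi_spec")
}

#' Define an ROI from a thresholded category contrast
#'
#' Selects voxels whose second-level category-contrast statistic is
#' suprathreshold (uncorrected p < `alpha`, one-tailed in the stated
#' direction) and intersects them with an anatomical mask, mirroring the
#' definition of category-selective ROIs from a faces-versus-scenes contrast
#' inclusively masked with an atlas label set.
#'
#' @param stat Named numeric vector of per-voxel t statistics (names = voxel
#'   ids).
#' @param df Degrees of freedom of the t statistics.
#' @param direction `"greater"` keeps voxels with significantly positive
#'   statistics, `"less"` significantly negative ones.
#' @param alpha Uncorrected threshold (default 0.01).
#' @param mask Vector of voxel ids defining the inclusive mask.
#' @param name,preferred,source Passed to [roi_spec()].
#' @return A [roi_spec()]; errors with class `dediffr_empty_roi` when no voxel
#'   survives.
#' @export
roi_from_contrast <- function(stat, df, direction = c("greater", "less"),
                              alpha = 0.01, mask, name, preferred,
                              source = "contrast-defined") {
  direction <- match.arg(direction)
  stopifnot(!is.null(names(stat)), df > 0, alpha > 0, alpha < 1)
  p <- if (direction == "greater") {
    stats::pt(stat, df, lower.tail = FALSE)
  } else {
    stats::pt(stat, df, lower.tail = TRUE)
  }
  keep <- names(stat)[p < alpha]
  keep <- intersect(keep, as.character(mask))
  if (length(keep) == 0L) {
    stop(errorCondition(
      sprintf("no suprathreshold voxels in mask for ROI '%s'", name),
      class = c("dediffr_empty_roi", "error", "condition")
    ))
  }
  roi_spec(name, preferred, keep, source)
}

#' Per-voxel second-level statistic for the face-versus-scene contrast
#'
#' Computes, for every voxel, a one-sample t statistic on the participant-wise
#' face-minus-scene difference of category-mean responses, pooled over groups
#' (age group is not a factor in ROI definition).
#'
#' @param face_maps,scene_maps Participants x voxels matrices of category-mean
#'   responses with matching column (voxel) names.
#' @return List with `stat` (named t values) and `df` (n - 1).
#' @export
category_contrast_map <- function(face_maps, scene_maps) {
  face_maps <- as.matrix(face_maps)
  scene_maps <- as.matrix(scene_maps)
  stopifnot(all(dim(face_maps) == dim(scene_maps)), nrow(face_maps) >= 2)
  d <- face_maps - scene_maps
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  n <- nrow(d)
  stat <- m / (s / sqrt(n))
  names(stat) <- colnames(face_maps)
  list(stat = stat, df = n - 1)
}
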