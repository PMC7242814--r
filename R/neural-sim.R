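#' Generative parameters for category-selective voxel patterns
#'
#' Defines the two-component generative model of trial-wise responses in a
#' category-selective ROI. A trial of category c in a given participant has
#' voxel vector
#'
#'   `amp[c] + kappa[c] * template_c + noise`,
#'
#' where `amp[c]` is a scalar mean amplitude added to every voxel (the
#' univariate component), `template_c` is a unit-norm voxel pattern drawn
#' fresh for each participant and category (the multivariate component,
#' weighted by the pattern-reliability parameter `kappa[c]`), and the noise is
#' i.i.d. Gaussian with SD `sigma` across trials and voxels. Age-group
#' differences are expressed by attenuating `amp`/`kappa` for the preferred
#' category and/or raising `amp` for the non-preferred one. Optional
#' between-participant SDs (`amp_sd`, `kappa_sd`) add individual differences
#' in amplitude and pattern reliability; both default to 0.
#'
#' @param roi_name ROI label (e.g., `"PPA"`).
#' @param preferred Preferred category, `"face"` or `"scene"`.
#' @param n_voxels Number of voxels (>= 2).
#' @param amp Named mean amplitudes `c(face=, scene=)` in beta units.
#' @param kappa Named pattern-reliability weights `c(face=, scene=)`, >= 0.
#' @param sigma Trial-noise SD per voxel, > 0.
#' @param amp_sd Between-participant SD of each category amplitude.
#' @param kappa_sd Between-participant SD of each kappa (draws truncated at 0).
#'
#' @return An object of class `neural_params`.
#' @export
neural_params <- function(roi_name, preferred, n_voxels,
                          amp = c(face = 0, scene = 0),
                          kappa = c(face = 0, scene = 0),
                          sigma = 1, amp_sd = 0, kappa_sd = 0) {
  np <- list(roi_name = roi_name, preferred = match.arg(preferred,
                                                        c("face", "scene")),
             n_voxels = as.integer(n_voxels), amp = amp, kappa = kappa,
             sigma = sigma, amp_sd = amp_sd, kappa_sd = kappa_sd)
  if (np$n_voxels < 2L) stop("n_voxels must be >= 2", call. = FALSE)
  if (!all(c("face", "scene") %in% names(amp)) ||
      !all(c("face", "scene") %in% names(kappa))) {
    stop("amp and kappa must be named with face and scene", call. = FALSE)
  }
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  stopifnot(amp_sd >= 0, kappa_sd >= 0)
  class(np) <- "neural_params"
  np
}

unit_norm <- function(v) v / sqrt(sum(v^2))

#' Simulate single-trial beta patterns for one ROI
#'
#' Draws a [beta_matrix()] per participant from the generative model described
#' in [neural_params()]: category templates are unit-norm voxel vectors drawn
#' once per participant per category, each study critical trial receives
#' `amp[c] + kappa[c] * template_c` plus i.i.d. Gaussian noise. Trial metadata
#' (category, session, and the subsequent-memory status when the design has
#' been through [simulate_behavior()]) is attached.
#'
#' @param design A design table from [generate_design()] (optionally with
#'   behavioral outcomes).
#' @param np A [neural_params()] object.
#' @param seed Integer seed.
#' @return A named list with one [beta_matrix()] per participant.
#' @export
simulate_betas <- function(design, np, seed) {
  stopifnot(inherits(np, "neural_params"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  d <- design[design$phase == "study" & design$trial_type == "critical", ]
  if (nrow(d) == 0L) stop("design has no study critical trials", call. = FALSE)
  parts <- unique(d$participant)
  out <- stats::setNames(vector("list", length(parts)), parts)
  roi <- list(name = np$roi_name, preferred = np$preferred)
  nv <- np$n_voxels
  for (pid in parts) {
    dd <- d[d$participant == pid, ]
    templates <- list(face = unit_norm(stats::rnorm(nv)),
                      scene = unit_norm(stats::rnorm(nv)))
    amp_p <- np$amp + stats::rnorm(2, 0, np$amp_sd)
    kappa_p <- stats::setNames(
      pmax(0, np$kappa + stats::rnorm(2, 0, np$kappa_sd)), names(np$kappa)
    )
    n_tr <- nrow(dd)
    vals <- matrix(stats::rnorm(n_tr * nv, 0, np$sigma), n_tr, nv)
    for (cat_lab in c("face", "scene")) {
      idx <- which(dd$category == cat_lab)
      if (length(idx)) {
        signal <- amp_p[cat_lab] + kappa_p[cat_lab] * templates[[cat_lab]]
        vals[idx, ] <- vals[idx, , drop = FALSE] +
          matrix(signal, length(idx), nv, byrow = TRUE)
      }
    }
    meta <- data.frame(
      trial_id = sprintf("%s_s%d_t%03d", pid, dd$session, dd$slot),
      category = dd$category, session = dd$session,
      word_id = dd$word_id, stringsAsFactors = FALSE
    )
    if (!is.null(dd$memory_status)) meta$memory_status <- dd$memory_status
    rownames(vals) <- meta$trial_id
    out[[pid]] <- beta_matrix(vals, meta, roi)
  }
  out
}

#' Simulate BOLD time series from a design (forward model)
#'
#' Generates per-session voxel time series by pushing ground-truth single-trial
#' amplitudes through the same boxcar-convolved-with-canonical-HRF forward
#' model used for estimation, then adding white noise. The truth is returned
#' so that least-squares-all recovery can be verified.
#'
#' True amplitudes follow the [neural_params()] generative model: per-trial
#' voxel vectors `amp[c] + kappa[c] * template_c` plus trial-level variation
#' with SD `sigma`.
#'
#' @param design Design table for a single participant (study phase rows are
#'   used; null and filler trials are not modeled).
#' @param np A [neural_params()] object.
#' @param glm_params List with elements `tr_s` (default 2), `noise_sd`
#'   (default 1) and optionally `n_scans_per_session` (named or unnamed
#'   integer vector; defaults to covering the last event plus the 32-s HRF
#'   kernel).
#' @param seed Integer seed.
#' @return A list with `series` (list of scans x voxels matrices, one per
#'   session), `truth` (trials x voxels matrix of true amplitudes), `events`
#'   (the modeled trials), `n_scans_per_session`, and `tr_s`.
#' @export
simulate_bold <- function(design, np, glm_params = list(), seed) {
  stopifnot(inherits(np, "neural_params"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  tr_s <- glm_params$tr_s %||% 2
  noise_sd <- glm_params$noise_sd %||% 1
  stopifnot(tr_s > 0, noise_sd >= 0)
  ev <- design[design$phase == "study" & design$trial_type == "critical", ]
  if (length(unique(ev$participant)) != 1L) {
    stop("simulate_bold expects a single participant's design", call. = FALSE)
  }
  ev <- ev[order(ev$session, ev$onset), ]
  ev$trial_id <- sprintf("s%d_t%03d", ev$session, ev$slot)
  sessions <- sort(unique(ev$session))
  kern_s <- 32
  n_scans <- glm_params$n_scans_per_session %||% vapply(
    sessions, function(s) {
      e <- ev[ev$session == s, ]
      as.integer(ceiling((max(e$onset + e$duration) + kern_s) / tr_s))
    }, integer(1)
  )
  if (length(n_scans) != length(sessions)) {
    stop("n_scans_per_session must have one entry per session", call. = FALSE)
  }
  for (i in seq_along(sessions)) {
    e <- ev[ev$session == sessions[i], ]
    if (any(e$onset + e$duration > n_scans[i] * tr_s)) {
      stop("events extend past the end of session ", sessions[i],
           call. = FALSE)
    }
  }
  nv <- np$n_voxels
  templates <- list(face = unit_norm(stats::rnorm(nv)),
                    scene = unit_norm(stats::rnorm(nv)))
  truth <- matrix(0, nrow(ev), nv, dimnames = list(ev$trial_id, NULL))
  for (cat_lab in c("face", "scene")) {
    idx <- which(ev$category == cat_lab)
    if (length(idx)) {
      base <- np$amp[cat_lab] + np$kappa[cat_lab] * templates[[cat_lab]]
      truth[idx, ] <- matrix(base, length(idx), nv, byrow = TRUE) +
        matrix(stats::rnorm(length(idx) * nv, 0, np$sigma), length(idx), nv)
    }
  }
  dsn <- build_lsa_design(ev, n_scans_per_session = n_scans, tr_s = tr_s)
  tc <- dsn$trial_columns[ev$trial_id]
  X <- dsn$matrix[, tc, drop = FALSE]
  series_all <- X %*% truth
  if (noise_sd > 0) {
    series_all <- series_all +
      matrix(stats::rnorm(length(series_all), 0, noise_sd),
             nrow(series_all), ncol(series_all))
  }
  series <- lapply(seq_along(sessions), function(i) {
    rows <- dsn$session_blocks[[i]]
    series_all[rows, , drop = FALSE]
  })
  names(series) <- paste0("session", sessions)
  list(series = series, truth = truth, events = ev,
       n_scans_per_session = n_scans, tr_s = tr_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
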