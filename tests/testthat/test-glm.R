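test_that("canonical HRF has the expected double-gamma shape", {
  h <- canonical_hrf(0.1)
  expect_equal(h[1], 0)
  peak_t <- (which.max(h) - 1) * 0.1
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 7)
  expect_gt(sum(h), 0) # positive main lobe dominates the undershoot
  expect_equal(max(h), 1) # peak-normalized
})

test_that("LSA design has one column per trial plus the stated nuisance", {
  ev <- data.frame(
    session = rep(1:4, length.out = 10),
    onset = rep(c(10, 40, 70), length.out = 10),
    duration = 2
  )
  n_scans <- rep(60L, 4)
  motion <- matrix(0, sum(n_scans), 6)
  dsn <- build_lsa_design(ev, n_scans, tr_s = 2, motion = motion)
  expect_equal(ncol(dsn$matrix), 10 + 6 + 4)
  # each trial regressor is exactly zero outside its own session's rows
  for (j in seq_len(10)) {
    si <- match(ev$session[j], sort(unique(ev$session)))
    outside <- setdiff(seq_len(sum(n_scans)), dsn$session_blocks[[si]])
    expect_true(all(dsn$matrix[outside, j] == 0))
    expect_gt(max(abs(dsn$matrix[dsn$session_blocks[[si]], j])), 0)
  }
})

test_that("a trial regressor is causal and peaks at the HRF lag", {
  dsn <- build_lsa_design(
    data.frame(session = 1, onset = 0, duration = 2),
    n_scans_per_session = 30, tr_s = 2
  )
  reg <- dsn$matrix[, 1]
  expect_equal(reg[1], 0) # nothing before/at onset sample
  # direct convolution oracle on a fine grid
  dt <- 0.01
  tt <- seq(0, 59.99, by = dt)
  u <- as.numeric(tt >= 0 & tt < 2)
  h <- dgamma(tt, shape = 6, scale = 1) - dgamma(tt, shape = 16, scale = 1) / 6
  h <- h / max(h)
  conv <- stats::convolve(u, rev(h), type = "open")[seq_along(tt)] * dt
  oracle_peak <- tt[which.max(conv)]
  scan_peak <- (which.max(reg) - 1) * 2
  expect_lte(abs(scan_peak - oracle_peak), 2) # within one TR
  # and the sampled values match the fine-grid convolution up to the
  # boxcar-edge quantization of the default microtime grid (TR/16)
  oracle_at_scans <- conv[round(seq(0, 58, by = 2) / dt) + 1]
  expect_lt(max(abs(reg - oracle_at_scans)), 0.05)
})

test_that("onsets beyond the session end fail naming the trial", {
  ev <- data.frame(session = 1, onset = c(5, 300), duration = 2,
                   trial_id = c("ok", "late"))
  expect_error(build_lsa_design(ev, 50, tr_s = 2), "late")
})

test_that("identity-like designs return the data rows as betas", {
  X <- diag(5)
  colnames(X) <- sprintf("t%d", 1:5)
  dsn <- structure(list(
    matrix = X, labels = colnames(X),
    trial_columns = stats::setNames(1:5, colnames(X)),
    session_blocks = list(session1 = 1:5), tr_s = 2
  ), class = "glm_design")
  Y <- matrix(rnorm(15), 5, 3)
  expect_equal(unname(fit_lsa(Y, dsn)), Y)
})

test_that("OLS betas equal the normal-equations oracle", {
  set.seed(42)
  for (rep in 1:5) {
    ev <- data.frame(session = rep(1:2, each = 4),
                     onset = rep(seq(5, 65, by = 20), 2), duration = 2)
    dsn <- build_lsa_design(ev, c(50, 50), tr_s = 2,
                            motion = matrix(rnorm(600), 100, 6))
    Y <- matrix(rnorm(100 * 3), 100, 3)
    est <- fit_lsa(Y, dsn)
    X <- dsn$matrix
    oracle <- solve(t(X) %*% X, t(X) %*% Y)[dsn$trial_columns, ]
    expect_lt(max(abs(est - oracle)), 1e-8)
  }
})

test_that("estimates are invariant to shifts along nuisance directions", {
  ev <- data.frame(session = rep(1:2, each = 3),
                   onset = rep(c(6, 30, 54), 2), duration = 2)
  dsn <- build_lsa_design(ev, c(40, 40), tr_s = 2)
  Y <- matrix(rnorm(80 * 2), 80, 2)
  b0 <- fit_lsa(Y, dsn)
  # add session-mean offsets (spanned by the session-mean regressors)
  Y2 <- Y
  Y2[dsn$session_blocks[[1]], ] <- Y2[dsn$session_blocks[[1]], ] + 7
  Y2[dsn$session_blocks[[2]], ] <- Y2[dsn$session_blocks[[2]], ] - 3
  expect_equal(fit_lsa(Y2, dsn), b0, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected with advice", {
  ev <- data.frame(session = 1, onset = c(10, 10), duration = 2)
  dsn <- build_lsa_design(ev, 40, tr_s = 2)
  expect_error(fit_lsa(matrix(rnorm(40), 40, 1), dsn), "ill-conditioned")
})

test_that("motion flagging honors strict thresholds and trial windows", {
  ev <- data.frame(session = 1, onset = c(10, 60), duration = 2)
  n_scans <- 60L
  motion <- matrix(0, 60, 6)
  expect_equal(flag_high_motion_trials(motion, ev, n_scans),
               c(FALSE, FALSE))
  # 1.2 mm translation at 12 s: inside trial 1's window only
  m2 <- motion; m2[7, 1] <- 1.2
  expect_equal(flag_high_motion_trials(m2, ev, n_scans), c(TRUE, FALSE))
  # exactly 1.0 mm is NOT flagged (strict >)
  m3 <- motion; m3[7, 1] <- 1.0
  expect_equal(flag_high_motion_trials(m3, ev, n_scans), c(FALSE, FALSE))
  # rotation axis works the same way
  m4 <- motion; m4[32, 5] <- 1.5
  expect_equal(flag_high_motion_trials(m4, ev, n_scans), c(FALSE, TRUE))
  expect_error(flag_high_motion_trials(motion[1:10, ], ev, n_scans),
               "one row per scan")
})

test_that("contrast ROIs recover truly selective voxels inside the mask", {
  set.seed(88)
  n_vox <- 200; n_sel <- 50; n_subj <- 40
  voxels <- sprintf("v%03d", seq_len(n_vox))
  effect <- c(rep(1, n_sel), rep(0, n_vox - n_sel)) # 5 x noise sd (0.2)
  face_maps <- matrix(rnorm(n_subj * n_vox, 0, 0.2), n_subj, n_vox,
                      dimnames = list(NULL, voxels))
  scene_maps <- matrix(rnorm(n_subj * n_vox, 0, 0.2), n_subj, n_vox,
                       dimnames = list(NULL, voxels))
  face_maps <- face_maps + matrix(effect, n_subj, n_vox, byrow = TRUE)
  cm <- category_contrast_map(face_maps, scene_maps)
  roi <- roi_from_contrast(cm$stat, cm$df, "greater", alpha = 0.01,
                           mask = voxels, name = "FFA", preferred = "face")
  expect_true(all(voxels[seq_len(n_sel)] %in% roi$voxel_ids))
  n_false <- length(setdiff(roi$voxel_ids, voxels[seq_len(n_sel)]))
  expect_lte(n_false, qbinom(0.999, n_vox - n_sel, 0.01))
})

test_that("empty contrast ROIs raise a typed error", {
  stat <- stats::setNames(rep(0, 20), sprintf("v%d", 1:20))
  expect_error(
    roi_from_contrast(stat, df = 30, "greater", mask = names(stat),
                      name = "none", preferred = "face"),
    class = "dediffr_empty_roi"
  )
})

test_that("ROI selection is monotone in alpha and confined to the mask", {
  set.seed(12)
  stat <- stats::setNames(rnorm(100, 0, 2), sprintf("v%03d", 1:100))
  mask <- sprintf("v%03d", 1:60)
  r1 <- roi_from_contrast(stat, 30, "greater", alpha = 0.01, mask = mask,
                          name = "a", preferred = "face")
  r2 <- roi_from_contrast(stat, 30, "greater", alpha = 0.05, mask = mask,
                          name = "a", preferred = "face")
  expect_true(all(r1$voxel_ids %in% r2$voxel_ids))
  expect_true(all(r2$voxel_ids %in% mask))
})
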