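# Independent oracles and shared configurations used across test files.

# Split-plot sum-of-squares oracle for a balanced 2 (between) x k (within)
# design, from the textbook mean-based decomposition. Deliberately written
# without any of the package's ANOVA machinery.
split_plot_oracle <- function(d) {
  gm <- mean(d$y)
  subj_means <- tapply(d$y, d$subject, mean)
  grp_of <- tapply(as.character(d$group), d$subject, unique)
  k <- length(unique(d$w))
  n_subj <- length(subj_means)
  ss_between_subj <- k * sum((subj_means - gm)^2)
  grp_means <- tapply(d$y, d$group, mean)
  n_per_grp <- table(grp_of)
  ss_A <- k * sum(n_per_grp * (grp_means[names(n_per_grp)] - gm)^2)
  ss_subj_within <- ss_between_subj - ss_A
  w_means <- tapply(d$y, d$w, mean)
  n_g <- n_subj / length(grp_means)
  ss_B <- n_subj * sum((w_means - gm)^2)
  cell_means <- tapply(d$y, list(d$group, d$w), mean)
  ss_cells <- n_g * sum((cell_means - gm)^2)
  ss_AB <- ss_cells - ss_A - ss_B
  ss_tot <- sum((d$y - gm)^2)
  ss_error_w <- ss_tot - ss_cells - ss_subj_within
  df_A <- length(grp_means) - 1
  df_sw <- n_subj - length(grp_means)
  df_B <- k - 1
  df_AB <- df_A * df_B
  df_ew <- df_sw * df_B
  list(
    F_A = (ss_A / df_A) / (ss_subj_within / df_sw),
    F_B = (ss_B / df_B) / (ss_error_w / df_ew),
    F_AB = (ss_AB / df_AB) / (ss_error_w / df_ew),
    ss_A = ss_A, ss_B = ss_B, ss_AB = ss_AB,
    ss_sw = ss_subj_within, ss_ew = ss_error_w
  )
}

# A trimmed run configuration: PPA + FFA with reduced voxel counts and the
# reduced list structure of tiny_params(); the same qualitative regime as the
# default study conditions (scene-ROI dedifferentiation, null face ROIs).
trim_config <- function(seed, n_per_group = 8, dediff = TRUE) {
  cfg <- default_run_config(n_per_group = n_per_group, seed = seed,
                            rois = c("PPA", "FFA"), min_bin_trials = 2L)
  cfg$design <- tiny_params()
  k <- function(r, nv) kappa_from_reliability(r, nv, 10)
  cfg$neural$PPA <- list(
    young = neural_params("PPA", "scene", 80,
                          amp = c(face = 0.2, scene = 2.4),
                          kappa = c(face = k(.05, 80), scene = k(.20, 80)),
                          sigma = 10, amp_sd = 0.45, kappa_sd = 10),
    older = neural_params("PPA", "scene", 80,
                          amp = c(face = if (dediff) 0.6 else 0.2,
                                  scene = if (dediff) 1.8 else 2.4),
                          kappa = c(face = k(.05, 80),
                                    scene = k(if (dediff) .10 else .20, 80)),
                          sigma = 10, amp_sd = 0.45, kappa_sd = 10)
  )
  cfg$neural$FFA <- list(
    young = neural_params("FFA", "face", 44,
                          amp = c(face = 1.4, scene = 0.2),
                          kappa = c(face = k(.12, 44), scene = k(.04, 44)),
                          sigma = 10, amp_sd = 0.25, kappa_sd = 6),
    older = neural_params("FFA", "face", 44,
                          amp = c(face = 1.4, scene = 0.2),
                          kappa = c(face = k(.12, 44), scene = k(.04, 44)),
                          sigma = 10, amp_sd = 0.25, kappa_sd = 6)
  )
  cfg
}
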