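# Shared fixtures: all built in code at test time.

# A reduced design: 1 cycle x 2 blocks, 16 critical pairs + 8 nulls per
# study sub-list, 8 new words per test sub-list. Fast to generate in bulk.
tiny_params <- function(...) {
  design_params(n_cycles = 1, blocks_per_cycle = 2, critical_per_block = 16,
                null_per_sublist = 8, new_words_per_test_sublist = 8,
                fillers_per_segment = 1, ...)
}

tiny_design <- function(n = 1, seed = 1, params = tiny_params()) {
  generate_design(params, n_participants = n, seed = seed)
}

# Build a beta_matrix directly from a values matrix and trial metadata.
make_bm <- function(values, category, session,
                    memory_status = NULL, preferred = "scene",
                    roi_name = "testROI") {
  meta <- data.frame(category = category, session = session,
                     stringsAsFactors = FALSE)
  if (!is.null(memory_status)) meta$memory_status <- memory_status
  rownames(values) <- meta$trial_id <-
    sprintf("t%03d", seq_len(nrow(values)))
  beta_matrix(values, meta, list(name = roi_name, preferred = preferred))
}

# Four trial patterns (2 categories x 2 sessions) with exact pairwise
# correlations: within-category pairs r = r_within, cross pairs r = 0.
# Built from an orthonormal basis of centered unit vectors, so that the
# Pearson correlation of two patterns equals their inner product.
exact_correlation_patterns <- function(r_within = 0.5, n_voxels = 12,
                                       seed = 99) {
  set.seed(seed)
  raw <- matrix(rnorm(n_voxels * 5), n_voxels, 5)
  centered <- scale(raw, center = TRUE, scale = FALSE)
  basis <- qr.Q(qr(centered))[, 1:4]
  basis <- apply(basis, 2, function(v) (v - mean(v)) / sqrt(sum((v - mean(v))^2)))
  # after centering, re-orthonormalize by Gram-Schmidt
  for (k in 2:4) {
    v <- basis[, k]
    for (m in seq_len(k - 1)) v <- v - sum(v * basis[, m]) * basis[, m]
    basis[, k] <- v / sqrt(sum(v^2))
  }
  a1 <- basis[, 1]
  a2 <- r_within * basis[, 1] + sqrt(1 - r_within^2) * basis[, 2]
  b1 <- basis[, 3]
  b2 <- r_within * basis[, 3] + sqrt(1 - r_within^2) * basis[, 4]
  vals <- rbind(a1, a2, b1, b2)
  make_bm(vals, category = c("scene", "scene", "face", "face"),
          session = c(1, 2, 1, 2))
}

# Minimal single-participant study event table (no list structure), handy for
# simulate_betas / simulate_bold without running the full design generator.
flat_study_events <- function(n_per_cat = 12, n_sessions = 2, gap_s = 8,
                              participant = "p01") {
  per_sess <- 2 * n_per_cat / n_sessions
  stopifnot(per_sess == round(per_sess))
  cat_seq <- rep(c("face", "scene"), n_per_cat)
  d <- data.frame(
    participant = participant, phase = "study", cycle = 1,
    sublist = rep(seq_len(n_sessions), each = per_sess),
    session = rep(seq_len(n_sessions), each = per_sess),
    slot = sequence(rep(per_sess, n_sessions)),
    trial_type = "critical", category = cat_seq,
    stringsAsFactors = FALSE
  )
  d$onset <- (d$slot - 1) * gap_s + 0.5
  d$duration <- 2
  d$word_id <- sprintf("w%03d", seq_len(nrow(d)))
  d$image_id <- sprintf("i%03d", seq_len(nrow(d)))
  d
}
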