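test_that("index equals atanh(0.5) on patterns with exact correlations", {
  bm <- exact_correlation_patterns(r_within = 0.5)
  res <- within_between_similarity(bm)
  expect_equal(res$index, atanh(0.5), tolerance = 1e-6)
  expect_equal(res$within_z, atanh(0.5), tolerance = 1e-6)
  expect_equal(res$between_z, 0, tolerance = 1e-6)
  expect_equal(res$n_within_pairs, 2)
  expect_equal(res$n_between_pairs, 2)
})

test_that("transform-then-average matches a naive pairwise oracle", {
  set.seed(14)
  n_tr <- 10; nv <- 8
  vals <- matrix(rnorm(n_tr * nv), n_tr, nv)
  category <- rep(c("scene", "face"), 5)
  session <- rep(1:2, each = 5)
  bm <- make_bm(vals, category, session, preferred = "scene")
  res <- within_between_similarity(bm)
  # oracle: enumerate all pairs with explicit loops
  zw <- c(); zb <- c()
  for (i in 1:(n_tr - 1)) for (j in (i + 1):n_tr) {
    if (session[i] == session[j]) next
    z <- atanh(cor(vals[i, ], vals[j, ]))
    if (category[i] == category[j]) zw <- c(zw, z) else zb <- c(zb, z)
  }
  expect_equal(res$within_z, mean(zw), tolerance = 1e-12)
  expect_equal(res$between_z, mean(zb), tolerance = 1e-12)
  expect_equal(res$n_within_pairs, length(zw))
  # preferred_only restricts the within average to the preferred category
  res_p <- within_between_similarity(bm, "preferred_only")
  zwp <- c()
  for (i in 1:(n_tr - 1)) for (j in (i + 1):n_tr) {
    if (session[i] == session[j] || category[i] != category[j]) next
    if (category[i] != "scene") next
    zwp <- c(zwp, atanh(cor(vals[i, ], vals[j, ])))
  }
  expect_equal(res_p$within_z, mean(zwp), tolerance = 1e-12)
})

test_that("randomly permuted category labels average to a null index", {
  set.seed(15)
  nv <- 16
  vals <- matrix(rnorm(12 * nv), 12, nv)
  session <- rep(1:2, each = 6)
  n_perm <- 500
  idx <- vapply(seq_len(n_perm), function(i) {
    category <- sample(rep(c("scene", "face"), 6))
    within_between_similarity(make_bm(vals, category, session))$index
  }, numeric(1))
  expect_lt(abs(mean(idx)), 3.5 * sd(idx) / sqrt(n_perm))
})

test_that("the index is invariant to per-trial affine pattern transforms", {
  set.seed(16)
  vals <- matrix(rnorm(48), 6, 8)
  bm <- make_bm(vals, rep(c("scene", "face"), 3), rep(1:2, each = 3))
  i0 <- within_between_similarity(bm)$index
  scl <- runif(6, 0.5, 3)
  off <- rnorm(6, 0, 5)
  vals2 <- vals * scl + off
  bm2 <- make_bm(vals2, bm$meta$category, bm$meta$session)
  expect_equal(within_between_similarity(bm2)$index, i0, tolerance = 1e-12)
})

test_that("session-shared noise does not bias the cross-session index", {
  # inflating same-session pair correlations (shared noise with unchanged
  # marginal variance) must leave the cross-session index untouched; a naive
  # all-pairs average is shifted by the same manipulation
  nv <- 24; n_per_sess <- 8; rho <- 0.6
  gen <- function(shared, seed, session_noise) {
    set.seed(seed)
    templ <- list(scene = rnorm(nv), face = rnorm(nv))
    templ <- lapply(templ, function(t) t / sqrt(sum(t^2)))
    category <- rep(c("scene", "face"), 2 * n_per_sess)
    session <- rep(1:2, each = 2 * n_per_sess)
    k <- 3
    vals <- t(vapply(seq_along(category), function(i) {
      e <- rnorm(nv)
      if (shared) {
        cs <- session_noise[[session[i]]]
        e <- sqrt(1 - rho) * e + sqrt(rho) * cs
      }
      k * templ[[category[i]]] + e
    }, numeric(nv)))
    make_bm(vals, category, session)
  }
  n_rep <- 150
  res <- vapply(seq_len(n_rep), function(r) {
    sn <- list(rnorm(nv), rnorm(nv))
    a <- within_between_similarity(gen(FALSE, 6000 + r, sn))$index
    b <- within_between_similarity(gen(TRUE, 6000 + r, sn))$index
    naive <- function(bm) { # includes same-session pairs
      R <- cor(t(bm$values))
      p <- which(upper.tri(R), arr.ind = TRUE)
      z <- atanh(R[p])
      same <- bm$meta$category[p[, 1]] == bm$meta$category[p[, 2]]
      mean(z[same]) - mean(z[!same])
    }
    c(a, b, naive(gen(TRUE, 6000 + r, sn)))
  }, numeric(3))
  diff_proper <- res[2, ] - res[1, ]
  expect_lt(abs(mean(diff_proper)), 3.5 * sd(diff_proper) / sqrt(n_rep))
  # the naive estimator IS biased upward by the shared session noise
  diff_naive <- res[3, ] - res[1, ]
  expect_gt(mean(diff_naive), 5 * sd(diff_naive) / sqrt(n_rep))
})

test_that("typed errors cover the degenerate similarity cases", {
  vals <- matrix(rnorm(16), 4, 4)
  bm1 <- make_bm(vals, rep(c("scene", "face"), 2), session = rep(1, 4))
  expect_error(within_between_similarity(bm1),
               class = "dediffr_no_cross_session_pairs")
  vals2 <- vals; vals2[2, ] <- 3 # constant pattern
  bm2 <- make_bm(vals2, rep(c("scene", "face"), 2), session = rep(1:2, 2))
  expect_error(within_between_similarity(bm2), "zero-variance")
  vals3 <- vals; vals3[3, ] <- 2 * vals3[1, ] # perfectly correlated pair
  bm3 <- make_bm(vals3, c("scene", "face", "scene", "face"),
                 session = c(1, 1, 2, 2)) # pair (1,3) is cross-session
  expect_error(within_between_similarity(bm3), "perfectly correlated")
})

test_that("memory-conditioned similarity behaves like its full counterpart", {
  set.seed(17)
  vals <- matrix(rnorm(96), 12, 8)
  category <- rep(c("scene", "face"), 6)
  session <- rep(1:2, each = 6)
  all_sc <- make_bm(vals, category, session,
                    memory_status = rep("source_correct", 12))
  full <- within_between_similarity(all_sc)
  cond <- memory_conditioned_similarity(all_sc)
  expect_equal(cond$index, full$index)
  expect_equal(cond$condition, "source_correct_only")
  # a subset whose trials all sit in one session is rejected
  status <- ifelse(session == 1, "source_correct", "other")
  one_sess <- make_bm(vals, category, session, memory_status = status)
  expect_error(memory_conditioned_similarity(one_sess),
               class = "dediffr_no_cross_session_pairs")
})

test_that("doubling voxel noise lowers expected within-category similarity", {
  d <- flat_study_events(n_per_cat = 8, n_sessions = 2)
  n_rep <- 150
  wz <- vapply(c(1, 2), function(sg) {
    np <- neural_params("n", "scene", 16, amp = c(face = 0, scene = 0),
                        kappa = c(face = 4, scene = 4), sigma = sg)
    mean(vapply(seq_len(n_rep), function(r) {
      within_between_similarity(simulate_betas(d, np, seed = 7000 + r)[[1]])$within_z
    }, numeric(1)))
  }, numeric(1))
  expect_lt(wz[2], wz[1])
})
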