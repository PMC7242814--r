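test_that("Welch t matches the hand-computed formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(3, 4, 5, 6, 7)
  res <- welch_t(x, y)
  # independent evaluation of Welch's statistic and Satterthwaite df
  v1 <- var(x) / 5; v2 <- var(y) / 5
  t_or <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df_or <- (v1 + v2)^2 / (v1^2 / 4 + v2^2 / 4)
  p_or <- 2 * pt(abs(t_or), df_or, lower.tail = FALSE)
  expect_lt(abs(res$statistic - t_or), 1e-10)
  expect_lt(abs(res$df - df_or), 1e-10)
  expect_lt(abs(res$p - p_or), 1e-10)
})

test_that("identical samples give t = 0 and p = 1", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  res <- welch_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch df respects the Satterthwaite bounds", {
  set.seed(19)
  for (i in 1:25) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0, runif(1, 0.2, 3))
    df <- welch_t(x, y)$df
    expect_gte(df, min(n1, n2) - 1 - 1e-9)
    expect_lte(df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("Cohen's d uses the n-1 weighted pooled SD", {
  expect_equal(cohens_d(c(0, 1, 2), c(-1, 0, 1)), 1)
  expect_equal(cohens_d(c(2, 4), c(2, 4)), 0)
  set.seed(20)
  x <- rnorm(14); y <- rnorm(9, 0.4)
  sp <- sqrt((13 * var(x) + 8 * var(y)) / 21)
  expect_lt(abs(cohens_d(x, y) - (mean(x) - mean(y)) / sp), 1e-12)
})

test_that("mixed ANOVA F matches the brute-force SS oracle", {
  set.seed(21)
  for (k in c(2, 4)) {
    d <- expand.grid(subject = sprintf("s%d", 1:8),
                     w = paste0("w", seq_len(k)), stringsAsFactors = FALSE)
    d$group <- ifelse(d$subject %in% sprintf("s%d", 1:4), "young", "older")
    d$y <- rnorm(nrow(d)) + ifelse(d$group == "young" & d$w == "w1", 1, 0)
    res <- mixed_anova(d, "y", "group", "w", "subject", correction = "none")
    or <- split_plot_oracle(d)
    expect_lt(abs(res$F[res$effect == "group"] - or$F_A), 1e-8)
    expect_lt(abs(res$F[res$effect == "w"] - or$F_B), 1e-8)
    expect_lt(abs(res$F[res$effect == "group:w"] - or$F_AB), 1e-8)
    expect_lt(abs(res$ss[res$effect == "w"] - or$ss_B), 1e-8)
    # partial eta squared from the same decomposition
    expect_lt(abs(res$pes[res$effect == "group"] -
                    or$ss_A / (or$ss_A + or$ss_sw)), 1e-8)
  }
})

test_that("two-level within factors have epsilon exactly 1", {
  set.seed(22)
  d <- expand.grid(subject = sprintf("s%d", 1:10), w = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:5), "g1", "g2")
  d$y <- rnorm(nrow(d))
  res <- mixed_anova(d, "y", "group", "w", "subject")
  expect_equal(res$epsilon[res$effect == "w"], 1)
  expect_equal(res$df_num_corr, res$df_num)
})

test_that("Greenhouse-Geisser correction shrinks df for k > 2", {
  set.seed(23)
  d <- expand.grid(subject = sprintf("s%d", 1:12), w = paste0("w", 1:4),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:6), "g1", "g2")
  # heterogeneous covariance to violate sphericity
  d$y <- rnorm(nrow(d), sd = as.integer(sub("w", "", d$w)))
  res <- mixed_anova(d, "y", "group", "w", "subject", correction = "GG")
  eps <- res$epsilon[res$effect == "w"]
  expect_lt(eps, 1)
  expect_gt(eps, 1 / 3) # lower bound 1/(k-1)
  expect_equal(res$df_num_corr[res$effect == "w"], 3 * eps)
})

test_that("ANOVA results are invariant to dv location shifts", {
  set.seed(24)
  d <- expand.grid(subject = sprintf("s%d", 1:8), w = c("a", "b", "c"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:4), "g1", "g2")
  d$y <- rnorm(nrow(d))
  r1 <- mixed_anova(d, "y", "group", "w", "subject")
  d$y <- d$y + 100
  r2 <- mixed_anova(d, "y", "group", "w", "subject")
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("two crossed within factors are decomposed with all interactions", {
  set.seed(25)
  d <- expand.grid(subject = sprintf("s%d", 1:8), roi = c("PPA", "RSC"),
                   category = c("face", "scene"), stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% sprintf("s%d", 1:4), "young", "older")
  d$y <- rnorm(nrow(d))
  res <- mixed_anova(d, "y", "group", c("roi", "category"), "subject")
  expect_setequal(res$effect,
                  c("group", "roi", "group:roi", "category", "group:category",
                    "roi:category", "group:roi:category"))
  expect_true(all(res$pes >= 0 & res$pes <= 1))
})

test_that("unbalanced designs are rejected naming the subjects", {
  d <- expand.grid(subject = sprintf("s%d", 1:4), w = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$group <- "g1"; d$y <- rnorm(8)
  expect_error(mixed_anova(d[-1, ], "y", "group", "w", "subject"), "s1")
})

test_that("partial correlation matches the residualize-then-correlate oracle", {
  set.seed(26)
  n <- 40
  Z <- cbind(rnorm(n), rnorm(n))
  x <- 0.5 * Z[, 1] + rnorm(n)
  y <- -0.3 * Z[, 2] + 0.4 * x + rnorm(n)
  res <- partial_correlation(x, y, Z)
  rx <- resid(lm(x ~ Z)); ry <- resid(lm(y ~ Z))
  r_or <- cor(rx, ry)
  expect_lt(abs(res$effect_size - r_or), 1e-10)
  df_or <- n - 2 - 2
  t_or <- r_or * sqrt(df_or / (1 - r_or^2))
  expect_lt(abs(res$statistic - t_or), 1e-8)
  expect_equal(res$df, df_or)
})

test_that("partial correlation degenerates gracefully", {
  set.seed(27)
  x <- rnorm(30); y <- rnorm(30)
  # no covariates: plain correlation
  expect_lt(abs(partial_correlation(x, y)$effect_size - cor(x, y)), 1e-12)
  # orthogonal covariate leaves the correlation unchanged
  z <- rnorm(30)
  z <- resid(lm(z ~ x + y)) # orthogonal to both by construction
  expect_lt(abs(partial_correlation(x, y, z)$effect_size - cor(x, y)), 1e-10)
  # y = x gives r = 1
  expect_equal(partial_correlation(x, x, z)$effect_size, 1)
  # collinear covariates fail
  expect_error(partial_correlation(x, y, cbind(z, z)), "singular")
})

test_that("interaction screening keeps strong interactions, drops null ones", {
  set.seed(28)
  n <- 60
  g <- rep(c("young", "older"), each = n / 2)
  x <- rnorm(n)
  # slopes differ by group, effect 5x the noise SD
  y_int <- ifelse(g == "young", 1.0, -1.0) * x + rnorm(n, 0, 0.2)
  scr <- interaction_screen_regression(y_int, x, g)
  expect_equal(scr$model_kept, "full")
  expect_null(scr$partial)
  # additive data: reduced model kept, partial r matches the direct call
  y_add <- 0.5 * x + ifelse(g == "young", 1, 0) + rnorm(n)
  scr2 <- interaction_screen_regression(y_add, x, g)
  expect_equal(scr2$model_kept, "reduced")
  direct <- partial_correlation(x, y_add,
                                as.numeric(factor(g, c("older", "young"))) - 1)
  expect_equal(scr2$partial$effect_size, direct$effect_size)
})

test_that("interaction screening keeps the null interaction at ~ alpha rate", {
  n_rep <- 400
  kept <- vapply(seq_len(n_rep), function(r) {
    set.seed(8000 + r)
    g <- rep(c("a", "b"), each = 15)
    x <- rnorm(30)
    y <- 0.3 * x + rnorm(30)
    interaction_screen_regression(y, x, g)$model_kept == "full"
  }, logical(1))
  ci <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(kept) - 0.05), ci + 0.005)
})

test_that("factor-score projection standardizes then multiplies", {
  set.seed(29)
  L <- read_factor_loadings()
  expect_equal(dim(L), c(12L, 4L))
  sc <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(NULL, rownames(L)))
  f <- apply_factor_loadings(sc, L)
  oracle <- scale(sc) %*% L # explicit matrix product
  expect_lt(max(abs(f - oracle)), 1e-12)
  # identity loadings reproduce the standardized scores
  I4 <- diag(4); rownames(I4) <- colnames(I4) <- colnames(sc)[1:4]
  f_id <- apply_factor_loadings(sc[, 1:4], I4)
  expect_lt(max(abs(f_id - scale(sc[, 1:4]))), 1e-12)
  # an all-zero loadings column yields an all-zero factor
  L0 <- L; L0[, 2] <- 0
  expect_true(all(apply_factor_loadings(sc, L0)[, 2] == 0))
  # zero-variance columns are rejected
  sc2 <- sc; sc2[, 3] <- 5
  expect_error(apply_factor_loadings(sc2, L), "zero-variance")
  # column alignment by name
  shuffled <- sc[, sample(ncol(sc))]
  expect_equal(apply_factor_loadings(shuffled, L), f)
})
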