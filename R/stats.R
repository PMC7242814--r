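#' Welch's unequal-variance t test
#'
#' Two-sided Welch t test with Satterthwaite degrees of freedom, reported
#' together with Cohen's d (first sample minus second, pooled SD).
#'
#' @param x,y Numeric samples (each n >= 2 with finite variance).
#' @return One-row data frame: `statistic` (t), `df` (fractional), `p`,
#'   `effect_size` (Cohen's d).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, effect_size = cohens_d(x, y))
}

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled`, with the
#' pooled SD using n - 1 weighting:
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' Sign convention: first sample minus second.
#'
#' @param x,y Numeric samples.
#' @return Numeric scalar.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD; d undefined", call. = FALSE)
  (mean(x) - mean(y)) / sp
}

#' Mixed-design ANOVA with nonsphericity correction
#'
#' Fits a mixed (split-plot) ANOVA with one between-subjects factor and one or
#' two fully crossed within-subjects factors, using the type-III multivariate
#' linear model route with effects coding. Degrees of freedom of
#' within-subject effects are corrected for nonsphericity with the
#' Greenhouse-Geisser epsilon by default (Huynh-Feldt optional); for a
#' two-level within factor sphericity cannot be violated and epsilon is 1.
#' Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param between Name of the between-subjects factor column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param subject Name of the subject-identifier column.
#' @param correction `"GG"` (Greenhouse-Geisser, default), `"HF"`
#'   (Huynh-Feldt), or `"none"`.
#' @return Data frame with one row per effect: `effect`, `ss`, `ss_error`,
#'   `df_num`, `df_den`, `epsilon`, `df_num_corr`, `df_den_corr`, `F`, `p`
#'   (corrected for within effects), `pes` (partial eta squared).
#' @export
mixed_anova <- function(data, dv, between, within, subject,
                        correction = c("GG", "HF", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(within) %in% 1:2,
            all(c(dv, between, within, subject) %in% names(data)))
  d <- data.frame(
    subject = factor(data[[subject]]),
    between = factor(data[[between]]),
    y = as.numeric(data[[dv]])
  )
  for (k in seq_along(within)) d[[within[k]]] <- factor(data[[within[k]]])

  ## balance checks: one between level and each within cell exactly once
  cell <- interaction(d[within], drop = FALSE)
  tab <- table(d$subject, cell)
  if (any(tab != 1)) {
    bad <- rownames(tab)[apply(tab != 1, 1, any)]
    stop("unbalanced within-subject cells for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  btab <- table(d$subject, d$between)
  if (any(rowSums(btab > 0) != 1)) {
    stop("each subject must belong to exactly one between-subjects group",
         call. = FALSE)
  }

  ## wide reshape: one column per within cell, ordered to match idata
  idata <- expand.grid(lapply(rev(within), function(w) levels(d[[w]])),
                       stringsAsFactors = TRUE)
  names(idata) <- rev(within)
  idata <- idata[, within, drop = FALSE]
  cell_names <- do.call(paste, c(idata, sep = "."))
  subj <- levels(d$subject)
  Y <- matrix(NA_real_, length(subj), length(cell_names),
              dimnames = list(subj, cell_names))
  key <- do.call(paste, c(d[within], sep = "."))
  for (r in seq_len(nrow(d))) {
    Y[as.character(d$subject[r]), key[r]] <- d$y[r]
  }
  grp <- d$between[match(subj, as.character(d$subject))]
  wide <- data.frame(grp = grp)
  mod <- stats::lm(Y ~ grp, data = wide,
                   contrasts = list(grp = stats::contr.sum))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  # HF epsilon can exceed 1; it is capped at 1 (summary warns about the cap)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  adj <- s$pval.adjustments

  effects <- setdiff(rownames(ut), "(Intercept)")
  res <- lapply(effects, function(e) {
    ss <- ut[e, "Sum Sq"]; ss_err <- ut[e, "Error SS"]
    df1 <- ut[e, "num Df"]; df2 <- ut[e, "den Df"]
    Fv <- ut[e, "F value"]; p_unc <- ut[e, "Pr(>F)"]
    eps <- 1
    p <- p_unc
    if (correction != "none" && !is.null(adj) && e %in% rownames(adj)) {
      col_eps <- paste0(correction, " eps")
      col_p <- paste0("Pr(>F[", correction, "])")
      if (!is.na(adj[e, col_eps])) {
        eps <- min(adj[e, col_eps], 1)
        p <- adj[e, col_p]
      }
    }
    data.frame(
      effect = gsub("grp", "between", e), ss = ss, ss_error = ss_err,
      df_num = df1, df_den = df2, epsilon = eps,
      df_num_corr = df1 * eps, df_den_corr = df2 * eps,
      F = Fv, p = p, pes = ss / (ss + ss_err),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$effect <- sub("^between$", between, out$effect)
  out$effect <- gsub("^between:", paste0(between, ":"), out$effect)
  rownames(out) <- NULL
  out
}

#' Partial correlation controlling for covariates
#'
#' Correlation between `x` and `y` after projecting out the covariates (and
#' an intercept) from both via QR-based orthogonal projection, with a t-based
#' two-sided p value on `n - 2 - k` degrees of freedom for k covariates. With
#' no covariates this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric vector, matrix, or data frame of
#'   covariates (factors with two levels may be supplied as 0/1 numerics).
#' @return One-row data frame: `statistic` (t), `df`, `p`, `effect_size`
#'   (partial r).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- NULL
    k <- 0L
  } else {
    Z <- as.matrix(as.data.frame(covariates))
    storage.mode(Z) <- "double"
    k <- ncol(Z)
  }
  n <- length(x)
  stopifnot(length(y) == n, is.null(Z) || nrow(Z) == n)
  if (n <= k + 2) stop("need n > number of covariates + 2", call. = FALSE)
  W <- cbind(intercept = rep(1, n), Z)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    stop("covariate matrix is singular (collinear covariates?)",
         call. = FALSE)
  }
  rx <- qr.resid(qrW, x)
  ry <- qr.resid(qrW, y)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- max(-1, min(1, r))
  df <- n - 2 - k
  tv <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  data.frame(statistic = tv, df = df, p = p, effect_size = r)
}

#' Interaction-screened regression of performance on a neural predictor
#'
#' Fits `y ~ predictor * group`; when the predictor-by-group interaction does
#' not account for a significant fraction of variance (p >= `alpha`), refits
#' the reduced additive model and reports the predictor's partial correlation
#' with `y` controlling for group. When the interaction is significant the
#' full model is retained and no partial correlation is reported.
#'
#' @param y Numeric outcome.
#' @param predictor Numeric predictor (e.g., a differentiation index).
#' @param group Two-level factor (or coercible).
#' @param alpha Screening threshold for the interaction term (default 0.05).
#' @return List with `model_kept` (`"full"` or `"reduced"`),
#'   `interaction_p`, `partial` (one-row data frame from
#'   [partial_correlation()], or `NULL` for the full model), and the fitted
#'   `lm` objects `full_model` and `reduced_model`.
#' @export
interaction_screen_regression <- function(y, predictor, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must be binary", call. = FALSE)
  n <- length(y)
  stopifnot(length(predictor) == n, length(group) == n)
  if (n < 8) stop("need at least 8 observations", call. = FALSE)
  d <- data.frame(y = y, x = predictor, g = group)
  full <- stats::lm(y ~ x * g, data = d)
  cf <- summary(full)$coefficients
  int_row <- grep(":", rownames(cf))
  if (length(int_row) != 1 || any(is.na(stats::coef(full)))) {
    stop("degenerate design: interaction not estimable", call. = FALSE)
  }
  p_int <- cf[int_row, "Pr(>|t|)"]
  reduced <- stats::lm(y ~ x + g, data = d)
  if (p_int >= alpha) {
    partial <- partial_correlation(d$x, d$y,
                                   covariates = as.numeric(d$g) - 1)
    list(model_kept = "reduced", interaction_p = p_int, partial = partial,
         full_model = full, reduced_model = reduced)
  } else {
    list(model_kept = "full", interaction_p = p_int, partial = NULL,
         full_model = full, reduced_model = reduced)
  }
}

#' Project neuropsychological scores onto rotated factor loadings
#'
#' Standardizes each test column across the sample (mean 0, SD 1) and
#' multiplies by the loadings matrix, yielding one composite score per
#' rotated component (e.g., speed, memory, crystallized intelligence,
#' fluency). The loadings are treated as fixed weights estimated on an
#' external reference sample.
#'
#' @param scores Data frame or matrix, participants x tests; column names
#'   must match the loadings' row names (order-insensitive).
#' @param loadings Matrix or data frame, tests x components, with row and
#'   column names.
#' @return Matrix, participants x components.
#' @export
apply_factor_loadings <- function(scores, loadings) {
  scores <- as.matrix(scores)
  loadings <- as.matrix(loadings)
  stopifnot(nrow(scores) >= 2)
  if (!is.null(rownames(loadings)) && !is.null(colnames(scores))) {
    if (!setequal(colnames(scores), rownames(loadings))) {
      stop("score columns do not match loadings rows", call. = FALSE)
    }
    scores <- scores[, rownames(loadings), drop = FALSE]
  } else if (ncol(scores) != nrow(loadings)) {
    stop("score columns do not match loadings rows", call. = FALSE)
  }
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance test column(s): ",
         paste(colnames(scores)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scale(scores) %*% loadings
}

#' Read a factor-loadings table
#'
#' Reads a labeled delimited table of rotated factor loadings (tests in rows,
#' components in columns). The packaged default is a varimax-rotated
#' four-component solution over a standard neuropsychological battery,
#' estimated on an external reference sample.
#'
#' @param path Path to a tab-separated file with row labels in the first
#'   column; defaults to the packaged table.
#' @return Numeric matrix with test row names and component column names.
#' @export
read_factor_loadings <- function(path = system.file("extdata",
                                                    "neuropsych_factor_loadings.tsv",
                                                    package = "dediffr")) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
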