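#' Behavioral outcome parameters for the synthetic cohort
#'
#' Probabilities governing simulated test-phase memory judgments and
#' study-phase vividness ratings / reaction times. Hit and source-accuracy
#' probabilities are per image category; the false-alarm, don't-know and
#' invalid-response probabilities apply across categories.
#'
#' @param p_hit Named probabilities `c(face=, scene=)` that a studied word is
#'   endorsed Old at test.
#' @param p_fa Probability that a new word is endorsed Old.
#' @param p_source_correct Named probabilities `c(face=, scene=)` that a
#'   recognized old word receives the correct source judgment.
#' @param p_dk Probability that a recognized old word receives a Don't know
#'   source response. Within each category, `p_source_correct + p_dk <= 1`;
#'   the remainder is the wrong source.
#' @param vividness_dist List with elements `source_correct` and `other`, each
#'   a probability triplet over ratings 1..3 for study trials conditioned on
#'   the trial's subsequent source-memory outcome.
#' @param rt_median_ms Median reaction time in ms (log-normal law).
#' @param rt_log_sd Standard deviation of log RT.
#' @param p_invalid Probability that a response is invalid (outside the valid
#'   response window or a multiple press).
#'
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(p_hit = c(face = 0.82, scene = 0.81),
                            p_fa = 0.13,
                            p_source_correct = c(face = 0.83, scene = 0.79),
                            p_dk = 0.14,
                            vividness_dist = list(
                              source_correct = c(0.10, 0.38, 0.52),
                              other = c(0.18, 0.50, 0.32)
                            ),
                            rt_median_ms = 2370,
                            rt_log_sd = 0.25,
                            p_invalid = 0.02) {
  bp <- list(
    p_hit = p_hit, p_fa = p_fa, p_source_correct = p_source_correct,
    p_dk = p_dk, vividness_dist = vividness_dist,
    rt_median_ms = rt_median_ms, rt_log_sd = rt_log_sd, p_invalid = p_invalid
  )
  probs <- c(p_hit, p_fa, p_source_correct, p_dk, p_invalid,
             unlist(vividness_dist))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p_source_correct + p_dk > 1 + 1e-12)) {
    stop("p_source_correct + p_dk must not exceed 1", call. = FALSE)
  }
  for (v in vividness_dist) {
    if (length(v) != 3 || abs(sum(v) - 1) > 1e-8) {
      stop("each vividness distribution must be a triplet summing to 1",
           call. = FALSE)
    }
  }
  stopifnot(rt_median_ms > 0, rt_log_sd > 0)
  class(bp) <- "behavior_params"
  bp
}

#' Default behavioral parameters for the younger-adult group
#' @return A [behavior_params()] object.
#' @export
young_behavior_params <- function() {
  behavior_params(
    p_hit = c(face = 0.82, scene = 0.81), p_fa = 0.13,
    p_source_correct = c(face = 0.83, scene = 0.79), p_dk = 0.14,
    vividness_dist = list(source_correct = c(0.10, 0.38, 0.52),
                          other = c(0.18, 0.48, 0.34)),
    rt_median_ms = 2370, rt_log_sd = 0.25, p_invalid = 0.02
  )
}

#' Default behavioral parameters for the older-adult group
#' @return A [behavior_params()] object.
#' @export
older_behavior_params <- function() {
  behavior_params(
    p_hit = c(face = 0.70, scene = 0.66), p_fa = 0.13,
    p_source_correct = c(face = 0.75, scene = 0.68), p_dk = 0.13,
    vividness_dist = list(source_correct = c(0.16, 0.47, 0.37),
                          other = c(0.22, 0.52, 0.26)),
    rt_median_ms = 2250, rt_log_sd = 0.25, p_invalid = 0.02
  )
}

rt_draw <- function(n, bp) {
  stats::rlnorm(n, meanlog = log(bp$rt_median_ms), sdlog = bp$rt_log_sd)
}

#' Simulate behavioral responses for a generated design
#'
#' Fills in test-phase Old/New and source judgments and study-phase vividness
#' ratings and reaction times. For each studied word an Old endorsement is
#' drawn with probability `p_hit[category]`; recognized words then receive a
#' correct source judgment with probability `p_source_correct[category]`, a
#' Don't-know with probability `p_dk`, and the wrong source otherwise. New
#' words are endorsed Old with probability `p_fa`. Study-trial vividness is
#' drawn conditional on the trial's eventual source-memory outcome. A fraction
#' `p_invalid` of responses is made invalid (out-of-window RT or a double
#' press).
#'
#' @param design A design table from [generate_design()].
#' @param bp A [behavior_params()] object, or a named list of one per
#'   participant group when `groups` is given.
#' @param seed Integer seed.
#' @param groups Optional named character vector mapping participant id to
#'   group label; when supplied, `bp` must be a named list of
#'   `behavior_params` keyed by group label, and a `group` column is added.
#'
#' @return The design table with columns `vividness`, `old_new`,
#'   `source_resp`, `rt_ms`, `n_responses`, and `memory_status`
#'   ("source_correct" or "other", study critical trials only) appended.
#' @export
simulate_behavior <- function(design, bp, seed, groups = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  if (!is.null(groups)) {
    stopifnot(is.list(bp), all(groups %in% names(bp)))
    design$group <- unname(groups[design$participant])
  }
  parts <- unique(design$participant)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    d <- design[design$participant == parts[i], ]
    b <- if (is.null(groups)) bp else bp[[groups[[parts[i]]]]]
    stopifnot(inherits(b, "behavior_params"))
    out[[i]] <- simulate_behavior_one(d, b)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

simulate_behavior_one <- function(d, bp) {
  d$vividness <- NA_integer_
  d$old_new <- NA_character_
  d$source_resp <- NA_character_
  d$rt_ms <- NA_real_
  d$n_responses <- 0L
  d$memory_status <- NA_character_

  is_test <- d$phase == "test"
  old_idx <- which(is_test & d$trial_type == "critical")
  new_idx <- which(is_test & d$trial_type == "new")

  ## test: old trials
  cat_old <- d$category[old_idx]
  hit <- stats::runif(length(old_idx)) < bp$p_hit[cat_old]
  d$old_new[old_idx] <- ifelse(hit, "old", "new")
  src <- rep(NA_character_, length(old_idx))
  u <- stats::runif(length(old_idx))
  p_sc <- bp$p_source_correct[cat_old]
  wrong_of <- c(face = "scene", scene = "face")
  src[hit & u < p_sc] <- cat_old[hit & u < p_sc]
  dk <- hit & u >= p_sc & u < p_sc + bp$p_dk
  src[dk] <- "dk"
  wrong <- hit & u >= p_sc + bp$p_dk
  src[wrong] <- wrong_of[cat_old[wrong]]
  d$source_resp[old_idx] <- src

  ## test: new trials
  fa <- stats::runif(length(new_idx)) < bp$p_fa
  d$old_new[new_idx] <- ifelse(fa, "old", "new")
  # false alarms attract an arbitrary source judgment
  fa_src <- sample(c("face", "scene", "dk"), sum(fa), replace = TRUE)
  d$source_resp[new_idx[fa]] <- fa_src

  resp_idx <- c(old_idx, new_idx)
  d$rt_ms[resp_idx] <- rt_draw(length(resp_idx), bp)
  d$n_responses[resp_idx] <- 1L

  ## invalid test responses
  inv <- resp_idx[stats::runif(length(resp_idx)) < bp$p_invalid]
  d[inv, ] <- invalidate(d[inv, , drop = FALSE])

  ## study: vividness conditioned on eventual source outcome
  study_idx <- which(d$phase == "study" & d$trial_type == "critical")
  test_rows <- d[old_idx, ]
  test_valid <- filter_test_trials(test_rows)
  sc_words <- test_rows$word_id[
    test_valid & test_rows$old_new == "old" &
      !is.na(test_rows$source_resp) &
      test_rows$source_resp == test_rows$category
  ]
  status <- ifelse(d$word_id[study_idx] %in% sc_words, "source_correct",
                   "other")
  d$memory_status[study_idx] <- status
  for (st in c("source_correct", "other")) {
    idx <- study_idx[status == st]
    d$vividness[idx] <- sample(1:3, length(idx), replace = TRUE,
                               prob = bp$vividness_dist[[st]])
  }
  d$rt_ms[study_idx] <- rt_draw(length(study_idx), bp)
  d$n_responses[study_idx] <- 1L
  inv <- study_idx[stats::runif(length(study_idx)) < bp$p_invalid]
  d[inv, ] <- invalidate(d[inv, , drop = FALSE])
  d
}

# Make responses invalid: half get an out-of-window RT, half a double press.
invalidate <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  mode <- sample(c("early", "double"), nrow(rows), replace = TRUE)
  rows$rt_ms[mode == "early"] <- stats::runif(sum(mode == "early"), 100, 440)
  rows$n_responses[mode == "double"] <- 2L
  rows
}
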