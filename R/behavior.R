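#' Validity filter for study-phase responses
#'
#' A study trial is valid when it attracted exactly one response whose
#' reaction time falls inside the response window (450-4500 ms poststimulus,
#' endpoints inclusive). Trials with no response, multiple responses, or
#' out-of-window responses are invalid.
#'
#' @param records Data frame with columns `rt_ms` and `n_responses`.
#' @param window_ms Length-2 numeric, inclusive window bounds in ms.
#' @return Logical validity mask, one element per row.
#' @export
filter_study_trials <- function(records, window_ms = c(450, 4500)) {
  valid_response_mask(records, window_ms)
}

#' Validity filter for test-phase responses
#'
#' As [filter_study_trials()] but with the test-phase window
#' (500-4500 ms poststimulus, endpoints inclusive).
#'
#' @inheritParams filter_study_trials
#' @return Logical validity mask.
#' @export
filter_test_trials <- function(records, window_ms = c(500, 4500)) {
  valid_response_mask(records, window_ms)
}

valid_response_mask <- function(records, window_ms) {
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2])
  n_resp <- records$n_responses
  if (is.null(n_resp)) n_resp <- rep(1L, nrow(records))
  rt <- records$rt_ms
  !is.na(rt) & n_resp == 1L & rt >= window_ms[1] & rt <= window_ms[2]
}

#' Item-recognition counts
#'
#' @param n_old,n_new Numbers of old (studied) and new test words with valid
#'   responses.
#' @param hits Old words endorsed Old (regardless of the source judgment).
#' @param false_alarms New words endorsed Old.
#' @return An object of class `item_counts`.
#' @export
item_counts <- function(n_old, n_new, hits, false_alarms) {
  stopifnot(hits <= n_old, false_alarms <= n_new, hits >= 0,
            false_alarms >= 0)
  structure(list(n_old = n_old, n_new = n_new, hits = hits,
                 false_alarms = false_alarms), class = "item_counts")
}

#' Source-judgment counts
#'
#' @param n_recognized_old Old words correctly endorsed Old with a valid
#'   response (the denominator of the source proportions).
#' @param source_hits Recognized words with a correct source judgment.
#' @param source_dk Recognized words receiving a Don't-know source response.
#' @return An object of class `source_counts`.
#' @export
source_counts <- function(n_recognized_old, source_hits, source_dk) {
  stopifnot(source_hits >= 0, source_dk >= 0,
            source_hits + source_dk <= n_recognized_old)
  structure(list(n_recognized_old = n_recognized_old,
                 source_hits = source_hits, source_dk = source_dk),
            class = "source_counts")
}

#' Item recognition score (pR)
#'
#' Item memory as the difference between the hit rate and the false-alarm
#' rate: `hits / n_old - false_alarms / n_new`.
#'
#' @param counts An [item_counts()] object.
#' @return Numeric in \[-1, 1\].
#' @export
score_item_memory <- function(counts) {
  stopifnot(inherits(counts, "item_counts"))
  if (counts$n_old == 0 || counts$n_new == 0) {
    stop("item memory requires old and new trials", call. = FALSE)
  }
  counts$hits / counts$n_old - counts$false_alarms / counts$n_new
}

#' Source memory score (pSR) under the single high-threshold model
#'
#' Estimates the probability of source recollection from the proportions of
#' correctly recognized items receiving a correct source judgment (h) and a
#' Don't-know response (k), correcting source hits for guessing between the
#' two categories:
#'
#'   `pSR = (h - 0.5 * (1 - k)) / (1 - 0.5 * (1 - k))`.
#'
#' Don't-know responses remove trials from the guessing pool; the metric is
#' computed collapsed across image categories.
#'
#' @param counts A [source_counts()] object.
#' @return Numeric `<= 1`; equals 1 only when every non-Don't-know source
#'   response is correct, 0 when source judgments are at chance.
#' @export
score_source_memory <- function(counts) {
  stopifnot(inherits(counts, "source_counts"))
  if (counts$n_recognized_old == 0) {
    stop("participant unscorable: no correctly recognized old trials",
         call. = FALSE)
  }
  h <- counts$source_hits / counts$n_recognized_old
  k <- counts$source_dk / counts$n_recognized_old
  (h - 0.5 * (1 - k)) / (1 - 0.5 * (1 - k))
}

#' Apply the source-memory exclusion rule
#'
#' Retains participants whose probability of source recollection reaches the
#' pre-determined cutoff; `psr < cutoff` excludes (strict inequality).
#'
#' @param psr_by_participant Named numeric vector of pSR scores.
#' @param cutoff Exclusion cutoff (default 0.1).
#' @return Character vector of retained participant ids.
#' @export
exclude_participants <- function(psr_by_participant, cutoff = 0.1) {
  as.character(names(which(psr_by_participant >= cutoff)))
}

#' Score item and source memory for every participant
#'
#' Applies the test-phase validity filter, tallies item-recognition counts per
#' image category and source-judgment counts collapsed across categories, and
#' computes pR per category plus pSR per participant. False-alarm rates are
#' category-unspecific (new words carry no image category).
#'
#' @param records Test-phase rows of a design table that has been through
#'   [simulate_behavior()] (or real data in the same dialect): columns
#'   `participant`, `trial_type` (`"critical"`/`"new"`), `category`,
#'   `old_new`, `source_resp`, `rt_ms`, `n_responses`.
#' @param window_ms Valid-response window passed to [filter_test_trials()].
#' @return Data frame with one row per participant: hit rates and pR per
#'   category, the false-alarm rate, source proportions, and `psr` (`NA` when
#'   unscorable).
#' @export
score_memory_performance <- function(records, window_ms = c(500, 4500)) {
  d <- records[records$phase == "test", ]
  d <- d[d$trial_type %in% c("critical", "new"), ]
  d$valid <- filter_test_trials(d, window_ms)
  parts <- unique(d$participant)
  rows <- lapply(parts, function(pid) {
    dd <- d[d$participant == pid & d$valid, ]
    new_tr <- dd[dd$trial_type == "new", ]
    fa_rate <- if (nrow(new_tr) > 0) {
      mean(new_tr$old_new == "old")
    } else {
      NA_real_
    }
    out <- list(participant = pid, fa_rate = fa_rate)
    rec_all <- 0L; sh_all <- 0L; dk_all <- 0L
    for (cat_lab in c("face", "scene")) {
      old_tr <- dd[dd$trial_type == "critical" & dd$category == cat_lab, ]
      hits <- sum(old_tr$old_new == "old")
      out[[paste0("hit_rate_", cat_lab)]] <-
        if (nrow(old_tr)) hits / nrow(old_tr) else NA_real_
      out[[paste0("item_pr_", cat_lab)]] <-
        if (nrow(old_tr) && !is.na(fa_rate)) {
          score_item_memory(item_counts(nrow(old_tr), nrow(new_tr), hits,
                                        sum(new_tr$old_new == "old")))
        } else {
          NA_real_
        }
      rec <- old_tr[old_tr$old_new == "old", ]
      rec_all <- rec_all + nrow(rec)
      sh_all <- sh_all + sum(rec$source_resp == cat_lab, na.rm = TRUE)
      dk_all <- dk_all + sum(rec$source_resp == "dk", na.rm = TRUE)
    }
    out$n_recognized_old <- rec_all
    out$p_source_correct <- if (rec_all) sh_all / rec_all else NA_real_
    out$p_source_dk <- if (rec_all) dk_all / rec_all else NA_real_
    out$psr <- if (rec_all) {
      score_source_memory(source_counts(rec_all, sh_all, dk_all))
    } else {
      NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Study-phase behavior binned by subsequent memory
#'
#' Summarizes valid study trials per participant, image category, and
#' subsequent-memory bin (source-correct versus everything else: wrong or
#' Don't-know source, item misses, and invalid test responses): the median
#' reaction time to the vividness rating and the mean vividness. Empty cells
#' yield `NA` (flagged missing, never zero).
#'
#' @param records Study-phase rows of a behavior-simulated design table (or
#'   real data in the same dialect) carrying `memory_status`, `vividness`,
#'   `rt_ms`, `n_responses`.
#' @param window_ms Valid-response window passed to [filter_study_trials()].
#' @return Data frame: `participant`, `category`, `memory_bin`, `n_trials`,
#'   `median_rt_ms`, `mean_vividness`.
#' @export
summarize_study_behavior <- function(records, window_ms = c(450, 4500)) {
  d <- records[records$phase == "study" & records$trial_type == "critical", ]
  d$valid <- filter_study_trials(d, window_ms)
  d <- d[d$valid, ]
  grid <- expand.grid(participant = unique(records$participant),
                      category = c("face", "scene"),
                      memory_bin = c("source_correct", "other"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    dd <- d[d$participant == g$participant & d$category == g$category &
              d$memory_status == g$memory_bin, ]
    data.frame(
      participant = g$participant, category = g$category,
      memory_bin = g$memory_bin, n_trials = nrow(dd),
      median_rt_ms = if (nrow(dd)) stats::median(dd$rt_ms) else NA_real_,
      mean_vividness = if (nrow(dd)) mean(dd$vividness) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
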