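#' Parameters of the associative-encoding experimental design
#'
#' Bundles the structural constants of the two-cycle face/scene
#' associative-encoding experiment: each participant completes two study-test
#' cycles, each cycle comprising two study blocks (sub-lists) of 48 critical
#' word-image pairs (half paired with a face, half with a scene) interspersed
#' with 24 null trials, followed by test sub-lists containing the studied
#' words, new words, and null trials. Study and test lists are pseudorandomized
#' so that no more than `max_category_run` consecutive trials share an image
#' class and no more than `max_null_run` null trials occur in a row.
#'
#' @param n_cycles Number of study-test cycles (default 2).
#' @param blocks_per_cycle Study blocks (= scanning sessions) per cycle.
#' @param critical_per_block Critical word-image pairs per study block; must be
#'   even (half face, half scene).
#' @param null_per_sublist Null (fixation) trials per study or test sub-list.
#' @param new_words_per_test_sublist Unstudied lure words per test sub-list.
#' @param fixation_ms,stim_ms,iti_ms Trial timing in milliseconds: red fixation
#'   preceding the stimulus, stimulus duration, and white-fixation ITI.
#' @param max_category_run Maximum run of consecutive trials of the same image
#'   class.
#' @param max_null_run Maximum run of consecutive null trials.
#' @param fillers_per_segment Non-analyzed filler trials inserted at the start
#'   of each half-session segment (session start and immediately after the
#'   mid-session rest break).
#' @param rest_break_s Duration in seconds of the rest period midway through
#'   each scanning session.
#' @param tr_s Repetition time of the EPI sequence in seconds.
#' @param retry_budget Maximum rejection-sampling attempts per list before
#'   giving up on the run-length constraints.
#'
#' @return An object of class `design_params` (a validated list).
#' @export
design_params <- function(n_cycles = 2L,
                          blocks_per_cycle = 2L,
                          critical_per_block = 48L,
                          null_per_sublist = 24L,
                          new_words_per_test_sublist = 24L,
                          fixation_ms = 500,
                          stim_ms = 2000,
                          iti_ms = 2000,
                          max_category_run = 3L,
                          max_null_run = 2L,
                          fillers_per_segment = 2L,
                          rest_break_s = 30,
                          tr_s = 2.0,
                          retry_budget = 1000L) {
  p <- list(
    n_cycles = as.integer(n_cycles),
    blocks_per_cycle = as.integer(blocks_per_cycle),
    critical_per_block = as.integer(critical_per_block),
    null_per_sublist = as.integer(null_per_sublist),
    new_words_per_test_sublist = as.integer(new_words_per_test_sublist),
    categories = c("face", "scene"),
    fixation_ms = fixation_ms,
    stim_ms = stim_ms,
    iti_ms = iti_ms,
    max_category_run = as.integer(max_category_run),
    max_null_run = as.integer(max_null_run),
    fillers_per_segment = as.integer(fillers_per_segment),
    rest_break_s = rest_break_s,
    tr_s = tr_s,
    retry_budget = as.integer(retry_budget)
  )
  stopifnot(
    p$n_cycles >= 1L, p$blocks_per_cycle >= 1L,
    p$critical_per_block >= 2L, p$critical_per_block %% 2L == 0L,
    p$null_per_sublist >= 0L, p$new_words_per_test_sublist >= 0L,
    p$max_category_run >= 1L, p$max_null_run >= 1L,
    p$fixation_ms > 0, p$stim_ms > 0, p$iti_ms > 0, p$tr_s > 0,
    p$fillers_per_segment >= 0L, p$retry_budget >= 1L
  )
  class(p) <- "design_params"
  p
}

# Longest run of TRUE in a logical vector
longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

# Rejection-sample an ordering of `symbols` such that runs of the same image
# class never exceed max_cat and runs of "null" never exceed max_null.
# `class_of` maps each symbol to its image class ("null" handled separately).
sample_list_order <- function(symbols, class_of, max_cat, max_null,
                              retry_budget, what) {
  n <- length(symbols)
  for (attempt in seq_len(retry_budget)) {
    ord <- sample.int(n)
    s <- symbols[ord]
    cls <- class_of[s]
    ok <- longest_run(cls == "null") <= max_null
    if (ok) {
      for (cat_lab in setdiff(unique(cls), "null")) {
        if (longest_run(cls == cat_lab) > max_cat) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) return(ord)
  }
  stop(sprintf(
    "could not find a constraint-satisfying order for %s within %d attempts",
    what, retry_budget
  ), call. = FALSE)
}

#' Generate study and test lists for a synthetic cohort
#'
#' Produces one row per trial for every participant: study sub-lists with
#' pseudorandomized critical (face/scene) and null trials, and yoked test
#' sub-lists containing the studied words of the paired study sub-list plus
#' new words and null trials. Word and image identifiers are assigned without
#' replacement from participant-specific pools; run-length constraints are
#' enforced on every list by rejection sampling.
#'
#' @param params A [design_params()] object.
#' @param n_participants Number of participants to generate.
#' @param seed Integer seed; the output is a deterministic function of
#'   (`params`, `n_participants`, `seed`).
#' @param participant_ids Optional character vector of ids (length
#'   `n_participants`); defaults to `sub01`, `sub02`, ...
#'
#' @return A data frame with one row per trial and columns `participant`,
#'   `phase` ("study"/"test"), `cycle`, `sublist` (1-based sub-list index,
#'   equal to the scanning session within phase), `session`, `slot` (position
#'   within the list), `onset` (seconds from session start), `duration`
#'   (stimulus duration, seconds), `trial_type` ("critical", "filler", "null",
#'   "new"), `category` ("face", "scene", "none"), `word_id`, `image_id`.
#' @export
generate_design <- function(params = design_params(), n_participants = 1L,
                            seed, participant_ids = NULL) {
  stopifnot(inherits(params, "design_params"), n_participants >= 1L)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(participant_ids)) {
    participant_ids <- sprintf("sub%02d", seq_len(n_participants))
  }
  stopifnot(length(participant_ids) == n_participants)
  set.seed(as.integer(seed))
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    out[[i]] <- generate_one_participant(params, participant_ids[[i]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

generate_one_participant <- function(p, pid) {
  n_sublists <- p$n_cycles * p$blocks_per_cycle
  per_cat <- p$critical_per_block %/% 2L
  n_study_words <- n_sublists * p$critical_per_block
  n_new_words <- n_sublists * p$new_words_per_test_sublist
  word_pool <- sample(sprintf("w%03d", seq_len(n_study_words + n_new_words)))
  face_pool <- sample(sprintf("f%03d", seq_len(n_sublists * per_cat)))
  scene_pool <- sample(sprintf("s%03d", seq_len(n_sublists * per_cat)))

  study_words <- word_pool[seq_len(n_study_words)]
  new_words <- word_pool[n_study_words + seq_len(n_new_words)]

  class_of <- c(face = "face", scene = "scene", null = "null", new = "new")
  rows <- list()
  for (sl in seq_len(n_sublists)) {
    cycle <- (sl - 1L) %/% p$blocks_per_cycle + 1L
    w_idx <- (sl - 1L) * p$critical_per_block + seq_len(p$critical_per_block)
    words <- study_words[w_idx]
    f_idx <- (sl - 1L) * per_cat + seq_len(per_cat)
    faces <- face_pool[f_idx]
    scenes <- scene_pool[f_idx]

    ## study sub-list ----
    symbols <- c(rep("face", per_cat), rep("scene", per_cat),
                 rep("null", p$null_per_sublist))
    ord <- sample_list_order(
      seq_along(symbols),
      stats::setNames(class_of[symbols], seq_along(symbols)),
      p$max_category_run, p$max_null_run, p$retry_budget,
      sprintf("participant %s study sub-list %d", pid, sl)
    )
    seq_cat <- symbols[ord]
    study <- data.frame(
      trial_type = ifelse(seq_cat == "null", "null", "critical"),
      category = ifelse(seq_cat == "null", "none", seq_cat),
      stringsAsFactors = FALSE
    )
    study$word_id <- NA_character_
    study$image_id <- NA_character_
    study$word_id[study$category == "face"] <- words[seq_len(per_cat)]
    study$word_id[study$category == "scene"] <- words[per_cat + seq_len(per_cat)]
    study$image_id[study$category == "face"] <- faces
    study$image_id[study$category == "scene"] <- scenes
    rows[[length(rows) + 1L]] <-
      finish_sublist(study, p, pid, "study", cycle, sl)

    ## test sub-list: studied words of this sub-list + new words + nulls ----
    tsym <- c(study$category[study$trial_type == "critical"],
              rep("new", p$new_words_per_test_sublist),
              rep("null", p$null_per_sublist))
    old_words <- study$word_id[study$trial_type == "critical"]
    nw_idx <- (sl - 1L) * p$new_words_per_test_sublist +
      seq_len(p$new_words_per_test_sublist)
    tword <- c(old_words, new_words[nw_idx],
               rep(NA_character_, p$null_per_sublist))
    ord <- sample_list_order(
      seq_along(tsym),
      stats::setNames(class_of[tsym], seq_along(tsym)),
      p$max_category_run, p$max_null_run, p$retry_budget,
      sprintf("participant %s test sub-list %d", pid, sl)
    )
    test <- data.frame(
      trial_type = ifelse(tsym[ord] == "null", "null",
                          ifelse(tsym[ord] == "new", "new", "critical")),
      category = ifelse(tsym[ord] %in% c("face", "scene"), tsym[ord], "none"),
      word_id = tword[ord],
      image_id = NA_character_,
      stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <-
      finish_sublist(test, p, pid, "test", cycle, sl)
  }
  # row order within a participant: cycle, then phase (study before test),
  # then sub-list — i.e. study 1,2 / test 1,2 / study 3,4 / test 3,4
  res <- do.call(rbind, rows)
  res <- res[order(res$cycle, match(res$phase, c("study", "test")),
                   res$sublist, res$slot), ]
  res
}

# Prepend fillers, insert the mid-session rest break, and lay down timing.
finish_sublist <- function(trials, p, pid, phase, cycle, sl) {
  nf <- p$fillers_per_segment
  half <- ceiling(nrow(trials) / 2)
  make_fillers <- function(k, seg) {
    if (k == 0L) return(trials[0, ])
    data.frame(
      trial_type = "filler",
      category = rep(c("face", "scene"), length.out = k),
      word_id = sprintf("wfill_%s_%d_%d_%d", phase, sl, seg, seq_len(k)),
      image_id = sprintf("ifill_%s_%d_%d_%d", phase, sl, seg, seq_len(k)),
      stringsAsFactors = FALSE
    )
  }
  pre <- make_fillers(nf, 1L)
  post <- make_fillers(nf, 2L)
  full <- rbind(pre, trials[seq_len(half), ], post,
                trials[setdiff(seq_len(nrow(trials)), seq_len(half)), ])
  n <- nrow(full)
  slot_s <- (p$fixation_ms + p$stim_ms + p$iti_ms) / 1000
  # rest break begins after the first segment (pre-fillers + first half)
  break_after <- nf + half
  slot_start <- (seq_len(n) - 1L) * slot_s +
    ifelse(seq_len(n) > break_after, p$rest_break_s, 0)
  full$participant <- pid
  full$phase <- phase
  full$cycle <- cycle
  full$sublist <- sl
  full$session <- sl
  full$slot <- seq_len(n)
  full$onset <- slot_start + p$fixation_ms / 1000
  full$duration <- p$stim_ms / 1000
  full[, c("participant", "phase", "cycle", "sublist", "session", "slot",
           "onset", "duration", "trial_type", "category", "word_id",
           "image_id")]
}

#' Check run-length and count constraints of a generated design
#'
#' Verifies, for every participant and list, the pseudorandomization
#' constraints (no more than `max_category_run` consecutive trials of the same
#' image class, no more than `max_null_run` consecutive null trials), strict
#' onset ordering, and the per-list trial counts implied by the parameters.
#'
#' @param design A design table from [generate_design()].
#' @param params The [design_params()] used to generate it.
#' @return Invisibly `TRUE`; aborts with a message naming the offending list
#'   otherwise.
#' @export
check_design_constraints <- function(design, params = design_params()) {
  per_cat <- params$critical_per_block %/% 2L
  sp <- split(design, list(design$participant, design$phase, design$sublist),
              drop = TRUE)
  for (d in sp) {
    d <- d[order(d$slot), ]
    who <- sprintf("%s %s sub-list %d", d$participant[1], d$phase[1],
                   d$sublist[1])
    if (any(diff(d$onset) <= 0)) {
      stop("onsets not strictly increasing in ", who, call. = FALSE)
    }
    core <- d[d$trial_type != "filler", ]
    cls <- ifelse(core$trial_type == "null", "null",
                  ifelse(core$trial_type == "new", "new", core$category))
    if (longest_run(cls == "null") > params$max_null_run) {
      stop("null-run constraint violated in ", who, call. = FALSE)
    }
    for (lab in setdiff(unique(cls), "null")) {
      if (longest_run(cls == lab) > params$max_category_run) {
        stop("category-run constraint violated in ", who, call. = FALSE)
      }
    }
    if (d$phase[1] == "study") {
      if (sum(core$category == "face") != per_cat ||
          sum(core$category == "scene") != per_cat) {
        stop("category counts wrong in ", who, call. = FALSE)
      }
    }
    if (sum(core$trial_type == "null") != params$null_per_sublist) {
      stop("null count wrong in ", who, call. = FALSE)
    }
  }
  invisible(TRUE)
}
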