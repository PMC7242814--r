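#' Pattern-reliability weight for a target within-category correlation
#'
#' Converts a target expected voxel-pattern correlation between two trials of
#' the same category into the corresponding kappa weight of the generative
#' model in [neural_params()]: with a unit-norm template spread over
#' `n_voxels` voxels and i.i.d. noise of SD `sigma`, two same-category trials
#' correlate (in expectation, across voxels) at
#' `r = kappa^2 / (kappa^2 + n_voxels * sigma^2)`.
#'
#' @param r Target correlation in \[0, 1).
#' @param n_voxels Number of voxels.
#' @param sigma Trial-noise SD per voxel.
#' @return Numeric kappa.
#' @export
kappa_from_reliability <- function(r, n_voxels, sigma) {
  stopifnot(r >= 0, r < 1, n_voxels >= 2, sigma > 0)
  sqrt(r / (1 - r) * n_voxels) * sigma
}

#' Default run configuration for the synthetic replication
#'
#' The packaged study conditions: two groups of 24 participants (younger,
#' older), the standard two-cycle design, group-specific behavioral
#' parameters, and four category-selective ROIs with bilateral voxel counts
#' (OFA 122, FFA 44, PPA 468, RSC 379). The older group's scene-selective
#' ROIs implement dedifferentiation as attenuation of the preferred-category
#' amplitude and pattern reliability plus broadening of the non-preferred
#' amplitude; face-selective parameters are identical across groups.
#'
#' @param n_per_group Participants per group (default 24).
#' @param seed Master integer seed (mandatory for a run).
#' @param rois Character subset of `c("PPA", "RSC", "FFA", "OFA")`.
#' @param within_scope Pattern-similarity scope (see
#'   [within_between_similarity()]).
#' @param memory_conditioning Also compute source-correct-only variants?
#' @param epsilon_method Nonsphericity correction for ANOVAs (`"GG"`/`"HF"`).
#' @param psr_cutoff Source-memory exclusion cutoff (default 0.1).
#' @param min_bin_trials Minimum study-trial count per category x
#'   subsequent-memory bin; participants below it in any bin are excluded
#'   (default 10, the conventional floor for a critical memory bin).
#' @return An object of class `run_config`.
#' @export
default_run_config <- function(n_per_group = 24L, seed = 1L,
                               rois = c("PPA", "RSC", "FFA", "OFA"),
                               within_scope = "both_categories",
                               memory_conditioning = TRUE,
                               epsilon_method = "GG",
                               psr_cutoff = 0.1,
                               min_bin_trials = 10L) {
  rois <- match.arg(rois, c("PPA", "RSC", "FFA", "OFA"), several.ok = TRUE)
  sig <- 10
  k <- function(r, nv) kappa_from_reliability(r, nv, sig)
  neural <- list(
    PPA = list(
      young = neural_params("PPA", "scene", 468,
                            amp = c(face = 0.08, scene = 1.00),
                            kappa = c(face = k(.05, 468), scene = k(.20, 468)),
                            sigma = sig, amp_sd = 0.2, kappa_sd = 15),
      older = neural_params("PPA", "scene", 468,
                            amp = c(face = 0.25, scene = 0.75),
                            kappa = c(face = k(.05, 468), scene = k(.10, 468)),
                            sigma = sig, amp_sd = 0.2, kappa_sd = 15)
    ),
    RSC = list(
      young = neural_params("RSC", "scene", 379,
                            amp = c(face = 0.10, scene = 0.70),
                            kappa = c(face = k(.04, 379), scene = k(.12, 379)),
                            sigma = sig, amp_sd = 0.2, kappa_sd = 12),
      older = neural_params("RSC", "scene", 379,
                            amp = c(face = 0.22, scene = 0.55),
                            kappa = c(face = k(.04, 379), scene = k(.07, 379)),
                            sigma = sig, amp_sd = 0.2, kappa_sd = 12)
    ),
    FFA = list(
      young = neural_params("FFA", "face", 44,
                            amp = c(face = 1.40, scene = 0.20),
                            kappa = c(face = k(.12, 44), scene = k(.04, 44)),
                            sigma = sig, amp_sd = 0.25, kappa_sd = 6),
      older = neural_params("FFA", "face", 44,
                            amp = c(face = 1.40, scene = 0.20),
                            kappa = c(face = k(.12, 44), scene = k(.04, 44)),
                            sigma = sig, amp_sd = 0.25, kappa_sd = 6)
    ),
    OFA = list(
      young = neural_params("OFA", "face", 122,
                            amp = c(face = 1.00, scene = 0.10),
                            kappa = c(face = k(.10, 122), scene = k(.04, 122)),
                            sigma = sig, amp_sd = 0.2, kappa_sd = 8),
      older = neural_params("OFA", "face", 122,
                            amp = c(face = 1.00, scene = 0.10),
                            kappa = c(face = k(.10, 122), scene = k(.04, 122)),
                            sigma = sig, amp_sd = 0.2, kappa_sd = 8)
    )
  )
  cfg <- list(
    design = design_params(),
    n_per_group = as.integer(n_per_group),
    groups = c("young", "older"),
    behavior = list(young = young_behavior_params(),
                    older = older_behavior_params()),
    neural = neural[rois],
    within_scope = within_scope,
    memory_conditioning = isTRUE(memory_conditioning),
    epsilon_method = epsilon_method,
    psr_cutoff = psr_cutoff,
    min_bin_trials = as.integer(min_bin_trials),
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

stage_seeds <- function(master, n = 10L) {
  # per-stage seeds derived from the master seed by a fixed splitting rule:
  # seed the generator with the master and draw one sub-seed per stage
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max, n)
}

#' Run the end-to-end synthetic replication
#'
#' Generates a cohort under the configured study conditions and runs the full
#' analysis graph: design generation, behavioral simulation, memory scoring
#' with the source-memory exclusion rule, study-phase summaries, trial-wise
#' beta simulation per ROI, differentiation indices (with memory-conditioned
#' variants), the category-mean beta decomposition, within-minus-between
#' pattern similarity, and the inferential battery (group Welch t tests with
#' Cohen's d, mixed ANOVAs with nonsphericity-corrected degrees of freedom,
#' and interaction-screened partial correlations between neural indices and
#' memory performance). Fully deterministic given `config$seed`.
#'
#' @param config A [default_run_config()]-style `run_config`.
#' @param out_dir Optional output directory; when given, every result table
#'   is written as CSV alongside a machine-readable JSON run manifest.
#' @return Named list of result tables (see Details in the vignette).
#' @export
run_synthetic_study <- function(config = default_run_config(seed = 1L),
                                out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed)
  n <- config$n_per_group
  ids <- c(sprintf("y%02d", seq_len(n)), sprintf("o%02d", seq_len(n)))
  groups <- stats::setNames(rep(config$groups, each = n), ids)

  design <- generate_design(config$design, length(ids), seed = seeds[1],
                            participant_ids = ids)
  behav <- simulate_behavior(design, config$behavior, seed = seeds[2],
                             groups = groups)

  memory <- score_memory_performance(behav)
  memory$group <- unname(groups[memory$participant])
  memory$item_pr <- rowMeans(memory[, c("item_pr_face", "item_pr_scene")])
  retained <- exclude_participants(
    stats::setNames(memory$psr, memory$participant), config$psr_cutoff
  )
  if (config$memory_conditioning) {
    # participants lacking enough study trials in any category x memory bin
    # cannot support conditioned indices and are excluded from the sample
    st <- behav[behav$phase == "study" & behav$trial_type == "critical", ]
    bins <- table(st$participant, st$category, st$memory_status)
    min_bin <- apply(bins, 1, min)
    retained <- intersect(retained,
                          names(min_bin)[min_bin >= config$min_bin_trials])
  }
  memory$retained <- memory$participant %in% retained

  study_summary <- summarize_study_behavior(behav)
  study_summary$group <- unname(groups[study_summary$participant])

  ## neural simulation + indices, retained participants only
  kept_behav <- behav[behav$participant %in% retained, ]
  di_rows <- list(); sim_rows <- list(); mb_rows <- list()
  roi_seed <- seeds[3]
  for (roi_name in names(config$neural)) {
    for (g in config$groups) {
      gp <- intersect(names(groups)[groups == g], retained)
      if (length(gp) == 0L) next
      bms <- simulate_betas(
        kept_behav[kept_behav$participant %in% gp, ],
        config$neural[[roi_name]][[g]],
        seed = (roi_seed + match(roi_name, names(config$neural)) * 131L +
                  match(g, config$groups)) %% .Machine$integer.max
      )
      for (pid in names(bms)) {
        bm <- bms[[pid]]
        conds <- "all_trials"
        if (config$memory_conditioning) {
          conds <- c(conds, "source_correct_only")
        }
        for (cond in conds) {
          di <- differentiation_index(bm, condition = cond)
          di$participant <- pid; di$group <- g
          di_rows[[length(di_rows) + 1L]] <- di
          sim <- if (cond == "all_trials") {
            within_between_similarity(bm, config$within_scope)
          } else {
            memory_conditioned_similarity(bm, "source_correct",
                                          config$within_scope)
          }
          sim$participant <- pid; sim$group <- g
          sim_rows[[length(sim_rows) + 1L]] <- sim
        }
        mb <- mean_category_betas(bm)
        mb_rows[[length(mb_rows) + 1L]] <- data.frame(
          participant = pid, group = g, roi = roi_name,
          category = names(mb), mean_beta = unname(mb),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  di_table <- do.call(rbind, di_rows)
  sim_table <- do.call(rbind, sim_rows)
  mean_beta_table <- do.call(rbind, mb_rows)
  rownames(di_table) <- rownames(sim_table) <-
    rownames(mean_beta_table) <- NULL

  stats_out <- pipeline_stats(config, memory, di_table, sim_table,
                              mean_beta_table)

  out <- c(list(
    design = design, behavior = behav, memory_scores = memory,
    study_summary = study_summary, di_table = di_table,
    similarity_table = sim_table, mean_beta_table = mean_beta_table,
    retained = retained
  ), stats_out)

  if (!is.null(out_dir)) write_run_outputs(out, config, out_dir)
  out
}

pipeline_stats <- function(config, memory, di_table, sim_table,
                           mean_beta_table) {
  eps <- config$epsilon_method
  mem <- memory[memory$retained, ]
  split_groups <- function(v, g) list(young = v[g == "young"],
                                      older = v[g == "older"])

  ## group comparisons on memory scores
  sg <- split_groups(mem$psr, mem$group)
  psr_test <- cbind(measure = "psr", welch_t(sg$young, sg$older))
  item_long <- rbind(
    data.frame(participant = mem$participant, group = mem$group,
               category = "face", item_pr = mem$item_pr_face),
    data.frame(participant = mem$participant, group = mem$group,
               category = "scene", item_pr = mem$item_pr_scene)
  )
  item_anova <- mixed_anova(item_long, dv = "item_pr", between = "group",
                            within = "category", subject = "participant",
                            correction = eps)

  ## DI and similarity: per-ROI Welch tests and group x ROI ANOVAs
  neural_tests <- function(tab, value_col) {
    tests <- list(); anovas <- list()
    for (cond in unique(tab$condition)) {
      tc <- tab[tab$condition == cond, ]
      for (r in unique(tc$roi)) {
        tr <- tc[tc$roi == r, ]
        w <- welch_t(tr[[value_col]][tr$group == "young"],
                     tr[[value_col]][tr$group == "older"])
        tests[[length(tests) + 1L]] <- cbind(
          data.frame(roi = r, condition = cond), w
        )
      }
      if (length(unique(tc$roi)) >= 2) {
        av <- mixed_anova(tc, dv = value_col, between = "group",
                          within = "roi", subject = "participant",
                          correction = eps)
        anovas[[length(anovas) + 1L]] <- cbind(
          data.frame(condition = cond), av
        )
      }
    }
    list(tests = do.call(rbind, tests), anova = do.call(rbind, anovas))
  }
  di_stats <- neural_tests(di_table, "di")
  sim_stats <- neural_tests(sim_table, "index")

  ## attenuation/broadening decomposition: group x ROI x category ANOVAs
  beta_anovas <- list()
  for (pref in c("scene", "face")) {
    rois <- names(config$neural)[vapply(config$neural, function(x) {
      x[[1]]$preferred == pref
    }, logical(1))]
    if (length(rois) >= 2) {
      mb <- mean_beta_table[mean_beta_table$roi %in% rois, ]
      av <- mixed_anova(mb, dv = "mean_beta", between = "group",
                        within = c("roi", "category"),
                        subject = "participant", correction = eps)
      beta_anovas[[length(beta_anovas) + 1L]] <- cbind(
        data.frame(roi_class = paste0(pref, "_selective")), av
      )
    }
  }

  ## interaction-screened partial correlations: neural index vs memory
  pc_rows <- list()
  for (cond in unique(di_table$condition)) {
    tc <- di_table[di_table$condition == cond, ]
    for (r in unique(tc$roi)) {
      tr <- tc[tc$roi == r, ]
      m <- mem[match(tr$participant, mem$participant), ]
      for (meas in c("item_pr", "psr")) {
        scr <- interaction_screen_regression(m[[meas]], tr$di, tr$group)
        pr <- if (is.null(scr$partial)) {
          data.frame(statistic = NA_real_, df = NA_real_, p = NA_real_,
                     effect_size = NA_real_)
        } else {
          scr$partial
        }
        pc_rows[[length(pc_rows) + 1L]] <- cbind(
          data.frame(roi = r, condition = cond, measure = meas,
                     model_kept = scr$model_kept,
                     interaction_p = scr$interaction_p), pr
        )
      }
    }
  }
  partial_correlations <- do.call(rbind, pc_rows)
  rownames(partial_correlations) <- NULL

  list(
    psr_test = psr_test,
    item_anova = item_anova,
    di_group_tests = di_stats$tests,
    di_anova = di_stats$anova,
    similarity_group_tests = sim_stats$tests,
    similarity_anova = sim_stats$anova,
    beta_decomposition_anova = do.call(rbind, beta_anovas),
    partial_correlations = partial_correlations
  )
}

write_run_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("memory_scores", "study_summary", "di_table",
              "similarity_table", "mean_beta_table", "psr_test",
              "item_anova", "di_group_tests", "di_anova",
              "similarity_group_tests", "similarity_anova",
              "beta_decomposition_anova", "partial_correlations")
  for (tb in tables) {
    utils::write.csv(out[[tb]], file.path(out_dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  write_events_tsv(out$behavior, file.path(out_dir, "events.tsv"))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(serialize_config(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    seed = config$seed,
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_per_group = config$n_per_group,
    retained = out$retained,
    package_version = as.character(utils::packageVersion("dediffr")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# strip S3 classes recursively so the config serializes as plain JSON
serialize_config <- function(config) {
  if (is.list(config)) {
    lapply(unclass(config), serialize_config)
  } else {
    config
  }
}
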