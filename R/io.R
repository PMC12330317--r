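.TRIAL_COLUMNS <- c("participant", "group", "session", "block_label",
                    "trial_index", "target_type", "start_x", "start_y",
                    "target_x", "target_y", "visual_offset",
                    "vcue_x", "vcue_y", "endpoint_x", "endpoint_y")

#' Write a trial table to CSV
#'
#' One row per trial, header row, '.' decimal, UTF-8; the format read back by
#' [read_trials()].
#'
#' @param trials Trial data frame (as from [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- intersect(.TRIAL_COLUMNS, names(trials))
  utils::write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads and validates a per-trial endpoint table: column presence, numeric
#' coordinates, known target types, and uniqueness plus within-block
#' monotonicity of trial indices. Errors name the offending column or row.
#'
#' @param path CSV file with a header row.
#' @return Typed data frame of trials (mm units).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "block_label", "trial_index", "target_type",
                "target_x", "target_y", "endpoint_x", "endpoint_y")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  num_cols <- intersect(c("trial_index", "start_x", "start_y", "target_x",
                          "target_y", "visual_offset", "vcue_x", "vcue_y",
                          "endpoint_x", "endpoint_y"), names(df))
  for (cl in num_cols) {
    v <- df[[cl]]
    coerced <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(coerced))
    if (length(bad))
      stop("non-numeric value in column '", cl, "' at row ", bad[1])
    df[[cl]] <- coerced
  }
  bad_type <- which(!df$target_type %in% c("V", "P", "VP"))
  if (length(bad_type))
    stop("unknown target_type at row ", bad_type[1])
  if (!("session" %in% names(df))) df$session <- "session1"
  if (!("group" %in% names(df))) df$group <- "all"
  key <- paste(df$participant, df$session, df$block_label, df$trial_index)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (participant, block, trial_index) at row ", dup[1])
  blk <- paste(df$participant, df$session, df$block_label)
  for (b in unique(blk)) {
    ti <- df$trial_index[blk == b]
    if (is.unsorted(ti))
      stop("trial_index not monotone within block: ", b)
  }
  df
}

#' Pipeline run configuration
#'
#' Assembles a validated configuration for [run_pipeline()]: the cohort
#' simulation settings plus analysis options. Unknown arguments are rejected.
#'
#' @param experiment `"expt1"`, `"expt2"`, or `"control"`.
#' @param seed Master seed.
#' @param n_per_group Participants per group (experiment default when `NULL`).
#' @param mep_window MEP analysis window, ms post-stimulus.
#' @param wv_min_valid Minimum valid per-trial weightings for a block mean.
#' @param ... Further arguments passed to [cohort_config()].
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(experiment = "expt1", seed = 0L,
                            n_per_group = NULL,
                            mep_window = c(15, 60), wv_min_valid = 3L, ...) {
  extra <- list(...)
  allowed <- setdiff(names(formals(cohort_config)),
                     c("experiment", "n_per_group", "seed"))
  unknown <- setdiff(names(extra), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cc <- do.call(cohort_config,
                c(list(experiment = experiment, n_per_group = n_per_group,
                       seed = seed), extra))
  structure(list(cohort = cc, mep_window = mep_window,
                 wv_min_valid = wv_min_valid),
            class = "run_config")
}

#' Run the full simulate-estimate-analyse pipeline
#'
#' Simulates a cohort, computes the behavioural estimates (and, for the
#' two-session experiment, the SAI measures), runs the experiment's
#' statistical analyses, and writes all intermediate CSVs plus a
#' machine-readable JSON summary and a log echoing the configuration and
#' master seed. Outputs are bit-identical across runs for a fixed
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `trials`, `estimates`, `sai` tables and
#'   the `summary` list written to JSON.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  result <- tryCatch({
    cohort <- simulate_cohort(config$cohort)
    write_trials(cohort$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(cohort$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    stage <- "estimate"
    est <- estimate_cohort(cohort$trials)
    utils::write.csv(est, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    if (!is.null(cohort$sai))
      utils::write.csv(cohort$sai, file.path(out_dir, "sai.csv"),
                       row.names = FALSE)
    stage <- "analyze"
    summ <- switch(config$cohort$experiment,
      expt1   = .analyze_expt1(est, cohort$sai, out_dir),
      expt2   = .analyze_expt2(est, out_dir),
      control = .analyze_control(est))
    summ$experiment <- config$cohort$experiment
    summ$seed <- config$cohort$seed
    summ$n_participants <- nrow(cohort$truth[!duplicated(cohort$truth$participant), ])
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("vpalign pipeline run: experiment=%s seed=%s",
              config$cohort$experiment, config$cohort$seed),
      sprintf("n_per_group=%d", config$cohort$n_per_group),
      utils::capture.output(utils::str(config$cohort))),
      file.path(out_dir, "run.log"))
    list(trials = cohort$trials, estimates = est, sai = cohort$sai,
         summary = summ)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

.tr <- function(x) {
  list(statistic = x$statistic, df = x$df, p = x$p,
       effect_size = x$effect_size, method = x$method)
}

.analyze_expt1 <- function(est, sai, out_dir) {
  conf <- est[est$block_label == "conflict", ]
  fit <- fit_sai_recalibration_model(sai)
  resid_p <- predictor_residuals(
    sai[sai$session == "conflict", ], "recal_p", "recal_v")
  utils::write.csv(resid_p, file.path(out_dir, "predictor_residuals_p.csv"),
                   row.names = FALSE)
  # session x time ANOVA on SAI
  long <- rbind(
    data.frame(participant = sai$participant, a = sai$session, b = "pre",
               value = sai$sai_pre),
    data.frame(participant = sai$participant, a = sai$session, b = "post",
               value = sai$sai_post))
  an <- rm_anova_2x2(long)
  utils::write.csv(fit$terms, file.path(out_dir, "model_terms.csv"),
                   row.names = FALSE)
  list(
    model = list(terms = fit$terms, vif = as.list(fit$vif),
                 converged = fit$converged,
                 n_participants = fit$n_participants,
                 n_observations = fit$n_observations),
    anova_session_time = lapply(an, .tr),
    recal_correlation = .tr(pearson_r(conf$recal_p_y, conf$recal_v_y)),
    mean_recal_p = mean(conf$recal_p_y),
    mean_recal_v = mean(conf$recal_v_y))
}

.analyze_expt2 <- function(est, out_dir) {
  v1 <- est[est$block_label == "veridical1", ]
  v2 <- est[est$block_label == "veridical2", ]
  cf <- est[est$block_label == "conflict", ]
  stopifnot(all(v1$participant == v2$participant))
  groups <- v1$group
  d_var_p <- v2$raw_var_p - v1$raw_var_p
  d_var_v <- v2$raw_var_v - v1$raw_var_v
  d_wv <- v2$w_v - v1$w_v
  ok_wv <- !is.na(d_wv)
  list(
    delta_p_variance = .tr(group_comparison(d_var_p, groups, "anova_tukey")),
    delta_v_variance = .tr(group_comparison(d_var_v, groups,
                                            "kruskal_wallis")),
    delta_weighting = .tr(group_comparison(d_wv[ok_wv], groups[ok_wv],
                                           "anova_tukey")),
    recal_p = .tr(group_comparison(cf$recal_p_y, cf$group, "anova_tukey")),
    recal_v = .tr(group_comparison(cf$recal_v_y, cf$group, "anova_tukey")),
    recal_total = .tr(group_comparison(cf$recal_total_y, cf$group,
                                       "anova_tukey")))
}

.analyze_control <- function(est) {
  sh <- est[est$block_label == "vshift_control", ]
  list(visual_recalibration_t = .tr(one_sample_t(sh$recal_v_y, mu0 = 0)),
       mean_visual_recalibration = mean(sh$recal_v_y))
}
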