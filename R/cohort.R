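#' Cohort simulation configuration
#'
#' Bundles everything needed to simulate a study cohort: the experiment
#' layout, group sizes, the distributions participant-level observer
#' parameters are drawn from, post-stimulation group effects, and the
#' coupling of the SAI change to behavioural recalibration.
#'
#' @param experiment `"expt1"` (two sessions: cue conflict and veridical,
#'   each a 40-trial baseline plus an 84-trial second block, with pre/post
#'   SAI), `"expt2"` (three blocks: veridical 1, veridical 2, conflict, with
#'   inhibitory stimulation between the veridical blocks), or `"control"`
#'   (veridical training block plus an 84-trial visual-shift block of V
#'   trials only).
#' @param n_per_group Participants per group (expt2 has groups S1, M1, Sham;
#'   the other experiments have a single group).
#' @param seed Master seed; all per-participant streams derive from it.
#' @param sigma_p_mean,sigma_p_sd,sigma_v_mean,sigma_v_sd Participant-level
#'   sensory noise SD distributions (mm; truncated normal, floor
#'   `sigma_floor`). Defaults put baseline 2D endpoint variances in the
#'   50--92 mm^2 range typical of this task.
#' @param sigma_floor Lower truncation bound for drawn SDs (mm).
#' @param eta_mean,eta_sd Recalibration-rate distribution (truncated to
#'   \[0.005, 0.5\]).
#' @param w_v_jitter_sd SD of the individual deviation of the visual weight
#'   from the minimum-variance prediction (truncated so weights stay in
#'   \[0.05, 0.95\]). Real observers' weights scatter around the
#'   reliability-derived value; this scatter also produces the inverse
#'   relationship between visual and proprioceptive recalibration seen
#'   across participants.
#' @param bias_sd SD of each baseline bias component (mm).
#' @param group_effects Named list mapping group to post-stimulation
#'   multipliers `list(sigma_p = ..., eta = ...)`. Defaults: S1 increases
#'   proprioceptive noise (x1.3) and recalibration rate (x1.4); M1 and Sham
#'   are unaffected.
#' @param sai_coupling List with `intercept` (%), `slope_p`, `slope_v`
#'   (%/mm), `noise_sd` (%): the SAI change (post/pre x 100) generated in the
#'   cue-conflict session is
#'   `intercept + slope_p * recal_P + slope_v * recal_V + noise`; the
#'   veridical session uses the intercept plus noise only.
#' @param sai_pre_mean Mean baseline SAI (% of unconditioned MEP).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(experiment = c("expt1", "expt2", "control"),
                          n_per_group = NULL,
                          seed = 0L,
                          sigma_p_mean = 8, sigma_p_sd = 2,
                          sigma_v_mean = 10.5, sigma_v_sd = 2.5,
                          sigma_floor = 3,
                          eta_mean = 0.08, eta_sd = 0.015,
                          w_v_jitter_sd = 0.25,
                          bias_sd = 6,
                          group_effects = list(
                            S1   = list(sigma_p = 1.3, eta = 1.4),
                            M1   = list(sigma_p = 1.0, eta = 1.0),
                            Sham = list(sigma_p = 1.0, eta = 1.0)),
                          sai_coupling = list(intercept = 105.94,
                                              slope_p = 1.80, slope_v = 0,
                                              noise_sd = 15),
                          sai_pre_mean = 58.5) {
  experiment <- match.arg(experiment)
  if (is.null(n_per_group)) {
    n_per_group <- switch(experiment, expt1 = 22L, expt2 = 27L,
                          control = 18L)
  }
  stopifnot(n_per_group >= 1)
  for (g in group_effects) {
    stopifnot(g$sigma_p > 0, g$eta > 0)
  }
  structure(list(experiment = experiment, n_per_group = as.integer(n_per_group),
                 seed = seed,
                 sigma_p_mean = sigma_p_mean, sigma_p_sd = sigma_p_sd,
                 sigma_v_mean = sigma_v_mean, sigma_v_sd = sigma_v_sd,
                 sigma_floor = sigma_floor,
                 eta_mean = eta_mean, eta_sd = eta_sd,
                 w_v_jitter_sd = w_v_jitter_sd, bias_sd = bias_sd,
                 group_effects = group_effects, sai_coupling = sai_coupling,
                 sai_pre_mean = sai_pre_mean),
            class = "cohort_config")
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

.draw_participant_params <- function(config) {
  sp <- .rtrunc_norm(1, config$sigma_p_mean, config$sigma_p_sd,
                     config$sigma_floor)
  sv <- .rtrunc_norm(1, config$sigma_v_mean, config$sigma_v_sd,
                     config$sigma_floor)
  eta <- .rtrunc_norm(1, config$eta_mean, config$eta_sd, 0.005, 0.5)
  # Baseline biases: opposite-signed y components keep the unimodal clouds
  # separated, as real observers' systematic V/P biases do.
  bp <- stats::rnorm(2, c(0, 5), config$bias_sd)
  bv <- stats::rnorm(2, c(0, 5), config$bias_sd)
  w_mv <- sp^2 / (sp^2 + sv^2)
  w <- .rtrunc_norm(1, w_mv, config$w_v_jitter_sd, 0.05, 0.95)
  observer_params(sigma_p = sp, sigma_v = sv, sigma_m = sp,
                  w_v = w, eta = eta, b_p0 = bp, b_v0 = bv)
}

.scale_params <- function(params, mult) {
  observer_params(sigma_p = params$sigma_p * mult$sigma_p,
                  sigma_v = params$sigma_v,
                  sigma_m = params$sigma_m,       # indicator hand unaffected
                  w_v = params$w_v,               # weight fixed at baseline
                  eta = min(params$eta * mult$eta, 1),
                  b_p0 = params$b_p0, b_v0 = params$b_v0)
}

#' Simulate a study cohort
#'
#' Draws participant-level observer parameters, builds the block schedules of
#' the requested experiment, simulates every trial, and (for the two-session
#' experiment) generates synthetic pre/post MEP traces whose SAI change is
#' coupled to the participant's expressed recalibration.
#'
#' @param config A [cohort_config()].
#' @param traces If `TRUE` (default) the two-session experiment also returns
#'   raw synthetic MEP traces; set `FALSE` to return only the realized SAI
#'   summary (faster).
#' @return A list of class `cohort_sim` with elements
#'   \item{trials}{data frame of all simulated trials (one row per trial,
#'     with `participant`, `group`, `session`, endpoints and ground-truth
#'     running biases),}
#'   \item{truth}{per-participant ground-truth parameter table,}
#'   \item{sai}{for `expt1`: per participant x session realized SAI summary
#'     (and traces when requested); otherwise `NULL`,}
#'   \item{config}{the configuration used.}
#' @export
simulate_cohort <- function(config, traces = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  local_rng(config$seed)
  groups <- if (config$experiment == "expt2") c("S1", "M1", "Sham") else "all"
  ids <- seq_len(config$n_per_group * length(groups))
  group_of <- rep(groups, each = config$n_per_group)
  pseeds <- sample.int(.Machine$integer.max - 1L, length(ids))

  trial_rows <- vector("list", length(ids))
  truth_rows <- vector("list", length(ids))
  sai_rows <- vector("list", length(ids))
  trace_store <- if (traces) vector("list", length(ids)) else NULL

  for (i in ids) {
    local_rng(pseeds[i])
    par <- .draw_participant_params(config)
    res <- switch(config$experiment,
      expt1   = .simulate_expt1_participant(i, par, config),
      expt2   = .simulate_expt2_participant(i, par, config, group_of[i]),
      control = .simulate_control_participant(i, par, config))
    trial_rows[[i]] <- res$trials
    truth_rows[[i]] <- res$truth
    if (!is.null(res$sai)) sai_rows[[i]] <- res$sai
    if (traces && !is.null(res$traces)) trace_store[[i]] <- res$traces
  }
  out <- list(trials = do.call(rbind, trial_rows),
              truth = do.call(rbind, truth_rows),
              sai = if (length(sai_rows) && !is.null(sai_rows[[1]]))
                do.call(rbind, sai_rows) else NULL,
              traces = trace_store,
              config = config)
  rownames(out$trials) <- NULL
  rownames(out$truth) <- NULL
  class(out) <- "cohort_sim"
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> experiment '%s': %d participants, %d trials\n",
              x$config$experiment, nrow(x$truth), nrow(x$trials)))
  invisible(x)
}

.truth_row <- function(id, group, par, session, terminal) {
  data.frame(participant = id, group = group, session = session,
             sigma_p = par$sigma_p, sigma_v = par$sigma_v,
             sigma_m = par$sigma_m, w_v = par$w_v, eta = par$eta,
             b_p0_y = par$b_p0[2], b_v0_y = par$b_v0[2],
             term_b_p_y = terminal$b_p[2] - par$b_p0[2],
             term_b_v_y = terminal$b_v[2] - par$b_v0[2],
             stringsAsFactors = FALSE)
}

# Expressed recalibration from simulated endpoints in the 84-trial block,
# computed exactly as the behavioural estimators do (y, target-relative).
.session_recal <- function(block_df, total_shift) {
  p <- block_df[block_df$target_type == "P", ]
  v <- block_df[block_df$target_type == "V", ]
  list(recal_p = recalibration_p(p$endpoint_y - p$target_y),
       recal_v = recalibration_v(v$endpoint_y - v$target_y,
                                 total_shift = total_shift))
}

.simulate_expt1_participant <- function(id, par, config) {
  s <- sample.int(.Machine$integer.max - 1L, 6)
  sessions <- list(
    conflict = list(
      build_baseline_block("expt1_baseline", seed = s[1]),
      build_conflict_block(seed = s[2], block_label = "conflict")),
    veridical = list(
      build_baseline_block("expt1_baseline", seed = s[3]),
      build_conflict_block(seed = s[4], max_offset = 0,
                           block_label = "veridical2")))
  rows <- list(); truth <- list(); sai <- list()
  tr <- list()
  k <- 0
  for (sess in names(sessions)) {
    k <- k + 1
    df <- simulate_session(sessions[[sess]], par, seed = s[4 + k])
    term <- attr(df, "terminal")[[2]]
    df <- cbind(participant = id, group = "all", session = sess, df)
    rows[[sess]] <- df
    truth[[sess]] <- .truth_row(id, "all", par, sess, term)
    # SAI change coupled to the expressed recalibration (conflict only)
    blk <- df[df$block_label %in% c("conflict", "veridical2"), ]
    rec <- .session_recal(blk, total_shift = if (sess == "conflict") 70 else 0)
    cp <- config$sai_coupling
    target_dsai <- cp$intercept +
      (if (sess == "conflict") cp$slope_p * rec$recal_p +
                               cp$slope_v * rec$recal_v else 0) +
      stats::rnorm(1, 0, cp$noise_sd)
    target_dsai <- max(target_dsai, 1)   # SAI change is a positive ratio
    sim <- simulate_sai(delta_sai = target_dsai,
                        sai_pre = config$sai_pre_mean)
    m <- sai_from_traces(sim$traces)
    sai[[sess]] <- data.frame(participant = id, session = sess,
                              recal_p = rec$recal_p, recal_v = rec$recal_v,
                              sai_pre = m$sai_pre, sai_post = m$sai_post,
                              delta_sai = m$delta_sai,
                              generative_delta_sai = target_dsai,
                              stringsAsFactors = FALSE)
    tr[[sess]] <- sim$traces
  }
  list(trials = do.call(rbind, rows), truth = do.call(rbind, truth),
       sai = do.call(rbind, sai), traces = tr)
}

.simulate_expt2_participant <- function(id, par, config, group) {
  eff <- config$group_effects[[group]]
  if (is.null(eff)) stop("unknown group label '", group, "'")
  s <- sample.int(.Machine$integer.max - 1L, 6)
  ver1 <- build_baseline_block("expt2_veridical", seed = s[1],
                               block_label = "veridical1")
  ver2 <- build_baseline_block("expt2_veridical", seed = s[2],
                               block_label = "veridical2")
  conf <- build_conflict_block(seed = s[3], block_label = "conflict")
  par_post <- .scale_params(par, eff)     # cTBS effects apply after ver1
  d1 <- simulate_session(list(ver1), par, seed = s[4])
  d2 <- simulate_session(list(ver2), par_post, seed = s[5])
  d3 <- simulate_session(list(conf), par_post, seed = s[6])
  term <- attr(d3, "terminal")[[1]]
  df <- rbind(d1, d2, d3)
  df <- cbind(participant = id, group = group, session = "expt2", df)
  truth <- .truth_row(id, group, par, "expt2", term)
  truth$sigma_p_post <- par_post$sigma_p
  truth$eta_post <- par_post$eta
  list(trials = df, truth = truth, sai = NULL, traces = NULL)
}

.simulate_control_participant <- function(id, par, config) {
  s <- sample.int(.Machine$integer.max - 1L, 4)
  train <- build_baseline_block("expt2_veridical", seed = s[1],
                                block_label = "veridical1")
  shift <- build_vshift_block(seed = s[2])
  # V-only block: endpoints track the cue; no VP trials so no recalibration.
  d1 <- simulate_session(list(train), par, seed = s[3])
  d2 <- simulate_session(list(shift), par, seed = s[4])
  term <- attr(d2, "terminal")[[1]]
  df <- rbind(d1, d2)
  df <- cbind(participant = id, group = "all", session = "control", df)
  truth <- .truth_row(id, "all", par, "control", term)
  list(trials = df, truth = truth, sai = NULL, traces = NULL)
}

# ---------------------------------------------------------------------------
# Synthetic SAI neurophysiology

# Deterministic MEP template: damped sinusoid starting at the stimulus
# artifact offset, unit peak-to-peak within the analysis window.
.mep_template <- function(n_samples, rate, onset_s = 0.020,
                          freq = 80, damp = 60) {
  t <- seq(0, by = 1 / rate, length.out = n_samples)
  shape <- ifelse(t > onset_s,
                  sin(2 * pi * freq * (t - onset_s)) *
                    exp(-damp * (t - onset_s)),
                  0)
  shape / (max(shape) - min(shape))
}

#' Simulate pre/post MEP traces with a specified SAI change
#'
#' Generates 20 conditioned and 20 unconditioned motor-evoked-potential
#' traces per timepoint (pre and post), sampled at 5,000 Hz, as
#' damped-sinusoid MEP shapes. Unconditioned peak-to-peak amplitudes average
#' 1 mV; conditioned amplitudes are scaled so that the realized SAI change
#' (post/pre x 100, computed by [sai_from_traces()]) equals `delta_sai`
#' exactly when `trace_noise_sd = 0`.
#'
#' @param delta_sai Target SAI change, percent (post/pre x 100).
#' @param sai_pre Baseline SAI, percent of the unconditioned MEP.
#' @param n_cond,n_uncond Trace counts per timepoint (must be positive).
#' @param rate Sampling rate (samples/s).
#' @param duration Trace duration (s).
#' @param trace_noise_sd Baseline EMG noise SD (mV) added to every sample.
#' @param amp_jitter Multiplicative trial-to-trial amplitude jitter SD;
#'   jitters are renormalized to mean 1 within each condition so the
#'   ratio-of-means is preserved.
#' @return A list with `traces` (data frame: `timepoint`, `condition`,
#'   `trial`, then sample columns `s1..sN`) and the generative `delta_sai`.
#' @export
simulate_sai <- function(delta_sai, sai_pre = 58.5,
                         n_cond = 20, n_uncond = 20,
                         rate = 5000, duration = 0.1,
                         trace_noise_sd = 0.01, amp_jitter = 0.15) {
  if (n_cond <= 0 || n_uncond <= 0) stop("trace counts must be positive")
  stopifnot(is.finite(delta_sai), delta_sai > 0, sai_pre > 0)
  n_samples <- round(rate * duration)
  template <- .mep_template(n_samples, rate)
  sai_post <- sai_pre * delta_sai / 100

  make <- function(timepoint, condition, n, mean_amp) {
    jit <- stats::rnorm(n, 1, amp_jitter)
    jit <- pmax(jit, 0.1)
    jit <- jit / mean(jit)                 # mean amplitude exact
    amps <- mean_amp * jit
    tr <- outer(amps, template)            # n x n_samples
    tr <- tr + matrix(stats::rnorm(length(tr), 0, trace_noise_sd), nrow = n)
    df <- data.frame(timepoint = timepoint, condition = condition,
                     trial = seq_len(n), stringsAsFactors = FALSE)
    cbind(df, as.data.frame(tr, col.names = paste0("s", seq_len(n_samples))))
  }
  traces <- rbind(
    make("pre",  "unconditioned", n_uncond, 1.0),
    make("pre",  "conditioned",   n_cond,   sai_pre / 100),
    make("post", "unconditioned", n_uncond, 1.0),
    make("post", "conditioned",   n_cond,   sai_post / 100))
  names(traces)[-(1:3)] <- paste0("s", seq_len(n_samples))
  attr(traces, "rate") <- rate
  list(traces = traces, delta_sai = delta_sai,
       sai_pre = sai_pre, sai_post = sai_post)
}

# ---------------------------------------------------------------------------
# Grating orientation test (tactile acuity staircase)

#' Simulate the adaptive grating orientation test
#'
#' Runs the two-alternative (vertical/horizontal) adaptive procedure over the
#' standard dome set. Testing starts at 3 mm; six consecutive correct reports
#' pass a width and move to the next smaller dome, any incorrect report moves
#' to the next larger dome. The returned threshold is the smallest grating
#' width passed with six consecutive correct reports (the floor width if the
#' observer never errs; `Inf` if even the largest dome is never passed).
#'
#' A report is correct with probability
#' `0.5 + (0.5 - lapse) * pnorm((width - true_threshold) / spread)`,
#' chance level 0.5 for the two-alternative judgement.
#'
#' @param true_threshold Observer's true threshold (mm), within the dome range.
#' @param lapse Lapse rate in \[0, 0.5).
#' @param seed Integer seed.
#' @param domes Dome grating widths (mm), ascending.
#' @param start Starting grating width (mm; must be in `domes`).
#' @param spread Psychometric spread (mm); default a tenth of the threshold.
#' @return Observed threshold (mm).
#' @export
simulate_got <- function(true_threshold, lapse = 0.02, seed = 0L,
                         domes = c(0.35, 0.5, 0.75, 1.0, 1.2, 1.5, 2, 3, 4, 5),
                         start = 3, spread = 0.1 * true_threshold) {
  if (!length(domes)) stop("empty dome set")
  stopifnot(lapse >= 0, lapse < 0.5)
  domes <- sort(domes)
  local_rng(seed)
  p_correct <- function(w) {
    0.5 + (0.5 - lapse) * stats::pnorm((w - true_threshold) / max(spread, 1e-9))
  }
  i <- match(start, domes)
  if (is.na(i)) stop("starting width not in the dome set")
  passed <- rep(FALSE, length(domes))
  for (step in seq_len(200L)) {
    # one run at width i: pass on 6 consecutive correct, fail on first miss
    ok <- TRUE
    for (t in 1:6) {
      if (stats::runif(1) > p_correct(domes[i])) { ok <- FALSE; break }
    }
    if (ok) {
      passed[i] <- TRUE
      if (i == 1L) return(domes[1])        # floor reached
      i <- i - 1L
    } else {
      if (i == length(domes)) {
        if (any(passed)) return(domes[which(passed)[1]])
        return(Inf)                        # never passed any width
      }
      if (passed[i + 1L]) return(domes[i + 1L])
      i <- i + 1L
    }
  }
  smallest <- which(passed)
  if (length(smallest)) domes[smallest[1]] else Inf
}
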