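#' Generative observer parameters
#'
#' Parameters of the minimum-variance cue-combination observer. The observer
#' forms noisy unimodal position estimates (proprioceptive SD `sigma_p`,
#' visual SD `sigma_v`, both per axis), combines them on bimodal trials with
#' visual weight `w_v`, and points with isotropic 2D motor noise `sigma_m`.
#' On bimodal trials a fraction `eta` of the currently perceived cue conflict
#' is absorbed into the modality biases, split `eta * w_v` to proprioception
#' and `eta * (1 - w_v)` to vision, so the lower-weighted modality
#' recalibrates more.
#'
#' @param sigma_p,sigma_v,sigma_m Noise SDs in mm (non-negative).
#' @param w_v Visual weight in \[0, 1\]; if `NULL` (default) derived as
#'   `sigma_p^2 / (sigma_p^2 + sigma_v^2)`, the minimum-variance weight.
#' @param eta Per-bimodal-trial recalibration rate in \[0, 1\].
#' @param b_p0,b_v0 Baseline constant biases (2-vectors, mm). A positive y
#'   component of `b_p0` makes proprioceptive targets overshot; a positive y
#'   component of `b_v0` makes visual targets undershot.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma_p = 8, sigma_v = 10.5, sigma_m = sigma_p,
                            w_v = NULL, eta = 0.08,
                            b_p0 = c(0, 0), b_v0 = c(0, 0)) {
  stopifnot(sigma_p >= 0, sigma_v >= 0, sigma_m >= 0,
            eta >= 0, eta <= 1,
            length(b_p0) == 2, length(b_v0) == 2)
  if (is.null(w_v)) {
    w_v <- if (sigma_p == 0 && sigma_v == 0) 0.5 else
      sigma_p^2 / (sigma_p^2 + sigma_v^2)
  }
  stopifnot(w_v >= 0, w_v <= 1)
  structure(list(sigma_p = sigma_p, sigma_v = sigma_v, sigma_m = sigma_m,
                 w_v = w_v, eta = eta,
                 b_p0 = as.numeric(b_p0), b_v0 = as.numeric(b_v0)),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> sigma_p=%.2f sigma_v=%.2f sigma_m=%.2f w_v=%.3f eta=%.3f\n",
    x$sigma_p, x$sigma_v, x$sigma_m, x$w_v, x$eta))
  cat(sprintf("  baseline biases: b_p0=(%g, %g)  b_v0=(%g, %g) mm\n",
              x$b_p0[1], x$b_p0[2], x$b_v0[1], x$b_v0[2]))
  invisible(x)
}

#' Observer state (accumulated recalibration biases)
#'
#' @param b_p,b_v Current proprioceptive / visual bias (2-vectors, mm).
#' @return An object of class `observer_state`.
#' @export
observer_state <- function(b_p = c(0, 0), b_v = c(0, 0)) {
  stopifnot(length(b_p) == 2, length(b_v) == 2)
  structure(list(b_p = as.numeric(b_p), b_v = as.numeric(b_v)),
            class = "observer_state")
}

#' Simulate one alignment-task trial
#'
#' Generates the indicator-finger endpoint for a single trial and, on
#' bimodal (VP) trials, updates the observer's recalibration state. Endpoint
#' laws (all noise terms isotropic bivariate normal):
#' \itemize{
#'   \item P trial: `p_target + b_p + eps_p + eps_m`
#'   \item V trial: `v_cue - b_v + eps_v + eps_m`
#'   \item VP trial: `w_v * (v_cue - b_v + eps_v) +
#'     (1 - w_v) * (p_target + b_p + eps_p) + eps_m`
#' }
#' On VP trials the perceived conflict
#' `c = (v_cue - b_v + eps_v) - (p_target + b_p + eps_p)` drives the update
#' `b_p <- b_p + eta * w_v * c`, `b_v <- b_v + eta * (1 - w_v) * c`.
#'
#' @param spec One-row trial specification (a row of a [build_conflict_block()]
#'   style schedule), or a list with fields `target_type`, `target_x`,
#'   `target_y`, `vcue_x`, `vcue_y`.
#' @param params An [observer_params()] object.
#' @param state An [observer_state()] object.
#' @return A list with `endpoint` (2-vector, mm) and `state` (updated
#'   `observer_state`).
#' @export
simulate_trial <- function(spec, params, state = observer_state(params$b_p0,
                                                                params$b_v0)) {
  type <- as.character(spec$target_type)
  p <- c(spec$target_x, spec$target_y)
  v <- c(spec$vcue_x, spec$vcue_y)
  if (type %in% c("P", "VP") && anyNA(p))
    stop("schedule error: P/VP trial without a proprioceptive target")
  if (type %in% c("V", "VP") && anyNA(v))
    stop("schedule error: V/VP trial without a visual cue")
  eps_m <- stats::rnorm(2, 0, params$sigma_m)
  if (type == "P") {
    eps_p <- stats::rnorm(2, 0, params$sigma_p)
    endpoint <- p + state$b_p + eps_p + eps_m
  } else if (type == "V") {
    eps_v <- stats::rnorm(2, 0, params$sigma_v)
    endpoint <- v - state$b_v + eps_v + eps_m
  } else if (type == "VP") {
    eps_p <- stats::rnorm(2, 0, params$sigma_p)
    eps_v <- stats::rnorm(2, 0, params$sigma_v)
    est_v <- v - state$b_v + eps_v
    est_p <- p + state$b_p + eps_p
    endpoint <- params$w_v * est_v + (1 - params$w_v) * est_p + eps_m
    conflict <- est_v - est_p
    state <- observer_state(state$b_p + params$eta * params$w_v * conflict,
                            state$b_v + params$eta * (1 - params$w_v) * conflict)
  } else stop("schedule error: unknown target type '", type, "'")
  list(endpoint = endpoint, state = state)
}

# Fast path used by the cohort simulator: simulate a whole block with plain
# vectors (same laws as simulate_trial). Returns endpoints plus the bias
# trajectory. Assumes the schedule's invariants hold.
.simulate_block_fast <- function(sched, params) {
  n <- nrow(sched)
  type <- sched$target_type
  px <- sched$target_x; py <- sched$target_y
  vx <- sched$vcue_x;   vy <- sched$vcue_y
  eps_p <- matrix(stats::rnorm(2L * n, 0, params$sigma_p), n, 2)
  eps_v <- matrix(stats::rnorm(2L * n, 0, params$sigma_v), n, 2)
  eps_m <- matrix(stats::rnorm(2L * n, 0, params$sigma_m), n, 2)
  w <- params$w_v; eta <- params$eta
  bp <- params$b_p0; bv <- params$b_v0
  ex <- numeric(n); ey <- numeric(n)
  bpy <- numeric(n); bvy <- numeric(n)
  for (i in seq_len(n)) {
    if (type[i] == "P") {
      ex[i] <- px[i] + bp[1] + eps_p[i, 1] + eps_m[i, 1]
      ey[i] <- py[i] + bp[2] + eps_p[i, 2] + eps_m[i, 2]
    } else if (type[i] == "V") {
      ex[i] <- vx[i] - bv[1] + eps_v[i, 1] + eps_m[i, 1]
      ey[i] <- vy[i] - bv[2] + eps_v[i, 2] + eps_m[i, 2]
    } else {
      evx <- vx[i] - bv[1] + eps_v[i, 1]
      evy <- vy[i] - bv[2] + eps_v[i, 2]
      epx <- px[i] + bp[1] + eps_p[i, 1]
      epy <- py[i] + bp[2] + eps_p[i, 2]
      ex[i] <- w * evx + (1 - w) * epx + eps_m[i, 1]
      ey[i] <- w * evy + (1 - w) * epy + eps_m[i, 2]
      cx <- evx - epx; cy <- evy - epy
      bp[1] <- bp[1] + eta * w * cx; bp[2] <- bp[2] + eta * w * cy
      bv[1] <- bv[1] + eta * (1 - w) * cx; bv[2] <- bv[2] + eta * (1 - w) * cy
    }
    bpy[i] <- bp[2]; bvy[i] <- bv[2]
  }
  list(endpoint_x = ex, endpoint_y = ey,
       b_p_y = bpy, b_v_y = bvy,
       terminal_b_p = bp, terminal_b_v = bv)
}

#' Simulate a session of alignment-task blocks
#'
#' Runs the generative observer over an ordered list of block schedules,
#' carrying the recalibration state within each block and resetting it to the
#' baseline biases at the start of every block.
#'
#' @param schedules A single `block_schedule` or a list of them, in session
#'   order.
#' @param params An [observer_params()] object.
#' @param seed Integer seed; output is bit-identical across runs for a fixed
#'   seed.
#' @return A data frame: the schedule rows plus `endpoint_x`, `endpoint_y`
#'   (mm) and the running bias components `b_p_y`, `b_v_y` (generative ground
#'   truth after each trial). Attribute `terminal` holds the terminal biases
#'   per block.
#' @export
simulate_session <- function(schedules, params, seed = 0L) {
  if (inherits(schedules, "block_schedule")) schedules <- list(schedules)
  local_rng(seed)
  out <- vector("list", length(schedules))
  term <- vector("list", length(schedules))
  for (k in seq_along(schedules)) {
    sched <- schedules[[k]]
    sim <- .simulate_block_fast(sched, params)
    df <- as.data.frame(sched)
    df$endpoint_x <- sim$endpoint_x
    df$endpoint_y <- sim$endpoint_y
    df$b_p_y <- sim$b_p_y
    df$b_v_y <- sim$b_v_y
    out[[k]] <- df
    term[[k]] <- list(block_label = df$block_label[1],
                      b_p = sim$terminal_b_p, b_v = sim$terminal_b_v)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "terminal") <- term
  res
}
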