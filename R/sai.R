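#' Peak-to-peak MEP amplitude
#'
#' Maximum minus minimum of an EMG trace within an analysis window after the
#' stimulus (default 15--60 ms, covering the motor evoked potential at
#' typical latencies).
#'
#' @param trace Numeric vector of EMG samples (mV), starting at the stimulus.
#' @param rate Sampling rate (samples/s), default 5000.
#' @param window Two-element numeric, window start and end in ms
#'   post-stimulus.
#' @return Peak-to-peak amplitude in mV.
#' @export
mep_peak_to_peak <- function(trace, rate = 5000, window = c(15, 60)) {
  stopifnot(is.numeric(trace), length(window) == 2, window[1] < window[2],
            rate > 0)
  i0 <- max(1L, floor(window[1] / 1000 * rate) + 1L)
  i1 <- min(length(trace), ceiling(window[2] / 1000 * rate) + 1L)
  if (i0 > i1) stop("empty analysis window for this trace")
  w <- trace[i0:i1]
  max(w) - min(w)
}

#' SAI as a percentage of the unconditioned response
#'
#' Short-latency afferent inhibition expressed as the mean conditioned MEP
#' peak-to-peak amplitude as a percentage of the mean unconditioned
#' amplitude (ratio of means). Values below 100 indicate inhibition by the
#' somatosensory afferent volley.
#'
#' @param conditioned,unconditioned Numeric vectors of peak-to-peak
#'   amplitudes (mV).
#' @return SAI in percent.
#' @export
sai_percent <- function(conditioned, unconditioned) {
  stopifnot(length(conditioned) > 0, length(unconditioned) > 0)
  mu <- mean(unconditioned)
  if (!is.finite(mu) || mu == 0)
    stop("unconditioned mean amplitude must be positive")
  mean(conditioned) / mu * 100
}

#' Change in SAI from pre to post
#'
#' Post-task SAI divided by pre-task SAI, times 100. Values below 100
#' indicate greater inhibition after the task; above 100, less.
#'
#' @param sai_pre,sai_post SAI percentages.
#' @return Change in SAI, percent.
#' @export
delta_sai <- function(sai_pre, sai_post) {
  if (!is.finite(sai_pre) || sai_pre <= 0)
    stop("pre-task SAI must be positive")
  sai_post / sai_pre * 100
}

#' SAI summary from a trace table
#'
#' Computes peak-to-peak amplitudes for every trace, then SAI per timepoint
#' and the pre-to-post change, from a trace table as produced by
#' [simulate_sai()] (columns `timepoint`, `condition`, `trial`, then sample
#' columns).
#'
#' @param traces Trace data frame; sampling rate read from its `rate`
#'   attribute (default 5000 when absent).
#' @param window Analysis window in ms post-stimulus.
#' @return A list of class `sai_measure`: `sai_pre`, `sai_post`, `delta_sai`
#'   (all %), and trace counts per timepoint/condition.
#' @export
sai_from_traces <- function(traces, window = c(15, 60)) {
  stopifnot(is.data.frame(traces),
            all(c("timepoint", "condition") %in% names(traces)))
  rate <- attr(traces, "rate")
  if (is.null(rate)) rate <- 5000
  meta <- c("timepoint", "condition", "trial")
  samp <- as.matrix(traces[, setdiff(names(traces), meta), drop = FALSE])
  p2p <- apply(samp, 1, mep_peak_to_peak, rate = rate, window = window)
  pick <- function(tp, cond) p2p[traces$timepoint == tp &
                                   traces$condition == cond]
  sai_pre <- sai_percent(pick("pre", "conditioned"),
                         pick("pre", "unconditioned"))
  sai_post <- sai_percent(pick("post", "conditioned"),
                          pick("post", "unconditioned"))
  structure(list(
    sai_pre = sai_pre, sai_post = sai_post,
    delta_sai = delta_sai(sai_pre, sai_post),
    n_cond_pre = length(pick("pre", "conditioned")),
    n_uncond_pre = length(pick("pre", "unconditioned")),
    n_cond_post = length(pick("post", "conditioned")),
    n_uncond_post = length(pick("post", "unconditioned"))),
    class = "sai_measure")
}

#' @export
print.sai_measure <- function(x, ...) {
  cat(sprintf(
    "<sai_measure> SAI pre = %.1f%%, post = %.1f%%, change = %.1f%%\n",
    x$sai_pre, x$sai_post, x$delta_sai))
  invisible(x)
}
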