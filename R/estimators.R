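#' Proprioceptive recalibration from P-trial endpoints
#'
#' Recalibration of the felt target position over a block, computed as the
#' mean y-endpoint of the last four proprioceptive trials minus the mean of
#' the first four, relative to any true shift of the target (zero for P
#' targets, whose true position never moves). Positive values indicate
#' overshoot of the proprioceptive target by block end, the direction
#' expected under a forward visual-cue conflict.
#'
#' @param p_endpoints_y Ordered numeric vector of P-trial y endpoints (mm),
#'   in trial order.
#' @param true_shift True change in target y position over the block (mm);
#'   0 for proprioceptive targets.
#' @return Recalibration in mm.
#' @export
recalibration_p <- function(p_endpoints_y, true_shift = 0) {
  y <- as.numeric(p_endpoints_y)
  if (length(y) < 8 || anyNA(y))
    stop("insufficient data: need >= 8 ordered endpoints")
  n <- length(y)
  mean(y[(n - 3):n]) - mean(y[1:4]) - true_shift
}

#' Visual recalibration from V-trial endpoints
#'
#' Recalibration of the seen target position over a conflict block: the total
#' forward cue displacement minus the observed change in V-trial endpoints
#' (mean of last four minus mean of first four). An observer who tracks the
#' shifting cue perfectly scores 0; undershooting the displaced cue yields a
#' positive value (visual recalibration).
#'
#' @param v_endpoints_y Ordered numeric vector of V-trial y endpoints (mm).
#' @param total_shift Total true displacement of the visual cue over the
#'   block (mm); 70 in a conflict block, 0 in a veridical block.
#' @return Recalibration in mm.
#' @export
recalibration_v <- function(v_endpoints_y, total_shift = 70) {
  y <- as.numeric(v_endpoints_y)
  if (length(y) < 8 || anyNA(y))
    stop("insufficient data: need >= 8 ordered endpoints")
  n <- length(y)
  total_shift - (mean(y[(n - 3):n]) - mean(y[1:4]))
}

#' Per-trial visual weighting
#'
#' Weighting of vision versus proprioception for a single bimodal trial,
#' computed from the bimodal endpoint and the centroids of the four nearest
#' unimodal trials per modality:
#' `W_v = |yP - yVP| / (|yP - yVP| + |yV - yVP|)`
#' with 2D Euclidean magnitudes. Values above 0.5 indicate greater reliance
#' on vision. When the two unimodal centroids are closer than half the
#' pooled centroid-distance SD of the contributing endpoints (or both
#' distances are zero) the trial is uninformative and `NA` is returned.
#'
#' @param vp_endpoint Bimodal-trial endpoint (2-vector, mm).
#' @param v_nearest,p_nearest 4 x 2 matrices (or data frames) of the four
#'   nearest unimodal endpoints of each modality.
#' @return `W_v` in \[0, 1\], or `NA` when invalid.
#' @export
per_trial_wv <- function(vp_endpoint, v_nearest, p_nearest) {
  v_nearest <- as.matrix(v_nearest); p_nearest <- as.matrix(p_nearest)
  stopifnot(nrow(v_nearest) == 4, nrow(p_nearest) == 4,
            ncol(v_nearest) == 2, ncol(p_nearest) == 2,
            length(vp_endpoint) == 2)
  cv <- colMeans(v_nearest)
  cp <- colMeans(p_nearest)
  # pooled spread: mean of the two modalities' centroid-distance SDs
  sd_v <- stats::sd(sqrt(colSums((t(v_nearest) - cv)^2)))
  sd_p <- stats::sd(sqrt(colSums((t(p_nearest) - cp)^2)))
  pooled <- mean(c(sd_v, sd_p))
  sep <- sqrt(sum((cv - cp)^2))
  if (sep < 0.5 * pooled) return(NA_real_)
  d_p <- sqrt(sum((cp - vp_endpoint)^2))
  d_v <- sqrt(sum((cv - vp_endpoint)^2))
  if (d_p + d_v == 0) return(NA_real_)
  d_p / (d_p + d_v)
}

#' Block-level visual weighting
#'
#' Computes a per-trial weighting for every bimodal trial of a block,
#' matching each against the four nearest unimodal V and P trials by trial
#' index (ties broken toward the earlier trial), and aggregates. Endpoints
#' are expressed relative to their trial's target before comparison so that
#' trials at different target positions are commensurable. The block mean is
#' defined only when at least `min_valid` per-trial values are valid,
#' mirroring the exclusion of participants whose unimodal endpoint clouds
#' overlap too much.
#'
#' @param trials Data frame of one block's trials with columns
#'   `trial_index`, `target_type`, `endpoint_x`, `endpoint_y`, `target_x`,
#'   `target_y` (and `vcue_x`, `vcue_y` used as the reference on V trials).
#' @param min_valid Minimum number of valid per-trial values for the block
#'   mean to be defined (default 3).
#' @return An object of class `weighting_estimate`: list with `per_trial`
#'   (data frame of `vp_trial_index`, `w_v`), `block_mean` (or `NA`),
#'   `n_valid`.
#' @export
block_wv <- function(trials, min_valid = 3L) {
  stopifnot(is.data.frame(trials))
  vp <- trials[trials$target_type == "VP", , drop = FALSE]
  if (nrow(vp) == 0) stop("insufficient data: block has no VP trials")
  v <- trials[trials$target_type == "V", , drop = FALSE]
  p <- trials[trials$target_type == "P", , drop = FALSE]
  if (nrow(v) < 4 || nrow(p) < 4)
    stop("insufficient data: need >= 4 V and >= 4 P trials")
  rel <- function(df, ref_x, ref_y) {
    cbind(df$endpoint_x - ref_x, df$endpoint_y - ref_y)
  }
  # target-relative endpoints; V trials referenced to the (veridical) cue base
  v_xy <- rel(v, ifelse(is.na(v$target_x), v$vcue_x, v$target_x),
                 ifelse(is.na(v$target_y), v$vcue_y - v$visual_offset,
                        v$target_y))
  p_xy <- rel(p, p$target_x, p$target_y)
  vp_xy <- rel(vp, vp$target_x, vp$target_y)
  nearest4 <- function(idx_pool, idx0) {
    d <- abs(idx_pool - idx0)
    order(d, idx_pool)[1:4]          # ties -> earlier trial
  }
  wv <- vapply(seq_len(nrow(vp)), function(j) {
    iv <- nearest4(v$trial_index, vp$trial_index[j])
    ip <- nearest4(p$trial_index, vp$trial_index[j])
    per_trial_wv(vp_xy[j, ], v_xy[iv, , drop = FALSE],
                 p_xy[ip, , drop = FALSE])
  }, numeric(1))
  n_valid <- sum(!is.na(wv))
  structure(list(
    per_trial = data.frame(vp_trial_index = vp$trial_index, w_v = wv),
    block_mean = if (n_valid >= min_valid) mean(wv, na.rm = TRUE) else NA_real_,
    n_valid = n_valid),
    class = "weighting_estimate")
}

#' @export
print.weighting_estimate <- function(x, ...) {
  cat(sprintf("<weighting_estimate> block mean W_v = %s (n_valid = %d of %d)\n",
              if (is.na(x$block_mean)) "undefined" else
                sprintf("%.3f", x$block_mean),
              x$n_valid, nrow(x$per_trial)))
  invisible(x)
}

#' 2D endpoint variance
#'
#' Variance of a 2D endpoint cloud computed on vector magnitudes: each
#' endpoint is expressed relative to the cloud centroid and the sample
#' variance (n - 1 denominator) of the Euclidean distances is returned. The
#' measure is invariant to translation and rotation of the cloud.
#'
#' @param endpoints n x 2 matrix or data frame of endpoints (mm).
#' @return Variance in mm^2.
#' @export
endpoint_variance_2d <- function(endpoints) {
  m <- as.matrix(endpoints)
  if (nrow(m) < 3 || anyNA(m))
    stop("insufficient data: need >= 3 complete 2D endpoints")
  ctr <- colMeans(m)
  mags <- sqrt(colSums((t(m) - ctr)^2))
  stats::var(mags)
}

#' Indicator-hand variance correction
#'
#' Corrects raw unimodal endpoint variances for the noise contributed by the
#' indicator (reporting) hand, assumed to account for half of the variance
#' seen on proprioceptive-target trials: the corrected proprioceptive
#' variance is `0.5 * raw_P` and the corrected visual variance is
#' `raw_V - 0.5 * raw_P`. A negative corrected visual variance is returned
#' as computed, with a flag, rather than clamped.
#'
#' @param raw_p,raw_v Raw endpoint variances (mm^2, non-negative).
#' @return A list of class `variance_estimate` with `raw_p`, `raw_v`,
#'   `corrected_p`, `corrected_v`, `negative_flag`.
#' @export
corrected_variances <- function(raw_p, raw_v) {
  stopifnot(raw_p >= 0, raw_v >= 0)
  corrected_v <- raw_v - 0.5 * raw_p
  structure(list(raw_p = raw_p, raw_v = raw_v,
                 corrected_p = 0.5 * raw_p,
                 corrected_v = corrected_v,
                 negative_flag = corrected_v < 0),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf(
    "<variance_estimate> raw P=%.2f V=%.2f; corrected P=%.2f V=%.2f%s\n",
    x$raw_p, x$raw_v, x$corrected_p, x$corrected_v,
    if (x$negative_flag) " [negative corrected V]" else ""))
  invisible(x)
}

#' Per-participant behavioural estimates for a simulated or recorded cohort
#'
#' Applies the recalibration, weighting, and variance estimators block by
#' block, reproducing the analysis pipeline of the alignment experiments:
#' recalibration from the 84-trial second block (x and y dimensions),
#' weighting and endpoint variances from veridical blocks.
#'
#' @param trials Trial table as produced by [simulate_cohort()] (columns
#'   `participant`, `group`, `session`, `block_label`, `trial_index`,
#'   `target_type`, targets, `visual_offset`, endpoints).
#' @param conflict_shift Total cue displacement of the conflict block (mm).
#' @return Data frame, one row per participant x block-role, with
#'   recalibration (both dimensions), block W_v, `n_valid`, raw and
#'   corrected variances, and flags.
#' @export
estimate_cohort <- function(trials, conflict_shift = 70) {
  stopifnot(is.data.frame(trials))
  out <- list()
  for (pid in unique(trials$participant)) {
    tp <- trials[trials$participant == pid, ]
    for (sess in unique(tp$session)) {
      ts <- tp[tp$session == sess, ]
      for (bl in unique(ts$block_label)) {
        tb <- ts[ts$block_label == bl, ]
        out[[length(out) + 1L]] <-
          .estimate_block(pid, as.character(tp$group[1]), sess, bl, tb,
                          conflict_shift)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.estimate_block <- function(pid, group, sess, bl, tb, conflict_shift) {
  types <- tb$target_type
  shift <- if (bl %in% c("conflict", "vshift_control") &&
               max(tb$visual_offset) > 0) conflict_shift else 0
  p <- tb[types == "P", ]
  v <- tb[types == "V", ]
  rec_p_y <- rec_p_x <- rec_v_y <- rec_v_x <- NA_real_
  if (nrow(p) >= 8) {
    rec_p_y <- recalibration_p(p$endpoint_y - p$target_y)
    rec_p_x <- recalibration_p(p$endpoint_x - p$target_x)
  }
  if (nrow(v) >= 8) {
    ref_x <- ifelse(is.na(v$target_x), v$vcue_x, v$target_x)
    ref_y <- ifelse(is.na(v$target_y), v$vcue_y - v$visual_offset, v$target_y)
    rec_v_y <- recalibration_v(v$endpoint_y - ref_y, total_shift = shift)
    rec_v_x <- recalibration_v(v$endpoint_x - ref_x, total_shift = 0)
  }
  raw_p <- raw_v <- corr_p <- corr_v <- NA_real_
  neg <- NA
  if (nrow(p) >= 3 && nrow(v) >= 3) {
    raw_p <- endpoint_variance_2d(cbind(p$endpoint_x - p$target_x,
                                        p$endpoint_y - p$target_y))
    vrx <- ifelse(is.na(v$target_x), v$vcue_x, v$target_x)
    vry <- ifelse(is.na(v$target_y), v$vcue_y - v$visual_offset, v$target_y)
    raw_v <- endpoint_variance_2d(cbind(v$endpoint_x - vrx,
                                        v$endpoint_y - vry))
    cv <- corrected_variances(raw_p, raw_v)
    corr_p <- cv$corrected_p; corr_v <- cv$corrected_v
    neg <- cv$negative_flag
  }
  wv_mean <- NA_real_; n_valid <- NA_integer_
  if (sum(types == "VP") > 0 && sum(types == "V") >= 4 &&
      sum(types == "P") >= 4 && max(tb$visual_offset) == 0) {
    w <- block_wv(tb)
    wv_mean <- w$block_mean; n_valid <- w$n_valid
  }
  data.frame(participant = pid, group = group, session = sess,
             block_label = bl,
             recal_p_y = rec_p_y, recal_v_y = rec_v_y,
             recal_p_x = rec_p_x, recal_v_x = rec_v_x,
             recal_total_y = rec_p_y + rec_v_y,
             w_v = wv_mean, n_valid = n_valid,
             raw_var_p = raw_p, raw_var_v = raw_v,
             corrected_var_p = corr_p, corrected_var_v = corr_v,
             negative_var_flag = neg,
             stringsAsFactors = FALSE)
}
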