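# Workspace geometry (mm). Origin at the body midline at the chest edge of
# the workspace; +y away from the body (the conflict dimension), +x to the
# participant's right.
.START_X <- c(-60, -30, 0, 30, 60)
.START_Y <- 200
.MARKERS <- matrix(c(-45, 300,
                     -15, 300), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y")))
.MAX_OFFSET <- 70

#' Start-position / target-position pairs
#'
#' The alignment task presents targets at one of two tactile-marker positions
#' (30 mm apart in x, ~30 cm in front of the body) while the indicator finger
#' starts from one of five positions centred on the body midline, giving 10
#' distinct start-target pairs that require different reach directions and
#' extents.
#'
#' @return A data frame with 10 rows and columns `start_x`, `start_y`,
#'   `target_x`, `target_y` (all mm), the Cartesian product of the five start
#'   positions and two marker positions.
#' @export
#' @examples
#' enumerate_start_target_pairs()
enumerate_start_target_pairs <- function() {
  g <- expand.grid(start = seq_along(.START_X), marker = 1:2,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(
    start_x  = .START_X[g$start],
    start_y  = rep(.START_Y, nrow(g)),
    target_x = .MARKERS[g$marker, "x"],
    target_y = .MARKERS[g$marker, "y"]
  )
}

# Assign a start/target pair to each trial from the seeded stream.
.assign_pairs <- function(n) {
  pairs <- enumerate_start_target_pairs()
  idx <- sample.int(nrow(pairs), n, replace = TRUE)
  pairs[idx, , drop = FALSE]
}

.new_schedule <- function(df, design_name, seed) {
  rownames(df) <- NULL
  structure(df, design_name = design_name, seed = seed,
            class = c("block_schedule", "data.frame"))
}

# Build the trial table common to all block builders. v_cue exists on V and
# VP trials (cue base + forward offset); p_target is the felt marker
# position, absent (NA) where the target hand rests in the lap.
.make_trials <- function(block_label, types, offsets, pairs,
                         p_target_present = TRUE) {
  n <- length(types)
  vx <- ifelse(types == "P", NA_real_, pairs$target_x)
  vy <- ifelse(types == "P", NA_real_, pairs$target_y + offsets)
  data.frame(
    block_label   = rep(block_label, n),
    trial_index   = seq_len(n) - 1L,
    target_type   = types,
    start_x       = pairs$start_x,
    start_y       = pairs$start_y,
    target_x      = if (p_target_present) pairs$target_x else NA_real_,
    target_y      = if (p_target_present) pairs$target_y else NA_real_,
    visual_offset = offsets,
    vcue_x        = vx,
    vcue_y        = vy,
    stringsAsFactors = FALSE
  )
}

#' Build a veridical baseline block
#'
#' Veridical blocks contain 15 V, 15 P and 10 VP trials with the visual cue
#' always on the fingertip (zero offset). The first-session baseline
#' (`expt1_baseline`) pseudorandomizes trial order under the constraint that
#' no target type occurs more than twice in a row; the pre/post-stimulation
#' design (`expt2_veridical`) uses a fixed repeating order so that the two
#' blocks flanking the intervention are structurally identical.
#'
#' @param design `"expt1_baseline"` or `"expt2_veridical"`.
#' @param seed Non-negative integer seed; schedules are bit-identical across
#'   runs for a fixed seed.
#' @param block_label Label stored on each trial (default `"veridical1"`).
#' @return A `block_schedule` (data frame of trial specifications).
#' @export
build_baseline_block <- function(design = c("expt1_baseline", "expt2_veridical"),
                                 seed = 0L, block_label = "veridical1") {
  if (!is.character(design) || !design[1] %in%
        c("expt1_baseline", "expt2_veridical")) {
    stop("unknown design name: ", design[1], call. = FALSE)
  }
  design <- design[1]
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  rng <- local_rng(seed)
  if (design == "expt2_veridical") {
    # 8-trial unit (3 V, 3 P, 2 VP) repeated 5 times: 15 V, 15 P, 10 VP.
    unit <- c("V", "P", "VP", "V", "P", "V", "P", "VP")
    types <- rep(unit, 5)
  } else {
    counts <- c(V = 15L, P = 15L, VP = 10L)
    types <- .pseudorandomize(counts, max_run = 2L)
  }
  pairs <- .assign_pairs(length(types))
  df <- .make_trials(block_label, types, rep(0, length(types)), pairs)
  .new_schedule(df, design, seed)
}

# Rejection-sample a type sequence with no run longer than max_run.
.pseudorandomize <- function(counts, max_run = 2L, max_tries = 10000L) {
  pool <- rep(names(counts), counts)
  for (i in seq_len(max_tries)) {
    s <- sample(pool)
    r <- rle(s)$lengths
    if (max(r) <= max_run) return(s)
  }
  stop("pseudorandomization failed after ", max_tries, " attempts")
}

#' Build a cue-conflict (or matched veridical) 84-trial block
#'
#' The second block of each session has 84 trials in the repeating quartet
#' VP, V, VP, P (42 VP, 21 V, 21 P). In a conflict block the visual cue is
#' displaced forward by 70/42 mm on each successive VP trial, reaching
#' exactly 70 mm on the last VP trial; interleaved V trials carry the current
#' accumulated offset. With `max_offset = 0` the same structure serves as the
#' veridical session's second block.
#'
#' @param seed Integer seed for the start/target pair assignment.
#' @param max_offset Total forward displacement in mm (default 70; use 0 for
#'   a veridical second block).
#' @param block_label Label stored on each trial.
#' @return A `block_schedule`.
#' @export
build_conflict_block <- function(seed = 0L, max_offset = .MAX_OFFSET,
                                 block_label = "conflict") {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(max_offset), max_offset >= 0)
  rng <- local_rng(seed)
  types <- rep(c("VP", "V", "VP", "P"), 21)        # 84 trials, 42/21/21
  n <- length(types)
  step <- max_offset / 42                           # exact rational increment
  n_vp <- cumsum(types == "VP")
  offsets <- pmin(n_vp * step, max_offset)          # carried to V trials
  pairs <- .assign_pairs(n)
  df <- .make_trials(block_label, types, offsets, pairs)
  .new_schedule(df, if (max_offset > 0) "conflict" else "veridical_second",
                seed)
}

#' Build the visual-shift control block
#'
#' The control experiment's second block has 84 V-only trials; the visual cue
#' ramps forward linearly at the same per-trial rate as the conflict block,
#' reaching exactly 70 mm after 84 trials. The target hand rests in the lap
#' throughout, so no proprioceptive target position exists on these trials.
#'
#' @inheritParams build_conflict_block
#' @return A `block_schedule` with `target_x`/`target_y` absent (`NA`).
#' @export
build_vshift_block <- function(seed = 0L, max_offset = .MAX_OFFSET,
                               block_label = "vshift_control") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  rng <- local_rng(seed)
  n <- 84L
  offsets <- pmin(seq_len(n) * (max_offset / n), max_offset)
  pairs <- .assign_pairs(n)
  df <- .make_trials(block_label, rep("V", n), offsets, pairs,
                     p_target_present = FALSE)
  # cue base still needed to place the white box: use the marker positions
  df$vcue_x <- pairs$target_x
  df$vcue_y <- pairs$target_y + offsets
  .new_schedule(df, "vshift_control", seed)
}

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("<block_schedule> design '%s', %d trials (seed %s)\n",
              attr(x, "design_name"), nrow(x), attr(x, "seed")))
  tab <- table(x$target_type)
  cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  visual offset: %.3f .. %.3f mm\n",
              min(x$visual_offset), max(x$visual_offset)))
  invisible(x)
}

# Seed R's generator from a (possibly large) integer-like value; keeps seeds
# within 32-bit range.
local_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}
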