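# Locomotor control metrics: activity fraction, Y-maze turning bias, KDE bands.

#' Detect Y-maze turns from a trajectory
#'
#' Each valid frame is assigned to the nearest of the three 120-degree arm
#' sectors; an arm visit is registered when the fly enters the arm's distal
#' half (radius beyond `arm_length / 2`). Consecutive distinct arm visits
#' produce one turn. Arms are labeled in clockwise order, so a turn is
#' rightward (`"R"`) when the new arm is the clockwise neighbor of the
#' previous one, else leftward (`"L"`).
#'
#' The distal-half entry rule and the clockwise-neighbor convention are
#' deterministic implementation choices; any consistent convention yields
#' the same bias distribution up to a global L/R flip.
#'
#' @param traj A [trajectory()] inside the maze footprint.
#' @param maze A [ymaze_spec()].
#' @return Object of class `turn_sequence` with fields `fly_id`, `turns`
#'   (character vector of `"L"`/`"R"`) and `n_turns`. A fly that never
#'   leaves one arm yields an empty sequence.
#' @export
detect_turns <- function(traj, maze = ymaze_spec()) {
  stopifnot(inherits(traj, "fly_trajectory"), inherits(maze, "ymaze_spec"))
  fr <- traj$frames[traj$frames$valid, , drop = FALSE]
  x <- fr$x - maze$center[1]; y <- fr$y - maze$center[2]
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) * 180 / pi
  # angular distance to each arm axis; nearest axis wins (sectors are 120 deg)
  dmat <- vapply(maze$arm_angles, function(a) abs(((ang - a + 180) %% 360) - 180),
                 numeric(length(ang)))
  dmat <- matrix(dmat, ncol = 3)
  arm <- max.col(-dmat, ties.method = "first") - 1L       # arms 0, 1, 2
  distal <- r > maze$arm_length / 2
  visits <- arm[distal]
  visits <- rle(visits)$values
  turns <- character(0)
  if (length(visits) >= 2) {
    prev <- visits[-length(visits)]; nxt <- visits[-1]
    turns <- ifelse((nxt - prev) %% 3 == 1, "R", "L")
  }
  structure(list(fly_id = traj$fly_id, turns = turns,
                 n_turns = length(turns)),
            class = "turn_sequence")
}

#' @export
print.turn_sequence <- function(x, ...) {
  cat(sprintf("<turn_sequence %s: %d turns (%d R)>\n", x$fly_id, x$n_turns,
              sum(x$turns == "R")))
  invisible(x)
}

#' Turning bias of a turn sequence
#'
#' Number of right turns divided by total turns; the standard locomotor
#' handedness (individuality) metric.
#'
#' @param seq A [detect_turns()] result, or a character vector of
#'   `"L"`/`"R"`.
#' @return Bias in `[0, 1]`.
#' @export
turning_bias <- function(seq) {
  turns <- if (inherits(seq, "turn_sequence")) seq$turns else as.character(seq)
  if (length(turns) == 0) {
    stop("turning bias undefined for a fly with no turns", call. = FALSE)
  }
  stopifnot(all(turns %in% c("L", "R")))
  mean(turns == "R")
}

#' Percentage of flies with supra-threshold activity
#'
#' @param mean_speeds Per-fly mean speeds, mm/s.
#' @param threshold Activity threshold, mm/s (default 0.1; flies strictly
#'   above are counted active).
#' @return Percentage in `[0, 100]`.
#' @export
activity_fraction <- function(mean_speeds, threshold = 0.1) {
  stopifnot(length(mean_speeds) >= 1)
  100 * mean(mean_speeds > threshold)
}

#' Kernel density estimate with a bootstrap confidence band
#'
#' Gaussian KDE (Silverman's bandwidth rule) on a fixed evaluation grid;
#' the band is the pointwise 2.5/97.5 percentile envelope of KDEs computed
#' on bootstrap resamples, all with the bandwidth of the original sample so
#' the band reflects sampling variability only.
#'
#' @param values Numeric sample (n >= 5).
#' @param n_boot Bootstrap resamples.
#' @param seed Optional integer seed.
#' @param n_grid Grid size.
#' @param conf Band coverage (default 0.95).
#' @return List with `grid`, `density`, `lower`, `upper`, `bw`.
#' @export
kde_with_bootstrap_band <- function(values, n_boot = 1000L, seed = NULL,
                                    n_grid = 512L, conf = 0.95) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 5, n_boot >= 2, conf > 0, conf < 1)
  if (!is.null(seed)) set.seed(seed)
  bw <- stats::bw.nrd0(values)
  from <- min(values) - 3 * bw; to <- max(values) + 3 * bw
  est <- stats::density(values, bw = bw, from = from, to = to, n = n_grid)
  n <- length(values)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = n_grid)
  for (b in seq_len(n_boot)) {
    res <- values[sample.int(n, n, replace = TRUE)]
    boot[b, ] <- stats::density(res, bw = bw, from = from, to = to, n = n_grid)$y
  }
  a <- (1 - conf) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  list(grid = est$x, density = est$y, lower = qs[1, ], upper = qs[2, ], bw = bw)
}
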