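# Trajectory data model, CSV I/O, gap interpolation, speeds, immobility.

#' Analysis configuration
#'
#' Bundles the tunable constants of the social-interaction pipeline.
#'
#' @param body_length Proximity scale defining the barrier-approach zone, mm.
#' @param speed_threshold Immobility/activity threshold on mean speed, mm/s.
#' @param fps Video frame rate, frames per second.
#' @param n_boot Bootstrap resamples for standard errors.
#' @param alpha Significance level.
#' @param max_gap_frames Longest run of missing frames that is linearly
#'   interpolated (longer dropouts stay invalid).
#' @param rng_seed Optional integer seed recorded with stochastic outputs.
#' @param use_imputed Whether interpolated frames enter the distance series
#'   and speed computations (`TRUE`) or are treated as invalid (`FALSE`).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(body_length = 3, speed_threshold = 0.1, fps = 29.9,
                            n_boot = 1000L, alpha = 0.05, max_gap_frames = 15L,
                            rng_seed = NULL, use_imputed = TRUE) {
  stopifnot(body_length > 0, speed_threshold > 0, fps > 0, n_boot >= 2,
            alpha > 0, alpha < 1, max_gap_frames >= 0)
  structure(list(body_length = body_length, speed_threshold = speed_threshold,
                 fps = fps, n_boot = as.integer(n_boot), alpha = alpha,
                 max_gap_frames = as.integer(max_gap_frames),
                 rng_seed = rng_seed, use_imputed = isTRUE(use_imputed)),
            class = "analysis_config")
}

#' Construct a single-fly trajectory
#'
#' @param fly_id Fly identifier.
#' @param frames Data frame with columns `frame` (strictly increasing
#'   integers), `x`, `y` (mm; `NA` where the detection was missing) and
#'   optionally `valid` and `imputed` logicals.
#' @param fps Frame rate, frames/s.
#' @param day,session Indices of the assay day and session.
#' @param arena_id,compartment Arena placement metadata.
#' @return An object of class `fly_trajectory`.
#' @export
trajectory <- function(fly_id, frames, fps = 29.9, day = 1L, session = 1L,
                       arena_id = "arena1", compartment = "left") {
  stopifnot(is.data.frame(frames), all(c("frame", "x", "y") %in% names(frames)),
            fps > 0)
  frames <- frames[order(frames$frame), , drop = FALSE]
  if (anyDuplicated(frames$frame)) stop("duplicate frame indices", call. = FALSE)
  if (is.null(frames$valid)) frames$valid <- is.finite(frames$x) & is.finite(frames$y)
  if (is.null(frames$imputed)) frames$imputed <- FALSE
  if (any(frames$valid & (!is.finite(frames$x) | !is.finite(frames$y)))) {
    stop("valid frames must have finite coordinates", call. = FALSE)
  }
  rownames(frames) <- NULL
  structure(list(fly_id = as.character(fly_id), day = as.integer(day),
                 session = as.integer(session), arena_id = as.character(arena_id),
                 compartment = as.character(compartment), fps = fps,
                 frames = frames[c("frame", "x", "y", "valid", "imputed")]),
            class = "fly_trajectory")
}

#' @export
print.fly_trajectory <- function(x, ...) {
  cat(sprintf("<fly_trajectory %s day %d session %d: %d frames (%d valid) @ %g fps>\n",
              x$fly_id, x$day, x$session, nrow(x$frames), sum(x$frames$valid), x$fps))
  invisible(x)
}

.traj_required_cols <- c("day", "session", "arena_id", "compartment",
                         "fly_id", "frame", "x_mm", "y_mm")

#' Read per-fly centroid trajectories from CSV
#'
#' Expects one row per frame per fly with header columns `day`, `session`,
#' `arena_id`, `compartment`, `fly_id`, `frame`, `x_mm`, `y_mm`. Rows with
#' empty coordinates are kept and marked invalid (missed detections). Row
#' order in the file does not matter; rows are grouped by
#' (fly, day, session) and sorted by frame.
#'
#' @param path CSV file path. Lines starting with `#` are treated as
#'   comments.
#' @param config An [analysis_config()] supplying the frame rate.
#' @return Named list of [trajectory()] objects, one per (fly, day, session).
#' @export
read_trajectories <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.traj_required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("trajectory file is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df$x_mm <- suppressWarnings(as.numeric(df$x_mm))
  df$y_mm <- suppressWarnings(as.numeric(df$y_mm))
  grp_key <- interaction(df$fly_id, df$day, df$session, drop = TRUE)
  dup <- duplicated(paste(grp_key, df$frame))
  if (any(dup)) {
    stop(sprintf("duplicate (fly, day, session, frame) rows, e.g. fly %s frame %d",
                 df$fly_id[dup][1], df$frame[dup][1]), call. = FALSE)
  }
  out <- lapply(split(df, grp_key), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    trajectory(fly_id = g$fly_id[1],
               frames = data.frame(frame = g$frame, x = g$x_mm, y = g$y_mm),
               fps = config$fps, day = g$day[1], session = g$session[1],
               arena_id = g$arena_id[1], compartment = g$compartment[1])
  })
  names(out) <- vapply(out, function(t) {
    sprintf("%s.d%d.s%d", t$fly_id, t$day, t$session)
  }, character(1))
  out[order(names(out))]
}

#' Write trajectories in the standard CSV dialect
#'
#' Inverse of [read_trajectories()]: emits the same column set, with empty
#' coordinate fields for invalid frames.
#'
#' @param trajs List of [trajectory()] objects.
#' @param path Output CSV path.
#' @param header_lines Optional character vector of `#`-prefixed comment
#'   lines written before the header (provenance metadata).
#' @export
write_trajectories <- function(trajs, path, header_lines = NULL) {
  if (inherits(trajs, "fly_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(t) {
    data.frame(day = t$day, session = t$session, arena_id = t$arena_id,
               compartment = t$compartment, fly_id = t$fly_id,
               frame = t$frames$frame,
               x_mm = ifelse(t$frames$valid, t$frames$x, NA_real_),
               y_mm = ifelse(t$frames$valid, t$frames$y, NA_real_))
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Linearly interpolate short tracking dropouts
#'
#' Runs of at most `max_gap_frames` consecutive invalid frames that are
#' flanked by valid frames are filled by linear interpolation on the frame
#' index and marked `imputed`; longer dropouts are left invalid. Valid
#' original samples are never altered.
#'
#' @param traj A [trajectory()].
#' @param max_gap_frames Maximum dropout length to fill, in frames.
#' @return The trajectory with imputed frames marked valid and `imputed`.
#' @export
interpolate_gaps <- function(traj, max_gap_frames = 15L) {
  stopifnot(inherits(traj, "fly_trajectory"))
  fr <- traj$frames
  if (all(fr$valid) || sum(fr$valid) < 2) return(traj)
  r <- rle(!fr$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] > max_gap_frames) next
    s <- starts[i]; e <- ends[i]
    if (s == 1L || e == nrow(fr)) next            # dropout at a recording edge
    if (!fr$valid[s - 1L] || !fr$valid[e + 1L]) next
    f0 <- fr$frame[s - 1L]; f1 <- fr$frame[e + 1L]
    w <- (fr$frame[s:e] - f0) / (f1 - f0)
    fr$x[s:e] <- fr$x[s - 1L] + w * (fr$x[e + 1L] - fr$x[s - 1L])
    fr$y[s:e] <- fr$y[s - 1L] + w * (fr$y[e + 1L] - fr$y[s - 1L])
    fr$valid[s:e] <- TRUE
    fr$imputed[s:e] <- TRUE
  }
  traj$frames <- fr
  traj
}

#' Per-step speed series of a trajectory
#'
#' Step `i` spans frames `i` to `i + 1`; its speed is the Euclidean
#' displacement divided by the elapsed time (`frame gap / fps`). Steps
#' touching an invalid frame are `NA` and are excluded from means.
#'
#' @param traj A [trajectory()].
#' @param use_imputed Whether interpolated frames count as valid.
#' @return Numeric vector of length `n_frames - 1`, mm/s, `NA` where
#'   undefined.
#' @export
compute_speed <- function(traj, use_imputed = TRUE) {
  stopifnot(inherits(traj, "fly_trajectory"))
  fr <- traj$frames
  ok <- fr$valid & (use_imputed | !fr$imputed)
  if (sum(ok) < 2) stop("compute_speed needs at least 2 valid frames", call. = FALSE)
  n <- nrow(fr)
  dx <- diff(fr$x); dy <- diff(fr$y)
  dgap <- diff(fr$frame)
  sp <- sqrt(dx^2 + dy^2) * traj$fps / dgap
  sp[!(ok[-n] & ok[-1])] <- NA_real_
  sp
}

#' Session-mean speed of a fly
#'
#' Mean over the defined speed steps of the session.
#'
#' @inheritParams compute_speed
#' @return Scalar mean speed, mm/s.
#' @export
mean_speed <- function(traj, use_imputed = TRUE) {
  mean(compute_speed(traj, use_imputed = use_imputed), na.rm = TRUE)
}

#' Flag immobile flies/dyads by mean speed
#'
#' Rows whose mean speed (any of the recognised speed columns) is at or
#' below the threshold are flagged for discard, mirroring the immobility
#' screen applied before social-interaction statistics: the interactivity
#' index is undefined for a fly that never moves.
#'
#' @param rows Data frame carrying one or more of the columns `mean_speed`,
#'   `mean_speed_a`, `mean_speed_b`.
#' @param config An [analysis_config()]; `speed_threshold` is used.
#' @return List with elements `kept`, `discarded` (row subsets) and
#'   `discard_fraction`.
#' @export
immobility_filter <- function(rows, config = analysis_config()) {
  stopifnot(is.data.frame(rows))
  cols <- intersect(c("mean_speed", "mean_speed_a", "mean_speed_b"), names(rows))
  if (length(cols) == 0) stop("no mean-speed column found", call. = FALSE)
  sp <- as.matrix(rows[cols])
  slow <- apply(sp, 1, function(v) any(!is.finite(v) | v <= config$speed_threshold))
  list(kept = rows[!slow, , drop = FALSE],
       discarded = rows[slow, , drop = FALSE],
       discard_fraction = mean(slow))
}
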