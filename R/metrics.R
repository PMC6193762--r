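# Dyadic affiliation statistics: interactivity index, coincidental approaches.

#' Dyad interactivity index
#'
#' Pearson correlation between the two dyad members' distance-to-barrier
#' series over the session. Frames where either series is `NA` are removed
#' pairwise. Significantly positive or negative values both indicate social
#' interaction: the sign distinguishes coordinated approach from avoidance,
#' the magnitude carries interaction strength.
#'
#' @param dist_a,dist_b Equal-length numeric distance series (mm); `NA`
#'   marks invalid frames.
#' @return The correlation coefficient in `[-1, 1]`, or `NA_real_` if either
#'   series has zero variance after pairwise deletion (the dyad must then be
#'   excluded, not scored 0).
#' @export
interactivity_index <- function(dist_a, dist_b) {
  if (length(dist_a) != length(dist_b)) {
    stop("distance series must have equal length", call. = FALSE)
  }
  ok <- is.finite(dist_a) & is.finite(dist_b)
  if (sum(ok) < 3) stop("need at least 3 jointly valid frames", call. = FALSE)
  a <- dist_a[ok]; b <- dist_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Count coincidental approaches
#'
#' A coincidental approach is a maximal episode in which both flies are
#' simultaneously within one body length of the interaction barrier. An
#' episode is scored as a single event irrespective of its duration; for a
#' subsequent event to count, at least one fly must leave and re-enter the
#' zone. Invalid (`NA`) frames never terminate an episode by themselves: an
#' episode ends only at a frame where a fly is observably outside the zone.
#'
#' @param dist_a,dist_b Aligned distance series (mm).
#' @param body_length Zone width, mm (default 3, one body length). The zone
#'   boundary is inclusive (`distance <= body_length`).
#' @return Integer event count.
#' @export
coincidental_approaches <- function(dist_a, dist_b, body_length = 3) {
  if (length(dist_a) != length(dist_b)) {
    stop("distance series must have equal length", call. = FALSE)
  }
  stopifnot(body_length > 0)
  z <- (dist_a <= body_length) & (dist_b <= body_length)
  z <- z[!is.na(z)]
  if (length(z) == 0) return(0L)
  sum(z & !c(FALSE, z[-length(z)]))
}

#' Normalize an approach count by dyad mean speed
#'
#' Dyad mean speed is the grand mean of the two flies' session-mean speeds;
#' the count is divided by it, yielding events per (mm/s).
#'
#' @param count Event count from [coincidental_approaches()].
#' @param fly_a_speeds,fly_b_speeds Speed series (mm/s) of the two flies,
#'   or scalar mean speeds.
#' @return Normalized count, events per (mm/s).
#' @export
normalize_approaches <- function(count, fly_a_speeds, fly_b_speeds) {
  ma <- mean(fly_a_speeds, na.rm = TRUE)
  mb <- mean(fly_b_speeds, na.rm = TRUE)
  dyad_mean <- mean(c(ma, mb))
  if (!is.finite(dyad_mean) || dyad_mean <= 0) {
    stop("dyad mean speed must be positive (immobile dyads are excluded upstream)",
         call. = FALSE)
  }
  count / dyad_mean
}

#' Construct a dyad record
#'
#' Binds the two time-aligned member trajectories of one dyad to the arena,
#' barrier, and design metadata needed to score it.
#'
#' @param fly_a,fly_b [trajectory()] objects sharing fps and frame range and
#'   occupying opposite compartments of the same arena.
#' @param arena An [arena_spec()].
#' @param barrier A [barrier_spec()].
#' @param genotype Genotype label.
#' @param dyad_id Identifier; defaults to `"<fly_a>x<fly_b>"`.
#' @param day,session Assay indices (taken from the trajectories by default).
#' @return An object of class `dyad_record`.
#' @export
dyad_record <- function(fly_a, fly_b, arena = arena_spec(),
                        barrier = barrier_spec("open_clear"),
                        genotype = "CantonS", dyad_id = NULL,
                        day = fly_a$day, session = fly_a$session) {
  stopifnot(inherits(fly_a, "fly_trajectory"), inherits(fly_b, "fly_trajectory"),
            inherits(arena, "arena_spec"), inherits(barrier, "barrier_spec"))
  if (!isTRUE(all.equal(fly_a$fps, fly_b$fps))) {
    stop("dyad members must share the frame rate", call. = FALSE)
  }
  if (!identical(fly_a$frames$frame, fly_b$frames$frame)) {
    stop("dyad members must share the frame range", call. = FALSE)
  }
  if (fly_a$compartment == fly_b$compartment ||
      !all(c(fly_a$compartment, fly_b$compartment) %in% arena$compartments)) {
    stop("dyad members must occupy opposite compartments of the arena", call. = FALSE)
  }
  if (is.null(dyad_id)) dyad_id <- paste0(fly_a$fly_id, "x", fly_b$fly_id)
  structure(list(dyad_id = as.character(dyad_id), fly_a = fly_a, fly_b = fly_b,
                 arena = arena, barrier = barrier, genotype = as.character(genotype),
                 day = as.integer(day), session = as.integer(session)),
            class = "dyad_record")
}

#' @export
print.dyad_record <- function(x, ...) {
  cat(sprintf("<dyad_record %s (%s, %s) day %d session %d: %d frames>\n",
              x$dyad_id, x$barrier$barrier_type, x$genotype, x$day, x$session,
              nrow(x$fly_a$frames)))
  invisible(x)
}

# Internal: per-frame barrier distances of both dyad members (NA where the
# frame is invalid or, with use_imputed = FALSE, imputed).
.dyad_distances <- function(dyad, config = analysis_config()) {
  one <- function(t) {
    ok <- t$frames$valid & (config$use_imputed | !t$frames$imputed)
    d <- rep(NA_real_, nrow(t$frames))
    if (any(ok)) {
      d[ok] <- suppressWarnings(
        barrier_distance(cbind(t$frames$x[ok], t$frames$y[ok]),
                         dyad$arena, t$compartment))
    }
    d
  }
  list(dist_a = one(dyad$fly_a), dist_b = one(dyad$fly_b))
}

#' Score one dyad-session
#'
#' Computes the distance-to-barrier series of both flies via
#' [barrier_distance()], then the interactivity index, coincidental
#' approaches (raw and speed-normalized), and speed summaries. Dyads with an
#' immobile member (mean speed at or below the threshold) or a zero-variance
#' distance series are flagged `excluded` with a reason instead of being
#' silently scored.
#'
#' @param dyad A [dyad_record()].
#' @param config An [analysis_config()].
#' @return One-row data frame (a `DyadMetricRow`).
#' @export
dyad_metrics <- function(dyad, config = analysis_config()) {
  stopifnot(inherits(dyad, "dyad_record"))
  d <- .dyad_distances(dyad, config)
  sa <- compute_speed(dyad$fly_a, use_imputed = config$use_imputed)
  sb <- compute_speed(dyad$fly_b, use_imputed = config$use_imputed)
  ma <- mean(sa, na.rm = TRUE); mb <- mean(sb, na.rm = TRUE)
  ok <- is.finite(d$dist_a) & is.finite(d$dist_b)
  n_used <- sum(ok)
  excluded <- FALSE; reason <- NA_character_
  idx <- NA_real_; napp <- NA_real_; appr <- NA_integer_
  if (!is.finite(ma) || !is.finite(mb) ||
      ma <= config$speed_threshold || mb <= config$speed_threshold) {
    excluded <- TRUE; reason <- "immobile"
  } else if (n_used < 3) {
    excluded <- TRUE; reason <- "too_few_frames"
  } else {
    idx <- interactivity_index(d$dist_a, d$dist_b)
    if (is.na(idx)) {
      excluded <- TRUE; reason <- "zero_variance"
    } else {
      appr <- coincidental_approaches(d$dist_a, d$dist_b, config$body_length)
      napp <- normalize_approaches(appr, ma, mb)
    }
  }
  data.frame(dyad_id = dyad$dyad_id, day = dyad$day, session = dyad$session,
             barrier_type = dyad$barrier$barrier_type, genotype = dyad$genotype,
             fly_a = dyad$fly_a$fly_id, fly_b = dyad$fly_b$fly_id,
             interactivity_index = idx, n_frames_used = n_used,
             coincidental_approaches = appr, normalized_approaches = napp,
             dyad_mean_speed = mean(c(ma, mb)),
             mean_speed_a = ma, mean_speed_b = mb,
             excluded = excluded, exclude_reason = reason,
             stringsAsFactors = FALSE)
}

#' Score a list of dyads into a metric table
#'
#' @param dyads List of [dyad_record()] objects.
#' @param config An [analysis_config()].
#' @return Data frame with one `DyadMetricRow` per dyad-session; the
#'   pipeline's central artifact.
#' @export
dyad_metric_table <- function(dyads, config = analysis_config()) {
  stopifnot(length(dyads) >= 1)
  out <- do.call(rbind, lapply(dyads, dyad_metrics, config = config))
  rownames(out) <- NULL
  out
}
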