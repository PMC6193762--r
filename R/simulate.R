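# Synthetic trajectory generator: coupled, reflected random walks in split
# arenas with sensory-channel gating, day-persistent individual couplings,
# immobility episodes, and tracking dropouts.

#' Coupling parameters for the dyad simulator
#'
#' Defaults are the shipped calibration (coarse grid search; see the
#' package vignette): the olfactory channel carries roughly two thirds of
#' the open-clear coupling so that knocking it out reproduces the observed
#' ~65% drop in mean absolute interactivity, and a vision-only dyad retains
#' roughly a third.
#'
#' @param w_vision,w_olfaction Channel coupling weights (>= 0,
#'   dimensionless; their gated sum is the distance-tracking weight, so it
#'   should stay well below 1).
#' @param sign +1 for coordinated approach, -1 for avoidance coupling.
#' @param step_sd Random-walk step standard deviation, mm/frame.
#' @param barrier_attraction Mean-reversion rate (per frame) of a fly's
#'   barrier distance toward its home distance; sets the mixing time of the
#'   walk (roughly `1 / barrier_attraction` frames).
#' @param home_distance Preferred distance from the barrier face, mm.
#' @param persistence_rho Day-to-day AR(1) retention of each fly's latent
#'   sociability, in `[0, 1]`.
#' @param immobile_prob Probability that a fly is immobile for a whole
#'   session (such dyads are later discarded by the immobility screen).
#' @param dropout_prob Per-frame probability of a tracking dropout.
#' @param seed Optional integer seed.
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(w_vision = 0.15, w_olfaction = 0.30, sign = 1,
                            step_sd = 0.35, barrier_attraction = 0.02,
                            home_distance = 4,
                            persistence_rho = 0.8, immobile_prob = 0.03,
                            dropout_prob = 0.005, seed = NULL) {
  stopifnot(w_vision >= 0, w_olfaction >= 0, sign %in% c(-1, 1), step_sd > 0,
            barrier_attraction > 0, barrier_attraction < 1, home_distance > 0,
            persistence_rho >= 0, persistence_rho <= 1,
            immobile_prob >= 0, immobile_prob <= 1,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(list(w_vision = w_vision, w_olfaction = w_olfaction, sign = sign,
                 step_sd = step_sd, barrier_attraction = barrier_attraction,
                 home_distance = home_distance,
                 persistence_rho = persistence_rho,
                 immobile_prob = immobile_prob, dropout_prob = dropout_prob,
                 seed = seed),
            class = "coupling_params")
}

#' Shipped default coupling calibration
#'
#' Returns the calibrated default [coupling_params()]; the coarse
#' grid-search script that produced these constants ships at
#' `inst/scripts/calibrate-weights.R`.
#'
#' @return A [coupling_params()] object.
#' @export
calibrate_channel_weights <- function() coupling_params()

#' Genotype sensory profile
#'
#' Wild type has both channels intact; the anosmic profile knocks out the
#' olfactory channel, the blind profile the visual channel; the
#' reduced-acuity profile keeps both channels but degrades the visual one.
#'
#' @param name One of `"CantonS"` (wild type), `"Orco"` (anosmic),
#'   `"NorpA"` (blind), `"w1118"` (reduced visual acuity).
#' @return Object of class `genotype_profile` with fields `vision_mask`,
#'   `olfaction_mask` (0/1) and `vision_noise_factor` (>= 1).
#' @export
genotype_profile <- function(name = c("CantonS", "Orco", "NorpA", "w1118")) {
  name <- match.arg(name)
  p <- switch(name,
    CantonS = list(vision_mask = 1, olfaction_mask = 1, vision_noise_factor = 1),
    Orco    = list(vision_mask = 1, olfaction_mask = 0, vision_noise_factor = 1),
    NorpA   = list(vision_mask = 0, olfaction_mask = 1, vision_noise_factor = 1),
    w1118   = list(vision_mask = 1, olfaction_mask = 1, vision_noise_factor = 2))
  structure(c(list(name = name), p), class = "genotype_profile")
}

# Internal: reflect a point into the compartment {s_dir * x >= xo, r <= R}.
.reflect_into <- function(x, y, s_dir, R, xo) {
  for (i in 1:8) {
    if (s_dir * x < xo) x <- s_dir * 2 * xo - x
    r <- sqrt(x * x + y * y)
    if (r > R) {
      f <- (2 * R - r) / r
      x <- x * f; y <- y * f
    } else if (s_dir * x >= xo) {
      return(c(x, y))
    }
  }
  # pathological large step: clamp
  if (s_dir * x < xo) x <- s_dir * xo
  r <- sqrt(x * x + y * y)
  if (r > R) { x <- x * R / r; y <- y * R / r }
  c(x, y)
}

# Internal: effective channel coupling for a dyad.
.effective_kappa <- function(params, barrier, gA, gB) {
  kv <- params$w_vision * as.numeric(barrier$allows_vision) *
    gA$vision_mask * gB$vision_mask /
    (gA$vision_noise_factor * gB$vision_noise_factor)
  ko <- params$w_olfaction * as.numeric(barrier$allows_olfaction) *
    gA$olfaction_mask * gB$olfaction_mask
  params$sign * (kv + ko)
}

#' Simulate one dyad session
#'
#' Each fly performs a reflected Gaussian random walk confined to its
#' semicircular compartment. Along the barrier axis the walk mean-reverts
#' (at rate `barrier_attraction` per frame) toward a target distance that
#' blends the fly's home distance with its partner's current barrier
#' distance; the blend weight is the effective coupling — the sum of the
#' channel weights gated through the barrier's open sensory channels and
#' both genotypes' channel masks, with the coupling sign selecting
#' coordinated approach (+) or avoidance (-). For this mutually tracking
#' process the stationary correlation of the two distance series equals the
#' signed coupling weight, so the interactivity index is controlled and
#' monotone in the coupling. Immobile flies stay put for the session;
#' dropout frames are marked invalid.
#'
#' @param params A [coupling_params()].
#' @param barrier A [barrier_spec()].
#' @param genotypes List of two [genotype_profile()]s (fly a, fly b).
#' @param arena An [arena_spec()].
#' @param n_frames Frames per session (default 10000).
#' @param fps Frame rate.
#' @param burn_in Equilibration frames simulated and discarded before
#'   recording starts, so both flies begin from their stationary occupancy
#'   distribution (a shared approach-the-barrier transient would otherwise
#'   masquerade as correlation).
#' @param dyad_id,fly_ids,day,session Identity metadata.
#' @param genotype_label Label stored on the dyad record (defaults to the
#'   two profile names collapsed, or the single shared name).
#' @param seed Optional integer seed (defaults to `params$seed`).
#' @return A [dyad_record()].
#' @export
simulate_dyad <- function(params = coupling_params(),
                          barrier = barrier_spec("open_clear"),
                          genotypes = list(genotype_profile("CantonS"),
                                           genotype_profile("CantonS")),
                          arena = arena_spec(), n_frames = 10000L, fps = 29.9,
                          burn_in = 300L,
                          dyad_id = "dyad1", fly_ids = c("flyA", "flyB"),
                          day = 1L, session = 1L, genotype_label = NULL,
                          seed = params$seed) {
  stopifnot(n_frames >= 2, burn_in >= 0, length(genotypes) == 2)
  if (!is.null(seed)) set.seed(seed)
  R <- arena$diameter / 2
  xo <- arena$barrier_thickness / 2
  h <- sqrt(R^2 - xo^2)
  kappa <- .effective_kappa(params, barrier, genotypes[[1]], genotypes[[2]])
  kappa <- max(-0.95, min(0.95, kappa))
  s <- params$step_sd
  theta <- params$barrier_attraction
  m0 <- params$home_distance
  n_tot <- n_frames + burn_in
  immobile <- stats::runif(2) < params$immobile_prob
  noise <- matrix(stats::rnorm(4 * n_tot, sd = s), ncol = 4)
  drop_a <- stats::runif(n_frames) < params$dropout_prob
  drop_b <- stats::runif(n_frames) < params$dropout_prob
  xa <- numeric(n_tot); ya <- numeric(n_tot)
  xb <- numeric(n_tot); yb <- numeric(n_tot)
  # start each fly mid-compartment with a little jitter; the burn-in then
  # forgets this choice before recording starts
  xa[1] <- -(xo + 0.5 * R) + noise[1, 1]; ya[1] <- noise[1, 2]
  xb[1] <- (xo + 0.5 * R) + noise[1, 3]; yb[1] <- noise[1, 4]
  pa <- .reflect_into(xa[1], ya[1], -1, R, xo); xa[1] <- pa[1]; ya[1] <- pa[2]
  pb <- .reflect_into(xb[1], yb[1], 1, R, xo); xb[1] <- pb[1]; yb[1] <- pb[2]
  bd <- function(x, y) sqrt((abs(x) - xo)^2 + max(abs(y) - h, 0)^2)
  da <- bd(xa[1], ya[1]); db <- bd(xb[1], yb[1])
  for (t in 2:n_tot) {
    target_a <- m0 + kappa * (db - m0)       # partner-tracking target distance
    target_b <- m0 + kappa * (da - m0)
    # reversion of the barrier distance toward the target, expressed as an
    # x-drift: for the left fly, larger x means smaller distance
    mu_a <- theta * (da - target_a)
    mu_b <- theta * (db - target_b)
    if (immobile[1]) {
      xa[t] <- xa[t - 1]; ya[t] <- ya[t - 1]
    } else {
      p <- .reflect_into(xa[t - 1] + mu_a + noise[t, 1], ya[t - 1] + noise[t, 2],
                         -1, R, xo)
      xa[t] <- p[1]; ya[t] <- p[2]
    }
    if (immobile[2]) {
      xb[t] <- xb[t - 1]; yb[t] <- yb[t - 1]
    } else {
      p <- .reflect_into(xb[t - 1] - mu_b + noise[t, 3], yb[t - 1] + noise[t, 4],
                         1, R, xo)
      xb[t] <- p[1]; yb[t] <- p[2]
    }
    da <- bd(xa[t], ya[t]); db <- bd(xb[t], yb[t])
  }
  keep <- seq.int(burn_in + 1L, n_tot)
  xa <- xa[keep]; ya <- ya[keep]; xb <- xb[keep]; yb <- yb[keep]
  mk <- function(x, y, dropped, fly_id, compartment) {
    trajectory(fly_id = fly_id,
               frames = data.frame(frame = seq_len(n_frames),
                                   x = ifelse(dropped, NA_real_, x + arena$center[1]),
                                   y = ifelse(dropped, NA_real_, y + arena$center[2]),
                                   valid = !dropped, imputed = FALSE),
               fps = fps, day = day, session = session,
               arena_id = arena$arena_id, compartment = compartment)
  }
  if (is.null(genotype_label)) {
    gn <- unique(c(genotypes[[1]]$name, genotypes[[2]]$name))
    genotype_label <- paste(gn, collapse = "x")
  }
  dyad_record(mk(xa, ya, drop_a, fly_ids[1], arena$compartments[1]),
              mk(xb, yb, drop_b, fly_ids[2], arena$compartments[2]),
              arena = arena, barrier = barrier, genotype = genotype_label,
              dyad_id = dyad_id, day = day, session = session)
}

#' Simulate a full multi-day social experiment
#'
#' Draws a latent sociability for every fly, evolves it across days as an
#' AR(1) process with retention `persistence_rho`, forms dyads according to
#' the pairing scheme, schedules them into sessions, and simulates every
#' dyad-session with [simulate_dyad()]. A dyad's signed coupling on a given
#' day is `tanh(s_i * s_j)` of its members' latent values, scaling the
#' channel weights, so day-to-day index correlation is controlled by
#' `persistence_rho`.
#'
#' Session scheduling: scheme 1 runs every (disjoint) dyad in every
#' session; schemes 2 and 3 partition dyads into conflict-free rounds
#' (greedy matchings for scheme 2, circle-method rounds for scheme 3)
#' assigned cyclically to the `days * sessions_per_day` session slots.
#'
#' @param n_flies Number of flies.
#' @param scheme A [dyad_scheme()] (its `n_flies` must match).
#' @param days Number of assay days.
#' @param sessions_per_day Sessions per day.
#' @param params A [coupling_params()].
#' @param barrier A [barrier_spec()].
#' @param genotype Genotype name (shared by all flies) passed to
#'   [genotype_profile()].
#' @param arena An [arena_spec()] (template; arenas are relabeled per slot).
#' @param n_frames Frames per session.
#' @param fps Frame rate.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param out_dir Optional directory; when given, `trajectories.csv`,
#'   `design.csv`, and `manifest.yaml` are written there.
#' @return List with `dyads` (list of [dyad_record()]s), `design` (data
#'   frame: day, session, round, arena_id, compartment, fly_id, dyad_id,
#'   barrier_type, genotype), `latents` (flies x days matrix), `params`.
#' @export
simulate_experiment <- function(n_flies = 20L,
                                scheme = dyad_scheme("scheme1_disjoint", n_flies),
                                days = 2L, sessions_per_day = 1L,
                                params = coupling_params(),
                                barrier = barrier_spec("open_clear"),
                                genotype = "CantonS", arena = arena_spec(),
                                n_frames = 10000L, fps = 29.9,
                                seed = params$seed, out_dir = NULL) {
  stopifnot(inherits(scheme, "dyad_scheme"), scheme$n_flies == n_flies,
            days >= 1, sessions_per_day >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_flies <- as.integer(n_flies)
  fly_ids <- sprintf("fly%02d", seq_len(n_flies))
  g <- genotype_profile(genotype)
  # latent sociability, AR(1) across days
  lat <- matrix(NA_real_, nrow = n_flies, ncol = days)
  lat[, 1] <- stats::rnorm(n_flies)
  rho <- params$persistence_rho
  if (days > 1) {
    for (d in 2:days) {
      lat[, d] <- rho * lat[, d - 1] + sqrt(1 - rho^2) * stats::rnorm(n_flies)
    }
  }
  scheme$seed <- NULL                      # master seed already set
  dyad_pairs <- enumerate_dyads(scheme)
  rounds <- switch(scheme$scheme,
    scheme1_disjoint = list(dyad_pairs),
    scheme2_kregular = .greedy_rounds(dyad_pairs, n_flies),
    scheme3_saturated = schedule_rounds(dyad_pairs, n_flies, scheme$repeats))
  n_slots <- days * sessions_per_day
  dyads <- list()
  design <- list()
  slot <- 0L
  for (d in seq_len(days)) {
    for (ses in seq_len(sessions_per_day)) {
      slot <- slot + 1L
      rnd <- if (scheme$scheme == "scheme3_saturated") {
        if (slot > length(rounds)) break
        rounds[[slot]]
      } else {
        rounds[[((slot - 1L) %% length(rounds)) + 1L]]
      }
      for (k in seq_len(nrow(rnd))) {
        i <- rnd[k, 1]; j <- rnd[k, 2]
        cpl <- tanh(lat[i, d] * lat[j, d])
        dy_params <- params
        dy_params$w_vision <- params$w_vision * abs(cpl)
        dy_params$w_olfaction <- params$w_olfaction * abs(cpl)
        dy_params$sign <- if (cpl >= 0) 1 else -1
        ar <- arena
        ar$arena_id <- sprintf("arena%03d", k)
        rec <- simulate_dyad(dy_params, barrier = barrier,
                             genotypes = list(g, g), arena = ar,
                             n_frames = n_frames, fps = fps,
                             dyad_id = sprintf("%sx%s", fly_ids[i], fly_ids[j]),
                             fly_ids = fly_ids[c(i, j)], day = d, session = ses,
                             seed = NULL)
        dyads[[length(dyads) + 1L]] <- rec
        design[[length(design) + 1L]] <- data.frame(
          day = d, session = ses, round = slot, arena_id = ar$arena_id,
          compartment = arena$compartments,
          fly_id = fly_ids[c(i, j)], dyad_id = rec$dyad_id,
          barrier_type = barrier$barrier_type, genotype = genotype,
          stringsAsFactors = FALSE)
      }
    }
  }
  design <- do.call(rbind, design)
  out <- list(dyads = dyads, design = design, latents = lat, params = params,
              scheme = scheme$scheme, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    trajs <- unlist(lapply(dyads, function(d) list(d$fly_a, d$fly_b)),
                    recursive = FALSE)
    write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
    utils::write.csv(design, file.path(out_dir, "design.csv"), row.names = FALSE)
    yaml::write_yaml(list(
      generator = "simulate_experiment", seed = seed, n_flies = n_flies,
      scheme = scheme$scheme, days = days, sessions_per_day = sessions_per_day,
      n_frames = n_frames, fps = fps, barrier_type = barrier$barrier_type,
      genotype = genotype,
      params = unclass(params)[setdiff(names(params), "seed")]),
      file.path(out_dir, "manifest.yaml"))
  }
  out
}

# Internal: partition the edges of a pairing graph into conflict-free rounds
# (greedy maximal matchings).
.greedy_rounds <- function(pairs, n_flies) {
  remaining <- pairs
  rounds <- list()
  while (nrow(remaining) > 0) {
    used <- logical(n_flies)
    take <- logical(nrow(remaining))
    for (r in seq_len(nrow(remaining))) {
      i <- remaining[r, 1]; j <- remaining[r, 2]
      if (!used[i] && !used[j]) {
        take[r] <- TRUE; used[i] <- TRUE; used[j] <- TRUE
      }
    }
    rounds[[length(rounds) + 1L]] <- remaining[take, , drop = FALSE]
    remaining <- remaining[!take, , drop = FALSE]
  }
  rounds
}

#' Simulate a Bernoulli turn sequence
#'
#' @param p Probability of a right turn.
#' @param n_turns Number of turns.
#' @param seed Optional integer seed.
#' @param fly_id Identifier.
#' @return A `turn_sequence`.
#' @export
simulate_turns <- function(p, n_turns, seed = NULL, fly_id = "fly1") {
  stopifnot(p >= 0, p <= 1, n_turns >= 0)
  if (!is.null(seed)) set.seed(seed)
  turns <- sample(c("R", "L"), n_turns, replace = TRUE, prob = c(p, 1 - p))
  structure(list(fly_id = fly_id, turns = turns, n_turns = length(turns)),
            class = "turn_sequence")
}

#' Simulate a mixed population of per-fly mean speeds
#'
#' Draws from a mixture of lognormal components; useful for exercising the
#' immobility filter and KDE machinery with a known composition.
#'
#' @param n Number of flies.
#' @param components Data frame with columns `weight`, `meanlog`, `sdlog`.
#' @param seed Optional integer seed.
#' @return Numeric vector of speeds, mm/s.
#' @export
simulate_speed_population <- function(n,
                                      components = data.frame(
                                        weight = c(0.9, 0.1),
                                        meanlog = c(log(8), log(0.02)),
                                        sdlog = c(0.4, 0.5)),
                                      seed = NULL) {
  stopifnot(n >= 1, is.data.frame(components),
            all(c("weight", "meanlog", "sdlog") %in% names(components)))
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(nrow(components), n, replace = TRUE,
                     prob = components$weight)
  stats::rlnorm(n, components$meanlog[comp], components$sdlog[comp])
}
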