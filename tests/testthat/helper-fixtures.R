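# Shared fixture builders: tiny trajectories and dyads built in code.

make_traj <- function(x, y, fly_id = "f1", fps = 29.9, frame = seq_along(x),
                      valid = NULL, day = 1, session = 1,
                      arena_id = "arena1", compartment = "left") {
  fr <- data.frame(frame = frame, x = x, y = y)
  if (!is.null(valid)) fr$valid <- valid
  trajectory(fly_id, fr, fps = fps, day = day, session = session,
             arena_id = arena_id, compartment = compartment)
}

# A deterministic dyad whose members mirror each other: both start at the
# compartment poles and walk toward the barrier in lockstep.
make_lockstep_dyad <- function(n = 40, fps = 29.9) {
  xs <- seq(-14, -1, length.out = n)
  a <- make_traj(xs, rep(0, n), fly_id = "fa", fps = fps, compartment = "left")
  b <- make_traj(-xs, rep(0, n), fly_id = "fb", fps = fps, compartment = "right")
  dyad_record(a, b, dyad_id = "lock1")
}

# Write a small well-formed trajectory CSV; returns the path.
write_fixture_csv <- function(path, n = 10, flies = c("f1", "f2"),
                              shuffle = FALSE) {
  rows <- do.call(rbind, lapply(seq_along(flies), function(i) {
    data.frame(day = 1, session = 1, arena_id = "arena1",
               compartment = c("left", "right")[i], fly_id = flies[i],
               frame = seq_len(n),
               x_mm = c(-1, 1)[i] * (1 + seq_len(n) / 10),
               y_mm = seq_len(n) / 20)
  }))
  if (shuffle) rows <- rows[sample.int(nrow(rows)), ]
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# Independent brute-force episode counter: walks the frames with an explicit
# both-in-zone state machine (NA frames carry the previous state forward).
brute_force_episodes <- function(in_zone) {
  count <- 0L
  state <- FALSE
  for (z in in_zone) {
    if (is.na(z)) next
    if (z && !state) count <- count + 1L
    state <- z
  }
  count
}

quiet_metrics <- function(...) suppressWarnings(dyad_metrics(...))
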