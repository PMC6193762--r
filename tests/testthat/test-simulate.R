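test_that("simulated dyads are seed-reproducible and stay in their compartments", {
  p <- coupling_params(seed = 77)
  d1 <- simulate_dyad(p, n_frames = 400)
  d2 <- simulate_dyad(p, n_frames = 400)
  expect_identical(d1, d2)

  arena <- arena_spec()
  R <- arena$diameter / 2
  xo <- arena$barrier_thickness / 2
  for (fly in list(d1$fly_a, d1$fly_b)) {
    fr <- fly$frames[fly$frames$valid, ]
    expect_true(all(fr$x^2 + fr$y^2 <= R^2 + 1e-9))
    if (fly$compartment == "left") {
      expect_true(all(fr$x <= -xo + 1e-9))
    } else {
      expect_true(all(fr$x >= xo - 1e-9))
    }
  }
})

test_that("sensory gating zeroes the coupling through barriers and genotypes", {
  p <- coupling_params()
  gate <- function(barrier, g1, g2) {
    flysin:::.effective_kappa(p, barrier_spec(barrier),
                              genotype_profile(g1), genotype_profile(g2))
  }
  expect_equal(gate("open_clear", "CantonS", "CantonS"),
               p$w_vision + p$w_olfaction)
  expect_equal(gate("solid_black", "CantonS", "CantonS"), 0)
  expect_equal(gate("open_clear", "Orco", "Orco"), p$w_vision)
  expect_equal(gate("open_clear", "NorpA", "NorpA"), p$w_olfaction)
  expect_equal(gate("open_black", "CantonS", "CantonS"), p$w_olfaction)
  expect_equal(gate("solid_clear", "Orco", "Orco"), p$w_vision)
  # reduced acuity degrades only the visual channel
  expect_equal(gate("open_clear", "w1118", "w1118"),
               p$w_vision / 4 + p$w_olfaction)
  # ordering: open_clear carries at least as much coupling as open_black
  expect_gte(gate("open_clear", "CantonS", "CantonS"),
             gate("open_black", "CantonS", "CantonS"))
})

test_that("uncoupled dyads score near-zero indices on average", {
  set.seed(60)
  p0 <- coupling_params(w_vision = 1e-9, w_olfaction = 0,
                        immobile_prob = 0, dropout_prob = 0)
  idx <- vapply(1:60, function(i) {
    dyad_metrics(simulate_dyad(p0, n_frames = 1500, seed = NULL))$interactivity_index
  }, numeric(1))
  expect_lt(abs(mean(idx)), 0.05)
})

test_that("index tracks the imposed coupling sign and strength", {
  set.seed(61)
  strong <- coupling_params(w_vision = 0.3, w_olfaction = 0.5,
                            immobile_prob = 0, dropout_prob = 0)
  avoid <- coupling_params(w_vision = 0.3, w_olfaction = 0.5, sign = -1,
                           immobile_prob = 0, dropout_prob = 0)
  i_pos <- vapply(1:12, function(i) {
    dyad_metrics(simulate_dyad(strong, n_frames = 2500, seed = NULL))$interactivity_index
  }, numeric(1))
  i_neg <- vapply(1:12, function(i) {
    dyad_metrics(simulate_dyad(avoid, n_frames = 2500, seed = NULL))$interactivity_index
  }, numeric(1))
  expect_gt(mean(i_pos), 0.4)
  expect_lt(mean(i_neg), -0.4)
})

test_that("dropouts and immobility propagate into the record", {
  p <- coupling_params(dropout_prob = 0.2, seed = 5)
  d <- simulate_dyad(p, n_frames = 500)
  expect_gt(sum(!d$fly_a$frames$valid), 0)
  expect_true(all(is.na(d$fly_a$frames$x[!d$fly_a$frames$valid])))
  p_imm <- coupling_params(immobile_prob = 1, seed = 6)
  row <- quiet_metrics(simulate_dyad(p_imm, n_frames = 300))
  expect_true(row$excluded)
  expect_equal(row$exclude_reason, "immobile")
})

test_that("simulated experiments carry the design and latent structure", {
  sch <- dyad_scheme("scheme1_disjoint", 8)
  exp1 <- simulate_experiment(8, sch, days = 2, params = coupling_params(),
                              n_frames = 300, seed = 12)
  expect_equal(dim(exp1$latents), c(8, 2))
  expect_equal(length(exp1$dyads), 4 * 2)  # 4 disjoint dyads x 2 days
  expect_equal(sort(unique(exp1$design$day)), 1:2)
  # same dyad composition both days under scheme 1
  d1 <- sort(unique(exp1$design$dyad_id[exp1$design$day == 1]))
  d2 <- sort(unique(exp1$design$dyad_id[exp1$design$day == 2]))
  expect_equal(d1, d2)
  exp2 <- simulate_experiment(8, sch, days = 2, params = coupling_params(),
                              n_frames = 300, seed = 12)
  expect_identical(exp1$design, exp2$design)

  # saturated scheme: rounds fill the session slots, each dyad twice
  sch3 <- dyad_scheme("scheme3_saturated", 6, repeats = 2)
  exp3 <- simulate_experiment(6, sch3, days = 2, sessions_per_day = 5,
                              params = coupling_params(), n_frames = 200,
                              seed = 13)
  counts <- table(exp3$design$dyad_id[!duplicated(
    paste(exp3$design$dyad_id, exp3$design$round))])
  expect_true(all(counts == 2))
  expect_equal(length(unique(exp3$design$dyad_id)), 15)
})

test_that("experiment CSV emission is consumable by the readers", {
  out <- tempfile("simexp")
  simulate_experiment(4, dyad_scheme("scheme1_disjoint", 4), days = 1,
                      params = coupling_params(immobile_prob = 0),
                      n_frames = 120, seed = 3, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  trajs <- read_trajectories(file.path(out, "trajectories.csv"))
  expect_length(trajs, 4)
  design <- utils::read.csv(file.path(out, "design.csv"))
  expect_equal(nrow(design), 4)  # one row per fly per session
  manifest <- yaml::read_yaml(file.path(out, "manifest.yaml"))
  expect_equal(manifest$seed, 3)
  unlink(out, recursive = TRUE)
})

test_that("turn and speed simulators honor their parameters", {
  expect_equal(turning_bias(simulate_turns(1, 50, seed = 1)), 1)
  b <- turning_bias(simulate_turns(0.5, 1e4, seed = 2))
  expect_lt(abs(b - 0.5), 0.02)
  expect_identical(simulate_turns(0.3, 100, seed = 9)$turns,
                   simulate_turns(0.3, 100, seed = 9)$turns)
  sp <- simulate_speed_population(500, seed = 4)
  expect_length(sp, 500)
  expect_true(all(sp > 0))
  expect_identical(sp, simulate_speed_population(500, seed = 4))
})
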