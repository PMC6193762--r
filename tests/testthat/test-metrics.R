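test_that("interactivity index is the Pearson correlation of distance series", {
  expect_equal(interactivity_index(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(interactivity_index(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  # from-definition sum-of-products oracle
  a <- c(0, 2, 1, 3, 2); b <- c(1, 1, 2, 2, 3)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(interactivity_index(a, b), num / den)
  expect_equal(interactivity_index(a, b), interactivity_index(b, a))
})

test_that("index handles invalid frames, degeneracy, and affine shifts", {
  a <- c(1, NA, 3, 4, 2); b <- c(2, 5, NA, 1, 3)
  ok <- is.finite(a) & is.finite(b)
  expect_equal(interactivity_index(a, b), stats::cor(a[ok], b[ok]))
  expect_true(is.na(interactivity_index(c(1, 1, 1, 1), c(1, 2, 3, 4))))
  expect_error(interactivity_index(1:3, 1:4), "equal length")
  expect_error(interactivity_index(c(1, NA, 2), c(NA, 1, 2)), "3 jointly valid")
  set.seed(5)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(interactivity_index(x + 10, y), interactivity_index(x, y))
  expect_equal(interactivity_index(mean(x) - (x - mean(x)), y),
               -interactivity_index(x, y))
})

test_that("coincidental approaches count maximal co-occupancy episodes", {
  expect_equal(coincidental_approaches(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_equal(coincidental_approaches(rep(1, 10), rep(2, 10)), 1)
  # two events: both in zone at frames 2 and 5, fly b exits in between
  expect_equal(coincidental_approaches(c(5, 2, 2, 5, 2), c(5, 2, 5, 5, 2)), 2)
  # boundary is inclusive
  expect_equal(coincidental_approaches(c(3, 5), c(3, 5)), 1)
})

test_that("episode counting equals brute force on random co-occupancy patterns", {
  set.seed(99)
  for (i in 1:400) {
    n <- sample(2:60, 1)
    da <- sample(c(1, 5), n, replace = TRUE)
    db <- sample(c(1, 5), n, replace = TRUE)
    if (i %% 3 == 0) da[sample(n, ceiling(n / 5))] <- NA
    got <- coincidental_approaches(da, db, 3)
    want <- brute_force_episodes((da <= 3) & (db <= 3))
    expect_identical(got, want)
    expect_lte(got, ceiling(n / 2))
  }
})

test_that("NA frames do not fabricate exits between episodes", {
  # in zone, dropout, in zone: still one episode
  expect_equal(coincidental_approaches(c(1, NA, 1), c(1, NA, 1)), 1)
  # in zone, dropout, observed exit, in zone: two episodes
  expect_equal(coincidental_approaches(c(1, NA, 5, 1), c(1, NA, 1, 1)), 2)
})

test_that("approach normalization uses the dyad grand mean speed", {
  expect_equal(normalize_approaches(2, 3, 5), 0.5)
  expect_equal(normalize_approaches(0, 2, 4), 0)
  base <- normalize_approaches(4, c(1, 3), c(2, 6))
  expect_equal(normalize_approaches(4, 2 * c(1, 3), 2 * c(2, 6)), base / 2)
  expect_error(normalize_approaches(1, 0, 0), "positive")
})

test_that("dyad_metrics composes geometry and the two statistics", {
  d <- make_lockstep_dyad()
  row <- dyad_metrics(d)
  expect_equal(row$interactivity_index, 1)
  expect_gte(row$coincidental_approaches, 1)
  expect_false(row$excluded)
  expect_equal(row$n_frames_used, 40)
  expect_equal(row$normalized_approaches,
               row$coincidental_approaches / row$dyad_mean_speed)

  # immobile member: flagged, not scored
  still <- make_traj(rep(-5, 40), rep(0, 40), fly_id = "fa")
  mover <- make_traj(seq(14, 1, length.out = 40), rep(0, 40), fly_id = "fb",
                     compartment = "right")
  row2 <- dyad_metrics(dyad_record(still, mover))
  expect_true(row2$excluded)
  expect_equal(row2$exclude_reason, "immobile")
  expect_true(is.na(row2$interactivity_index))
})

test_that("dyad_record validates alignment and compartments", {
  a <- make_traj(1:5 - 10, rep(0, 5), fly_id = "fa", compartment = "left")
  b_bad <- make_traj(1:4 + 5, rep(0, 4), fly_id = "fb", compartment = "right")
  expect_error(dyad_record(a, b_bad), "frame range")
  b_same <- make_traj(1:5 - 11, rep(0, 5), fly_id = "fb", compartment = "left")
  expect_error(dyad_record(a, b_same), "opposite compartments")
})
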