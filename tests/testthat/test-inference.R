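# Small deterministic dyads for shuffle-machinery tests: each fly follows an
# independent seeded OU-like wander so every fictive pair is well defined.
make_session_dyads <- function(n_dyads, n = 120, seed = 1) {
  set.seed(seed)
  wander <- function(id, comp) {
    x0 <- if (comp == "left") -7 else 7
    dx <- stats::filter(rnorm(n, sd = 1.2), 0.9, method = "recursive")
    x <- pmin(pmax(x0 + as.numeric(dx), -14), 14)
    x <- if (comp == "left") pmin(x, -1) else pmax(x, 1)
    make_traj(x, rep(0, n), fly_id = id, compartment = comp)
  }
  lapply(seq_len(n_dyads), function(i) {
    dyad_record(wander(sprintf("a%d", i), "left"),
                wander(sprintf("b%d", i), "right"),
                dyad_id = sprintf("dy%d", i))
  })
}

test_that("shuffled null enumerates exactly the non-true cross-pairings", {
  dyads <- make_session_dyads(2)
  nd <- shuffled_null(dyads, n_perm = 200, seed = 11)
  # dyad 1 = (a1, b1), dyad 2 = (a2, b2): exactly the 4 cross-pairings remain
  seen <- unique(paste(pmin(nd$pairs$fly_i, nd$pairs$fly_j),
                       pmax(nd$pairs$fly_i, nd$pairs$fly_j)))
  expect_setequal(seen, c("a1 a2", "a1 b2", "a2 b1", "b1 b2"))
  # no true pairing ever appears
  expect_false(any(seen %in% c("a1 b1", "a2 b2")))
})

test_that("shuffled null is seed-reproducible and excludes true pairs generally", {
  dyads <- make_session_dyads(5, seed = 3)
  n1 <- shuffled_null(dyads, n_perm = 30, seed = 42)
  n2 <- shuffled_null(dyads, n_perm = 30, seed = 42)
  expect_identical(n1$values, n2$values)
  true_keys <- vapply(dyads, function(d) {
    paste(sort(c(d$fly_a$fly_id, d$fly_b$fly_id)), collapse = " ")
  }, character(1))
  got_keys <- paste(pmin(n1$pairs$fly_i, n1$pairs$fly_j),
                    pmax(n1$pairs$fly_i, n1$pairs$fly_j))
  expect_false(any(got_keys %in% true_keys))
  # side-preserving mode only pairs across compartments
  ns <- shuffled_null(dyads, n_perm = 30, seed = 1, mode = "side_preserving")
  expect_true(all(grepl("^a", ns$pairs$fly_i) & grepl("^b", ns$pairs$fly_j)))
  expect_error(shuffled_null(dyads[1], 10), "at least 2")
  expect_error(shuffled_null(dyads, 0), "n_perm")
})

test_that("KS statistic matches a brute-force ECDF scan and stats::ks.test", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  x <- c(1, 2, 3); y <- c(1.5, 2.5)
  pts <- c(x, y)
  brute <- max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t),
                          numeric(1))))
  expect_equal(ks_two_sample(x, y)$statistic, brute)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(10:80, 1)); b <- rnorm(sample(10:80, 1), mean = runif(1))
    ours <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-6)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})

test_that("bootstrap SE approximates sigma/sqrt(n) and is seed-stable", {
  expect_equal(bootstrap_se(rep(3, 20), n_boot = 50, seed = 1), 0)
  set.seed(123)
  x <- rnorm(100)
  se <- bootstrap_se(x, mean, n_boot = 1000, seed = 5)
  expect_equal(se, 0.1, tolerance = 0.2)
  expect_identical(se, bootstrap_se(x, mean, n_boot = 1000, seed = 5))
})

test_that("Bonferroni correction multiplies and clips", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(0.03), 0.03)
  expect_equal(bonferroni(c(0.6, 0.9)), c(1, 1))
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group contrast summarises |index| and tests group pairs", {
  set.seed(8)
  idx <- rnorm(40, sd = 0.1)
  tbl <- data.frame(interactivity_index = c(idx, idx),
                    barrier_type = "open_clear",
                    genotype = rep(c("g1", "g2"), each = 40))
  gc <- group_contrast(tbl, config = analysis_config(rng_seed = 2))
  expect_equal(nrow(gc$summary), 2)
  expect_equal(gc$summary$mean_abs_index[1], mean(abs(idx)))
  expect_equal(gc$summary$n_dyads, c(40L, 40L))
  # identical groups: t = 0, adjusted p = 1
  expect_equal(gc$tests$t, 0)
  expect_equal(gc$tests$p_adj, 1)
  expect_false(gc$tests$significant)
  # zero-index group: mean and SE are 0
  tbl0 <- data.frame(interactivity_index = rep(0, 10),
                     barrier_type = "solid_black", genotype = "g1")
  gc0 <- group_contrast(tbl0, config = analysis_config(rng_seed = 2))
  expect_equal(gc0$summary$mean_abs_index, 0)
  expect_equal(gc0$summary$se, 0)
  # undersized groups are dropped with a warning
  tbl_small <- rbind(tbl, data.frame(interactivity_index = 0.5,
                                     barrier_type = "open_black",
                                     genotype = "g3"))
  expect_warning(group_contrast(tbl_small, config = analysis_config(rng_seed = 2)),
                 "< 2 dyads")
})
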