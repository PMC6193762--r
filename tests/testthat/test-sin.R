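make_index_table <- function(idx_by_day) {
  do.call(rbind, lapply(seq_along(idx_by_day), function(d) {
    v <- idx_by_day[[d]]
    data.frame(dyad_id = sprintf("dy%02d", seq_along(v)), day = d, session = 1,
               fly_a = sprintf("f%02da", seq_along(v)),
               fly_b = sprintf("f%02db", seq_along(v)),
               interactivity_index = v)
  }))
}

test_that("Fisher z-test matches the closed form", {
  zt <- fisher_z_test(0.5, 30)
  expect_equal(zt$z, atanh(0.5) * sqrt(27))
  expect_equal(zt$z, 2.854, tolerance = 2e-4)
  expect_equal(zt$p, 2 * pnorm(-atanh(0.5) * sqrt(27)))
  expect_equal(zt$p, 0.0043, tolerance = 2e-2)
  expect_equal(fisher_z_test(0, 30)$p, 1)
})

test_that("day persistence correlates matched dyads across days", {
  set.seed(21)
  v1 <- rnorm(30, sd = 0.3)
  tbl <- make_index_table(list(v1, v1))
  pr <- day_persistence(tbl, 1, 2)
  expect_equal(pr$r, 1)
  expect_equal(pr$n_dyads, 30)
  expect_equal(pr$p, 0)

  v2 <- 0.5 * v1 + rnorm(30, sd = 0.2)
  tbl2 <- make_index_table(list(v1, v2))
  pr2 <- day_persistence(tbl2, 1, 2)
  expect_equal(pr2$r, cor(v1, v2))
  expect_equal(pr2$z, atanh(pr2$r) * sqrt(27))
  # only the intersection of dyads is used
  tbl3 <- tbl2[-(1:5), ]
  expect_message(pr3 <- day_persistence(tbl3, 1, 2), "matched")
  expect_equal(pr3$n_dyads, 25)
  expect_error(day_persistence(make_index_table(list(rnorm(2), rnorm(2))), 1, 2),
               "at least 3")
})

test_that("session aggregation averages the first and last two sessions", {
  tbl <- data.frame(dyad_id = "d1", day = 1, session = 1:6,
                    interactivity_index = c(0.2, 0.4, 0.9, -0.9, 0.1, 0.3))
  agg <- aggregate_sessions(tbl)
  expect_equal(agg$early_index, 0.3)
  expect_equal(agg$late_index, 0.2)
  # session order within a window does not change the mean
  tbl_perm <- tbl[c(2, 1, 3, 4, 6, 5), ]
  expect_equal(aggregate_sessions(tbl_perm), agg)
  # single-session dyads are excluded with a warning
  tbl2 <- rbind(tbl, data.frame(dyad_id = "d2", day = 1, session = 1,
                                interactivity_index = 0.5))
  expect_warning(agg2 <- aggregate_sessions(tbl2), "excluded")
  expect_equal(agg2$dyad_id, "d1")
})

test_that("SIN threshold is the quartile midpoint of |index|", {
  expect_equal(sin_threshold(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_equal(sin_threshold(c(-0.1, 0.2, -0.3, 0.4)), 0.25)  # absolute values
  expect_equal(sin_threshold(rep(0.3, 6)), 0.3)
  v <- c(0.05, 0.12, 0.31, 0.44, 0.27)
  expect_equal(sin_threshold(3 * v), 3 * sin_threshold(v))
  expect_equal(sin_threshold(v),
               mean(quantile(abs(v), c(0.25, 0.75), type = 7, names = FALSE)))
  expect_error(sin_threshold(c(0.1, 0.2, 0.3)), "at least 4")
})

test_that("SIN graphs threshold strictly and keep isolates", {
  idx <- data.frame(fly_a = c("a", "b", "c", "a"),
                    fly_b = c("b", "c", "d", "d"),
                    interactivity_index = c(0.1, 0.2, 0.3, 0.4))
  g_mid <- build_sin(idx, 0.25)
  expect_equal(igraph::ecount(g_mid$graph), 2)
  expect_equal(igraph::vcount(g_mid$graph), 4)
  g_hi <- build_sin(idx, 0.5)
  expect_equal(igraph::ecount(g_hi$graph), 0)
  expect_equal(igraph::vcount(g_hi$graph), 4)  # isolates kept
  g_lo <- build_sin(idx, 0.05)
  expect_equal(igraph::ecount(g_lo$graph), 4)
  # strict inequality at the threshold
  g_eq <- build_sin(idx, 0.4)
  expect_equal(igraph::ecount(g_eq$graph), 0)
})

test_that("network overlap counts shared edges and Jaccard", {
  idx1 <- data.frame(fly_a = c("a", "b"), fly_b = c("b", "c"),
                     interactivity_index = c(1, 1))
  idx2 <- data.frame(fly_a = c("b", "c"), fly_b = c("c", "d"),
                     interactivity_index = c(1, 1))
  nodes <- c("a", "b", "c", "d")
  g1 <- build_sin(idx1, 0.5, nodes = nodes)
  g2 <- build_sin(idx2, 0.5, nodes = nodes)
  ov <- sin_overlap(g1, g2)
  expect_equal(ov$shared, 1)
  expect_equal(ov$jaccard, 1 / 3)
  expect_equal(sin_overlap(g1, g1)$jaccard, 1)
  # disjoint nonempty edge sets
  idx3 <- data.frame(fly_a = "a", fly_b = "d", interactivity_index = 1)
  expect_equal(sin_overlap(g1, build_sin(idx3, 0.5, nodes = nodes))$jaccard, 0)
  # both empty is degenerate
  e1 <- build_sin(idx1, 2, nodes = nodes)
  ove <- sin_overlap(e1, e1)
  expect_true(ove$degenerate)
  expect_equal(ove$jaccard, 1)
  expect_error(sin_overlap(g1, build_sin(idx1, 0.5, nodes = c("a", "b", "c"))),
               "node universes")
})

test_that("graph exports are written", {
  idx <- data.frame(fly_a = "a", fly_b = "b", interactivity_index = 0.9)
  g <- build_sin(idx, 0.5, nodes = c("a", "b", "c"), day = 1)
  gml <- tempfile(fileext = ".graphml")
  write_sin_graphml(g, gml)
  expect_true(file.exists(gml))
  csv <- tempfile(fileext = ".csv")
  write_sin_edgelist(g, csv)
  out <- utils::read.csv(csv, comment.char = "#")
  expect_equal(nrow(out), 1)
  expect_equal(out$index, 0.9)
})
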