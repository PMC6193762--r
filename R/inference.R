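# Null models, resampling, and hypothesis tests.

#' Shuffled-pair null distribution of the interactivity index
#'
#' Builds the permutation null for dyad specificity: flies recorded
#' simultaneously in the same session are re-paired across arenas into
#' fictive dyads (all true pairings excluded), the interactivity index is
#' computed on the time-aligned distance series of each fictive pair, and
#' the values are pooled over permutations. Because the index is a temporal
#' correlation, only same-session flies may be shuffled together.
#'
#' @param dyads List of [dyad_record()] objects from the same session.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @param mode `"free"` re-pairs across all flies; `"side_preserving"` pairs
#'   each first-compartment fly with a non-partner second-compartment fly.
#' @param config An [analysis_config()].
#' @return Object of class `null_distribution`: `values` (pooled indices),
#'   `pairs` (data frame of fictive pairings), `n_perm`, `construction`,
#'   `seed`.
#' @export
shuffled_null <- function(dyads, n_perm = 100L, seed = NULL,
                          mode = c("free", "side_preserving"),
                          config = analysis_config()) {
  mode <- match.arg(mode)
  if (length(dyads) < 2) stop("need at least 2 dyads to shuffle", call. = FALSE)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nd <- length(dyads)
  dists <- lapply(dyads, .dyad_distances, config = config)
  n_frames <- min(vapply(dists, function(d) length(d$dist_a), integer(1)))
  series <- vector("list", 2 * nd)          # flies 2i-1 (side a), 2i (side b)
  fly_ids <- character(2 * nd)
  for (i in seq_len(nd)) {
    series[[2 * i - 1]] <- dists[[i]]$dist_a[seq_len(n_frames)]
    series[[2 * i]] <- dists[[i]]$dist_b[seq_len(n_frames)]
    fly_ids[2 * i - 1] <- dyads[[i]]$fly_a$fly_id
    fly_ids[2 * i] <- dyads[[i]]$fly_b$fly_id
  }
  true_pair <- function(i, j) ceiling(i / 2) == ceiling(j / 2)
  draw_pairs <- function() {
    for (try in seq_len(1000)) {
      if (mode == "free") {
        p <- matrix(sample.int(2 * nd), ncol = 2)
        if (!any(true_pair(p[, 1], p[, 2]))) return(p)
      } else {
        pb <- sample.int(nd)
        if (!any(pb == seq_len(nd))) {
          return(cbind(2 * seq_len(nd) - 1L, 2L * pb))
        }
      }
    }
    stop("could not draw a non-true re-pairing", call. = FALSE)
  }
  vals <- vector("list", n_perm)
  pair_rows <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    pp <- draw_pairs()
    v <- vapply(seq_len(nrow(pp)), function(r) {
      a <- series[[pp[r, 1]]]; b <- series[[pp[r, 2]]]
      okn <- sum(is.finite(a) & is.finite(b))
      if (okn < 3) return(NA_real_)
      interactivity_index(a, b)
    }, numeric(1))
    vals[[p]] <- v
    pair_rows[[p]] <- data.frame(perm = p,
                                 fly_i = fly_ids[pp[, 1]],
                                 fly_j = fly_ids[pp[, 2]],
                                 index = v, stringsAsFactors = FALSE)
  }
  values <- unlist(vals)
  structure(list(values = values[is.finite(values)],
                 pairs = do.call(rbind, pair_rows),
                 n_perm = n_perm,
                 construction = if (mode == "free") "computational_shuffle"
                                else "computational_shuffle_side_preserving",
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution: %d values over %d permutations (%s), mean %.4f>\n",
              length(x$values), x$n_perm, x$construction, mean(x$values)))
  invisible(x)
}

# Asymptotic Kolmogorov survival function Q(lambda) = P(K > lambda).
.kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical CDFs; the
#' p-value comes from the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_eff) * D` with effective sample size
#' `n_eff = n_x * n_y / (n_x + n_y)`. The asymptotic p-value is a documented
#' limitation for very small samples.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `statistic` (D), `p.value`, and `n_eff`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  list(statistic = D, p.value = .kolmogorov_q(sqrt(n_eff) * D), n_eff = n_eff)
}

#' Bootstrap standard error of a statistic
#'
#' Resamples the values with replacement at the original size `n_boot`
#' times; the standard error estimate is the standard deviation (with
#' `n_boot - 1` denominator) of the statistic across resamples.
#'
#' @param values Numeric vector (n >= 2).
#' @param statistic Function of a numeric vector returning a scalar.
#' @param n_boot Number of resamples (>= 2; 1000 by convention).
#' @param seed Optional integer seed.
#' @return Scalar standard error.
#' @export
bootstrap_se <- function(values, statistic = mean, n_boot = 1000L, seed = NULL) {
  stopifnot(length(values) >= 2, n_boot >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  stats::sd(vapply(seq_len(n_boot), function(i) {
    statistic(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1)))
}

#' Bonferroni correction
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values (`p * m`, clipped at 1).
#' @export
bonferroni <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Group contrasts of mean absolute interactivity
#'
#' Summarises mean |interactivity index| per group (e.g. barrier type by
#' genotype) with bootstrap standard errors, and runs Welch two-sample
#' t-tests on |index| between every pair of groups, Bonferroni-adjusted.
#' Excluded dyads and groups with fewer than 2 dyads are dropped (with a
#' warning for the latter).
#'
#' @param table A [dyad_metric_table()] data frame.
#' @param grouping Character vector of grouping column names.
#' @param config An [analysis_config()] (`n_boot`, `alpha`, `rng_seed`).
#' @return Object of class `group_contrast`: `summary` (one row per group)
#'   and `tests` (one row per group pair).
#' @export
group_contrast <- function(table, grouping = c("barrier_type", "genotype"),
                           config = analysis_config()) {
  stopifnot(is.data.frame(table), all(grouping %in% names(table)),
            "interactivity_index" %in% names(table))
  tbl <- table[is.finite(table$interactivity_index), , drop = FALSE]
  if (!is.null(tbl$excluded)) tbl <- tbl[!tbl$excluded, , drop = FALSE]
  key <- interaction(tbl[grouping], drop = TRUE, sep = ":")
  groups <- split(abs(tbl$interactivity_index), key)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small) > 0) {
    warning(sprintf("group(s) with < 2 dyads excluded: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) == 0) stop("no group has >= 2 dyads", call. = FALSE)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  summ <- data.frame(
    group = names(groups),
    mean_abs_index = vapply(groups, mean, numeric(1)),
    se = vapply(groups, bootstrap_se, numeric(1), n_boot = config$n_boot),
    n_dyads = vapply(groups, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  tests <- NULL
  if (length(groups) >= 2) {
    cmb <- utils::combn(names(groups), 2)
    tests <- data.frame(
      group1 = cmb[1, ], group2 = cmb[2, ],
      t = NA_real_, df = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(cmb))) {
      tt <- stats::t.test(groups[[cmb[1, i]]], groups[[cmb[2, i]]],
                          var.equal = FALSE)
      tests$t[i] <- unname(tt$statistic)
      tests$df[i] <- unname(tt$parameter)
      tests$p[i] <- tt$p.value
    }
    tests$p_adj <- bonferroni(tests$p)
    tests$significant <- tests$p_adj < config$alpha
  }
  structure(list(summary = summ, tests = tests, grouping = grouping,
                 alpha = config$alpha),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast over %s>\n", paste(x$grouping, collapse = " x ")))
  print(x$summary)
  if (!is.null(x$tests)) {
    cat(sprintf("%d pairwise Welch t-test(s), Bonferroni-adjusted at alpha = %g\n",
                nrow(x$tests), x$alpha))
  }
  invisible(x)
}
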