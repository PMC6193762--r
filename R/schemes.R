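# Dyad pairing schemes, round-robin session schedules, and array layouts.

#' Define a dyad pairing scheme
#'
#' Three designs for forming dyads from a pool of flies:
#' * `scheme1_disjoint` — one random perfect matching; every fly is in
#'   exactly one dyad (high throughput).
#' * `scheme2_kregular` — every fly is a member of exactly `k` dyads; the
#'   pairing graph is a uniform simple k-regular graph.
#' * `scheme3_saturated` — all `choose(n, 2)` dyads (saturated design, run
#'   as a round-robin tournament; see [schedule_rounds()]).
#'
#' @param scheme Scheme name.
#' @param n_flies Number of flies (even for schemes 1 and 3).
#' @param k Dyads per fly (scheme 2 only; `n_flies * k` must be even and
#'   `k < n_flies`).
#' @param repeats Times each dyad is tested (scheme 3 scheduling).
#' @param seed Optional integer seed for the random constructions.
#' @return An object of class `dyad_scheme`.
#' @export
dyad_scheme <- function(scheme = c("scheme1_disjoint", "scheme2_kregular",
                                   "scheme3_saturated"),
                        n_flies, k = NULL, repeats = 1L, seed = NULL) {
  scheme <- match.arg(scheme)
  n_flies <- as.integer(n_flies)
  stopifnot(n_flies >= 2, repeats >= 1)
  if (scheme == "scheme1_disjoint" && n_flies %% 2 != 0) {
    stop("scheme1_disjoint requires an even number of flies", call. = FALSE)
  }
  if (scheme == "scheme2_kregular") {
    if (is.null(k)) stop("scheme2_kregular requires k", call. = FALSE)
    k <- as.integer(k)
    if (k >= n_flies || k < 1) stop("scheme2 requires 1 <= k < n_flies", call. = FALSE)
    if ((n_flies * k) %% 2 != 0) {
      stop("scheme2 requires n_flies * k to be even", call. = FALSE)
    }
  }
  if (scheme == "scheme3_saturated" && n_flies %% 2 != 0) {
    stop("scheme3_saturated requires an even number of flies for conflict-free rounds",
         call. = FALSE)
  }
  structure(list(scheme = scheme, n_flies = n_flies, k = k,
                 repeats = as.integer(repeats), seed = seed),
            class = "dyad_scheme")
}

#' Enumerate the dyads of a pairing scheme
#'
#' @param design A [dyad_scheme()].
#' @return Integer matrix with columns `fly_a`, `fly_b` (fly indices,
#'   `fly_a < fly_b`), one row per dyad.
#' @examples
#' nrow(enumerate_dyads(dyad_scheme("scheme3_saturated", 10)))  # 45
#' @export
enumerate_dyads <- function(design) {
  stopifnot(inherits(design, "dyad_scheme"))
  n <- design$n_flies
  if (!is.null(design$seed)) set.seed(design$seed)
  pairs <- switch(design$scheme,
    scheme1_disjoint = matrix(sample.int(n), ncol = 2),
    scheme2_kregular = {
      g <- igraph::sample_k_regular(n, design$k)
      igraph::as_edgelist(g)
    },
    scheme3_saturated = t(utils::combn(n, 2))
  )
  pairs <- cbind(fly_a = pmin(pairs[, 1], pairs[, 2]),
                 fly_b = pmax(pairs[, 1], pairs[, 2]))
  storage.mode(pairs) <- "integer"
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Round-robin schedule for the saturated scheme
#'
#' Partitions the `choose(n, 2)` dyads into `(n - 1) * repeats` rounds by
#' the classical circle method, so that every round is a perfect matching
#' (each fly assayed exactly once per round) and every dyad appears exactly
#' `repeats` times across the schedule.
#'
#' @param dyads Dyad matrix from [enumerate_dyads()] on a saturated scheme
#'   (used for validation).
#' @param n_flies Even number of flies.
#' @param repeats Number of passes through the full dyad set.
#' @return List of rounds; each round is an integer matrix with columns
#'   `fly_a`, `fly_b`.
#' @export
schedule_rounds <- function(dyads, n_flies, repeats = 1L) {
  n <- as.integer(n_flies)
  if (n %% 2 != 0) stop("schedule_rounds requires an even number of flies", call. = FALSE)
  all_pairs <- t(utils::combn(n, 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  if (!setequal(key(dyads), key(all_pairs)) || nrow(dyads) != nrow(all_pairs)) {
    stop("dyads must be exactly the full set of C(n, 2) pairs", call. = FALSE)
  }
  idx <- function(i) ((i - 1L) %% (n - 1L)) + 1L
  one_cycle <- lapply(seq_len(n - 1L), function(r) {
    a <- c(n, vapply(seq_len(n / 2 - 1L), function(i) idx(r + i), integer(1)))
    b <- c(idx(r), vapply(seq_len(n / 2 - 1L), function(i) idx(r - i), integer(1)))
    m <- cbind(fly_a = pmin(a, b), fly_b = pmax(a, b))
    storage.mode(m) <- "integer"
    m[order(m[, 1]), , drop = FALSE]
  })
  if (n == 2L) {
    one_cycle <- list(matrix(c(1L, 2L), ncol = 2,
                             dimnames = list(NULL, c("fly_a", "fly_b"))))
  }
  rep(one_cycle, times = repeats)
}

#' Lay out an array of arenas on a grid
#'
#' @param kind `"social"` (bisected circular arenas, two compartments each),
#'   `"ymaze"`, or `"flyplate"` (one compartment each).
#' @param rows,cols Grid dimensions (>= 1).
#' @param pitch Center-to-center spacing in mm.
#' @param diameter,barrier_thickness Arena geometry passed to [arena_spec()]
#'   for social arrays.
#' @return An object of class `array_layout` with the arena list and the
#'   total arena and compartment counts.
#' @examples
#' array_layout("social", 9, 9)$n_compartments  # 162
#' @export
array_layout <- function(kind = c("social", "ymaze", "flyplate"),
                         rows, cols, pitch = 33,
                         diameter = 30, barrier_thickness = 1.5) {
  kind <- match.arg(kind)
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1, cols >= 1, pitch > 0)
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  centers <- cbind(x = (grid$col - 1) * pitch, y = (grid$row - 1) * pitch)
  arenas <- NULL
  if (kind == "social") {
    arenas <- lapply(seq_len(nrow(grid)), function(i) {
      arena_spec(arena_id = sprintf("arena%03d", i), center = centers[i, ],
                 diameter = diameter, barrier_thickness = barrier_thickness)
    })
  }
  per_arena <- if (kind == "social") 2L else 1L
  structure(list(kind = kind, rows = rows, cols = cols, pitch = pitch,
                 centers = data.frame(arena_id = sprintf("arena%03d", seq_len(nrow(grid))),
                                      x = centers[, 1], y = centers[, 2]),
                 arenas = arenas,
                 n_arenas = rows * cols,
                 n_compartments = rows * cols * per_arena),
            class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("<array_layout %s: %dx%d, %d arenas, %d compartments>\n",
              x$kind, x$rows, x$cols, x$n_arenas, x$n_compartments))
  invisible(x)
}

#' Export an array layout as CSV
#'
#' Writes one row per arena with its center coordinates.
#'
#' @param layout An [array_layout()].
#' @param path Output CSV path.
#' @export
write_array_layout <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  utils::write.csv(layout$centers, path, row.names = FALSE)
  invisible(path)
}
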