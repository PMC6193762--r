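# End-to-end pipeline over CSV artifacts: simulate -> metrics -> null ->
# persist -> sin -> locomotor.

# Internal: polynomial rolling hash of a serialized object, for provenance
# headers (stays in double precision; 2^32 modulus keeps it exact).
.config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.pkg_version <- function() {
  as.character(utils::packageVersion("flysin"))
}

.provenance <- function(config) {
  # hash the parameters, not the output location
  params <- unclass(config)[setdiff(names(config), "out_dir")]
  c(sprintf("flysin %s", .pkg_version()),
    sprintf("config_hash %s", .config_hash(params)),
    sprintf("seed %s", format(config$seed)))
}

#' Pipeline run configuration
#'
#' Layered configuration for [run_pipeline()]: built-in defaults, overridden
#' by a YAML file (if given), overridden by `...` arguments.
#'
#' @param path Optional YAML file of overrides.
#' @param ... Named overrides (see Details).
#' @details Recognised fields: `out_dir`, `seed`, `n_flies`, `scheme`
#'   (`"scheme1_disjoint"`, `"scheme2_kregular"`, `"scheme3_saturated"`),
#'   `k`, `repeats`, `days`, `sessions_per_day`, `n_frames`, `fps`,
#'   `barrier_type`, `genotype`, `n_perm`, `shuffle_mode`, plus the
#'   [analysis_config()] fields under `analysis`.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(out_dir = "flysin-run", seed = 1L, n_flies = 20L,
              scheme = "scheme1_disjoint", k = NULL, repeats = 1L,
              days = 2L, sessions_per_day = 1L, n_frames = 10000L, fps = 29.9,
              barrier_type = "open_clear", genotype = "CantonS",
              n_perm = 100L, shuffle_mode = "free",
              analysis = list())
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg$analysis <- do.call(analysis_config,
                          c(cfg$analysis, list(fps = cfg$fps)))
  structure(cfg, class = "run_config")
}

.write_csv_with_header <- function(df, path, config, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(.provenance(config), extra)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_design <- function(config) {
  utils::read.csv(file.path(config$out_dir, "design.csv"),
                  stringsAsFactors = FALSE, comment.char = "#")
}

# Internal: rebuild dyad_record objects from trajectory + design CSVs.
.load_dyads <- function(config) {
  trajs <- read_trajectories(file.path(config$out_dir, "trajectories.csv"),
                             config$analysis)
  design <- .read_design(config)
  key <- unique(design[c("day", "session", "dyad_id", "arena_id",
                         "barrier_type", "genotype")])
  lapply(seq_len(nrow(key)), function(r) {
    rows <- design[design$day == key$day[r] & design$session == key$session[r] &
                     design$dyad_id == key$dyad_id[r], ]
    tr <- lapply(rows$fly_id, function(f) {
      trajs[[sprintf("%s.d%d.s%d", f, key$day[r], key$session[r])]]
    })
    gap <- config$analysis$max_gap_frames
    tr <- lapply(tr, interpolate_gaps, max_gap_frames = gap)
    dyad_record(tr[[1]], tr[[2]],
                arena = arena_spec(arena_id = key$arena_id[r]),
                barrier = barrier_spec(key$barrier_type[r]),
                genotype = key$genotype[r], dyad_id = key$dyad_id[r],
                day = key$day[r], session = key$session[r])
  })
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over CSV artifacts in `config$out_dir`:
#' * `simulate` — synthetic experiment ([simulate_experiment()]) written as
#'   `trajectories.csv` + `design.csv` + `manifest.yaml`;
#' * `metrics` — [dyad_metric_table()] from the trajectory and design files
#'   (`dyad_metrics.csv`);
#' * `null` — shuffled-pair null per session plus a KS comparison of
#'   observed vs shuffled indices (`null_distribution.csv`, `ks_test.csv`);
#' * `persist` — day-to-day persistence for consecutive day pairs
#'   (`persistence.csv`);
#' * `sin` — day-1 quartile-midpoint threshold, per-day networks (edge
#'   lists + GraphML), and day-pair edge overlap (`sin_summary.csv`);
#' * `locomotor` — per-fly mean speeds, activity fraction, and a KDE with
#'   bootstrap band (`locomotor.csv`, `speed_kde.csv`).
#'
#' Every CSV carries `#` header lines recording the package version, a
#' config hash, and the seed. Stages read only the CSV artifacts of earlier
#' stages, so `metrics` onward also run on externally supplied files in the
#' same dialect.
#'
#' @param config A [pipeline_config()].
#' @param stages Stage names, or `"all"`.
#' @return Invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "metrics", "null", "persist",
                                    "sin", "locomotor")) {
  stopifnot(inherits(config, "run_config"))
  if (identical(stages, "all")) {
    stages <- c("simulate", "metrics", "null", "persist", "sin", "locomotor")
  }
  known <- c("simulate", "metrics", "null", "persist", "sin", "locomotor")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  for (st in known[known %in% stages]) {
    res[[st]] <- switch(st,
      simulate = .stage_simulate(config),
      metrics = .stage_metrics(config),
      null = .stage_null(config),
      persist = .stage_persist(config),
      sin = .stage_sin(config),
      locomotor = .stage_locomotor(config))
    message(sprintf("[flysin] stage '%s' done", st))
  }
  invisible(res)
}

.stage_simulate <- function(config) {
  sch <- dyad_scheme(config$scheme, config$n_flies, k = config$k,
                     repeats = config$repeats)
  simulate_experiment(
    n_flies = config$n_flies, scheme = sch, days = config$days,
    sessions_per_day = config$sessions_per_day,
    params = coupling_params(seed = config$seed),
    barrier = barrier_spec(config$barrier_type), genotype = config$genotype,
    n_frames = config$n_frames, fps = config$fps, seed = config$seed,
    out_dir = config$out_dir)
  invisible(file.path(config$out_dir, "trajectories.csv"))
}

.stage_metrics <- function(config) {
  dyads <- .load_dyads(config)
  tbl <- dyad_metric_table(dyads, config$analysis)
  .write_csv_with_header(tbl, file.path(config$out_dir, "dyad_metrics.csv"),
                         config)
  tbl
}

.stage_null <- function(config) {
  dyads <- .load_dyads(config)
  tbl <- utils::read.csv(file.path(config$out_dir, "dyad_metrics.csv"),
                         stringsAsFactors = FALSE, comment.char = "#")
  by_sess <- split(dyads, vapply(dyads, function(d) {
    sprintf("d%d.s%d", d$day, d$session)
  }, character(1)))
  by_sess <- Filter(function(g) length(g) >= 2, by_sess)
  nulls <- lapply(seq_along(by_sess), function(i) {
    shuffled_null(by_sess[[i]], n_perm = config$n_perm,
                  seed = config$seed + i, mode = config$shuffle_mode,
                  config = config$analysis)
  })
  null_values <- unlist(lapply(nulls, `[[`, "values"))
  observed <- tbl$interactivity_index[is.finite(tbl$interactivity_index) &
                                        !tbl$excluded]
  ks <- ks_two_sample(observed, null_values)
  .write_csv_with_header(data.frame(index = null_values),
                         file.path(config$out_dir, "null_distribution.csv"),
                         config, extra = sprintf("construction %s n_perm %d",
                                                 nulls[[1]]$construction,
                                                 config$n_perm))
  .write_csv_with_header(
    data.frame(D = ks$statistic, p = ks$p.value, n_eff = ks$n_eff,
               n_observed = length(observed), n_null = length(null_values)),
    file.path(config$out_dir, "ks_test.csv"), config)
  list(null_values = null_values, ks = ks)
}

.stage_persist <- function(config) {
  tbl <- utils::read.csv(file.path(config$out_dir, "dyad_metrics.csv"),
                         stringsAsFactors = FALSE, comment.char = "#")
  days <- sort(unique(tbl$day))
  if (length(days) < 2) stop("persist stage needs at least 2 days", call. = FALSE)
  rows <- lapply(days[-length(days)], function(d) {
    pr <- day_persistence(tbl, d, d + 1)
    data.frame(day_i = d, day_j = d + 1, r = pr$r, n_dyads = pr$n_dyads,
               z = pr$z, p = pr$p)
  })
  out <- do.call(rbind, rows)
  .write_csv_with_header(out, file.path(config$out_dir, "persistence.csv"),
                         config)
  out
}

.stage_sin <- function(config) {
  tbl <- utils::read.csv(file.path(config$out_dir, "dyad_metrics.csv"),
                         stringsAsFactors = FALSE, comment.char = "#")
  tbl <- tbl[is.finite(tbl$interactivity_index) & !tbl$excluded, ]
  days <- sort(unique(tbl$day))
  day1 <- tbl[tbl$day == days[1], ]
  thr <- sin_threshold(day1$interactivity_index)
  nodes <- sort(unique(c(tbl$fly_a, tbl$fly_b)))
  graphs <- lapply(days, function(d) {
    sub <- tbl[tbl$day == d, ]
    per_dyad <- stats::aggregate(interactivity_index ~ fly_a + fly_b, sub, mean)
    rule <- if (d == days[1]) "mean of Q1 and Q3 of day-1 |index| (type 7)"
            else sprintf("day-%d threshold reused", days[1])
    g <- build_sin(per_dyad, thr, nodes = nodes, day = d, threshold_rule = rule)
    write_sin_edgelist(g, file.path(config$out_dir,
                                    sprintf("sin_day%d_edges.csv", d)),
                       header_lines = .provenance(config))
    write_sin_graphml(g, file.path(config$out_dir,
                                   sprintf("sin_day%d.graphml", d)))
    g
  })
  overlaps <- NULL
  if (length(graphs) >= 2) {
    overlaps <- do.call(rbind, lapply(seq_len(length(graphs) - 1), function(i) {
      ov <- sin_overlap(graphs[[i]], graphs[[i + 1]])
      data.frame(day_i = days[i], day_j = days[i + 1], shared = ov$shared,
                 jaccard = ov$jaccard, degenerate = ov$degenerate)
    }))
  }
  summ <- data.frame(day = days, threshold = thr,
                     n_edges = vapply(graphs, function(g)
                       igraph::ecount(g$graph), numeric(1)),
                     n_nodes = length(nodes))
  .write_csv_with_header(summ, file.path(config$out_dir, "sin_summary.csv"),
                         config)
  if (!is.null(overlaps)) {
    .write_csv_with_header(overlaps,
                           file.path(config$out_dir, "sin_overlap.csv"), config)
  }
  list(threshold = thr, graphs = graphs, overlap = overlaps)
}

.stage_locomotor <- function(config) {
  trajs <- read_trajectories(file.path(config$out_dir, "trajectories.csv"),
                             config$analysis)
  speeds <- vapply(trajs, function(t) {
    tryCatch(mean_speed(t), error = function(e) NA_real_)
  }, numeric(1))
  speeds <- speeds[is.finite(speeds)]
  act <- activity_fraction(speeds, config$analysis$speed_threshold)
  per_fly <- data.frame(fly_session = names(speeds), mean_speed = speeds,
                        row.names = NULL)
  .write_csv_with_header(per_fly, file.path(config$out_dir, "locomotor.csv"),
                         config,
                         extra = sprintf("activity_fraction %.4f", act))
  kde <- kde_with_bootstrap_band(speeds, n_boot = config$analysis$n_boot,
                                 seed = config$seed)
  .write_csv_with_header(
    data.frame(grid = kde$grid, density = kde$density, lower = kde$lower,
               upper = kde$upper),
    file.path(config$out_dir, "speed_kde.csv"), config,
    extra = sprintf("bandwidth %.6g (silverman)", kde$bw))
  list(activity_fraction = act, mean_speeds = speeds, kde = kde)
}
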