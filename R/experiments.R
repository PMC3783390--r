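#' Replicate a scenario and aggregate trajectory statistics
#'
#' Runs the scenario with seeds `base_seed + 0 .. n_reps - 1` and aggregates
#' per-phase means and standard deviations of total productivity and active
#' occupation count for every society present, plus extinction counts, the
#' final per-occupation productivity samples and a Shapiro-Wilk normality
#' result per surviving replicate. Statistics are aligned by phase index
#' (all replicates share `n_phases`). Deterministic given `base_seed`.
#'
#' @param scenario scenario name, see [run_scenario()].
#' @param cfg a [scenario_config()].
#' @param n_reps replication count (default `cfg$n_reps`).
#' @param base_seed first seed (default `cfg$seed`).
#' @return An object of class `replicate_summary` with elements `stats`
#'   (data frame: phase, society, mean_X, sd_X, mean_count, sd_count),
#'   `extinctions` (named counts), `final_productivity` (list of numeric
#'   vectors), `normality` (data frame: rep, W, p_value), `seeds`,
#'   `scenario`, `config` and the list of `trajectories`.
#' @export
replicate_scenario <- function(scenario, cfg, n_reps = NULL,
                               base_seed = NULL) {
  n_reps <- as.integer(n_reps %||% cfg$n_reps)
  base_seed <- as.integer(base_seed %||% cfg$seed)
  if (n_reps < 1) stop("n_reps must be >= 1")
  seeds <- base_seed + seq_len(n_reps) - 1L
  trajs <- lapply(seeds, function(s) run_scenario(scenario, cfg, seed = s))

  societies <- names(trajs[[1]]$extinct)
  stats <- do.call(rbind, lapply(societies, function(soc) {
    Xs <- vapply(trajs, function(t) t$records[[paste0("X_", soc)]],
                 numeric(nrow(trajs[[1]]$records)))
    Ns <- vapply(trajs, function(t) t$records[[paste0("n_", soc)]],
                 numeric(nrow(trajs[[1]]$records)))
    Xs <- matrix(Xs, ncol = n_reps)
    Ns <- matrix(Ns, ncol = n_reps)
    data.frame(phase = trajs[[1]]$records$phase, society = soc,
               mean_X = rowMeans(Xs), sd_X = apply(Xs, 1, sd),
               mean_count = rowMeans(Ns), sd_count = apply(Ns, 1, sd))
  }))
  if (n_reps == 1L) stats$sd_X <- stats$sd_count <- 0

  extinctions <- vapply(societies, function(soc)
    extinction_count(trajs, soc), integer(1))

  final_productivity <- lapply(trajs, function(t)
    t$final_state$x[t$final_state$active])

  surviving <- which(!vapply(trajs, function(t) all(t$extinct), logical(1)))
  normality <- do.call(rbind, lapply(surviving, function(k) {
    xs <- final_productivity[[k]]
    if (length(xs) < 3 || sd(xs) == 0) return(NULL)
    nt <- normality_test(xs)
    data.frame(rep = k, W = nt$W, p_value = nt$p_value)
  }))
  if (is.null(normality))
    normality <- data.frame(rep = integer(0), W = numeric(0),
                            p_value = numeric(0))

  structure(list(scenario = scenario, stats = stats,
                 extinctions = extinctions,
                 final_productivity = final_productivity,
                 normality = normality, seeds = seeds, config = cfg,
                 trajectories = trajs),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("<replicate_summary> ", x$scenario, " scenario, ",
      length(x$seeds), " replicates\n", sep = "")
  fin <- x$stats[x$stats$phase == max(x$stats$phase), ]
  for (k in seq_len(nrow(fin))) {
    cat(sprintf("  %s: final X = %.2f (sd %.2f), count = %.1f, extinct in %d/%d\n",
                fin$society[k], fin$mean_X[k], fin$sd_X[k],
                fin$mean_count[k], x$extinctions[[fin$society[k]]],
                length(x$seeds)))
  }
  invisible(x)
}

#' Count replicates in which a society went extinct
#'
#' @param trajectories list of `trajectory` objects.
#' @param society society label (`"original"`, `"derived"`, `"invader"`).
#' @return Number of trajectories whose final state has no active occupation
#'   with that label.
#' @export
extinction_count <- function(trajectories, society) {
  if (length(trajectories) == 0) stop("no trajectories given")
  sum(vapply(trajectories, function(t) {
    if (!society %in% names(t$extinct))
      stop("unknown society label: ", society)
    t$extinct[[society]]
  }, logical(1)))
}

#' Shapiro-Wilk normality test of a productivity sample
#'
#' @param values numeric sample of steady-state productivities (length >= 3,
#'   non-constant).
#' @return List with the `W` statistic and `p_value`.
#' @export
normality_test <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (sd(values) == 0) stop("sample is constant")
  sh <- shapiro.test(values)
  list(W = unname(sh$statistic), p_value = sh$p.value)
}

#' Write a replicate summary to disk
#'
#' Emits `trajectory_stats.csv` (phase, society, mean_X, sd_X, mean_count,
#' sd_count; floats at 10 significant digits) and `run_metadata.json`
#' (scenario, full configuration under its parameter-table names, seeds,
#' extinction counts and the per-replicate normality results) into `dir`.
#' The pair round-trips through [read_summary()].
#'
#' @param summary a `replicate_summary`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stats <- summary$stats
  num <- vapply(stats, is.numeric, logical(1))
  stats[num] <- lapply(stats[num], signif, digits = 10)
  write.csv(stats, file.path(dir, "trajectory_stats.csv"), row.names = FALSE)
  meta <- list(scenario = summary$scenario,
               config = unclass(summary$config),
               seeds = summary$seeds,
               n_reps = length(summary$seeds),
               extinctions = as.list(summary$extinctions),
               normality = summary$normality,
               normality_mean = list(
                 W = if (nrow(summary$normality)) mean(summary$normality$W)
                     else NA,
                 p_value = if (nrow(summary$normality))
                     mean(summary$normality$p_value) else NA))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}

#' Read back a summary written by [write_summary()]
#' @param dir directory holding `trajectory_stats.csv` and
#'   `run_metadata.json`.
#' @return List with `stats` (data frame) and `metadata` (list).
#' @export
read_summary <- function(dir) {
  stats <- read.csv(file.path(dir, "trajectory_stats.csv"),
                    stringsAsFactors = FALSE)
  metadata <- jsonlite::read_json(file.path(dir, "run_metadata.json"),
                                  simplifyVector = TRUE)
  list(stats = stats, metadata = metadata)
}

#' Write a run manifest
#'
#' Records the resolved parameter set, seed, output directory, tool version
#' and wall-clock start before any run output is produced.
#'
#' @param cfg a [scenario_config()].
#' @param seed the seed the run will use.
#' @param out_dir run output directory.
#' @param config_path path of the source config file, if any.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(cfg, seed, out_dir, config_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_path = config_path %||% NA,
                   parameters = unclass(cfg),
                   seed = seed,
                   out_dir = out_dir,
                   tool_version =
                     as.character(utils::packageVersion("evosoc")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
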