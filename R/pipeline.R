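#' @name pipeline
#' @title End-to-end pipeline orchestration
#'
#' @description Runs (optionally) simulate -> mine-pairs ->
#' build-trajectories -> export from a single configuration, writing all
#' tables with a provenance header (package version, config digest, seed)
#' and a machine-readable stage-count report. Identical configuration and
#' seed give byte-identical outputs.
NULL

#' Run the full trajectory-mining pipeline
#'
#' @param config either a YAML file path or a named list with entries:
#'   * `simulate` — a [simulation_config()] (or list of its arguments); when
#'     absent, `events` and `patients` must point to registry files,
#'   * `events`, `patients` — input registry paths (ignored when simulating),
#'   * `thresholds` — list of [threshold_config()] overrides,
#'   * `min_followers` (default 20), `max_length` (default 6),
#'   * `sex_filter` ("all"/"male"/"female"),
#'   * `min_patients` — suppression threshold (default 5),
#'   * `seed` — integer seed.
#' @param out_dir output directory, created if needed.
#' @param seed optional seed override.
#' @return invisibly, a list with the `registry`, `pairs`, `trajectories`,
#'   `network`, `stage_counts` and the output `paths`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config) && length(config) == 1L)
    yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(rapply(cfg, function(x)
    if (inherits(x, "Date")) format(x) else x, how = "replace"), cfg_path)
  cfg_md5 <- unname(tools::md5sum(cfg_path))
  prov <- c(paste0("trajmine ", as.character(utils::packageVersion("trajmine"))),
            paste0("seed: ", cfg$seed),
            paste0("config_md5: ", cfg_md5))

  ## stage: registry ------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (!inherits(sim, "simulation_config")) {
      if (!is.null(sim$rules)) sim$rules <- data.table::rbindlist(
        lapply(sim$rules, as.data.frame))
      if (!is.null(sim$code_universe)) sim$code_universe <- unlist(sim$code_universe)
      sim$seed <- cfg$seed
      sim <- do.call(simulation_config, sim)
    }
    reg <- tryCatch(simulate_registry(sim),
                    error = function(e) stop("stage simulate failed: ",
                                             conditionMessage(e), call. = FALSE))
    write_registry(reg, file.path(out_dir, "events.csv"),
                   file.path(out_dir, "patients.csv"), provenance = prov)
  } else {
    if (is.null(cfg$events) || is.null(cfg$patients))
      stop("config needs either a 'simulate' block or 'events' + 'patients' paths",
           call. = FALSE)
    reg <- tryCatch(read_registry(cfg$events, cfg$patients),
                    error = function(e) stop("stage read-registry failed: ",
                                             conditionMessage(e), call. = FALSE))
  }

  ## stage: mine-pairs ----------------------------------------------------
  th_args <- cfg$thresholds
  thresholds <- if (is.null(th_args)) threshold_config()
                else do.call(threshold_config, th_args)
  sexf <- if (is.null(cfg$sex_filter)) "all" else cfg$sex_filter
  mined <- tryCatch(
    mine_directional_pairs(reg, thresholds, sex_filter = sexf,
                           seed = cfg$seed),
    error = function(e) stop("stage mine-pairs failed: ",
                             conditionMessage(e), call. = FALSE))
  pair_path <- file.path(out_dir, "pairs.csv")
  writeLines(paste0("# ", prov), pair_path)
  data.table::fwrite(mined$pairs, pair_path, append = TRUE, col.names = TRUE)

  ## stage: build-trajectories -------------------------------------------
  min_f <- if (is.null(cfg$min_followers)) 20L else as.integer(cfg$min_followers)
  max_l <- if (is.null(cfg$max_length)) 6L else as.integer(cfg$max_length)
  traj <- tryCatch({
    tr <- build_trajectories(mined, reg, min_followers = min_f,
                             max_length = max_l)
    trajectory_summary(reg, tr)
  }, error = function(e) stop("stage build-trajectories failed: ",
                              conditionMessage(e), call. = FALSE))
  min_p <- if (is.null(cfg$min_patients)) 5L else as.integer(cfg$min_patients)
  traj_path <- file.path(out_dir, "trajectories.csv")
  export_csv(traj, traj_path, min_patients = min_p, provenance = prov)

  ## stage: export --------------------------------------------------------
  net <- tryCatch(
    merge_network(traj, reg = reg,
                  provenance = list(seed = cfg$seed, config_md5 = cfg_md5,
                                    thresholds = unclass(thresholds))),
    error = function(e) stop("stage export failed: ",
                             conditionMessage(e), call. = FALSE))
  cyjs_path <- file.path(out_dir, "network.cyjs")
  export_cyjs(net, cyjs_path, min_patients = min_p)
  edge_path <- file.path(out_dir, "edges.csv")
  export_csv(net, edge_path, min_patients = min_p, provenance = prov)

  ## stage report ---------------------------------------------------------
  lens <- table(factor(traj$length, levels = 2:max_l))
  report <- list(
    seed = cfg$seed, config_md5 = cfg_md5,
    n_patients = nrow(reg$patients), n_events = nrow(reg$events),
    stage_counts = as.list(mined$stage_counts),
    trajectories_by_length = as.list(stats::setNames(as.integer(lens),
                                                     paste0("length_", names(lens)))),
    n_trajectories = nrow(traj))
  report_path <- file.path(out_dir, "stage_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(registry = reg, pairs = mined, trajectories = traj,
                 network = net, stage_counts = mined$stage_counts,
                 paths = c(pairs = pair_path, trajectories = traj_path,
                           cyjs = cyjs_path, edges = edge_path,
                           report = report_path)))
}
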