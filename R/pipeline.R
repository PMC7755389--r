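#' Read a declarative run configuration
#'
#' A single YAML file with optional blocks `geometry`, `kinematics`,
#' `solver`, `tracers` and `synthetic`; keys are the arguments of
#' [chamber_geometry()], [beat_kinematics()], [solver_config()],
#' [track_particles()] and [generator_config()] (lengths in um, frequency in
#' Hz).
#'
#' @param path Path to a YAML config file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1) return(read_config(config))
  if (is.list(config)) return(structure(config, class = "run_config"))
  stop("config must be a path or a list", call. = FALSE)
}

config_objects <- function(config) {
  config <- as_run_config(config)
  geom <- do.call(chamber_geometry, config$geometry %||% list())
  kin_args <- config$kinematics %||% list()
  if (!is.null(kin_args$vane_width)) {
    kin_args$vane_width <- unlist(kin_args$vane_width)
  }
  kin <- do.call(beat_kinematics, kin_args)
  solver <- do.call(solver_config, config$solver %||% list())
  list(geom = geom, kin = kin, solver = solver, config = config)
}

#' Run one simulation case end to end
#'
#' Geometry, kinematics, phase-resolved solve, time averaging, diagnostics
#' (pumping/filtration rates, stagnation height) and optional particle
#' tracking, bundled with a reproducibility manifest.
#'
#' @param config A `run_config`, path to one, or plain list (see
#'   [read_config()]).
#' @param tracers Run particle tracking (default: only if the config has a
#'   `tracers` block).
#' @param out_dir Optional directory: writes `rates.tsv`, `phases.tsv`,
#'   `stagnation.tsv` (and `tracer_fates.tsv`) plus `manifest.yaml`.
#' @return A `run_manifest` list: `rates`, `phases`, `stagnation`,
#'   optionally `tracers` + `efficiency`, the `chamber_flow`, and `manifest`
#'   (config snapshot, package version, seeds, residuals, content hashes,
#'   wall time).
#' @export
run_case <- function(config, tracers = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  obj <- config_objects(config)
  tracers <- tracers %||% !is.null(obj$config$tracers)
  flow <- tryCatch(
    solve_cycle(obj$geom, obj$kin, obj$solver, keep_phases = tracers),
    error = function(e) stop("stage [solver] failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  stag <- stagnation_height(flow)
  result <- list(
    rates = flow$rates,
    phases = flow$phases,
    stagnation = stag,
    flow = flow
  )
  if (tracers) {
    targs <- obj$config$tracers %||% list()
    ens <- tryCatch(
      track_particles(flow, n = targs$n %||% 2000, seed = targs$seed %||% 1),
      error = function(e) stop("stage [tracers] failed: ", conditionMessage(e),
                               call. = FALSE)
    )
    result$tracers <- ens
    result$efficiency <- encounter_efficiency(ens)
  }
  result$manifest <- list(
    package_version = as.character(utils::packageVersion("syconpump")),
    config = unclass(as_run_config(config)),
    seeds = list(tracers = if (tracers) attr(result$tracers, "seed") else NULL),
    residual_max = max(flow$phases$residual),
    div_max = max(flow$phases$div_max),
    hashes = list(
      rates = rlang::hash(result$rates),
      phases = rlang::hash(result$phases)
    ),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(out_dir)) write_case_outputs(result, out_dir)
  class(result) <- "run_manifest"
  result
}

write_case_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(out_dir, name),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(result$rates, "rates.tsv")
  wt(result$phases, "phases.tsv")
  wt(result$stagnation, "stagnation.tsv")
  if (!is.null(result$tracers)) {
    wt(result$tracers, "tracer_fates.tsv")
    wt(result$efficiency, "efficiency.tsv")
  }
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(result)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Simulation case\n")
  print(x$rates)
  if (!is.null(x$efficiency)) {
    cat(sprintf("encounter efficiency: %.3f\n", x$efficiency$efficiency))
  }
  cat(sprintf("wall time: %.1f s\n", x$manifest$wall_time_s))
  invisible(x)
}

#' Sweep the flagellar vane width
#'
#' Repeats the cycle simulation for several vane widths and tabulates the
#' pumping and filtration rates (the vane-width dependence of the two rates
#' is the key confinement effect: filtration gains more than pumping).
#'
#' @param widths Vane widths (um); scalars or a list with two-element
#'   piecewise widths `c(confined, unconfined)`.
#' @param geom,kin,config As in [solve_cycle()]; `kin$vane_width` is
#'   replaced per run.
#' @return Tibble: one row per width with `q_ost`, `q_col`, `power_sheets`.
#' @export
sweep_vane_width <- function(widths, geom = reference_geometry(),
                             kin = beat_kinematics(),
                             config = solver_config()) {
  cell <- build_unit_cell(geom, h = config$h)
  purrr::map_dfr(widths, function(wd) {
    k <- kin
    k$vane_width <- wd
    fl <- solve_cycle(geom, k, config, cell = cell)
    dplyr::mutate(
      fl$rates[, c("q_ost", "q_col", "power_sheets")],
      vane_width = paste(wd, collapse = "/"), .before = 1)
  })
}

#' Sweep the collar length, with or without a physical gasket
#'
#' @param lengths Collar lengths (um).
#' @param gasket Logical vector (recycled over lengths x gasket grid).
#' @param geom,kin,config As in [solve_cycle()].
#' @return Tibble: `l_col`, `gasket`, `q_ost`, `q_col`.
#' @export
sweep_collar_length <- function(lengths, gasket = c(FALSE, TRUE),
                                geom = reference_geometry(),
                                kin = beat_kinematics(),
                                config = solver_config()) {
  grid <- tidyr::expand_grid(l_col = lengths, gasket = gasket)
  purrr::pmap_dfr(grid, function(l_col, gasket) {
    g <- geom
    g$l_col <- l_col
    g$gasket <- gasket
    g$gasket_height <- l_col
    fl <- solve_cycle(g, kin, config)
    dplyr::mutate(fl$rates[, c("q_ost", "q_col")],
                  l_col = l_col, gasket = gasket, .before = 1)
  })
}

#' Analyse an experiment (In-Ex retention and/or dye-speed flux)
#'
#' Runs the full experimental pipeline on real or synthetic tables: paired
#' In-Ex retention per prey class with box-plot summaries, dye-speed
#' excurrent flux, and per-ostium / per-choanocyte rates for comparison with
#' the simulated pumping rate.
#'
#' @param inex Paired cytometry table (see [inex_retention()]); `NULL` skips
#'   the retention stage.
#' @param flux Dye-front table (see [excurrent_flow()]); `NULL` skips the
#'   flux stage.
#' @param bead_stock_per_ul Bead spike stock concentration (beads/uL).
#' @param n_ostia Estimated ostia per sponge (for per-unit rates); `NULL`
#'   skips that stage.
#' @param choanocytes_per_ostium Choanocytes per pumping unit.
#' @param q_ost_sim Optional simulated per-ostium rate (um^3/s) to include in
#'   the comparison table.
#' @return A `run_manifest`-style list with `retention`, `retention_summary`,
#'   `flux`, `per_unit`, `comparison`, `manifest`.
#' @export
run_experiment_analysis <- function(inex = NULL, flux = NULL,
                                    bead_stock_per_ul = 50,
                                    n_ostia = NULL,
                                    choanocytes_per_ostium = 24,
                                    q_ost_sim = NULL) {
  t0 <- Sys.time()
  if (is.null(inex) && is.null(flux)) {
    stop("provide at least one of `inex`, `flux`", call. = FALSE)
  }
  out <- list()
  if (!is.null(inex)) {
    out$retention <- inex_retention(inex, bead_stock_per_ul)
    out$retention_summary <- retention_summary(
      out$retention[, c("class", "retention_pct")])
  } else {
    message("no In-Ex table supplied: retention stage skipped")
  }
  if (!is.null(flux)) {
    out$flux <- excurrent_flow(flux)
    if (!is.null(n_ostia)) {
      total <- mean(out$flux$flow_um3_s)
      out$per_unit <- per_unit_rates(total, n_ostia, choanocytes_per_ostium)
      if (!is.null(q_ost_sim)) {
        out$comparison <- tibble::tibble(
          q_ost_experiment = out$per_unit$q_ost_um3_s,
          q_ost_simulated = q_ost_sim,
          ratio = q_ost_sim / out$per_unit$q_ost_um3_s
        )
      }
    }
  }
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("syconpump")),
    stages = names(out),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  out
}
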