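# cli_io: configuration files (YAML), metrics/snapshot output, run manifests
# and deterministic test fixtures.

#' Write a scenario configuration to a YAML file
#'
#' YAML is the only accepted configuration format.
#' @param spec A [scenario_spec()].
#' @param path Output file.
#' @export
write_config <- function(spec, path) {
  tree <- as_config_tree(spec)
  yaml::write_yaml(tree, path, precision = 15)
  invisible(path)
}

#' Read and validate a YAML scenario configuration
#' @param path YAML file written by [write_config()] or by hand.
#' @return A validated [scenario_spec()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' Export every built-in preset as a YAML configuration file
#'
#' Writes one human-readable file per preset so each experiment in the
#' scenario library exists as a plain-text configuration.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
export_preset_configs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(preset_names(), function(nm) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    write_config(scenario_preset(nm), p)
    p
  }, "")
  invisible(paths)
}

#' Write a metrics table to CSV
#'
#' Fixed column order as produced by [run_simulation()] (`time`, `n_cells`,
#' `capacity_fraction`, then per-strain biomass, frequency and
#' near-epithelium frequency), full float precision, header row included.
#'
#' @param metrics Non-empty data frame of metric records.
#' @param path Output file.
#' @export
write_metrics <- function(metrics, path) {
  if (!is.data.frame(metrics) || !nrow(metrics))
    stop("metrics must be a non-empty data frame (writing to ", path, ")")
  readr::write_csv(metrics, path)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics()]
#' @param path CSV file.
#' @return Data frame; numeric values round-trip exactly.
#' @export
read_metrics <- function(path) {
  as.data.frame(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a cell snapshot table
#'
#' One row per cell: time, id, strain name, x, z, radius, biomass.
#' @param state Simulation state.
#' @param spec The scenario.
#' @param path Output CSV.
#' @export
write_cell_snapshot <- function(state, spec, path) {
  pop <- state$pop
  snames <- vapply(spec$strains, `[[`, "", "name")
  df <- data.frame(time = state$time, id = pop$id,
                   strain = snames[pop$strain], x = pop$x, z = pop$z,
                   radius = cell_radius(pop$m, spec$params$density),
                   biomass = pop$m)
  readr::write_csv(df, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the resolved
#' configuration, the seed, the package version, timestamps and checksums of
#' the output files.
#'
#' @param spec The [scenario_spec()] that was run.
#' @param out_dir Directory containing the run outputs.
#' @param files Output files (paths relative to `out_dir`) to checksum.
#' @param started,finished POSIXct timestamps.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(spec, out_dir, files = character(),
                           started = Sys.time(), finished = Sys.time()) {
  manifest <- list(
    scenario = spec$name,
    config = as_config_tree(spec),
    seed = spec$seed,
    package_version = as.character(utils::packageVersion("mucosim")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(files, function(f) list(
      file = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 15)
  invisible(path)
}

#' Re-run a simulation from a manifest
#'
#' Reads the resolved configuration and seed back from a manifest and re-runs
#' the scenario; the metrics stream reproduces the original exactly.
#' @param path Manifest file.
#' @return As [run_simulation()].
#' @export
run_from_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  spec <- validate_config(man$config)
  run_simulation(spec)
}

#' Run a scenario and write its outputs
#'
#' Convenience wrapper used by the command-line interface: runs the scenario
#' and writes `metrics.csv`, `cells.csv` (final snapshot) and
#' `manifest.yaml` into `out_dir`.
#'
#' @param spec A [scenario_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The [run_simulation()] result, invisibly.
#' @export
run_and_write <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- Sys.time()
  res <- run_simulation(spec)
  write_metrics(res$metrics, file.path(out_dir, "metrics.csv"))
  write_cell_snapshot(res$state, spec, file.path(out_dir, "cells.csv"))
  write_manifest(spec, out_dir, c("metrics.csv", "cells.csv"),
                 started, Sys.time())
  invisible(res)
}

#' Deterministic test fixtures
#'
#' Writes small plain-text inputs used by the test suite; the same seed
#' yields byte-identical files.
#'
#' * `tiny_colony`: 20 cells in a 40 x 20 um domain (CSV cell table).
#' * `dense_cluster`: 50 heavily overlapping cells for the shoving audit.
#' * `linear_field_case`: a source-free epithelial-flux diffusion problem
#'   with its closed-form profile `C(z) = (J/D)(H - z)` (YAML, including the
#'   expected slope `J/D` and node values).
#' * `parabolic_field_case`: a uniform-sink problem with lumen Dirichlet and
#'   its closed form `C(z) = Cb + (r/2D)(z^2 - H^2)` (YAML).
#'
#' @param kind One of the fixture names above.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Path of the written file.
#' @export
make_fixture <- function(kind, seed, dir = tempdir()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  fmt <- function(x) sprintf("%.12g", x)
  switch(kind,
    tiny_colony = {
      n <- 20
      df <- data.frame(id = 1:n, strain = rep(c("A", "B"), n / 2),
                       x = fmt(runif(n, 0, 40)), z = fmt(runif(n, 0.8, 6)),
                       biomass = fmt(runif(n, 0.42, 0.84)))
      p <- file.path(dir, sprintf("tiny_colony_seed%d.csv", seed))
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
      p
    },
    dense_cluster = {
      n <- 50
      df <- data.frame(id = 1:n, strain = rep(c("A", "B"), n / 2),
                       x = fmt(20 + runif(n, -2, 2)),
                       z = fmt(3 + runif(n, -2, 2)),
                       biomass = fmt(rep(0.6, n)))
      p <- file.path(dir, sprintf("dense_cluster_seed%d.csv", seed))
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
      p
    },
    linear_field_case = {
      J <- 2; D <- 4e4; H <- 40; dx <- 4
      z <- seq(dx / 2, H - dx / 2, by = dx)
      case <- list(J = J, D = D, H = H, dx = dx,
                   expected_slope = J / D,
                   node_heights = z,
                   expected_values = (J / D) * (H - z))
      p <- file.path(dir, sprintf("linear_field_case_seed%d.yaml", seed))
      yaml::write_yaml(case, p, precision = 15)
      p
    },
    parabolic_field_case = {
      Cb <- 1e-3; r <- 4e-5; D <- 4e4; H <- 40; dx <- 4
      z <- seq(dx / 2, H - dx / 2, by = dx)
      case <- list(Cb = Cb, sink = r, D = D, H = H, dx = dx,
                   node_heights = z,
                   expected_values = Cb + r / (2 * D) * (z^2 - H^2))
      p <- file.path(dir, sprintf("parabolic_field_case_seed%d.yaml", seed))
      yaml::write_yaml(case, p, precision = 15)
      p
    },
    stop("unknown fixture kind '", kind, "'; available: tiny_colony, ",
         "dense_cluster, linear_field_case, parabolic_field_case"))
}

#' Read a fixture cell table into a population
#'
#' @param path CSV written by [make_fixture()].
#' @param strain_names Strain labels mapping to indices.
#' @return A [population()].
#' @export
read_cell_table <- function(path, strain_names = c("A", "B")) {
  df <- utils::read.csv(path)
  population(id = df$id, strain = match(df$strain, strain_names),
             x = df$x, z = df$z, m = df$biomass)
}
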