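# Scenario-suite runners shared by analyses, the test suite and the
# acceptance script.

#' Sweep the epithelial growth-rate advantage in the opposing-selection scenario
#'
#' Runs the opposing-selection scenario (lumen nutrients at five times the
#' epithelial-equivalent concentration, strain B with a 100% growth-rate
#' advantage on them) across a grid of epithelial advantages for strain A,
#' with several seeds per advantage, and reports strain A's final frequency
#' for each run. Runs stop early on strain loss or once frequencies have
#' settled.
#'
#' @param advantages Epithelial advantages for strain A (fractions).
#' @param n_seeds Independent seeds per advantage.
#' @param base_seed Integer; per-run seeds are drawn from this.
#' @param overrides Extra preset overrides (see [scenario_preset()]).
#' @return Data frame with `advantage`, `seed`, `final_freq_A`, `end_time`.
#' @export
sweep_epithelial_advantage <- function(advantages = c(0.01, 0.05, 0.1, 0.25, 0.5, 1),
                                       n_seeds = 5, base_seed = 1,
                                       overrides = list()) {
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_seeds)
  rows <- list()
  for (a in advantages) for (s in seeds) {
    ov <- overrides
    # sweep horizon and stepping chosen for a single-CPU sweep: a nine-day
    # horizon with settle-based stopping, records every 2 h
    ov$duration <- ov$duration %||% 216
    ov$dt_max <- ov$dt_max %||% 0.15
    ov$metrics_every <- ov$metrics_every %||% 2
    ov$epithelial_advantage <- a
    ov$seed <- s
    res <- run_simulation(scenario_preset("fig4_opposing", ov),
                          stop_on_strain_loss = TRUE,
                          stop_when_settled = TRUE,
                          settle_window = 48, settle_tol = 0.02,
                          settle_min_time = 120)
    rows[[length(rows) + 1L]] <- data.frame(
      advantage = a, seed = s,
      final_freq_A = unname(res$final_frequency["A"]),
      end_time = res$state$time)
  }
  do.call(rbind, rows)
}

#' Minimum selectivity: smallest advantage whose mean final frequency exceeds 1/2
#'
#' @param sweep Result of [sweep_epithelial_advantage()].
#' @return The smallest advantage (in percent) at which strain A's mean final
#'   frequency exceeds 0.5, or `NA` if none does.
#' @export
selectivity_threshold <- function(sweep) {
  means <- tapply(sweep$final_freq_A, sweep$advantage, mean)
  adv <- as.numeric(names(means))[order(as.numeric(names(means)))]
  means <- means[order(as.numeric(names(means)))]
  win <- adv[means > 0.5]
  if (!length(win)) return(NA_real_)
  100 * win[1]
}

#' Paired epithelial-versus-lumen selection comparison
#'
#' Runs the single-source selection scenarios (same advantage for the
#' favoured strain, equal total influx calibration, same seeds) and returns
#' the favoured strain's final frequency under each source direction.
#'
#' @param n_pairs Number of paired seeds.
#' @param base_seed Integer seed for the seed draw.
#' @param overrides Extra preset overrides applied to both arms.
#' @return Data frame with `seed`, `epithelial`, `lumen` (final frequencies
#'   of the favoured strain B).
#' @export
compare_selection_sources <- function(n_pairs = 10, base_seed = 1,
                                      overrides = list()) {
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_pairs)
  rows <- lapply(seeds, function(s) {
    ov <- overrides; ov$seed <- s
    fe <- run_simulation(scenario_preset("fig3_epithelial", ov),
                         stop_on_strain_loss = TRUE)$final_frequency["B"]
    fl <- run_simulation(scenario_preset("fig3_lumen", ov),
                         stop_on_strain_loss = TRUE)$final_frequency["B"]
    data.frame(seed = s, epithelial = unname(fe), lumen = unname(fl))
  })
  do.call(rbind, rows)
}

#' Final frequencies for a preset over several seeds
#'
#' @param preset Preset name.
#' @param n_seeds Number of seeds.
#' @param base_seed Integer seed for the seed draw.
#' @param overrides Preset overrides.
#' @param strain Strain whose frequency to report.
#' @param ... Passed to [run_simulation()].
#' @return Numeric vector of final frequencies, one per seed.
#' @export
replicate_final_frequencies <- function(preset, n_seeds = 5, base_seed = 1,
                                        overrides = list(), strain = "A",
                                        ...) {
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_seeds)
  vapply(seeds, function(s) {
    ov <- overrides; ov$seed <- s
    unname(run_simulation(scenario_preset(preset, ov), ...)$final_frequency[strain])
  }, 0)
}
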