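# model_config: domain types, validation, scenario presets.
#
# All quantities use um / h / pg units; concentrations pg/um^3.

#' Default simulation parameters
#'
#' Numeric defaults used wherever a scenario does not override them. These are
#' implementation choices documented in the methods vignette (the modelling
#' framework this package follows does not fix them): biomass density
#' 0.2 pg/um^3 (~200 g/l), division radius 1 um, baseline maximum specific
#' growth rate 0.7 1/h, Monod constant 3e-5 pg/um^3, solute diffusivity
#' 4e4 um^2/h, yield 0.5, grid spacing 4 um.
#'
#' @return Named list of defaults.
#' @export
sim_defaults <- function() {
  list(
    density          = 0.2,    # biomass density, pg/um^3
    division_radius  = 1.0,    # um; daughters get half the biomass
    mu_base          = 0.7,    # 1/h
    Ks_default       = 3e-5,   # pg/um^3
    diffusivity      = 4e4,    # um^2/h
    yield_default    = 0.5,    # biomass produced per nutrient consumed
    grid_spacing     = 4,      # um
    dt_max           = 0.1,    # h
    growth_per_step  = 0.05,   # stability bound: rate * dt <= this
    shove_tol        = 0.5,    # um residual overlap target (~30% of radius)
    shove_maxit      = 5000L,  # cap for strict stand-alone relaxation
    shove_budget     = 200L,   # relaxation iterations per engine step
    shove_damp       = 0.6,    # Jacobi damping factor
    shove_margin     = 2.0,    # um, Verlet pair-list margin
    shove_hard_cap   = 1.0,    # um; mechanics error if residual exceeds this
    solver_tol       = 1e-8,   # relative residual for the diffusion solver
    solver_maxit     = 20000L,
    couple_tol       = 1e-3,   # reaction/diffusion fixed-point tolerance
    couple_maxit     = 40L,
    inoculum_total   = 250L,
    near_band_frac   = 0.1,    # near-epithelium metric band, fraction of h_max
    packing_fraction = 0.8,    # nominal packing for the capacity normalisation
    metrics_every    = 1,      # h
    wellmixed_influx = 6       # pg/um^2/h, lumen supply in well-mixed mode
  )
}

#' Strain specification
#'
#' @param name Strain label.
#' @param mu_max Named numeric: maximum specific growth rate (1/h) per
#'   nutrient.
#' @param Ks Named numeric: Monod half-saturation constant (pg/um^3) per
#'   nutrient. Defaults to `sim_defaults()$Ks_default` for every nutrient in
#'   `mu_max`.
#' @param susceptibility Named numeric: per antimicrobial, the concentration
#'   `S` at which death within one hour has probability one half. May be
#'   empty.
#' @param yield Named numeric: biomass yield per nutrient consumed. Defaults
#'   to `sim_defaults()$yield_default`.
#' @param frequency Initial frequency of this strain in the inoculum.
#' @return A `strain_spec` object.
#' @export
strain_spec <- function(name, mu_max, Ks = NULL, susceptibility = numeric(),
                        yield = NULL, frequency = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(mu_max) == 0L)
    stop("strain '", name, "': at least one nutrient entry is required")
  if (is.null(names(mu_max)) || any(!nzchar(names(mu_max))))
    stop("strain '", name, "': mu_max must be a named vector")
  d <- sim_defaults()
  if (is.null(Ks)) Ks <- setNames(rep(d$Ks_default, length(mu_max)), names(mu_max))
  if (is.null(yield)) yield <- setNames(rep(d$yield_default, length(mu_max)), names(mu_max))
  Ks <- Ks[names(mu_max)]; yield <- yield[names(mu_max)]
  if (any(is.na(Ks))) stop("strain '", name, "': Ks missing for some nutrient")
  if (any(is.na(yield))) stop("strain '", name, "': yield missing for some nutrient")
  if (any(mu_max < 0)) stop("strain '", name, "': mu_max must be >= 0")
  if (any(Ks <= 0)) stop("strain '", name, "': Ks must be > 0")
  if (any(yield <= 0)) stop("strain '", name, "': yield must be > 0")
  susceptibility <- unlist(susceptibility) %||% numeric()
  if (length(susceptibility) && any(susceptibility <= 0))
    stop("strain '", name, "': susceptibility S must be > 0")
  structure(list(name = name, mu_max = unlist(mu_max), Ks = unlist(Ks),
                 susceptibility = susceptibility, yield = unlist(yield),
                 frequency = frequency),
            class = "strain_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solute specification
#'
#' A diffusible compound. Either the reaction-diffusion solver computes its
#' field from the boundary conditions, or `prescribed` fixes an analytic
#' height profile and the solver is bypassed (exactly one of the two).
#'
#' @param name Solute label.
#' @param kind `"nutrient"` or `"antimicrobial"`.
#' @param diffusivity um^2/h.
#' @param lumen Lumen (top) face boundary: `list(type = "dirichlet", value =
#'   c)` or `list(type = "zero_flux")`.
#' @param epithelial Epithelial (bottom) face boundary: `list(type = "flux",
#'   value = J)` (pg/um^2/h into the domain) or `list(type = "zero_flux")`.
#' @param prescribed Optional analytic profile descriptor, see
#'   [profile_value()]: `list(kind = "constant", value = c0)`,
#'   `list(kind = "exponential", value = c0, lambda = l)` (decay from the
#'   epithelium), or `list(kind = "linear", value = c0, slope = s)`.
#' @return A `solute_spec` object.
#' @export
solute_spec <- function(name, kind = c("nutrient", "antimicrobial"),
                        diffusivity = sim_defaults()$diffusivity,
                        lumen = list(type = "zero_flux"),
                        epithelial = list(type = "zero_flux"),
                        prescribed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L)
  if (diffusivity <= 0) stop("solute '", name, "': diffusivity must be > 0")
  if (!is.null(prescribed)) {
    if (!is.list(prescribed) || is.null(prescribed$kind) ||
        !prescribed$kind %in% c("constant", "exponential", "linear"))
      stop("solute '", name, "': unknown prescribed profile kind")
  } else {
    if (!lumen$type %in% c("dirichlet", "zero_flux"))
      stop("solute '", name, "': lumen boundary must be dirichlet or zero_flux")
    if (lumen$type == "dirichlet" && (is.null(lumen$value) || lumen$value < 0))
      stop("solute '", name, "': dirichlet lumen boundary needs value >= 0")
    if (!epithelial$type %in% c("flux", "zero_flux"))
      stop("solute '", name, "': epithelial boundary must be flux or zero_flux")
    if (epithelial$type == "flux" && is.null(epithelial$value))
      stop("solute '", name, "': flux epithelial boundary needs a value")
    if (lumen$type == "zero_flux" && epithelial$type == "flux" &&
        epithelial$value != 0)
      stop("solute '", name, "': ill-posed boundaries (net flux with no ",
           "outlet); use a dirichlet lumen boundary")
  }
  structure(list(name = name, kind = kind, diffusivity = diffusivity,
                 lumen = lumen, epithelial = epithelial,
                 prescribed = prescribed),
            class = "solute_spec")
}

#' Evaluate a prescribed concentration profile at height z
#'
#' @param profile Profile descriptor, see [solute_spec()].
#' @param z Heights above the epithelium (um).
#' @return Concentrations (pg/um^3).
#' @export
profile_value <- function(profile, z) {
  switch(profile$kind,
    constant    = rep(profile$value, length(z)),
    exponential = profile$value * exp(-z / profile$lambda),
    linear      = profile$value + profile$slope * z,
    stop("unknown profile kind '", profile$kind, "'"))
}

#' Height-averaged value of a prescribed profile over \[0, H\]
#'
#' Used to build well-mixed controls carrying identical total solute amounts.
#' @param profile Profile descriptor.
#' @param H Domain height (um).
#' @export
profile_mean <- function(profile, H) {
  switch(profile$kind,
    constant    = profile$value,
    exponential = profile$value * profile$lambda / H * (1 - exp(-H / profile$lambda)),
    linear      = profile$value + profile$slope * H / 2,
    stop("unknown profile kind '", profile$kind, "'"))
}

#' Domain specification
#'
#' @param width Lateral extent (um); lateral boundaries are always periodic.
#' @param slough_height Height above the epithelium (um) beyond which cell
#'   centres are removed.
#' @param grid_spacing Solute grid spacing (um); must divide both width and
#'   slough height evenly.
#' @param dimensionality `"2D"` (the only implemented case).
#' @return A `domain_spec` object.
#' @export
domain_spec <- function(width, slough_height, grid_spacing = sim_defaults()$grid_spacing %||% 4,
                        dimensionality = "2D") {
  if (identical(dimensionality, "3D"))
    stop("3D domains are not implemented; use dimensionality = '2D'")
  if (!identical(dimensionality, "2D"))
    stop("dimensionality must be '2D'")
  if (slough_height <= 0) stop("slough_height must be > 0")
  if (width <= 0) stop("width must be > 0")
  if (abs(width / grid_spacing - round(width / grid_spacing)) > 1e-9)
    stop("grid_spacing must divide width evenly")
  if (abs(slough_height / grid_spacing - round(slough_height / grid_spacing)) > 1e-9)
    stop("grid_spacing must divide slough_height evenly")
  if (round(slough_height / grid_spacing) < 2)
    stop("domain must be at least two grid rows high")
  structure(list(width = width, slough_height = slough_height,
                 grid_spacing = grid_spacing, dimensionality = "2D",
                 lateral_boundaries = "periodic"),
            class = "domain_spec")
}

#' Assemble a full scenario specification
#'
#' Collects domain, strains, solutes and schedule into a validated
#' `scenario_spec`. Most users should start from [scenario_preset()].
#'
#' @param name Scenario label.
#' @param domain A [domain_spec()].
#' @param strains List of [strain_spec()] with `frequency` set; frequencies
#'   must sum to 1.
#' @param solutes List of [solute_spec()].
#' @param duration Simulated time (h).
#' @param seed Integer RNG seed.
#' @param well_mixed If `TRUE`, no spatial solute gradients: a single uniform
#'   nutrient concentration is computed each step from the balance of total
#'   influx against total uptake.
#' @param feast_famine Optional `list(period = hours, solutes = names)`:
#'   square-wave modulation of the named lumen boundary values (each phase
#'   lasts `period` hours; feast doubles the base value, famine sets it to 0,
#'   so the time average is unchanged).
#' @param inoculum_total Number of founder cells (default 250).
#' @param metrics_every Metrics cadence (h).
#' @param dt_max Upper bound on the timestep (h).
#' @param params Named list overriding entries of [sim_defaults()].
#' @return A validated `scenario_spec`.
#' @export
scenario_spec <- function(name, domain, strains, solutes, duration,
                          seed = 1L, well_mixed = FALSE, feast_famine = NULL,
                          inoculum_total = NULL, metrics_every = NULL,
                          dt_max = NULL, params = list()) {
  p <- modifyList(sim_defaults(), params)
  spec <- structure(list(
    name = name, domain = domain, strains = strains,
    solutes = setNames(solutes, vapply(solutes, `[[`, "", "name")),
    duration = duration, seed = as.integer(seed), well_mixed = isTRUE(well_mixed),
    feast_famine = feast_famine,
    inoculum_total = as.integer(inoculum_total %||% p$inoculum_total),
    metrics_every = metrics_every %||% p$metrics_every,
    dt_max = dt_max %||% p$dt_max,
    params = p), class = "scenario_spec")
  assert_scenario(spec)
  spec
}

# Invariant checks shared by scenario_spec() and validate_config().
assert_scenario <- function(spec) {
  if (spec$duration < 0) stop("duration must be >= 0")
  if (!length(spec$strains)) stop("at least one strain is required")
  freqs <- vapply(spec$strains, `[[`, 0, "frequency")
  if (any(is.na(freqs))) stop("every strain needs an initial frequency")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("initial frequencies must sum to 1 (got ", sum(freqs), ")")
  if (!is.null(spec$feast_famine)) {
    if (is.null(spec$feast_famine$period) || spec$feast_famine$period <= 0)
      stop("feast_famine$period must be > 0")
    bad <- setdiff(spec$feast_famine$solutes, names(spec$solutes))
    if (length(bad)) stop("feast_famine references unknown solute '", bad[1L], "'")
  }
  nutrients <- names(spec$solutes)[vapply(spec$solutes, `[[`, "", "kind") == "nutrient"]
  antimicrobials <- setdiff(names(spec$solutes), nutrients)
  if (!length(nutrients)) stop("at least one nutrient solute is required")
  for (s in spec$strains) {
    bad <- setdiff(names(s$mu_max), nutrients)
    if (length(bad))
      stop("strain '", s$name, "' references undefined nutrient '", bad[1L],
           "' in mu_max")
    missing <- setdiff(nutrients, names(s$mu_max))
    if (length(missing))
      stop("strain '", s$name, "' has no mu_max entry for nutrient '",
           missing[1L], "'")
    bad <- setdiff(names(s$susceptibility), antimicrobials)
    if (length(bad))
      stop("strain '", s$name, "' references undefined antimicrobial '",
           bad[1L], "'")
    missing <- setdiff(antimicrobials, names(s$susceptibility))
    if (length(missing))
      stop("strain '", s$name, "' has no susceptibility entry for '",
           missing[1L], "'")
  }
  if (spec$well_mixed) {
    if (length(nutrients) != 1L)
      stop("well-mixed mode supports exactly one nutrient solute")
    if (length(antimicrobials))
      stop("well-mixed mode does not support antimicrobial solutes")
  }
  invisible(spec)
}

#' Validate a raw configuration tree
#'
#' Turns a nested list (typically parsed from a YAML file, see
#' [read_config()]) into a fully populated [scenario_spec()], filling defaults
#' and checking every invariant and cross-reference. Errors name the offending
#' field.
#'
#' @param raw Nested list with elements `name`, `domain`, `strains`,
#'   `solutes`, `duration`, and optionally `seed`, `well_mixed`,
#'   `feast_famine`, `inoculum_total`, `metrics_every`, `dt_max`, `params`.
#' @return A validated `scenario_spec`.
#' @export
validate_config <- function(raw) {
  if (inherits(raw, "scenario_spec")) { assert_scenario(raw); return(raw) }
  if (!is.list(raw)) stop("configuration must be a list")
  need <- function(x, f, where) {
    if (is.null(x[[f]])) stop("missing field '", f, "' in ", where)
    x[[f]]
  }
  dom <- need(raw, "domain", "configuration")
  domain <- domain_spec(width = need(dom, "width", "domain"),
                        slough_height = need(dom, "slough_height", "domain"),
                        grid_spacing = dom$grid_spacing %||% sim_defaults()$grid_spacing %||% 4,
                        dimensionality = dom$dimensionality %||% "2D")
  strains <- lapply(need(raw, "strains", "configuration"), function(s) {
    strain_spec(name = need(s, "name", "strain"),
                mu_max = unlist(need(s, "mu_max", paste0("strain '", s$name, "'"))),
                Ks = if (!is.null(s$Ks)) unlist(s$Ks),
                susceptibility = if (!is.null(s$susceptibility)) unlist(s$susceptibility) else numeric(),
                yield = if (!is.null(s$yield)) unlist(s$yield),
                frequency = need(s, "frequency", paste0("strain '", s$name, "'")))
  })
  solutes <- lapply(need(raw, "solutes", "configuration"), function(s) {
    solute_spec(name = need(s, "name", "solute"),
                kind = need(s, "kind", paste0("solute '", s$name, "'")),
                diffusivity = s$diffusivity %||% sim_defaults()$diffusivity,
                lumen = s$lumen %||% list(type = "zero_flux"),
                epithelial = s$epithelial %||% list(type = "zero_flux"),
                prescribed = s$prescribed)
  })
  scenario_spec(name = raw$name %||% "scenario",
                domain = domain, strains = strains, solutes = solutes,
                duration = need(raw, "duration", "configuration"),
                seed = raw$seed %||% 1L,
                well_mixed = isTRUE(raw$well_mixed),
                feast_famine = raw$feast_famine,
                inoculum_total = raw$inoculum_total,
                metrics_every = raw$metrics_every,
                dt_max = raw$dt_max,
                params = raw$params %||% list())
}

#' Convert a scenario back to a plain configuration tree
#'
#' Inverse of [validate_config()]; the result serialises cleanly to YAML and
#' round-trips through `validate_config()` unchanged.
#' @param spec A `scenario_spec`.
#' @return Nested plain list.
#' @export
as_config_tree <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  list(
    name = spec$name,
    domain = list(width = spec$domain$width,
                  slough_height = spec$domain$slough_height,
                  grid_spacing = spec$domain$grid_spacing,
                  dimensionality = spec$domain$dimensionality),
    strains = lapply(spec$strains, function(s) list(
      name = s$name, mu_max = as.list(s$mu_max), Ks = as.list(s$Ks),
      susceptibility = as.list(s$susceptibility), yield = as.list(s$yield),
      frequency = s$frequency)),
    solutes = lapply(unname(spec$solutes), function(s) list(
      name = s$name, kind = s$kind, diffusivity = s$diffusivity,
      lumen = s$lumen, epithelial = s$epithelial, prescribed = s$prescribed)),
    duration = spec$duration, seed = spec$seed, well_mixed = spec$well_mixed,
    feast_famine = spec$feast_famine, inoculum_total = spec$inoculum_total,
    metrics_every = spec$metrics_every, dt_max = spec$dt_max,
    params = spec$params)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, "\n", sep = "")
  cat("  domain: ", x$domain$width, " x ", x$domain$slough_height,
      " um (dx ", x$domain$grid_spacing, "), periodic lateral\n", sep = "")
  for (s in x$strains)
    cat("  strain ", s$name, ": f0 = ", s$frequency, ", mu_max = [",
        paste(sprintf("%s %.3g", names(s$mu_max), s$mu_max), collapse = ", "),
        "]\n", sep = "")
  for (s in x$solutes)
    cat("  solute ", s$name, " (", s$kind, ")",
        if (!is.null(s$prescribed)) " [prescribed]", "\n", sep = "")
  cat("  duration ", x$duration, " h, seed ", x$seed,
      if (x$well_mixed) ", well-mixed", "\n", sep = "")
  invisible(x)
}
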