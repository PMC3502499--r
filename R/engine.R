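# engine: inoculation, the per-step ordering (feast-famine modulation ->
# solute solve -> growth/division -> mortality -> shoving -> sloughing ->
# metrics), and the run loop.

#' Inoculate a scenario
#'
#' Places the configured number of founder cells (default 250) on the
#' epithelial surface at uniformly random lateral positions. Strain counts
#' are the rounded-down share of each initial frequency, with the remainder
#' assigned randomly in proportion to the frequencies. Founder biomass is
#' uniform between half and the full division mass, so divisions are not
#' synchronised.
#'
#' @param spec A [scenario_spec()].
#' @return A [population()] resting on the epithelium, shoved apart.
#' @export
inoculate <- function(spec) {
  p <- spec$params
  total <- spec$inoculum_total
  freqs <- vapply(spec$strains, `[[`, 0, "frequency")
  counts <- floor(freqs * total)
  rem <- total - sum(counts)
  if (rem > 0) {
    extra <- sample(seq_along(freqs), rem, replace = TRUE, prob = freqs)
    for (k in extra) counts[k] <- counts[k] + 1
  }
  strain <- rep(seq_along(freqs), counts)
  n <- length(strain)
  m_div <- cell_mass(p$division_radius, p$density)
  m <- runif(n, 0.5, 1) * m_div
  pop <- population(id = seq_len(n), strain = strain,
                    x = runif(n, 0, spec$domain$width),
                    z = cell_radius(m, p$density), m = m)
  if (n) {
    pop <- shove_relax(pop, spec$domain, p$shove_tol, p$shove_maxit, p,
                       enforce = FALSE)
    if ((attr(pop, "max_overlap") %||% 0) > p$shove_hard_cap)
      stop("inoculum could not be relaxed below the mechanical bound")
  }
  pop
}

#' Feast-famine modulation of a boundary concentration
#'
#' Square wave with phases of length `period`: the value is doubled during
#' feast phases and zero during famine phases, so the time average over a
#' full cycle equals the base value. The cycle starts with a feast.
#'
#' @param base Base (continuous-supply) concentration.
#' @param period Phase length (h), > 0.
#' @param time Simulation time (h).
#' @return The modulated concentration.
#' @export
feast_famine_boundary <- function(base, period, time) {
  if (period <= 0) stop("period must be > 0")
  phase <- floor(time / period) %% 2
  ifelse(phase == 0, 2 * base, 0)
}

# Feast-famine factor (2 feast / 0 famine / 1 when inactive) for a solute.
ff_factor <- function(spec, solute_name, time) {
  ff <- spec$feast_famine
  if (is.null(ff) || !solute_name %in% ff$solutes) return(1)
  if (floor(time / ff$period) %% 2 == 0) 2 else 0
}

# Uniform nutrient concentration in well-mixed mode: the concentration at
# which total Monod uptake balances the total influx, capped at the bulk.
wellmixed_concentration <- function(pop, strains, nutrient, bulk, influx_total) {
  if (influx_total <= 0 || bulk <= 0) return(0)
  demand <- function(N) {
    if (!length(pop)) return(0)
    mu_max <- vapply(strains, function(s) s$mu_max[[nutrient]], 0)[pop$strain]
    Ks <- vapply(strains, function(s) s$Ks[[nutrient]], 0)[pop$strain]
    yld <- vapply(strains, function(s) s$yield[[nutrient]], 0)[pop$strain]
    sum(monod_rate(mu_max, Ks, N) * pop$m / yld)
  }
  if (demand(bulk) <= influx_total) return(bulk)
  uniroot(function(N) demand(N) - influx_total, c(0, bulk),
          tol = bulk * 1e-12)$root
}

# Initialise the simulation state: seed the RNG, inoculate, build fields.
# Antimicrobial fields carry no sink and constant boundaries, so they are
# solved once here and reused.
init_state <- function(spec) {
  assert_scenario(spec)
  set.seed(spec$seed)
  p <- spec$params
  pop <- inoculate(spec)
  kinds <- vapply(spec$solutes, `[[`, "", "kind")
  fields <- list()
  for (s in spec$solutes) {
    if (!is.null(s$prescribed)) {
      fields[[s$name]] <- prescribed_profile_field(s, spec$domain)
    } else if (s$kind == "antimicrobial") {
      f <- solute_field(s, spec$domain)
      fields[[s$name]] <- solve_steady_state(f, NULL, p$solver_tol, p$solver_maxit)
    } else {
      init <- if (s$lumen$type == "dirichlet") s$lumen$value else 0
      fields[[s$name]] <- solute_field(s, spec$domain, value = init)
    }
  }
  state <- list(time = 0, pop = pop, fields = fields,
                nutrients = names(kinds)[kinds == "nutrient"],
                antimicrobials = names(kinds)[kinds == "antimicrobial"],
                metrics = list(), profiles = list(),
                capacity = p$packing_fraction * p$density *
                  spec$domain$width * spec$domain$slough_height,
                last_rates = numeric(), last_max_rate = p$mu_base,
                audit = list(growth = 0, died = 0, sloughed = 0),
                terminated = FALSE, extinct = FALSE)
  state
}

# Reaction-diffusion coupling: alternate (rates, uptake) assembly and field
# relaxation until the fields stop changing. Uptake is booked only to the
# substrate each cell forages on. Returns updated fields plus the realised
# rates and per-nutrient reactions.
solve_nutrient_fields <- function(state, spec, time) {
  p <- spec$params
  strains <- spec$strains
  pop <- state$pop
  nuts <- state$nutrients
  dom <- spec$domain

  # boundary values for this step (feast-famine modulation of lumen faces)
  lumen_now <- vapply(nuts, function(nm) {
    s <- spec$solutes[[nm]]
    if (is.null(s$prescribed) && s$lumen$type == "dirichlet")
      s$lumen$value * ff_factor(spec, nm, time) else NA_real_
  }, 0)

  if (spec$well_mixed) {
    nm <- nuts[1L]
    s <- spec$solutes[[nm]]
    fac <- ff_factor(spec, nm, time)
    bulk <- s$lumen$value * fac
    influx <- p$wellmixed_influx * dom$width * fac
    N <- wellmixed_concentration(pop, strains, nm, bulk, influx)
    f <- state$fields[[nm]]
    f$grid[] <- N; f$converged <- TRUE; f$residual <- 0
    state$fields[[nm]] <- f
    mu_max <- vapply(strains, function(st) st$mu_max[[nm]], 0)[pop$strain]
    Ks <- vapply(strains, function(st) st$Ks[[nm]], 0)[pop$strain]
    rates <- monod_rate(mu_max, Ks, rep(N, length(pop)))
    return(list(state = state, rates = rates, which = rep(1L, length(pop)),
                reactions = NULL))
  }

  gi <- grid_index(dom, pop$x, pop$z)
  n <- length(pop)
  nk <- length(nuts)
  vol <- dom$grid_spacing^2
  solved <- nuts[vapply(nuts, function(nm) is.null(spec$solutes[[nm]]$prescribed), TRUE)]
  conc <- matrix(0, n, nk, dimnames = list(NULL, nuts))
  reactions <- setNames(vector("list", nk), nuts)
  # per-cell parameter matrices, built once per step
  mu_m <- Ks_m <- Y_m <- matrix(0, n, nk)
  for (j in seq_len(nk)) {
    nm <- nuts[j]
    mu_m[, j] <- vapply(strains, function(st) st$mu_max[[nm]], 0)[pop$strain]
    Ks_m[, j] <- vapply(strains, function(st) st$Ks[[nm]], 0)[pop$strain]
    Y_m[, j] <- vapply(strains, function(st) st$yield[[nm]], 0)[pop$strain]
  }
  softness <- 0.035
  diet <- function() {
    R <- mu_m * conc / (Ks_m + conc)
    rmax <- R[, 1]
    if (nk > 1) for (j in 2:nk) rmax <- pmax(rmax, R[, j])
    W <- exp((R - rmax) / softness)
    W <- W / rowSums(W)
    list(R = R, W = W, rate = rowSums(W * R))
  }

  # Picard iteration on the Monod sink: each cell's uptake of substrate j is
  # linearised as k * C_j with k = w_j * mu_max * m / (yield * (Ks + C_prev)),
  # so uptake enters the operator diagonally and the solve stays positive no
  # matter how far demand exceeds supply. Diet weights w_j are refreshed each
  # iteration and the field update is damped, which together give a stable
  # fixed point even at substrate-indifference margins.
  idx <- cbind(gi$iz, gi$ix)
  for (iter in seq_len(p$couple_maxit)) {
    for (j in seq_len(nk))
      conc[, j] <- state$fields[[nuts[j]]]$grid[idx]
    gr <- diet()
    maxchg <- 0
    for (j in seq_len(nk)) {
      nm <- nuts[j]
      if (!nm %in% solved) next
      kcoef <- gr$W[, j] * mu_m[, j] * pop$m / (Y_m[, j] * (Ks_m[, j] + conc[, j]))
      lin <- matrix(0, gi$nz, gi$nx)
      acc <- rowsum(kcoef, gi$lin)
      lin[as.integer(rownames(acc))] <- acc / vol
      f <- state$fields[[nm]]
      f$solute$lumen$value <- lumen_now[[nm]]
      old <- f$grid
      f <- solve_steady_state(f, NULL, p$solver_tol, p$solver_maxit,
                              linear_sink = lin)
      f$grid <- 0.3 * old + 0.7 * f$grid   # damped Picard update
      state$fields[[nm]] <- f
      ref <- max(abs(f$grid), abs(old), 1e-300)
      maxchg <- max(maxchg, max(abs(f$grid - old)) / ref)
    }
    if (length(solved) == 0L || (iter >= 2L && maxchg < p$couple_tol)) break
  }
  # realised rates and booked uptake from the converged fields
  for (j in seq_len(nk))
    conc[, j] <- state$fields[[nuts[j]]]$grid[idx]
  gr <- diet()
  for (j in seq_len(nk)) {
    uptake <- gr$W[, j] * gr$R[, j] * pop$m / Y_m[, j]
    grid <- matrix(0, gi$nz, gi$nx)
    sel <- uptake > 0
    if (any(sel)) {
      acc <- rowsum(uptake[sel], gi$lin[sel])
      grid[as.integer(rownames(acc))] <- acc / vol
    }
    reactions[[nuts[j]]] <- structure(list(grid = grid, total = sum(uptake)),
                                      class = "reaction_field")
  }
  list(state = state, rates = gr$rate, which = max.col(gr$R, ties.method = "first"),
       reactions = reactions)
}

#' Advance the simulation by one step
#'
#' Executes, in order: feast-famine modulation of boundary values, the
#' pseudo-steady-state solute solve (or the uniform well-mixed balance, or
#' prescribed profiles), growth and division, antimicrobial mortality,
#' shoving relaxation, sloughing, and metrics capture. The requested `dt` is
#' reduced if needed so that no cell grows by more than the configured
#' fraction (default 5%) of its biomass in one step.
#'
#' @param state Simulation state from `init_state()` / previous steps.
#' @param spec The [scenario_spec()].
#' @param dt Requested timestep (h).
#' @return The advanced state; `state$last_step` holds the biomass ledger
#'   (growth, died, sloughed) and the dt actually used.
#' @export
sim_step <- function(state, spec, dt = spec$dt_max) {
  p <- spec$params
  if (!length(state$pop)) {
    state$time <- state$time + dt
    state$extinct <- TRUE
    state$last_step <- list(dt = dt, growth = 0, died = 0, sloughed = 0)
    return(state)
  }
  sol <- solve_nutrient_fields(state, spec, state$time)
  state <- sol$state
  rates <- sol$rates
  # stability bound: total biomass growth per step stays below the configured
  # fraction (biomass-weighted mean rate; individual fast cells still satisfy
  # rate * dt << 1/2)
  wmr <- if (length(rates)) sum(rates * state$pop$m) / sum(state$pop$m) else 0
  if (wmr > 0) dt <- min(dt, p$growth_per_step / wmr)
  state$last_max_rate <- wmr
  m_before <- sum(state$pop$m)

  # Pre-stretch: growth adds volume that must lift the packed bed above it,
  # which pairwise shoving alone resolves only through a slow global
  # compression wave. Each cell is lifted by the cumulative relative volume
  # growth of the bed below its height (biomass growth g adds (2/3) g of
  # cross-sectional area for spheres in a 2D slab, and the lateral extent is
  # fixed, so the increase goes into height). Following the realised vertical
  # growth profile matters: a uniform stretch would dilate non-growing strata
  # and let fast-growing layers mix downward into them.
  dxg <- spec$domain$grid_spacing
  nzrow <- as.integer(round(spec$domain$slough_height / dxg))
  bin0 <- pmin(nzrow, pmax(1L, floor(state$pop$z / dxg) + 1L))
  dm_row <- rep(0, nzrow); m_row <- rep(0, nzrow)
  dm <- state$pop$m * (exp(rates * dt) - 1)
  for (k in seq_len(0L)) NULL  # (vectorised accumulation below)
  acc <- rowsum(cbind(dm, state$pop$m), bin0)
  kk <- as.integer(rownames(acc))
  dm_row[kk] <- acc[, 1]; m_row[kk] <- acc[, 2]
  rel_row <- ifelse(m_row > 0, (2 / 3) * dm_row / m_row, 0)
  cum_below <- c(0, cumsum(rel_row * dxg))[seq_len(nzrow)]

  gd <- grow_and_divide(state$pop, rates, dt, p)
  pop <- gd$pop
  if (gd$growth > 0) {
    binp <- pmin(nzrow, pmax(1L, floor(pop$z / dxg) + 1L))
    pop$z <- pop$z + cum_below[binp] + rel_row[binp] * (pop$z - (binp - 1L) * dxg)
  }

  am_fields <- state$fields[state$antimicrobials]
  mort <- apply_mortality(pop, am_fields, spec$strains, dt)
  pop <- mort$pop

  # per-step relaxation runs on a fixed iteration budget; residual overlaps
  # below the target tolerance carry over and are worked off in later steps
  # (the bed is slightly compressible). A residual past the hard cap is a
  # genuine mechanics failure.
  shove_residual <- 0
  if (length(pop)) {
    pop <- shove_relax(pop, spec$domain, p$shove_tol, p$shove_budget, p,
                       enforce = FALSE)
    shove_residual <- attr(pop, "max_overlap") %||% 0
    if (shove_residual > p$shove_hard_cap)
      stop("shoving residual overlap ", signif(shove_residual, 3),
           " um exceeds the mechanical bound of ", p$shove_hard_cap, " um")
  }
  sl <- slough(pop, spec$domain$slough_height, length(spec$strains))
  pop <- sl$pop

  state$pop <- pop
  state$time <- state$time + dt
  state$extinct <- length(pop) == 0L
  state$last_rates <- rates
  state$last_which <- sol$which
  state$last_reactions <- sol$reactions
  state$last_step <- list(dt = dt, growth = gd$growth,
                          died = sum(mort$died), sloughed = sum(sl$removed),
                          m_before = m_before, m_after = sum(pop$m),
                          shove_residual = shove_residual)
  state$audit$growth <- state$audit$growth + gd$growth
  state$audit$died <- state$audit$died + sum(mort$died)
  state$audit$sloughed <- state$audit$sloughed + sum(sl$removed)
  state
}

# One metrics record. Realised growth rates are taken from the rates used in
# the step that landed on this time point.
capture_metrics <- function(state, spec) {
  pop <- state$pop
  ns <- length(spec$strains)
  biomass <- rep(0, ns)
  if (length(pop)) {
    tab <- tapply(pop$m, pop$strain, sum)
    biomass[as.integer(names(tab))] <- tab
  }
  total <- sum(biomass)
  freq <- if (total > 0) biomass / total else rep(NA_real_, ns)
  band <- spec$params$near_band_frac * spec$domain$slough_height
  near <- length(pop) && any(pop$z <= band)
  nearf <- rep(NA_real_, ns)
  if (near) {
    sel <- pop$z <= band
    nb <- rep(0, ns)
    tab <- tapply(pop$m[sel], pop$strain[sel], sum)
    nb[as.integer(names(tab))] <- tab
    nearf <- nb / sum(nb)
  }
  rec <- list(time = state$time, n_cells = length(pop), biomass = biomass,
              frequency = freq, near_epithelium_frequency = nearf,
              capacity_fraction = total / state$capacity)
  # mean realised growth rate per strain per grid row
  if (length(pop) && length(state$last_rates) == length(pop)) {
    nz <- as.integer(round(spec$domain$slough_height / spec$domain$grid_spacing))
    bin <- pmin(nz, pmax(1L, floor(pop$z / spec$domain$grid_spacing) + 1L))
    prof <- matrix(NA_real_, nz, ns)
    for (s in seq_len(ns)) {
      sel <- pop$strain == s
      if (any(sel)) {
        mtab <- tapply(state$last_rates[sel], bin[sel], mean)
        prof[as.integer(names(mtab)), s] <- mtab
      }
    }
    rec$growth_rate_profile <- prof
  }
  rec
}

metrics_to_df <- function(records, strain_names) {
  if (!length(records)) stop("no metrics records")
  rows <- lapply(records, function(r) {
    out <- c(list(time = r$time, n_cells = r$n_cells,
                  capacity_fraction = r$capacity_fraction),
             setNames(as.list(r$biomass), paste0("biomass_", strain_names)),
             setNames(as.list(r$frequency), paste0("freq_", strain_names)),
             setNames(as.list(r$near_epithelium_frequency),
                      paste0("nearfreq_", strain_names)))
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' Run a scenario
#'
#' Seeds the RNG from the scenario, inoculates, and steps until the duration
#' is reached, the population is extinct, or (optionally) one strain has been
#' lost. Metrics are captured at the configured cadence; timesteps are capped
#' so records land exactly on the cadence marks, making the metrics stream a
#' deterministic function of (spec, seed).
#'
#' @param spec A [scenario_spec()].
#' @param stop_on_strain_loss If `TRUE`, stop early once only one strain
#'   remains (without mortality the outcome is then fixed).
#' @param stop_when_settled If `TRUE`, stop once strain frequencies have
#'   changed by less than `settle_tol` over the trailing `settle_window`
#'   hours (checked after `settle_min_time` hours).
#' @param settle_window,settle_tol,settle_min_time Settling detection
#'   parameters (hours, frequency units, hours).
#' @return List with `state` (final simulation state), `metrics` (data frame,
#'   one row per record), and `final_frequency` (biomass frequencies, named
#'   by strain).
#' @export
run_simulation <- function(spec, stop_on_strain_loss = FALSE,
                           stop_when_settled = FALSE, settle_window = 48,
                           settle_tol = 0.01, settle_min_time = 120) {
  state <- init_state(spec)
  snames <- vapply(spec$strains, `[[`, "", "name")
  state$metrics <- list(capture_metrics(state, spec))
  next_mark <- spec$metrics_every
  t_end <- spec$duration
  while (state$time < t_end - 1e-9) {
    dt <- min(spec$dt_max, next_mark - state$time, t_end - state$time)
    state <- sim_step(state, spec, dt)
    if (state$time >= next_mark - 1e-9) {
      state$metrics <- c(state$metrics, list(capture_metrics(state, spec)))
      next_mark <- next_mark + spec$metrics_every
    }
    if (state$extinct) { state$terminated <- TRUE; break }
    if (stop_when_settled && state$time >= settle_min_time &&
        state$time >= next_mark - spec$metrics_every) {
      times <- vapply(state$metrics, `[[`, 0, "time")
      inwin <- times >= state$time - settle_window
      if (sum(inwin) >= 3) {
        fr <- vapply(state$metrics[inwin], function(r) r$frequency[1], 0)
        if (!anyNA(fr) && diff(range(fr)) < settle_tol) {
          state$terminated <- TRUE
          break
        }
      }
    }
    if (stop_on_strain_loss && length(unique(state$pop$strain)) == 1L) {
      state$terminated <- TRUE
      last_t <- state$metrics[[length(state$metrics)]]$time
      if (state$time > last_t + 1e-9)
        state$metrics <- c(state$metrics, list(capture_metrics(state, spec)))
      break
    }
  }
  metrics <- metrics_to_df(state$metrics, snames)
  last <- state$metrics[[length(state$metrics)]]
  list(state = state, metrics = metrics,
       final_frequency = setNames(last$frequency, snames))
}
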