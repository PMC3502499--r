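# agents: per-cell biology and mechanics. Cells are solid spheres; a
# population is a column-oriented record (id, strain index, x, z, biomass).

#' Radius of a spherical cell from its biomass
#'
#' @param m Biomass (pg).
#' @param density Biomass density (pg/um^3).
#' @return Radius (um).
#' @export
cell_radius <- function(m, density = sim_defaults()$density) {
  (3 * m / (4 * pi * density))^(1 / 3)
}

#' Biomass of a cell of given radius
#' @param r Radius (um).
#' @param density Biomass density (pg/um^3).
#' @export
cell_mass <- function(r, density = sim_defaults()$density) {
  density * 4 / 3 * pi * r^3
}

#' Construct a population of cells
#'
#' @param id Integer ids (unique).
#' @param strain Integer strain indices (into the scenario's strain list).
#' @param x,z Centre coordinates (um; the epithelium is at z = 0).
#' @param m Biomass (pg), positive.
#' @return A `population` object.
#' @export
population <- function(id = integer(), strain = integer(),
                       x = numeric(), z = numeric(), m = numeric()) {
  n <- length(id)
  stopifnot(length(strain) == n, length(x) == n, length(z) == n,
            length(m) == n)
  if (anyDuplicated(id)) stop("cell ids must be unique")
  if (any(m <= 0)) stop("cell biomass must be > 0")
  if (any(z < 0)) stop("cell height must be >= 0")
  structure(list(id = as.integer(id), strain = as.integer(strain),
                 x = as.numeric(x), z = as.numeric(z), m = as.numeric(m)),
            class = "population")
}

#' Number of cells in a population
#' @param x A `population`.
#' @param ... Unused.
#' @export
length.population <- function(x) length(x$id)

pop_subset <- function(pop, keep) {
  population(pop$id[keep], pop$strain[keep], pop$x[keep], pop$z[keep],
             pop$m[keep])
}

#' Monod specific growth rate
#'
#' `mu = mu_max * N / (Ks + N)`: saturating dependence of growth on the local
#' nutrient concentration.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param Ks Half-saturation constant (pg/um^3), > 0.
#' @param N Local nutrient concentration (pg/um^3), >= 0.
#' @return Specific growth rate (1/h).
#' @export
monod_rate <- function(mu_max, Ks, N) {
  if (any(N < 0)) stop("negative nutrient concentration")
  if (any(Ks <= 0)) stop("Ks must be > 0")
  mu_max * N / (Ks + N)
}

#' Effective growth rate under substrate switching
#'
#' A cell forages on whichever substrate gives it the highest Monod rate at
#' its position, so its realised rate is the maximum over nutrients and can
#' never exceed its largest `mu_max`.
#'
#' @param strain A [strain_spec()].
#' @param concentrations Named local concentrations, one per nutrient in the
#'   strain's tables.
#' @return List with `rate` (1/h) and `nutrient` (the substrate consumed, for
#'   uptake accounting).
#' @export
effective_growth_rate <- function(strain, concentrations) {
  if (!length(concentrations)) stop("empty nutrient map")
  nuts <- names(concentrations)
  bad <- setdiff(nuts, names(strain$mu_max))
  if (length(bad))
    stop("strain '", strain$name, "' has no entry for nutrient '", bad[1L], "'")
  rates <- monod_rate(strain$mu_max[nuts], strain$Ks[nuts],
                      as.numeric(concentrations))
  k <- which.max(rates)
  list(rate = unname(rates[k]), nutrient = nuts[k])
}

# Vectorised substrate switching for the engine: conc is an n_cells x
# n_nutrients matrix of local concentrations. The hard best-substrate rule is
# smoothed with a sharp softmax over the per-substrate Monod rates (width
# `softness`, 1/h): away from the indifference margin this is the pure
# maximum rule, while exactly at the margin cells split their uptake. The
# split is what makes the reaction-diffusion fixed point stable -- a cell
# whose best substrate is locally exhausted tops up with the next-best
# instead of flip-flopping -- and the realised rate is a weighted mean, so
# the maximum growth rate is never exceeded.
growth_rates_vec <- function(pop, strains, conc, nutrients,
                             softness = 0.035) {
  n <- length(pop)
  k <- length(nutrients)
  if (n == 0L)
    return(list(rate = numeric(), which = integer(),
                weights = matrix(0, 0, k), rates = matrix(0, 0, k)))
  R <- matrix(0, n, k)
  for (j in seq_len(k)) {
    mu_max <- vapply(strains, function(s) s$mu_max[[nutrients[j]]], 0)[pop$strain]
    Ks <- vapply(strains, function(s) s$Ks[[nutrients[j]]], 0)[pop$strain]
    R[, j] <- monod_rate(mu_max, Ks, conc[, j])
  }
  rmax <- do.call(pmax, c(as.data.frame(R), list(0)))
  W <- exp((R - rmax) / softness)
  W <- W / rowSums(W)
  list(rate = rowSums(W * R), which = max.col(R, ties.method = "first"),
       weights = W, rates = R)
}

#' Grow cells and divide those past the division threshold
#'
#' Biomass is multiplied by `exp(rate * dt)`; any cell whose radius then
#' exceeds the division radius splits into two daughters of equal biomass
#' (total conserved) displaced by a small offset along a uniformly random
#' direction. Daughters inherit the strain; one keeps the parent id.
#'
#' @param pop A `population`.
#' @param rate Specific growth rates (1/h), one per cell.
#' @param dt Timestep (h); `rate * dt` must stay below 0.5.
#' @param params Parameter list (see [sim_defaults()]).
#' @return List with the new `population` and `growth`, the biomass added.
#' @export
grow_and_divide <- function(pop, rate, dt, params = sim_defaults()) {
  if (length(rate) != length(pop)) stop("one rate per cell required")
  if (length(pop) && max(rate) * dt >= 0.5)
    stop("rate * dt too large for a single step")
  m0 <- pop$m
  pop$m <- pop$m * exp(rate * dt)
  growth <- sum(pop$m) - sum(m0)
  m_div <- cell_mass(params$division_radius, params$density)
  div <- which(pop$m > m_div)
  if (length(div)) {
    theta <- runif(length(div), 0, 2 * pi)
    # daughters are placed just touching (one newborn radius each side);
    # shoving resolves the overlap they create with their neighbours
    off <- cell_radius(pop$m[div] / 2, params$density)
    half <- pop$m[div] / 2
    maxid <- max(pop$id)
    d1 <- list(id = pop$id[div], strain = pop$strain[div],
               x = pop$x[div] - off * cos(theta),
               z = pmax(0, pop$z[div] - off * sin(theta)), m = half)
    d2 <- list(id = maxid + seq_along(div), strain = pop$strain[div],
               x = pop$x[div] + off * cos(theta),
               z = pmax(0, pop$z[div] + off * sin(theta)), m = half)
    keep <- setdiff(seq_along(pop$id), div)
    pop <- population(c(pop$id[keep], d1$id, d2$id),
                      c(pop$strain[keep], d1$strain, d2$strain),
                      c(pop$x[keep], d1$x, d2$x),
                      c(pop$z[keep], d1$z, d2$z),
                      c(pop$m[keep], d1$m, d2$m))
  }
  list(pop = pop, growth = growth, n_divisions = length(div))
}

#' Probability of death from an antimicrobial
#'
#' The one-hour death probability is `p1 = T / (S + T)`, where `S` is the
#' concentration at which death within one hour has probability one half.
#' For other timesteps the constant-hazard scaling `1 - (1 - p1)^dt` is used
#' (dt in hours).
#'
#' @param T_conc Local antimicrobial concentration (pg/um^3), >= 0.
#' @param S Strain susceptibility parameter (pg/um^3), > 0.
#' @param dt Exposure time (h), > 0.
#' @return Death probability in `[0, 1)`.
#' @export
death_probability <- function(T_conc, S, dt = 1) {
  if (any(T_conc < 0)) stop("negative antimicrobial concentration")
  if (any(S <= 0)) stop("S must be > 0")
  if (any(dt <= 0)) stop("dt must be > 0")
  p1 <- T_conc / (S + T_conc)
  1 - (1 - p1)^dt
}

#' Apply antimicrobial mortality to a population
#'
#' Each cell dies independently with [death_probability()] evaluated at its
#' local antimicrobial concentration and its strain's susceptibility; dead
#' cells are removed immediately.
#'
#' @param pop A `population`.
#' @param fields List of converged antimicrobial `solute_field`s.
#' @param strains List of [strain_spec()] in strain-index order.
#' @param dt Timestep (h).
#' @return List with the surviving `population`, `died` (biomass removed,
#'   per strain index) and `n_died`.
#' @export
apply_mortality <- function(pop, fields, strains, dt) {
  died <- rep(0, length(strains))
  if (!length(fields) || !length(pop))
    return(list(pop = pop, died = died, n_died = 0L))
  dead <- rep(FALSE, length(pop))
  for (f in fields) {
    Tc <- local_concentration(f, pop$x, pop$z)
    S <- vapply(strains, function(s) s$susceptibility[[f$solute$name]], 0)[pop$strain]
    p <- death_probability(Tc, S, dt)
    dead <- dead | (runif(length(pop)) < p)
  }
  if (any(dead)) {
    tab <- tapply(pop$m[dead], pop$strain[dead], sum)
    died[as.integer(names(tab))] <- tab
    pop <- pop_subset(pop, !dead)
  }
  list(pop = pop, died = died, n_died = sum(dead))
}

#' Relax overlaps by shoving
#'
#' Iteratively displaces overlapping pairs along their centre line, half the
#' overlap each, wrapping laterally and reflecting at the epithelial floor
#' (centres never below one radius), until the maximum pairwise overlap is at
#' most `tol`.
#'
#' @param pop A `population`.
#' @param domain A [domain_spec()].
#' @param tol Residual overlap tolerance (um).
#' @param maxit Sweep cap; non-termination raises an error reporting the
#'   residual overlap.
#' @param params Parameter list (for the biomass density).
#' @return The relaxed `population`.
#' @export
shove_relax <- function(pop, domain, tol = sim_defaults()$shove_tol,
                        maxit = sim_defaults()$shove_maxit,
                        params = sim_defaults(), enforce = TRUE) {
  if (!length(pop)) return(pop)
  r <- cell_radius(pop$m, params$density)
  res <- shove_cpp(pop$x, pop$z, r, domain$width, tol, as.integer(maxit),
                   params$shove_damp %||% 0.6, params$shove_margin %||% 2.0)
  if (enforce && !res$converged)
    stop("shoving failed to relax within ", maxit,
         " sweeps (max residual overlap ", signif(res$max_overlap, 3), " um)")
  pop$x <- res$x
  pop$z <- res$z
  attr(pop, "max_overlap") <- res$max_overlap
  pop
}

#' Remove cells shoved past the sloughing height
#'
#' Cells whose centre height strictly exceeds `h_max` are removed (a cell
#' exactly at the boundary is kept).
#'
#' @param pop A `population`.
#' @param h_max Sloughing height (um), > 0.
#' @param n_strains Number of strains (length of the returned tally).
#' @return List with the remaining `population`, `removed` (biomass per
#'   strain index) and `n_removed`.
#' @export
slough <- function(pop, h_max, n_strains = max(pop$strain, 1L)) {
  if (h_max <= 0) stop("h_max must be > 0")
  removed <- rep(0, n_strains)
  gone <- pop$z > h_max
  if (any(gone)) {
    tab <- tapply(pop$m[gone], pop$strain[gone], sum)
    removed[as.integer(names(tab))] <- tab
    pop <- pop_subset(pop, !gone)
  }
  list(pop = pop, removed = removed, n_removed = sum(gone))
}
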