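# solute_field: pseudo-steady-state concentration fields on a regular grid.
#
# Grids are nz x nx matrices; row 1 is the grid row touching the epithelium,
# row nz touches the lumen face at the slough height. Node k sits at height
# (k - 1/2) * dx. Columns are lateral and periodic.

#' Create an (unsolved) solute field
#'
#' @param solute A [solute_spec()].
#' @param domain A [domain_spec()].
#' @param value Initial uniform concentration (pg/um^3).
#' @return A `solute_field` object.
#' @export
solute_field <- function(solute, domain, value = 0) {
  nz <- as.integer(round(domain$slough_height / domain$grid_spacing))
  nx <- as.integer(round(domain$width / domain$grid_spacing))
  structure(list(solute = solute, domain = domain,
                 grid = matrix(value, nz, nx),
                 converged = FALSE, residual = NA_real_, tol = NA_real_),
            class = "solute_field")
}

# Grid indices of cell centres (clamped so a centre exactly at the slough
# height maps to the top row). Errors if a cell lies outside the domain.
grid_index <- function(domain, x, z) {
  dx <- domain$grid_spacing
  nz <- as.integer(round(domain$slough_height / dx))
  nx <- as.integer(round(domain$width / dx))
  if (length(x)) {
    if (any(x < -1e-9 | x > domain$width + 1e-9))
      stop("cell outside domain laterally")
    if (any(z < -1e-9 | z > domain$slough_height + 1e-9))
      stop("cell outside domain vertically")
  }
  ix <- pmin(nx, pmax(1L, floor(x / dx) + 1L))
  iz <- pmin(nz, pmax(1L, floor(z / dx) + 1L))
  list(ix = as.integer(ix), iz = as.integer(iz),
       lin = as.integer((ix - 1L) * nz + iz), nz = nz, nx = nx)
}

#' Concentration of a field at given positions
#'
#' @param field A `solute_field`.
#' @param x,z Coordinates (um).
#' @return Concentrations at the grid nodes containing the positions.
#' @export
local_concentration <- function(field, x, z) {
  gi <- grid_index(field$domain, x, z)
  field$grid[cbind(gi$iz, gi$ix)]
}

# Deposit per-cell uptake rates (pg/h) into a volumetric reaction grid
# (pg/um^3/h); each cell's uptake goes wholly to the grid cell containing
# its centre.
deposit_uptake <- function(domain, x, z, uptake) {
  gi <- grid_index(domain, x, z)
  vol <- domain$grid_spacing^2  # unit depth
  grid <- matrix(0, gi$nz, gi$nx)
  if (length(uptake)) {
    acc <- vapply(split(uptake, gi$lin), sum, 0)
    grid[as.integer(names(acc))] <- acc / vol
  }
  structure(list(grid = grid, total = sum(uptake)), class = "reaction_field")
}

#' Assemble the volumetric reaction field for one nutrient
#'
#' Each living cell consumes at (Monod rate on this nutrient x biomass) /
#' yield, deposited into the grid cell containing its centre. This is the
#' single-substrate uptake; the simulation engine books uptake only to the
#' substrate each cell actually forages on (see
#' [effective_growth_rate()]).
#'
#' @param pop A [population()].
#' @param strains List of [strain_spec()] in strain-index order.
#' @param field The nutrient's current `solute_field`.
#' @return A `reaction_field`: volumetric consumption rates (pg/um^3/h) plus
#'   the summed uptake in `$total`.
#' @export
assemble_reaction_field <- function(pop, strains, field) {
  nut <- field$solute$name
  N <- local_concentration(field, pop$x, pop$z)
  mu_max <- vapply(strains, function(s) s$mu_max[[nut]], 0)[pop$strain]
  Ks <- vapply(strains, function(s) s$Ks[[nut]], 0)[pop$strain]
  yield <- vapply(strains, function(s) s$yield[[nut]], 0)[pop$strain]
  rate <- monod_rate(mu_max, Ks, N)
  deposit_uptake(field$domain, pop$x, pop$z, rate * pop$m / yield)
}

# Over-relaxation factor: near-optimal for the pure Laplacian, backed off
# towards 1.5 when a first-order sink strengthens the diagonal (the heavily
# damped system over-relaxes poorly).
sor_omega <- function(nz, nx, beta_max = 0) {
  if (beta_max > 0.5) 1.5 else 2 / (1 + sin(pi / max(nz, nx)))
}

#' Solve a solute field to pseudo-steady state
#'
#' Solves `D lap(C) - r = 0` by successive over-relaxation with the field's
#' boundary conditions (Dirichlet bulk value or zero flux at the lumen face,
#' prescribed flux or zero flux at the epithelial face, periodic laterally)
#' until the relative residual is at most `tol`.
#'
#' @param field A `solute_field` (its grid is the initial guess).
#' @param reaction A `reaction_field` (volumetric sink, pg/um^3/h), or `NULL`
#'   for no reaction.
#' @param tol Relative residual tolerance.
#' @param maxit Iteration cap.
#' @param linear_sink Optional matrix of first-order sink coefficients (1/h):
#'   an additional sink `linear_sink * C`, the Picard linearisation of Monod
#'   uptake used by the simulation engine. It enters the operator diagonal,
#'   keeping the solve positive and diagonally dominant.
#' @return The field with `grid` updated and `converged`/`residual` set.
#' @export
solve_steady_state <- function(field, reaction = NULL,
                               tol = sim_defaults()$solver_tol,
                               maxit = sim_defaults()$solver_maxit,
                               linear_sink = NULL) {
  sp <- field$solute
  if (!is.null(sp$prescribed))
    stop("solute '", sp$name, "' has a prescribed profile; it is never solved")
  grid <- field$grid
  sink <- if (is.null(reaction)) matrix(0, nrow(grid), ncol(grid)) else reaction$grid
  J <- if (sp$epithelial$type == "flux") sp$epithelial$value else 0
  if (sp$lumen$type == "zero_flux") {
    if (abs(J) > 0 || sum(sink) != 0 || !is.null(linear_sink))
      stop("ill-posed boundaries for solute '", sp$name,
           "': zero-flux lumen face with a nonzero net source/sink")
    field$converged <- TRUE; field$residual <- 0; field$tol <- tol
    return(field)
  }
  lin <- if (is.null(linear_sink)) matrix(0, nrow(grid), ncol(grid))
         else linear_sink
  # no sources at all (e.g. the famine phase of a feast-famine cycle):
  # the steady state is identically zero and the relative residual has no
  # scale to converge against
  if (sp$lumen$value == 0 && J == 0 && all(sink == 0)) {
    field$grid[] <- 0
    field$converged <- TRUE; field$residual <- 0; field$tol <- tol
    return(field)
  }
  dxg <- field$domain$grid_spacing
  beta_max <- max(lin) * dxg^2 / sp$diffusivity
  # converge the pointwise residual three orders below the quoted tolerance:
  # the boundary-flux imbalance amplifies the residual by up to the number of
  # nodes, and the mass-balance contract is 10x the quoted tolerance
  res <- sor_solve_cpp(grid, sink, lin, sp$diffusivity, dxg,
                       0L, sp$lumen$value, J, max(1e-3 * tol, 1e-14),
                       as.integer(maxit),
                       sor_omega(nrow(grid), ncol(grid), beta_max))
  # the stricter internal target can stall at machine precision; the quoted
  # tolerance is the contract
  if (!res$converged && res$residual > tol)
    stop("diffusion solver did not converge for solute '", sp$name,
         "' within ", maxit, " iterations (residual ", signif(res$residual, 3), ")")
  field$grid <- res$C
  field$converged <- TRUE
  field$residual <- res$residual
  field$tol <- tol
  if (res$n_clipped > 0)
    attr(field, "n_clipped") <- res$n_clipped
  field
}

#' Boundary-flux and consumption report for a converged field
#'
#' @param field A converged `solute_field`.
#' @param reaction The `reaction_field` used in the solve (or `NULL`).
#' @return List with `influx_lumen`, `influx_epithelial` (pg/h into the
#'   domain, per unit depth; the lumen entry is negative when the solute
#'   leaves through the lumen face), `consumption`, `net` and
#'   `relative_imbalance`.
#' @export
mass_balance <- function(field, reaction = NULL) {
  if (!isTRUE(field$converged)) stop("field is not converged")
  sp <- field$solute
  dx <- field$domain$grid_spacing
  influx_top <- if (!is.null(sp$prescribed) || sp$lumen$type != "dirichlet") 0
    else top_influx_cpp(field$grid, sp$diffusivity, dx, 0L, sp$lumen$value)
  influx_bottom <- if (is.null(sp$prescribed) && sp$epithelial$type == "flux")
    sp$epithelial$value * field$domain$width else 0
  consumption <- if (is.null(reaction)) 0 else sum(reaction$grid) * dx^2
  net <- influx_top + influx_bottom - consumption
  scale <- max(abs(influx_top) + abs(influx_bottom), consumption, 1e-300)
  list(influx_lumen = influx_top, influx_epithelial = influx_bottom,
       consumption = consumption, net = net,
       relative_imbalance = abs(net) / scale)
}

#' Build a field from a prescribed analytic profile
#'
#' Evaluates the solute's `prescribed` height profile at every grid node;
#' such fields are never passed to the solver.
#'
#' @param solute A [solute_spec()] with `prescribed` set.
#' @param domain A [domain_spec()].
#' @return A converged `solute_field`.
#' @export
prescribed_profile_field <- function(solute, domain) {
  if (is.null(solute$prescribed))
    stop("solute '", solute$name, "' has no prescribed profile")
  f <- solute_field(solute, domain)
  z <- (seq_len(nrow(f$grid)) - 0.5) * domain$grid_spacing
  vals <- profile_value(solute$prescribed, z)
  if (any(vals < 0))
    stop("prescribed profile for '", solute$name,
         "' is negative at some height")
  f$grid <- matrix(vals, nrow(f$grid), ncol(f$grid))
  f$converged <- TRUE
  f$residual <- 0
  f
}
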