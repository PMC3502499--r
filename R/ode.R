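# ode_reference: closed-form and compartment oracles for the individual-based
# model. The well-mixed limit is the classic replicator/logistic frequency
# curve; the two-zone model is a deliberately simple thickness-structured
# surrogate (epithelial-fed bottom band, lumen-fed top band, growth-driven
# upward advection, sloughing from the top).

#' Closed-form logistic frequency curve
#'
#' In a well-mixed exponential-competition model `dX_i/dt = (mu_i - d) X_i`,
#' the frequency of the faster strain B follows
#' `f(t) = f0 e^{dmu t} / (1 - f0 + f0 e^{dmu t})` with `dmu = mu_B - mu_A`
#' (the dilution rate cancels from the frequency dynamics).
#'
#' @param f0 Initial frequency of strain B.
#' @param dmu Growth-rate difference `mu_B - mu_A` (1/h).
#' @param t Times (h).
#' @return Frequencies of strain B.
#' @export
logistic_frequency <- function(f0, dmu, t) {
  e <- exp(dmu * t)
  f0 * e / (1 - f0 + f0 * e)
}

#' Well-mixed two-strain competition trajectory
#'
#' Integrates `dX_i/dt = (mu_i - dilution) X_i` (the saturating-nutrient
#' limit) and reports the frequency time series of strain B, which follows
#' [logistic_frequency()] exactly.
#'
#' @param mu_A,mu_B Specific growth rates (1/h), >= 0.
#' @param dilution Removal rate (1/h); affects biomass, not frequency.
#' @param f0_B Initial frequency of strain B.
#' @param t_end End time (h).
#' @param by Output time resolution (h).
#' @return Data frame with `time`, `biomass_A`, `biomass_B`, `freq_B`.
#' @export
wellmixed_trajectory <- function(mu_A, mu_B, dilution = 0, f0_B = 0.5,
                                 t_end = 48, by = 0.5) {
  if (mu_A < 0 || mu_B < 0) stop("rates must be >= 0")
  t <- seq(0, t_end, by = by)
  XA <- (1 - f0_B) * exp((mu_A - dilution) * t)
  XB <- f0_B * exp((mu_B - dilution) * t)
  data.frame(time = t, biomass_A = XA, biomass_B = XB,
             freq_B = XB / (XA + XB))
}

#' Two-zone thickness-structured competition surrogate
#'
#' A minimal compartment model of the mucus community of total thickness `H`:
#' a bottom band of thickness `min(delta_e, H/2)` fed by a non-selective
#' epithelial supply, and a top band fed by a lumen supply on which strain B
#' grows `lumen_advantage` faster than strain A. Lumen nutrients reach only
#' `delta_l` below the lumen face, so when the top band is thinner than
#' `delta_l` the remaining lumen supply spills into the bottom band (thin
#' communities are lumen-dominated throughout). Each band has a biomass
#' capacity proportional to its thickness; net growth in a full bottom band
#' advects biomass (at bottom-band composition) into the top band, and top
#' band overflow is sloughed. Growth in a band is supply-limited: realised
#' rates are `mu_i * phi` with a shared saturation factor
#' `phi = min(1, yield * supply / demand)`.
#'
#' Integration is explicit Euler with capacity clamping (the
#' capacity/overflow events make the right-hand side discontinuous, which
#' stiff integrators handle poorly); a divergence check raises an error with
#' diagnostics.
#'
#' @param H Community thickness (um), > 0.
#' @param lumen_advantage Strain B's advantage on lumen nutrients (fraction).
#' @param mu Baseline maximum growth rate (1/h).
#' @param sigma_e,sigma_l Epithelial and lumen supply rates (pg/um/h per unit
#'   width, i.e. per um of epithelium).
#' @param delta_e Bottom (epithelial) band thickness (um).
#' @param delta_l Lumen nutrient penetration depth (um).
#' @param kappa Packed biomass density (pg/um^3).
#' @param yield Biomass yield on nutrient.
#' @param f0_B Initial frequency of strain B.
#' @param t_end Integration time (h).
#' @param dt Euler step (h).
#' @return List with `freq_B` (final frequency of strain B), `trajectory`
#'   (data frame of time, zone biomasses, freq_B) and `mass_audit` (maximum
#'   absolute biomass-conservation error per step, pg).
#' @export
twozone_final_frequency <- function(H, lumen_advantage = 1, mu = 0.7,
                                    sigma_e = 0.03, sigma_l = 0.03,
                                    delta_e = 20, delta_l = 15,
                                    kappa = 0.16, yield = 0.5,
                                    f0_B = 0.5, t_end = 600, dt = 0.02) {
  if (H <= 0) stop("H must be > 0")
  h_b <- min(delta_e, H / 2)
  h_t <- H - h_b
  cap_b <- kappa * h_b
  cap_t <- kappa * h_t
  # lumen supply not absorbed in the top band spills into the bottom band
  spill <- sigma_l * max(0, 1 - h_t / delta_l)
  lum_top <- sigma_l - spill

  mu_A <- mu; mu_B <- mu * (1 + lumen_advantage)
  m0 <- 0.05 * kappa * H
  X <- c(A_b = (1 - f0_B) * m0 * h_b / H, B_b = f0_B * m0 * h_b / H,
         A_t = (1 - f0_B) * m0 * h_t / H, B_t = f0_B * m0 * h_t / H)
  nt <- ceiling(t_end / dt)
  keep <- max(1L, floor(nt / 200))
  traj <- vector("list", 0L)
  max_err <- 0

  grow <- function(XA, XB, muA, muB, supply) {
    demand <- muA * XA + muB * XB
    if (demand <= 0) return(c(0, 0))
    phi <- min(1, yield * supply / demand)
    c(muA * XA, muB * XB) * phi
  }

  for (k in seq_len(nt)) {
    m_before <- sum(X)
    # growth: bottom band (neutral epithelial supply + lumen spill, which is
    # selective), top band (selective lumen supply)
    g_b_neutral <- grow(X[1], X[2], mu_A, mu_A, sigma_e)
    g_b_spill <- grow(X[1], X[2], mu_A, mu_B, spill)
    g_t <- grow(X[3], X[4], mu_A, mu_B, lum_top)
    dX <- c(g_b_neutral + g_b_spill, g_t) * dt
    X <- X + dX
    grown <- sum(dX)
    sloughed <- 0
    # advection: bottom overflow moves up at bottom composition
    Mb <- X[1] + X[2]
    if (Mb > cap_b) {
      ex <- Mb - cap_b
      fb <- X[1:2] / Mb
      X[1:2] <- X[1:2] - ex * fb
      X[3:4] <- X[3:4] + ex * fb
    }
    # sloughing: top overflow leaves the system
    Mt <- X[3] + X[4]
    if (Mt > cap_t) {
      ex <- Mt - cap_t
      ft <- X[3:4] / Mt
      X[3:4] <- X[3:4] - ex * ft
      sloughed <- ex
    }
    if (any(!is.finite(X)) || any(X < -1e-9))
      stop("two-zone integration diverged at t = ", k * dt,
           " (state: ", paste(signif(X, 4), collapse = ", "), ")")
    # conservation: growth in, slough out, advection internal
    max_err <- max(max_err, abs(sum(X) - (m_before + grown - sloughed)))
    if (k %% keep == 0L)
      traj[[length(traj) + 1L]] <- c(time = k * dt, X,
                                     freq_B = (X[2] + X[4]) / sum(X))
  }
  traj <- as.data.frame(do.call(rbind, traj))
  names(traj) <- c("time", "A_b", "B_b", "A_t", "B_t", "freq_B")
  list(freq_B = (X[["B_b"]] + X[["B_t"]]) / sum(X),
       trajectory = traj, mass_audit = max_err)
}

#' Sweep community thickness in the two-zone model
#'
#' @param H_values Thicknesses to evaluate (um).
#' @param ... Passed to [twozone_final_frequency()].
#' @return Data frame with `H` and `freq_B` (final frequency of the faster,
#'   lumen-favoured strain).
#' @export
twozone_sweep <- function(H_values = c(5, 10, 20, 40, 60, 80, 120, 160), ...) {
  freq <- vapply(H_values, function(H) twozone_final_frequency(H, ...)$freq_B, 0)
  data.frame(H = H_values, freq_B = freq)
}
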