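# Scenario presets covering the package's experiment library: well-mixed
# competition, single-direction selection, opposing epithelial vs lumen
# selection, antimicrobial selection, prescribed profiles, neutral-nutrient
# controls, rare invaders and feast-famine cycles.

# Calibration comparing a lumen (Dirichlet) supply with an epithelial (flux)
# supply at "equal total influx": C_b = J*H/(2D) is the bulk concentration at
# which a uniform volumetric sink filling the whole domain of height H
# consumes exactly the flux J as the concentration reaches zero at the base
# (the fully-penetrated limit of the parabolic profile).
lumen_equiv_conc <- function(J, H, D) J * H / (2 * D)

preset_builders <- function() {
  d <- sim_defaults()
  mu <- d$mu_base; D <- d$diffusivity

  two_strains <- function(mu_A, mu_B, fA = 0.5, S_A = NULL, S_B = NULL) {
    sus <- function(S) if (is.null(S)) numeric() else S
    list(strain_spec("A", mu_max = mu_A, susceptibility = sus(S_A), frequency = fA),
         strain_spec("B", mu_max = mu_B, susceptibility = sus(S_B), frequency = 1 - fA))
  }

  list(
    # Gradient-free competition: one lumen nutrient, uniform concentration
    # from a per-step mass balance. `advantage` is strain B's growth-rate
    # advantage (fraction, e.g. 0.1 = 10%).
    fig1_wellmixed = function(ov) {
      a <- ov$advantage %||% 0.1
      scenario_spec(
        name = "fig1_wellmixed",
        domain = domain_spec(ov$width %||% 100, ov$slough_height %||% 40),
        strains = two_strains(c(lumen_sugar = mu), c(lumen_sugar = mu * (1 + a)),
                              fA = ov$frequency_A %||% 0.5),
        solutes = list(solute_spec("lumen_sugar", "nutrient", D,
                                   lumen = list(type = "dirichlet", value = 9e-4))),
        duration = ov$duration %||% 96, seed = ov$seed %||% 1L,
        well_mixed = TRUE,
        params = modifyList(list(wellmixed_influx = ov$influx %||% 6), ov$params %||% list()))
    },

    # Nutrients diffuse in exclusively from the epithelium (flux J at the
    # base, washout into the lumen); strain B has `advantage` on them.
    fig3_epithelial = function(ov) {
      a <- ov$advantage %||% 0.5; J <- ov$influx %||% 3
      scenario_spec(
        name = "fig3_epithelial",
        domain = domain_spec(ov$width %||% 60, ov$slough_height %||% 80),
        strains = two_strains(c(host_sugar = mu), c(host_sugar = mu * (1 + a)),
                              fA = ov$frequency_A %||% 0.5),
        solutes = list(solute_spec("host_sugar", "nutrient", D,
                                   lumen = list(type = "dirichlet", value = 0),
                                   epithelial = list(type = "flux", value = J))),
        duration = ov$duration %||% 192, seed = ov$seed %||% 1L,
        params = ov$params %||% list())
    },

    # Nutrients diffuse in exclusively from the lumen at the equal-influx
    # bulk concentration (see lumen_equiv_conc).
    fig3_lumen = function(ov) {
      a <- ov$advantage %||% 0.5; J <- ov$influx %||% 3
      H <- ov$slough_height %||% 80
      scenario_spec(
        name = "fig3_lumen",
        domain = domain_spec(ov$width %||% 60, H),
        strains = two_strains(c(lumen_sugar = mu), c(lumen_sugar = mu * (1 + a)),
                              fA = ov$frequency_A %||% 0.5),
        solutes = list(solute_spec("lumen_sugar", "nutrient", D,
                                   lumen = list(type = "dirichlet",
                                                value = lumen_equiv_conc(J, H, D)))),
        duration = ov$duration %||% 192, seed = ov$seed %||% 1L,
        params = ov$params %||% list())
    },

    # Opposing selection: epithelial nutrients favour strain A by
    # `epithelial_advantage`; lumen nutrients favour strain B by 100% and are
    # supplied at five times the epithelial-equivalent concentration.
    fig4_opposing = function(ov) {
      a <- ov$epithelial_advantage %||% 0.05
      J <- ov$influx %||% 0.5
      H <- ov$slough_height %||% 40
      scenario_spec(
        name = "fig4_opposing",
        domain = domain_spec(ov$width %||% 100, H),
        strains = two_strains(
          c(host_sugar = mu * (1 + a), lumen_sugar = mu),
          c(host_sugar = mu,           lumen_sugar = 2 * mu),
          fA = ov$frequency_A %||% 0.5),
        solutes = list(
          solute_spec("host_sugar", "nutrient", D,
                      lumen = list(type = "dirichlet", value = 0),
                      epithelial = list(type = "flux", value = J)),
          solute_spec("lumen_sugar", "nutrient", D,
                      lumen = list(type = "dirichlet",
                                   value = 5 * lumen_equiv_conc(J, H, D)))),
        duration = ov$duration %||% 288, seed = ov$seed %||% 1L,
        params = ov$params %||% list())
    },

    # As fig4_opposing, but the host selects with antimicrobials instead:
    # host nutrients are neutral and strain A tolerates `susceptibility_
    # advantage` more antimicrobial than strain B (S_A = (1+x) S_B).
    fig4b_antimicrobial = function(ov) {
      sa <- ov$susceptibility_advantage %||% 0.5
      J <- ov$influx %||% 0.5
      H <- ov$slough_height %||% 40
      S_B <- 1e-4
      scenario_spec(
        name = "fig4b_antimicrobial",
        domain = domain_spec(ov$width %||% 100, H),
        strains = two_strains(
          c(host_sugar = mu, lumen_sugar = mu),
          c(host_sugar = mu, lumen_sugar = 2 * mu),
          fA = ov$frequency_A %||% 0.5,
          S_A = c(defensin = (1 + sa) * S_B), S_B = c(defensin = S_B)),
        solutes = list(
          solute_spec("host_sugar", "nutrient", D,
                      lumen = list(type = "dirichlet", value = 0),
                      epithelial = list(type = "flux", value = J)),
          solute_spec("lumen_sugar", "nutrient", D,
                      lumen = list(type = "dirichlet",
                                   value = 5 * lumen_equiv_conc(J, H, D))),
          solute_spec("defensin", "antimicrobial", D,
                      lumen = list(type = "dirichlet", value = 0),
                      epithelial = list(type = "flux", value = 0.2))),
        duration = ov$duration %||% 288, seed = ov$seed %||% 1L,
        params = ov$params %||% list())
    },

    # Prescribed profiles (solver bypassed): saturating lumen nutrient with
    # no gradient, host nutrient decaying steeply from the epithelium so that
    # strain A outgrows B only in a thin basal layer. With `control = TRUE`
    # both profiles are flattened to their height averages (identical total
    # solute amounts, no spatial differences).
    fig5_prescribed = function(ov) {
      H <- ov$slough_height %||% 40
      lam <- ov$lambda %||% 3
      lumen_prof <- list(kind = "constant", value = 9e-4)
      host_prof <- list(kind = "exponential", value = 6e-4, lambda = lam)
      if (isTRUE(ov$control)) {
        lumen_prof <- list(kind = "constant", value = profile_mean(lumen_prof, H))
        host_prof <- list(kind = "constant", value = profile_mean(host_prof, H))
      }
      scenario_spec(
        name = if (isTRUE(ov$control)) "fig5_wellmixed_control" else "fig5_prescribed",
        domain = domain_spec(ov$width %||% 60, H),
        strains = two_strains(
          c(host_sugar = 3 * mu, lumen_sugar = mu),
          c(host_sugar = mu,     lumen_sugar = 2 * mu),
          fA = ov$frequency_A %||% 0.5),
        solutes = list(
          solute_spec("host_sugar", "nutrient", D, prescribed = host_prof),
          solute_spec("lumen_sugar", "nutrient", D, prescribed = lumen_prof)),
        duration = ov$duration %||% 72, seed = ov$seed %||% 1L,
        params = ov$params %||% list())
    },

    # Selective nutrients from one direction plus non-selective (neutral)
    # nutrients from the other. `selective_source` is "lumen" or
    # "epithelial"; `include_neutral = FALSE` drops the neutral solute,
    # giving the matching single-source baseline.
    s3_neutral_nutrients = function(ov) {
      src <- ov$selective_source %||% "lumen"
      if (!src %in% c("lumen", "epithelial"))
        stop("selective_source must be 'lumen' or 'epithelial'")
      a <- ov$advantage %||% 0.5; J <- ov$influx %||% 3
      H <- ov$slough_height %||% 80
      incl <- ov$include_neutral %||% TRUE
      Cb <- lumen_equiv_conc(J, H, D)
      if (src == "lumen") {
        sel <- solute_spec("lumen_sugar", "nutrient", D,
                           lumen = list(type = "dirichlet", value = Cb))
        neu <- solute_spec("host_neutral", "nutrient", D,
                           lumen = list(type = "dirichlet", value = 0),
                           epithelial = list(type = "flux", value = J))
        selname <- "lumen_sugar"; neuname <- "host_neutral"
      } else {
        sel <- solute_spec("host_sugar", "nutrient", D,
                           lumen = list(type = "dirichlet", value = 0),
                           epithelial = list(type = "flux", value = J))
        neu <- solute_spec("lumen_neutral", "nutrient", D,
                           lumen = list(type = "dirichlet", value = Cb))
        selname <- "host_sugar"; neuname <- "lumen_neutral"
      }
      mk <- function(msel) {
        v <- c(msel, if (incl) setNames(mu, neuname))
        names(v)[1] <- selname
        v
      }
      scenario_spec(
        name = paste0("s3_neutral_", src),
        domain = domain_spec(ov$width %||% 60, H),
        strains = two_strains(mk(mu), mk(mu * (1 + a)),
                              fA = ov$frequency_A %||% 0.5),
        solutes = if (incl) list(sel, neu) else list(sel),
        duration = ov$duration %||% 192, seed = ov$seed %||% 1L,
        params = ov$params %||% list())
    },

    # fig4 conditions with strain A initially rare (frequency 0.1).
    s4_rare_invader = function(ov) {
      ov$frequency_A <- ov$frequency_A %||% 0.1
      ov$epithelial_advantage <- ov$epithelial_advantage %||% 0.5
      sp <- preset_builders()$fig4_opposing(ov)
      sp$name <- "s4_rare_invader"
      sp
    },

    # Antimicrobial selection alone: neutral lumen nutrients at a bulk high
    # enough to saturate the whole colony, plus a host antimicrobial with a
    # susceptibility advantage for strain A.
    s5_antimicrobial_only = function(ov) {
      sa <- ov$susceptibility_advantage %||% 1.0
      S_B <- 1e-4
      scenario_spec(
        name = "s5_antimicrobial_only",
        domain = domain_spec(ov$width %||% 60, ov$slough_height %||% 40),
        strains = two_strains(
          c(lumen_sugar = mu), c(lumen_sugar = mu),
          fA = ov$frequency_A %||% 0.5,
          S_A = c(defensin = (1 + sa) * S_B), S_B = c(defensin = S_B)),
        solutes = list(
          solute_spec("lumen_sugar", "nutrient", D,
                      lumen = list(type = "dirichlet", value = 0.01)),
          solute_spec("defensin", "antimicrobial", D,
                      lumen = list(type = "dirichlet", value = 0),
                      epithelial = list(type = "flux", value = 0.2))),
        duration = ov$duration %||% 192, seed = ov$seed %||% 1L,
        params = ov$params %||% list())
    },

    # fig4 conditions with a feast-famine square wave on the lumen nutrient:
    # phases of 8 h at twice the base concentration alternate with 8 h at
    # zero, so the time-averaged supply is unchanged.
    s6_feast_famine = function(ov) {
      ov$epithelial_advantage <- ov$epithelial_advantage %||% 0.25
      sp <- preset_builders()$fig4_opposing(ov)
      sp$name <- "s6_feast_famine"
      sp$feast_famine <- list(period = ov$period %||% 8, solutes = "lumen_sugar")
      assert_scenario(sp)
      sp
    }
  )
}

#' Names of the built-in scenario presets
#' @export
preset_names <- function() names(preset_builders())

#' Build a scenario from the built-in preset library
#'
#' Presets encode the package's experiment suite: `fig1_wellmixed`
#' (gradient-free two-strain competition), `fig3_epithelial` / `fig3_lumen`
#' (selection from one direction at equal total influx), `fig4_opposing`
#' (weak epithelial selection against 100% lumen selection at five-fold lumen
#' concentration), `fig4b_antimicrobial`, `fig5_prescribed` (thin favourable
#' basal layer vs an equal-totals well-mixed control), `s3_neutral_nutrients`,
#' `s4_rare_invader` (initial frequency 0.1), `s5_antimicrobial_only` and
#' `s6_feast_famine` (8 h feast-famine phases).
#'
#' @param name Preset name, one of [preset_names()].
#' @param overrides Named list of preset parameters to override. Generic keys:
#'   `width`, `slough_height`, `duration`, `seed`, `frequency_A`, `influx`,
#'   `params`. Preset-specific keys: `advantage` (fig1, fig3, s3),
#'   `epithelial_advantage` (fig4, s4, s6), `susceptibility_advantage`
#'   (fig4b, s5), `control` and `lambda` (fig5), `selective_source` and
#'   `include_neutral` (s3), `period` (s6).
#' @return A validated [scenario_spec()].
#' @export
scenario_preset <- function(name, overrides = list()) {
  builders <- preset_builders()
  if (!name %in% names(builders))
    stop("unknown preset '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  known <- c("width", "slough_height", "duration", "seed", "frequency_A",
             "influx", "params", "advantage", "epithelial_advantage",
             "susceptibility_advantage", "control", "lambda",
             "selective_source", "include_neutral", "period",
             "metrics_every", "inoculum_total", "dt_max")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown override key '", bad[1L], "'")
  spec <- builders[[name]](overrides)
  if (!is.null(overrides$metrics_every)) spec$metrics_every <- overrides$metrics_every
  if (!is.null(overrides$inoculum_total))
    spec$inoculum_total <- as.integer(overrides$inoculum_total)
  if (!is.null(overrides$dt_max)) spec$dt_max <- overrides$dt_max
  assert_scenario(spec)
  spec
}
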