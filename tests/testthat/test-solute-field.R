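# Reaction-diffusion solver against 1D closed forms, mass balance,
# prescribed profiles, reaction assembly.

D <- sim_defaults()$diffusivity

test_that("solver reproduces the three 1D closed forms to 1e-6", {
  dom <- domain_spec(40, 40, 4)
  z <- (1:10 - 0.5) * 4
  tol <- 1e-10

  # uniform: zero reaction, lumen Dirichlet Cb, epithelial zero flux
  Cb <- 2e-3
  f <- solute_field(solute_spec("u", "nutrient",
        lumen = list(type = "dirichlet", value = Cb)), dom)
  f <- solve_steady_state(f, NULL, tol)
  expect_lt(max(abs(f$grid - Cb)) / Cb, 1e-6)

  # linear: zero reaction, lumen Dirichlet 0, epithelial flux J
  J <- 2
  f <- solute_field(solute_spec("l", "nutrient",
        lumen = list(type = "dirichlet", value = 0),
        epithelial = list(type = "flux", value = J)), dom, value = 1e-3)
  f <- solve_steady_state(f, NULL, tol)
  lin <- (J / D) * (40 - z)
  expect_lt(max(abs(f$grid[, 1] - lin)) / max(lin), 1e-6)
  expect_true(f$converged)
  expect_lte(f$residual, tol)

  # parabolic: uniform volumetric sink r, lumen Dirichlet Cb, bottom zero flux
  # D C'' = r, C'(0) = 0, C(H) = Cb  =>  C(z) = Cb + r/(2D) (z^2 - H^2)
  r <- 4e-5; Cb <- 1e-3
  sink <- structure(list(grid = matrix(r, 10, 10), total = r * 1600),
                    class = "reaction_field")
  f <- solute_field(solute_spec("p", "nutrient",
        lumen = list(type = "dirichlet", value = Cb)), dom, value = Cb)
  f <- solve_steady_state(f, sink, tol)
  par <- Cb + r / (2 * D) * (z^2 - 40^2)
  expect_lt(max(abs(f$grid[, 1] - par)) / max(par), 1e-6)
})

test_that("mass balance closes to within 10x solver tolerance", {
  dom <- domain_spec(40, 40, 4)
  tol <- 1e-9

  # linear case: epithelial influx J crosses the slab and exits at the lumen
  J <- 2
  f <- solute_field(solute_spec("l", "nutrient",
        lumen = list(type = "dirichlet", value = 0),
        epithelial = list(type = "flux", value = J)), dom)
  f <- solve_steady_state(f, NULL, tol)
  mb <- mass_balance(f, NULL)
  expect_equal(mb$influx_epithelial, J * 40)
  expect_equal(mb$influx_lumen, -J * 40, tolerance = 1e-6)
  expect_lte(mb$relative_imbalance, 10 * tol)

  # uniform-sink case: lumen influx equals total consumption
  r <- 4e-5
  sink <- structure(list(grid = matrix(r, 10, 10), total = r * 1600),
                    class = "reaction_field")
  f <- solute_field(solute_spec("p", "nutrient",
        lumen = list(type = "dirichlet", value = 1e-3)), dom, value = 1e-3)
  f <- solve_steady_state(f, sink, tol)
  mb <- mass_balance(f, sink)
  expect_equal(mb$consumption, r * 40 * 40)
  expect_lte(mb$relative_imbalance, 10 * tol)

  # zero everything: 0 = 0
  f0 <- solute_field(solute_spec("z", "nutrient"), dom)
  f0 <- solve_steady_state(f0, NULL, tol)
  mb0 <- mass_balance(f0, NULL)
  expect_equal(mb0$net, 0)
  expect_equal(mb0$relative_imbalance, 0)
})

test_that("grid refinement changes converged concentrations by under 5%", {
  J <- 1.5
  base <- NULL
  for (dx in c(4, 2)) {
    dom <- domain_spec(40, 40, dx)
    f <- solute_field(solute_spec("l", "nutrient",
          lumen = list(type = "dirichlet", value = 1e-4),
          epithelial = list(type = "flux", value = J)), dom)
    # localized sink band near the bottom (one physical band, both grids)
    nz <- nrow(f$grid)
    sink <- matrix(0, nz, ncol(f$grid))
    band <- which((seq_len(nz) - 0.5) * dx <= 8)
    sink[band, ] <- 0.02
    rf <- structure(list(grid = sink, total = sum(sink) * dx^2),
                    class = "reaction_field")
    f <- solve_steady_state(f, rf, 1e-10)
    # compare mean concentrations over identical physical bands
    zc <- (seq_len(nz) - 0.5) * dx
    probe <- vapply(list(c(0, 8), c(16, 24), c(32, 40)), function(b)
      mean(f$grid[zc > b[1] & zc < b[2], ]), 0)
    if (is.null(base)) base <- probe
    else expect_lt(max(abs(probe - base) / pmax(base, 1e-12)), 0.05)
  }
})

test_that("solved fields are laterally periodic under translation of the sinks", {
  dom <- domain_spec(40, 20, 4)
  nz <- 5; nx <- 10
  set.seed(2)
  sink <- matrix(0, nz, nx)
  sink[1:2, 3:5] <- 0.01
  mk <- function(sk) {
    f <- solute_field(solute_spec("l", "nutrient",
          lumen = list(type = "dirichlet", value = 2e-3)), dom, value = 2e-3)
    solve_steady_state(f, structure(list(grid = sk, total = sum(sk) * 16),
                                    class = "reaction_field"), 1e-11)
  }
  f1 <- mk(sink)
  shift <- 3
  f2 <- mk(sink[, c((nx - shift + 1):nx, 1:(nx - shift))])
  expect_equal(f2$grid, f1$grid[, c((nx - shift + 1):nx, 1:(nx - shift))],
               tolerance = 1e-6)
})

test_that("reaction assembly deposits Monod uptake at cell centres", {
  dom <- domain_spec(40, 20, 4)
  strains <- list(strain_spec("A", c(sugar = 0.8), Ks = c(sugar = 1e-4),
                              yield = c(sugar = 0.5)))
  bulk <- 10  # vastly saturating
  f <- solute_field(solute_spec("sugar", "nutrient",
        lumen = list(type = "dirichlet", value = bulk)), dom, value = bulk)

  # no cells -> all-zero field
  empty <- population()
  rf0 <- assemble_reaction_field(empty, strains, f)
  expect_equal(sum(rf0$grid), 0)

  # one cell at saturation: uptake = mu_max * m / yield in its grid cell
  pop1 <- population(1L, 1L, x = 6, z = 6, m = 0.5)
  rf1 <- assemble_reaction_field(pop1, strains, f)
  expect_equal(rf1$total, 0.8 * 0.5 / 0.5, tolerance = 1e-4)
  expect_equal(rf1$grid[2, 2], rf1$total / 16, tolerance = 1e-6)
  expect_equal(sum(rf1$grid > 0), 1L)

  # two co-located cells: exactly twice the single-cell uptake
  pop2 <- population(1:2, c(1L, 1L), x = c(6, 6), z = c(6, 6), m = c(0.5, 0.5))
  rf2 <- assemble_reaction_field(pop2, strains, f)
  expect_equal(rf2$total, 2 * rf1$total)

  # a cell outside the domain is a geometry error
  bad <- population(1L, 1L, x = 45, z = 6, m = 0.5)
  expect_error(assemble_reaction_field(bad, strains, f), "outside domain")
})

test_that("prescribed profiles fill fields exactly and reject negatives", {
  dom <- domain_spec(40, 40, 4)
  z <- (1:10 - 0.5) * 4

  cst <- prescribed_profile_field(solute_spec("c", "nutrient",
        prescribed = list(kind = "constant", value = 3e-4)), dom)
  expect_true(all(cst$grid == 3e-4))
  expect_true(cst$converged)

  ex <- prescribed_profile_field(solute_spec("e", "nutrient",
        prescribed = list(kind = "exponential", value = 6e-4, lambda = 3)), dom)
  expect_equal(ex$grid[, 4], 6e-4 * exp(-z / 3))

  neg <- solute_spec("n", "nutrient",
        prescribed = list(kind = "linear", value = 1e-4, slope = -1e-5))
  expect_error(prescribed_profile_field(neg, dom), "negative")

  # equal-totals well-mixed control: uniform field matching the integral
  H <- 40
  flat <- prescribed_profile_field(solute_spec("f", "nutrient",
        prescribed = list(kind = "constant",
                          value = profile_mean(list(kind = "exponential",
                                                    value = 6e-4, lambda = 3), H))), dom)
  expect_equal(mean(flat$grid) * H, 6e-4 * 3 * (1 - exp(-H / 3)),
               tolerance = 1e-12)
})

test_that("ill-posed boundary combinations are rejected", {
  dom <- domain_spec(40, 20, 4)
  f <- solute_field(solute_spec("z", "nutrient"), dom)  # both zero flux
  sink <- structure(list(grid = matrix(1e-3, 5, 10), total = 1), class = "reaction_field")
  expect_error(solve_steady_state(f, sink), "ill-posed")
})
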