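# Per-cell biology and mechanics.

test_that("Monod kinetics has the defining half-saturation behaviour", {
  expect_equal(monod_rate(1.0, 2e-4, 2e-4), 0.5)     # N = Ks -> mu_max / 2
  expect_equal(monod_rate(0.9, 1e-4, 0), 0)          # no nutrient, no growth
  expect_equal(monod_rate(0.5, 2, 6), 0.375)         # direct evaluation
  # monotone in N and bounded by mu_max
  N <- seq(0, 1e-2, length.out = 50)
  r <- monod_rate(0.7, 3e-5, N)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 0.7))
  expect_error(monod_rate(1, 1e-4, -1), "negative")
  expect_error(monod_rate(1, 0, 1), "Ks")
})

test_that("substrate switching forages on the best substrate, capped at mu_max", {
  st <- strain_spec("A", mu_max = c(glc = 1.0, fuc = 1.0),
                    Ks = c(glc = 1e-4, fuc = 1e-4))
  one <- effective_growth_rate(st, c(glc = 1e-4))
  expect_equal(one$rate, 0.5)
  expect_equal(one$nutrient, "glc")
  # two substrates: takes the better, books uptake to it
  st2 <- strain_spec("A", mu_max = c(glc = 0.6, fuc = 1.0),
                     Ks = c(glc = 1e-9, fuc = 1e-4))
  two <- effective_growth_rate(st2, c(glc = 1, fuc = 1e-4))
  expect_equal(two$rate, 0.6, tolerance = 1e-6)
  expect_equal(two$nutrient, "glc")
  # both saturating at mu_max 1.0: rate is 1.0, never the sum
  sat <- effective_growth_rate(st, c(glc = 1, fuc = 1))
  expect_lt(sat$rate, 1.0 + 1e-12)
  expect_gt(sat$rate, 0.999)
  expect_error(effective_growth_rate(st, numeric()), "empty nutrient map")
  expect_error(effective_growth_rate(st, c(mannose = 1)), "no entry")
})

test_that("growth is exponential and division conserves biomass", {
  p <- sim_defaults()
  m0 <- 0.4
  pop <- population(1L, 1L, x = 5, z = 1, m = m0)
  # zero rate: identical cell back
  out <- grow_and_divide(pop, 0, 0.5, p)
  expect_equal(out$pop$m, m0)
  expect_equal(out$n_divisions, 0L)
  # closed-form exponential growth over many small steps, below threshold
  rate <- 0.3; dt <- 0.05
  for (k in 1:10) pop <- grow_and_divide(pop, rate, dt, p)$pop
  expect_equal(pop$m, m0 * exp(rate * 0.5), tolerance = 1e-12)
  # push over the division threshold: two daughters, biomass conserved
  m_div <- cell_mass(p$division_radius, p$density)
  pop <- population(7L, 2L, x = 5, z = 1, m = 0.999 * m_div)
  set.seed(1)
  out <- grow_and_divide(pop, 0.4, 0.1, p)
  expect_equal(length(out$pop$id), 2L)
  expect_equal(sum(out$pop$m), 0.999 * m_div * exp(0.4 * 0.1))
  expect_equal(out$pop$strain, c(2L, 2L))
  expect_false(anyDuplicated(out$pop$id) > 0)
})

test_that("population-level biomass follows e^{mu t} in saturating nutrient", {
  # one founder cell, effectively unlimited nutrient, no sloughing reach:
  # after 5 doublings total biomass matches the closed form within 1%
  sp <- tiny_lumen_scenario(advantage = 0, duration = 5, n0 = 1,
                            bulk = 0.3, slough = 40, width = 40)
  sp$well_mixed <- TRUE
  sp$params$wellmixed_influx <- 1e5
  res <- run_simulation(sp)
  m <- res$metrics
  mu_eff <- 0.7 * 0.3 / (sim_defaults()$Ks_default + 0.3)
  m0 <- m$biomass_A[1] + m$biomass_B[1]
  final <- tail(m$biomass_A + m$biomass_B, 1)
  expect_gt(final / m0, 2^5)  # at least five doublings happened
  expect_equal(final, m0 * exp(mu_eff * 5), tolerance = 0.01)
})

test_that("death probability matches the one-hour contract and hazard scaling", {
  S <- 2e-4
  expect_equal(death_probability(S, S, 1), 0.5)
  expect_equal(death_probability(0, S, 5), 0)
  expect_equal(death_probability(3 * S, S, 1), 0.75)
  # constant-hazard compounding: two hours at T = S
  expect_equal(death_probability(S, S, 2), 1 - 0.25)
  # monotone in T and dt
  expect_true(all(diff(death_probability(seq(0, 1e-3, length.out = 20), S, 1)) > 0))
  expect_lt(death_probability(S, S, 0.5), death_probability(S, S, 1))
  expect_error(death_probability(-1, S, 1), "negative")
})

test_that("mortality kills at binomial rates and differentiates strains", {
  dom <- domain_spec(40, 20)
  am <- solute_spec("tox", "antimicrobial",
                    prescribed = list(kind = "constant", value = 2e-4))
  field <- prescribed_profile_field(am, dom)
  S_B <- 2e-4
  strains <- list(
    strain_spec("A", c(sugar = 0.7), susceptibility = c(tox = 3 * S_B)),
    strain_spec("B", c(sugar = 0.7), susceptibility = c(tox = S_B)))
  n <- 1000
  pop <- population(1:n, rep(1:2, each = n / 2),
                    x = runif(n, 0, 40), z = runif(n, 1, 19), m = rep(0.5, n))
  set.seed(42)
  out <- apply_mortality(pop, list(field), strains, dt = 1)
  survA <- sum(out$pop$strain == 1); survB <- sum(out$pop$strain == 2)
  # expected survival: A at T = S_B, S_A = 3 S_B -> p = 1/4; B -> p = 1/2
  expect_gt(survA, qbinom(0.005, n / 2, 0.75))
  expect_lt(survA, qbinom(0.995, n / 2, 0.75))
  expect_gt(survB, qbinom(0.005, n / 2, 0.5))
  expect_lt(survB, qbinom(0.995, n / 2, 0.5))
  # biomass ledger matches removed cells
  expect_equal(sum(out$died), 0.5 * (n - survA - survB))
  # zero antimicrobial: nothing happens
  none <- apply_mortality(pop, list(), strains, 1)
  expect_equal(none$pop, pop)
})

test_that("shoving resolves a dense cluster with no residual overlap or floor breach", {
  dom <- domain_spec(40, 20)
  set.seed(3)
  n <- 50
  pop <- population(1:n, rep(1:2, 25), x = 20 + runif(n, -2, 2),
                    z = pmax(1, 3 + runif(n, -2, 2)), m = rep(0.6, n))
  tol <- 0.05
  out <- shove_relax(pop, dom, tol = tol, maxit = 5000)
  r <- cell_radius(out$m)
  # exhaustive brute-force pair audit
  worst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- abs(out$x[i] - out$x[j]); dx <- min(dx, 40 - dx)
    d <- sqrt(dx^2 + (out$z[i] - out$z[j])^2)
    worst <- max(worst, r[i] + r[j] - d)
  }
  expect_lte(worst, tol + 1e-9)
  expect_true(all(out$z >= r - 1e-9))
  # idempotence: relaxing a relaxed population moves nothing appreciably
  again <- shove_relax(out, dom, tol = tol, maxit = 5000)
  expect_lt(max(abs(again$x - out$x), abs(again$z - out$z)), tol + 1e-9)
  # non-overlapping population is untouched
  sparse <- population(1:3, c(1L, 1L, 2L), x = c(5, 15, 25),
                       z = c(2, 2, 2), m = rep(0.5, 3))
  out2 <- shove_relax(sparse, dom)
  expect_equal(out2$x, sparse$x)
  expect_equal(out2$z, sparse$z)
})

test_that("sloughing removes exactly the cells above the cutoff", {
  pop <- scatter_population(80, 40, 30, seed = 5)
  h <- 17.3
  out <- slough(pop, h, n_strains = 2)
  # brute-force filter comparison
  expect_equal(sort(out$pop$id), sort(pop$id[pop$z <= h]))
  for (s in 1:2)
    expect_equal(out$removed[s], sum(pop$m[pop$z > h & pop$strain == s]))
  # boundary cell kept, cell just above removed
  pb <- population(1:2, c(1L, 1L), x = c(1, 2), z = c(h, h + 1e-9), m = c(1, 1))
  ob <- slough(pb, h, 1)
  expect_equal(ob$pop$id, 1L)
  expect_equal(ob$removed, 1)
  # nothing below: nothing removed
  expect_equal(slough(pop, 100, 2)$n_removed, 0L)
})
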