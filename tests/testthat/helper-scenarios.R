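# Shared builders for small test scenarios (built in code, no stored data).

# Two strains on one lumen-supplied nutrient; strain B faster by `advantage`.
tiny_lumen_scenario <- function(advantage = 0, width = 40, slough = 20,
                                duration = 4, seed = 1, bulk = 9e-4,
                                n0 = 60) {
  scenario_spec(
    name = "tiny_lumen",
    domain = domain_spec(width, slough),
    strains = list(
      strain_spec("A", c(sugar = 0.7), frequency = 0.5),
      strain_spec("B", c(sugar = 0.7 * (1 + advantage)), frequency = 0.5)),
    solutes = list(
      solute_spec("sugar", "nutrient",
                  lumen = list(type = "dirichlet", value = bulk))),
    duration = duration, seed = seed, inoculum_total = n0)
}

# A raw configuration tree (as parsed from YAML) for validate_config tests.
raw_config_tree <- function() {
  list(
    name = "raw",
    domain = list(width = 40, slough_height = 20, grid_spacing = 4),
    strains = list(
      list(name = "A", mu_max = list(sugar = 0.7), frequency = 0.5),
      list(name = "B", mu_max = list(sugar = 0.77), frequency = 0.5)),
    solutes = list(
      list(name = "sugar", kind = "nutrient",
           lumen = list(type = "dirichlet", value = 9e-4))),
    duration = 2)
}

# Deterministic loose population: n cells on a width x height patch.
scatter_population <- function(n, width, height, seed = 1, m = 0.6) {
  set.seed(seed)
  population(id = seq_len(n), strain = rep(1:2, length.out = n),
             x = runif(n, 0, width), z = runif(n, 1, height),
             m = rep(m, n))
}
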