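# Domain types, validation, presets and config round-trips.

test_that("a minimal raw tree round-trips through validation with defaults", {
  spec <- validate_config(raw_config_tree())
  expect_s3_class(spec, "scenario_spec")
  expect_equal(spec$domain$width, 40)
  expect_equal(spec$inoculum_total, 250L)
  expect_equal(spec$strains[[2]]$Ks[["sugar"]], sim_defaults()$Ks_default)
  expect_equal(spec$strains[[2]]$yield[["sugar"]], sim_defaults()$yield_default)
  # explicit fields survive unchanged
  expect_equal(spec$strains[[2]]$mu_max[["sugar"]], 0.77)
})

test_that("invariant violations are rejected with informative errors", {
  bad <- raw_config_tree()
  bad$strains[[1]]$frequency <- 0.4  # sums to 0.9
  expect_error(validate_config(bad), "frequencies must sum to 1")

  bad <- raw_config_tree()
  bad$strains[[1]]$mu_max <- list(glucoze = 0.7)
  expect_error(validate_config(bad), "undefined nutrient 'glucoze'")

  bad <- raw_config_tree()
  bad$strains[[1]]$mu_max <- list(sugar = -1)
  expect_error(validate_config(bad), "mu_max must be >= 0")

  bad <- raw_config_tree()
  bad$domain$grid_spacing <- 7
  expect_error(validate_config(bad), "divide width evenly")

  expect_error(domain_spec(40, 20, dimensionality = "3D"), "not implemented")
  expect_error(strain_spec("A", numeric()), "at least one nutrient")
  expect_error(solute_spec("s", "nutrient",
                           lumen = list(type = "zero_flux"),
                           epithelial = list(type = "flux", value = 1)),
               "ill-posed")
})

test_that("strain cross-references to antimicrobials are checked", {
  tree <- raw_config_tree()
  tree$solutes[[2]] <- list(name = "defensin", kind = "antimicrobial",
                            lumen = list(type = "dirichlet", value = 0),
                            epithelial = list(type = "flux", value = 0.1))
  expect_error(validate_config(tree), "no susceptibility entry")
  tree$strains <- lapply(tree$strains, function(s) {
    s$susceptibility <- list(defensin = 1e-4); s
  })
  expect_s3_class(validate_config(tree), "scenario_spec")
})

test_that("presets encode the stated parameter relations", {
  # opposing selection: A's epithelial mu_max = (1+a) x B's; B's lumen
  # mu_max = 2 x A's; lumen bulk five times the epithelial-equivalent supply
  a <- 0.05
  sp <- scenario_preset("fig4_opposing", list(epithelial_advantage = a))
  A <- sp$strains[[1]]; B <- sp$strains[[2]]
  expect_equal(A$mu_max[["host_sugar"]], (1 + a) * B$mu_max[["host_sugar"]])
  expect_equal(B$mu_max[["lumen_sugar"]], 2 * A$mu_max[["lumen_sugar"]])
  J <- sp$solutes$host_sugar$epithelial$value
  H <- sp$domain$slough_height
  D <- sp$solutes$host_sugar$diffusivity
  expect_equal(sp$solutes$lumen_sugar$lumen$value, 5 * J * H / (2 * D))

  # identical strains under zero advantage
  sp0 <- scenario_preset("fig1_wellmixed", list(advantage = 0))
  expect_equal(sp0$strains[[1]]$mu_max[["lumen_sugar"]],
               sp0$strains[[2]]$mu_max[["lumen_sugar"]])

  # feast-famine phases last 8 h
  s6 <- scenario_preset("s6_feast_famine", list())
  expect_equal(s6$feast_famine$period, 8)
  expect_equal(s6$feast_famine$solutes, "lumen_sugar")

  # rare invader starts at frequency 0.1
  s4 <- scenario_preset("s4_rare_invader", list())
  expect_equal(s4$strains[[1]]$frequency, 0.1)

  expect_error(scenario_preset("fig9_nonsense"), "available")
  expect_error(scenario_preset("fig1_wellmixed", list(bogus_key = 1)),
               "unknown override")
})

test_that("every preset round-trips through YAML serialisation unchanged", {
  dir <- withr::local_tempdir()
  for (nm in preset_names()) {
    sp <- scenario_preset(nm)
    path <- file.path(dir, paste0(nm, ".yaml"))
    write_config(sp, path)
    back <- read_config(path)
    expect_equal(back, sp, tolerance = 1e-12, label = nm)
  }
})

test_that("checked-in preset configs match the preset builders", {
  dir <- system.file("scenarios", package = "mucosim")
  skip_if(dir == "" || !length(list.files(dir)), "no shipped scenario files")
  for (nm in preset_names()) {
    path <- file.path(dir, paste0(nm, ".yaml"))
    expect_true(file.exists(path), label = path)
    expect_equal(read_config(path), scenario_preset(nm), tolerance = 1e-12,
                 label = nm)
  }
})

test_that("prescribed profiles evaluate and average correctly", {
  prof <- list(kind = "exponential", value = 6e-4, lambda = 3)
  z <- c(0, 3, 9)
  expect_equal(profile_value(prof, z), 6e-4 * exp(-z / 3))
  # analytic height average over [0, H]
  H <- 40
  expect_equal(profile_mean(prof, H),
               6e-4 * 3 / H * (1 - exp(-H / 3)))
  expect_equal(profile_mean(list(kind = "constant", value = 2), 10), 2)
})

test_that("the fig5 control flattens profiles but keeps total amounts", {
  grad <- scenario_preset("fig5_prescribed")
  ctrl <- scenario_preset("fig5_prescribed", list(control = TRUE))
  H <- grad$domain$slough_height
  for (nm in names(grad$solutes)) {
    expect_equal(ctrl$solutes[[nm]]$prescribed$kind, "constant")
    expect_equal(profile_mean(ctrl$solutes[[nm]]$prescribed, H),
                 profile_mean(grad$solutes[[nm]]$prescribed, H))
  }
})
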