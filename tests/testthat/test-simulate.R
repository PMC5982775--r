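test_that("simulation is deterministic given the seed", {
  cfg <- simulation_config(seed = 99, n_families = 60)
  s1 <- simulate_families(cfg)
  s2 <- simulate_families(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  write_kincohort_table(s1$families, p1)
  write_kincohort_table(s2$families, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth, s2$truth)
  # and the global RNG stream is left untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_families(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("impossible ascertainment aborts with a message", {
  cfg <- simulation_config(seed = 1, n_families = 10,
                           F_breast_70 = c(carrier = 0, noncarrier = 0))
  expect_error(simulate_families(cfg), "acceptance rate")
})

test_that("probands are affected, genotyped, and families well formed", {
  sim <- small_registry()
  kc <- sim$families
  pb <- kc[kc$role == "proband", ]
  expect_true(all(!is.na(pb$age_breast_dx)))
  expect_true(all(pb$genotype != "untested"))
  fu <- kinpen:::derive_followup_table(pb, "breast")
  expect_true(all(fu$event == 1L))
  ft <- family_table(kc)
  expect_identical(nrow(ft), 300L)
  expect_true(all(table(kc$family_id[kc$role == "mother"]) == 1))
})

test_that("genotype masking hits the requested fraction", {
  sim <- simulate_families(simulation_config(seed = 7, n_families = 250,
                                             gamma = 1))
  kc <- sim$families
  rel <- kc$role != "proband"
  expect_true(all(kc$genotype[rel] != "untested"))

  m0 <- mask_genotypes(kc, 0, seed = 2)
  expect_true(all(m0$genotype[m0$role != "proband"] == "untested"))
  expect_true(all(m0$genotype[m0$role == "proband"] != "untested"))

  m1 <- mask_genotypes(kc, 1, seed = 2)
  expect_identical(m1$genotype, kc$genotype)

  m3 <- mask_genotypes(kc, 0.3, seed = 2)
  n <- sum(rel)
  frac <- sum(m3$genotype[rel] != "untested") / n
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("relative genotypes follow Mendelian conditionals", {
  # neutral hazards so ascertainment carries no genotype information at all
  cfg <- simulation_config(seed = 31, n_families = 900, gamma = 1, q = 0.15,
                           F_breast_70 = c(carrier = 0.3, noncarrier = 0.3),
                           F_ovarian_70 = c(carrier = 0, noncarrier = 0))
  sim <- simulate_families(cfg)
  kc <- sim$families
  model <- genotype_model(0.15, "BRCA1")

  # mothers are population founders here: genotype frequencies near HWE
  mothers <- kc[kc$role == "mother", ]
  p_car <- 1 - (1 - 0.15)^2
  obs <- mean(mothers$genotype == "carrier")
  expect_lt(abs(obs - p_car), 3 * sqrt(p_car * (1 - p_car) / nrow(mothers)))

  # relative carrier fraction given proband status matches the enumeration,
  # per relation
  for (ps in c("BRCA1", "negative")) {
    pstat <- if (ps == "BRCA1") "carrier" else "noncarrier"
    for (rl in c("mother", "sister", "daughter")) {
      sub <- kc[kc$proband_gene_status == ps & kc$role == rl, ]
      if (nrow(sub) < 30) next
      expected <- relative_carrier_prob(pstat, rl, model)
      obs <- mean(sub$genotype == "carrier")
      tol <- 3 * sqrt(expected * (1 - expected) / nrow(sub)) + 1e-9
      expect_lt(abs(obs - expected), tol)
    }
  }
})

test_that("ascertainment enriches carriers among probands", {
  sim <- small_registry()   # carriers at markedly higher breast risk
  kc <- sim$families
  frac_carrier_probands <-
    mean(kc$proband_gene_status[kc$role == "proband"] == "BRCA1")
  p_pop <- 1 - (1 - 0.02)^2
  expect_gt(frac_carrier_probands, p_pop)
})

test_that("the YAML scenario file reproduces the programmatic config", {
  path <- system.file("extdata", "default_scenario.yaml", package = "kinpen")
  cfg <- read_simulation_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$q, 0.02)
  expect_equal(cfg$n_families, 1600L)
  expect_equal(cfg$gamma, 0.3)
  expect_equal(unname(cfg$F_breast_70), c(0.50, 0.16))
  # the calibrated true hazards reproduce the target cumulative risks
  cv <- cumulative_risk(cfg$hazards_breast, 20, 70, at = 70)
  expect_equal(cv$F_carrier, 0.50, tolerance = 1e-10)
  expect_equal(cv$F_noncarrier, 0.16, tolerance = 1e-10)

  # a seedless config is refused
  tmp <- tempfile(fileext = ".yaml")
  writeLines("q: 0.02\nn_families: 10", tmp)
  expect_error(read_simulation_config(tmp), "seed")
})
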