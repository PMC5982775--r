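test_that("marginal log-likelihood evaluates the mixture formula", {
  hz <- hazard_table(c(50, 60), c(0.2, 0.3), c(0.1, 0.1))

  # censored individual with zero hazards has survival probability 1
  hz0 <- hazard_table(c(50, 60), c(0, 0), c(0, 0))
  fu <- data.frame(time = 55, event = 0L)
  expect_identical(marginal_loglik(fu, 0.5, hz0), 0)

  # degenerate mixture: p = 1, event at the only age seen
  hz1 <- hazard_table(50, 0.2, 0.05)
  fu <- data.frame(time = 50, event = 1L)
  expect_equal(marginal_loglik(fu, 1, hz1), log(0.2))

  # two relatives, hand-computed:
  #   A: event at 50, p = 0.5 -> 0.5*0.2 + 0.5*0.1 = 0.15
  #   B: censored at 60 (on grid), p = 0.5 ->
  #      0.5*(0.8*0.7) + 0.5*(0.9*0.9) = 0.685
  fu <- data.frame(time = c(50, 60), event = c(1L, 0L))
  expect_equal(marginal_loglik(fu, c(0.5, 0.5), hz),
               log(0.15) + log(0.685))

  # an event age missing from the grid is an error
  fu <- data.frame(time = 55, event = 1L)
  expect_error(marginal_loglik(fu, 0.5, hz), "absent from the hazard grid")
  # weight/record length mismatch is an error
  expect_error(marginal_loglik(fu, c(0.5, 0.5), hz), "one weight per")
})

test_that("fully genotyped data collapse to stratified actuarial hazards", {
  set.seed(11)
  n <- 300
  carrier <- runif(n) < 0.3
  time <- sample(40:70, n, replace = TRUE)
  event <- as.integer(runif(n) < ifelse(carrier, 0.5, 0.2))
  fit <- kinpen:::.fit_mml_core(time, event, as.numeric(carrier),
                                tol = 1e-10, max_iter = 5000)
  oracle <- oracle_actuarial(time, event, carrier)
  expect_equal(fit$hazards$grid, oracle$grid)
  expect_equal(fit$hazards$lambda_carrier, oracle$lambda_carrier,
               tolerance = 1e-8)
  expect_equal(fit$hazards$lambda_noncarrier, oracle$lambda_noncarrier,
               tolerance = 1e-8)
})

test_that("a class without events gets zero hazards", {
  time <- c(45, 50, 55, 60)
  event <- c(0L, 1L, 1L, 0L)
  p <- c(1, 0, 0, 1)       # events only among genotyped non-carriers
  fit <- suppressWarnings(
    kinpen:::.fit_mml_core(time, event, p, 1e-10, 1000))
  expect_true(all(fit$hazards$lambda_carrier == 0))
  expect_true(any(fit$hazards$lambda_noncarrier > 0))
})

test_that("EM matches direct maximization on mixed-weight toys", {
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(6:10, 1)
    time <- sample(c(40, 50, 60, 65), n, replace = TRUE)
    event <- as.integer(runif(n) < 0.5)
    if (sum(event) == 0) event[1] <- 1L
    p <- round(runif(n), 2)
    fit <- kinpen:::.fit_mml_core(time, event, p, 1e-12, 1e5)
    grid <- fit$hazards$grid
    K <- length(grid)
    fu <- data.frame(time = time, event = event)
    nll <- function(x) {
      lam <- stats::plogis(x)
      -marginal_loglik(fu, p, hazard_table(grid, lam[1:K], lam[K + 1:K]))
    }
    opt <- stats::optim(rep(stats::qlogis(0.3), 2 * K), nll,
                        method = "BFGS",
                        control = list(maxit = 10000, reltol = 1e-14))
    expect_gte(fit$loglik, -opt$value - 1e-6)
    # the EM solution is also a (local) maximum of the marginal likelihood
    expect_equal(
      marginal_loglik(fu, p, fit$hazards), fit$loglik, tolerance = 1e-8)
  }
})

test_that("the EM log-likelihood never decreases", {
  set.seed(31)
  # toys and a realistic registry fit
  for (rep in 1:3) {
    n <- 50
    time <- sample(35:70, n, replace = TRUE)
    event <- as.integer(runif(n) < 0.3)
    if (sum(event) == 0) event[1] <- 1L
    p <- runif(n)
    fit <- kinpen:::.fit_mml_core(time, event, p, 1e-10, 5000)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  }
  sim <- small_registry()
  em <- suppressMessages(fit_mml_em(
    sim$families, "breast", genotype_model(0.02, "BRCA1"),
    estimator_config(B = 0)))
  expect_true(all(diff(em$loglik_trace) >= -1e-9))
  expect_true(em$converged)
  expect_true(all(em$posterior >= 0 & em$posterior <= 1))
})

test_that("cumulative risk follows the product-limit identity", {
  hz <- hazard_table(21:70, rep(0.01, 50), rep(0, 50))
  cv <- cumulative_risk(hz, 20, 70, at = c(40, 70))
  expect_equal(cv$F_carrier[2], 1 - 0.99^50)
  expect_equal(cv$F_carrier[1], 1 - 0.99^20)
  expect_equal(cv$F_noncarrier, c(0, 0))

  # all-zero hazards give zero risk
  hz0 <- hazard_table(c(30, 40), c(0, 0), c(0, 0))
  expect_true(all(cumulative_risk(hz0, 20, 70)$F_carrier == 0))

  # a hazard of 1 absorbs
  hz1 <- hazard_table(c(30, 40), c(0.2, 1), c(0, 0))
  cv <- cumulative_risk(hz1, 20, 70, at = c(40, 50, 70))
  expect_equal(cv$F_carrier, c(1, 1, 1))

  # risk accrues only after the origin age
  hzo <- hazard_table(c(30, 40), c(0.5, 0.1), c(0, 0))
  cv <- cumulative_risk(hzo, 35, 70, at = 70)
  expect_equal(cv$F_carrier, 0.1)

  # monotone and bounded on a fitted object
  sim <- small_registry()
  em <- suppressMessages(fit_mml_em(
    sim$families, "breast", genotype_model(0.02, "BRCA1"),
    estimator_config(B = 0)))
  cv <- cumulative_risk(em$hazards, 20, 70)
  for (col in c("F_carrier", "F_noncarrier")) {
    expect_true(all(diff(cv[[col]]) >= 0))
    expect_true(all(cv[[col]] >= 0 & cv[[col]] <= 1))
  }
  expect_error(cumulative_risk(em$hazards, 70, 20), "from_age")
})

test_that("the family bootstrap is reproducible and honest about width", {
  sim <- small_registry()
  kc <- sim$families
  cfg <- estimator_config(B = 25, seed = 77)
  f1 <- suppressMessages(suppressWarnings(fit_penetrance(kc, "breast", cfg,
                                                         q = 0.02)))
  f2 <- suppressMessages(suppressWarnings(fit_penetrance(kc, "breast", cfg,
                                                         q = 0.02)))
  expect_identical(f1$curve, f2$curve)
  expect_true(all(f1$curve$ci_low_carrier <= f1$curve$F_carrier + 1e-12))
  expect_true(all(f1$curve$ci_high_carrier >= f1$curve$F_carrier - 1e-12))

  # identical families give a zero-width interval at the point estimate
  rows <- unlist(lapply(1:5, function(i) {
    fid <- paste0("C", i)
    list(
      kc_row(fid, paste0(fid, "_P"), "proband", "BRCA1", "carrier",
             age_breast_dx = 40, age_last = 50),
      kc_row(fid, paste0(fid, "_M"), "mother", "none", "untested",
             age_breast_dx = 55, age_last = 70),
      kc_row(fid, paste0(fid, "_S"), "sister", "BRCA1", "carrier",
             age_breast_dx = 45, age_last = 52),
      kc_row(fid, paste0(fid, "_S2"), "sister", "none", "untested",
             age_last = 60)
    )
  }), recursive = FALSE)
  kc5 <- read_kincohort_table(write_kc_file(rows), "BRCA1")
  f <- fit_penetrance(
    kc5, "breast",
    estimator_config(B = 10, seed = 5, min_events_ci = 0), q = 0.02)
  expect_equal(f$curve$ci_low_carrier, f$curve$F_carrier)
  expect_equal(f$curve$ci_high_carrier, f$curve$F_carrier)
})

test_that("the ovarian outcome reports from age 30 with its own censoring", {
  sim <- small_registry()
  f <- suppressMessages(fit_penetrance(
    sim$families, "ovarian", estimator_config(B = 20, seed = 9)))
  expect_identical(f$age_origin, 30)
  expect_identical(f$curve$age, c(50, 60, 70))
  for (col in c("F_carrier", "F_noncarrier")) {
    expect_true(all(diff(f$curve[[col]]) >= 0))
    expect_true(all(f$curve[[col]] >= 0 & f$curve[[col]] <= 1))
  }
  # far fewer ovarian than breast events in the same registry
  fb <- suppressMessages(fit_penetrance(
    sim$families, "breast", estimator_config(B = 0)))
  expect_lt(f$n_events, fb$n_events / 5)
})

test_that("sparse strata suppress the confidence band", {
  sim <- small_registry()
  cfg <- estimator_config(B = 10, seed = 3, min_events_ci = 1e6)
  expect_warning(
    f <- suppressMessages(fit_penetrance(sim$families, "breast", cfg,
                                         q = 0.02)),
    "confidence band suppressed")
  expect_true(all(is.na(f$curve$ci_low_carrier)))
})
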