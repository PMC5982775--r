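#' Discrete-time hazard table for carriers and non-carriers
#'
#' The estimator's parameter set: hazards on a grid of ages (the distinct
#' observed event ages), one hazard vector per genotype class. A hazard
#' `lambda(t_k)` is the probability of onset at age `t_k` given being
#' disease-free just before `t_k`.
#'
#' @param grid strictly increasing ages.
#' @param lambda_carrier,lambda_noncarrier hazards in `[0, 1]`, same length
#'   as `grid`.
#' @return object of class `hazard_table`.
#' @export
hazard_table <- function(grid, lambda_carrier, lambda_noncarrier) {
  grid <- as.numeric(grid)
  if (length(grid) && any(diff(grid) <= 0)) {
    stop_kinpen("grid ages must be strictly increasing")
  }
  if (length(lambda_carrier) != length(grid) ||
      length(lambda_noncarrier) != length(grid)) {
    stop_kinpen("hazard vectors must match the grid length")
  }
  lam <- c(lambda_carrier, lambda_noncarrier)
  if (length(lam) && (any(lam < 0) || any(lam > 1) || anyNA(lam))) {
    stop_kinpen("hazards must lie in [0, 1]")
  }
  structure(
    list(grid = grid,
         lambda_carrier = as.numeric(lambda_carrier),
         lambda_noncarrier = as.numeric(lambda_noncarrier)),
    class = "hazard_table"
  )
}

#' @export
print.hazard_table <- function(x, ...) {
  cat("hazard_table on", length(x$grid), "ages",
      if (length(x$grid)) paste0("(", min(x$grid), "-", max(x$grid), ")"),
      "\n")
  invisible(x)
}

#' Estimator configuration
#'
#' @param tol convergence tolerance on the marginal log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param B bootstrap replicates (0 skips the bootstrap).
#' @param seed RNG seed for the bootstrap; required when `B > 0`.
#' @param age_origin reporting start age; defaults to 20 for breast and 30
#'   for ovarian outcomes when left `NULL`.
#' @param report_ages ages at which cumulative risk is reported; default
#'   `c(40, 50, 60, 70)` for breast and `c(50, 60, 70)` for ovarian.
#' @param min_events_ci minimum expected number of events in a genotype
#'   class for its confidence band to be reported; sparse strata return
#'   point estimates only.
#' @param transmission `"exact"` relation-specific Mendelian probabilities
#'   or the classical `"half"` first-degree approximation.
#' @return object of class `estimator_config`.
#' @export
estimator_config <- function(tol = 1e-8, max_iter = 5000, B = 1000,
                             seed = NULL, age_origin = NULL,
                             report_ages = NULL, min_events_ci = 10,
                             transmission = c("exact", "half")) {
  transmission <- match.arg(transmission)
  if (!is.numeric(tol) || tol <= 0) stop_kinpen("tol must be positive")
  if (B < 0) stop_kinpen("B must be nonnegative")
  if (B > 0 && is.null(seed)) stop_kinpen("a seed is required when B > 0")
  structure(
    list(tol = tol, max_iter = as.integer(max_iter), B = as.integer(B),
         seed = seed, age_origin = age_origin, report_ages = report_ages,
         min_events_ci = min_events_ci, transmission = transmission),
    class = "estimator_config"
  )
}

.default_origin <- function(outcome) if (outcome == "breast") 20 else 30
.default_report_ages <- function(outcome) {
  if (outcome == "breast") c(40, 50, 60, 70) else c(50, 60, 70)
}

# Index a set of follow-up times against a hazard grid. pos = number of grid
# ages <= t; j = exact grid position (NA when t is off-grid).
.mml_index <- function(time, event, grid) {
  j <- match(time, grid)
  in_grid <- !is.na(j)
  if (any(event == 1 & !in_grid)) {
    stop_kinpen("event age absent from the hazard grid")
  }
  pos <- findInterval(time, grid)
  list(pos = pos, j = j, in_grid = in_grid, nlt = pos - in_grid,
       event = as.integer(event))
}

# Per-individual likelihood under one hazard vector:
#   L(t, d) = lambda(t)^d * prod_{t_k < t} (1 - lambda(t_k))
#             * (1 - lambda(t))^{(1-d) [t in grid]}
.mml_class_lik <- function(idx, lambda) {
  logcum <- c(0, cumsum(log1p(-lambda)))
  logL <- logcum[idx$nlt + 1L]
  ev <- idx$event == 1L
  logL[ev] <- logL[ev] + log(lambda[idx$j[ev]])
  cg <- !ev & idx$in_grid
  logL[cg] <- logL[cg] + log1p(-lambda[idx$j[cg]])
  exp(logL)
}

#' Marginal log-likelihood of follow-up data under mixed genotypes
#'
#' Each relative contributes
#' `log(p_i * L1(t_i, d_i) + (1 - p_i) * L0(t_i, d_i))`, where `L_g` is the
#' discrete-time survival likelihood under the class-`g` hazards and `p_i`
#' her carrier mixing weight.
#'
#' @param followups data.frame with columns `time` and `event` (as from
#'   [derive_followup()]).
#' @param weights numeric vector of carrier probabilities, one per row of
#'   `followups`.
#' @param hazards a [hazard_table()]; every event age must be on its grid.
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(followups, weights, hazards) {
  stopifnot(inherits(hazards, "hazard_table"))
  if (length(weights) != nrow(followups)) {
    stop_kinpen("one weight per follow-up record is required")
  }
  idx <- .mml_index(followups$time, followups$event, hazards$grid)
  L1 <- .mml_class_lik(idx, hazards$lambda_carrier)
  L0 <- .mml_class_lik(idx, hazards$lambda_noncarrier)
  sum(log(weights * L1 + (1 - weights) * L0))
}

# EM fit on prepared vectors; shared by the user-facing fit and the
# bootstrap loop. Grid = distinct event ages in `time`. The iteration
# itself runs in compiled code.
.fit_mml_core <- function(time, event, p, tol, max_iter, warn = TRUE) {
  grid <- sort(unique(time[event == 1]))
  K <- length(grid)
  if (K == 0L) {
    return(list(
      hazards = hazard_table(numeric(0), numeric(0), numeric(0)),
      posterior = p, loglik = 0, iterations = 0L, converged = TRUE,
      n_events = 0
    ))
  }
  idx <- .mml_index(time, event, grid)
  j0 <- ifelse(idx$in_grid, idx$j, 0L)
  fit <- .em_mml_fit_cpp(as.integer(idx$pos), as.integer(j0),
                         as.integer(idx$event), as.numeric(p),
                         K, tol, as.integer(max_iter))
  if (warn && fit$empty_risk) {
    warning("empty weighted risk set at some grid ages; hazards set to 0",
            call. = FALSE)
  }
  if (warn && !fit$converged) {
    warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  list(
    hazards = hazard_table(grid, fit$lambda_carrier, fit$lambda_noncarrier),
    posterior = fit$posterior,
    loglik = fit$loglik,
    iterations = fit$iterations,
    converged = fit$converged,
    loglik_trace = fit$trace,
    n_events = sum(event == 1)
  )
}

# Assemble follow-up times and mixing weights for a single-gene analysis.
# Families positive for the other gene are excluded (the analysis contrasts
# carrier-proband families with mutation-negative families).
.analysis_inputs <- function(kc, outcome, model, transmission) {
  gene <- model$gene
  other <- setdiff(c("BRCA1", "BRCA2"), gene)
  keep <- kc$proband_gene_status != other
  n_drop <- length(unique(kc$family_id[!keep]))
  if (n_drop > 0L) {
    message(n_drop, " ", other, "-positive families excluded from the ",
            gene, " analysis")
  }
  kc <- kc[keep, , drop = FALSE]
  rel <- kc[kc$role != "proband", , drop = FALSE]
  if (nrow(rel) == 0L) stop_kinpen("no relatives available for analysis")
  fu <- derive_followup_table(rel, outcome)
  p <- mixing_weight_table(rel, model, transmission)
  list(time = fu$time, event = fu$event, p = p,
       family_id = rel$family_id,
       families = unique(kc$family_id))
}

#' Fit carrier and non-carrier hazards by EM over the marginal likelihood
#'
#' Fits nonparametric discrete-time hazards for the carrier and non-carrier
#' classes from the follow-up of first-degree relatives, treating each
#' relative's genotype as a two-point mixture with her Mendelian mixing
#' weight. The E-step computes the posterior carrier probability of each
#' relative from her full follow-up; the M-step is a weighted
#' occurrence/exposure update on the grid of distinct event ages. The
#' marginal log-likelihood is nondecreasing across iterations.
#'
#' @param kc a `kin_cohort` object from [read_kincohort_table()] or
#'   [simulate_families()]. Families positive for the gene not under
#'   analysis are excluded.
#' @param outcome `"breast"` or `"ovarian"`.
#' @param model a [genotype_model()] for the gene under analysis.
#' @param config an [estimator_config()].
#' @return object of class `kinpen_em`: hazards ([hazard_table()]),
#'   `posterior` carrier probabilities, `loglik`, `iterations`, `converged`.
#' @export
fit_mml_em <- function(kc, outcome = c("breast", "ovarian"), model,
                       config = estimator_config(B = 0)) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(model, "genotype_model"),
            inherits(config, "estimator_config"))
  inp <- .analysis_inputs(kc, outcome, model, config$transmission)
  if (sum(inp$event) == 0L) {
    stop_kinpen("no ", outcome, " events among relatives; nothing to fit")
  }
  fit <- .fit_mml_core(inp$time, inp$event, inp$p,
                       tol = config$tol, max_iter = config$max_iter)
  structure(
    c(fit, list(outcome = outcome, gene = model$gene, q = model$q,
                n_relatives = length(inp$time))),
    class = "kinpen_em"
  )
}

#' @export
print.kinpen_em <- function(x, ...) {
  cat("kin-cohort EM fit:", x$gene, x$outcome, "\n")
  cat("  relatives:", x$n_relatives, " events:", x$n_events,
      " grid ages:", length(x$hazards$grid), "\n")
  cat("  log-likelihood:", format(x$loglik), "after", x$iterations,
      "iterations", if (!x$converged) "(NOT converged)", "\n")
  invisible(x)
}

#' Cumulative risk implied by discrete-time hazards
#'
#' `F(t) = 1 - prod_{from_age < t_k <= t} (1 - lambda(t_k))` for each
#' genotype class: the probability of onset by age `t` given freedom from
#' disease at `from_age`.
#'
#' @param hazards a [hazard_table()].
#' @param from_age start of the reporting interval (risk accrues strictly
#'   after this age).
#' @param to_age end of the reporting interval.
#' @param at ages at which to evaluate `F`; default the grid ages within
#'   `(from_age, to_age]` plus `to_age`.
#' @return object of class `penetrance_curve`: data.frame with columns
#'   `age`, `F_carrier`, `F_noncarrier`.
#' @export
cumulative_risk <- function(hazards, from_age, to_age, at = NULL) {
  stopifnot(inherits(hazards, "hazard_table"))
  if (from_age >= to_age) stop_kinpen("from_age must be below to_age")
  if (is.null(at)) {
    at <- sort(unique(c(
      hazards$grid[hazards$grid > from_age & hazards$grid <= to_age],
      to_age
    )))
  }
  Fofage <- function(lambda) {
    use <- hazards$grid > from_age
    logS <- c(0, cumsum(log1p(-lambda[use])))
    n_le <- findInterval(at, hazards$grid[use])
    1 - exp(logS[n_le + 1L])
  }
  structure(
    data.frame(
      age = at,
      F_carrier = Fofage(hazards$lambda_carrier),
      F_noncarrier = Fofage(hazards$lambda_noncarrier)
    ),
    from_age = from_age, to_age = to_age,
    class = c("penetrance_curve", "data.frame")
  )
}

#' Penetrance with family-bootstrap confidence band
#'
#' Fits the marginal-likelihood estimator, then resamples whole families
#' with replacement `B` times, refits on each resample, and reports
#' percentile 2.5/97.5 bounds of the cumulative risk at the report ages.
#' Families are the resampling unit because relatives within a family share
#' a proband and are not independent. A replicate without any event is
#' recorded as a zero penetrance curve and counted. A genotype class whose
#' expected number of events falls below `config$min_events_ci` reports the
#' point estimate without a confidence band.
#'
#' @inheritParams fit_mml_em
#' @return object of class `penetrance_fit`; see [fit_penetrance()].
#' @export
bootstrap_ci <- function(kc, outcome = c("breast", "ovarian"), model,
                         config = estimator_config()) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(model, "genotype_model"),
            inherits(config, "estimator_config"))
  origin <- config$age_origin %||% .default_origin(outcome)
  report_ages <- config$report_ages %||% .default_report_ages(outcome)

  inp <- .analysis_inputs(kc, outcome, model, config$transmission)
  if (sum(inp$event) == 0L) {
    stop_kinpen("no ", outcome, " events among relatives; nothing to fit")
  }
  fit <- .fit_mml_core(inp$time, inp$event, inp$p,
                       tol = config$tol, max_iter = config$max_iter)
  curve <- cumulative_risk(fit$hazards, origin, max(report_ages),
                           at = report_ages)

  # expected events per class under the fitted posterior
  ev <- inp$event == 1
  n_events_carrier <- sum(fit$posterior[ev])
  n_events_noncarrier <- sum((1 - fit$posterior)[ev])

  boot <- NULL
  n_zero <- 0L
  if (config$B > 0) {
    # all analysed families are resampling units, including any that
    # contribute no relative follow-up
    fam_rows <- split(seq_along(inp$time),
                      factor(inp$family_id, levels = inp$families))
    n_fam <- length(fam_rows)
    F1 <- matrix(NA_real_, config$B, length(report_ages))
    F0 <- matrix(NA_real_, config$B, length(report_ages))
    draws <- with_seed(config$seed, {
      matrix(sample.int(n_fam, n_fam * config$B, replace = TRUE),
             nrow = config$B)
    })
    for (b in seq_len(config$B)) {
      rows <- unlist(fam_rows[draws[b, ]], use.names = FALSE)
      tb <- inp$time[rows]; eb <- inp$event[rows]; pb <- inp$p[rows]
      if (sum(eb) == 0L) {
        n_zero <- n_zero + 1L
        F1[b, ] <- 0; F0[b, ] <- 0
        next
      }
      fb <- .fit_mml_core(tb, eb, pb, tol = config$tol,
                          max_iter = config$max_iter, warn = FALSE)
      cb <- cumulative_risk(fb$hazards, origin, max(report_ages),
                            at = report_ages)
      F1[b, ] <- cb$F_carrier
      F0[b, ] <- cb$F_noncarrier
    }
    qs <- function(m) apply(m, 2L, stats::quantile,
                            probs = c(0.025, 0.975), names = FALSE)
    q1 <- qs(F1); q0 <- qs(F0)
    curve$ci_low_carrier <- q1[1L, ]
    curve$ci_high_carrier <- q1[2L, ]
    curve$ci_low_noncarrier <- q0[1L, ]
    curve$ci_high_noncarrier <- q0[2L, ]
    if (n_events_carrier < config$min_events_ci) {
      curve$ci_low_carrier <- curve$ci_high_carrier <- NA_real_
      warning("fewer than ", config$min_events_ci, " expected carrier ",
              "events; carrier confidence band suppressed", call. = FALSE)
    }
    if (n_events_noncarrier < config$min_events_ci) {
      curve$ci_low_noncarrier <- curve$ci_high_noncarrier <- NA_real_
      warning("fewer than ", config$min_events_ci, " expected non-carrier ",
              "events; non-carrier confidence band suppressed",
              call. = FALSE)
    }
    boot <- list(B = config$B, seed = config$seed,
                 n_zero_event_replicates = n_zero,
                 F_carrier = F1, F_noncarrier = F0)
  }

  if (any(curve$F_carrier < curve$F_noncarrier)) {
    warning("estimated carrier penetrance crosses below non-carrier ",
            "penetrance at some report ages", call. = FALSE)
  }

  structure(
    list(curve = curve, hazards = fit$hazards, loglik = fit$loglik,
         iterations = fit$iterations, converged = fit$converged,
         posterior = fit$posterior,
         n_relatives = length(inp$time), n_events = fit$n_events,
         n_events_carrier = n_events_carrier,
         n_events_noncarrier = n_events_noncarrier,
         gene = model$gene, outcome = outcome, q = model$q,
         age_origin = origin, report_ages = report_ages,
         boot = boot, config = config),
    class = "penetrance_fit"
  )
}

#' Estimate age-specific penetrance from a kin-cohort registry
#'
#' High-level wrapper: estimates the mutant allele frequency from the
#' probands (half the proband carrier frequency), builds the genotype
#' model, and runs the marginal-likelihood estimator with family-bootstrap
#' confidence intervals for the gene the cohort was read with.
#'
#' @param kc a `kin_cohort` object.
#' @param outcome `"breast"` or `"ovarian"`.
#' @param config an [estimator_config()].
#' @param q optional allele frequency overriding the proband-based estimate.
#' @return object of class `penetrance_fit` whose `curve` element holds the
#'   cumulative risk (and bootstrap bounds when `B > 0`) at the report ages.
#' @export
fit_penetrance <- function(kc, outcome = c("breast", "ovarian"),
                           config = estimator_config(), q = NULL) {
  outcome <- match.arg(outcome)
  gene <- attr(kc, "gene")
  if (is.null(gene)) stop_kinpen("kc must be a kin_cohort with a gene attribute")
  if (is.null(q)) q <- estimate_allele_frequency(kc, gene)
  if (q <= 0 || q >= 1) {
    stop_kinpen("estimated allele frequency ", format(q),
                " is degenerate; supply q explicitly")
  }
  model <- genotype_model(q, gene)
  bootstrap_ci(kc, outcome, model, config)
}

#' @export
print.penetrance_fit <- function(x, digits = 1, ...) {
  cat("Age-specific penetrance of", x$outcome, "cancer --", x$gene,
      "(x100 scale)\n")
  cat("  allele frequency q =", format(x$q, digits = 4),
      "; relatives =", x$n_relatives, "; events =", x$n_events, "\n")
  cv <- x$curve
  has_ci <- "ci_low_carrier" %in% names(cv)
  fmt <- function(f, lo, hi) {
    if (has_ci && !all(is.na(lo))) {
      sprintf("%5.1f (%.1f-%.1f)", 100 * f, 100 * lo, 100 * hi)
    } else {
      sprintf("%5.1f", 100 * f)
    }
  }
  for (i in seq_len(nrow(cv))) {
    cat(sprintf(
      "  %d-%d years: carrier %s | non-carrier %s\n",
      x$age_origin, cv$age[i],
      fmt(cv$F_carrier[i],
          if (has_ci) cv$ci_low_carrier[i] else NA,
          if (has_ci) cv$ci_high_carrier[i] else NA),
      fmt(cv$F_noncarrier[i],
          if (has_ci) cv$ci_low_noncarrier[i] else NA,
          if (has_ci) cv$ci_high_noncarrier[i] else NA)
    ))
  }
  if (!is.null(x$boot)) {
    cat("  bootstrap: B =", x$boot$B, "; seed =", x$boot$seed,
        "; zero-event replicates =", x$boot$n_zero_event_replicates, "\n")
  }
  invisible(x)
}
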