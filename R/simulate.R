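#' Configuration for the synthetic family-registry generator
#'
#' Describes a registry of families ascertained through an affected,
#' genotyped proband, in the image of a hereditary breast-ovarian cancer
#' registry: every family has a mother, the proband, a number of sisters and
#' daughters drawn from distributions matching the registry's per-family
#' medians (sisters median 2, IQR 1-3; daughters median 0, IQR 0-1), partial
#' relative genotyping, and censoring by competing cancer, risk-reducing
#' surgery, last follow-up, or death.
#'
#' True onset-age distributions are discrete yearly hazards per genotype
#' class. The defaults place a constant yearly hazard on ages 21-90 (breast,
#' risk accruing from age 20) and 31-90 (ovarian, from 30) calibrated so
#' that the cumulative risk by age 70 is `F_breast_70 = (0.50, 0.16)` and
#' `F_ovarian_70 = (0.215, 0.014)` for carriers and non-carriers.
#'
#' @param q true mutant allele frequency, in `(0, 1)`.
#' @param n_families number of ascertained families to emit.
#' @param gamma probability that an eligible relative is genotyped.
#' @param seed RNG seed (mandatory).
#' @param gene gene label written into the table.
#' @param F_breast_70,F_ovarian_70 true cumulative risks by age 70 (carrier,
#'   non-carrier), used to calibrate the constant yearly hazards.
#' @param sisters_dist,daughters_dist probability vectors over counts
#'   `0, 1, 2, ...` of sisters and daughters per family.
#' @param p_rrso,p_rrm probabilities of risk-reducing surgery for a relative.
#' @param p_dead probability that the last age is a death rather than a
#'   last follow-up.
#' @param max_age oldest simulated age.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(q = 0.02, n_families = 1600, gamma = 0.3,
                              seed = NULL, gene = "BRCA1",
                              F_breast_70 = c(carrier = 0.50,
                                              noncarrier = 0.16),
                              F_ovarian_70 = c(carrier = 0.215,
                                               noncarrier = 0.014),
                              sisters_dist = c(0.10, 0.25, 0.30, 0.20,
                                               0.10, 0.05),
                              daughters_dist = c(0.60, 0.25, 0.15),
                              p_rrso = 0.03, p_rrm = 0.01, p_dead = 0.15,
                              max_age = 90) {
  if (is.null(seed)) stop_kinpen("a seed is mandatory for simulation")
  if (q <= 0 || q >= 1) stop_kinpen("q must lie strictly in (0, 1)")
  if (gamma < 0 || gamma > 1) stop_kinpen("gamma must lie in [0, 1]")
  calib <- function(F70, origin) {
    # constant yearly hazard on (origin, max_age] with F(70) = F70
    grid <- seq(origin + 1, max_age)
    lam <- 1 - (1 - F70)^(1 / (70 - origin))
    hazard_table(grid, rep(lam[1L], length(grid)), rep(lam[2L], length(grid)))
  }
  structure(
    list(q = q, n_families = as.integer(n_families), gamma = gamma,
         seed = seed, gene = gene,
         hazards_breast = calib(F_breast_70, 20),
         hazards_ovarian = calib(F_ovarian_70, 30),
         F_breast_70 = F_breast_70, F_ovarian_70 = F_ovarian_70,
         sisters_dist = sisters_dist, daughters_dist = daughters_dist,
         p_rrso = p_rrso, p_rrm = p_rrm, p_dead = p_dead,
         max_age = max_age),
    class = "simulation_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simulation_config()]; `F_breast_70` and
#' `F_ovarian_70` are two-element lists `(carrier, noncarrier)`. The seed
#' must be present.
#'
#' @param path YAML file path.
#' @return object of class `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop_kinpen("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop_kinpen("simulation config must set a seed")
  args <- list(
    q = y$q %||% 0.02,
    n_families = y$n_families %||% 1600,
    gamma = y$gamma %||% 0.3,
    seed = y$seed,
    gene = y$gene %||% "BRCA1"
  )
  if (!is.null(y$F_breast_70)) args$F_breast_70 <- unlist(y$F_breast_70)
  if (!is.null(y$F_ovarian_70)) args$F_ovarian_70 <- unlist(y$F_ovarian_70)
  for (k in c("sisters_dist", "daughters_dist", "p_rrso", "p_rrm", "p_dead",
              "max_age")) {
    if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
  }
  do.call(simulation_config, args)
}

# Sample onset ages from a discrete yearly hazard vector; Inf = never.
# u ~ U(0,1) vectorised over individuals.
.sample_onset <- function(n, hazards, lambda) {
  Fgrid <- 1 - cumprod(1 - lambda)
  u <- stats::runif(n)
  idx <- findInterval(u, c(0, Fgrid), left.open = TRUE)
  ifelse(idx > length(hazards$grid) | u > Fgrid[length(Fgrid)],
         Inf, hazards$grid[pmin(idx, length(hazards$grid))])
}

#' Simulate a kin-cohort registry with known truth
#'
#' Generates families under Hardy-Weinberg founder genotypes and Mendelian
#' transmission, draws each woman's breast and ovarian onset ages from her
#' genotype's discrete hazards, draws censoring (risk-reducing surgery, last
#' follow-up or death), and retains a family only when the proband is
#' affected with breast cancer before any censoring -- the registry's entry
#' route. Relatives are genotyped independently with probability `gamma`;
#' probands are always genotyped.
#'
#' The family contains a mother (a founder), the proband and her sisters
#' (children of two founders), and the proband's daughters (children of the
#' proband and a random Hardy-Weinberg mate).
#'
#' @param config a [simulation_config()].
#' @return list with `families` (a `kin_cohort` read for `config$gene`),
#'   `truth` (data.frame `family_id`, `person_id`, `true_carrier`),
#'   `true_hazards` (list of breast/ovarian [hazard_table()]s), and
#'   `n_attempted` (families generated before ascertainment).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, .simulate_families_impl(config))
}

.simulate_families_impl <- function(config) {
  q <- config$q
  target <- config$n_families
  rows <- vector("list", target)
  truth <- vector("list", target)
  accepted <- 0L
  attempted <- 0L
  fam_counter <- 0L

  # founders and mates carry mutant alleles at HWE frequencies
  draw_founder <- function(n) stats::rbinom(n, 2L, q)
  transmit <- function(gp, gm) {
    stats::rbinom(length(gp), 1L, gp / 2) + stats::rbinom(length(gm), 1L, gm / 2)
  }

  while (accepted < target) {
    attempted <- attempted + 1L
    if (attempted > 1000L && accepted / attempted < 1e-4) {
      stop_kinpen("ascertainment acceptance rate below 1e-4; check the ",
                  "true hazards and censoring law")
    }
    n_sis <- sample.int(length(config$sisters_dist), 1L,
                        prob = config$sisters_dist) - 1L
    n_dau <- sample.int(length(config$daughters_dist), 1L,
                        prob = config$daughters_dist) - 1L

    father <- draw_founder(1L)
    mother <- draw_founder(1L)
    kids <- transmit(rep(father, n_sis + 1L), rep(mother, n_sis + 1L))
    proband_g <- kids[1L]
    sisters_g <- kids[-1L]
    daughters_g <- if (n_dau > 0L) {
      transmit(rep(proband_g, n_dau), draw_founder(n_dau))
    } else integer(0)

    role <- c("proband", "mother", rep("sister", n_sis),
              rep("daughter", n_dau))
    geno <- c(proband_g, mother, sisters_g, daughters_g)
    n <- length(role)
    carrier <- geno >= 1L

    onset_b <- ifelse(
      carrier,
      .sample_onset(n, config$hazards_breast,
                    config$hazards_breast$lambda_carrier),
      .sample_onset(n, config$hazards_breast,
                    config$hazards_breast$lambda_noncarrier)
    )
    onset_o <- ifelse(
      carrier,
      .sample_onset(n, config$hazards_ovarian,
                    config$hazards_ovarian$lambda_carrier),
      .sample_onset(n, config$hazards_ovarian,
                    config$hazards_ovarian$lambda_noncarrier)
    )

    # censoring: current age at last contact by generation, plus rare
    # risk-reducing surgeries
    age_last <- round(c(
      stats::rnorm(1L, 50, 10),                   # proband
      stats::rnorm(1L, 75, 8),                    # mother
      stats::rnorm(n_sis, 50, 12),                # sisters
      stats::rnorm(n_dau, 30, 8)                  # daughters
    ))
    age_last <- pmin(pmax(age_last, 18), config$max_age)
    rrso <- ifelse(stats::runif(n) < config$p_rrso,
                   round(stats::runif(n, 35, 60)), Inf)
    rrm <- ifelse(stats::runif(n) < config$p_rrm,
                  round(stats::runif(n, 30, 55)), Inf)
    dead <- stats::runif(n) < config$p_dead

    # observation ends at last contact; events/surgeries after it are unseen
    obs_b <- ifelse(onset_b <= pmin(age_last, onset_o, rrso, rrm),
                    onset_b, NA_real_)
    obs_o <- ifelse(onset_o <= pmin(age_last, rrso), onset_o, NA_real_)
    obs_rrso <- ifelse(rrso <= age_last, rrso, NA_real_)
    obs_rrm <- ifelse(rrm <= age_last, rrm, NA_real_)

    # ascertainment: proband affected with breast cancer and genotyped
    if (is.na(obs_b[1L])) next

    accepted <- accepted + 1L
    fam_counter <- fam_counter + 1L
    fid <- sprintf("F%05d", fam_counter)
    pid <- sprintf("%s_P%02d", fid, seq_len(n))

    genotyped <- c(TRUE, stats::runif(n - 1L) < config$gamma)
    gt_token <- ifelse(genotyped,
                       ifelse(carrier, "carrier", "noncarrier"),
                       "untested")
    gene_token <- ifelse(genotyped & carrier, config$gene,
                         ifelse(genotyped, "BRCA1/2", "none"))

    rows[[accepted]] <- data.frame(
      family_id = fid,
      person_id = pid,
      role = role,
      gene = gene_token,
      genotype = gt_token,
      age_breast_dx = obs_b,
      age_ovarian_dx = obs_o,
      age_rrso = obs_rrso,
      age_rrm = obs_rrm,
      age_last = age_last,
      vital = ifelse(dead, "dead", "alive"),
      stringsAsFactors = FALSE
    )
    truth[[accepted]] <- data.frame(
      family_id = fid, person_id = pid, true_carrier = carrier,
      stringsAsFactors = FALSE
    )
  }

  tab <- do.call(rbind, rows)
  # the ascertainment condition guarantees usable follow-up for everyone
  kc <- suppressMessages(as_kin_cohort(
    data.frame(lapply(tab, as.character), stringsAsFactors = FALSE),
    gene = config$gene
  ))
  list(
    families = kc,
    truth = do.call(rbind, truth),
    true_hazards = list(breast = config$hazards_breast,
                        ovarian = config$hazards_ovarian),
    n_attempted = attempted
  )
}

#' Mask relative genotypes to emulate partial genotyping
#'
#' Sets the genotype of each non-selected relative to `untested`; each
#' relative is independently retained as genotyped with probability
#' `gamma`. Probands are never masked.
#'
#' @param kc a `kin_cohort` object.
#' @param gamma probability a relative keeps her genotype.
#' @param seed RNG seed.
#' @return the masked `kin_cohort`.
#' @export
mask_genotypes <- function(kc, gamma, seed) {
  if (gamma < 0 || gamma > 1) stop_kinpen("gamma must lie in [0, 1]")
  rel <- kc$role != "proband"
  keep <- with_seed(seed, stats::runif(nrow(kc)) < gamma)
  mask <- rel & !keep
  kc$genotype[mask] <- "untested"
  kc$gene[mask] <- "none"
  kc$carrier_status[mask] <- "untested"
  kc
}
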