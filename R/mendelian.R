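#' Genotype frequencies under Hardy-Weinberg equilibrium
#'
#' @param q mutant allele frequency in `[0, 1]`.
#' @return named numeric vector `(P_aa, P_Aa, P_AA)` of the frequencies of
#'   0, 1 and 2 mutant alleles; sums to 1.
#' @export
hwe_genotype_freqs <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    stop_kinpen("allele frequency q must be a single value in [0, 1]")
  }
  c(P_aa = (1 - q)^2, P_Aa = 2 * q * (1 - q), P_AA = q^2)
}

#' Genotype model for a dominant rare-mutation analysis
#'
#' A two-class dominant model: an individual is a carrier when she has at
#' least one mutant allele; heterozygotes and homozygotes are pooled, as is
#' standard for rare BRCA alleles.
#'
#' @param q mutant allele frequency, strictly in `(0, 1)`.
#' @param gene gene label.
#' @return object of class `genotype_model`.
#' @export
genotype_model <- function(q, gene = "BRCA1") {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop_kinpen("allele frequency q must lie strictly in (0, 1)")
  }
  structure(list(q = q, gene = gene), class = "genotype_model")
}

#' @export
print.genotype_model <- function(x, ...) {
  cat("genotype_model:", x$gene, " q =", format(x$q), "\n")
  invisible(x)
}

# P(child allele count = 0..2 | parent allele counts gp, gm): each parent
# transmits a mutant allele with probability (allele count)/2, independently.
.transmission_dist <- function(gp, gm) {
  a <- gp / 2
  b <- gm / 2
  c(`0` = (1 - a) * (1 - b), `1` = a * (1 - b) + (1 - a) * b, `2` = a * b)
}

# Joint distribution (3x3 matrix) of mutant-allele counts for a
# parent-offspring pair: parent is HWE, the other parent a random HWE mate.
.joint_parent_offspring <- function(q) {
  hw <- hwe_genotype_freqs(q)
  joint <- matrix(0, 3L, 3L, dimnames = list(parent = 0:2, child = 0:2))
  for (i in 0:2) {
    for (m in 0:2) {
      joint[i + 1L, ] <- joint[i + 1L, ] +
        hw[i + 1L] * hw[m + 1L] * .transmission_dist(i, m)
    }
  }
  joint
}

# Joint distribution of mutant-allele counts for two full siblings: both
# parents HWE, transmissions independent given parents.
.joint_siblings <- function(q) {
  hw <- hwe_genotype_freqs(q)
  joint <- matrix(0, 3L, 3L, dimnames = list(sib1 = 0:2, sib2 = 0:2))
  for (f in 0:2) {
    for (m in 0:2) {
      td <- .transmission_dist(f, m)
      joint <- joint + hw[f + 1L] * hw[m + 1L] * outer(td, td)
    }
  }
  joint
}

#' Carrier probability of a first-degree relative given proband status
#'
#' Exact conditional probability that a relative carries at least one mutant
#' allele, given the proband's dominant-pooled carrier status, the
#' relationship, and the population allele frequency. Computed by
#' enumerating the joint genotype distribution: parent-offspring pairs share
#' one transmitted allele (the other parent is a random Hardy-Weinberg
#' mate); full siblings are conditionally independent transmissions from two
#' Hardy-Weinberg parents. A carrier proband is the Hardy-Weinberg mixture
#' of heterozygote and homozygote.
#'
#' With `method = "half"` the relation-specific calculation is replaced by
#' the classical first-degree approximation: probability 1/2 given a carrier
#' proband and 0 given a non-carrier proband (exact only as q tends to 0).
#'
#' @param proband_status `"carrier"` or `"noncarrier"`.
#' @param relation `"mother"`, `"daughter"` or `"sister"`.
#' @param model a [genotype_model()].
#' @param method `"exact"` (default) or `"half"`.
#' @return carrier probability in `[0, 1]`.
#' @export
relative_carrier_prob <- function(proband_status = c("carrier", "noncarrier"),
                                  relation = c("mother", "daughter", "sister"),
                                  model,
                                  method = c("exact", "half")) {
  proband_status <- match.arg(proband_status)
  relation <- match.arg(relation)
  method <- match.arg(method)
  stopifnot(inherits(model, "genotype_model"))

  if (method == "half") {
    return(if (proband_status == "carrier") 0.5 else 0)
  }

  joint <- if (relation == "sister") {
    .joint_siblings(model$q)
  } else {
    # mother and daughter are the same parent-offspring joint law (symmetric)
    .joint_parent_offspring(model$q)
  }
  # margin 1 indexes the proband
  pb_carrier <- if (proband_status == "carrier") 2:3 else 1L
  block <- joint[pb_carrier, , drop = FALSE]
  sum(block[, 2:3]) / sum(block)
}

#' Mixing weight: carrier probability for one relative
#'
#' The probability that a relative carries the mutation, used to weight the
#' carrier and non-carrier likelihood contributions in the marginal
#' likelihood. An observed genotype overrides the Mendelian imputation:
#' genotyped carriers get weight 1, genotyped non-carriers 0; untested
#' relatives get [relative_carrier_prob()] given the proband's status.
#'
#' @param relative one-row data.frame or list with fields `role` and
#'   `carrier_status` (`carrier`/`noncarrier`/`untested`).
#' @param proband_status `"carrier"` or `"noncarrier"`.
#' @param model a [genotype_model()].
#' @param method passed to [relative_carrier_prob()].
#' @return probability in `[0, 1]`.
#' @export
mixing_weight <- function(relative, proband_status, model,
                          method = c("exact", "half")) {
  method <- match.arg(method)
  role <- relative$role
  if (!(role %in% c("mother", "sister", "daughter"))) {
    stop_kinpen("mixing weights are defined for first-degree relatives only")
  }
  status <- relative$carrier_status
  if (status == "carrier") return(1)
  if (status == "noncarrier") return(0)
  relative_carrier_prob(proband_status, role, model, method)
}

# Vectorised mixing weights for all relatives of a kin_cohort, for the gene
# the cohort was read with. Families positive for the other gene are not
# part of a single-gene analysis and must be excluded upstream.
mixing_weight_table <- function(rel, model, method = c("exact", "half")) {
  method <- match.arg(method)
  pstat <- ifelse(rel$proband_gene_status == model$gene,
                  "carrier", "noncarrier")
  p <- numeric(nrow(rel))
  # cache the four conditional probabilities
  for (ps in c("carrier", "noncarrier")) {
    for (rl in c("mother", "daughter", "sister")) {
      idx <- rel$carrier_status == "untested" & pstat == ps & rel$role == rl
      if (any(idx)) {
        p[idx] <- relative_carrier_prob(ps, rl, model, method)
      }
    }
  }
  p[rel$carrier_status == "carrier"] <- 1
  p[rel$carrier_status == "noncarrier"] <- 0
  p
}

#' Estimate the mutant allele frequency from probands
#'
#' The allele frequency is taken as half the carrier frequency among the
#' index family members: `q_hat = 0.5 * n_carrier_probands / n_probands`,
#' counting probands across all families in the registry.
#'
#' @param kc a `kin_cohort` object (or data.frame with `role` and
#'   `proband_gene_status`).
#' @param gene gene label, `"BRCA1"` or `"BRCA2"`.
#' @return estimated allele frequency (may be 0, with a warning, when no
#'   proband carries the mutation).
#' @export
estimate_allele_frequency <- function(kc, gene = c("BRCA1", "BRCA2")) {
  gene <- match.arg(gene)
  pb <- kc[kc$role == "proband", , drop = FALSE]
  if (nrow(pb) == 0L) stop_kinpen("no probands in the data")
  n_car <- sum(pb$proband_gene_status == gene)
  q_hat <- 0.5 * n_car / nrow(pb)
  if (n_car == 0L) {
    warning("no carrier probands for ", gene,
            "; allele frequency estimated as 0", call. = FALSE)
  }
  q_hat
}
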