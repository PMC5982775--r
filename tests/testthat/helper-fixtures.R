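# Shared fixtures and independent oracles, built in code at test time.

# One individual row in the kin-cohort table layout (character form, as a
# file would carry it).
kc_row <- function(family_id = "F1", person_id = "P1", role = "proband",
                   gene = "BRCA1", genotype = "carrier",
                   age_breast_dx = NA, age_ovarian_dx = NA,
                   age_rrso = NA, age_rrm = NA, age_last = 60,
                   vital = "alive") {
  data.frame(
    family_id = family_id, person_id = person_id, role = role,
    gene = gene, genotype = genotype,
    age_breast_dx = age_breast_dx, age_ovarian_dx = age_ovarian_dx,
    age_rrso = age_rrso, age_rrm = age_rrm, age_last = age_last,
    vital = vital, stringsAsFactors = FALSE
  )
}

# Write rows to a temporary kin-cohort file and return its path.
write_kc_file <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

# A small hand-built registry: two BRCA1 families, one BRCA2, one negative.
toy_registry_rows <- function() {
  list(
    kc_row("F1", "F1_P", "proband", "BRCA1", "carrier", age_breast_dx = 40,
           age_last = 50),
    kc_row("F1", "F1_M", "mother", "none", "untested", age_breast_dx = 55,
           age_last = 70),
    kc_row("F1", "F1_S1", "sister", "BRCA1", "carrier", age_last = 45),
    kc_row("F2", "F2_P", "proband", "BRCA1", "carrier", age_breast_dx = 38,
           age_last = 42),
    kc_row("F2", "F2_M", "mother", "BRCA1/2", "noncarrier", age_last = 72,
           vital = "dead"),
    kc_row("F3", "F3_P", "proband", "BRCA2", "carrier", age_breast_dx = 44,
           age_last = 51),
    kc_row("F3", "F3_S1", "sister", "BRCA2", "carrier", age_breast_dx = 47,
           age_last = 60),
    kc_row("F4", "F4_P", "proband", "BRCA1/2", "noncarrier",
           age_breast_dx = 45, age_last = 58),
    kc_row("F4", "F4_M", "mother", "none", "untested", age_rrso = 48,
           age_last = 75),
    kc_row("F4", "F4_D1", "daughter", "none", "untested", age_last = 30)
  )
}

# Independent allele-level oracle for the relative carrier probability.
# Enumerates the four founder alleles (each mutant with probability q) and
# every transmission choice explicitly; never touches genotype-level
# transition matrices, so it shares no code with the implementation.
oracle_rel_carrier_prob <- function(proband_status, relation, q) {
  pa <- function(bit) if (bit) q else 1 - q
  num <- 0
  den <- 0
  for (a1 in 0:1) for (a2 in 0:1) for (a3 in 0:1) for (a4 in 0:1) {
    p_alleles <- pa(a1) * pa(a2) * pa(a3) * pa(a4)
    father <- c(a1, a2)
    mother <- c(a3, a4)
    if (relation == "sister") {
      # proband and sister each draw one paternal and one maternal allele
      for (pf in 1:2) for (pm in 1:2) for (sf in 1:2) for (sm in 1:2) {
        pr <- p_alleles / 16
        proband_car <- father[pf] + mother[pm] >= 1
        rel_car <- father[sf] + mother[sm] >= 1
        ok <- if (proband_status == "carrier") proband_car else !proband_car
        if (ok) {
          den <- den + pr
          if (rel_car) num <- num + pr
        }
      }
    } else {
      # parent-offspring: proband is the child of 'mother' and 'father';
      # the relative is the mother (the daughter case is the same law with
      # roles swapped, which this oracle covers by symmetry of the joint)
      for (pf in 1:2) for (pm in 1:2) {
        pr <- p_alleles / 4
        proband_car <- father[pf] + mother[pm] >= 1
        rel_car <- sum(mother) >= 1
        ok <- if (proband_status == "carrier") proband_car else !proband_car
        if (ok) {
          den <- den + pr
          if (rel_car) num <- num + pr
        }
      }
    }
  }
  num / den
}

# Stratified actuarial (occurrence/exposure) hazard oracle for a fully
# genotyped data set: events / at-risk per distinct event age, per class.
oracle_actuarial <- function(time, event, carrier) {
  grid <- sort(unique(time[event == 1]))
  per_class <- function(keep) {
    vapply(grid, function(tk) {
      at_risk <- sum(keep & time >= tk)
      if (at_risk == 0) 0 else sum(keep & time == tk & event == 1) / at_risk
    }, numeric(1))
  }
  list(grid = grid,
       lambda_carrier = per_class(carrier),
       lambda_noncarrier = per_class(!carrier))
}

# Incidence fixture reconstructed from published group counts: families per
# group, each with `n_rel` relatives of whom `n_case` have a breast
# diagnosis inside follow-up.
incidence_fixture <- function() {
  specs <- list(
    list(gene = "BRCA1", n_rel = 230, n_case = 49),
    list(gene = "BRCA2", n_rel = 309, n_case = 63),
    list(gene = "negative", n_rel = 5410, n_case = 456)
  )
  rows <- list()
  for (s in specs) {
    fid <- paste0("G", s$gene)
    pb_gene <- if (s$gene == "negative") "BRCA1/2" else s$gene
    pb_gt <- if (s$gene == "negative") "noncarrier" else "carrier"
    rows[[length(rows) + 1L]] <- kc_row(fid, paste0(fid, "_P"), "proband",
                                        pb_gene, pb_gt,
                                        age_breast_dx = 42, age_last = 50)
    case <- c(rep(TRUE, s$n_case), rep(FALSE, s$n_rel - s$n_case))
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = fid,
      person_id = paste0(fid, "_R", seq_len(s$n_rel)),
      role = "sister",
      gene = "none", genotype = "untested",
      age_breast_dx = ifelse(case, 45, NA),
      age_ovarian_dx = NA, age_rrso = NA, age_rrm = NA,
      age_last = 70, vital = "alive",
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Small simulated registry shared by several test files.
small_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_families(
        simulation_config(seed = 424242, n_families = 300, gamma = 0.3)
      )
    }
    cache
  }
})
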