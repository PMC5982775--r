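#' Derive outcome-specific follow-up for one individual
#'
#' Converts an individual's event, surgery and follow-up ages into a
#' (time, event) pair under the registry's censoring rules. For breast
#' cancer, follow-up runs from birth to breast cancer diagnosis, censored at
#' the earliest of ovarian cancer diagnosis, risk-reducing
#' salpingo-oophorectomy (RRSO), risk-reducing mastectomy (RRM), or last
#' follow-up/death. For ovarian cancer, follow-up runs to ovarian cancer
#' diagnosis, censored at the earliest of RRSO or last follow-up/death.
#'
#' Ages are whole years and a within-year tie between the event and a
#' censoring cause counts as an event (observed diagnoses are never
#' discarded to a same-age censoring). RRM censors only individuals without
#' a prior breast diagnosis.
#'
#' @param individual a one-row data.frame (or list) with fields
#'   `age_breast_dx`, `age_ovarian_dx`, `age_rrso`, `age_rrm`, `age_last`,
#'   `vital` (absent ages as `NA`).
#' @param outcome `"breast"` or `"ovarian"`.
#' @return list with `time` (age in years), `event` (0/1) and
#'   `censor_reason` (one of `none`, `competing_cancer`, `rrso`, `rrm`,
#'   `last_followup`, `death`).
#' @export
derive_followup <- function(individual, outcome = c("breast", "ovarian")) {
  outcome <- match.arg(outcome)
  fu <- derive_followup_table(as.data.frame(as.list(individual)), outcome)
  if (nrow(fu) != 1L) stop_kinpen("expected exactly one individual")
  list(time = fu$time, event = fu$event, censor_reason = fu$censor_reason)
}

# Vectorised follow-up derivation over the rows of a kin_cohort-shaped
# data.frame. Returns one row per input row.
derive_followup_table <- function(kc, outcome = c("breast", "ovarian")) {
  outcome <- match.arg(outcome)
  n <- nrow(kc)
  num <- function(col) {
    v <- kc[[col]]
    if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
  }
  age_last <- num("age_last")
  vital <- kc[["vital"]] %||% rep("alive", n)
  last_reason <- ifelse(!is.na(vital) & vital == "dead",
                        "death", "last_followup")

  if (outcome == "breast") {
    event_age <- num("age_breast_dx")
    cens <- cbind(
      competing_cancer = num("age_ovarian_dx"),
      rrso = num("age_rrso"),
      rrm = num("age_rrm"),
      last = age_last
    )
  } else {
    event_age <- num("age_ovarian_dx")
    cens <- cbind(
      rrso = num("age_rrso"),
      last = age_last
    )
  }
  all_absent <- is.na(event_age) & apply(cens, 1L, function(r) all(is.na(r)))
  if (any(all_absent)) {
    stop_kinpen(
      "no usable time-to-event data for person '",
      (kc$person_id %||% rownames(kc))[all_absent][1L], "'"
    )
  }

  cmin <- suppressWarnings(apply(cens, 1L, min, na.rm = TRUE))  # Inf if none
  # ties event-first: an event at the same age as any censoring cause counts
  is_event <- !is.na(event_age) & event_age <= cmin
  time <- ifelse(is_event, event_age, cmin)
  # censoring reason: earliest cause, tie priority = column order
  reason_idx <- apply(cens, 1L, function(r) {
    if (all(is.na(r))) NA_integer_ else which.min(r)
  })
  reason <- colnames(cens)[reason_idx]
  idx_last <- !is.na(reason) & reason == "last"
  reason[idx_last] <- last_reason[idx_last]
  reason[is_event | is.na(reason)] <- "none"

  data.frame(
    family_id = kc$family_id %||% rep(NA_character_, n),
    person_id = kc$person_id %||% rep(NA_character_, n),
    outcome = outcome,
    time = time,
    event = as.integer(is_event),
    censor_reason = reason,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Incidence of an outcome among first-degree relatives, by proband status
#'
#' Counts outcome events among relatives with derivable follow-up, grouped
#' by the proband's mutation status (`BRCA1`, `BRCA2`, `negative`), and the
#' crude incidence percentage `100 * n_cases / n_relatives`. A group with no
#' relatives reports `NA` (undefined), not zero.
#'
#' @param kc a `kin_cohort` object.
#' @param outcome `"breast"` or `"ovarian"`.
#' @return data.frame with columns `group`, `n_relatives`, `n_cases`,
#'   `percent`.
#' @export
incidence_summary <- function(kc, outcome = c("breast", "ovarian")) {
  outcome <- match.arg(outcome)
  rel <- kc[kc$role != "proband", , drop = FALSE]
  groups <- c("BRCA1", "BRCA2", "negative")
  out <- data.frame(
    group = groups,
    n_relatives = 0L,
    n_cases = 0L,
    percent = NA_real_,
    stringsAsFactors = FALSE
  )
  if (nrow(rel) > 0L) {
    fu <- derive_followup_table(rel, outcome)
    g <- factor(rel$proband_gene_status, levels = groups)
    out$n_relatives <- as.integer(table(g))
    out$n_cases <- as.integer(tapply(fu$event, g, sum, default = 0L))
  }
  nonzero <- out$n_relatives > 0L
  out$percent[nonzero] <- 100 * out$n_cases[nonzero] / out$n_relatives[nonzero]
  out
}
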