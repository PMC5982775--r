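#' Read a kin-cohort table
#'
#' Reads a delimited registry export with one row per individual and returns
#' a validated `kin_cohort` object for the analysis of one gene. The file
#' must carry the header
#' `family_id,person_id,role,gene,genotype,age_breast_dx,age_ovarian_dx,age_rrso,age_rrm,age_last,vital`.
#' Absent ages are empty fields. The `gene` column names the gene a carrier
#' genotype refers to (`none` or empty for untested individuals); `genotype`
#' is one of `carrier`, `noncarrier` (negative on the BRCA1/2 panel) or
#' `untested`.
#'
#' For the requested `gene`, each individual's working carrier status is:
#' `carrier` if genotyped carrier of that gene; `noncarrier` if panel
#' negative; `untested` otherwise (including carriers of the other gene,
#' whose status for the requested gene is unknown here). Families are
#' classified by the proband's raw genotype: `BRCA1`, `BRCA2`, or `negative`.
#'
#' Relatives with no usable time-to-event data (missing `age_last`) are
#' excluded with a message; the count is kept in the
#' `n_excluded_missing_followup` attribute. Rows whose role marks a relative
#' beyond first degree are dropped with a warning.
#'
#' @param path path to the delimited file. Lines starting with `#` are
#'   ignored.
#' @param gene gene under analysis, `"BRCA1"` or `"BRCA2"`.
#' @param sep field separator (default comma).
#' @return A `kin_cohort` object: a data.frame with the file's columns plus
#'   `carrier_status` (mapped for `gene`) and `proband_gene_status`
#'   (per family), and attributes `gene` and `n_excluded_missing_followup`.
#' @seealso [write_kincohort_table()], [derive_followup()],
#'   [incidence_summary()]
#' @export
read_kincohort_table <- function(path, gene = c("BRCA1", "BRCA2"), sep = ",") {
  gene <- match.arg(gene)
  if (!file.exists(path)) stop_kinpen("file not found: ", path)
  raw <- utils::read.table(
    path, header = TRUE, sep = sep, comment.char = "#",
    colClasses = "character", stringsAsFactors = FALSE, quote = "\"",
    blank.lines.skip = TRUE, strip.white = TRUE
  )
  if (!identical(names(raw), .KC_COLUMNS)) {
    stop_kinpen(
      "unexpected header; expected columns: ",
      paste(.KC_COLUMNS, collapse = ",")
    )
  }
  as_kin_cohort(raw, gene = gene)
}

# Build and validate a kin_cohort from a raw character data.frame with the
# canonical columns. `line` offsets parse errors to file line numbers
# (header = line 1).
as_kin_cohort <- function(raw, gene, line_offset = 1L) {
  n <- nrow(raw)
  kc <- data.frame(
    family_id = raw$family_id,
    person_id = raw$person_id,
    role = raw$role,
    gene = ifelse(is.na(raw$gene) | raw$gene == "", "none", raw$gene),
    genotype = raw$genotype,
    stringsAsFactors = FALSE
  )
  lines <- seq_len(n) + line_offset

  bad_role <- !(kc$role %in% c(.KC_ROLES, .KC_DISTANT_ROLES))
  if (any(bad_role)) {
    stop_kinpen(
      "unknown role token '", kc$role[bad_role][1L],
      "' at line ", lines[bad_role][1L]
    )
  }
  bad_gt <- !(kc$genotype %in% .KC_GENOTYPES)
  if (any(bad_gt)) {
    stop_kinpen(
      "unknown genotype token '", kc$genotype[bad_gt][1L],
      "' at line ", lines[bad_gt][1L]
    )
  }
  bad_vital <- !(raw$vital %in% .KC_VITAL)
  if (any(bad_vital)) {
    stop_kinpen(
      "unknown vital token '", raw$vital[bad_vital][1L],
      "' at line ", lines[bad_vital][1L]
    )
  }
  kc$vital <- raw$vital

  for (col in c("age_breast_dx", "age_ovarian_dx", "age_rrso", "age_rrm",
                "age_last")) {
    v <- raw[[col]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- !blank & is.na(num)
    if (any(bad)) {
      stop_kinpen(
        "non-numeric ", col, " '", v[bad][1L], "' at line ", lines[bad][1L]
      )
    }
    num[blank] <- NA_real_
    out_of_range <- !is.na(num) & (num < 0 | num > 120)
    if (any(out_of_range)) {
      stop_kinpen(
        col, " out of range [0, 120] at line ", lines[out_of_range][1L]
      )
    }
    kc[[col]] <- num
  }
  kc <- kc[, .KC_COLUMNS]

  # event/surgery ages must not exceed last follow-up where both are known
  for (col in c("age_breast_dx", "age_ovarian_dx", "age_rrso", "age_rrm")) {
    bad <- !is.na(kc[[col]]) & !is.na(kc$age_last) & kc[[col]] > kc$age_last
    if (any(bad)) {
      stop_kinpen(
        col, " exceeds age_last for person '", kc$person_id[bad][1L],
        "' in family '", kc$family_id[bad][1L], "'"
      )
    }
  }

  distant <- kc$role %in% .KC_DISTANT_ROLES
  if (any(distant)) {
    warning(
      sum(distant), " relative(s) beyond first degree dropped",
      call. = FALSE
    )
    kc <- kc[!distant, , drop = FALSE]
  }

  # family structure: exactly one proband, genotyped
  is_proband <- kc$role == "proband"
  counts <- table(factor(kc$family_id[is_proband],
                         levels = unique(kc$family_id)))
  if (any(counts == 0L)) {
    stop_kinpen(
      "family '", names(counts)[counts == 0L][1L], "' has no proband"
    )
  }
  if (any(counts > 1L)) {
    stop_kinpen(
      "family '", names(counts)[counts > 1L][1L],
      "' has more than one proband"
    )
  }
  if (any(kc$genotype[is_proband] == "untested")) {
    fam <- kc$family_id[is_proband & kc$genotype == "untested"][1L]
    stop_kinpen("proband of family '", fam, "' is untested")
  }
  dup <- duplicated(kc[, c("family_id", "person_id")])
  if (any(dup)) {
    stop_kinpen(
      "duplicate person_id '", kc$person_id[dup][1L],
      "' in family '", kc$family_id[dup][1L], "'"
    )
  }

  # proband gene status per family
  pb <- kc[is_proband, c("family_id", "gene", "genotype")]
  pb_status <- ifelse(
    pb$genotype == "carrier" & pb$gene %in% c("BRCA1", "BRCA2"),
    pb$gene, "negative"
  )
  if (any(pb$genotype == "carrier" & !(pb$gene %in% c("BRCA1", "BRCA2")))) {
    bad <- pb$family_id[pb$genotype == "carrier" &
                          !(pb$gene %in% c("BRCA1", "BRCA2"))][1L]
    stop_kinpen(
      "carrier proband of family '", bad, "' lacks a gene label"
    )
  }
  kc$proband_gene_status <- pb_status[match(kc$family_id, pb$family_id)]

  # working carrier status for the requested gene
  kc$carrier_status <- ifelse(
    kc$genotype == "carrier" & kc$gene == gene, "carrier",
    ifelse(kc$genotype == "noncarrier", "noncarrier",
           ifelse(kc$genotype == "carrier", "untested", "untested"))
  )

  # exclude relatives with no usable follow-up (probands kept: their genotype
  # classifies the family even when their own follow-up is absent)
  drop <- kc$role != "proband" & is.na(kc$age_last)
  n_excluded <- sum(drop)
  if (n_excluded > 0L) {
    message(n_excluded, " relative(s) without time-to-event data excluded")
    kc <- kc[!drop, , drop = FALSE]
  }

  rownames(kc) <- NULL
  structure(
    kc,
    gene = gene,
    n_excluded_missing_followup = n_excluded,
    class = c("kin_cohort", "data.frame")
  )
}

#' Write a kin-cohort table
#'
#' Writes the canonical one-row-per-individual delimited format read by
#' [read_kincohort_table()]. Absent ages become empty fields. Reading the
#' written file back yields structurally identical families.
#'
#' @param kc a `kin_cohort` object or a data.frame with the canonical
#'   columns.
#' @param path output path.
#' @param sep field separator.
#' @param header_comment optional character vector written as leading `#`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_kincohort_table <- function(kc, path, sep = ",", header_comment = NULL) {
  out <- as.data.frame(kc)[, .KC_COLUMNS]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(
    out, con, sep = sep, row.names = FALSE, quote = FALSE, na = ""
  )
  invisible(path)
}

#' @export
print.kin_cohort <- function(x, ...) {
  fam <- unique(x$family_id)
  status <- x$proband_gene_status[x$role == "proband"]
  cat("kin_cohort:", length(fam), "families,",
      sum(x$role != "proband"), "first-degree relatives",
      "(gene under analysis:", attr(x, "gene"), ")\n")
  tab <- table(factor(status, levels = c("BRCA1", "BRCA2", "negative")))
  cat("  proband status: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  gt <- table(factor(x$carrier_status[x$role != "proband"],
                     levels = .KC_GENOTYPES))
  cat("  relative genotypes (", attr(x, "gene"), "): ",
      paste(names(gt), gt, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Families represented in a kin-cohort
#'
#' @param kc a `kin_cohort` object.
#' @return data.frame with one row per family: `family_id`,
#'   `proband_gene_status`, `n_relatives`.
#' @export
family_table <- function(kc) {
  pb <- kc[kc$role == "proband", c("family_id", "proband_gene_status")]
  n_rel <- table(factor(kc$family_id[kc$role != "proband"],
                        levels = pb$family_id))
  data.frame(
    family_id = pb$family_id,
    proband_gene_status = pb$proband_gene_status,
    n_relatives = as.integer(n_rel),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
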