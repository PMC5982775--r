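# Internal helpers shared across modules.

.KC_ROLES <- c("proband", "mother", "sister", "daughter")
# Roles that identify a relative beyond first degree; rows with these are
# dropped with a warning rather than rejected (registries often export them).
.KC_DISTANT_ROLES <- c(
  "grandmother", "granddaughter", "aunt", "niece", "cousin",
  "half-sister", "half_sister"
)
.KC_GENOTYPES <- c("carrier", "noncarrier", "untested")
.KC_VITAL <- c("alive", "dead")
.KC_COLUMNS <- c(
  "family_id", "person_id", "role", "gene", "genotype",
  "age_breast_dx", "age_ovarian_dx", "age_rrso", "age_rrm",
  "age_last", "vital"
)

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FNV-1a hash of a character scalar, reported as 8 hex digits. Used to stamp
# output files with a configuration fingerprint without a digest dependency.
# Doubles hold the split 16-bit products exactly, so the arithmetic is an
# exact 32-bit multiply.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo31 <- h %% 2147483648
    h <- (h - lo31) + bitwXor(as.integer(lo31), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kinpen <- function(...) stop(..., call. = FALSE)
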