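# Internal helpers: error signalling, identifier normalisation, rounding,
# seeded sub-streams, and a tiny stable hash for provenance headers.

#' @importFrom stats pnorm rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "sennet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_validation <- function(msg) abort(msg, "sennet_validation_error")
abort_parameter  <- function(msg) abort(msg, "sennet_parameter_error")
abort_parse      <- function(msg) abort(msg, "sennet_parse_error")

#' Normalise gene identifiers for matching
#'
#' Gene symbols are matched case-insensitively after whitespace trimming.
#' Aliased identifiers such as `"LINC00086/SMIM10L2A"` are handled by
#' [id_match_keys()], which expands them into one key per synonym.
#'
#' @param x character vector of gene identifiers.
#' @return upper-cased, trimmed identifiers.
#' @keywords internal
normalize_gene_id <- function(x) toupper(trimws(as.character(x)))

#' Normalise miRNA identifiers for matching
#'
#' miRBase-style names are reconciled by stripping a three-letter species
#' prefix (e.g. `"hsa-"`) so `"hsa-miR-335-3p"` and `"miR-335-3p"` match,
#' then comparing case-insensitively. Display names are never altered.
#'
#' @param x character vector of miRNA identifiers.
#' @return normalised matching keys.
#' @keywords internal
normalize_mirna_id <- function(x) {
  x <- tolower(trimws(as.character(x)))
  sub("^[a-z]{3}-(mir)", "\\1", x)
}

normalize_regulator_id <- function(x, class) {
  ifelse(class == "miRNA", normalize_mirna_id(x), normalize_gene_id(x))
}

# One matching key per synonym: "LINC00086/SMIM10L2A" -> two rows pointing
# back at the same display id.
id_match_keys <- function(ids, normalizer = normalize_gene_id) {
  parts <- strsplit(as.character(ids), "/", fixed = TRUE)
  n <- lengths(parts)
  data.frame(
    key = normalizer(unlist(parts, use.names = FALSE)),
    display = rep(as.character(ids), n),
    stringsAsFactors = FALSE
  )
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; reported percentages here use the
#' convention of rounding halves away from zero (so 26.25 -> 26.3 at one
#' decimal). A small guard absorbs binary representation error.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Percentage with the reporting convention: one decimal half-away-from-zero,
# or truncation to a whole percent (the "26%" display style).
format_pct <- function(num, den, display = c("decimal", "integer")) {
  display <- match.arg(display)
  if (den == 0) return(0)
  pct <- 100 * num / den
  if (display == "integer") trunc(pct + 1e-9) else round_half_away(pct, 1)
}

# Deterministic per-table sub-seed so adding one simulated table does not
# perturb the stream of another. Streams are indexed by small integers.
sub_seed <- function(seed, stream) {
  s <- (abs(as.double(seed)) %% 2147400000) + 7919 * stream
  as.integer(s %% 2147483647L)
}

# FNV-1a 32-bit hash of a string, returned as 8 hex digits. Used only for
# provenance headers (config fingerprints), not for anything cryptographic.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # XOR with a byte touches low 8 bits only
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply split into 16-bit halves (doubles stay exact)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_parameter(sprintf("'%s' must be a single non-missing number", name))
  if (x < min || x > max)
    abort_parameter(sprintf("'%s' must be in [%s, %s], got %s", name, min, max, x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
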