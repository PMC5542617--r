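# Nucleotide-alphabet algebra shared by every scanning routine.
#
# Each IUPAC code is stored as a 4-bit mask over {A=1, C=2, G=4, T=8} so that
# set intersection and subset tests reduce to bitwAnd(). Inosine (I), a
# synthesis base found only in primers, expands to the universal set like N.

.NUC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, I = 15L
)

.MASK_BASES <- list(A = "A", C = "C", G = "G", T = "T")

#' Expand one IUPAC nucleotide code to its base set
#'
#' Returns the set of unambiguous bases an IUPAC code stands for. Inosine
#' (`I`) and `N` both expand to all four bases: inosine pairs promiscuously
#' and is treated as universal throughout the in-silico PCR model.
#'
#' @param code Single character: an IUPAC nucleotide code or `I`.
#' @return Character vector of bases from `c("A","C","G","T")`.
#' @examples
#' base_set("R")
#' base_set("I")
#' @export
base_set <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  m <- .NUC_MASK[toupper(code)]
  if (is.na(m)) {
    stop("unknown nucleotide code: '", code, "'", call. = FALSE)
  }
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

# Convert a residue string to its mask vector; errors name the offending
# position. `allow_inosine = FALSE` rejects I (templates are sequencing
# calls, not synthesis products).
seq_masks <- function(residues, allow_inosine = TRUE, what = "sequence") {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  m <- .NUC_MASK[chars]
  if (anyNA(m)) {
    at <- which(is.na(m))[1L]
    stop(what, " contains invalid character '", chars[at], "' at position ",
         at, call. = FALSE)
  }
  if (!allow_inosine && any(chars == "I")) {
    at <- which(chars == "I")[1L]
    stop(what, " contains inosine (I) at position ", at,
         "; inosine is permitted in primers only", call. = FALSE)
  }
  unname(m)
}

#' Reverse complement under IUPAC rules
#'
#' Complements every IUPAC ambiguity code (R to Y, B to V, and so on) and
#' reverses the string. Inosine maps to `N`: its pairing is universal, so the
#' complementary position is unconstrained.
#'
#' @param residues Residue string over the IUPAC alphabet plus `I`.
#' @return The reverse-complement string.
#' @examples
#' revcomp("AGGTC")
#' revcomp("AATATT") # palindromic SspI site
#' @export
revcomp <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  seq_masks(residues, allow_inosine = TRUE) # validation only
  flipped <- chartr("ACGTRYSWKMBDHVNI", "TGCAYRSWMKVHDBNN", toupper(residues))
  paste(rev(strsplit(flipped, "", fixed = TRUE)[[1]]), collapse = "")
}

# Positions (0-based) where a motif mask matches a template mask.
# conservative: every template resolution is covered (template set a subset
# of the motif set at each position); liberal: the sets merely intersect.
scan_motif <- function(tmask, pmask, match_mode = c("conservative", "liberal")) {
  match_mode <- match.arg(match_mode)
  n <- length(tmask)
  m <- length(pmask)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    w <- tmask[j:(n - m + j)]
    ok <- ok & if (match_mode == "conservative") {
      bitwAnd(w, bitwAnd(bitwNot(pmask[j]), 15L)) == 0L
    } else {
      bitwAnd(w, pmask[j]) > 0L
    }
  }
  which(ok) - 1L
}

# Per-offset mismatch counts of a pattern against a template (intersection
# test per position). Returns an integer vector over 0-based offsets, plus
# a logical matrix row for seed checking when requested.
pattern_mismatches <- function(tmask, pmask) {
  n <- length(tmask)
  m <- length(pmask)
  if (n < m) {
    return(list(mismatches = integer(0), miss = matrix(FALSE, 0, 0)))
  }
  k <- n - m + 1L
  miss <- matrix(FALSE, nrow = k, ncol = m)
  for (j in seq_len(m)) {
    miss[, j] <- bitwAnd(tmask[j:(n - m + j)], pmask[j]) == 0L
  }
  list(mismatches = as.integer(rowSums(miss)), miss = miss)
}

# Resolve ambiguity codes to concrete bases, drawing uniformly from each
# base set (uses the current RNG stream).
resolve_iupac <- function(residues) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  out <- vapply(chars, function(ch) {
    s <- base_set(ch)
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1))
  paste(out, collapse = "")
}
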