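# Restriction-enzyme catalog and IUPAC-aware digestion of linear templates.
#
# Coordinates are 0-based and half-open throughout: a cut falling between
# template positions k-1 and k is stored as cut_coord = k, so fragment
# lengths are plain coordinate differences. Fragment sizes are read from the
# top strand only (duplex length is what a gel resolves); bottom-strand
# offsets of sticky-end cutters are stored but do not change lengths.

#' Construct a restriction enzyme record
#'
#' @param name Enzyme name (e.g. `"SspI"`).
#' @param recognition IUPAC recognition motif, optionally with a single caret
#'   marking the top-strand cut (`"AAT^ATT"`). Without a caret, `cut_top`
#'   must be given.
#' @param cut_top Top-strand cut offset from the motif start (0 to motif
#'   length). Ignored when the motif carries a caret.
#' @param cut_bottom Bottom-strand cut offset, in top-strand coordinates.
#'   Defaults to `motif length - cut_top` (symmetric cutter).
#' @return One-row tibble with columns `name`, `recognition`, `cut_top`,
#'   `cut_bottom`.
#' @examples
#' restriction_enzyme("SspI", "AAT^ATT")
#' @export
restriction_enzyme <- function(name, recognition, cut_top = NULL,
                               cut_bottom = NULL) {
  recognition <- toupper(recognition)
  n_caret <- stringr::str_count(recognition, stringr::fixed("^"))
  if (n_caret > 1L) {
    stop("malformed motif '", recognition, "' for ", name,
         ": more than one caret", call. = FALSE)
  }
  if (n_caret == 1L) {
    cut_top <- as.integer(regexpr("^", recognition, fixed = TRUE)) - 1L
    recognition <- sub("^", "", recognition, fixed = TRUE)
  } else if (is.null(cut_top)) {
    stop("enzyme ", name, ": no caret in motif and no cut_top given",
         call. = FALSE)
  }
  cut_top <- as.integer(cut_top)
  len <- nchar(recognition)
  if (len < 4L) {
    stop("enzyme ", name, ": motif shorter than 4 bases", call. = FALSE)
  }
  seq_masks(recognition, allow_inosine = FALSE,
            what = paste0("motif of ", name))
  if (is.null(cut_bottom)) cut_bottom <- len - cut_top
  cut_bottom <- as.integer(cut_bottom)
  if (cut_top < 0L || cut_top > len || cut_bottom < 0L || cut_bottom > len) {
    stop("enzyme ", name, ": cut offset outside the recognition site ",
         "(only within-site type II cutters are supported)", call. = FALSE)
  }
  tibble::tibble(name = name, recognition = recognition,
                 cut_top = cut_top, cut_bottom = cut_bottom)
}

#' Load a restriction-enzyme catalog
#'
#' Reads a CSV/TSV catalog with columns `name` and `recognition` (REBASE-style
#' caret notation) or `name`, `recognition`, `cut_top` and optionally
#' `cut_bottom`. Enzymes cutting outside their recognition site are rejected.
#'
#' @param path Path to a delimited file, or a literal data string.
#' @return Tibble of enzymes (one row each), class `enzyme_catalog`.
#' @export
read_enzyme_catalog <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("name", "recognition") %in% names(tab))) {
    stop("catalog needs columns 'name' and 'recognition'", call. = FALSE)
  }
  if (anyDuplicated(tab$name)) {
    stop("duplicate enzyme name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::pmap_dfr(tab, function(name, recognition,
                                       cut_top = NULL, cut_bottom = NULL, ...) {
    restriction_enzyme(name, recognition, cut_top = cut_top,
                       cut_bottom = cut_bottom)
  })
  class(out) <- c("enzyme_catalog", class(out))
  out
}

as_enzyme_rows <- function(enzymes) {
  if (is.data.frame(enzymes)) return(enzymes)
  stop("expected an enzyme tibble (see restriction_enzyme())", call. = FALSE)
}

#' Find restriction cut sites on both strands
#'
#' Scans the forward strand for the recognition motif and for its reverse
#' complement. In `conservative` mode a template position matches only when
#' every resolution of its ambiguity code is covered by the motif code
#' (the site is cut in all resolutions); in `liberal` mode an intersection
#' of base sets suffices (some resolution is cut). Overlapping occurrences
#' are all reported. For palindromic motifs the redundant minus-strand hit
#' is suppressed.
#'
#' @param residues Template residue string (inosine-free).
#' @param enzyme One-row enzyme tibble from [restriction_enzyme()].
#' @param match_mode `"conservative"` or `"liberal"`.
#' @return Tibble with columns `motif_start` (0-based), `strand` (`+`/`-`)
#'   and `cut_coord` (0-based top-strand cut position), sorted by
#'   `cut_coord`.
#' @examples
#' sspi <- restriction_enzyme("SspI", "AAT^ATT")
#' find_cut_sites("GGAATATTCC", sspi)
#' @export
find_cut_sites <- function(residues, enzyme,
                           match_mode = c("conservative", "liberal")) {
  match_mode <- match.arg(match_mode)
  enzyme <- as_enzyme_rows(enzyme)
  stopifnot(nrow(enzyme) == 1L)
  tmask <- seq_masks(residues, allow_inosine = FALSE, what = "template")
  motif <- enzyme$recognition
  len <- nchar(motif)
  pmask <- seq_masks(motif)
  fw <- scan_motif(tmask, pmask, match_mode)
  hits <- tibble::tibble(
    motif_start = fw, strand = rep("+", length(fw)),
    cut_coord = fw + enzyme$cut_top
  )
  rc <- revcomp(motif)
  if (!identical(rc, motif)) {
    rv <- scan_motif(tmask, seq_masks(rc), match_mode)
    hits <- dplyr::bind_rows(hits, tibble::tibble(
      motif_start = rv, strand = rep("-", length(rv)),
      cut_coord = rv + (len - enzyme$cut_bottom)
    ))
  }
  dplyr::arrange(hits, .data$cut_coord, .data$motif_start)
}

#' Predict fragment sizes of a linear digest
#'
#' Pools the top-strand cut coordinates of all enzymes, deduplicates and
#' sorts them, and reports the gap lengths between the template ends and the
#' cuts. Lengths always sum to the template length.
#'
#' @param residues Template residue string.
#' @param enzymes Enzyme tibble (one or more rows).
#' @param match_mode Passed to [find_cut_sites()].
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @examples
#' sspi <- restriction_enzyme("SspI", "AAT^ATT")
#' digest_fragments(strrep("C", 10), sspi)
#' @export
digest_fragments <- function(residues, enzymes,
                             match_mode = c("conservative", "liberal")) {
  match_mode <- match.arg(match_mode)
  enzymes <- as_enzyme_rows(enzymes)
  n <- nchar(residues)
  cuts <- unlist(lapply(seq_len(nrow(enzymes)), function(i) {
    find_cut_sites(residues, enzymes[i, ], match_mode)$cut_coord
  }))
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < n]
  as.integer(diff(c(0L, cuts, n)))
}

#' Can a gel tell two fragment patterns apart?
#'
#' Two banding patterns are indistinguishable when the sorted fragment lists
#' can be matched one-to-one with every pairwise size difference within the
#' gel resolution; differing band counts are always distinguishable.
#'
#' @param frags_a,frags_b Integer vectors of fragment lengths.
#' @param resolution_bp Smallest resolvable size difference, in bp.
#' @return `TRUE` when the patterns are distinguishable.
#' @examples
#' gel_distinguishable(c(242, 496), c(228, 481), resolution_bp = 20)
#' @export
gel_distinguishable <- function(frags_a, frags_b, resolution_bp) {
  stopifnot(resolution_bp > 0)
  if (length(frags_a) == 0L || length(frags_b) == 0L) {
    stop("empty fragment list", call. = FALSE)
  }
  if (length(frags_a) != length(frags_b)) return(TRUE)
  any(abs(sort(frags_a) - sort(frags_b)) > resolution_bp)
}
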