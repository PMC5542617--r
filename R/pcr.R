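# Degenerate-primer binding-site search and amplicon extraction for primer
# cocktails. Primers may carry 5' non-binding tails (M13 sequencing tails on
# the "_t1" cocktail primers): tails are excluded from matching but appear
# verbatim in the amplicon, so predicted product sizes include them.

#' Construct a primer record
#'
#' @param name Primer name.
#' @param sequence Full 5'-3' residue string (IUPAC codes and inosine
#'   allowed).
#' @param direction `"forward"` or `"reverse"`.
#' @param tail_len Length of the 5' non-binding tail (0 for untailed
#'   primers). The binding region is `substr(sequence, tail_len + 1, ...)`.
#' @param cocktail Optional cocktail label.
#' @return One-row primer tibble.
#' @export
primer <- function(name, sequence, direction = c("forward", "reverse"),
                   tail_len = 0L, cocktail = NA_character_) {
  direction <- match.arg(direction)
  sequence <- toupper(sequence)
  seq_masks(sequence, allow_inosine = TRUE, what = paste0("primer ", name))
  tail_len <- as.integer(tail_len)
  stopifnot(tail_len >= 0L, tail_len < nchar(sequence))
  tibble::tibble(name = name, sequence = sequence, direction = direction,
                 tail_len = tail_len, cocktail = cocktail)
}

#' Read a primer table
#'
#' CSV with columns `name`, `sequence`, `direction`, `tail_len` and
#' optionally `cocktail`.
#'
#' @param path Path to the CSV.
#' @return Primer tibble.
#' @export
read_primer_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("name", "sequence", "direction", "tail_len")
  if (!all(need %in% names(tab))) {
    stop("primer table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"cocktail" %in% names(tab)) tab$cocktail <- NA_character_
  purrr::pmap_dfr(tab[, c(need, "cocktail")], primer)
}

binding_region <- function(p) {
  substr(p$sequence, p$tail_len + 1L, nchar(p$sequence))
}

#' Find binding sites of a degenerate primer
#'
#' Forward primers are matched against the forward strand, reverse primers
#' against the reverse strand (their reverse complement is located on the
#' forward strand). A position matches when the IUPAC base sets intersect;
#' inosine matches anything. A site is reported when the total mismatch
#' count is at most `max_mismatch` and the 3'-most `seed_len` positions are
#' mismatch-free (polymerase extension requires a matched 3' end). Tails are
#' excluded from matching.
#'
#' @param template Inosine-free template string.
#' @param primer One-row primer tibble.
#' @param max_mismatch Maximum mismatches outside the seed (default 2).
#' @param seed_len Length of the mismatch-free 3' seed (default 5).
#' @return Tibble with 0-based half-open `start`, `end` (span of the binding
#'   region on the forward strand), `direction` and `mismatches`.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 2L,
                              seed_len = 5L) {
  stopifnot(nrow(primer) == 1L)
  bind <- binding_region(primer)
  m <- nchar(bind)
  if (seed_len > m) {
    stop("seed_len (", seed_len, ") exceeds binding-region length (", m, ")",
         call. = FALSE)
  }
  tmask <- seq_masks(template, allow_inosine = FALSE, what = "template")
  if (primer$direction == "forward") {
    pat <- bind
    seed_cols <- (m - seed_len + 1L):m # 3' end is the pattern's right edge
  } else {
    pat <- revcomp(bind)
    seed_cols <- 1L:seed_len # 3' end maps to the left edge
  }
  pm <- pattern_mismatches(tmask, seq_masks(pat, allow_inosine = TRUE))
  if (length(pm$mismatches) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          direction = character(0), mismatches = integer(0)))
  }
  seed_ok <- rowSums(pm$miss[, seed_cols, drop = FALSE]) == 0L
  keep <- which(pm$mismatches <= max_mismatch & seed_ok)
  tibble::tibble(
    start = keep - 1L,
    end = keep - 1L + m,
    direction = primer$direction,
    mismatches = pm$mismatches[keep]
  )
}

#' Extract amplicons for a primer cocktail
#'
#' Every compatible pair of a forward and a reverse binding site (forward
#' upstream of reverse, product length within bounds) yields one amplicon.
#' The amplicon carries the full primer sequences (tails included) verbatim
#' at its ends around the template interior, so its length is the tailed
#' primer lengths plus the interior length.
#'
#' @param template Template residue string.
#' @param cocktail Primer tibble with at least one `forward` and one
#'   `reverse` row.
#' @param max_mismatch,seed_len Passed to [find_primer_sites()].
#' @param min_len,max_len Product-length bounds (defaults 50 and 3000).
#' @return Tibble with columns `fwd_primer`, `rev_primer`, `start`, `end`
#'   (template span covered by the product's binding sites), `length` and
#'   `amplicon`; zero rows when no pair is found.
#' @export
extract_amplicons <- function(template, cocktail, max_mismatch = 2L,
                              seed_len = 5L, min_len = 50L, max_len = 3000L) {
  fw <- dplyr::filter(cocktail, .data$direction == "forward")
  rv <- dplyr::filter(cocktail, .data$direction == "reverse")
  stopifnot(nrow(fw) >= 1L, nrow(rv) >= 1L)
  out <- list()
  for (i in seq_len(nrow(fw))) {
    fsites <- find_primer_sites(template, fw[i, ], max_mismatch, seed_len)
    if (nrow(fsites) == 0L) next
    for (j in seq_len(nrow(rv))) {
      rsites <- find_primer_sites(template, rv[j, ], max_mismatch, seed_len)
      if (nrow(rsites) == 0L) next
      for (a in seq_len(nrow(fsites))) {
        for (b in seq_len(nrow(rsites))) {
          if (fsites$end[a] > rsites$start[b]) next
          interior <- substr(template, fsites$end[a] + 1L, rsites$start[b])
          prod <- paste0(fw$sequence[i], interior, revcomp(rv$sequence[j]))
          len <- nchar(prod)
          if (len < min_len || len > max_len) next
          out[[length(out) + 1L]] <- tibble::tibble(
            fwd_primer = fw$name[i], rev_primer = rv$name[j],
            start = fsites$start[a], end = rsites$end[b],
            length = len, amplicon = prod
          )
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(fwd_primer = character(0), rev_primer = character(0),
                          start = integer(0), end = integer(0),
                          length = integer(0), amplicon = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end)
}
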