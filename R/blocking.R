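# Dual-priming-oligonucleotide (DPO) blocking-primer outcome model.
#
# A DPO blocker is two specificity segments joined by a poly-deoxyinosine
# linker: a long "stabilizer" that anchors annealing and a short
# "determiner". A 3' C3 spacer (written as a trailing "3") makes the oligo
# non-extendable. Whether a template's amplification is blocked depends only
# on which segments find a perfect complement:
#
#   conventional (5' stabilizer, 3' determiner):
#     stabilizer matched            -> blocked (a mismatched 3' determiner
#                                      acts like the C3 spacer itself)
#     stabilizer mismatched         -> unaffected
#   reversed (5' determiner, 3' stabilizer):
#     both matched                  -> blocked
#     stabilizer only               -> arrest_only (elongation arrest:
#                                      truncates but does not stop PCR)
#     stabilizer mismatched         -> unaffected
#   non-DPO blocker with spacer:
#     full-length match             -> blocked, else unaffected

#' Parse a blocking primer
#'
#' Segments a blocking oligo at its poly-inosine linker (the single run of
#' three or more `I`) and records whether a 3' C3 spacer (trailing `3`) is
#' present. Orientation is taken from `orientation` when given, otherwise
#' inferred from the name: names containing `DPOr` are reversed
#' (5' determiner, 3' stabilizer), other `DPO` names conventional
#' (5' stabilizer, 3' determiner); oligos without a linker are non-DPO.
#'
#' @param name Blocker name.
#' @param sequence Residue string, optionally ending in `3` (C3 spacer).
#' @param orientation `"conventional"`, `"reversed"`, `"none"` (non-DPO) or
#'   `NULL` to infer from the name.
#' @return One-row tibble with the core sequence (spacer stripped), segment
#'   spans (1-based inclusive, `NA` for empty), `orientation`, `has_spacer`
#'   and `is_dpo`.
#' @examples
#' blocking_primer("COIR-blkMsa", "ACCAGAATAAGTGCTGGTAAAGA3")
#' @export
blocking_primer <- function(name, sequence, orientation = NULL) {
  sequence <- toupper(sequence)
  has_spacer <- grepl("3$", sequence)
  core <- sub("3$", "", sequence)
  seq_masks(core, allow_inosine = TRUE, what = paste0("blocker ", name))
  runs <- gregexpr("I{3,}", core)[[1]]
  is_dpo <- runs[1] != -1L
  if (is_dpo && length(runs) > 1L) {
    stop("blocker ", name, ": more than one poly-inosine linker is not ",
         "supported", call. = FALSE)
  }
  if (is.null(orientation) || is.na(orientation)) {
    orientation <- if (!is_dpo) "none"
      else if (grepl("DPOr", name)) "reversed"
      else "conventional"
  }
  orientation <- match.arg(orientation, c("conventional", "reversed", "none"))
  n <- nchar(core)
  if (is_dpo) {
    if (orientation == "none") {
      stop("blocker ", name, ": has a linker but orientation 'none'",
           call. = FALSE)
    }
    lk_start <- as.integer(runs[1])
    lk_end <- lk_start + attr(runs, "match.length")[1] - 1L
    if (lk_start == 1L || lk_end == n) {
      stop("blocker ", name, ": linker must separate two segments",
           call. = FALSE)
    }
    seg5 <- c(1L, lk_start - 1L)
    seg3 <- c(lk_end + 1L, n)
    if (orientation == "conventional") {
      stab <- seg5; det <- seg3
    } else {
      det <- seg5; stab <- seg3
    }
  } else {
    det <- c(1L, n)
    stab <- c(NA_integer_, NA_integer_)
  }
  tibble::tibble(
    name = name, core = core, orientation = orientation,
    det_start = det[1], det_end = det[2],
    stab_start = stab[1], stab_end = stab[2],
    has_spacer = has_spacer, is_dpo = is_dpo
  )
}

#' Read a blocking-primer table
#'
#' CSV with columns `name`, `sequence` and optionally `orientation`.
#'
#' @param path Path to the CSV.
#' @return Tibble of parsed blockers, one row each.
#' @export
read_blocking_primers <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"orientation" %in% names(tab)) tab$orientation <- NA_character_
  purrr::pmap_dfr(tab[, c("name", "sequence", "orientation")],
                  blocking_primer)
}

# Locate the blocker on the forward strand (blockers overlap reverse-primer
# sites, so the reverse complement of the core is searched) and report
# per-position matches of the best window in blocker coordinates.
locate_blocker <- function(template, blocker) {
  pat <- revcomp(blocker$core)
  m <- nchar(pat)
  tmask <- seq_masks(template, allow_inosine = FALSE, what = "template")
  pm <- pattern_mismatches(tmask, seq_masks(pat, allow_inosine = TRUE))
  if (length(pm$mismatches) == 0L) return(NULL)
  best <- which.min(pm$mismatches)
  # pattern column j corresponds to blocker position m - j + 1
  list(
    start = best - 1L, end = best - 1L + m,
    match = rev(!pm$miss[best, ]) # indexed by blocker position, 5' to 3'
  )
}

#' Predict the outcome of a blocking primer on a template
#'
#' Locates the blocker's best-matching window on the template and applies
#' the segment-match rules (see the orientation table in
#' [blocking_primer()]): a matched stabilizer is necessary for any effect,
#' and whether a determiner mismatch still blocks or merely arrests
#' elongation depends on the segment orientation.
#'
#' @param template Template residue string.
#' @param blocker One-row parsed blocker tibble from [blocking_primer()].
#' @return One of `"blocked"`, `"arrest_only"`, `"unaffected"`.
#' @export
blocking_outcome <- function(template, blocker) {
  stopifnot(nrow(blocker) == 1L)
  if (!blocker$has_spacer) {
    stop("extendable blocker unsupported: ", blocker$name,
         " has no 3' spacer", call. = FALSE)
  }
  loc <- locate_blocker(template, blocker)
  if (is.null(loc)) return("unaffected")
  seg_ok <- function(a, b) all(loc$match[a:b])
  if (!blocker$is_dpo) {
    return(if (all(loc$match)) "blocked" else "unaffected")
  }
  s <- seg_ok(blocker$stab_start, blocker$stab_end)
  d <- seg_ok(blocker$det_start, blocker$det_end)
  if (blocker$orientation == "conventional") {
    if (s) "blocked" else "unaffected"
  } else {
    if (s && d) "blocked" else if (s) "arrest_only" else "unaffected"
  }
}

#' Blocking outcomes across a species panel
#'
#' Applies [blocking_outcome()] to every species template and blocker, and
#' flags blockers that are predator-specific: blocked for every predator
#' template and not blocked for any other (prey) template.
#'
#' @param templates Named character vector (names = species) or tibble with
#'   columns `species`, `sequence`.
#' @param blockers Parsed blocker tibble (rows from [blocking_primer()]).
#' @param predators Character vector of predator species names (optional;
#'   needed for the specificity flag).
#' @param cocktail Optional primer tibble; when given, a column reports
#'   whether the blocker window overlaps a reverse-primer binding site.
#' @return Tibble (class `blocking_panel`) with one row per species and
#'   blocker and an `outcome` column; the per-blocker summary is in
#'   `attr(, "summary")`.
#' @export
blocking_panel <- function(templates, blockers, predators = NULL,
                           cocktail = NULL) {
  if (is.character(templates)) {
    templates <- tibble::tibble(species = names(templates),
                                sequence = unname(templates))
  }
  if (nrow(templates) == 0L) stop("empty template map", call. = FALSE)
  grid <- tidyr::expand_grid(species = templates$species,
                             blocker = blockers$name)
  if (nrow(grid) == 0L) {
    out <- tibble::tibble(species = character(0), blocker = character(0),
                          outcome = character(0))
    attr(out, "summary") <- tibble::tibble(blocker = character(0),
                                           predator_specific = logical(0))
    class(out) <- c("blocking_panel", class(out))
    return(out)
  }
  grid$outcome <- purrr::map2_chr(grid$species, grid$blocker, function(sp, bl) {
    tmpl <- templates$sequence[templates$species == sp][1]
    blocking_outcome(tmpl, blockers[blockers$name == bl, ])
  })
  if (!is.null(cocktail)) {
    grid$overlaps_reverse_primer <-
      purrr::map2_lgl(grid$species, grid$blocker, function(sp, bl) {
        tmpl <- templates$sequence[templates$species == sp][1]
        loc <- locate_blocker(tmpl, blockers[blockers$name == bl, ])
        if (is.null(loc)) return(FALSE)
        rv <- dplyr::filter(cocktail, .data$direction == "reverse")
        any(purrr::map_lgl(seq_len(nrow(rv)), function(j) {
          st <- find_primer_sites(tmpl, rv[j, ])
          any(st$start < loc$end & st$end > loc$start)
        }))
      })
  }
  summary <- if (is.null(predators)) {
    tibble::tibble(blocker = unique(grid$blocker),
                   predator_specific = NA)
  } else {
    grid |>
      dplyr::mutate(is_predator = .data$species %in% predators) |>
      dplyr::group_by(.data$blocker) |>
      dplyr::summarise(
        predator_specific =
          all(.data$outcome[.data$is_predator] == "blocked") &&
          !any(.data$outcome[!.data$is_predator] == "blocked"),
        .groups = "drop"
      )
  }
  attr(grid, "summary") <- summary
  class(grid) <- c("blocking_panel", class(grid))
  grid
}
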