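# Accessors for the data shipped with the package: the published bass
# stomach-content tables, the primer and blocking-primer sequences, a small
# restriction-enzyme catalog, and a synthetic Round Goby voucher set.

rflp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "rflpdiet", mustWork = TRUE)
  path
}

#' Prey classification and identification success by digestion rank
#'
#' Counts of bass stomach items per five-tier digestion rank ((1) empty
#' stomach through (5) fully intact prey) for Largemouth (LMB) and
#' Smallmouth Bass (SMB): items classified, visually identified, DNA
#' extracted and barcode identified. Rank-1 counts are empty stomachs, not
#' items.
#'
#' @return Tibble, one row per rank.
#' @export
bass_classification <- function() {
  readr::read_csv(rflp_extdata("classification_counts.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Prey abundance in bass stomachs (occurrence, weight, number)
#'
#' Per-prey-species occurrence (stomach counts), total wet weight and item
#' number for LMB and SMB. The coarse `Fish` and `Crayfish` rows are class
#' totals that include the identified species plus unidentifiable remains.
#'
#' @return Tibble, one row per prey taxon.
#' @export
bass_prey_table <- function() {
  readr::read_csv(rflp_extdata("prey_abundance.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Predator sample sizes and empty-stomach counts
#'
#' @return Tibble with columns `species`, `n_predators`, `n_empty`
#'   (LMB: 46 of 84 empty; SMB: 97 of 264).
#' @export
bass_stomach_counts <- function() {
  readr::read_csv(rflp_extdata("stomach_counts.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Aggregate diet table for one bass species
#'
#' Reshapes [bass_prey_table()] into the [diet_iri()] input layout, dropping
#' prey never observed in that predator.
#'
#' @param species `"LMB"` or `"SMB"`.
#' @return Tibble with columns `prey_taxon`, `occurrence`, `weight_g`,
#'   `number`, `is_coarse`.
#' @export
bass_diet <- function(species = c("SMB", "LMB")) {
  species <- match.arg(species)
  pre <- tolower(species)
  t4 <- bass_prey_table()
  out <- tibble::tibble(
    prey_taxon = t4$prey_taxon,
    occurrence = t4[[paste0(pre, "_occurrence")]],
    weight_g = t4[[paste0(pre, "_weight_g")]],
    number = t4[[paste0(pre, "_number")]],
    is_coarse = t4$is_coarse
  )
  dplyr::filter(out, .data$number > 0)
}

#' Bundled restriction-enzyme catalog
#'
#' A small catalog holding the three assay enzymes (SspI, NsiI, BglII) plus
#' common decoys. The published search ran over 263 commercial enzymes; that
#' list is not redistributed, and any user catalog in the same format is
#' accepted by [read_enzyme_catalog()].
#'
#' @return Enzyme tibble.
#' @export
bundled_enzymes <- function() {
  read_enzyme_catalog(rflp_extdata("enzymes.csv"))
}

#' Bundled PCR primers for COI and 16S barcoding
#'
#' The four primer cocktails used for fish and crayfish prey barcoding:
#' COI-3 (M13-tailed VF2_t1/FishF2_t1 forwards, FishR2_t1/FR1d_t1 reverses),
#' Folmer (LCO1490/HCO2198), orcoCOI and 16S. `tail_len` marks the
#' non-binding M13 sequencing tails.
#'
#' @param cocktail Optional cocktail name to filter on (`"COI-3"`,
#'   `"Folmer"`, `"orcoCOI"`, `"16S"`).
#' @return Primer tibble.
#' @export
bundled_primers <- function(cocktail = NULL) {
  p <- read_primer_table(rflp_extdata("primers.csv"))
  if (!is.null(cocktail)) {
    p <- p[p$cocktail == cocktail, ]
    if (nrow(p) == 0L) stop("unknown cocktail: ", cocktail, call. = FALSE)
  }
  p
}

#' Bundled COI blocking primers for Largemouth Bass
#'
#' The three predator blockers: a plain spacer-capped oligo (COIR-blkMsa), a
#' conventional DPO (5' stabilizer / 3' determiner, COIR-DPO-blkMsa) and a
#' reversed DPO (5' determiner / 3' stabilizer, COIR-DPOr-blkMsa).
#'
#' @return Parsed blocker tibble (see [blocking_primer()]).
#' @export
bundled_blocking_primers <- function() {
  read_blocking_primers(rflp_extdata("blocking_primers.csv"))
}

#' Path to the synthetic Round Goby voucher FASTA
#'
#' A synthetic stand-in for the 24-voucher Round Goby COI reference set used
#' to design the RFLP test (the real records live in public barcode
#' repositories and are not redistributed). Generated with
#' [simulate_voucher_set()] at a fixed seed: all 24 target vouchers carry an
#' SspI site at one shared locus and the non-target species carry none, even
#' under liberal matching.
#'
#' @return File path; read with [read_voucher_fasta()].
#' @export
goby_voucher_fasta <- function() {
  rflp_extdata("goby_vouchers_synthetic.fasta")
}
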