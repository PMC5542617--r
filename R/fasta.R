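# Voucher-set ingestion. A voucher set is a plain tibble with one row per
# reference barcode: id, species, residues. BOLD-style exports carry the
# binomial in the second pipe-delimited header field.

normalize_species <- function(x) {
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

parse_species <- function(headers, header_dialect) {
  if (identical(header_dialect, "plain")) {
    return(rep("", length(headers)))
  }
  if (identical(header_dialect, "bold_pipe")) {
    sp <- vapply(strsplit(headers, "|", fixed = TRUE), function(f) {
      if (length(f) >= 2L) f[2L] else ""
    }, character(1))
    return(normalize_species(sp))
  }
  if (startsWith(header_dialect, "regex:")) {
    pat <- sub("^regex:", "", header_dialect)
    m <- regmatches(headers, regexec(pat, headers))
    sp <- vapply(m, function(g) if (length(g) >= 2L) g[2L] else "", character(1))
    return(normalize_species(sp))
  }
  stop("unknown header_dialect: ", header_dialect, call. = FALSE)
}

#' Read a species-labelled voucher FASTA
#'
#' Reads a FASTA file of barcode vouchers into a tibble with columns `id`,
#' `species` and `residues`. Residues are upper-cased and `U` is mapped to
#' `T`, so one canonical DNA alphabet is used downstream. Records whose
#' species label cannot be parsed get `species = ""` and a warning.
#'
#' @param path Path to a FASTA file.
#' @param header_dialect How the species label is encoded in the header:
#'   `"bold_pipe"` (pipe-delimited, species in field 2, the BOLD export
#'   layout), `"plain"` (no species label), or `"regex:<pattern>"` with one
#'   capture group extracting the binomial.
#' @param min_length Optional minimum sequence length filter (default none).
#' @param max_n Optional maximum count of `N` residues per record (default
#'   none). The voucher sets used for assay design are typically used
#'   unfiltered; both filters default to off.
#' @return A tibble with columns `id`, `species`, `residues`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x|Neogobius melanostomus|COI-5P", "AATATT"), fa)
#' read_voucher_fasta(fa)
#' @export
read_voucher_fasta <- function(path, header_dialect = "bold_pipe",
                               min_length = NULL, max_n = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no records in ", path, call. = FALSE)
  }
  ids <- names(set)
  residues <- unname(toupper(as.character(set)))
  residues <- chartr("U", "T", residues)
  for (i in seq_along(residues)) {
    if (nchar(residues[i]) == 0L) {
      stop("record '", ids[i], "' is empty", call. = FALSE)
    }
    seq_masks(residues[i], allow_inosine = FALSE,
              what = paste0("record '", ids[i], "'"))
  }
  species <- parse_species(ids, header_dialect)
  if (!identical(header_dialect, "plain") && any(species == "")) {
    warning(sum(species == ""), " record(s) with unparseable species label; ",
            "assigned to the empty-species bucket", call. = FALSE)
  }
  if (identical(header_dialect, "bold_pipe")) {
    # keep the accession-like first field as the record id
    ids <- vapply(strsplit(ids, "|", fixed = TRUE), `[[`, character(1), 1L)
  }
  out <- tibble::tibble(id = ids, species = species, residues = residues)
  if (!is.null(min_length)) {
    out <- dplyr::filter(out, nchar(.data$residues) >= min_length)
  }
  if (!is.null(max_n)) {
    out <- dplyr::filter(out, stringr::str_count(.data$residues, "N") <= max_n)
  }
  out
}

#' Write a voucher set to FASTA
#'
#' Headers are written as `id` for unlabelled records and `id|species|COI-5P`
#' otherwise, so a write/read round trip through the `bold_pipe` dialect is
#' the identity on (id, species, residues). Sequences wrap at 80 columns.
#'
#' @param vouchers Tibble with columns `id`, `species`, `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voucher_fasta <- function(vouchers, path) {
  stopifnot(all(c("id", "species", "residues") %in% names(vouchers)))
  headers <- ifelse(vouchers$species == "",
                    vouchers$id,
                    paste(vouchers$id, vouchers$species, "COI-5P", sep = "|"))
  set <- Biostrings::BStringSet(vouchers$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Per-species voucher counts
#'
#' @param vouchers A voucher tibble.
#' @return Tibble with columns `species`, `n`, in first-appearance order.
#' @export
species_counts <- function(vouchers) {
  dplyr::count(vouchers, species = factor(.data$species,
                                          levels = unique(.data$species))) |>
    dplyr::mutate(species = as.character(.data$species))
}
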