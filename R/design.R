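# Automated diagnostic-RFLP design over a voucher library: cut matrix,
# single-enzyme diagnostics, parallel-digest enzyme sets, predicted gel
# patterns and error rates against corroborated identifications.
#
# The diagnostic predicate is deliberately asymmetric: the target species
# must be cut under conservative matching (every resolution of every target
# voucher is cut) while non-targets must be uncut even under liberal
# matching (no resolution of any non-target voucher is cut). A diagnostic
# claim has to survive worst-case ambiguity in both directions.

#' Species-by-enzyme cut matrix
#'
#' Counts, per species and enzyme, how many vouchers carry at least one
#' recognition site under conservative and under liberal matching.
#'
#' @param vouchers Voucher tibble (`id`, `species`, `residues`).
#' @param catalog Enzyme tibble.
#' @return Tibble (class `cut_matrix`) with columns `species`, `enzyme`,
#'   `n_conservative`, `n_liberal`, `n_total`; species in first-appearance
#'   order, enzymes in catalog order.
#' @export
cut_matrix <- function(vouchers, catalog) {
  stopifnot(nrow(vouchers) >= 1L, nrow(catalog) >= 1L)
  species <- unique(vouchers$species)
  tmasks <- lapply(vouchers$residues, seq_masks, allow_inosine = FALSE,
                   what = "voucher")
  cells <- list()
  for (e in seq_len(nrow(catalog))) {
    motif <- catalog$recognition[e]
    pats <- list(seq_masks(motif))
    rc <- revcomp(motif)
    if (!identical(rc, motif)) pats <- c(pats, list(seq_masks(rc)))
    has_site <- function(tm, mode) {
      any(vapply(pats, function(p) length(scan_motif(tm, p, mode)) > 0L,
                 logical(1)))
    }
    cons <- vapply(tmasks, has_site, logical(1), mode = "conservative")
    lib <- cons # conservative hits are liberal hits
    if (any(!cons)) {
      lib[!cons] <- vapply(tmasks[!cons], has_site, logical(1),
                           mode = "liberal")
    }
    cells[[e]] <- tibble::tibble(
      species = factor(vouchers$species, levels = species),
      enzyme = catalog$name[e],
      cons = cons, lib = lib
    )
  }
  out <- dplyr::bind_rows(cells) |>
    dplyr::group_by(.data$species, .data$enzyme) |>
    dplyr::summarise(n_conservative = sum(.data$cons),
                     n_liberal = sum(.data$lib),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(species = as.character(.data$species),
                  enzyme = factor(.data$enzyme, levels = catalog$name)) |>
    dplyr::arrange(.data$enzyme) |>
    dplyr::mutate(enzyme = as.character(.data$enzyme))
  class(out) <- c("cut_matrix", class(out))
  out
}

#' Enzymes diagnostic for one target species
#'
#' An enzyme qualifies when it cuts every target voucher under conservative
#' matching and no voucher of any other species under liberal matching.
#'
#' @param matrix A [cut_matrix()] tibble.
#' @param target Target species name.
#' @return Character vector of qualifying enzyme names, in catalog order.
#' @export
diagnostic_enzymes <- function(matrix, target) {
  if (!target %in% matrix$species) {
    stop("unknown target species: ", target, call. = FALSE)
  }
  per <- matrix |>
    dplyr::mutate(enzyme = factor(.data$enzyme,
                                  levels = unique(.data$enzyme))) |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(
      target_complete = all(.data$n_conservative[.data$species == target] ==
                              .data$n_total[.data$species == target]),
      nontarget_clean = sum(.data$n_liberal[.data$species != target]) == 0L,
      .groups = "drop"
    )
  as.character(per$enzyme[per$target_complete & per$nontarget_clean])
}

#' Full diagnostic report for a target species
#'
#' Wraps [diagnostic_enzymes()] and adds near-misses: enzymes failing
#' exactly one half of the diagnostic predicate, with the offending counts.
#'
#' @inheritParams diagnostic_enzymes
#' @return List (class `rflp_diagnostics`) with elements `target`,
#'   `qualifying` and `near_misses` (tibble: enzyme, n_target_missed,
#'   n_nontarget_cut).
#' @export
rflp_diagnostics <- function(matrix, target) {
  qualifying <- diagnostic_enzymes(matrix, target)
  per <- matrix |>
    dplyr::mutate(enzyme = factor(.data$enzyme,
                                  levels = unique(.data$enzyme))) |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(
      n_target_missed = sum(.data$n_total[.data$species == target]) -
        sum(.data$n_conservative[.data$species == target]),
      n_nontarget_cut = sum(.data$n_liberal[.data$species != target]),
      .groups = "drop"
    ) |>
    dplyr::mutate(enzyme = as.character(.data$enzyme))
  near <- dplyr::filter(
    per,
    xor(.data$n_target_missed == 0L, .data$n_nontarget_cut == 0L),
    !.data$enzyme %in% qualifying
  )
  structure(list(target = target, qualifying = qualifying,
                 near_misses = near),
            class = "rflp_diagnostics")
}

#' @export
print.rflp_diagnostics <- function(x, ...) {
  cat("Diagnostic RFLP search for", x$target, "\n")
  cat("  qualifying enzymes:",
      if (length(x$qualifying)) paste(x$qualifying, collapse = ", ")
      else "(none)", "\n")
  cat("  near-misses:", nrow(x$near_misses), "\n")
  invisible(x)
}

#' Minimal parallel-digest enzyme sets for several target species
#'
#' Enumerates enzyme subsets of size at most `max_set_size` in which every
#' target species has all its vouchers cut (conservative) by at least one
#' member while no non-target voucher is cut (liberal) by any member.
#' Enzymes that cut any non-target are pruned before enumeration. Only
#' minimal sets are returned (no returned set contains another), ordered by
#' size then catalog order.
#'
#' @param matrix A [cut_matrix()] tibble.
#' @param targets Character vector of target species.
#' @param max_set_size Largest subset size to enumerate (default 2, the
#'   two-enzyme parallel-digest use case).
#' @return List of character vectors of enzyme names.
#' @export
parallel_digest_sets <- function(matrix, targets, max_set_size = 2L) {
  stopifnot(max_set_size >= 1L)
  if (!all(targets %in% matrix$species)) {
    stop("targets not in matrix: ",
         paste(setdiff(targets, matrix$species), collapse = ", "),
         call. = FALSE)
  }
  enz <- unique(matrix$enzyme)
  info <- lapply(enz, function(e) {
    sub <- matrix[matrix$enzyme == e, ]
    list(
      clean = sum(sub$n_liberal[!sub$species %in% targets]) == 0L,
      covers = sub$species[sub$species %in% targets &
                             sub$n_conservative == sub$n_total]
    )
  })
  names(info) <- enz
  cand <- enz[vapply(info, function(x) x$clean && length(x$covers) > 0L,
                     logical(1))]
  results <- list()
  for (k in seq_len(min(max_set_size, length(cand)))) {
    for (combo in utils::combn(cand, k, simplify = FALSE)) {
      if (any(vapply(results, function(r) all(r %in% combo), logical(1)))) {
        next # a smaller qualifying subset exists
      }
      covered <- unique(unlist(lapply(combo, function(e) info[[e]]$covers)))
      if (all(targets %in% covered)) {
        results[[length(results) + 1L]] <- combo
      }
    }
  }
  results
}

#' Predicted RFLP gel patterns for target vouchers
#'
#' Extracts the cocktail amplicon from each voucher, digests it, and tallies
#' the distinct fragment patterns. More than one pattern flags a polymorphic
#' cut site in the target population.
#'
#' @param vouchers Voucher tibble; rows must contain both primer sites, or
#'   be pre-extracted amplicons (pass `cocktail = NULL`).
#' @param enzyme One-row enzyme tibble.
#' @param cocktail Primer tibble, or `NULL` when `vouchers$residues` already
#'   are amplicons.
#' @param match_mode Passed to [digest_fragments()].
#' @param ... Passed to [extract_amplicons()].
#' @return Tibble (class `rflp_pattern`) with `pattern` (comma-joined
#'   lengths), `fragments` (list column) and `n_vouchers`;
#'   `attr(, "polymorphic")` is `TRUE` when more than one pattern occurs and
#'   `attr(, "n_no_amplicon")` counts vouchers without a recoverable product.
#' @export
predict_rflp_pattern <- function(vouchers, enzyme, cocktail = NULL,
                                 match_mode = "conservative", ...) {
  frags <- list()
  skipped <- 0L
  for (i in seq_len(nrow(vouchers))) {
    amp <- if (is.null(cocktail)) {
      vouchers$residues[i]
    } else {
      hits <- extract_amplicons(vouchers$residues[i], cocktail, ...)
      if (nrow(hits) == 0L) {
        skipped <- skipped + 1L
        next
      }
      hits$amplicon[1]
    }
    frags[[length(frags) + 1L]] <- digest_fragments(amp, enzyme, match_mode)
  }
  if (length(frags) == 0L) {
    stop("no amplicon recoverable from any voucher", call. = FALSE)
  }
  key <- vapply(frags, paste, character(1), collapse = ",")
  out <- tibble::tibble(pattern = key, fragments = frags) |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(fragments = .data$fragments[1],
                     n_vouchers = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_vouchers))
  attr(out, "polymorphic") <- nrow(out) > 1L
  attr(out, "n_no_amplicon") <- skipped
  class(out) <- c("rflp_pattern", class(out))
  out
}

#' First- and second-order error of an RFLP species test
#'
#' Compares RFLP calls with corroborated (visual and/or sequence)
#' identifications. The first-order error is the false-positive rate
#' (positives among true non-targets); the second-order error is the
#' false-negative rate (negatives among true targets). An empty denominator
#' yields `NA`, not 0.
#'
#' @param records Tibble with columns `prey_id`, `rflp_call`
#'   (`"positive"`/`"negative"`) and `truth_call` (species).
#' @param target Target species of the test.
#' @return List (class `rflp_error`) with `first_order`, `second_order` and
#'   a `confusion` tibble.
#' @export
estimate_rflp_error <- function(records, target) {
  stopifnot(nrow(records) >= 1L,
            all(c("rflp_call", "truth_call") %in% names(records)))
  if (any(records$truth_call == "")) {
    stop("truth_call must be non-empty", call. = FALSE)
  }
  is_target <- records$truth_call == target
  pos <- records$rflp_call == "positive"
  fo_den <- sum(!is_target)
  so_den <- sum(is_target)
  structure(list(
    first_order = if (fo_den > 0L) sum(pos & !is_target) / fo_den else NA_real_,
    second_order = if (so_den > 0L) sum(!pos & is_target) / so_den else NA_real_,
    confusion = dplyr::count(
      tibble::tibble(
        rflp = records$rflp_call,
        truth = ifelse(is_target, "target", "non-target")
      ),
      .data$rflp, .data$truth
    )
  ), class = "rflp_error")
}
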