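# Stomach-content diet metrics: percent occurrence / weight / number, the
# index of relative importance IRI_i = %O_i * (%W_i + %N_i) normalized to
# %IRI across identified prey species, and Hill-number diversity profiles.
#
# Two table shapes are supported. Aggregate tables (diet_iri) mirror the
# published layout: one row per prey species with occurrence, total weight
# and item number, plus coarse "Fish"/"Crayfish" rows that are class totals
# including the identified species. Record-level tables (diet_composition)
# carry one prey item per row; there the coarse rows aggregate only the
# unidentified remains, and the including-unidentified denominators are the
# sums over all rows.

COARSE_CLASSES <- c("Fish", "Crayfish", "unknown")

#' Index of relative importance from an aggregate diet table
#'
#' @param diet Tibble with columns `prey_taxon`, `occurrence`, `weight_g`,
#'   `number` and logical `is_coarse`.
#' @param n_predators Number of predators sampled.
#' @param n_empty Number of empty stomachs among them.
#' @param occ_denom Percent-occurrence denominator: `"non_empty"` stomachs
#'   (default) or `"all"` predators. %IRI is invariant to this choice.
#' @param include_unidentified Use weight/number denominators that include
#'   unidentifiable remains (default `TRUE`); identified-only denominators
#'   otherwise.
#' @param coarse_are_totals Whether coarse rows are class totals that already
#'   include the identified species of the class (the published-table
#'   convention, default `TRUE`) or only the unidentified remains (the
#'   record-level convention).
#' @return Tibble (class `diet_table`) adding `pct_occurrence`, `pct_weight`,
#'   `pct_number`, `iri` and `pct_iri` (both `NA` on coarse rows, which never
#'   get IRI rows); the denominators used are stored as attributes.
#' @examples
#' diet_iri(bass_diet("SMB"), n_predators = 264, n_empty = 97)
#' @export
diet_iri <- function(diet, n_predators, n_empty,
                     occ_denom = c("non_empty", "all"),
                     include_unidentified = TRUE,
                     coarse_are_totals = TRUE) {
  occ_denom <- match.arg(occ_denom)
  stopifnot(all(c("prey_taxon", "occurrence", "weight_g", "number") %in%
                  names(diet)))
  if (!"is_coarse" %in% names(diet)) {
    diet$is_coarse <- diet$prey_taxon %in% COARSE_CLASSES
  }
  if (!any(!diet$is_coarse)) stop("no identified species rows", call. = FALSE)
  n_occ <- if (occ_denom == "non_empty") n_predators - n_empty else n_predators
  sp <- !diet$is_coarse
  if (include_unidentified && any(diet$is_coarse)) {
    if (coarse_are_totals) {
      w_den <- sum(diet$weight_g[diet$is_coarse])
      n_den <- sum(diet$number[diet$is_coarse])
    } else {
      w_den <- sum(diet$weight_g)
      n_den <- sum(diet$number)
    }
  } else {
    w_den <- sum(diet$weight_g[sp])
    n_den <- sum(diet$number[sp])
  }
  if (n_occ <= 0 || w_den <= 0 || n_den <= 0) {
    stop("zero denominator (occurrence ", n_occ, ", weight ", w_den,
         ", number ", n_den, ")", call. = FALSE)
  }
  out <- diet |>
    dplyr::mutate(
      pct_occurrence = 100 * .data$occurrence / n_occ,
      pct_weight = 100 * .data$weight_g / w_den,
      pct_number = 100 * .data$number / n_den,
      iri = ifelse(.data$is_coarse, NA_real_,
                   .data$pct_occurrence * (.data$pct_weight + .data$pct_number))
    )
  out$pct_iri <- ifelse(out$is_coarse, NA_real_,
                        100 * out$iri / sum(out$iri[sp]))
  attr(out, "denominators") <- list(occurrence = n_occ, weight_g = w_den,
                                    number = n_den)
  attr(out, "n_predators") <- n_predators
  attr(out, "n_empty") <- n_empty
  class(out) <- c("diet_table", class(out))
  out
}

#' Index of relative importance from prey records
#'
#' Aggregates a one-row-per-prey-item table to per-species occurrence
#' (distinct stomachs), total weight and item count, then applies
#' [diet_iri()]. Records whose taxon is a coarse class (`Fish`, `Crayfish`,
#' `unknown`) contribute to the including-unidentified denominators but
#' never get an IRI row. Rank-1 records mark empty stomachs.
#'
#' @param records Tibble with columns `predator_id`, `prey_taxon`,
#'   `digestion_rank`, `wet_weight_g` (other columns are ignored).
#' @inheritParams diet_iri
#' @return A `diet_table` tibble (see [diet_iri()]).
#' @export
diet_composition <- function(records, occ_denom = c("non_empty", "all"),
                             include_unidentified = TRUE) {
  occ_denom <- match.arg(occ_denom)
  n_predators <- dplyr::n_distinct(records$predator_id)
  empties <- records$digestion_rank == 1L
  n_empty <- dplyr::n_distinct(records$predator_id[empties])
  items <- records[!empties, ]
  if (nrow(items) == 0L) stop("no identified prey records", call. = FALSE)
  diet <- items |>
    dplyr::group_by(prey_taxon = .data$prey_taxon) |>
    dplyr::summarise(
      occurrence = dplyr::n_distinct(.data$predator_id),
      weight_g = sum(.data$wet_weight_g),
      number = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(is_coarse = .data$prey_taxon %in% COARSE_CLASSES)
  diet_iri(diet, n_predators, n_empty, occ_denom = occ_denom,
           include_unidentified = include_unidentified,
           coarse_are_totals = FALSE)
}

#' Hill number (effective number of species)
#'
#' The Hill number of order `q` is `(sum p_i^q)^(1/(1-q))`, with the
#' Shannon limit `exp(-sum p_i log p_i)` at `q = 1`. `q = 0` is species
#' richness, `q = 2` the inverse Simpson concentration. The plug-in
#' (empirical) form is computed; no small-sample bias correction is applied.
#'
#' @param proportions Positive proportions summing to 1 (tolerance 1e-9).
#' @param q Diversity order(s), non-negative; may be a vector.
#' @return Numeric vector of effective species numbers, one per `q`.
#' @examples
#' hill_diversity(rep(0.25, 4), q = c(0, 1, 2))
#' @export
hill_diversity <- function(proportions, q) {
  if (any(proportions <= 0)) {
    stop("proportions must be strictly positive", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")",
         call. = FALSE)
  }
  stopifnot(all(q >= 0))
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-12) {
      exp(-sum(proportions * log(proportions)))
    } else {
      sum(proportions^qq)^(1 / (1 - qq))
    }
  }, numeric(1))
}

#' Diversity profiles of identified prey per predator species
#'
#' Builds the numerical prey composition (identified prey only: coarse
#' classes are dropped) for each predator species and evaluates the Hill
#' number over a grid of orders.
#'
#' @param counts Tibble with columns `predator_species`, `prey_taxon` and
#'   either a count column `n` or one row per prey item.
#' @param q_grid Diversity orders (default `seq(0, 3, by = 0.1)`).
#' @return Tibble (class `diversity_profile`) with columns
#'   `predator_species`, `q`, `D`.
#' @export
diversity_profile <- function(counts, q_grid = seq(0, 3, by = 0.1)) {
  stopifnot(all(c("predator_species", "prey_taxon") %in% names(counts)))
  if (!"n" %in% names(counts)) {
    counts <- dplyr::count(counts, .data$predator_species, .data$prey_taxon)
  }
  counts <- dplyr::filter(counts, !.data$prey_taxon %in% COARSE_CLASSES,
                          .data$n > 0)
  if (nrow(counts) == 0L) {
    stop("no identified prey for any predator", call. = FALSE)
  }
  out <- counts |>
    dplyr::group_by(.data$predator_species) |>
    dplyr::reframe(q = q_grid,
                   D = hill_diversity(.data$n / sum(.data$n), q_grid))
  class(out) <- c("diversity_profile", class(out))
  out
}

#' Relative diversity curve between two predators
#'
#' Ratio of two predators' diversity profiles over the shared order grid,
#' with the grid point where the ratio peaks.
#'
#' @param profile A [diversity_profile()] tibble.
#' @param numerator,denominator Predator species names.
#' @return Tibble with columns `q` and `ratio`; `attr(, "argmax")` holds the
#'   grid order maximizing the ratio and `attr(, "max_ratio")` its value.
#' @export
diversity_ratio <- function(profile, numerator, denominator) {
  num <- profile[profile$predator_species == numerator, ]
  den <- profile[profile$predator_species == denominator, ]
  stopifnot(nrow(num) > 0L, nrow(den) > 0L, all(num$q == den$q))
  out <- tibble::tibble(q = num$q, ratio = num$D / den$D)
  best <- which.max(out$ratio)
  attr(out, "argmax") <- out$q[best]
  attr(out, "max_ratio") <- out$ratio[best]
  out
}

#' Descriptive stomach-content summaries
#'
#' Means and standard errors of prey items per stomach (empty stomachs count
#' as zero items), prey wet weight per item, and total wet weight per
#' stomach, plus the percent of empty stomachs, per predator species. Items
#' include unidentifiable remains. SE is the sample standard deviation over
#' the square root of n.
#'
#' @param records Prey-record tibble (`predator_id`, `predator_species`,
#'   `digestion_rank`, `wet_weight_g`).
#' @return One row per predator species.
#' @export
stomach_summaries <- function(records) {
  stopifnot(nrow(records) >= 1L)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  records |>
    dplyr::group_by(.data$predator_species) |>
    dplyr::group_modify(function(g, key) {
      per_stomach <- g |>
        dplyr::group_by(.data$predator_id) |>
        dplyr::summarise(
          n_items = sum(.data$digestion_rank > 1L),
          total_weight = sum(.data$wet_weight_g[.data$digestion_rank > 1L]),
          .groups = "drop"
        )
      items <- g[g$digestion_rank > 1L, ]
      tibble::tibble(
        n_predators = nrow(per_stomach),
        n_empty = sum(per_stomach$n_items == 0L),
        pct_empty = 100 * mean(per_stomach$n_items == 0L),
        mean_items_per_stomach = mean(per_stomach$n_items),
        se_items_per_stomach = se(per_stomach$n_items),
        mean_item_weight_g = if (nrow(items)) mean(items$wet_weight_g)
          else 0,
        se_item_weight_g = if (nrow(items) > 1L) se(items$wet_weight_g)
          else NA_real_,
        mean_stomach_weight_g = mean(per_stomach$total_weight),
        se_stomach_weight_g = se(per_stomach$total_weight)
      )
    }) |>
    dplyr::ungroup()
}

#' Trophic position from a nitrogen isotope ratio
#'
#' `TP = (d15N - baseline) / enrichment + 2`: the baseline organism sits at
#' trophic position 2 and each `enrichment` (per-mille) step of d15N adds
#' one level.
#'
#' @param d15N Consumer nitrogen isotope ratio, per mille.
#' @param baseline Baseline d15N, per mille (default 8.5).
#' @param enrichment Per-trophic-level enrichment, per mille (default 3.4).
#' @return Trophic position (unitless); vectorized over `d15N`.
#' @examples
#' trophic_position(8.5)
#' trophic_position(15.64)
#' @export
trophic_position <- function(d15N, baseline = 8.5, enrichment = 3.4) {
  if (enrichment <= 0) stop("enrichment must be positive", call. = FALSE)
  (d15N - baseline) / enrichment + 2
}
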