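# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a diet table
#'
#' @param x A `diet_table` from [diet_iri()] or [diet_composition()].
#' @param ... Unused.
#' @return The table as a plain tibble.
#' @export
tidy.diet_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diet_table")
  attr(out, "denominators") <- NULL
  attr(out, "n_predators") <- NULL
  attr(out, "n_empty") <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of a diet table
#'
#' Reports the denominators used, the dominant prey species with its %IRI,
#' and the per-stomach descriptive means implied by the aggregate totals
#' (items per stomach and weight per stomach over all predators including
#' empty ones, mean weight per item).
#'
#' @param x A `diet_table`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.diet_table <- function(x, ...) {
  den <- attr(x, "denominators")
  n_pred <- attr(x, "n_predators")
  n_empty <- attr(x, "n_empty")
  sp <- x[!x$is_coarse, ]
  top <- sp[which.max(sp$pct_iri), ]
  tibble::tibble(
    n_species = nrow(sp),
    n_predators = n_pred,
    n_empty = n_empty,
    pct_empty = 100 * n_empty / n_pred,
    occurrence_denom = den$occurrence,
    weight_denom_g = den$weight_g,
    number_denom = den$number,
    dominant_taxon = top$prey_taxon,
    dominant_pct_iri = top$pct_iri,
    mean_items_per_stomach = den$number / n_pred,
    mean_item_weight_g = den$weight_g / den$number,
    mean_stomach_weight_g = den$weight_g / n_pred
  )
}

#' Tidy a diversity profile
#'
#' @param x A `diversity_profile`.
#' @param ... Unused.
#' @return Plain tibble with `predator_species`, `q`, `D`.
#' @export
tidy.diversity_profile <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "diversity_profile")
  tibble::as_tibble(out)
}

#' Per-predator summary of a diversity profile
#'
#' Richness (`q = 0`) and the Shannon (`q = 1`) and Simpson (`q = 2`) Hill
#' numbers, interpolated from the profile grid where available.
#'
#' @param x A `diversity_profile`.
#' @param ... Unused.
#' @return One row per predator species.
#' @export
glance.diversity_profile <- function(x, ...) {
  at_q <- function(d, qq) {
    hit <- which(abs(d$q - qq) < 1e-9)
    if (length(hit)) d$D[hit[1]] else NA_real_
  }
  x |>
    dplyr::group_by(.data$predator_species) |>
    dplyr::group_modify(function(g, key) {
      tibble::tibble(richness = at_q(g, 0), D1 = at_q(g, 1), D2 = at_q(g, 2))
    }) |>
    dplyr::ungroup()
}

#' Tidy an RFLP diagnostics report
#'
#' One row per enzyme mentioned in the report: qualifying enzymes first,
#' then near-misses with their offending counts.
#'
#' @param x An `rflp_diagnostics` object.
#' @param ... Unused.
#' @return Tibble with `enzyme`, `qualifies`, `n_target_missed`,
#'   `n_nontarget_cut`.
#' @export
tidy.rflp_diagnostics <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(enzyme = x$qualifying, qualifies = TRUE,
                   n_target_missed = 0L, n_nontarget_cut = 0L),
    dplyr::mutate(x$near_misses, qualifies = FALSE) |>
      dplyr::select("enzyme", "qualifies", "n_target_missed",
                    "n_nontarget_cut")
  )
}

#' One-row summary of an RFLP diagnostics report
#'
#' @param x An `rflp_diagnostics` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.rflp_diagnostics <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_qualifying = length(x$qualifying),
    n_near_misses = nrow(x$near_misses)
  )
}
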