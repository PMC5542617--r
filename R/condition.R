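# Fish body-condition indices: relative weight against a species-specific
# standard-weight power law, and Fulton's condition factor.

#' Standard-weight parameters for black bass
#'
#' Coefficients of `log10 Ws = intercept + exponent * log10 L` with total
#' length `L` in mm and standard weight `Ws` in g: Largemouth Bass
#' `Ws = 10^-5.528 * L^3.273`, Smallmouth Bass `Ws = 10^-5.329 * L^3.200`.
#'
#' @return Tibble with columns `species`, `intercept`, `exponent`.
#' @export
standard_weight_params <- function() {
  tibble::tibble(
    species = c("LMB", "SMB"),
    intercept = c(-5.528, -5.329),
    exponent = c(3.273, 3.200)
  )
}

#' Relative weight
#'
#' Fish weight as a percent of the length-specific standard weight,
#' `Wr = 100 * W / Ws(L)` with `Ws(L) = 10^intercept * L^exponent`.
#'
#' @param total_length_mm Total length, mm.
#' @param weight_g Weight, g.
#' @param species `"LMB"` or `"SMB"` (looked up in `params`).
#' @param params Standard-weight parameter table (default
#'   [standard_weight_params()]).
#' @return Relative weight, percent; vectorized.
#' @export
relative_weight <- function(total_length_mm, weight_g, species,
                            params = standard_weight_params()) {
  if (any(total_length_mm <= 0) || any(weight_g <= 0)) {
    stop("length and weight must be positive", call. = FALSE)
  }
  row <- params[params$species == species, ]
  if (nrow(row) != 1L) stop("unknown species: ", species, call. = FALSE)
  ws <- 10^row$intercept * total_length_mm^row$exponent
  100 * weight_g / ws
}

#' Fulton's condition factor
#'
#' `K = constant * W / L^3`. With weight in g and fork length in cm the
#' conventional constant is 100; it is configurable so unit-consistent
#' (kg, m) inputs with the matching constant give the same K.
#'
#' @param weight_g Weight (g by default convention).
#' @param fork_length_cm Fork length (cm by default convention).
#' @param constant Scaling constant (default 100).
#' @return Condition factor; vectorized.
#' @examples
#' fulton_k(1000, 10)
#' @export
fulton_k <- function(weight_g, fork_length_cm, constant = 100) {
  if (any(weight_g <= 0) || any(fork_length_cm <= 0)) {
    stop("weight and length must be positive", call. = FALSE)
  }
  constant * weight_g / fork_length_cm^3
}
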