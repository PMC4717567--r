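#' Per-species ovipositor summaries
#'
#' Collapses individual measurements to the two species-level quantities the
#' comparative analysis works with: AOS, the median absolute ovipositor-sheath
#' length (micrometres), and ROS, the median of the per-individual ratio of
#' sheath length to metatibia length (dimensionless; the ratio is computed
#' individual by individual, then the species median of the ratios is taken).
#'
#' @param records trait records as returned by [read_trait_table()] (or any
#'   data frame passing [validate_trait_records()]).
#' @return a tibble with one row per species, in canonical label order:
#'   `species`, `n_individuals`, `aos_median`, `ros_median`.
#' @examples
#' recs <- tibble::tibble(
#'   species = "sp1", individual_id = c("a", "b"),
#'   sheath_length = c(400, 600), metatibia_length = c(500, 500)
#' )
#' species_summaries(recs) # AOS 500, ROS 1
#' @export
species_summaries <- function(records) {
  records <- validate_trait_records(records)
  out <- records |>
    mutate(ros = .data$sheath_length / .data$metatibia_length) |>
    group_by(.data$species) |>
    summarise(n_individuals = dplyr::n(),
              aos_median = median(.data$sheath_length),
              ros_median = median(.data$ros),
              .groups = "drop")
  out[order(out$species, method = "radix"), ]
}

#' A validated binary trait vector
#'
#' The common currency of the phylogenetic-signal tests: one 0/1 state per
#' species, with a trait name. Stored as a tibble (`species`, `state`) with
#' a `trait_name` attribute.
#'
#' @param species character vector of unique species labels.
#' @param state integer/logical vector of 0/1 states, same length.
#' @param trait_name single string naming the trait.
#' @return a `binary_trait` tibble in canonical label order.
#' @export
binary_trait <- function(species, state, trait_name = "trait") {
  species <- as.character(species)
  if (anyDuplicated(species) || any(!nzchar(species)) || anyNA(species)) {
    abort("species labels must be unique, non-empty and non-missing.")
  }
  state <- as.integer(state)
  if (length(state) != length(species) || anyNA(state) ||
      !all(state %in% c(0L, 1L))) {
    abort("states must be 0/1, one per species.")
  }
  ord <- order(species, method = "radix")
  structure(tibble(species = species[ord], state = state[ord]),
            trait_name = as.character(trait_name)[1],
            class = c("binary_trait", class(tibble())))
}

as_binary_trait <- function(x, trait_name = "trait") {
  if (inherits(x, "binary_trait")) return(x)
  if (is.data.frame(x)) return(binary_trait(x$species, x$state, trait_name))
  if (!is.null(names(x))) return(binary_trait(names(x), x, trait_name))
  abort("cannot interpret input as a binary trait (need names or columns).")
}

#' Dichotomize a continuous species trait at its third quartile
#'
#' Species whose value strictly exceeds the third quartile of the values are
#' scored 1 ("long"); ties at exactly Q3 and everything below are scored 0
#' ("short"). The quartile is the linear-interpolation estimator at position
#' `1 + 0.75 * (n - 1)` over the species values themselves
#' ([stats::quantile()] type 7), so for 19 distinct values exactly 5 species
#' are "long", or 4 when a tie straddles the interpolation interval.
#'
#' @param values named numeric vector (names = species), or a data frame with
#'   columns `species` and `value`. At least 4 species are required.
#' @param trait_name name recorded on the returned trait.
#' @return a [binary_trait()] with attributes `q3` (the threshold used),
#'   `quartile_type` (7) and `all_equal` (`TRUE`, with a warning, when every
#'   value is identical and the vector is all-zero).
#' @export
binarize_by_quartile <- function(values, trait_name = "trait") {
  if (is.data.frame(values)) {
    check_columns(values, c("species", "value"), "trait value table")
    values <- setNames(values$value, values$species)
  }
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    abort("values must be named by unique species.")
  }
  if (anyNA(values) || any(!is.finite(values))) abort("values must be finite.")
  n <- length(values)
  if (n < 4) abort("at least 4 species are required to take a third quartile.")
  q3 <- unname(quantile(values, probs = 0.75, type = 7))
  all_equal <- length(unique(values)) == 1
  if (all_equal) {
    warn("all values identical: every species scored 0 ('short').")
  }
  out <- binary_trait(names(values), as.integer(values > q3), trait_name)
  attr(out, "q3") <- q3
  attr(out, "quartile_type") <- 7L
  attr(out, "all_equal") <- all_equal
  out
}
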