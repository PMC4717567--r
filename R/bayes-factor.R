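#' Penalized harmonic-mean Bayes factor between partitioning schemes
#'
#' Compares two partitioning schemes of a Bayesian phylogenetic analysis
#' from their harmonic-mean log marginal likelihoods, penalizing free
#' parameters: `BF = 2 * (lnM1 - lnM0) + (P1 - P0) * ln(0.01)`, with `lnMi`
#' the harmonic-mean ln likelihood and `Pi` the free-parameter count of
#' model i. `ln(0.01)` is evaluated in double precision. Positive BF favours
#' model 1.
#'
#' @param m1,m0 one-row data frames (or named lists) with fields `name`,
#'   `ln_marginal` (finite) and `n_free_parameters` (integer >= 1).
#' @return a `bf_comparison`: `model_1`, `model_0`, `bf`, `category` (see
#'   [interpret_bf()]).
#' @examples
#' m6 <- list(name = "M2", ln_marginal = -38118.57, n_free_parameters = 59)
#' m2 <- list(name = "M1", ln_marginal = -38664.20, n_free_parameters = 19)
#' bayes_factor(m6, m2)$bf # ~907.05
#' @export
bayes_factor <- function(m1, m0) {
  m1 <- validate_partition_model(m1)
  m0 <- validate_partition_model(m0)
  bf <- 2 * (m1$ln_marginal - m0$ln_marginal) +
    (m1$n_free_parameters - m0$n_free_parameters) * log(0.01)
  structure(list(model_1 = m1$name, model_0 = m0$name, bf = bf,
                 category = interpret_bf(bf)),
            class = "bf_comparison")
}

validate_partition_model <- function(m) {
  m <- as.list(m)
  if (!all(c("name", "ln_marginal", "n_free_parameters") %in% names(m))) {
    abort("a model needs fields name, ln_marginal, n_free_parameters.")
  }
  if (!is.finite(m$ln_marginal)) abort("ln_marginal must be finite.")
  p <- m$n_free_parameters
  if (!is.finite(p) || p < 1 || p != as.integer(p)) {
    abort("n_free_parameters must be an integer >= 1.")
  }
  list(name = as.character(m$name), ln_marginal = as.numeric(m$ln_marginal),
       n_free_parameters = as.integer(p))
}

#' Evidence category of a Bayes factor
#'
#' BF in (2, 6] is positive evidence, (6, 10] strong, above 10 very strong;
#' 2 and below (including all negative values) is labelled
#' `negative_or_weak`. Boundaries are closed on the right.
#'
#' @param bf numeric vector of finite Bayes factors.
#' @return character vector of categories.
#' @export
interpret_bf <- function(bf) {
  if (anyNA(bf) || any(!is.finite(bf))) abort("bf must be finite.")
  as.character(cut(bf, breaks = c(-Inf, 2, 6, 10, Inf),
                   labels = c("negative_or_weak", "positive", "strong",
                              "very_strong"), right = TRUE))
}

#' @export
print.bf_comparison <- function(x, ...) {
  cat(sprintf("BF(%s vs %s) = %.2f [%s]\n", x$model_1, x$model_0, x$bf,
              x$category))
  invisible(x)
}

#' @describeIn bayes_factor one-row tibble of the comparison.
#' @param x a `bf_comparison`.
#' @param ... unused.
#' @method tidy bf_comparison
#' @export
tidy.bf_comparison <- function(x, ...) {
  tibble(model_1 = x$model_1, model_0 = x$model_0, bf = x$bf,
         category = x$category)
}

#' Rank partitioning schemes by pairwise Bayes factors
#'
#' Computes the penalized Bayes factor for every pair, orienting each
#' comparison as later-listed model versus earlier-listed model (the layout
#' of published partition-selection tables, where schemes are listed from
#' simplest to most complex).
#'
#' @param models data frame with columns `name`, `ln_marginal`,
#'   `n_free_parameters`; one row per scheme, simplest first. Names must be
#'   unique.
#' @return a tibble of all pairwise comparisons (`model_1`, `model_0`, `bf`,
#'   `category`) with attributes `best` (the model(s) never disfavoured —
#'   non-negative BF in every one of their comparisons) and `tie` (`TRUE`
#'   when several models are never disfavoured).
#' @export
rank_schemes <- function(models) {
  models <- check_columns(as_tibble(models),
                          c("name", "ln_marginal", "n_free_parameters"),
                          "model table")
  if (nrow(models) < 2) abort("need at least 2 models to rank.")
  if (anyDuplicated(models$name)) {
    abort(paste0("duplicate model names: ",
                 toString(unique(models$name[duplicated(models$name)]))))
  }
  pairs <- which(upper.tri(diag(nrow(models))), arr.ind = TRUE)
  comps <- purrr::map2(pairs[, 2], pairs[, 1], function(i1, i0) {
    tidy(bayes_factor(models[i1, ], models[i0, ]))
  }) |> bind_rows()
  # a model is disfavoured if any comparison has positive BF against it
  worst <- vapply(models$name, function(nm) {
    max(c(-comps$bf[comps$model_1 == nm], comps$bf[comps$model_0 == nm]))
  }, numeric(1))
  best <- models$name[worst <= 0]
  attr(comps, "best") <- best
  attr(comps, "tie") <- length(best) > 1
  comps
}

#' Read a partition-model table
#'
#' @param path TSV with columns `name`, `ln_marginal`, `n_free_parameters`.
#' @return a validated tibble usable by [rank_schemes()].
#' @export
read_partition_models <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    ln_marginal = readr::col_double(),
    n_free_parameters = readr::col_integer()
  ), progress = FALSE)
  purrr::walk(seq_len(nrow(df)), function(i) validate_partition_model(df[i, ]))
  df
}
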