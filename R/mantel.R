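#' Pearson correlation of two distance matrices' lower triangles
#'
#' The Mantel statistic: matrix B is aligned to A's labels, both strict
#' lower triangles are vectorized, and their Pearson correlation returned.
#'
#' @param A,B [dist_matrix()] objects over identical label sets (any order).
#' @return the correlation, a number in `[-1, 1]`.
#' @export
lower_triangle_correlation <- function(A, B) {
  al <- align_pair(A, B)
  tri_cor(al$a, al$b)
}

align_pair <- function(A, B) {
  stopifnot(is_dist_matrix(A), is_dist_matrix(B))
  la <- rownames(A); lb <- rownames(B)
  if (!setequal(la, lb)) {
    abort(paste0("label sets differ; symmetric difference: ",
                 toString(lex_sort(c(setdiff(la, lb), setdiff(lb, la))))))
  }
  if (nrow(A) < 3) abort("need at least 3 labels for a Mantel statistic.")
  B <- align_dist(B, la) # canonical order == A's order by construction
  tp <- tri_pairs(nrow(A))
  idx <- cbind(tp$i, tp$j)
  list(a = unclass(A)[idx], b = unclass(B)[idx], n = nrow(A),
       labels = la, Bm = unclass(B), tp = tp)
}

tri_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("zero variance in a lower triangle: correlation undefined.")
  }
  cor(a, b)
}

# all n! permutations of seq_len(n), rows = permutations; n is capped by the
# exhaustive-mode threshold so this stays small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, k] <- n
    out[rows, -k] <- sub
  }
  out
}

# lower triangles of M[p, p] for every permutation p (rows of P);
# returns a nperm x npairs matrix
permuted_triangles <- function(M, P, tp) {
  n <- ncol(P)
  R <- P[, tp$i, drop = FALSE]
  C <- P[, tp$j, drop = FALSE]
  matrix(M[cbind(as.vector(R), as.vector(C))], nrow = nrow(P))
}

# rowwise Pearson correlation of each row of V with vector y
row_cor <- function(V, y) {
  yc <- y - mean(y)
  Vc <- V - rowMeans(V)
  num <- as.vector(Vc %*% yc)
  den <- sqrt(rowSums(Vc^2) * sum(yc^2))
  num / den
}

count_extreme <- function(r_perm, r_obs, tail, eps = 1e-12) {
  switch(tail,
         two_sided = sum(abs(r_perm) >= abs(r_obs) - eps),
         greater = sum(r_perm >= r_obs - eps),
         less = sum(r_perm <= r_obs + eps))
}

new_mantel_result <- function(r, p, nperm, tail, exhaustive, seed, permuted,
                              method, n_labels) {
  structure(list(r_observed = r, p_value = p, n_permutations = nperm,
                 tail = tail, exhaustive = exhaustive,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 permuted_matrix = permuted, method = method,
                 n_labels = n_labels),
            class = "mantel_result")
}

#' Simple Mantel permutation test
#'
#' Tests the correlation between two labelled distance matrices by jointly
#' permuting the rows and columns of `B` and recomputing the lower-triangle
#' correlation. When `n! <= exhaustive_cap` every relabelling is enumerated
#' and the p-value is the exact proportion of permutations at least as
#' extreme as the observed statistic (the identity included); otherwise a
#' Monte-Carlo p-value with the +1 correction in numerator and denominator
#' is returned, so p is never 0 and never below `1/(n_permutations+1)`.
#'
#' @param A,B [dist_matrix()] objects over identical label sets.
#' @param n_permutations Monte-Carlo permutation count (default 9999).
#' @param tail `"two_sided"` (default; the test compares `|r|`), `"greater"`
#'   or `"less"`.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param exhaustive_cap enumerate all `n!` relabelings when `n!` is at most
#'   this (default 40320 = 8!). Set to 0 to force Monte-Carlo.
#' @return a `mantel_result` with fields `r_observed`, `p_value`,
#'   `n_permutations` (the count actually used), `tail`, `exhaustive`,
#'   `seed`, `permuted_matrix` ("B"), and `null_r` (the permutation
#'   distribution, for plotting).
#' @examples
#' m <- dist_matrix(as.matrix(dist(1:5)), labels = letters[1:5])
#' mantel_test(m, m, seed = 1)$r_observed # 1
#' @export
mantel_test <- function(A, B, n_permutations = 9999,
                        tail = c("two_sided", "greater", "less"),
                        seed = NULL, exhaustive_cap = 40320) {
  tail <- match.arg(tail)
  al <- align_pair(A, B)
  r_obs <- tri_cor(al$a, al$b)
  exhaustive <- factorial(al$n) <= exhaustive_cap
  if (exhaustive) {
    P <- all_permutations(al$n)
    r_perm <- row_cor(permuted_triangles(al$Bm, P, al$tp), al$a)
    p <- count_extreme(r_perm, r_obs, tail) / nrow(P)
    nperm <- nrow(P)
  } else {
    if (n_permutations < 99) abort("n_permutations must be at least 99.")
    P <- with_seed_or_stream(seed, t(replicate(n_permutations, sample.int(al$n))))
    r_perm <- row_cor(permuted_triangles(al$Bm, P, al$tp), al$a)
    p <- (count_extreme(r_perm, r_obs, tail) + 1) / (n_permutations + 1)
    nperm <- n_permutations
  }
  out <- new_mantel_result(r_obs, p, nperm, tail, exhaustive, seed, "B",
                           "simple", al$n)
  out$null_r <- r_perm
  out
}

partial_r <- function(r_ab, r_ac, r_bc) {
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

#' Partial Mantel permutation test
#'
#' Correlation between `A` and `B` conditional on `C`:
#' \eqn{r_{AB.C} = (r_{AB} - r_{AC} r_{BC}) / \sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}}
#' on lower triangles. The null distribution permutes the labels of `A`
#' while holding `B` and `C` fixed, recomputing the partial statistic each
#' time; p-values follow the same exhaustive / +1 Monte-Carlo rules as
#' [mantel_test()].
#'
#' @inheritParams mantel_test
#' @param C the conditioning [dist_matrix()].
#' @return a `mantel_result` with `permuted_matrix = "A"`.
#' @export
partial_mantel_test <- function(A, B, C, n_permutations = 9999,
                                tail = c("two_sided", "greater", "less"),
                                seed = NULL, exhaustive_cap = 40320) {
  tail <- match.arg(tail)
  al_ab <- align_pair(A, B)
  al_ac <- align_pair(A, C)
  a <- al_ab$a; b <- al_ab$b; cc <- al_ac$b
  r_ac <- tri_cor(a, cc); r_bc <- tri_cor(b, cc)
  if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) {
    abort("degenerate conditioning: |r_AC| or |r_BC| is 1.")
  }
  r_obs <- partial_r(tri_cor(a, b), r_ac, r_bc)
  n <- al_ab$n
  exhaustive <- factorial(n) <= exhaustive_cap
  if (!exhaustive && n_permutations < 99) {
    abort("n_permutations must be at least 99.")
  }
  P <- if (exhaustive) all_permutations(n) else {
    with_seed_or_stream(seed, t(replicate(n_permutations, sample.int(n))))
  }
  V <- permuted_triangles(unclass(align_dist(A, al_ab$labels)), P, al_ab$tp)
  r1 <- row_cor(V, b)
  r2 <- row_cor(V, cc)
  r_perm <- partial_r(r1, r2, r_bc)
  if (exhaustive) {
    p <- count_extreme(r_perm, r_obs, tail) / nrow(P)
    nperm <- nrow(P)
  } else {
    p <- (count_extreme(r_perm, r_obs, tail) + 1) / (n_permutations + 1)
    nperm <- n_permutations
  }
  out <- new_mantel_result(r_obs, p, nperm, tail, exhaustive, seed, "A",
                           "partial", n)
  out$null_r <- r_perm
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.4f, p = %.4g (%s, %d %s permutations of %s)\n",
              if (x$method == "partial") "Partial" else "Simple",
              x$r_observed, x$p_value, x$tail, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$permuted_matrix))
  invisible(x)
}

#' @describeIn mantel_test one-row tibble of the test result.
#' @param x a `mantel_result`.
#' @param ... unused.
#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(method = x$method, r = x$r_observed, p_value = x$p_value,
         n_permutations = x$n_permutations, tail = x$tail,
         exhaustive = x$exhaustive, permuted_matrix = x$permuted_matrix,
         n_labels = x$n_labels, seed = x$seed)
}

#' @describeIn mantel_test alias of `tidy()` (the result is one row either way).
#' @method glance mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy(x)

#' @describeIn mantel_test histogram of the permutation null with the
#'   observed statistic marked.
#' @param object a `mantel_result`.
#' @method autoplot mantel_result
#' @export
autoplot.mantel_result <- function(object, ...) {
  df <- tibble(r = object$null_r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$r_observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "permutation Mantel r", y = "count",
      title = sprintf("%s Mantel test: r = %.3f, p = %.3g",
                      if (object$method == "partial") "Partial" else "Simple",
                      object$r_observed, object$p_value)
    )
}
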