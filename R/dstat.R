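#' @name dstat
#' @title Phylogenetic signal in binary traits: the D statistic
#'
#' @description
#' The strength of phylogenetic clustering of a binary trait is measured by
#' the sum of state changes along the tree, scaled between two null
#' expectations. Internal nodes receive branch-length-weighted averages of
#' their daughters' values (contrasts-style nodal estimation, daughters
#' weighted by the inverse of their adjusted branch lengths and the
#' parent-facing branch extended by the product-over-sum of the daughter
#' lengths); the observed change sum d is the sum over all edges of the
#' absolute difference between the child and parent values. d is then
#' located between its mean under phylogenetically random tip shuffles
#' (D = 1) and under a Brownian-threshold model (D = 0):
#' `D = (d_obs - mean_d_brownian) / (mean_d_random - mean_d_brownian)`.
#' Both nulls preserve the observed prevalence exactly. D > 1 means the
#' trait is more overdispersed than random; D < 0 more conserved than
#' Brownian.
NULL

# floor used wherever a weight divides by a branch length; stored trees are
# never modified
BL_FLOOR <- 1e-9

# One-time traversal bookkeeping for a tree: deterministic polytomy
# resolution, postorder node sequence with children and contrast weights,
# and the edge list for the change-sum. Everything downstream that depends
# only on the tree (not the states) lives here so that thousands of
# simulated state vectors can be scored with a handful of vector ops each.
dstat_prep <- function(tree) {
  tree <- validate_phylogeny(tree)
  tree <- resolve_polytomies(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  edge <- tree$edge
  adj <- rep(NA_real_, ntot)
  adj[edge[, 2]] <- pmax(tree$edge.length, BL_FLOOR)
  nodes <- unique(edge[, 1]) # postorder: children always precede parents
  ch1 <- integer(length(nodes)); ch2 <- integer(length(nodes))
  w1 <- numeric(length(nodes)); w2 <- numeric(length(nodes))
  kids <- split(edge[, 2], edge[, 1])
  for (k in seq_along(nodes)) {
    ch <- kids[[as.character(nodes[k])]]
    if (length(ch) != 2) abort("internal: tree not binary after resolution.")
    l1 <- adj[ch[1]]; l2 <- adj[ch[2]]
    ch1[k] <- ch[1]; ch2[k] <- ch[2]
    w1[k] <- (1 / l1) / (1 / l1 + 1 / l2)
    w2[k] <- 1 - w1[k]
    adj[nodes[k]] <- adj[nodes[k]] + l1 * l2 / (l1 + l2) # NA at root is fine
  }
  list(tree = tree, ntip = ntip, ntot = ntot, edge = edge,
       nodes = nodes, ch1 = ch1, ch2 = ch2, w1 = w1, w2 = w2,
       tip_labels = tree$tip.label)
}

# nodal values for a matrix of tip states (ntip x m); returns ntot x m
node_value_matrix <- function(prep, S) {
  V <- matrix(0, prep$ntot, ncol(S))
  V[seq_len(prep$ntip), ] <- S
  for (k in seq_along(prep$nodes)) {
    V[prep$nodes[k], ] <- prep$w1[k] * V[prep$ch1[k], ] +
      prep$w2[k] * V[prep$ch2[k], ]
  }
  V
}

# change sum d for each column of a tip-state matrix
batch_observed_d <- function(prep, S) {
  V <- node_value_matrix(prep, S)
  colSums(abs(V[prep$edge[, 2], , drop = FALSE] -
                V[prep$edge[, 1], , drop = FALSE]))
}

align_states <- function(prep, states, trait_name = "trait") {
  bt <- as_binary_trait(states, trait_name)
  missing <- setdiff(prep$tip_labels, bt$species)
  if (length(missing) > 0) {
    abort(paste0("missing tip state(s): ", toString(lex_sort(missing))))
  }
  extra <- setdiff(bt$species, prep$tip_labels)
  if (length(extra) > 0) {
    abort(paste0("states for unknown tip(s): ", toString(lex_sort(extra))))
  }
  bt$state[match(prep$tip_labels, bt$species)]
}

#' Contrasts-style nodal estimates of a binary trait
#'
#' @param tree a validated [ape::phylo]; polytomies are resolved
#'   deterministically with zero-length edges first.
#' @param states a [binary_trait()], a data frame with `species`/`state`
#'   columns, or a named 0/1 vector covering every tip.
#' @return named numeric vector of trait values for every node of the
#'   (resolved) tree: observed 0/1 at tips (named by tip label), weighted
#'   averages at internal nodes (named `node_<id>` by ape node number).
#' @export
nodal_estimates <- function(tree, states) {
  prep <- dstat_prep(tree)
  s <- align_states(prep, states)
  v <- drop(node_value_matrix(prep, matrix(s, ncol = 1)))
  names(v) <- c(prep$tip_labels,
                paste0("node_", seq(prep$ntip + 1, prep$ntot)))
  v
}

#' Observed sum of state changes of a binary trait on a tree
#'
#' @inheritParams nodal_estimates
#' @return d, the sum over all edges of `|value(child) - value(parent)|`,
#'   with observed states at tips and nodal estimates at internal nodes.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1);")
#' observed_d(tr, c(A = 0, B = 1)) # 1
#' @export
observed_d <- function(tree, states) {
  prep <- dstat_prep(tree)
  s <- align_states(prep, states)
  unname(batch_observed_d(prep, matrix(s, ncol = 1)))
}

# Brownian tip values for m replicates: ntip x m matrix (uses the current
# RNG stream; callers wrap in with_seed_or_stream)
bm_tip_matrix <- function(tree, sigma2 = 1, m = 1, root_value = 0) {
  if (sigma2 <= 0) abort("sigma2 must be > 0.")
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  nedge <- nrow(tree$edge)
  # column-major fill recycles the per-edge sd down each replicate column
  incr <- matrix(rnorm(nedge * m, mean = 0,
                       sd = sqrt(sigma2 * tree$edge.length)), nedge, m)
  V <- matrix(0, ntot, m)
  V[ntip + 1L, ] <- root_value # root is the first internal node, cladewise
  for (e in seq_len(nedge)) {
    V[tree$edge[e, 2], ] <- V[tree$edge[e, 1], ] + incr[e, ]
  }
  out <- V[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# dichotomize BM tip values at the observed prevalence: the k largest get 1
threshold_at_prevalence <- function(X, prevalence) {
  apply(X, 2, function(x) {
    as.integer(rank(-x, ties.method = "random") <= prevalence)
  })
}

#' Simulate a binary trait under the Brownian-threshold model
#'
#' A continuous trait evolves by Brownian motion (root value 0, rate
#' `sigma2`) along the branch lengths; state 1 is assigned to exactly the
#' `prevalence` tips with the largest continuous values (ties, which have
#' probability zero for positive branch lengths, are broken by a seeded
#' random rank). Because thresholding is rank-based, the distribution of the
#' resulting trait does not depend on `sigma2`.
#'
#' @param tree a validated [ape::phylo].
#' @param prevalence number of tips to set to 1; between 1 and `n_tips - 1`.
#' @param sigma2 Brownian rate (variance per unit branch length), default 1.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return a [binary_trait()] with exactly `prevalence` ones.
#' @export
simulate_brownian_threshold <- function(tree, prevalence, sigma2 = 1,
                                        seed = NULL) {
  validate_phylogeny(tree)
  ntip <- length(tree$tip.label)
  prevalence <- as.integer(prevalence)
  if (prevalence < 1 || prevalence > ntip - 1) {
    abort(sprintf("prevalence must be in 1..%d.", ntip - 1))
  }
  with_seed_or_stream(seed, {
    x <- bm_tip_matrix(tree, sigma2 = sigma2, m = 1)
    binary_trait(rownames(x), threshold_at_prevalence(x, prevalence),
                 "brownian_threshold")
  })
}

#' D statistic of a binary trait on a phylogeny
#'
#' Computes the observed change sum, its null distributions under
#' prevalence-preserving tip shuffles (phylogenetic randomness) and under
#' Brownian-threshold simulation at the observed prevalence, the scaled
#' statistic `D = (d_obs - mean_brownian) / (mean_random - mean_brownian)`,
#' and two one-tailed permutation p-values: `p_random`, the probability that
#' a randomly shuffled trait is at least as *conserved* (change sum <=
#' observed), and `p_brownian`, the probability that a Brownian trait is at
#' least as *overdispersed* (change sum >= observed). Both use the +1
#' correction.
#'
#' @inheritParams nodal_estimates
#' @param n_simulations simulations per null (default 1000, minimum 100).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param sigma2 Brownian rate for the threshold null; D is invariant to it.
#' @return a `dstat_result` list: `trait_name`, `D`, `d_observed`,
#'   `p_random`, `p_brownian`, `mean_d_random`, `mean_d_brownian`,
#'   `prevalence`, `n_tips`, `n_simulations`, `seed`, and the two simulated
#'   null change-sum vectors (`null_d_random`, `null_d_brownian`).
#' @examples
#' tr <- simulate_yule_tree(10, 1, seed = 1)
#' tr$tip.label
#' phylo_d(tr, setNames(c(rep(1, 3), rep(0, 7)), tr$tip.label),
#'         n_simulations = 200, seed = 2)
#' @export
phylo_d <- function(tree, states, n_simulations = 1000, seed = NULL,
                    sigma2 = 1) {
  if (n_simulations < 100) abort("n_simulations must be at least 100.")
  prep <- dstat_prep(tree)
  bt <- as_binary_trait(states)
  s <- align_states(prep, bt)
  k <- sum(s)
  if (k == 0 || k == prep$ntip) {
    abort("monomorphic trait: phylogenetic signal undefined.")
  }
  d_obs <- unname(batch_observed_d(prep, matrix(s, ncol = 1)))
  sims <- with_seed_or_stream(seed, {
    S_rand <- replicate(n_simulations, sample(s))
    X <- bm_tip_matrix(prep$tree, sigma2 = sigma2, m = n_simulations)
    S_brown <- threshold_at_prevalence(X, k)
    list(d_rand = batch_observed_d(prep, S_rand),
         d_brown = batch_observed_d(prep, S_brown))
  })
  mean_rand <- mean(sims$d_rand)
  mean_brown <- mean(sims$d_brown)
  if (abs(mean_rand - mean_brown) < 1e-12) {
    abort("degenerate scaling: the two null means coincide.")
  }
  eps <- 1e-12
  structure(list(
    trait_name = attr(bt, "trait_name"),
    D = (d_obs - mean_brown) / (mean_rand - mean_brown),
    d_observed = d_obs,
    p_random = (sum(sims$d_rand <= d_obs + eps) + 1) / (n_simulations + 1),
    p_brownian = (sum(sims$d_brown >= d_obs - eps) + 1) / (n_simulations + 1),
    mean_d_random = mean_rand,
    mean_d_brownian = mean_brown,
    prevalence = k,
    n_tips = prep$ntip,
    n_simulations = n_simulations,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    null_d_random = sims$d_rand,
    null_d_brownian = sims$d_brown
  ), class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf(
    "D statistic for '%s': D = %.3f (d_obs = %.3f, prevalence %d/%d)\n",
    x$trait_name, x$D, x$d_observed, x$prevalence, x$n_tips))
  cat(sprintf("  p (vs random shuffles)    = %.4g\n", x$p_random))
  cat(sprintf("  p (vs Brownian threshold) = %.4g  [%d simulations each]\n",
              x$p_brownian, x$n_simulations))
  invisible(x)
}

#' @describeIn phylo_d one-row tibble of the result.
#' @param x a `dstat_result`.
#' @param ... unused.
#' @method tidy dstat_result
#' @export
tidy.dstat_result <- function(x, ...) {
  tibble(trait = x$trait_name, D = x$D, d_observed = x$d_observed,
         p_random = x$p_random, p_brownian = x$p_brownian,
         mean_d_random = x$mean_d_random,
         mean_d_brownian = x$mean_d_brownian,
         prevalence = x$prevalence, n_tips = x$n_tips,
         n_simulations = x$n_simulations, seed = x$seed)
}

#' @describeIn phylo_d alias of `tidy()`.
#' @method glance dstat_result
#' @export
glance.dstat_result <- function(x, ...) tidy(x)

#' @describeIn phylo_d overlaid histograms of the two null change-sum
#'   distributions with the observed value marked.
#' @param object a `dstat_result`.
#' @method autoplot dstat_result
#' @export
autoplot.dstat_result <- function(object, ...) {
  df <- bind_rows(
    tibble(d = object$null_d_random, null = "random shuffle"),
    tibble(d = object$null_d_brownian, null = "Brownian threshold")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, fill = .data$null)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = object$d_observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "sum of state changes d", y = "count", fill = "null model",
      title = sprintf("'%s': D = %.2f, p_random = %.3g, p_brownian = %.3g",
                      object$trait_name, object$D, object$p_random,
                      object$p_brownian)
    )
}
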