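# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately naive and shares no code path with the package internals.

# --- trees ------------------------------------------------------------------

newick_10tip <- paste0(
  "(((t1:0.3,t2:0.7):0.5,(t3:1.1,(t4:0.2,t5:0.9):0.4):0.6):0.8,",
  "((t6:0.5,t7:0.5):1.2,(t8:0.3,(t9:0.6,t10:0.1):0.2):0.7):0.4);")

random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = TRUE)
    tr$edge.length <- round(runif(nrow(tr$edge), 0.05, 2), 3)
    tr
  })
}

# patristic distance by explicit root-to-tip path enumeration
brute_patristic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (node != root) {
      nodes <- c(nodes, node)
      node <- parent_of[node]
    }
    nodes
  }
  out <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi <- path_to_root(i)
    for (j in seq(i + 1, n)) {
      pj <- path_to_root(j)
      shared <- intersect(pi, pj) # edges above the MRCA, counted twice
      d <- sum(len_of[pi]) + sum(len_of[pj]) - 2 * sum(len_of[shared])
      out[i, j] <- d
      out[j, i] <- d
    }
  }
  out
}

# --- matrices ---------------------------------------------------------------

random_dist <- function(n, seed, labels = sprintf("s%02d", seq_len(n))) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(labels, labels)
    dist_matrix(m)
  })
}

lower_vec <- function(m) {
  m <- unclass(m)
  m[lower.tri(m)]
}

# textbook Pearson correlation written out longhand
textbook_cor <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# exhaustive Mantel enumeration: recompute r for every relabelling of B with
# plain loops and the longhand correlation
brute_exhaustive_mantel <- function(A, B, tail = "two_sided") {
  A <- unclass(A); B <- unclass(B)
  n <- nrow(A)
  a <- A[lower.tri(A)]
  r_obs <- textbook_cor(a, B[lower.tri(B)])
  perms <- gtools_permutations(n)
  r_all <- apply(perms, 1, function(p) {
    Bp <- B[p, p]
    textbook_cor(a, Bp[lower.tri(Bp)])
  })
  crit <- switch(tail,
                 two_sided = abs(r_all) >= abs(r_obs) - 1e-12,
                 greater = r_all >= r_obs - 1e-12,
                 less = r_all <= r_obs + 1e-12)
  list(r = r_obs, p = mean(crit), r_all = r_all)
}

# iterative Heap-style permutation generation, independent of the package's
# recursive generator
gtools_permutations <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      t(vapply(seq_len(k), function(pos) {
        append(out[i, ], k, after = pos - 1)
      }, integer(k)))
    }))
  }
  out
}

# residual-regression partial correlation: correlate the residuals of a ~ c
# and b ~ c
residual_partial_cor <- function(a, b, c) {
  ra <- stats::residuals(stats::lm(a ~ c))
  rb <- stats::residuals(stats::lm(b ~ c))
  textbook_cor(ra, rb)
}

# --- D statistic ------------------------------------------------------------

# hand recursion for nodal values and change sum on an arbitrary binary tree,
# written as plain tree recursion over ape's edge table
hand_d <- function(tree, states) {
  n <- length(tree$tip.label)
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  len_of <- numeric(max(tree$edge))
  len_of[tree$edge[, 2]] <- pmax(tree$edge.length, 1e-9)
  value <- numeric(max(tree$edge))
  adj <- len_of
  visit <- function(node) {
    ch <- kids_of[[as.character(node)]]
    if (is.null(ch)) {
      value[node] <<- states[[tree$tip.label[node]]]
      return(invisible())
    }
    for (c_ in ch) visit(c_)
    l1 <- adj[ch[1]]; l2 <- adj[ch[2]]
    value[node] <<- (value[ch[1]] / l1 + value[ch[2]] / l2) /
      (1 / l1 + 1 / l2)
    adj[node] <<- adj[node] + l1 * l2 / (l1 + l2)
    invisible()
  }
  visit(n + 1L)
  sum(abs(value[tree$edge[, 2]] - value[tree$edge[, 1]]))
}

# --- tables -----------------------------------------------------------------

tiny_trait_table <- function() {
  tibble::tibble(
    species = rep(c("spA", "spB", "spC", "spD"), each = 2),
    individual_id = paste0("i", 1:8),
    sheath_length = c(400, 600, 700, 700, 500, 540, 900, 1100),
    metatibia_length = c(500, 500, 700, 700, 520, 560, 800, 1000)
  )
}

tiny_host_table <- function() {
  tibble::tibble(
    parasitoid_species = c("spA", "spA", "spB", "spB", "spC", "spD"),
    host_species = c("h1", "h2", "h2", "h3", "h4", "h5"),
    host_family = c("f1", "f1", "f1", "f2", "f2", "f3"),
    host_order = c("o1", "o1", "o1", "o1", "o1", "o2"),
    plant_family = c("p1", "p2", "p2", NA, "p1", "p3")
  )
}

write_tsv_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, na = "")
  path
}
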