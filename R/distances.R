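#' Patristic distance matrix of a phylogeny
#'
#' The "phylogenetic matrix" of the analysis: the distance between two
#' species is the sum of branch lengths along the tree path between their
#' tips. With one tip per species (`mode = "exemplar"`, the default) this is
#' the plain patristic matrix. With several individuals per species,
#' `mode = "between_species_median"` takes, for each species pair, the
#' median patristic distance over all between-species tip pairs.
#'
#' @param tree a validated [ape::phylo].
#' @param mode `"exemplar"` (tips are species) or `"between_species_median"`.
#' @param species_map named character vector (individual tip -> species);
#'   required for `between_species_median`.
#' @return a [dist_matrix()] labelled by species.
#' @export
patristic_matrix <- function(tree,
                             mode = c("exemplar", "between_species_median"),
                             species_map = NULL) {
  validate_phylogeny(tree)
  mode <- match.arg(mode)
  pat <- ape::cophenetic.phylo(tree)
  if (mode == "exemplar") {
    return(dist_matrix(pat, metadata = list(distance = "patristic",
                                            mode = mode)))
  }
  if (is.null(species_map)) {
    abort("between_species_median mode requires a species_map.")
  }
  unmapped <- setdiff(tree$tip.label, names(species_map))
  if (length(unmapped) > 0) {
    abort(paste0("tips missing from species_map: ", toString(unmapped)))
  }
  sp <- unname(species_map[tree$tip.label])
  species <- lex_sort(unique(sp))
  n <- length(species)
  out <- matrix(0, n, n, dimnames = list(species, species))
  tips_by_sp <- split(tree$tip.label, sp)
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      d <- median(pat[tips_by_sp[[species[a]]], tips_by_sp[[species[b]]]])
      out[a, b] <- d
      out[b, a] <- d
    }
  }
  dist_matrix(out, metadata = list(distance = "patristic", mode = mode))
}

#' Relative-difference dissimilarity of species medians
#'
#' The "morphological matrix": for species medians \eqn{d_i} and \eqn{d_j},
#' the dissimilarity is \eqn{|d_i - d_j| / ((d_i + d_j)/2)}. It is scale-free
#' (multiplying all medians by a constant changes nothing) and bounded by 2,
#' the value reached when one median is zero. The 0/0 case is defined as 0:
#' two species with identical values are maximally similar.
#'
#' @param medians named non-negative numeric vector (names = species), or a
#'   data frame with columns `species` and `value`.
#' @return a [dist_matrix()] with entries in `[0, 2]`.
#' @export
relative_difference_matrix <- function(medians) {
  if (is.data.frame(medians)) {
    check_columns(medians, c("species", "value"), "median table")
    medians <- setNames(medians$value, medians$species)
  }
  if (is.null(names(medians)) || anyDuplicated(names(medians))) {
    abort("medians must be named by unique species.")
  }
  if (anyNA(medians) || any(!is.finite(medians))) abort("medians must be finite.")
  if (any(medians < 0)) abort("medians must be non-negative.")
  num <- abs(outer(medians, medians, `-`))
  den <- outer(medians, medians, `+`) / 2
  vals <- ifelse(den == 0, 0, num / den)
  diag(vals) <- 0
  dist_matrix(vals, labels = names(medians),
              metadata = list(distance = "relative_difference"))
}

#' Collapse host records to a binary incidence matrix
#'
#' Each host taxon is treated qualitatively — at least one rearing record
#' versus none — at the requested taxonomic level: host insect species,
#' family or order, or host-plant family. Records with a missing
#' `plant_family` are dropped (with a message and a `dropped_records`
#' attribute) when collapsing at the plant level; a parasitoid left with no
#' positive entry at the requested level is excluded with a warning, since
#' it cannot enter a Bray-Curtis comparison.
#'
#' @param records validated host records ([read_host_records()]).
#' @param level one of `"host_species"`, `"host_family"`, `"host_order"`,
#'   `"plant_family"`.
#' @return an `incidence_matrix`: binary matrix, parasitoid rows and host
#'   taxon columns in canonical order, with attributes `level`,
#'   `dropped_records` and `excluded_parasitoids`.
#' @export
collapse_incidence <- function(records,
                               level = c("host_species", "host_family",
                                         "host_order", "plant_family")) {
  records <- validate_host_records(records)
  level <- match.arg(level)
  all_parasitoids <- unique(records$parasitoid_species)
  dropped <- 0L
  if (level == "plant_family") {
    keep <- !is.na(records$plant_family) & nzchar(records$plant_family)
    dropped <- sum(!keep)
    if (dropped > 0) {
      inform(sprintf("dropped %d record(s) with missing plant_family.", dropped))
    }
    records <- records[keep, ]
  }
  excluded <- setdiff(all_parasitoids, unique(records$parasitoid_species))
  if (length(excluded) > 0) {
    warn(paste0("parasitoid(s) with no positive entry at level '", level,
                "' excluded: ", toString(lex_sort(excluded))))
  }
  if (nrow(records) == 0) abort("no records left at the requested level.")
  pairs <- distinct(tibble(parasitoid = records$parasitoid_species,
                           taxon = records[[level]]))
  p_lab <- lex_sort(unique(pairs$parasitoid))
  t_lab <- lex_sort(unique(pairs$taxon))
  mat <- matrix(0L, length(p_lab), length(t_lab),
                dimnames = list(p_lab, t_lab))
  mat[cbind(match(pairs$parasitoid, p_lab), match(pairs$taxon, t_lab))] <- 1L
  structure(mat, class = c("incidence_matrix", "matrix", "array"),
            level = level, dropped_records = dropped,
            excluded_parasitoids = excluded)
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix: %d parasitoids x %d %s taxa>\n",
              nrow(x), ncol(x), attr(x, "level") %||% "host"))
  print(`attributes<-`(x, list(dim = dim(x), dimnames = dimnames(x))), ...)
  invisible(x)
}

#' Binary Bray-Curtis dissimilarity between host ranges
#'
#' For binary incidence rows the Bray-Curtis dissimilarity reduces to the
#' closed form \eqn{(b + c) / (2a + b + c)}, with \eqn{a} the number of host
#' taxa shared by the two parasitoids and \eqn{b}, \eqn{c} the taxa unique
#' to each: the complement of the Sørensen similarity. Identical host ranges
#' give 0, disjoint ones 1.
#'
#' @param inc an `incidence_matrix` from [collapse_incidence()] (any binary
#'   matrix with unique rownames and at least one positive per row works).
#' @return a [dist_matrix()] over parasitoids with entries in `[0, 1]`.
#' @export
bray_curtis_matrix <- function(inc) {
  mat <- as.matrix(unclass(inc))
  if (is.null(rownames(mat))) abort("incidence matrix must have rownames.")
  if (nrow(mat) < 2) abort("need at least 2 parasitoids.")
  if (!all(mat %in% c(0L, 1L))) abort("incidence entries must be 0/1.")
  if (any(rowSums(mat) == 0)) {
    abort("every parasitoid must have at least one positive entry.")
  }
  a <- mat %*% t(mat)                   # shared positives
  rs <- rowSums(mat)
  tot <- outer(rs, rs, `+`)             # 2a + b + c
  bc <- (tot - 2 * a) / tot
  diag(bc) <- 0
  dist_matrix(bc, labels = rownames(mat),
              metadata = list(distance = "bray_curtis_binary",
                              level = attr(inc, "level")))
}
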