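#' Read and validate a rooted newick phylogeny
#'
#' Strict reader for the trees the comparative analysis consumes: the tree
#' must parse, be rooted, carry a finite non-negative branch length on every
#' edge, and have unique non-empty tip labels. Nothing is repaired silently;
#' polytomies are accepted here and only resolved (deterministically, with
#' zero-length edges) where an algorithm requires a binary tree.
#'
#' @param path path to a newick file (single tree, branch lengths required).
#' @return an [ape::phylo] object that passes [validate_phylogeny()].
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:2):0.5,C:3);", tf)
#' tr <- read_newick(tf)
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  check_newick_syntax(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) abort(paste0("malformed newick in ", path))
  if (inherits(tree, "multiPhylo")) {
    abort("file contains more than one tree; expected exactly one.")
  }
  validate_phylogeny(tree)
}

# cheap positional syntax check so parse errors can name a character offset
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1
    if (chars[k] == ")") {
      depth <- depth - 1
      if (depth < 0) {
        abort(sprintf("malformed newick: unmatched ')' at character %d.", k))
      }
    }
  }
  if (depth != 0) {
    abort(sprintf(
      "malformed newick: %d '(' left unclosed (input ends at character %d).",
      depth, length(chars)))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    abort(sprintf(
      "malformed newick: missing terminating ';' (input ends at character %d).",
      length(chars)))
  }
  invisible(TRUE)
}

#' Validate phylogeny invariants
#'
#' @param tree an [ape::phylo] object.
#' @return `tree`, invisibly usable, unchanged; errors describe the first
#'   violated invariant (duplicate/empty tip labels, missing or negative
#'   branch lengths, unrooted topology).
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("expected an ape 'phylo' tree.")
  tips <- tree$tip.label
  if (anyNA(tips) || any(!nzchar(tips))) abort("empty or missing tip labels.")
  dup <- unique(tips[duplicated(tips)])
  if (length(dup) > 0) {
    abort(paste0("duplicate tip labels: ", toString(dup)))
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; lengths are required.")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    abort("every edge must have a finite branch length.")
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths.")
  # exactly one root: a single node that never appears as a child (basal
  # multifurcations, e.g. collapsed poorly supported nodes, are accepted)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) abort("tree must have exactly one root.")
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree a validated [ape::phylo].
#' @param path output path.
#' @param digits significant digits for branch lengths (default 10, ample
#'   for round-tripping to 1e-9).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Collapse a multi-individual tree to one exemplar tip per species
#'
#' Trees inferred from several sequenced individuals per species must be
#' reduced to one tip per species before species-level comparative analysis.
#' Branch lengths along retained paths are untouched; the retained tip is
#' relabelled with its species name.
#'
#' @param tree a validated [ape::phylo] whose tips are individuals.
#' @param species_map named character vector: names are individual tip
#'   labels, values are species names. Every tip of `tree` must be mapped.
#' @param exemplar_rule `"first"` keeps, per species, the first mapped tip in
#'   the tree's tip order; `"min_mean_conspecific_distance"` keeps the tip
#'   whose mean patristic distance to its conspecifics is smallest (ties go
#'   to tip order; singletons are kept as-is).
#' @return a [ape::phylo] with one tip per species, tip labels = species.
#' @export
prune_to_species <- function(tree, species_map,
                             exemplar_rule = c("first",
                                               "min_mean_conspecific_distance")) {
  validate_phylogeny(tree)
  exemplar_rule <- match.arg(exemplar_rule)
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(species_map))
  if (length(unmapped) > 0) {
    abort(paste0("tips missing from species_map: ", toString(unmapped)))
  }
  empty_species <- setdiff(unique(unname(species_map)),
                           unique(unname(species_map[tips])))
  if (length(empty_species) > 0) {
    abort(paste0("species with zero tips in tree: ",
                 toString(lex_sort(empty_species))))
  }
  sp_of_tip <- unname(species_map[tips])
  if (exemplar_rule == "first") {
    keep_idx <- vapply(split(seq_along(tips), sp_of_tip), `[`, integer(1), 1)
  } else {
    pat <- ape::cophenetic.phylo(tree)
    keep_idx <- vapply(split(seq_along(tips), sp_of_tip), function(idx) {
      if (length(idx) == 1) return(idx)
      mean_d <- vapply(idx, function(i) {
        mean(pat[tips[i], tips[setdiff(idx, i)]])
      }, numeric(1))
      idx[which.min(mean_d)] # which.min resolves ties to tip order
    }, integer(1))
  }
  pruned <- ape::keep.tip(tree, tips[sort(unname(keep_idx))])
  pruned$tip.label <- unname(species_map[pruned$tip.label])
  validate_phylogeny(pruned)
}

# deterministic binary resolution of polytomies (zero-length edges,
# left-to-right), used by algorithms that assume bifurcating trees
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  tree <- ape::multi2di(tree, random = FALSE)
  tree$edge.length[is.na(tree$edge.length)] <- 0
  tree
}
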