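#' Per-parasitoid host-range summary
#'
#' @param records validated host records.
#' @return tibble with one row per parasitoid: distinct host species,
#'   families, orders and plant families (missing plants not counted), and
#'   a specialist flag at each level (exactly one distinct taxon).
#' @export
summarize_host_ranges <- function(records) {
  records <- validate_host_records(records)
  records |>
    group_by(parasitoid = .data$parasitoid_species) |>
    summarise(
      n_host_species = dplyr::n_distinct(.data$host_species),
      n_host_families = dplyr::n_distinct(.data$host_family),
      n_host_orders = dplyr::n_distinct(.data$host_order),
      n_plant_families = dplyr::n_distinct(.data$plant_family[
        !is.na(.data$plant_family)]),
      .groups = "drop") |>
    mutate(specialist_species = .data$n_host_species == 1L,
           specialist_family = .data$n_host_families == 1L,
           specialist_order = .data$n_host_orders == 1L,
           specialist_plant = .data$n_plant_families == 1L) |>
    arrange(.data$parasitoid)
}

#' Fraction of host taxa shared by at least two parasitoids
#'
#' @param inc an incidence matrix from [collapse_incidence()].
#' @return fraction of columns with column sum >= 2, in `[0, 1]`.
#' @export
shared_host_fraction <- function(inc) {
  mat <- as.matrix(unclass(inc))
  if (length(mat) == 0 || ncol(mat) == 0) abort("empty incidence matrix.")
  mean(colSums(mat) >= 2)
}

restrict_tree <- function(tree, labels) {
  ape::keep.tip(tree, labels)
}

subset_incidence <- function(inc, labels) {
  keep <- intersect(rownames(inc), labels)
  structure(unclass(inc)[keep, , drop = FALSE],
            class = class(inc), level = attr(inc, "level"))
}

#' Run the full comparative analysis
#'
#' Orchestrates every stage of the pipeline on one dataset: species-level
#' trait summaries; phylogenetic, morphological and ecological distance
#' matrices; the grid of simple and partial Mantel tests; D-statistic tests
#' of the binarized ovipositor traits, of host specificity (at the host
#' species and at the family level, plus an optional robustness variant that
#' recodes a supplied list of rarely collected species as specialists), of
#' the ability to parasitize each well-represented host order and family,
#' and of the use of each well-represented plant family; and, when a model
#' table is supplied, the Bayes-factor ranking of partitioning schemes.
#'
#' The analysis universe is derived from data availability: morphological
#' tests run on the intersection of tree tips and measured species,
#' ecological tests on its intersection with the parasitoids having host
#' records. All matrices are aligned by label; exclusions are logged in the
#' report. Given the same inputs and `seed` the report is identical to the
#' byte when serialized with [write_report_json()]. Raw p-values are
#' reported with no multiple-testing correction (stated in the metadata).
#'
#' @param tree a validated [ape::phylo] or path to a newick file.
#' @param traits trait records (tibble or TSV path).
#' @param hosts host records (tibble or TSV path).
#' @param models optional partition-model table (tibble or TSV path).
#' @param species_map optional named vector collapsing a multi-individual
#'   tree to species tips first (see [prune_to_species()]).
#' @param exemplar_rule passed to [prune_to_species()].
#' @param n_permutations Mantel permutations (default 9999).
#' @param n_simulations D-statistic simulations per null (default 1000).
#' @param seed master seed; every stochastic stage draws from the stream it
#'   starts.
#' @param min_taxon_users a host order/family or plant family is
#'   "well-represented", and gets its own ability trait, when at least this
#'   many analyzed parasitoids use it (default 4).
#' @param rare_species optional character vector of rarely collected species
#'   to recode as specialists in the robustness variant.
#' @return an `analysis_report` list; see the report fields and
#'   [write_report_json()].
#' @export
run_comparative_analysis <- function(tree, traits, hosts, models = NULL,
                                     species_map = NULL,
                                     exemplar_rule = "first",
                                     n_permutations = 9999,
                                     n_simulations = 1000,
                                     seed = 1,
                                     min_taxon_users = 4,
                                     rare_species = NULL) {
  digests <- list()
  if (is.character(tree)) {
    digests$tree_md5 <- unname(tools::md5sum(tree))
    tree <- read_newick(tree)
  } else validate_phylogeny(tree)
  if (is.character(traits)) {
    digests$traits_md5 <- unname(tools::md5sum(traits))
    traits <- read_trait_table(traits)
  } else traits <- validate_trait_records(traits)
  if (is.character(hosts)) {
    digests$hosts_md5 <- unname(tools::md5sum(hosts))
    hosts <- read_host_records(hosts)
  } else hosts <- validate_host_records(hosts)
  if (is.character(models)) models <- read_partition_models(models)
  if (!is.null(species_map)) {
    tree <- prune_to_species(tree, species_map, exemplar_rule)
  }
  notes <- character()
  note <- function(...) notes <<- c(notes, sprintf(...))

  summaries <- species_summaries(traits)
  morpho_universe <- lex_sort(intersect(tree$tip.label, summaries$species))
  if (length(morpho_universe) < 4) {
    abort(sprintf(
      "only %d species shared by tree and trait table; need at least 4.",
      length(morpho_universe)))
  }
  for (lab in setdiff(tree$tip.label, summaries$species)) {
    note("tip '%s' has no measurements: excluded from morphology.", lab)
  }
  for (lab in setdiff(summaries$species, tree$tip.label)) {
    note("measured species '%s' is not in the tree: excluded.", lab)
  }
  host_universe <- lex_sort(intersect(morpho_universe,
                                      unique(hosts$parasitoid_species)))
  for (lab in setdiff(unique(hosts$parasitoid_species), morpho_universe)) {
    note("parasitoid '%s' lacks tree or trait data: excluded from ecology.",
         lab)
  }

  withr::with_seed(as.integer(seed), {
    run_stages(tree, summaries, hosts, models, morpho_universe,
               host_universe, n_permutations, n_simulations, seed,
               min_taxon_users, rare_species, digests, notes, note)
  })
}

# everything stochastic happens here, inside the master-seed RNG scope
run_stages <- function(tree, summaries, hosts, models, morpho_universe,
                       host_universe, n_permutations, n_simulations, seed,
                       min_taxon_users, rare_species, digests, notes, note) {
  tree_m <- restrict_tree(tree, morpho_universe)
  phylo_m <- patristic_matrix(tree_m)
  aos <- setNames(summaries$aos_median, summaries$species)[morpho_universe]
  ros <- setNames(summaries$ros_median, summaries$species)[morpho_universe]
  morpho <- list(AOS = relative_difference_matrix(aos),
                 ROS = relative_difference_matrix(ros))

  mantel_rows <- list()
  add_mantel <- function(comparison, level, fun) {
    res <- tryCatch(fun(), error = function(e) {
      note("Mantel '%s' (%s) skipped: %s", comparison, level,
           conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      mantel_rows[[length(mantel_rows) + 1]] <<-
        mutate(tidy(res), comparison = comparison, level = level,
               .before = 1)
    }
  }
  for (trait in c("AOS", "ROS")) {
    add_mantel(paste0("phylogeny_x_", trait), "morphology", function() {
      mantel_test(phylo_m, morpho[[trait]], n_permutations)
    })
  }

  dstat_rows <- list()
  add_dstat <- function(bt, tr, label) {
    res <- tryCatch(phylo_d(tr, bt, n_simulations), error = function(e) {
      note("D test '%s' skipped: %s", label, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      row <- tidy(res)
      row$trait <- label
      dstat_rows[[length(dstat_rows) + 1]] <<- row
    }
  }
  binar <- list()
  for (trait in c("AOS", "ROS")) {
    bt <- suppressWarnings(binarize_by_quartile(
      if (trait == "AOS") aos else ros, paste0(trait, "_long")))
    binar[[trait]] <- bt
    add_dstat(bt, tree_m, paste0(trait, "_long"))
  }

  # ecological stage
  eco <- list()
  levels <- c("host_species", "host_family", "host_order", "plant_family")
  host_summary <- summarize_host_ranges(hosts)
  shared <- tibble(level = character(), fraction = numeric())
  if (length(host_universe) < 4) {
    note("fewer than 4 species with host data (%d): ecological stage skipped.",
         length(host_universe))
  } else {
    tree_e <- restrict_tree(tree, host_universe)
    phylo_e <- align_dist(phylo_m, host_universe)
    morpho_e <- lapply(morpho, align_dist, labels = host_universe)
    for (lv in levels) {
      inc <- tryCatch(
        suppressMessages(suppressWarnings(collapse_incidence(hosts, lv))),
        error = function(e) {
          note("incidence at level '%s' failed: %s", lv, conditionMessage(e))
          NULL
        })
      if (is.null(inc)) next
      inc_u <- subset_incidence(inc, host_universe)
      universe_lv <- rownames(inc_u)
      if (length(universe_lv) < 4) {
        note("level '%s': only %d analyzable parasitoids, skipped.",
             lv, length(universe_lv))
        next
      }
      shared <- bind_rows(shared,
                          tibble(level = lv,
                                 fraction = shared_host_fraction(inc_u)))
      eco[[lv]] <- bray_curtis_matrix(inc_u)
      ph <- align_dist(phylo_e, universe_lv)
      add_mantel("phylogeny_x_hostrange", lv, function() {
        mantel_test(ph, eco[[lv]], n_permutations)
      })
      for (trait in c("AOS", "ROS")) {
        mo <- align_dist(morpho_e[[trait]], universe_lv)
        add_mantel(paste0(trait, "_x_hostrange"), lv, function() {
          mantel_test(mo, eco[[lv]], n_permutations)
        })
        add_mantel(paste0(trait, "_x_hostrange_given_phylogeny"), lv,
                   function() {
                     partial_mantel_test(eco[[lv]], mo, ph, n_permutations)
                   })
      }
    }

    # host specificity traits
    hs <- filter(host_summary, .data$parasitoid %in% host_universe)
    spec_sp <- binary_trait(hs$parasitoid,
                            as.integer(hs$specialist_species),
                            "specialist_host_species")
    spec_fam <- binary_trait(hs$parasitoid,
                             as.integer(hs$specialist_family),
                             "specialist_family_order")
    add_dstat(spec_sp, tree_e, "specialist_host_species")
    add_dstat(spec_fam, tree_e, "specialist_family_order")
    if (!is.null(rare_species)) {
      recode <- function(bt, nm) {
        binary_trait(bt$species,
                     pmax(bt$state, as.integer(bt$species %in% rare_species)),
                     nm)
      }
      add_dstat(recode(spec_sp, "specialist_host_species_rare_as_specialist"),
                tree_e, "specialist_host_species_rare_as_specialist")
      add_dstat(recode(spec_fam, "specialist_family_order_rare_as_specialist"),
                tree_e, "specialist_family_order_rare_as_specialist")
    }

    # ability to use well-represented taxa
    hosts_u <- filter(hosts, .data$parasitoid_species %in% host_universe)
    ability_traits <- function(column, prefix) {
      users <- distinct(tibble(p = hosts_u$parasitoid_species,
                               taxon = hosts_u[[column]]))
      users <- users[!is.na(users$taxon), ]
      taxa <- users |> count(.data$taxon) |>
        filter(.data$n >= min_taxon_users) |> pull(.data$taxon)
      for (tx in lex_sort(taxa)) {
        st <- as.integer(host_universe %in% users$p[users$taxon == tx])
        add_dstat(binary_trait(host_universe, st,
                               paste0(prefix, "_", tx)),
                  tree_e, paste0(prefix, "_", tx))
      }
    }
    ability_traits("host_order", "parasitizes_order")
    ability_traits("host_family", "parasitizes_family")
    ability_traits("plant_family", "uses_plant_family")
  }

  bayes <- NULL
  if (!is.null(models)) {
    comps <- rank_schemes(models)
    bayes <- list(comparisons = as_tibble(comps),
                  best = attr(comps, "best"), tie = attr(comps, "tie"))
  }

  structure(list(
    metadata = list(
      seed = as.integer(seed),
      n_permutations = n_permutations,
      n_simulations = n_simulations,
      min_taxon_users = min_taxon_users,
      rare_species = rare_species,
      decisions = list(
        quartile_type = 7L,
        quartile_ties = "ties at Q3 are 'short' (strictly greater is 'long')",
        ros = "per-individual ratios, then species median",
        mantel_tail = "two_sided",
        mantel_permuted = "B in simple tests, A in partial tests",
        patristic_mode = "exemplar",
        dstat_tails = paste("p_random: d_random <= d_obs;",
                            "p_brownian: d_brownian >= d_obs"),
        multiple_testing = "none: raw p-values reported"
      ),
      digests = digests
    ),
    universes = list(morphology = morpho_universe, ecology = host_universe),
    trait_summaries = summaries,
    binarization = purrr::map(binar, function(b) {
      list(q3 = attr(b, "q3"), species = b$species, state = b$state)
    }),
    host_range_summary = host_summary,
    shared_host_fraction = shared,
    matrices = c(list(phylogeny = dist_matrix_to_list(phylo_m)),
                 setNames(lapply(names(morpho), function(nm) {
                   dist_matrix_to_list(morpho[[nm]])
                 }), paste0("morphology_", names(morpho))),
                 setNames(lapply(names(eco), function(nm) {
                   dist_matrix_to_list(eco[[nm]])
                 }), paste0("hostrange_", names(eco)))),
    mantel = bind_rows(mantel_rows),
    dstat = bind_rows(dstat_rows),
    bayes_factors = bayes,
    notes = notes
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Comparative analysis report\n")
  cat(sprintf("  species: %d with morphology, %d with host data\n",
              length(x$universes$morphology), length(x$universes$ecology)))
  cat(sprintf("  Mantel tests: %d | D-statistic tests: %d | notes: %d\n",
              nrow(x$mantel), nrow(x$dstat), length(x$notes)))
  if (!is.null(x$bayes_factors)) {
    cat(sprintf("  Bayes factors: best scheme %s\n",
                toString(x$bayes_factors$best)))
  }
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serialization is deterministic (no timestamps, full-precision numbers),
#' so identical inputs and seed produce a byte-identical file.
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
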