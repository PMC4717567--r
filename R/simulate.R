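#' Synthetic study scenario
#'
#' Bundles the dimensions and rates of the synthetic data the pipeline is
#' exercised with. The defaults emulate the marginal structure of a
#' West-Palearctic parasitoid host-range study: 19 ingroup species measured
#' for ovipositor morphology (~121 individuals, at least 2 per species with
#' 2 singletons), species-median absolute sheath lengths (AOS) spanning
#' 398-1179 micrometres and sheath/metatibia ratios (ROS) 0.58-1.16, and
#' host ranges known for 13 species drawn from 95 host insect species in 22
#' families and 6 orders, feeding on 18 host-plant families, with roughly a
#' quarter of parasitoids strict specialists and generalists reared from up
#' to 21 host species.
#'
#' @param n_species number of parasitoid species (tree tips).
#' @param birth_rate Yule speciation rate (per lineage per unit time).
#' @param n_individuals_range range (min, max) of measured individuals per
#'   non-singleton species.
#' @param n_singletons number of species represented by a single individual.
#' @param aos_range range of species-level true AOS medians, micrometres.
#' @param ros_range range of species-level true ROS medians.
#' @param measurement_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise on each individual length.
#' @param n_species_with_hosts number of parasitoid species with host data.
#' @param n_host_species,n_host_families,n_host_orders host-insect taxonomy
#'   sizes (must nest: orders <= families <= species).
#' @param n_plant_families number of host-plant families.
#' @param specialist_fraction probability a parasitoid is a strict
#'   specialist (one host species).
#' @param generalist_host_range range (min, max) of host-species counts for
#'   generalists.
#' @return a validated `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_species = 19,
                               birth_rate = 1,
                               n_individuals_range = c(2, 12),
                               n_singletons = 2,
                               aos_range = c(398, 1179),
                               ros_range = c(0.58, 1.16),
                               measurement_cv = 0.05,
                               n_species_with_hosts = 13,
                               n_host_species = 95,
                               n_host_families = 22,
                               n_host_orders = 6,
                               n_plant_families = 18,
                               specialist_fraction = 3 / 13,
                               generalist_host_range = c(2, 21)) {
  sc <- list(n_species = as.integer(n_species), birth_rate = birth_rate,
             n_individuals_range = as.integer(n_individuals_range),
             n_singletons = as.integer(n_singletons),
             aos_range = aos_range, ros_range = ros_range,
             measurement_cv = measurement_cv,
             n_species_with_hosts = as.integer(n_species_with_hosts),
             n_host_species = as.integer(n_host_species),
             n_host_families = as.integer(n_host_families),
             n_host_orders = as.integer(n_host_orders),
             n_plant_families = as.integer(n_plant_families),
             specialist_fraction = specialist_fraction,
             generalist_host_range = as.integer(generalist_host_range))
  if (sc$n_species < 4) abort("n_species must be at least 4.")
  if (sc$birth_rate <= 0) abort("birth_rate must be > 0.")
  ranges <- list(n_individuals_range = sc$n_individuals_range,
                 aos_range = sc$aos_range, ros_range = sc$ros_range,
                 generalist_host_range = sc$generalist_host_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      abort(paste0(nm, " must be an ordered positive (min, max) pair."))
    }
  }
  if (sc$n_individuals_range[1] < 2) {
    abort("non-singleton species need at least 2 individuals.")
  }
  if (sc$n_singletons < 0 || sc$n_singletons > sc$n_species) {
    abort("n_singletons out of range.")
  }
  if (sc$measurement_cv < 0) abort("measurement_cv must be >= 0.")
  if (!(sc$n_host_orders <= sc$n_host_families &&
        sc$n_host_families <= sc$n_host_species)) {
    abort("host taxonomy must nest: orders <= families <= species.")
  }
  if (sc$n_plant_families > sc$n_host_species) {
    abort("n_plant_families cannot exceed n_host_species.")
  }
  if (sc$specialist_fraction < 0 || sc$specialist_fraction > 1) {
    abort("specialist_fraction must be in [0, 1].")
  }
  if (sc$n_species_with_hosts < 2 || sc$n_species_with_hosts > sc$n_species) {
    abort("n_species_with_hosts must be in 2..n_species.")
  }
  if (sc$generalist_host_range[2] > sc$n_host_species) {
    abort("generalist_host_range exceeds the host-species pool.")
  }
  structure(sc, class = "synthetic_scenario")
}

species_labels <- function(n) sprintf("sp%02d", seq_len(n))

#' Simulate a pure-birth (Yule) tree
#'
#' Forward crown simulation: starting from two lineages, the waiting time to
#' the next speciation with k extant lineages is exponential with rate
#' `k * birth_rate` and a uniformly chosen lineage splits; after the n-th
#' tip appears the tree is extended by one further exponential waiting time
#' so every terminal branch is positive. The result is ultrametric with
#' tips `sp01..spNN`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage, > 0.
#' @param seed optional integer seed; a fixed seed gives a bit-identical
#'   tree.
#' @return a validated [ape::phylo].
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 2) abort("n_tips must be at least 2.")
  if (birth_rate <= 0) abort("birth_rate must be > 0.")
  with_seed_or_stream(seed, {
    parent <- c(NA_integer_, 1L, 1L)
    start <- c(0, 0, 0)
    split_t <- rep(NA_real_, 3)
    active <- c(2L, 3L)
    t <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t <- t + rexp(1, rate = birth_rate * k)
      l <- active[sample.int(k, 1)]
      split_t[l] <- t
      id <- length(parent) + c(1L, 2L)
      parent <- c(parent, l, l)
      start <- c(start, t, t)
      split_t <- c(split_t, NA_real_, NA_real_)
      active <- c(active[active != l], id)
    }
    t_end <- t + rexp(1, rate = birth_rate * n_tips)
    kids <- split(seq_along(parent)[-1], parent[-1])
    tip_ids <- sort(active)
    tip_name <- setNames(species_labels(n_tips), tip_ids)
    build <- function(node) {
      len <- (if (is.na(split_t[node])) t_end else split_t[node]) - start[node]
      ch <- kids[[as.character(node)]]
      if (is.null(ch)) {
        sprintf("%s:%.12g", tip_name[[as.character(node)]], len)
      } else {
        sprintf("(%s,%s):%.12g", build(ch[1]), build(ch[2]), len)
      }
    }
    ch <- kids[["1"]]
    txt <- sprintf("(%s,%s);", build(ch[1]), build(ch[2]))
    validate_phylogeny(ape::read.tree(text = txt))
  })
}

#' Simulate a continuous trait by Brownian motion along a tree
#'
#' Independent Gaussian increments per branch, with variance
#' `sigma2 * branch length`, accumulated from the root.
#'
#' @param tree a validated [ape::phylo].
#' @param sigma2 rate (variance per unit branch length), > 0.
#' @param root_value trait value at the root.
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root_value = 0, seed = NULL) {
  validate_phylogeny(tree)
  with_seed_or_stream(seed, {
    drop(bm_tip_matrix(tree, sigma2 = sigma2, m = 1, root_value = root_value))
  })
}

#' Simulate a binary trait at fixed prevalence
#'
#' `mode = "random"` draws a uniformly random subset of `prevalence` tips to
#' carry state 1 (phylogenetic randomness); `mode = "brownian_threshold"`
#' delegates to [simulate_brownian_threshold()].
#'
#' @inheritParams simulate_brownian_threshold
#' @param mode `"random"` or `"brownian_threshold"`.
#' @return a [binary_trait()] with exactly `prevalence` ones.
#' @export
simulate_binary_trait <- function(tree, prevalence,
                                  mode = c("random", "brownian_threshold"),
                                  seed = NULL) {
  validate_phylogeny(tree)
  mode <- match.arg(mode)
  ntip <- length(tree$tip.label)
  prevalence <- as.integer(prevalence)
  if (prevalence < 1 || prevalence > ntip - 1) {
    abort(sprintf("prevalence must be in 1..%d.", ntip - 1))
  }
  if (mode == "brownian_threshold") {
    return(simulate_brownian_threshold(tree, prevalence, seed = seed))
  }
  with_seed_or_stream(seed, {
    ones <- sample(tree$tip.label, prevalence)
    binary_trait(tree$tip.label,
                 as.integer(tree$tip.label %in% ones), "random")
  })
}

#' Simulate individual morphometric measurements
#'
#' Each species receives a true AOS median and true ROS median drawn
#' uniformly within the scenario ranges (independently of any phylogeny, so
#' the default data carry no phylogenetic signal). Individuals get sheath
#' and metatibia lengths equal to the species truth times multiplicative
#' lognormal noise with the scenario's coefficient of variation; with zero
#' noise the species medians recover the truth exactly. A configurable
#' number of randomly chosen species are singletons (one individual);
#' every other species gets between `n_individuals_range[1]` and
#' `n_individuals_range[2]` individuals.
#'
#' @param scenario a [synthetic_scenario()].
#' @param tree_species character vector of species labels to measure.
#' @param seed optional integer seed.
#' @return a validated trait-record tibble with attribute `truth` (tibble
#'   of the per-species true AOS/ROS).
#' @export
simulate_measurements <- function(scenario, tree_species, seed = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (length(tree_species) == 0) abort("tree_species must be non-empty.")
  if (scenario$n_singletons > length(tree_species)) {
    abort("more singletons than species.")
  }
  with_seed_or_stream(seed, {
    n_sp <- length(tree_species)
    singles <- sample(tree_species, scenario$n_singletons)
    n_ind <- setNames(sample(seq(scenario$n_individuals_range[1],
                                 scenario$n_individuals_range[2]),
                             n_sp, replace = TRUE), tree_species)
    n_ind[singles] <- 1L
    aos_true <- setNames(runif(n_sp, scenario$aos_range[1],
                               scenario$aos_range[2]), tree_species)
    ros_true <- setNames(runif(n_sp, scenario$ros_range[1],
                               scenario$ros_range[2]), tree_species)
    sdlog <- sqrt(log(1 + scenario$measurement_cv^2))
    recs <- purrr::map(tree_species, function(sp) {
      m <- n_ind[[sp]]
      tibble(species = sp,
             individual_id = sprintf("%s_i%02d", sp, seq_len(m)),
             sheath_length = aos_true[[sp]] * exp(rnorm(m, 0, sdlog)),
             metatibia_length = (aos_true[[sp]] / ros_true[[sp]]) *
               exp(rnorm(m, 0, sdlog)))
    }) |> bind_rows()
    out <- validate_trait_records(recs)
    attr(out, "truth") <- tibble(species = tree_species,
                                 aos_true = unname(aos_true),
                                 ros_true = unname(ros_true),
                                 n_individuals = unname(n_ind))
    out
  })
}

# nested host taxonomy with exactly the configured numbers of distinct taxa
# at every level: the first members of each level seed the level above so no
# taxon is empty, the rest are assigned uniformly
build_host_taxonomy <- function(scenario) {
  n_s <- scenario$n_host_species
  n_f <- scenario$n_host_families
  n_o <- scenario$n_host_orders
  n_p <- scenario$n_plant_families
  fam_of_sp <- c(seq_len(n_f), sample.int(n_f, n_s - n_f, replace = TRUE))
  ord_of_fam <- c(seq_len(n_o), sample.int(n_o, n_f - n_o, replace = TRUE))
  plant_of_sp <- c(seq_len(n_p), sample.int(n_p, n_s - n_p, replace = TRUE))
  tibble(host_species = sprintf("host%03d", seq_len(n_s)),
         host_family = sprintf("fam%02d", fam_of_sp),
         host_order = sprintf("ord%d", ord_of_fam[fam_of_sp]),
         plant_family = sprintf("plant%02d", plant_of_sp))
}

#' Simulate host-rearing records
#'
#' Builds a nested host taxonomy of exactly the scenario's dimensions, then
#' assigns each parasitoid a host set: with probability
#' `specialist_fraction` a single host species, otherwise a generalist
#' host-species count drawn uniformly from `generalist_host_range`. In the
#' default `regime = "none"` hosts are sampled independently of the
#' phylogeny, so host-range traits carry no phylogenetic signal; in
#' `regime = "signal"` a Brownian latent affinity for each host order is
#' simulated on `tree` and hosts are drawn with probability proportional to
#' the parasitoid's affinity for their order, so related parasitoids share
#' host orders.
#'
#' @param scenario a [synthetic_scenario()].
#' @param parasitoid_species character vector of parasitoid labels.
#' @param seed optional integer seed.
#' @param regime `"none"` (default) or `"signal"`.
#' @param tree required for `regime = "signal"`: a tree containing every
#'   parasitoid as a tip.
#' @return a validated host-record tibble (one row per parasitoid x host
#'   species pair), with the taxonomy tibble in attribute `taxonomy`.
#' @export
simulate_host_records <- function(scenario, parasitoid_species, seed = NULL,
                                  regime = c("none", "signal"), tree = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  regime <- match.arg(regime)
  if (length(parasitoid_species) == 0) abort("no parasitoid species given.")
  if (regime == "signal") {
    if (is.null(tree)) abort("regime = 'signal' requires a tree.")
    validate_phylogeny(tree)
    if (!all(parasitoid_species %in% tree$tip.label)) {
      abort("every parasitoid must be a tip of the tree.")
    }
  }
  with_seed_or_stream(seed, {
    tax <- build_host_taxonomy(scenario)
    orders <- unique(tax$host_order)
    if (regime == "signal") {
      z <- vapply(orders, function(o) {
        simulate_bm_trait(tree, sigma2 = 1)[parasitoid_species]
      }, numeric(length(parasitoid_species)))
      affinity <- exp(2 * z) # rows parasitoids, cols orders
      rownames(affinity) <- parasitoid_species
    }
    recs <- purrr::map(parasitoid_species, function(p) {
      specialist <- runif(1) < scenario$specialist_fraction
      n_h <- if (specialist) 1L else {
        sample(seq(scenario$generalist_host_range[1],
                   scenario$generalist_host_range[2]), 1)
      }
      prob <- if (regime == "signal") {
        unname(affinity[p, ][match(tax$host_order, orders)])
      } else NULL
      hosts <- sample(tax$host_species, n_h, prob = prob)
      tibble(parasitoid_species = p, host_species = sort(hosts))
    }) |> bind_rows()
    out <- validate_host_records(left_join(recs, tax, by = "host_species"))
    attr(out, "taxonomy") <- tax
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Generates everything the comparative pipeline consumes: a Yule tree over
#' the scenario's species, individual morphometric measurements, and host
#' records for a random subset of `n_species_with_hosts` species. With
#' `dir` set, the fixture is also written to disk (newick tree, trait and
#' host TSVs, scenario JSON) in exactly the formats the package readers
#' accept.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed; the study is a pure function of
#'   (scenario, seed, regime).
#' @param regime host-assignment regime, see [simulate_host_records()].
#' @param dir optional directory to write the fixture into.
#' @return list with `tree`, `traits`, `hosts`, `scenario`, `regime`,
#'   `seed`, and (when written) `paths`.
#' @export
simulate_study <- function(scenario = synthetic_scenario(), seed = 1,
                           regime = c("none", "signal"), dir = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  regime <- match.arg(regime)
  out <- with_seed_or_stream(seed, {
    tree <- simulate_yule_tree(scenario$n_species, scenario$birth_rate)
    traits <- simulate_measurements(scenario, tree$tip.label)
    with_hosts <- sort(sample(tree$tip.label, scenario$n_species_with_hosts))
    hosts <- simulate_host_records(scenario, with_hosts, regime = regime,
                                   tree = tree)
    list(tree = tree, traits = traits, hosts = hosts)
  })
  out$scenario <- scenario
  out$regime <- regime
  out$seed <- seed
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(tree = file.path(dir, "tree.nwk"),
                  traits = file.path(dir, "traits.tsv"),
                  hosts = file.path(dir, "hosts.tsv"),
                  scenario = file.path(dir, "scenario.json"))
    write_newick(out$tree, paths$tree)
    readr::write_tsv(out$traits, paths$traits)
    readr::write_tsv(out$hosts, paths$hosts)
    jsonlite::write_json(c(unclass(scenario),
                           list(seed = seed, regime = regime)),
                         paths$scenario, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
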