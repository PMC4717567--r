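test_that("Yule trees are ultrametric, deterministic and exponential-waited", {
  tr <- simulate_yule_tree(2, seed = 1)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1], d[2])
  expect_equal(sort(tr$tip.label), c("sp01", "sp02"))

  t1 <- simulate_yule_tree(12, 1.3, seed = 7)
  t2 <- simulate_yule_tree(12, 1.3, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_yule_tree(1), "at least 2")

  # crown waiting time 2 -> 3 lineages is Exp(2 * birth_rate)
  lambda <- 1.5
  waits <- withr::with_seed(17, {
    vapply(1:2000, function(i) {
      tr <- simulate_yule_tree(6, lambda)
      bt <- sort(ape::branching.times(tr), decreasing = TRUE)
      unname(bt[1] - bt[2])
    }, numeric(1))
  })
  mu <- 1 / (2 * lambda)
  expect_lt(abs(mean(waits) - mu), 3 * mu / sqrt(2000))
})

test_that("lineage count through time matches the Yule expectation", {
  lambda <- 1
  t_probe <- 0.5 # early enough that hitting the tip cap is negligible
  counts <- withr::with_seed(19, {
    vapply(1:2000, function(i) {
      tr <- simulate_yule_tree(25, lambda)
      bt <- ape::branching.times(tr)
      height <- max(bt)
      # lineages at time t after the crown: 2 + later branchings before t
      2 + sum((height - bt) < t_probe & (height - bt) > 0)
    }, numeric(1))
  })
  expected <- 2 * exp(lambda * t_probe) # two independent Yule processes
  expect_lt(abs(mean(counts) - expected),
            3 * stats::sd(counts) / sqrt(2000))
})

test_that("random binary traits are uniform over k-subsets", {
  tr <- simulate_yule_tree(4, seed = 23)
  draws <- withr::with_seed(24, {
    vapply(1:6000, function(i) {
      bt <- simulate_binary_trait(tr, 2, "random")
      paste(bt$species[bt$state == 1], collapse = "+")
    }, character(1))
  })
  tab <- table(draws)
  expect_equal(length(tab), 6) # all C(4,2) subsets observed
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  bt <- simulate_binary_trait(tr, 3, "random", seed = 1)
  expect_equal(sum(bt$state), 3)
})

test_that("Brownian-threshold traits cluster within clades", {
  # deep two-clade tree: both 1-tips land in the same clade far more often
  # under the Brownian threshold than under random assignment
  tr <- ape::read.tree(
    text = "((a:0.1,b:0.1):5,(c:0.1,d:0.1):5);")
  same_clade <- function(mode) {
    withr::with_seed(29, {
      mean(vapply(1:2000, function(i) {
        bt <- simulate_binary_trait(tr, 2, mode)
        ones <- bt$species[bt$state == 1]
        all(ones %in% c("a", "b")) || all(ones %in% c("c", "d"))
      }, logical(1)))
    })
  }
  expect_gt(same_clade("brownian_threshold"), same_clade("random") + 0.2)
})

test_that("measurements recover the truth and honour the scenario", {
  sc <- synthetic_scenario()
  species <- species_labels(sc$n_species)

  noiseless <- synthetic_scenario(measurement_cv = 0)
  recs0 <- simulate_measurements(noiseless, species, seed = 31)
  truth <- attr(recs0, "truth")
  s0 <- species_summaries(recs0)
  expect_equal(s0$aos_median, truth$aos_true[match(s0$species, truth$species)])
  expect_equal(s0$ros_median, truth$ros_true[match(s0$species, truth$species)])

  recs <- simulate_measurements(sc, species, seed = 32)
  expect_equal(nrow(recs), sum(attr(recs, "truth")$n_individuals))
  expect_equal(sum(attr(recs, "truth")$n_individuals == 1), sc$n_singletons)
  expect_true(all(attr(recs, "truth")$n_individuals[
    attr(recs, "truth")$n_individuals > 1] >= 2))

  # default noise: recovered medians within 10% of truth for >=95% of species
  hits <- withr::with_seed(33, {
    unlist(lapply(1:50, function(i) {
      r <- simulate_measurements(sc, species)
      tr <- attr(r, "truth")
      s <- species_summaries(r)
      abs(s$aos_median / tr$aos_true[match(s$species, tr$species)] - 1) < 0.1
    }))
  })
  expect_gt(mean(hits), 0.95)
})

test_that("host records honour the scenario taxonomy and specialist rules", {
  sc <- synthetic_scenario()
  hosts <- simulate_host_records(sc, species_labels(13), seed = 41)
  tax <- attr(hosts, "taxonomy")
  expect_equal(nrow(tax), sc$n_host_species)
  expect_equal(dplyr::n_distinct(tax$host_family), sc$n_host_families)
  expect_equal(dplyr::n_distinct(tax$host_order), sc$n_host_orders)
  expect_equal(dplyr::n_distinct(tax$plant_family), sc$n_plant_families)

  all_spec <- synthetic_scenario(specialist_fraction = 1)
  hosts1 <- simulate_host_records(all_spec, species_labels(13), seed = 42)
  counts <- summarize_host_ranges(hosts1)
  expect_true(all(counts$n_host_species == 1))

  # signal regime needs the tree and clusters host orders in clades
  tr <- simulate_yule_tree(13, seed = 43)
  expect_error(simulate_host_records(sc, tr$tip.label, regime = "signal"),
               "requires a tree")
  hosts_sig <- simulate_host_records(sc, tr$tip.label, seed = 44,
                                     regime = "signal", tree = tr)
  expect_s3_class(hosts_sig, "tbl_df")
})

test_that("a simulated study round-trips through the readers", {
  dir <- withr::local_tempdir()
  study <- simulate_study(synthetic_scenario(), seed = 51, dir = dir)
  tree <- read_newick(study$paths$tree)
  traits <- read_trait_table(study$paths$traits)
  hosts <- read_host_records(study$paths$hosts)
  expect_true(ape::all.equal.phylo(tree, study$tree, use.edge.length = TRUE,
                                   tolerance = 1e-8))
  expect_equal(as.data.frame(traits), as.data.frame(study$traits),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(hosts), as.data.frame(study$hosts),
               ignore_attr = TRUE)
  expect_equal(length(tree$tip.label), study$scenario$n_species)
  expect_equal(dplyr::n_distinct(hosts$parasitoid_species),
               study$scenario$n_species_with_hosts)

  # pure function of (scenario, seed)
  study2 <- simulate_study(synthetic_scenario(), seed = 51)
  expect_identical(ape::write.tree(study2$tree), ape::write.tree(study$tree))
  expect_equal(as.data.frame(study2$traits), as.data.frame(study$traits),
               ignore_attr = TRUE)
})
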