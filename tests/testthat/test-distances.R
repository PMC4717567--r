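test_that("patristic matrix equals brute-force path enumeration", {
  tr2 <- ape::read.tree(text = "(A:1,B:2);")
  pm <- patristic_matrix(tr2)
  expect_equal(pm["A", "B"], 3)
  expect_equal(diag(unclass(pm)), c(A = 0, B = 0))

  for (seed in 1:6) {
    n <- withr::with_seed(seed, sample(4:10, 1))
    tr <- random_tree(n, seed = seed * 100)
    pm <- patristic_matrix(tr)
    brute <- brute_patristic(tr)
    expect_equal(unclass(pm), brute[rownames(pm), colnames(pm)],
                 tolerance = 1e-10, ignore_attr = TRUE)
    # triangle inequality on the fuzzed tree
    m <- unclass(pm)
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      expect_true(m[i, j] <= m[i, k] + m[k, j] + 1e-9)
    }
  }
})

test_that("between-species-median patristic mode medians conspecific pairs", {
  tr <- ape::read.tree(text = "((k1:1,k2:2):1,(u1:1,u2:3):2);")
  map <- c(k1 = "K", k2 = "K", u1 = "U", u2 = "U")
  pm <- patristic_matrix(tr, "between_species_median", map)
  pat <- ape::cophenetic.phylo(tr)
  expect_equal(pm["K", "U"],
               median(c(pat["k1", "u1"], pat["k1", "u2"],
                        pat["k2", "u1"], pat["k2", "u2"])))
  expect_error(patristic_matrix(tr, "between_species_median",
                                c(k1 = "K", k2 = "K", u1 = "U")), "u2")
})

test_that("relative-difference matrix hits its analytic values", {
  rd <- relative_difference_matrix(c(a = 5, b = 5, c = 1, d = 3, e = 0))
  expect_equal(rd["a", "b"], 0)           # identical medians
  expect_equal(rd["c", "d"], 1.0)         # |1-3| / 2
  expect_equal(rd["e", "c"], 2.0)         # zero vs positive: the supremum
  expect_true(all(unclass(rd) <= 2 + 1e-12))

  # 0/0 defined as 0
  rd0 <- relative_difference_matrix(c(a = 0, b = 0, c = 1))
  expect_equal(rd0["a", "b"], 0)

  # scale-free: multiplying all medians by k changes nothing
  v <- c(x = 2, y = 7, z = 11, w = 3)
  expect_equal(unclass(relative_difference_matrix(v * 137)),
               unclass(relative_difference_matrix(v)))

  expect_error(relative_difference_matrix(c(a = -1, b = 2)), "non-negative")
})

test_that("incidence collapse counts distinct taxa per level", {
  recs <- tibble::tibble(
    parasitoid_species = c("P1", "P1"), host_species = c("h1", "h2"),
    host_family = "f1", host_order = "o1", plant_family = c("p1", "p1"))
  inc_f <- collapse_incidence(recs, "host_family")
  expect_equal(dim(inc_f), c(1L, 1L))
  expect_equal(sum(inc_f), 1)
  inc_s <- collapse_incidence(recs, "host_species")
  expect_equal(sum(inc_s), 2)

  # set-count oracle on a synthetic table
  hosts <- simulate_host_records(synthetic_scenario(), species_labels(13),
                                 seed = 21)
  for (lv in c("host_species", "host_family", "host_order", "plant_family")) {
    inc <- suppressMessages(collapse_incidence(hosts, lv))
    expect_equal(ncol(inc), length(unique(stats::na.omit(hosts[[lv]]))))
    expect_true(all(rowSums(inc) >= 1))
  }
})

test_that("missing plant families are dropped and empty parasitoids excluded", {
  recs <- tiny_host_table()
  expect_message(inc <- collapse_incidence(recs, "plant_family"),
                 "dropped 1 record")
  expect_equal(attr(inc, "dropped_records"), 1L)
  expect_true(all(c("spA", "spC", "spD") %in% rownames(inc)))

  only_na <- recs
  only_na$plant_family[recs$parasitoid_species == "spD"] <- NA
  expect_warning(
    inc2 <- suppressMessages(collapse_incidence(only_na, "plant_family")),
    "excluded: spD")
  expect_false("spD" %in% rownames(inc2))
})

test_that("binary Bray-Curtis matches the closed form and a set oracle", {
  inc <- matrix(c(1, 1, 0,   0, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("P1", "P2"), c("h1", "h2", "h3")))
  bc <- bray_curtis_matrix(inc)
  expect_equal(bc["P1", "P2"], 0.5) # a=1, b=1, c=1

  ident <- matrix(1, 2, 3, dimnames = list(c("P1", "P2"), c("a", "b", "c")))
  expect_equal(bray_curtis_matrix(ident)["P1", "P2"], 0)
  disj <- rbind(P1 = c(1, 1, 0, 0), P2 = c(0, 0, 1, 1))
  colnames(disj) <- letters[1:4]
  expect_equal(bray_curtis_matrix(disj)["P1", "P2"], 1)

  # fuzzed: (b+c)/(2a+b+c) via explicit set operations, and vegan cross-check
  withr::with_seed(9, {
    for (rep in 1:10) {
      m <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12,
                  dimnames = list(sprintf("P%02d", 1:8), sprintf("h%02d", 1:12)))
      m[rowSums(m) == 0, 1] <- 1L
      bc <- bray_curtis_matrix(m)
      for (i in 1:7) for (j in (i + 1):8) {
        si <- which(m[i, ] == 1); sj <- which(m[j, ] == 1)
        a <- length(intersect(si, sj))
        b <- length(setdiff(si, sj)); c_ <- length(setdiff(sj, si))
        expect_equal(unclass(bc)[rownames(m)[i], rownames(m)[j]],
                     (b + c_) / (2 * a + b + c_))
      }
      veg <- as.matrix(vegan::vegdist(m, method = "bray"))
      expect_equal(unclass(bc), veg[rownames(bc), colnames(bc)],
                   tolerance = 1e-12, ignore_attr = TRUE)
      # duplicating every host column leaves the matrix unchanged
      m_dup <- cbind(m, m)
      colnames(m_dup) <- c(colnames(m), paste0(colnames(m), "_dup"))
      expect_equal(unclass(bray_curtis_matrix(m_dup)), unclass(bc),
                   ignore_attr = TRUE)
    }
  })
})
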