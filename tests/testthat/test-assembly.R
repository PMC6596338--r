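test_that("patristic distances sum branch lengths along tip paths", {
  two <- ape::read.tree(text = "(A:0.1,B:0.2);")
  D <- patristic_distances(two)
  expect_equal(D["A", "B"], 0.3)
  expect_equal(diag(D), c(A = 0, B = 0))
  tree <- generate_tree(10, seed = 3, ultrametric = FALSE)
  expect_equal(patristic_distances(tree),
               patristic_oracle(tree)[tree$tip.label, tree$tip.label],
               tolerance = 1e-12)
  noblen <- ape::read.tree(text = "(A,B);")
  expect_error(patristic_distances(noblen), "branch length")
})

test_that("Bray-Curtis matches hand arithmetic and vegan", {
  expect_equal(bray_curtis(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5)), 0)
  expect_equal(bray_curtis(c(A = 1), c(B = 1)), 1)
  expect_equal(bray_curtis(c(A = 0.7, B = 0.3), c(A = 0.3, B = 0.7)), 0.4)
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- stats::runif(8)
      y <- stats::runif(8)
      names(x) <- names(y) <- letters[1:8]
      expect_equal(bray_curtis(x, y),
                   as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                   tolerance = 1e-12)
    }
  })
})

test_that("beta-MNTD equals the naive double-loop oracle", {
  # hand-computed two-vs-one community case
  D <- matrix(c(0, 0.1, 0.2,
                0.1, 0, 0.4,
                0.2, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(beta_mntd(c(A = 0.5, B = 0.5), c(C = 1), D), 0.25)
  # identical communities have zero turnover
  expect_equal(beta_mntd(c(A = 0.4, C = 0.6), c(A = 0.4, C = 0.6), D), 0)
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(4:15, 1)
      tree <- ape::rtree(n)
      tree$tip.label <- paste0("t", seq_len(n))
      Dm <- patristic_distances(tree)
      k <- sample(n, sample(2:n, 1))
      m <- sample(n, sample(2:n, 1))
      rk <- stats::runif(length(k)); rk <- setNames(rk / sum(rk), paste0("t", k))
      rm_ <- stats::runif(length(m)); rm_ <- setNames(rm_ / sum(rm_), paste0("t", m))
      expect_equal(beta_mntd(rk, rm_, Dm), bmntd_oracle(rk, rm_, Dm),
                   tolerance = 1e-12)
    }
  })
})

test_that("beta-MNTD agrees with picante's abundance-weighted comdistnt", {
  skip_if_not_installed("picante")
  withr::with_seed(21, {
    tree <- ape::rtree(12)
    counts <- matrix(stats::rpois(24, 8), 2, 12,
                     dimnames = list(c("s1", "s2"), tree$tip.label))
    counts[counts == 0] <- 1
    rel <- counts / rowSums(counts)
    ours <- beta_mntd(rel[1, ], rel[2, ], patristic_distances(tree))
    theirs <- as.numeric(picante::comdistnt(counts, ape::cophenetic.phylo(tree),
                                            abundance.weighted = TRUE))
    expect_equal(ours, theirs, tolerance = 1e-10)
  })
})

test_that("beta-NTI handles degenerate nulls and is reproducible", {
  # star tree: all pairwise distances equal, the tip shuffle cannot move
  # beta-MNTD, so the null sd collapses
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  D <- patristic_distances(star)
  expect_warning(
    r <- beta_nti(c(A = 0.6, B = 0.4), c(C = 0.5, D = 0.5), D,
                  n_reps = 25, seed = 1),
    "degenerate"
  )
  expect_true(is.na(r$beta_nti))
  tree <- generate_tree(20, seed = 2)
  Dm <- patristic_distances(tree)
  rk <- setNames(rep(0.2, 5), tree$tip.label[1:5])
  rm_ <- setNames(rep(0.25, 4), tree$tip.label[10:13])
  a <- beta_nti(rk, rm_, Dm, n_reps = 99, seed = 7)
  b <- beta_nti(rk, rm_, Dm, n_reps = 99, seed = 7)
  expect_identical(a, b)
  expect_equal(a$beta_nti, (a$beta_mntd - a$null_mean) / a$null_sd)
})

test_that("RC-bray saturates for disjoint pairs and stays within [-1, 1]", {
  withr::with_seed(31, {
    pool <- paste0("o", 1:40)
    meta <- matrix(stats::rpois(6 * 40, 15), 6, 40,
                   dimnames = list(paste0("s", 1:6), pool))
    k <- setNames(c(stats::rpois(20, 50) + 1, rep(0, 20)), pool)
    m <- setNames(c(rep(0, 20), stats::rpois(20, 50) + 1), pool)
    rc <- rc_bray(k, m, meta, n_reps = 199, seed = 3)
    expect_equal(rc, 1)
    # identical composition undercuts essentially every null
    same <- setNames(stats::rpois(40, 20) + 1, pool)
    rc2 <- rc_bray(same, same, meta, n_reps = 199, seed = 3)
    expect_lte(rc2, -0.95)
    expect_true(abs(rc) <= 1 && abs(rc2) <= 1)
  })
})

test_that("assembly classification follows the two-stage thresholds", {
  expect_equal(classify_assembly(2.5, 0.1), "variable_selection")
  expect_equal(classify_assembly(-2.5, 0.99), "homogeneous_selection")
  expect_equal(classify_assembly(1.63, 1.0), "dispersal_limitation")
  expect_equal(classify_assembly(-0.61, -0.99), "homogenizing_dispersal")
  expect_equal(classify_assembly(0, 0), "undominated")
  expect_equal(classify_assembly(NA, 0.5), "undefined")
  expect_equal(classify_assembly(c(3, 0), c(0, 1)),
               c("variable_selection", "dispersal_limitation"))
})

test_that("assembly analysis yields one row per unordered pair, reproducibly", {
  sc <- suppressMessages(generate_scenario(scenario_config(seed = 9)))
  gw <- sc$bundle$bulk_water[grepl("^H[1-9][0-9]_", sc$bundle$bulk_water$sample_id), ]
  r1 <- suppressMessages(assembly_analysis(gw, sc$bundle$tree, depth = 2000,
                                           n_reps = 49, seed = 5))
  expect_equal(nrow(r1), choose(4, 2))
  expect_true(all(r1$sample_1 < r1$sample_2))
  r2 <- suppressMessages(assembly_analysis(gw, sc$bundle$tree, depth = 2000,
                                           n_reps = 49, seed = 5))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(r1$process %in% c("variable_selection", "homogeneous_selection",
                                    "dispersal_limitation", "homogenizing_dispersal",
                                    "undominated", "undefined")))
})

test_that("fraction-merged assembly integerizes merged profiles to depth", {
  sc <- suppressMessages(generate_scenario(scenario_config(seed = 13)))
  b <- sc$bundle
  gw_ids <- b$metadata$sample_id[b$metadata$compartment == "groundwater"]
  res <- suppressMessages(
    assembly_analysis(b$counts, b$tree, samples = gw_ids, depth = 1500,
                      n_reps = 29, seed = 2, metadata = b$metadata,
                      qpcr = b$qpcr)
  )
  expect_equal(nrow(res), choose(4, 2))
  expect_true(all(is.finite(res$rc_bray)))
})
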