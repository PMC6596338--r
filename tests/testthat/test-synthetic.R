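test_that("simulated trees have the requested size, shape and determinism", {
  t3 <- generate_tree(3, seed = 1)
  expect_equal(length(t3$tip.label), 3)
  expect_equal(t3$Nnode, 2)
  tu <- generate_tree(25, seed = 2, ultrametric = TRUE)
  depths <- ape::node.depth.edgelength(tu)[seq_len(25)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_identical(ape::write.tree(generate_tree(40, seed = 9)),
                   ape::write.tree(generate_tree(40, seed = 9)))
  expect_error(generate_tree(2), "n_otus")
})

test_that("filter-fraction counts add back to the pre-split sample exactly", {
  sc <- suppressMessages(generate_scenario(scenario_config(seed = 4)))
  counts <- as.matrix(sc$bundle$counts[, -1])
  rownames(counts) <- sc$bundle$counts$sample_id
  bulk <- as.matrix(sc$bundle$bulk_water[, -1])
  rownames(bulk) <- sc$bundle$bulk_water$sample_id
  for (bid in rownames(bulk)) {
    expect_identical(counts[paste0(bid, "_F01"), ] + counts[paste0(bid, "_F02"), ],
                     bulk[bid, ])
  }
})

test_that("qPCR fraction totals are consistent with read partition shares", {
  sc <- suppressMessages(generate_scenario(scenario_config(seed = 6)))
  b <- sc$bundle
  w <- fraction_weights(b$qpcr)
  counts <- as.matrix(b$counts[, -1])
  rownames(counts) <- b$counts$sample_id
  h13 <- w[w$site == "H13" & w$time_point == "T1", ]
  share01 <- sum(counts["H13_T1_F01", ]) /
    (sum(counts["H13_T1_F01", ]) + sum(counts["H13_T1_F02", ]))
  expect_equal(h13$w_f01, share01, tolerance = 1e-9)
})

test_that("the disjoint regime produces wells sharing no OTUs", {
  sc <- suppressMessages(generate_scenario(
    scenario_config(seed = 3, regime = "disjoint", background_share = 0)
  ))
  bulk <- as.matrix(sc$bundle$bulk_water[, -1])
  rownames(bulk) <- sc$bundle$bulk_water$sample_id
  wells <- grep("^H[1-9][0-9]_", rownames(bulk), value = TRUE)
  for (i in seq_along(wells)[-1]) {
    a <- bulk[wells[1], ] > 0
    b <- bulk[wells[i], ] > 0
    expect_equal(sum(a & b), 0)
  }
})

test_that("scenario metadata, taxonomy and tree cross-validate", {
  sc <- suppressMessages(generate_scenario(scenario_config(seed = 8)))
  b <- sc$bundle
  expect_silent(validate_bundle(b$counts, metadata = b$metadata,
                                tree = b$tree, taxonomy = b$taxonomy))
  expect_s3_class(validate_sample_metadata(b$metadata), "tbl_df")
  # soil samples are bulk; water samples carry F01/F02
  md <- b$metadata
  expect_true(all(md$fraction[md$compartment == "soil"] == "bulk"))
  expect_true(all(md$fraction[md$compartment != "soil"] %in% c("F01", "F02")))
})

test_that("ground truth records the scenario wiring", {
  pg <- planted_association_graph(sprintf("Otu%04d", 1:60))
  sc <- suppressMessages(generate_scenario(
    scenario_config(seed = 5, n_otus = 60, regime = "neutral", planted_graph = pg)
  ))
  tr <- sc$truth
  expect_equal(tr$regime, "neutral")
  expect_equal(tr$passage_prob[["focal"]], 0.25)
  expect_equal(tr$mobilization_multiplier, 100)
  expect_true(all(tr$focal_otus %in% sc$bundle$tree$tip.label))
  expect_equal(nrow(tr$planted_edges), nrow(pg))
  expect_error(
    generate_scenario(scenario_config(
      seed = 5, n_otus = 60, planted_graph = tibble::tibble(
        from = "OtuXXXX", to = "Otu0001", effect = 1)
    )),
    "unknown OTU"
  )
  expect_error(planted_association_graph(c("a", "b")), "at least")
  expect_error(scenario_config(planted_graph = tibble::tibble(
    from = "a", to = "a", effect = 1)), "self-edges")
})

test_that("bundles round-trip through the package readers", {
  sc <- suppressMessages(generate_scenario(scenario_config(seed = 10)))
  dir <- withr::local_tempdir()
  write_bundle(sc, dir)
  back <- suppressMessages(read_bundle(dir))
  expect_equal(as.data.frame(back$counts), as.data.frame(sc$bundle$counts))
  expect_equal(as.data.frame(back$bulk_water), as.data.frame(sc$bundle$bulk_water))
  expect_equal(sort(back$tree$tip.label), sort(sc$bundle$tree$tip.label))
  expect_equal(patristic_distances(back$tree)[back$tree$tip.label, back$tree$tip.label],
               patristic_distances(sc$bundle$tree)[back$tree$tip.label, back$tree$tip.label],
               tolerance = 1e-8)
  expect_equal(as.data.frame(back$metadata), as.data.frame(sc$bundle$metadata))
  expect_equal(back$qpcr$gene_copies_per_l, sc$bundle$qpcr$gene_copies_per_l,
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$hydrochem), as.data.frame(sc$bundle$hydrochem),
               tolerance = 1e-12)
  expect_equal(back$truth$regime, sc$truth$regime)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("selection scenarios carry niche-sign ground truth", {
  sc <- suppressMessages(generate_scenario(
    scenario_config(seed = 2, regime = "selection")
  ))
  ns <- sc$truth$niche_signs
  expect_true(all(c("clade", "parameter", "sign") %in% names(ns)))
  expect_true(all(ns$sign %in% c(-1, 0, 1) | is.na(ns$sign)))
  # TOC has no environmental slope, so no defined niche sign
  expect_true(all(is.na(ns$sign[ns$parameter == "TOC"]) |
                    ns$sign[ns$parameter == "TOC"] == 0))
  # neutral regimes have no environmental axis
  sc0 <- suppressMessages(generate_scenario(scenario_config(seed = 2)))
  expect_null(sc0$truth$niche_signs)
})
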