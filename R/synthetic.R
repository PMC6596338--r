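# synthetic datasets with known ground truth for every pipeline stage

# deterministic hydrochemistry model: per-parameter baseline, slope against
# the latent environmental axis, noise sd, and a positivity floor
.hydro_params <- function() {
  tibble::tibble(
    parameter = c("DO", "nitrate", "sulfate", "ammonium", "sodium",
                  "potassium", "magnesium", "calcium", "TIC", "TOC"),
    base  = c(5,   2,    40,  0.5, 10,  2,   30,  90,  60,  1.5),
    slope = c(2.5, 1.2,  15, -0.25, -3, 0.8, -8,  10,  -5,  0),
    noise = c(0.3, 0.25, 3,  0.05, 0.8, 0.2, 2,   4,   3,   0.2),
    floor = c(0.05, 0.02, 1, 0.01, 0.5, 0.1, 2,   10,  5,   0.1)
  )
}

#' Scenario configuration for the synthetic-data generator
#'
#' The defaults mirror the emulated study design: a forested recharge area
#' (10 soil samples, 10 seepage lysimeter samples), a hillslope series of
#' four connected groundwater wells, a rare-in-soil focal clade mobilized
#' into seepage with 100-fold odds, a quarter of the focal clade's
#' population passing the 0.2 um filter, and amplicon depths in the
#' 10^4 range.
#'
#' @param seed integer seed for all generation randomness.
#' @param n_otus number of OTUs (tree tips).
#' @param n_clades number of designated clades cut from the tree.
#' @param n_soil,n_seepage numbers of soil and seepage samples.
#' @param wells well labels along the hillslope transect.
#' @param well_distances_km distance of each well from the recharge area.
#' @param n_timepoints sampling time points per well.
#' @param regime assembly regime shaping the groundwater series: one of
#'   `"selection"`, `"homogeneous_selection"`, `"dispersal_limitation"`,
#'   `"homogenizing_dispersal"`, `"neutral"`, `"disjoint"`.
#' @param mobilization_multiplier seepage-transfer odds multiplier of the
#'   focal clade relative to all others.
#' @param soil_focal_share relative abundance of the focal clade in the soil
#'   metacommunity (rare in soil, as for the emulated ultra-small phylum).
#' @param passage_prob_focal,passage_prob_other probability that an
#'   individual of the focal / any other clade passes the 0.2 um filter
#'   (ends up in the 0.1 um fraction).
#' @param read_depth reads per sample (multinomial draw).
#' @param sad_sdlog log-sd of the log-normal species-abundance distribution.
#' @param sample_noise_sdlog per-sample log-normal abundance noise.
#' @param drift_sigma_km Brownian drift variance per km of transect for the
#'   dispersal-limitation regime.
#' @param coupling_sdlog residual log-noise under homogenizing dispersal.
#' @param neutral_sdlog log-noise for the neutral regime.
#' @param niche_breadth Gaussian niche breadth (selection regimes), on the
#'   standardized niche-optimum scale.
#' @param selection_drift_sdlog log-sd of the per-sample fitness lottery in
#'   the selection regimes (within-environment community drift).
#' @param community_size maximum number of resident taxa per groundwater
#'   community (niche packing; the best-scoring taxa become residents).
#' @param background_share relative-abundance share contributed by
#'   background immigration from the seepage source community (mass
#'   effects keeping the regional pool detectable at low abundance).
#' @param env_contrast half-separation of the two environments in the
#'   `"selection"` regime (wells split into env = -contrast / +contrast).
#' @param env_homogeneous common environment value for
#'   `"homogeneous_selection"` (off-centre so filtering favours one flank of
#'   the phylogeny).
#' @param qpcr_log10_range log10 range of total 16S gene copies per litre.
#' @param planted_graph optional tibble (`from`, `to`, `effect`) of planted
#'   positive associations realized as shared log-normal latent factors on
#'   the groundwater samples; see [planted_association_graph()].
#' @param ultrametric whether the simulated tree is ultrametric.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, n_otus = 150, n_clades = 6,
                            n_soil = 10, n_seepage = 10,
                            wells = c("H13", "H31", "H41", "H51"),
                            well_distances_km = c(0.4, 1.6, 3.5, 5.4),
                            n_timepoints = 1,
                            regime = c("dispersal_limitation", "selection",
                                       "homogeneous_selection",
                                       "homogenizing_dispersal", "neutral",
                                       "disjoint"),
                            mobilization_multiplier = 100,
                            soil_focal_share = 0.01,
                            passage_prob_focal = 0.25,
                            passage_prob_other = 0.02,
                            read_depth = 15000,
                            sad_sdlog = 1.5,
                            sample_noise_sdlog = 0.3,
                            drift_sigma_km = 4,
                            coupling_sdlog = 0.05,
                            neutral_sdlog = 0.3,
                            niche_breadth = 0.25,
                            selection_drift_sdlog = 0.5,
                            community_size = 30,
                            background_share = 0.02,
                            env_contrast = 1.5,
                            env_homogeneous = 1.2,
                            qpcr_log10_range = c(7.5, 8.7),
                            planted_graph = NULL,
                            ultrametric = TRUE) {
  regime <- match.arg(regime)
  stopifnot(n_otus >= 3, n_clades >= 2, n_soil >= 1, n_seepage >= 1,
            length(wells) == length(well_distances_km),
            passage_prob_focal >= 0, passage_prob_focal <= 1,
            passage_prob_other >= 0, passage_prob_other <= 1,
            soil_focal_share > 0, soil_focal_share < 1,
            mobilization_multiplier > 0, read_depth >= 100)
  if (!is.null(planted_graph)) {
    if (any(planted_graph$from == planted_graph$to)) {
      rlang::abort("planted graph must not contain self-edges")
    }
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate a birth-death OTU phylogeny
#'
#' @param n_otus number of tips (>= 3).
#' @param seed integer seed.
#' @param ultrametric if `TRUE` (default) a reconstructed birth-death tree
#'   with equal root-to-tip distances; otherwise branch lengths are
#'   independently drawn.
#' @return a rooted `phylo` tree with tip labels `Otu0001`, `Otu0002`, ...
#' @export
generate_tree <- function(n_otus, seed = 1, ultrametric = TRUE) {
  if (n_otus < 3) rlang::abort("n_otus must be >= 3")
  tree <- with_seed_opt(seed, {
    if (ultrametric) {
      ape::rphylo(n_otus, birth = 1, death = 0.5, fossils = FALSE)
    } else {
      ape::rtree(n_otus)
    }
  })
  tree$tip.label <- sprintf("Otu%04d", seq_len(n_otus))
  tree
}

# cut the tree into k clades by average-linkage on patristic distances
.assign_clades <- function(tree, k) {
  D <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, k = k)
  cl[tree$tip.label]
}

#' Planted positive-association graph
#'
#' A sparse design with two hubs (six spokes each) and three five-node
#' chains, used as ground truth for network recovery. Node indices refer to
#' positions in the OTU id vector supplied later.
#'
#' @param otu_ids character vector of OTU ids (needs >= 29).
#' @param effect shared latent-factor effect size on the log-abundance
#'   scale.
#' @return tibble with columns `from`, `to`, `effect`.
#' @export
planted_association_graph <- function(otu_ids, effect = 0.9) {
  if (length(otu_ids) < 29) rlang::abort("need at least 29 OTUs for the default planted graph")
  edges <- rbind(
    cbind(1, 3:8),     # hub 1
    cbind(2, 9:14),    # hub 2
    cbind(15:18, 16:19),
    cbind(20:23, 21:24),
    cbind(25:28, 26:29)
  )
  tibble::tibble(from = otu_ids[edges[, 1]], to = otu_ids[edges[, 2]],
                 effect = effect)
}

# multinomial counts for one sample given unnormalized weights
.draw_counts <- function(weights, depth) {
  as.integer(rmultinom(1, depth, weights / sum(weights)))
}

# split a bulk count vector into F01/F02 by per-OTU passage probabilities
.split_fractions <- function(counts, q) {
  f01 <- rbinom(length(counts), counts, q)
  list(F01 = as.integer(f01), F02 = as.integer(counts - f01))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Builds an internally consistent bundle emulating the soil -> seepage ->
#' groundwater study design: a log-normal soil metacommunity in which a
#' designated focal clade is rare, seepage communities formed by multiplying
#' soil abundances with per-clade mobilization odds, groundwater wells
#' propagated from the seepage community under the configured assembly
#' regime, every water sample split into 0.1 um / 0.2 um filter-fraction
#' counts by per-clade binomial partitioning, qPCR totals consistent with
#' the partition, hydrochemistry driven by the latent environmental axis,
#' and (optionally) planted positive associations via shared log-normal
#' latent factors.
#'
#' @param cfg a [scenario_config()].
#' @return list with `bundle` (elements `tree`, `counts` — soil bulk plus
#'   water fraction samples —, `bulk_water` — pre-split water counts —,
#'   `metadata`, `qpcr`, `hydrochem`, `taxonomy`, `config`) and `truth`
#'   (clade map, focal clade, mobilization and passage parameters, expected
#'   pairwise assembly processes, niche optima and signs, planted edges,
#'   environment values).
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  withr::with_seed(as.integer(cfg$seed), .generate_scenario_impl(cfg))
}

.generate_scenario_impl <- function(cfg) {
  tree <- generate_tree(cfg$n_otus, seed = NULL, ultrametric = cfg$ultrametric)
  # generate_tree(seed = NULL) uses the ambient (seeded) stream
  otus <- tree$tip.label
  clades <- .assign_clades(tree, cfg$n_clades)
  focal <- as.integer(names(sort(table(clades), decreasing = TRUE))[1])

  # soil metacommunity: log-normal SAD, focal clade scaled to its soil share
  ab <- rlnorm(cfg$n_otus, 0, cfg$sad_sdlog)
  names(ab) <- otus
  in_focal <- clades == focal
  ab[in_focal] <- ab[in_focal] / sum(ab[in_focal]) * cfg$soil_focal_share
  ab[!in_focal] <- ab[!in_focal] / sum(ab[!in_focal]) * (1 - cfg$soil_focal_share)

  # seepage metacommunity: mobilization odds
  mult <- ifelse(in_focal, cfg$mobilization_multiplier, 1)
  ab_seep <- ab * mult
  ab_seep <- ab_seep / sum(ab_seep)

  # passage probabilities (0.2 um filter passage -> 0.1 um fraction)
  q <- ifelse(in_focal, cfg$passage_prob_focal, cfg$passage_prob_other)

  # phylogenetically conserved niche optima: clade-level base optima plus
  # Brownian variation along the tree, standardized. The clade component
  # guarantees that a niche flank is phylogenetically clustered regardless
  # of tree shape, which is the conservatism premise the phylogenetic
  # null-model analysis assumes.
  opt_base <- rnorm(cfg$n_clades)
  bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  bm <- (bm - mean(bm)) / stats::sd(bm)
  opt <- opt_base[clades] + 0.35 * bm
  opt <- (opt - mean(opt)) / stats::sd(opt)

  n_wells <- length(cfg$wells)
  env <- switch(cfg$regime,
    selection = ifelse(seq_len(n_wells) <= ceiling(n_wells / 2),
                       -cfg$env_contrast, cfg$env_contrast),
    homogeneous_selection = rep(cfg$env_homogeneous, n_wells),
    rep(0, n_wells)
  )
  names(env) <- cfg$wells

  # Brownian drift along the transect (dispersal limitation)
  drift <- matrix(0, n_wells, cfg$n_otus)
  if (cfg$regime == "dispersal_limitation") {
    d_prev <- 0
    eps <- rnorm(cfg$n_otus, 0, sqrt(cfg$drift_sigma_km * cfg$well_distances_km[1]))
    drift[1, ] <- eps
    for (w in seq_len(n_wells)[-1]) {
      step <- cfg$well_distances_km[w] - cfg$well_distances_km[w - 1]
      eps <- eps + rnorm(cfg$n_otus, 0, sqrt(cfg$drift_sigma_km * max(step, 0.1)))
      drift[w, ] <- eps
    }
  }
  # disjoint regime: contiguous OTU blocks per well
  block <- ((seq_len(cfg$n_otus) - 1) %% n_wells) + 1

  counts_rows <- list(); bulk_rows <- list()
  md_rows <- list(); qpcr_rows <- list(); hydro_rows <- list()

  add_water_sample <- function(rel, site, tp, compartment, assemblage) {
    bulk <- .draw_counts(rel, cfg$read_depth)
    sp <- .split_fractions(bulk, q)
    bid <- paste(site, tp, sep = "_")
    bulk_rows[[bid]] <<- setNames(bulk, otus)
    total_copies <- 10^runif(1, cfg$qpcr_log10_range[1], cfg$qpcr_log10_range[2])
    share01 <- sum(sp$F01) / cfg$read_depth
    for (f in c("F01", "F02")) {
      sid <- paste(site, tp, f, sep = "_")
      counts_rows[[sid]] <<- setNames(sp[[f]], otus)
      md_rows[[sid]] <<- tibble::tibble(sample_id = sid, compartment = compartment,
                                        site = site, time_point = tp, fraction = f,
                                        assemblage = assemblage)
      qpcr_rows[[sid]] <<- tibble::tibble(site = site, time_point = tp, fraction = f,
                                          gene_copies_per_l = total_copies *
                                            if (f == "F01") share01 else 1 - share01)
    }
  }

  # soil samples (bulk, unfractionated)
  for (i in seq_len(cfg$n_soil)) {
    sid <- sprintf("H1-TS%d", i)
    rel <- ab * exp(rnorm(cfg$n_otus, 0, cfg$sample_noise_sdlog))
    counts_rows[[sid]] <- setNames(.draw_counts(rel, cfg$read_depth), otus)
    md_rows[[sid]] <- tibble::tibble(sample_id = sid, compartment = "soil",
                                     site = sid, time_point = "T1",
                                     fraction = "bulk", assemblage = "none")
  }

  # seepage samples (fractionated lysimeter water)
  for (i in seq_len(cfg$n_seepage)) {
    site <- sprintf("H1L1-%d", i)
    rel <- ab_seep * exp(rnorm(cfg$n_otus, 0, cfg$sample_noise_sdlog))
    add_water_sample(rel, site, "T1", "seepage", "none")
  }

  # groundwater wells x time points under the assembly regime
  tps <- sprintf("T%d", seq_len(cfg$n_timepoints))
  edge_idx <- NULL
  if (!is.null(cfg$planted_graph)) {
    edge_idx <- cbind(match(cfg$planted_graph$from, otus),
                      match(cfg$planted_graph$to, otus))
    if (anyNA(edge_idx)) rlang::abort("planted graph references unknown OTU ids")
  }
  for (w in seq_len(n_wells)) {
    well <- cfg$wells[w]
    assemblage <- if (env[w] > 0) "HTU" else "HTL"
    for (tp in tps) {
      # regime-specific local fitness score; under selection, local fitness
      # is the niche match (decoupled from regional abundance), otherwise it
      # tracks the seepage source community
      score <- switch(cfg$regime,
        selection = ,
        homogeneous_selection =
          exp(-(opt - env[w])^2 / (2 * cfg$niche_breadth^2) +
                rnorm(cfg$n_otus, 0, cfg$selection_drift_sdlog)),
        dispersal_limitation =
          ab_seep * exp(drift[w, ] + rnorm(cfg$n_otus, 0, 0.2)),
        homogenizing_dispersal =
          ab_seep * exp(rnorm(cfg$n_otus, 0, cfg$coupling_sdlog)),
        neutral = ab_seep * exp(rnorm(cfg$n_otus, 0, cfg$neutral_sdlog)),
        disjoint = ifelse(block == w, ab_seep, 0)
      )
      # niche packing: under environmental filtering or homogenizing
      # exchange a local community hosts at most `community_size` resident
      # taxa (the best-scoring ones); under drift-driven regimes residency
      # is not niche-bounded. A small mass share of background immigrants
      # from the source keeps the regional species pool detectable at low
      # abundance in either case.
      K <- if (cfg$regime %in% c("selection", "homogeneous_selection",
                                 "homogenizing_dispersal")) {
        min(cfg$community_size, sum(score > 0))
      } else {
        sum(score > 0)
      }
      resident <- rank(-score, ties.method = "first") <= K & score > 0
      sel <- score * resident
      rel <- (1 - cfg$background_share) * sel / sum(sel) +
        cfg$background_share * ab_seep / sum(ab_seep)
      if (!is.null(edge_idx)) {
        z <- rnorm(nrow(edge_idx))
        eff <- cfg$planted_graph$effect * z
        # both endpoints of an edge share that edge's latent factor; a hub
        # accumulates the factors of all its incident edges
        bump <- numeric(cfg$n_otus)
        for (k in seq_len(nrow(edge_idx))) {
          bump[edge_idx[k, 1]] <- bump[edge_idx[k, 1]] + eff[k]
          bump[edge_idx[k, 2]] <- bump[edge_idx[k, 2]] + eff[k]
        }
        rel <- rel * exp(bump)
      }
      add_water_sample(rel, well, tp, "groundwater", assemblage)

      hp <- .hydro_params()
      vals <- pmax(hp$floor, hp$base + hp$slope * env[w] + rnorm(nrow(hp), 0, hp$noise))
      hydro_rows[[paste(well, tp, sep = "_")]] <-
        tibble::as_tibble(c(list(site = well, time_point = tp),
                            setNames(as.list(vals), hp$parameter)))
    }
  }

  counts_m <- do.call(rbind, counts_rows)
  counts <- otu_tibble(counts_m)
  bulk_water <- otu_tibble(do.call(rbind, bulk_rows))
  metadata <- dplyr::bind_rows(md_rows)
  qpcr <- dplyr::bind_rows(qpcr_rows)
  hydrochem <- dplyr::bind_rows(hydro_rows) |>
    dplyr::mutate(sample_id = paste(.data$site, .data$time_point, sep = "_"),
                  .before = 1)

  taxonomy <- tibble::tibble(
    otu_id = otus,
    domain = "Bacteria",
    phylum = ifelse(clades == focal, "Cand_Patescibacteria_like",
                    paste0("Phylum", clades)),
    class = paste0("Class", clades),
    order = paste0("Order", clades),
    family = paste0("Family", clades, "_", ((match(otus, otus) %% 2) + 1)),
    genus = "unclassified"
  )

  truth <- list(
    clades = clades,
    focal_clade = focal,
    focal_otus = otus[in_focal],
    mobilization_multiplier = cfg$mobilization_multiplier,
    passage_prob = c(focal = cfg$passage_prob_focal,
                     other = cfg$passage_prob_other),
    regime = cfg$regime,
    expected_pair_process = .expected_pair_process(cfg, env),
    env = env,
    niche_optima = opt,
    niche_signs = .niche_signs(cfg, clades, opt, env),
    planted_edges = cfg$planted_graph,
    soil_focal_share = cfg$soil_focal_share
  )

  list(bundle = list(tree = tree, counts = counts, bulk_water = bulk_water,
                     metadata = metadata, qpcr = qpcr, hydrochem = hydrochem,
                     taxonomy = taxonomy, config = cfg),
       truth = truth)
}

# expected assembly classification for each unordered well pair
.expected_pair_process <- function(cfg, env) {
  wells <- cfg$wells
  if (length(wells) < 2) return(tibble::tibble())
  pairs <- utils::combn(wells, 2)
  label <- switch(cfg$regime,
    selection = ifelse(env[pairs[1, ]] == env[pairs[2, ]],
                       "homogeneous_selection", "variable_selection"),
    homogeneous_selection = rep("homogeneous_selection", ncol(pairs)),
    dispersal_limitation = rep("dispersal_limitation", ncol(pairs)),
    homogenizing_dispersal = rep("homogenizing_dispersal", ncol(pairs)),
    disjoint = rep("dispersal_limitation", ncol(pairs)),
    neutral = rep(NA_character_, ncol(pairs))
  )
  tibble::tibble(well_1 = pairs[1, ], well_2 = pairs[2, ], expected = label)
}

# sign of the deterministic clade-share vs parameter relationship across
# wells: the expected relative share of a clade at environment e is the
# summed niche weight of its members over the total; NA when the
# environment does not vary
.niche_signs <- function(cfg, clades, opt, env) {
  if (length(unique(env)) < 2) return(NULL)
  hp <- .hydro_params()
  wmat <- vapply(env, function(e) exp(-(opt - e)^2 / (2 * cfg$niche_breadth^2)),
                 numeric(length(opt)))
  total <- colSums(wmat)
  clade_ids <- sort(unique(clades))
  rows <- lapply(clade_ids, function(cl) {
    share <- colSums(wmat[clades == cl, , drop = FALSE]) / total
    sgn <- vapply(seq_len(nrow(hp)), function(i) {
      par_det <- hp$base[i] + hp$slope[i] * env
      if (stats::sd(share) == 0 || stats::sd(par_det) == 0) return(NA_real_)
      sign(stats::cor(share, par_det))
    }, numeric(1))
    tibble::tibble(clade = cl, parameter = hp$parameter, sign = sgn)
  })
  dplyr::bind_rows(rows)
}

#' Write a synthetic bundle to disk in the package's canonical formats
#'
#' Emits `otu_table.tsv`, `bulk_water.tsv`, `tree.nwk`, `taxonomy.tsv`,
#' `metadata.csv`, `qpcr.csv`, `hydrochem.csv` and `ground_truth.json`, all
#' round-trippable through the package readers.
#'
#' @param scenario the list returned by [generate_scenario()] (or its
#'   `bundle` element).
#' @param dir destination directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(scenario, dir) {
  bundle <- scenario$bundle %||% scenario
  truth <- scenario$truth
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(bundle$counts, file.path(dir, "otu_table.tsv"))
  write_otu_table(bundle$bulk_water, file.path(dir, "bulk_water.tsv"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(bundle$taxonomy, file.path(dir, "taxonomy.tsv"), progress = FALSE)
  readr::write_csv(bundle$metadata, file.path(dir, "metadata.csv"), progress = FALSE)
  readr::write_csv(bundle$qpcr, file.path(dir, "qpcr.csv"), progress = FALSE)
  readr::write_csv(dplyr::select(bundle$hydrochem, -"sample_id"),
                   file.path(dir, "hydrochem.csv"), progress = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @return list with `counts`, `bulk_water`, `tree`, `taxonomy`, `metadata`,
#'   `qpcr`, `hydrochem` and (if present) `truth`.
#' @export
read_bundle <- function(dir) {
  out <- list(
    counts = read_otu_table(file.path(dir, "otu_table.tsv")),
    bulk_water = read_otu_table(file.path(dir, "bulk_water.tsv")),
    tree = ape::read.tree(file.path(dir, "tree.nwk")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    metadata = read_sample_metadata(file.path(dir, "metadata.csv")),
    qpcr = read_qpcr(file.path(dir, "qpcr.csv")),
    hydrochem = read_hydrochem(file.path(dir, "hydrochem.csv"))
  )
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) out$truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  out
}

#' Named scenario presets for the assembly regimes
#'
#' Each preset couples an assembly regime with a sampling design sized for
#' its signal: the selection regimes need a wide regional pool relative to
#' local richness (300 OTUs, three time points per well), while the
#' dispersal regimes are sharpest with the compact four-well single-time
#' design (150 OTUs). The returned list also records the rarefaction depth
#' at which the assembly analysis resolves the regime.
#'
#' @param regime one of `"selection"`, `"homogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"neutral"`,
#'   `"disjoint"`.
#' @param seed integer seed.
#' @param ... further overrides passed to [scenario_config()].
#' @return list with `config` (a [scenario_config()]) and `depth` (the
#'   recommended rarefaction depth for [assembly_analysis()]).
#' @export
scenario_preset <- function(regime, seed = 1, ...) {
  selectionish <- regime %in% c("selection", "homogeneous_selection")
  cfg <- scenario_config(
    seed = seed, regime = regime,
    n_otus = if (selectionish) 300 else 150,
    n_timepoints = if (selectionish) 3 else 1,
    ...
  )
  list(config = cfg, depth = if (selectionish) 2000 else 5000)
}
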