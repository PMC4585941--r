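# a unit-variance background usable for any k in k_set, decoupled from the
# data under test
fixed_background <- function(k_set, seed = 123, universe = "genes") {
  pool <- local({set.seed(seed); as.numeric(scale(rnorm(400)))})
  build_background(pool, k_set, n_samples = 500, seed = seed,
                   universe = universe)
}

test_that("a network with all-null genes has zero raw metabolite scores", {
  net <- toy_network()
  stats <- make_gene_stats(paste0("g", 1:4), rep(0.5, 4))  # z = 0 everywhere
  rs <- map_genes_to_reactions(net, stats)
  mets <- reporter_metabolites(net, rs, background = fixed_background(1:2))
  expect_equal(mets$raw_z, rep(0, nrow(mets)))
  expect_equal(mets$k[mets$metabolite == "B"], 2L)   # g1 and g2
})

test_that("metabolites without measured neighbors are omitted with a message", {
  net <- metabolic_network(
    reaction_metabolites = list(R1 = c("A", "B"), R2 = c("C", "D")),
    reaction_genes = list(R1 = "g1", R2 = "g2"))
  stats <- make_gene_stats("g1", 0.2)   # R2 unmeasured
  rs <- map_genes_to_reactions(net, stats)
  expect_message(
    mets <- reporter_metabolites(net, rs, background = fixed_background(1),
                                 gene_pool = c(g1 = 1, gx = -1)),
    "omitted")
  expect_setequal(mets$metabolite, c("A", "B"))
  stats_none <- make_gene_stats("gz", 0.2)
  map_rs <- map_genes_to_reactions(net, stats_none)
  expect_error(reporter_metabolites(net, map_rs), "no measured reactions")
})

test_that("an isolated strong gene makes its metabolite the top reporter", {
  net <- toy_network()
  stats <- make_gene_stats(paste0("g", 1:4), c(1e-6, 0.5, 0.6, 0.5))
  rs <- map_genes_to_reactions(net, stats)
  mets <- reporter_metabolites(net, rs, background = fixed_background(1:2))
  expect_equal(mets$metabolite[which.min(mets$p_value)], "A")  # only g1
})

test_that("metabolite and pathway tables match the brute-force evaluator", {
  for (seed in c(31, 32)) {
    net <- generate_network(n_pathways = 3, reactions_per_pathway = 4,
                            cross_link_fraction = 0.4,
                            genes_per_reaction = 2, seed = seed)
    genes <- network_genes(net)
    stats <- make_gene_stats(genes,
                             local({set.seed(seed); runif(length(genes))}))
    rs <- map_genes_to_reactions(net, stats)
    mets <- reporter_metabolites(net, rs, n_samples = 300, seed = seed)
    want_m <- oracle_metabolites(net, rs, attr(mets, "background"))
    expect_equal(mets$metabolite, want_m$metabolite)
    expect_equal(mets$raw_z, want_m$raw_z, tolerance = 1e-9)
    expect_equal(mets$corrected_z, want_m$corrected_z, tolerance = 1e-9)
    expect_equal(mets$p_value, want_m$p_value, tolerance = 1e-9)

    idx <- build_pathway_index(net)
    rpam <- reporter_pathways_rpam(net, idx, mets, universe = "metabolite",
                                   n_samples = 300, seed = seed + 1)
    want_p <- oracle_rpam(net, mets, attr(rpam, "background"))
    expect_equal(rpam$pathway, want_p$pathway)
    expect_equal(rpam$raw_z, want_p$raw_z, tolerance = 1e-9)
    expect_equal(rpam$corrected_z, want_p$corrected_z, tolerance = 1e-9)

    rpar <- reporter_pathways_rpar(net, idx, rs, n_samples = 300,
                                   seed = seed + 2)
    want_r <- oracle_rpar(net, rs, attr(rpar, "background"))
    expect_equal(rpar$pathway, want_r$pathway)
    expect_equal(rpar$raw_z, want_r$raw_z, tolerance = 1e-9)
    expect_equal(rpar$corrected_z, want_r$corrected_z, tolerance = 1e-9)
    expect_equal(rpar$p_value, want_r$p_value, tolerance = 1e-9)
  }
})

test_that("gene-universe pathway correction is consistent with its reported moments", {
  net <- generate_network(n_pathways = 3, reactions_per_pathway = 4,
                          cross_link_fraction = 0.3, seed = 41)
  genes <- network_genes(net)
  stats <- make_gene_stats(genes, local({set.seed(41); runif(length(genes))}))
  rs <- map_genes_to_reactions(net, stats)
  mets <- reporter_metabolites(net, rs, n_samples = 300, seed = 42)
  idx <- build_pathway_index(net)
  rpam <- reporter_pathways_rpam(net, idx, mets, universe = "gene",
                                 n_samples = 300, seed = 43)
  # raw aggregates must equal the brute-force Stouffer sum of corrected
  # metabolite scores, and corrected scores must standardize raw against the
  # reported per-pathway background moments
  for (i in seq_len(nrow(rpam))) {
    pw <- rpam$pathway[i]
    mets_pw <- intersect(idx$metabolites[[pw]], mets$metabolite)
    raw <- sum(mets$corrected_z[match(mets_pw, mets$metabolite)]) /
      sqrt(length(mets_pw))
    expect_equal(rpam$raw_z[i], raw, tolerance = 1e-9)
    expect_equal(rpam$corrected_z[i],
                 (raw - rpam$bg_mu[i]) / rpam$bg_sigma[i], tolerance = 1e-12)
    expect_equal(rpam$p_value[i],
                 pnorm(rpam$corrected_z[i], lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("lowering a gene p-value never lowers a touching pathway's raw score", {
  net <- generate_network(n_pathways = 4, reactions_per_pathway = 4,
                          cross_link_fraction = 0.3, seed = 51)
  genes <- network_genes(net)
  p0 <- local({set.seed(51); runif(length(genes), 0.2, 0.9)})
  idx <- build_pathway_index(net)
  met_bg <- fixed_background(1:4)
  score <- function(p) {
    stats <- make_gene_stats(genes, p)
    rs <- map_genes_to_reactions(net, stats)
    mets <- reporter_metabolites(net, rs, background = met_bg)
    reporter_pathways_rpam(net, idx, mets, universe = "metabolite",
                           background = fixed_background(1:30))
  }
  before <- score(p0)
  g <- genes[7]
  rxns_of_g <- names(net$reaction_genes)[vapply(net$reaction_genes,
    function(x) g %in% x, logical(1))]
  touched_mets <- unique(unlist(net$reaction_metabolites[rxns_of_g]))
  touching <- names(idx$metabolites)[vapply(idx$metabolites,
    function(m) any(touched_mets %in% m), logical(1))]
  p1 <- p0; p1[genes == g] <- 0.001
  after <- score(p1)
  for (pw in touching) {
    expect_gte(after$raw_z[after$pathway == pw],
               before$raw_z[before$pathway == pw])
  }
})

test_that("branch-point genes contribute once per adjacent metabolite", {
  # hub pathway: R1..R3 all touch M00; gene gi also touches Mi
  net <- generate_network(n_pathways = 2, reactions_per_pathway = 3,
                          cross_link_fraction = 0, seed = 61,
                          topology = "hub")
  genes <- network_genes(net)
  p <- local({set.seed(61); runif(length(genes), 0.05, 0.5)})
  stats <- make_gene_stats(genes, p)
  rs <- map_genes_to_reactions(net, stats)
  mets <- reporter_metabolites(net, rs, background = fixed_background(1:3))
  idx <- build_pathway_index(net)
  rpam <- reporter_pathways_rpam(net, idx, mets, universe = "metabolite",
                                 metabolite_value = "raw",
                                 background = fixed_background(4))
  z <- stats::setNames(stats$z, stats$gene)
  for (pw in c("P01", "P02")) {
    gpw <- sort(grep(pw, genes, value = TRUE))
    zs <- z[gpw]
    # raw metabolite scores: hub = (z1+z2+z3)/sqrt(3), spokes = z_i, so the
    # pathway aggregate counts every gene twice (hub + its spoke):
    hand <- (sum(zs) / sqrt(3) + sum(zs)) / sqrt(4)
    dedup <- (sum(zs) / sqrt(3)) / sqrt(4) + 0  # genes counted once
    expect_equal(rpam$raw_z[rpam$pathway == pw], unname(hand),
                 tolerance = 1e-12)
    expect_false(isTRUE(all.equal(hand, dedup)))
  }
})

test_that("cross-link genes move the metabolite-centric score only", {
  net <- crosslink_toy()
  idx <- build_pathway_index(net)
  met_bg <- fixed_background(1:2)
  pw_bg <- fixed_background(3:4)
  rx_bg <- fixed_background(3)
  run <- function(p_gB1) {
    p <- c(gA1 = 0.3, gA2 = 0.4, gA3 = 0.35, gB1 = p_gB1, gB2 = 0.45,
           gB3 = 0.4)
    stats <- make_gene_stats(names(p), unname(p))
    rs <- map_genes_to_reactions(net, stats)
    mets <- reporter_metabolites(net, rs, background = met_bg)
    list(rpam = reporter_pathways_rpam(net, idx, mets,
                                       universe = "metabolite",
                                       background = pw_bg),
         rpar = reporter_pathways_rpar(net, idx, rs, background = rx_bg))
  }
  base <- run(0.5)
  hot <- run(0.001)
  # PA's member genes are untouched, yet its metabolite-centric score moves
  # because gB1's reaction consumes PA's metabolite "shared"
  expect_gt(hot$rpam$raw_z[hot$rpam$pathway == "PA"],
            base$rpam$raw_z[base$rpam$pathway == "PA"])
  # while its reaction-centric evidence is bit-identical (the q-value may
  # still move because BH adjusts across the whole table)
  cols <- c("n_reactions", "n_scored", "raw_z", "bg_mu", "bg_sigma",
            "corrected_z", "p_value")
  expect_identical(hot$rpar[hot$rpar$pathway == "PA", cols],
                   base$rpar[base$rpar$pathway == "PA", cols])
})

test_that("pathways with no scored metabolite or reaction are dropped with a warning", {
  net <- metabolic_network(
    reaction_metabolites = list(R1 = c("A", "B"), R2 = c("B", "C"),
                                R3 = c("X", "Y")),
    reaction_genes = list(R1 = "g1", R2 = "g2"),   # R3 geneless
    pathways = list(PA = c("R1", "R2"), PX = "R3"))
  idx <- build_pathway_index(net, min_reactions = 1)
  stats <- make_gene_stats(c("g1", "g2"), c(0.2, 0.3))
  rs <- map_genes_to_reactions(net, stats)
  mets <- suppressMessages(
    reporter_metabolites(net, rs, background = fixed_background(1:2)))
  expect_warning(
    rpam <- reporter_pathways_rpam(net, idx, mets, universe = "metabolite",
                                   background = fixed_background(3)),
    "PX")
  expect_equal(rpam$pathway, "PA")
  expect_warning(
    rpar <- reporter_pathways_rpar(net, idx, rs,
                                   background = fixed_background(2)),
    "PX")
  expect_equal(rpar$pathway, "PA")
})

test_that("significance filtering and ranking follow the cutoff semantics", {
  scores <- structure(
    data.frame(pathway = c("Pa", "Pb", "Pc"), n_scored = c(5L, 9L, 2L),
               p_value = c(0.005, 0.02, 0.5),
               q_value = c(0.015, 0.03, 0.5), stringsAsFactors = FALSE),
    class = c("pathway_scores", "data.frame"))
  expect_equal(significant_pathways(scores, alpha = 1)$pathway,
               c("Pa", "Pb", "Pc"))
  expect_equal(nrow(significant_pathways(scores, alpha = 0)), 0L)
  expect_equal(significant_pathways(scores, alpha = 0.01)$pathway, "Pa")
  # ties: by p, then scored count descending, then id
  tied <- scores; tied$p_value <- c(0.02, 0.02, 0.02)
  expect_equal(significant_pathways(tied, alpha = 1)$pathway,
               c("Pb", "Pa", "Pc"))
  expect_error(significant_pathways(scores, alpha = 2), "alpha")
})

test_that("up-analysis on all-upregulated genes is the one-tailed full analysis", {
  net <- generate_network(n_pathways = 3, reactions_per_pathway = 4,
                          cross_link_fraction = 0.2, seed = 71)
  genes <- network_genes(net)
  p <- local({set.seed(71); runif(length(genes))})
  gs <- make_gene_stats(genes, p, sign = rep(1, length(genes)))
  idx <- build_pathway_index(net)
  up <- suppressMessages(reporter_pathways_directional(
    net, idx, gs, "up", n_samples = 300, seed = 81))
  # manual pipeline on the one-tailed table with the same seeds
  one <- make_gene_stats(genes, p / 2, sign = rep(1, length(genes)))
  rs <- map_genes_to_reactions(net, one)
  mets <- suppressMessages(reporter_metabolites(net, rs, n_samples = 300,
                                                seed = 81))
  full <- reporter_pathways_rpam(net, idx, mets, n_samples = 300, seed = 82)
  expect_equal(as.data.frame(up), as.data.frame(full), ignore_attr = TRUE)
  expect_equal(attr(up, "direction"), "up")
  expect_error(reporter_pathways_directional(net, idx, gs, "down"),
               "down-regulated")
})

test_that("discordance comparison flags metabolite-only hits", {
  rpam <- structure(data.frame(
    pathway = c("PA", "PB"), n_metabolites = c(4L, 4L),
    n_scored = c(4L, 4L), p_value = c(0.002, 0.5),
    q_value = c(0.004, 0.5), stringsAsFactors = FALSE),
    class = c("pathway_scores", "data.frame"))
  rpar <- structure(data.frame(
    pathway = c("PA", "PB"), n_reactions = c(3L, 3L), n_scored = c(3L, 3L),
    p_value = c(0.3, 0.6), q_value = c(0.6, 0.6),
    stringsAsFactors = FALSE),
    class = c("pathway_scores", "data.frame"))
  cmp <- compare_reports(rpam, rpar)
  expect_true(cmp$discordant[cmp$pathway == "PA"])
  expect_false(cmp$discordant[cmp$pathway == "PB"])
  # concordant reports produce no flags
  rpar2 <- rpar; rpar2$p_value <- c(0.001, 0.6)
  expect_false(any(compare_reports(rpam, rpar2)$discordant))
  expect_warning(compare_reports(rpam[0, ], rpar[0, ]), NA)
})
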