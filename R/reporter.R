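#' Reporter metabolite scoring
#'
#' Scores every metabolite of the network by Stouffer aggregation of the
#' Z-scores of its distinct neighbor genes: the selected (minimum-p) genes of
#' all measured reactions that consume or produce the metabolite. If the same
#' gene is selected for two adjacent reactions it contributes a single term.
#' The raw aggregate over `k` genes is standardized against a Monte Carlo
#' background of random size-`k` gene sets drawn from the measured gene pool,
#' and converted to an upper-tail p-value (`1 - pnorm`): large positive
#' corrected scores indicate coordinated transcriptional change around the
#' metabolite. Metabolites with no measured neighbor reaction cannot be
#' scored and are omitted (a message reports how many).
#'
#' @param network a `metabolic_network`.
#' @param reaction_stats a `reaction_stats` table from
#'   [map_genes_to_reactions()].
#' @param background optional prebuilt `background_model` over the gene pool
#'   covering every neighbor count; built internally when `NULL`.
#' @param n_samples,seed Monte Carlo background parameters (used when
#'   `background` is `NULL`).
#' @param gene_pool optional named numeric vector of gene Z-scores to sample
#'   backgrounds from; defaults to the distinct selected genes in
#'   `reaction_stats`.
#' @return A data.frame of class `feature_scores` with one row per scorable
#'   metabolite: `metabolite`, `k` (distinct neighbor genes), `raw_z`,
#'   `bg_mu`, `bg_sigma`, `corrected_z`, `p_value`, `q_value`. Attributes
#'   `background`, `gene_sets` (metabolite -> neighbor gene ids) and
#'   `gene_pool` are attached for pathway-level scoring.
#' @export
reporter_metabolites <- function(network, reaction_stats, background = NULL,
                                 n_samples = 10000L, seed = 1L,
                                 gene_pool = NULL) {
  validate_network(network)
  stopifnot(inherits(reaction_stats, "reaction_stats") ||
              all(c("reaction", "gene", "z") %in% names(reaction_stats)))
  if (nrow(reaction_stats) == 0L)
    stop("no measured reactions: nothing to score", call. = FALSE)

  gene_z <- reaction_stats$z[!duplicated(reaction_stats$gene)]
  names(gene_z) <- reaction_stats$gene[!duplicated(reaction_stats$gene)]
  if (is.null(gene_pool)) gene_pool <- gene_z[sort(names(gene_z))]

  adj <- metabolite_reactions(network)
  measured <- reaction_stats$reaction
  sel_gene <- stats::setNames(reaction_stats$gene, reaction_stats$reaction)

  gene_sets <- lapply(adj, function(rxns)
    sort(unique(unname(sel_gene[intersect(rxns, measured)]))))
  gene_sets <- gene_sets[order(names(gene_sets))]
  scorable <- lengths(gene_sets) > 0L
  if (!any(scorable))
    stop("no metabolite has a measured neighbor reaction", call. = FALSE)
  if (any(!scorable))
    message(sum(!scorable),
            " metabolite(s) without measured neighbors omitted from scoring")
  gene_sets <- gene_sets[scorable]

  k <- lengths(gene_sets)
  raw <- vapply(gene_sets, function(g) aggregate_z(gene_z[g]), numeric(1))
  if (is.null(background))
    background <- build_background(unname(gene_pool), unique(k),
                                   n_samples = n_samples, seed = seed,
                                   universe = "genes")
  bg <- background_lookup(background, k)
  corrected <- (raw - bg$mu) / bg$sigma
  p <- stats::pnorm(corrected, lower.tail = FALSE)
  p <- clamp_p(p)

  out <- data.frame(
    metabolite = names(gene_sets),
    k = unname(k),
    raw_z = unname(raw),
    bg_mu = bg$mu,
    bg_sigma = bg$sigma,
    corrected_z = unname(corrected),
    p_value = unname(p),
    q_value = bh_adjust(unname(p)),
    stringsAsFactors = FALSE,
    row.names = NULL)
  structure(out, background = background, gene_sets = gene_sets,
            gene_pool = gene_pool, feature = "metabolite",
            class = c("feature_scores", "data.frame"))
}

# Pathway-level gene-permutation background: substitutes random distinct
# genes into the pathway's metabolite-neighborhood incidence structure and
# re-applies the metabolite and pathway aggregation. Calibrated under a
# global null even though a pathway's metabolite scores are correlated
# (adjacent metabolites share neighbor genes).
pathway_gene_background <- function(gene_sets, pool, met_bg, n_samples,
                                    corrected = TRUE) {
  mets <- names(gene_sets)
  genes <- sort(unique(unlist(gene_sets, use.names = FALSE)))
  n <- length(mets)
  M <- vapply(mets, function(m) as.numeric(genes %in% gene_sets[[m]]),
              numeric(length(genes)))          # |genes| x n incidence
  k <- lengths(gene_sets)
  idx <- sample_sets(length(pool), length(genes), n_samples)
  Z <- matrix(pool[idx], nrow = n_samples)     # n_samples x |genes|
  rawm <- (Z %*% M) / rep(sqrt(k), each = n_samples)
  if (corrected) {
    bg <- background_lookup(met_bg, k)
    rawm <- (rawm - rep(bg$mu, each = n_samples)) /
      rep(bg$sigma, each = n_samples)
  }
  vals <- rowSums(rawm) / sqrt(n)
  c(mu = mean(vals), sigma = stats::sd(vals))
}

#' Metabolite-centric reporter pathway scoring
#'
#' Scores each retained pathway by Stouffer aggregation of the
#' background-corrected scores of its metabolites (from
#' [reporter_metabolites()]), over `n` = the number of the pathway's
#' metabolites that could be scored. Because a metabolite's score draws on
#' *every* reaction touching it, this statistic credits a pathway with
#' cross-linking reactions catalogued under other pathways, and implicitly
#' up-weights genes adjacent to several of the pathway's metabolites (branch
#' points). The pathway aggregate is itself background-corrected before
#' conversion to an upper-tail p-value.
#'
#' Two background universes are available. The default, `"gene"`, is a
#' structure-preserving permutation null: random distinct genes from the
#' measured pool are substituted into the pathway's own
#' metabolite-neighborhood incidence structure and the full metabolite +
#' pathway aggregation is re-applied; this keeps the correlation between a
#' pathway's metabolite scores in the null and makes corrected pathway
#' Z-scores standard normal under a global null. `"metabolite"` standardizes
#' against random size-`n` sets of corrected metabolite scores drawn
#' network-wide; it ignores that correlation and is anti-conservative for
#' connected pathways, but is retained as the simpler formulation.
#'
#' @param network a `metabolic_network`.
#' @param pathway_index a `pathway_index` from [build_pathway_index()].
#' @param metabolite_scores output of [reporter_metabolites()].
#' @param universe pathway background universe, `"gene"` (default) or
#'   `"metabolite"`.
#' @param metabolite_value which metabolite score enters the aggregation:
#'   `"corrected"` (default) or `"raw"`.
#' @param n_samples,seed Monte Carlo background parameters.
#' @param background optional prebuilt `background_model` over the corrected
#'   metabolite score pool (only used with `universe = "metabolite"`).
#' @return A data.frame of class `pathway_scores`: `pathway`,
#'   `n_metabolites` (nominal metabolite neighbors), `n_scored` (metabolites
#'   entering the aggregate), `raw_z`, `bg_mu`, `bg_sigma`, `corrected_z`,
#'   `p_value`, `q_value`, sorted by pathway id.
#' @export
reporter_pathways_rpam <- function(network, pathway_index, metabolite_scores,
                                   universe = c("gene", "metabolite"),
                                   metabolite_value = c("corrected", "raw"),
                                   n_samples = 10000L, seed = 2L,
                                   background = NULL) {
  universe <- match.arg(universe)
  metabolite_value <- match.arg(metabolite_value)
  stopifnot(inherits(pathway_index, "pathway_index"),
            inherits(metabolite_scores, "feature_scores"))

  val <- if (metabolite_value == "corrected") metabolite_scores$corrected_z
         else metabolite_scores$raw_z
  names(val) <- metabolite_scores$metabolite

  sets <- lapply(pathway_index$metabolites, intersect,
                 y = metabolite_scores$metabolite)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " pathway(s) with no scored metabolite omitted: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  if (length(sets) == 0L)
    stop("no pathway has a scored metabolite", call. = FALSE)
  sets <- sets[sort(names(sets))]
  n <- lengths(sets)
  raw <- vapply(sets, function(m) aggregate_z(val[m]), numeric(1))

  if (universe == "metabolite") {
    if (is.null(background))
      background <- build_background(unname(val), unique(n),
                                     n_samples = n_samples, seed = seed,
                                     universe = "metabolite-scores")
    bg <- background_lookup(background, n)
    mu <- bg$mu; sigma <- bg$sigma
  } else {
    gene_sets <- attr(metabolite_scores, "gene_sets")
    pool <- attr(metabolite_scores, "gene_pool")
    met_bg <- attr(metabolite_scores, "background")
    if (is.null(gene_sets) || is.null(pool) || is.null(met_bg))
      stop("metabolite_scores lacks the gene-level attributes needed for ",
           "the 'gene' background universe; use reporter_metabolites()",
           call. = FALSE)
    ms <- with_seed(seed, {
      vapply(names(sets), function(pw)
        pathway_gene_background(gene_sets[sets[[pw]]], unname(pool), met_bg,
                                n_samples,
                                corrected = metabolite_value == "corrected"),
        numeric(2))
    })
    mu <- ms["mu", ]; sigma <- ms["sigma", ]
    if (any(sigma <= 0))
      stop("degenerate pathway background (sigma = 0)", call. = FALSE)
  }

  corrected <- (raw - mu) / sigma
  p <- clamp_p(stats::pnorm(corrected, lower.tail = FALSE))
  nominal <- pathway_index$table$n_metabolites[
    match(names(sets), pathway_index$table$pathway)]

  out <- data.frame(
    pathway = names(sets),
    n_metabolites = nominal,
    n_scored = unname(n),
    raw_z = unname(raw),
    bg_mu = unname(mu),
    bg_sigma = unname(sigma),
    corrected_z = unname(corrected),
    p_value = unname(p),
    q_value = bh_adjust(unname(p)),
    stringsAsFactors = FALSE,
    row.names = NULL)
  structure(out, universe = universe, metabolite_value = metabolite_value,
            statistic = "rpam", direction = "none",
            background = if (universe == "metabolite") background else NULL,
            class = c("pathway_scores", "data.frame"))
}

#' Reaction-centric reporter pathway scoring
#'
#' The classical formulation: each retained pathway is scored by Stouffer
#' aggregation of the selected-gene Z-scores of its own member reactions, one
#' term per measured reaction (the same gene selected for several member
#' reactions contributes once per reaction), over `p` = the number of
#' measured member reactions. Reactions touching the pathway's metabolites
#' but catalogued under other pathways play no role. The aggregate is
#' standardized against random size-`p` sets of reaction-level Z-scores drawn
#' network-wide.
#'
#' @param network a `metabolic_network`.
#' @param pathway_index a `pathway_index`.
#' @param reaction_stats a `reaction_stats` table.
#' @param n_samples,seed Monte Carlo background parameters.
#' @param background optional prebuilt `background_model` over the
#'   reaction-level Z pool.
#' @return A data.frame of class `pathway_scores`: `pathway`, `n_reactions`
#'   (nominal member reactions), `n_scored` (measured member reactions),
#'   `raw_z`, `bg_mu`, `bg_sigma`, `corrected_z`, `p_value`, `q_value`.
#' @export
reporter_pathways_rpar <- function(network, pathway_index, reaction_stats,
                                   n_samples = 10000L, seed = 3L,
                                   background = NULL) {
  stopifnot(inherits(pathway_index, "pathway_index"))
  rz <- stats::setNames(reaction_stats$z, reaction_stats$reaction)
  sets <- lapply(pathway_index$reactions, intersect, y = names(rz))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " pathway(s) with no measured reaction omitted: ",
            paste(names(sets)[empty], collapse = ", "), call. = FALSE)
    sets <- sets[!empty]
  }
  if (length(sets) == 0L)
    stop("no pathway has a measured member reaction", call. = FALSE)
  sets <- sets[sort(names(sets))]
  p_cnt <- lengths(sets)
  raw <- vapply(sets, function(r) aggregate_z(rz[r]), numeric(1))

  if (is.null(background))
    background <- build_background(unname(rz), unique(p_cnt),
                                   n_samples = n_samples, seed = seed,
                                   universe = "reaction-z")
  bg <- background_lookup(background, p_cnt)
  corrected <- (raw - bg$mu) / bg$sigma
  p <- clamp_p(stats::pnorm(corrected, lower.tail = FALSE))
  nominal <- pathway_index$table$n_reactions[
    match(names(sets), pathway_index$table$pathway)]

  out <- data.frame(
    pathway = names(sets),
    n_reactions = nominal,
    n_scored = unname(p_cnt),
    raw_z = unname(raw),
    bg_mu = bg$mu,
    bg_sigma = bg$sigma,
    corrected_z = unname(corrected),
    p_value = unname(p),
    q_value = bh_adjust(unname(p)),
    stringsAsFactors = FALSE,
    row.names = NULL)
  structure(out, statistic = "rpar", direction = "none",
            background = background,
            class = c("pathway_scores", "data.frame"))
}

#' Directional (up/down) reporter pathway analysis
#'
#' Re-runs the metabolite-centric analysis on the genes changing in one
#' direction only: the gene table is restricted to matching-sign genes with
#' one-tailed p-values ([directional_gene_stats()]), the gene-to-reaction
#' mapping and metabolite scores are recomputed on that subset (each
#' metabolite's neighbor count shrinks accordingly), and pathways are scored
#' as in [reporter_pathways_rpam()]. Restricting the gene set discards
#' connectivity information, so directional results complement, and never
#' replace, the undirected analysis.
#'
#' @param network a `metabolic_network`.
#' @param pathway_index a `pathway_index`.
#' @param gene_stats a two-sided `gene_stats` table with signs.
#' @param direction `"up"` or `"down"`.
#' @param universe,n_samples,seed passed to the scoring steps.
#' @return A `pathway_scores` data.frame with attribute `direction`; the
#'   directional metabolite score table is attached as attribute
#'   `metabolite_scores`.
#' @export
reporter_pathways_directional <- function(network, pathway_index, gene_stats,
                                          direction = c("up", "down"),
                                          universe = "gene",
                                          n_samples = 10000L, seed = 4L) {
  direction <- match.arg(direction)
  dstats <- directional_gene_stats(gene_stats, direction)
  rstats <- map_genes_to_reactions(network, dstats)
  if (nrow(rstats) == 0L)
    stop("no network reaction is controlled by a ", direction,
         "-regulated gene", call. = FALSE)
  mets <- reporter_metabolites(network, rstats, n_samples = n_samples,
                               seed = seed)
  pw <- reporter_pathways_rpam(network, pathway_index, mets,
                               universe = universe, n_samples = n_samples,
                               seed = seed + 1L)
  attr(pw, "direction") <- direction
  attr(pw, "metabolite_scores") <- mets
  pw
}

#' Significant pathways, ranked
#'
#' Filters a pathway score table at significance level `alpha` and ranks it
#' ascending by p-value; ties are broken by the scored neighbor count
#' (descending) and then pathway id.
#'
#' @param scores a `pathway_scores` (or `feature_scores`) data.frame.
#' @param alpha significance cutoff on the uncorrected p-value (default
#'   0.01; 0.005 is a useful stricter choice for the metabolite-centric
#'   statistic, which reports more pathways).
#' @param use_q rank and filter on BH q-values instead.
#' @return The filtered, ranked data.frame.
#' @export
significant_pathways <- function(scores, alpha = 0.01, use_q = FALSE) {
  stopifnot(is.data.frame(scores), "p_value" %in% names(scores))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]", call. = FALSE)
  pcol <- if (use_q) scores$q_value else scores$p_value
  keep <- scores[pcol < alpha, , drop = FALSE]
  cnt <- if ("n_scored" %in% names(keep)) keep$n_scored
         else if ("k" %in% names(keep)) keep$k else rep(0L, nrow(keep))
  idcol <- if ("pathway" %in% names(keep)) keep$pathway else keep[[1L]]
  keep <- keep[order(keep$p_value, -cnt, idcol), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Combined metabolite-/reaction-centric pathway report
#'
#' Outer-joins the two pathway score tables on pathway id into the layout of
#' the package's TSV reports: nominal and scored neighbor counts plus
#' p-/q-values for both statistics.
#'
#' @param rpam metabolite-centric `pathway_scores`.
#' @param rpar reaction-centric `pathway_scores`.
#' @param direction direction flag recorded in the report (default taken
#'   from `rpam`).
#' @return A data.frame with columns `pathway`, `n_metabolite_neighbors`,
#'   `n_metabolites_scored`, `p_rpam`, `q_rpam`, `n_reaction_neighbors`,
#'   `n_reactions_scored`, `p_rpar`, `q_rpar`, `direction`, sorted by
#'   `p_rpam`.
#' @export
build_report <- function(rpam, rpar, direction = NULL) {
  if (is.null(direction))
    direction <- attr(rpam, "direction") %||% "none"
  a <- data.frame(pathway = rpam$pathway,
                  n_metabolite_neighbors = rpam$n_metabolites,
                  n_metabolites_scored = rpam$n_scored,
                  p_rpam = rpam$p_value, q_rpam = rpam$q_value,
                  stringsAsFactors = FALSE)
  b <- data.frame(pathway = rpar$pathway,
                  n_reaction_neighbors = rpar$n_reactions,
                  n_reactions_scored = rpar$n_scored,
                  p_rpar = rpar$p_value, q_rpar = rpar$q_value,
                  stringsAsFactors = FALSE)
  rep <- merge(a, b, by = "pathway", all = TRUE, sort = TRUE)
  rep$direction <- rep(direction, nrow(rep))
  rep <- rep[order(rep$p_rpam, rep$pathway), , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Flag pathways captured by the metabolite-centric statistic only
#'
#' Joins two pathway score tables and flags the discordance class of
#' interest: pathways significant under the metabolite-centric statistic
#' (`p_rpam < alpha_m`) but not under the reaction-centric one
#' (`p_rpar > alpha_r`, or unscored there). These are typically pathways
#' whose perturbation arrives through cross-linking reactions catalogued
#' under other pathways.
#'
#' @param rpam,rpar `pathway_scores` tables from one run.
#' @param alpha_m significance cutoff for the metabolite-centric p-value.
#' @param alpha_r non-significance threshold for the reaction-centric
#'   p-value.
#' @return The joined report of [build_report()] plus a logical `discordant`
#'   column.
#' @export
compare_reports <- function(rpam, rpar, alpha_m = 0.01, alpha_r = 0.05) {
  if (length(intersect(rpam$pathway, rpar$pathway)) == 0L &&
      nrow(rpam) && nrow(rpar))
    warning("the two reports share no pathway; outer join returned",
            call. = FALSE)
  rep <- build_report(rpam, rpar)
  rep$discordant <- !is.na(rep$p_rpam) & rep$p_rpam < alpha_m &
    (is.na(rep$p_rpar) | rep$p_rpar > alpha_r)
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
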