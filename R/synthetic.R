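#' Generate a synthetic metabolic network
#'
#' Builds a multi-pathway network with known structure for validation. Each
#' pathway is, by default, a linear chain: reaction `i` converts metabolite
#' `i-1` into metabolite `i`, so interior metabolites have two neighbor
#' reactions. A `hub` topology instead connects every reaction of a pathway
#' to one shared hub metabolite, which exercises the branch-point weighting
#' of the metabolite-centric statistic. A fraction of reactions additionally
#' consume or produce one metabolite of a uniformly chosen *other* pathway —
#' these cross-links are the inter-pathway reactions through which the
#' metabolite-centric statistic propagates signal across pathway boundaries.
#' Each reaction carries `genes_per_reaction` unique genes;
#' `shared_genes = TRUE` additionally lets consecutive reactions of a pathway
#' share a gene (isozyme sharing), exercising the minimum-p gene selection
#' and distinct-gene rules.
#'
#' The generator is a pure function of its arguments: the same seed yields
#' an identical network.
#'
#' @param n_pathways number of pathways (>= 2).
#' @param reactions_per_pathway reactions per pathway (>= 3, so all pathways
#'   survive the default pathway filter).
#' @param cross_link_fraction fraction of reactions receiving one foreign
#'   metabolite, in `[0, 1]`.
#' @param genes_per_reaction genes per reaction (>= 1).
#' @param seed integer RNG seed.
#' @param topology `"chain"` (default) or `"hub"`.
#' @param shared_genes if `TRUE`, consecutive reactions within a pathway
#'   share one gene.
#' @return A `metabolic_network`.
#' @export
generate_network <- function(n_pathways = 20L, reactions_per_pathway = 6L,
                             cross_link_fraction = 0.2,
                             genes_per_reaction = 1L, seed = 1L,
                             topology = c("chain", "hub"),
                             shared_genes = FALSE) {
  topology <- match.arg(topology)
  if (n_pathways < 2L)
    stop("n_pathways must be >= 2", call. = FALSE)
  if (reactions_per_pathway < 3L)
    stop("reactions_per_pathway must be >= 3", call. = FALSE)
  if (cross_link_fraction < 0 || cross_link_fraction > 1)
    stop("cross_link_fraction must lie in [0, 1]", call. = FALSE)
  if (genes_per_reaction < 1L)
    stop("genes_per_reaction must be >= 1", call. = FALSE)

  pw_ids <- sprintf("P%02d", seq_len(n_pathways))
  rmet <- list(); rgen <- list(); pmap <- list()
  for (pw in pw_ids) {
    rxns <- sprintf("%s_R%02d", pw, seq_len(reactions_per_pathway))
    for (i in seq_len(reactions_per_pathway)) {
      rmet[[rxns[i]]] <- if (topology == "chain")
        sprintf("%s_M%02d", pw, c(i - 1L, i))
      else
        c(sprintf("%s_M00", pw), sprintf("%s_M%02d", pw, i))
      g <- sprintf("g_%s_%d", rxns[i], seq_len(genes_per_reaction))
      if (shared_genes && i > 1L)
        g <- c(g, sprintf("g_%s_%d", rxns[i - 1L], 1L))
      rgen[[rxns[i]]] <- g
    }
    pmap[[pw]] <- rxns
  }

  rmet0 <- rmet  # pristine chains: cross-link targets are native metabolites
  with_seed(seed, {
    all_rxns <- names(rmet)
    n_cross <- round(cross_link_fraction * length(all_rxns))
    if (n_cross > 0L) {
      crossers <- sample(all_rxns, n_cross)
      pw_of <- sub("_R[0-9]+$", "", crossers)
      for (j in seq_along(crossers)) {
        other <- sample(setdiff(pw_ids, pw_of[j]), 1L)
        other_mets <- sort(unique(unlist(
          rmet0[pmap[[other]]], use.names = FALSE)))
        foreign <- sample(other_mets, 1L)
        rmet[[crossers[j]]] <- c(rmet[[crossers[j]]], foreign)
      }
    }
  })

  net <- metabolic_network(rmet, rgen, pmap)
  attr(net, "params") <- list(
    n_pathways = as.integer(n_pathways),
    reactions_per_pathway = as.integer(reactions_per_pathway),
    cross_link_fraction = cross_link_fraction,
    genes_per_reaction = as.integer(genes_per_reaction),
    seed = as.integer(seed), topology = topology,
    shared_genes = shared_genes)
  net
}

#' Plant a perturbation on one pathway's neighborhood
#'
#' Defines the ground truth for a synthetic experiment: the genes whose
#' expression will be shifted. With the default scope, the affected genes
#' are exactly the genes of all reactions that consume or produce any
#' metabolite of the perturbed pathway — the pathway's metabolite
#' neighborhood, including cross-linking reactions that belong to other
#' pathways. `"members_only"` restricts to the pathway's own reactions;
#' `"cross_links_only"` keeps only the foreign reactions touching the
#' pathway's metabolites, the configuration under which the
#' metabolite-centric statistic sees a perturbation the reaction-centric one
#' cannot.
#'
#' @param network a `metabolic_network`.
#' @param pathway pathway id to perturb; chosen uniformly at random (under
#'   `seed`) when `NULL`.
#' @param effect_size non-negative mean shift, in expression units, applied
#'   to affected genes (sign carried by `direction`).
#' @param direction `"up"` or `"down"`.
#' @param scope `"neighborhood"` (default), `"members_only"` or
#'   `"cross_links_only"`.
#' @param seed RNG seed for the random pathway choice.
#' @return An object of class `synthetic_truth`: list with `pathway`,
#'   `effect_size`, `direction`, `scope`, `affected_reactions`,
#'   `affected_genes`, `seed`.
#' @export
plant_perturbation <- function(network, pathway = NULL, effect_size = 3,
                               direction = c("up", "down"),
                               scope = c("neighborhood", "members_only",
                                         "cross_links_only"),
                               seed = 1L) {
  direction <- match.arg(direction)
  scope <- match.arg(scope)
  if (effect_size < 0)
    stop("effect_size must be non-negative (direction carries the sign)",
         call. = FALSE)
  if (length(network$pathways) == 0L)
    stop("network has no pathways", call. = FALSE)
  if (is.null(pathway))
    pathway <- with_seed(seed, sample(names(network$pathways), 1L))
  if (!pathway %in% names(network$pathways))
    stop("unknown pathway: ", pathway, call. = FALSE)

  members <- network$pathways[[pathway]]
  pw_mets <- unique(unlist(network$reaction_metabolites[members],
                           use.names = FALSE))
  touching <- names(network$reaction_metabolites)[
    vapply(network$reaction_metabolites,
           function(m) any(m %in% pw_mets), logical(1))]
  rxns <- switch(scope,
    neighborhood = touching,
    members_only = members,
    cross_links_only = setdiff(touching, members))
  if (length(rxns) == 0L)
    stop("no reactions in scope '", scope, "' for pathway ", pathway,
         call. = FALSE)
  genes <- sort(unique(unlist(network$reaction_genes[
    intersect(rxns, names(network$reaction_genes))], use.names = FALSE)))
  if (length(genes) == 0L)
    stop("no genes associated with the reactions in scope", call. = FALSE)

  structure(
    list(pathway = pathway, effect_size = effect_size,
         direction = direction, scope = scope,
         affected_reactions = sort(rxns), affected_genes = genes,
         seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: pathway %s %s-shifted by %.3g (%s scope, %d genes)\n",
    x$pathway, x$direction, x$effect_size, x$scope,
    length(x$affected_genes)))
  invisible(x)
}

#' Generate synthetic expression data
#'
#' Draws a genes-by-samples expression matrix with two groups. Every gene is
#' i.i.d. normal noise, `N(0, noise_sd^2)`; genes named in
#' `truth$affected_genes` have their condition-group mean shifted by
#' `+effect_size` (direction `"up"`) or `-effect_size` (`"down"`). This
#' additive-shift model is the one under which the two-sample t-test is
#' exact. Deterministic given `seed`.
#'
#' @param network a `metabolic_network`; the gene universe is its gene set.
#' @param truth a `synthetic_truth` from [plant_perturbation()], or `NULL`
#'   for pure-null data.
#' @param n_per_group samples per group (>= 2; default 5).
#' @param noise_sd residual standard deviation (default 1).
#' @param seed integer RNG seed.
#' @return A list with `expression` (matrix, genes x samples) and `groups`
#'   (factor with levels `reference`, `condition`).
#' @export
generate_expression <- function(network, truth = NULL, n_per_group = 5L,
                                noise_sd = 1, seed = 1L) {
  if (n_per_group < 2L)
    stop("n_per_group must be >= 2", call. = FALSE)
  if (noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)
  genes <- network_genes(network)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "synthetic_truth"))
    if (!all(truth$affected_genes %in% genes))
      stop("truth$affected_genes is not a subset of the network's genes",
           call. = FALSE)
  }
  n <- 2L * n_per_group
  x <- with_seed(seed,
    matrix(stats::rnorm(length(genes) * n, sd = noise_sd),
           nrow = length(genes), ncol = n,
           dimnames = list(genes,
                           c(sprintf("ref_%d", seq_len(n_per_group)),
                             sprintf("cond_%d", seq_len(n_per_group))))))
  groups <- factor(rep(c("reference", "condition"), each = n_per_group),
                   levels = c("reference", "condition"))
  if (!is.null(truth) && truth$effect_size > 0) {
    shift <- if (truth$direction == "up") truth$effect_size
             else -truth$effect_size
    x[truth$affected_genes, groups == "condition"] <-
      x[truth$affected_genes, groups == "condition"] + shift
  }
  list(expression = x, groups = groups)
}

#' Cross-linked neighbor pathways of a perturbed pathway
#'
#' Pathways other than the perturbed one whose metabolite neighborhood
#' shares at least one affected gene with the planted perturbation. Signal
#' is expected to propagate to these pathways by design, so recovery
#' metrics report them separately from false positives.
#'
#' @param network a `metabolic_network`.
#' @param truth a `synthetic_truth`.
#' @return Character vector of pathway ids.
#' @export
neighbor_pathways <- function(network, truth) {
  adj <- metabolite_reactions(network)
  out <- character(0)
  for (pw in setdiff(names(network$pathways), truth$pathway)) {
    members <- network$pathways[[pw]]
    mets <- unique(unlist(network$reaction_metabolites[members],
                          use.names = FALSE))
    touching <- unique(unlist(adj[mets], use.names = FALSE))
    genes <- unlist(network$reaction_genes[
      intersect(touching, names(network$reaction_genes))], use.names = FALSE)
    if (any(genes %in% truth$affected_genes)) out <- c(out, pw)
  }
  sort(out)
}

#' Evaluate recovery of a planted perturbation
#'
#' Measures how well a ranked pathway score table recovers the planted
#' truth: the 1-based rank of the perturbed pathway (by p-value, with the
#' ranking tie-breaks of [significant_pathways()]), whether it ranks first,
#' and the number of significant pathways at `alpha` that are neither the
#' perturbed pathway nor one of its cross-linked neighbors (to which signal
#' propagates by design).
#'
#' @param scores a `pathway_scores` table (typically the metabolite-centric
#'   one).
#' @param truth a `synthetic_truth`.
#' @param alpha significance cutoff for the false-positive count.
#' @param network optional `metabolic_network`; when supplied, cross-linked
#'   neighbor pathways are identified and excluded from the false-positive
#'   count.
#' @return List with `rank` (`Inf` if the perturbed pathway is absent),
#'   `hit_top1`, `n_false_positives`, `false_positives`,
#'   `neighbor_pathways`.
#' @export
evaluate_recovery <- function(scores, truth, alpha = 0.01, network = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), is.data.frame(scores))
  if (nrow(scores) == 0L)
    stop("empty score table", call. = FALSE)
  ranked <- significant_pathways(scores, alpha = 1)  # full ranking
  pos <- match(truth$pathway, ranked$pathway)
  rank <- if (is.na(pos)) Inf else pos
  nbr <- if (is.null(network)) character(0)
         else neighbor_pathways(network, truth)
  sig <- scores$pathway[scores$p_value < alpha]
  fp <- setdiff(sig, c(truth$pathway, nbr))
  list(rank = rank, hit_top1 = identical(pos, 1L),
       n_false_positives = length(fp), false_positives = sort(fp),
       neighbor_pathways = nbr)
}

#' Serialize a synthetic truth object
#'
#' Writes the planted-truth description as a plain key-value text file
#' (one `key: value` per line, list values comma-separated).
#'
#' @param truth a `synthetic_truth`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  lines <- c(
    paste0("pathway: ", truth$pathway),
    paste0("effect_size: ", format(truth$effect_size)),
    paste0("direction: ", truth$direction),
    paste0("scope: ", truth$scope),
    paste0("seed: ", truth$seed),
    paste0("affected_reactions: ",
           paste(truth$affected_reactions, collapse = ",")),
    paste0("affected_genes: ", paste(truth$affected_genes, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
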