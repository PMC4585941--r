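#' Read an expression matrix and sample groups from TSV
#'
#' @param expression_file TSV, genes as rows (first column or rownames =
#'   gene ids), samples as columns.
#' @param groups_file two-column TSV (`sample`, `group`) assigning each
#'   sample column to one of two groups; the first group level encountered
#'   is the reference.
#' @return List with `expression` (numeric matrix) and `groups` (factor).
#' @export
read_expression <- function(expression_file, groups_file) {
  for (f in c(expression_file, groups_file))
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  tab <- utils::read.delim(expression_file, sep = "\t", header = TRUE,
                           quote = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  x <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(x) <- as.character(tab[[1L]])
  storage.mode(x) <- "double"
  g <- utils::read.delim(groups_file, sep = "\t", header = TRUE, quote = "",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(g) < 2L)
    stop("groups file needs columns sample, group", call. = FALSE)
  idx <- match(colnames(x), as.character(g[[1L]]))
  if (any(is.na(idx)))
    stop("samples missing from groups file: ",
         paste(colnames(x)[is.na(idx)], collapse = ", "), call. = FALSE)
  grp <- as.character(g[[2L]])[idx]
  list(expression = x,
       groups = factor(grp, levels = unique(as.character(g[[2L]]))))
}

#' Write an expression matrix and groups to TSV
#'
#' Companion of [read_expression()]; used by the synthetic generator to
#' produce self-hosting fixtures in the formats the pipeline reads.
#'
#' @param expression numeric matrix, genes x samples.
#' @param groups factor of length `ncol(expression)`.
#' @param expression_file,groups_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(expression, groups, expression_file,
                             groups_file) {
  tab <- data.frame(gene = rownames(expression), expression,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expression_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(expression), group = as.character(groups)),
    groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression_file, groups_file))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full reporter pathway analysis
#'
#' End-to-end pipeline: parse the network, obtain per-gene statistics (from
#' an expression matrix + groups, or a precomputed p-value table), map genes
#' to reactions by the minimum-p rule, score reporter metabolites, score
#' pathways with both the metabolite-centric and reaction-centric
#' statistics, adjust with Benjamini-Hochberg, and write ranked TSV reports
#' plus a plain-text run manifest that records every materialized setting
#' (so a run can be reproduced exactly from its manifest). Optionally runs
#' the directional (up/down) variants.
#'
#' @param network_file path to a network TSV (see [parse_network()]).
#' @param output_dir directory for outputs (created if absent).
#' @param expression_file,groups_file expression-matrix inputs (see
#'   [read_expression()]); mutually exclusive with `pvalues_file`.
#' @param pvalues_file precomputed per-gene p-value TSV (see
#'   [read_gene_stats()]).
#' @param columns column mapping passed to [parse_network()].
#' @param tail,var_equal t-test options (see [compute_gene_pvalues()]).
#' @param min_reactions pathway filter (see [build_pathway_index()]).
#' @param universe pathway background universe for the metabolite-centric
#'   statistic.
#' @param n_samples,seed Monte Carlo background parameters; all randomness
#'   in the run derives from this one seed.
#' @param alpha significance cutoff used in the ranked report.
#' @param direction `"none"`, `"up"`, `"down"` or `"both"`: which
#'   directional analyses to run in addition to the undirected one.
#' @return Invisibly, a list with the computed tables (`metabolites`,
#'   `rpam`, `rpar`, `report`, `significant`, optional `up`/`down`),
#'   the parsed `network`, and `manifest` (named character vector).
#' @export
rpa_run <- function(network_file, output_dir,
                    expression_file = NULL, groups_file = NULL,
                    pvalues_file = NULL, columns = list(),
                    tail = "two_sided", var_equal = TRUE,
                    min_reactions = 3L, universe = "gene",
                    n_samples = 10000L, seed = 1L, alpha = 0.01,
                    direction = c("none", "up", "down", "both")) {
  direction <- match.arg(direction)
  if (!file.exists(network_file))
    stop("network file not found: ", network_file, call. = FALSE)
  have_expr <- !is.null(expression_file)
  if (have_expr == !is.null(pvalues_file))
    stop("supply either expression_file + groups_file or pvalues_file",
         call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  network <- parse_network(network_file, columns = columns)
  index <- build_pathway_index(network, min_reactions = min_reactions)
  gstats <- if (have_expr) {
    dat <- read_expression(expression_file, groups_file)
    compute_gene_pvalues(dat$expression, dat$groups, tail = tail,
                         var_equal = var_equal)
  } else {
    read_gene_stats(pvalues_file)
  }

  rstats <- map_genes_to_reactions(network, gstats)
  mets <- reporter_metabolites(network, rstats, n_samples = n_samples,
                               seed = seed)
  rpam <- reporter_pathways_rpam(network, index, mets, universe = universe,
                                 n_samples = n_samples, seed = seed + 1L)
  rpar <- reporter_pathways_rpar(network, index, rstats,
                                 n_samples = n_samples, seed = seed + 2L)
  report <- build_report(rpam, rpar)
  sig <- significant_pathways(rpam, alpha = alpha)

  out <- list(network = network, gene_stats = gstats,
              reaction_stats = rstats, metabolites = mets, rpam = rpam,
              rpar = rpar, report = report, significant = sig)

  write_tsv(mets, file.path(output_dir, "metabolites.tsv"))
  write_tsv(rpam, file.path(output_dir, "rpam.tsv"))
  write_tsv(rpar, file.path(output_dir, "rpar.tsv"))
  write_tsv(report, file.path(output_dir, "report.tsv"))
  write_tsv(sig, file.path(output_dir, "significant.tsv"))

  if (direction %in% c("up", "both") || direction %in% c("down", "both")) {
    dirs <- if (direction == "both") c("up", "down") else direction
    for (d in dirs) {
      pw <- reporter_pathways_directional(network, index, gstats,
                                          direction = d,
                                          universe = universe,
                                          n_samples = n_samples,
                                          seed = seed + 10L)
      out[[d]] <- pw
      write_tsv(pw, file.path(output_dir, paste0("rpam_", d, ".tsv")))
    }
  }

  manifest <- c(
    network_file = network_file,
    expression_file = expression_file %||% "",
    groups_file = groups_file %||% "",
    pvalues_file = pvalues_file %||% "",
    tail = tail, var_equal = as.character(var_equal),
    min_reactions = as.character(min_reactions), universe = universe,
    n_samples = as.character(n_samples), seed = as.character(seed),
    alpha = as.character(alpha), direction = direction,
    n_metabolites = as.character(length(network$metabolites)),
    n_reactions = as.character(length(network$reactions)),
    n_genes = as.character(length(network_genes(network))),
    n_pathways_total = as.character(length(network$pathways)),
    n_pathways_retained = as.character(length(index$reactions)),
    n_genes_measured = as.character(nrow(gstats)),
    package_version = as.character(utils::packageVersion("reporterpa")))
  writeLines(paste0(names(manifest), ": ", manifest),
             file.path(output_dir, "manifest.txt"))
  out$manifest <- manifest
  invisible(out)
}

#' Simulate a complete synthetic study to disk
#'
#' Generates a network and a planted-perturbation expression dataset and
#' writes them in the TSV formats [rpa_run()] reads, together with the
#' serialized ground truth — a self-hosting fixture generator.
#'
#' @param output_dir directory for the fixture files.
#' @param seed master seed.
#' @param effect_size mean shift on the perturbed pathway's neighborhood
#'   genes (0 for a null dataset).
#' @param direction,scope passed to [plant_perturbation()].
#' @param n_per_group,noise_sd passed to [generate_expression()].
#' @param ... network parameters passed to [generate_network()].
#' @return Invisibly, list with `network`, `truth`, `data` and the file
#'   paths.
#' @export
rpa_simulate <- function(output_dir, seed = 1L, effect_size = 3,
                         direction = "up", scope = "neighborhood",
                         n_per_group = 5L, noise_sd = 1, ...) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  network <- generate_network(seed = seed, ...)
  truth <- if (effect_size > 0)
    plant_perturbation(network, effect_size = effect_size,
                       direction = direction, scope = scope, seed = seed)
  else NULL
  dat <- generate_expression(network, truth, n_per_group = n_per_group,
                             noise_sd = noise_sd, seed = seed + 1L)
  paths <- list(
    network = file.path(output_dir, "network.tsv"),
    expression = file.path(output_dir, "expression.tsv"),
    groups = file.path(output_dir, "groups.tsv"),
    truth = file.path(output_dir, "truth.txt"))
  write_network(network, paths$network)
  write_expression(dat$expression, dat$groups, paths$expression,
                   paths$groups)
  if (!is.null(truth)) write_truth(truth, paths$truth)
  invisible(list(network = network, truth = truth, data = dat,
                 paths = paths))
}
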