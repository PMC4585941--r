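#' Construct a metabolic network object
#'
#' Low-level constructor for the bipartite metabolite-reaction connectivity
#' structure used throughout the package. Most users will call
#' [parse_network()] or [generate_network()] instead.
#'
#' @param reaction_metabolites named list, reaction id -> character vector of
#'   metabolite ids participating as substrate or product (direction-agnostic,
#'   non-empty per reaction).
#' @param reaction_genes named list, reaction id -> character vector of gene
#'   ids controlling the reaction. Reactions without gene association are
#'   simply absent from this list; they still contribute to metabolite sets.
#' @param pathways named list, pathway id -> character vector of member
#'   reaction ids.
#'
#' @return An object of class `metabolic_network`: a list with elements
#'   `metabolites`, `reactions`, `reaction_metabolites`, `reaction_genes`,
#'   `pathways`, all with sorted, deduplicated identifiers.
#' @export
metabolic_network <- function(reaction_metabolites, reaction_genes = list(),
                              pathways = list()) {
  if (length(reaction_metabolites) == 0L)
    stop("network must contain at least one reaction", call. = FALSE)
  reaction_metabolites <- lapply(reaction_metabolites,
                                 function(m) sort(unique(as.character(m))))
  reaction_genes <- lapply(reaction_genes,
                           function(g) sort(unique(as.character(g))))
  reaction_genes <- reaction_genes[lengths(reaction_genes) > 0L]
  pathways <- lapply(pathways, function(r) sort(unique(as.character(r))))

  net <- structure(
    list(
      metabolites = sort(unique(unlist(reaction_metabolites, use.names = FALSE))),
      reactions = sort(names(reaction_metabolites)),
      reaction_metabolites = reaction_metabolites[sort(names(reaction_metabolites))],
      reaction_genes = reaction_genes[sort(names(reaction_genes))],
      pathways = pathways[sort(names(pathways))]
    ),
    class = "metabolic_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  empty <- names(net$reaction_metabolites)[lengths(net$reaction_metabolites) == 0L]
  if (length(empty))
    stop("reactions with empty metabolite sets: ",
         paste(empty, collapse = ", "), call. = FALSE)
  if (!all(names(net$reaction_genes) %in% net$reactions))
    stop("reaction_genes refers to unknown reactions", call. = FALSE)
  bad <- !vapply(net$pathways, function(r) all(r %in% net$reactions), logical(1))
  if (any(bad))
    stop("pathways refer to unknown reactions: ",
         paste(names(net$pathways)[bad], collapse = ", "), call. = FALSE)
  invisible(net)
}

#' Genes of the network
#'
#' @param network a `metabolic_network`.
#' @return Sorted character vector of all gene ids with at least one
#'   associated reaction.
#' @export
network_genes <- function(network) {
  sort(unique(unlist(network$reaction_genes, use.names = FALSE)))
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "metabolic_network: %d metabolites, %d reactions (%d with genes), %d genes, %d pathways\n",
    length(x$metabolites), length(x$reactions),
    length(x$reaction_genes), length(network_genes(x)), length(x$pathways)))
  invisible(x)
}

# metabolite -> adjacent reactions (inverted index, computed on demand)
metabolite_reactions <- function(network) {
  rxn <- rep(names(network$reaction_metabolites),
             lengths(network$reaction_metabolites))
  met <- unlist(network$reaction_metabolites, use.names = FALSE)
  split(rxn, met)
}

default_network_columns <- function() {
  list(reaction_id = "reaction", metabolites = "metabolites",
       substrates = "substrates", products = "products",
       genes = "genes", pathways = "pathways",
       list_delimiter = " // ")
}

split_cell <- function(x, delim) {
  parts <- strsplit(x, delim, fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

#' Parse a metabolic network export
#'
#' Reads a tab-separated reaction table in the BioCyc SmartTables dialect:
#' one row per reaction, with metabolite, gene and pathway associations as
#' delimited lists within a cell (default delimiter `" // "`). Metabolites may
#' be given either as a single `metabolites` column or as separate
#' `substrates` and `products` columns; the two are pooled, since scoring is
#' direction-agnostic. Duplicate reaction rows are merged by taking the union
#' of their annotations. Rows without gene association are retained (their
#' metabolites count towards pathway metabolite sets) but carry no statistic.
#'
#' @param path path to a UTF-8 TSV file with a header row.
#' @param columns named list overriding default column names; recognized keys
#'   are `reaction_id`, `metabolites`, `substrates`, `products`, `genes`,
#'   `pathways`, `list_delimiter`. Compartment-qualified metabolite names are
#'   kept verbatim; no cross-compartment merging is attempted.
#' @param exclude_metabolites optional character vector of metabolite ids
#'   (e.g. currency cofactors) to drop from connectivity. None are excluded by
#'   default.
#'
#' @return A validated [metabolic_network()].
#' @export
parse_network <- function(path, columns = list(), exclude_metabolites = NULL) {
  if (!file.exists(path))
    stop("network file not found: ", path, call. = FALSE)
  cfg <- utils::modifyList(default_network_columns(), columns)
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                      check.names = FALSE, colClasses = "character",
                      na.strings = NULL, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot read network file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L)
    stop("network file is empty: ", path, call. = FALSE)

  need <- cfg$reaction_id
  if (!need %in% names(tab))
    stop("required column missing from network file: '", need, "'",
         call. = FALSE)
  has_met <- cfg$metabolites %in% names(tab)
  has_sp <- all(c(cfg$substrates, cfg$products) %in% names(tab))
  if (!has_met && !has_sp)
    stop("required column missing from network file: '", cfg$metabolites,
         "' (or '", cfg$substrates, "' + '", cfg$products, "')",
         call. = FALSE)
  if (!cfg$genes %in% names(tab))
    stop("required column missing from network file: '", cfg$genes, "'",
         call. = FALSE)

  ids <- trimws(tab[[cfg$reaction_id]])
  if (any(!nzchar(ids)))
    stop("network file contains rows with empty reaction ids", call. = FALSE)

  if (has_met) {
    mets <- split_cell(tab[[cfg$metabolites]], cfg$list_delimiter)
  } else {
    sub <- split_cell(tab[[cfg$substrates]], cfg$list_delimiter)
    prd <- split_cell(tab[[cfg$products]], cfg$list_delimiter)
    mets <- Map(c, sub, prd)
  }
  if (!is.null(exclude_metabolites))
    mets <- lapply(mets, setdiff, y = exclude_metabolites)
  bad <- lengths(mets) == 0L
  if (any(bad))
    stop("reactions with empty metabolite lists: ",
         paste(unique(ids[bad]), collapse = ", "), call. = FALSE)

  genes <- split_cell(tab[[cfg$genes]], cfg$list_delimiter)
  pws <- if (cfg$pathways %in% names(tab))
    split_cell(tab[[cfg$pathways]], cfg$list_delimiter)
  else
    rep(list(character(0)), nrow(tab))

  # merge duplicate reaction rows by union of annotations
  rmet <- lapply(split(mets, ids), function(l) unique(unlist(l)))
  rgen <- lapply(split(genes, ids), function(l) unique(unlist(l)))
  pw_long <- data.frame(
    reaction = rep(ids, lengths(pws)),
    pathway = unlist(pws, use.names = FALSE),
    stringsAsFactors = FALSE)
  pmap <- if (nrow(pw_long)) split(pw_long$reaction, pw_long$pathway) else list()

  metabolic_network(reaction_metabolites = rmet, reaction_genes = rgen,
                    pathways = pmap)
}

#' Serialize a metabolic network to TSV
#'
#' Writes the canonical one-row-per-reaction form read by [parse_network()];
#' `parse_network(write_network(net, f))` reproduces `net` exactly
#' (round-trip identity). Reactions and within-cell lists are sorted.
#'
#' @param network a `metabolic_network`.
#' @param path output file path.
#' @param list_delimiter delimiter joining within-cell lists.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, list_delimiter = " // ") {
  validate_network(network)
  rxns <- network$reactions
  pw_of <- lapply(stats::setNames(rxns, rxns), function(r)
    sort(names(network$pathways)[vapply(network$pathways, function(m) r %in% m,
                                        logical(1))]))
  join <- function(x) paste(x, collapse = list_delimiter)
  tab <- data.frame(
    reaction = rxns,
    metabolites = vapply(network$reaction_metabolites[rxns], join, character(1)),
    genes = vapply(rxns, function(r)
      join(if (r %in% names(network$reaction_genes))
        network$reaction_genes[[r]] else character(0)), character(1)),
    pathways = vapply(pw_of, join, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Neighbor genes of a metabolite
#'
#' Returns the distinct genes attached to the reactions that consume or
#' produce a metabolite. When a reaction-level statistic table is supplied
#' (see [map_genes_to_reactions()]), only the selected (minimum-p) gene of
#' each measured adjacent reaction is returned, which is the gene set entering
#' the reporter metabolite score; otherwise all annotated genes of adjacent
#' reactions are returned.
#'
#' @param network a `metabolic_network`.
#' @param metabolite a metabolite id present in the network.
#' @param reaction_stats optional `reaction_stats` table from
#'   [map_genes_to_reactions()].
#' @return Lexicographically sorted character vector of distinct gene ids.
#' @export
metabolite_gene_neighbors <- function(network, metabolite,
                                      reaction_stats = NULL) {
  if (!metabolite %in% network$metabolites)
    stop("unknown metabolite: ", metabolite, call. = FALSE)
  adj <- names(network$reaction_metabolites)[
    vapply(network$reaction_metabolites, function(m) metabolite %in% m,
           logical(1))]
  if (is.null(reaction_stats)) {
    genes <- unlist(network$reaction_genes[intersect(adj,
      names(network$reaction_genes))], use.names = FALSE)
  } else {
    genes <- reaction_stats$gene[reaction_stats$reaction %in% adj]
  }
  sort(unique(genes))
}

#' Build a pathway index
#'
#' Restricts the network's pathway map to pathways with at least
#' `min_reactions` member reactions and precomputes, per retained pathway, its
#' reaction set, its metabolite set (union of member reactions' metabolites),
#' and the two nominal neighbor counts reported alongside pathway scores: the
#' number of metabolite neighbors `n` and the number of reaction neighbors
#' `p`.
#'
#' @param network a `metabolic_network`.
#' @param min_reactions minimum member-reaction count for a pathway to be
#'   retained (default 3).
#' @return An object of class `pathway_index`: list with `reactions`
#'   (pathway -> reaction ids), `metabolites` (pathway -> metabolite ids), and
#'   `table`, a data.frame with columns `pathway`, `n_reactions`,
#'   `n_metabolites`.
#' @export
build_pathway_index <- function(network, min_reactions = 3L) {
  validate_network(network)
  if (!is.numeric(min_reactions) || length(min_reactions) != 1L ||
      min_reactions < 1)
    stop("min_reactions must be a single integer >= 1", call. = FALSE)
  keep <- network$pathways[lengths(network$pathways) >= min_reactions]
  mets <- lapply(keep, function(rxns)
    sort(unique(unlist(network$reaction_metabolites[rxns], use.names = FALSE))))
  structure(
    list(
      reactions = keep,
      metabolites = mets,
      table = data.frame(
        pathway = names(keep),
        n_reactions = unname(lengths(keep)),
        n_metabolites = unname(lengths(mets)),
        stringsAsFactors = FALSE,
        row.names = NULL)
    ),
    min_reactions = as.integer(min_reactions),
    class = "pathway_index"
  )
}

#' @export
print.pathway_index <- function(x, ...) {
  cat(sprintf("pathway_index: %d pathways (min_reactions = %d)\n",
              length(x$reactions), attr(x, "min_reactions")))
  invisible(x)
}
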