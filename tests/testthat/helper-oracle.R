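# Independent brute-force evaluator of the reporter statistics, written
# directly from the scoring definitions with plain loops. It shares only the
# background models (mu_k / sigma_k tables) with the implementation under
# test; adjacency scans, neighbor-gene collection, aggregation, correction
# and p-value conversion are all recomputed here from first principles.

oracle_lookup <- function(background, k) {
  i <- which(background$table$k == k)
  stopifnot(length(i) == 1L)
  list(mu = background$table$mu[i], sigma = background$table$sigma[i])
}

oracle_metabolites <- function(network, reaction_stats, background) {
  rows <- list()
  for (m in network$metabolites) {
    genes <- character(0)
    for (r in names(network$reaction_metabolites)) {
      if (m %in% network$reaction_metabolites[[r]]) {
        hit <- reaction_stats$reaction == r
        if (any(hit)) genes <- c(genes, reaction_stats$gene[hit])
      }
    }
    genes <- sort(unique(genes))
    if (length(genes) == 0L) next
    z <- numeric(0)
    for (g in genes)
      z <- c(z, reaction_stats$z[match(g, reaction_stats$gene)])
    k <- length(z)
    raw <- sum(z) / sqrt(k)
    bg <- oracle_lookup(background, k)
    cz <- (raw - bg$mu) / bg$sigma
    rows[[m]] <- data.frame(metabolite = m, k = k, raw_z = raw,
                            corrected_z = cz,
                            p_value = 1 - pnorm(cz),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# metabolite-centric pathway scores, random-score-set background universe
oracle_rpam <- function(network, met_table, background, min_reactions = 3L) {
  rows <- list()
  for (pw in names(network$pathways)) {
    members <- network$pathways[[pw]]
    if (length(members) < min_reactions) next
    mets <- character(0)
    for (r in members)
      mets <- c(mets, network$reaction_metabolites[[r]])
    mets <- sort(unique(mets))
    scored <- mets[mets %in% met_table$metabolite]
    if (length(scored) == 0L) next
    v <- met_table$corrected_z[match(scored, met_table$metabolite)]
    n <- length(v)
    raw <- sum(v) / sqrt(n)
    bg <- oracle_lookup(background, n)
    cz <- (raw - bg$mu) / bg$sigma
    rows[[pw]] <- data.frame(pathway = pw, n_scored = n, raw_z = raw,
                             corrected_z = cz, p_value = 1 - pnorm(cz),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_rpar <- function(network, reaction_stats, background,
                        min_reactions = 3L) {
  rows <- list()
  for (pw in names(network$pathways)) {
    members <- network$pathways[[pw]]
    if (length(members) < min_reactions) next
    z <- numeric(0)
    for (r in sort(members)) {
      hit <- match(r, reaction_stats$reaction)
      if (!is.na(hit)) z <- c(z, reaction_stats$z[hit])
    }
    if (length(z) == 0L) next
    p_cnt <- length(z)
    raw <- sum(z) / sqrt(p_cnt)
    bg <- oracle_lookup(background, p_cnt)
    cz <- (raw - bg$mu) / bg$sigma
    rows[[pw]] <- data.frame(pathway = pw, n_scored = p_cnt, raw_z = raw,
                             corrected_z = cz, p_value = 1 - pnorm(cz),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# min-p gene selection, coded independently
oracle_reaction_stats <- function(network, gene_stats) {
  rows <- list()
  for (r in names(network$reaction_genes)) {
    best_g <- NA_character_; best_p <- Inf
    for (g in sort(network$reaction_genes[[r]])) {
      i <- match(g, gene_stats$gene)
      if (is.na(i)) next
      if (gene_stats$p_value[i] < best_p) {
        best_p <- gene_stats$p_value[i]; best_g <- g
      }
    }
    if (is.na(best_g)) next
    i <- match(best_g, gene_stats$gene)
    rows[[r]] <- data.frame(reaction = r, gene = best_g,
                            p_value = gene_stats$p_value[i],
                            z = gene_stats$z[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$reaction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
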