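P_CLAMP <- 1e-15

clamp_p <- function(p) pmin(pmax(p, P_CLAMP), 1 - P_CLAMP)

#' Convert a p-value to a standard-normal Z-score
#'
#' `z = qnorm(1 - p)`: small p-values map to large positive deviates. Input is
#' clamped to `[1e-15, 1 - 1e-15]` so the quantile stays finite.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector of Z-scores, strictly decreasing in `p`.
#' @export
pvalue_to_z <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite numbers in [0, 1]", call. = FALSE)
  stats::qnorm(clamp_p(p), lower.tail = FALSE)
}

#' Per-gene differential expression statistics
#'
#' Runs a two-sample t-test on every gene of an expression matrix and returns
#' p-values, Z-scores (via [pvalue_to_z()]), and the direction of change. The
#' first level of `groups` is the reference condition; `sign` is the sign of
#' `mean(condition) - mean(reference)`. The pooled-variance (equal-variance)
#' test is the default, with a Welch option.
#'
#' Genes that are constant across all samples carry no information: their
#' p-value is set to `1 - 1e-15` with a warning and their sign to 0.
#'
#' @param expression numeric matrix (or data.frame), genes in rows (rownames
#'   are gene ids), samples in columns.
#' @param groups factor or character vector of length `ncol(expression)` with
#'   exactly two levels, each represented by at least two samples.
#' @param tail `"two_sided"` for the standard analysis; `"greater"` /
#'   `"less"` give one-tailed p-values for up-/down-regulation in the
#'   condition group (used by the directional variants).
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch if
#'   `FALSE`.
#' @return A data.frame of class `gene_stats` with columns `gene`, `p_value`,
#'   `z`, `sign`; attribute `tail` records the tail used.
#' @export
compute_gene_pvalues <- function(expression, groups,
                                 tail = c("two_sided", "greater", "less"),
                                 var_equal = TRUE) {
  tail <- match.arg(tail)
  x <- as.matrix(expression)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("expression matrix must be numeric with finite values",
         call. = FALSE)
  if (is.null(rownames(x)))
    stop("expression matrix must have gene ids as rownames", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) != 2L || length(groups) != ncol(x))
    stop("groups must be a two-level factor of length ncol(expression)",
         call. = FALSE)
  cnt <- table(groups)
  if (any(cnt < 2L))
    stop("each group needs at least 2 samples (got ",
         paste(cnt, collapse = ", "), ")", call. = FALSE)

  ref <- x[, groups == levels(groups)[1L], drop = FALSE]
  cond <- x[, groups == levels(groups)[2L], drop = FALSE]
  n1 <- ncol(ref); n2 <- ncol(cond)
  m1 <- rowMeans(ref); m2 <- rowMeans(cond)
  v1 <- apply(ref, 1L, stats::var); v2 <- apply(cond, 1L, stats::var)
  diff <- m2 - m1

  if (var_equal) {
    df <- rep(n1 + n2 - 2, nrow(x))
    se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }

  tstat <- diff / se
  p <- switch(tail,
    two_sided = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
    greater = stats::pt(tstat, df, lower.tail = FALSE),
    less = stats::pt(tstat, df))

  degenerate <- !is.finite(tstat) & diff == 0  # constant gene, no variance
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) constant across samples; p set to 1-eps",
            call. = FALSE)
    p[degenerate] <- 1 - P_CLAMP
  }
  p <- clamp_p(p)

  out <- data.frame(
    gene = rownames(x),
    p_value = unname(p),
    z = unname(pvalue_to_z(p)),
    sign = unname(sign(diff)),
    stringsAsFactors = FALSE)
  structure(out, tail = tail, var_equal = var_equal,
            class = c("gene_stats", "data.frame"))
}

#' Read a precomputed per-gene p-value table
#'
#' Bypasses the t-test: accepts a TSV with columns `gene` and `p_value`, plus
#' an optional `sign` or `log_fold_change` column for directional analysis.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A `gene_stats` data.frame (see [compute_gene_pvalues()]); `sign`
#'   is 0 for all genes when no direction column is present.
#' @export
read_gene_stats <- function(path) {
  if (!file.exists(path))
    stop("p-value file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  for (col in c("gene", "p_value"))
    if (!col %in% names(tab))
      stop("required column missing from p-value file: '", col, "'",
           call. = FALSE)
  p <- as.numeric(tab$p_value)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p_value column must contain numbers in [0, 1]", call. = FALSE)
  p <- clamp_p(p)
  sgn <- if ("sign" %in% names(tab)) sign(as.numeric(tab$sign))
         else if ("log_fold_change" %in% names(tab))
           sign(as.numeric(tab$log_fold_change))
         else rep(0, nrow(tab))
  out <- data.frame(gene = as.character(tab$gene), p_value = p,
                    z = pvalue_to_z(p), sign = sgn, stringsAsFactors = FALSE)
  structure(out, tail = "two_sided", class = c("gene_stats", "data.frame"))
}

#' Map gene statistics onto reactions (minimum-p rule)
#'
#' A reaction controlled by several genes is represented by the gene with the
#' smallest differential-expression p-value; ties are broken
#' lexicographically by gene id so the mapping is deterministic. Reactions
#' whose genes are all unmeasured (absent from `stats`) are omitted, as are
#' reactions without gene association.
#'
#' @param network a `metabolic_network`.
#' @param stats a `gene_stats` table.
#' @return A data.frame of class `reaction_stats` with columns `reaction`,
#'   `gene` (the selected gene), `p_value`, `z`, `sign`, sorted by reaction
#'   id.
#' @export
map_genes_to_reactions <- function(network, stats) {
  validate_network(network)
  stopifnot(is.data.frame(stats), all(c("gene", "p_value", "z") %in% names(stats)))
  long <- data.frame(
    reaction = rep(names(network$reaction_genes),
                   lengths(network$reaction_genes)),
    gene = unlist(network$reaction_genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  idx <- match(long$gene, stats$gene)
  long <- long[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  long$p_value <- stats$p_value[idx]
  long$z <- stats$z[idx]
  long$sign <- if ("sign" %in% names(stats)) stats$sign[idx] else 0
  ord <- order(long$reaction, long$p_value, long$gene)
  long <- long[ord, , drop = FALSE]
  out <- long[!duplicated(long$reaction), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, tail = attr(stats, "tail"),
            class = c("reaction_stats", "data.frame"))
}

#' Restrict gene statistics to one regulation direction
#'
#' Keeps only the genes whose change matches `direction` and converts their
#' two-sided p-values to one-tailed ones (`p/2`, exact for the symmetric t
#' statistic), recomputing Z-scores. This is the gene table the directional
#' (up/down) reporter analysis runs on; because it discards network
#' connectivity carried by the opposite-sign genes, its results are meant to
#' be read alongside the undirected analysis, not instead of it.
#'
#' @param stats a two-sided `gene_stats` table with a `sign` column.
#' @param direction `"up"` or `"down"` (relative to the reference group).
#' @return A `gene_stats` table restricted to matching genes, with attribute
#'   `direction`.
#' @export
directional_gene_stats <- function(stats, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(stats), "sign" %in% names(stats))
  if (!identical(attr(stats, "tail"), "two_sided"))
    stop("directional restriction expects two-sided input p-values",
         call. = FALSE)
  want <- if (direction == "up") 1 else -1
  keep <- stats[stats$sign == want, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no ", direction, "-regulated genes in the statistic table",
         call. = FALSE)
  keep$p_value <- clamp_p(keep$p_value / 2)
  keep$z <- pvalue_to_z(keep$p_value)
  rownames(keep) <- NULL
  structure(keep, tail = if (direction == "up") "greater" else "less",
            direction = direction, class = c("gene_stats", "data.frame"))
}
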