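# Shared fixtures, built in code at test time.

# Three-reaction toy: R1{A,B; g1; P1}, R2{B,C; g2,g3; P1}, R3{C,D; g4; P2}
toy_network_lines <- function() {
  c("reaction\tmetabolites\tgenes\tpathways",
    "R1\tA // B\tg1\tP1",
    "R2\tB // C\tg2 // g3\tP1",
    "R3\tC // D\tg4\tP2")
}

toy_network_file <- function(lines = toy_network_lines()) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

toy_network <- function() parse_network(toy_network_file())

make_gene_stats <- function(genes, p, sign = rep(0, length(genes))) {
  structure(
    data.frame(gene = genes, p_value = p, z = pvalue_to_z(p), sign = sign,
               stringsAsFactors = FALSE),
    tail = "two_sided", class = c("gene_stats", "data.frame"))
}

# Two pathways sharing metabolite "shared": PA's chain ends in it, and PB's
# reaction B1 consumes it while being a member of PB only. The gene of B1 is
# a cross-link gene for PA (counted by the metabolite-centric statistic,
# invisible to the reaction-centric one).
crosslink_toy <- function() {
  metabolic_network(
    reaction_metabolites = list(
      A1 = c("a0", "a1"), A2 = c("a1", "a2"), A3 = c("a2", "shared"),
      B1 = c("shared", "b1"), B2 = c("b1", "b2"), B3 = c("b2", "b3")),
    reaction_genes = list(A1 = "gA1", A2 = "gA2", A3 = "gA3",
                          B1 = "gB1", B2 = "gB2", B3 = "gB3"),
    pathways = list(PA = c("A1", "A2", "A3"), PB = c("B1", "B2", "B3")))
}
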