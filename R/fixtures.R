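#' Generate a toy alignment fixture exercising every clustering branch
#'
#' Writes a small, fully hand-constructed gene universe (3 genomes, 14
#' genes) whose alignment table drives the strict-clique clusterer through
#' each of its branches at the default thresholds (i = c = 0.74): a
#' three-gene clique that forms one family, a two-edge path whose far end
#' fails the clique test, a both-endpoints-already-assigned edge that must
#' be skipped, a gene with no qualifying alignments (singleton), a
#' below-threshold distractor alignment, a self-hit, and a within-genome
#' paralog pair that collapses to one family occurrence. The expected
#' family catalog is written alongside for comparison.
#'
#' @param dir Output directory (created if needed).
#' @param seed Accepted for interface uniformity; the fixture is
#'   hand-constructed and identical for every seed.
#' @return Invisibly, a named list of the file paths written: `alignments`,
#'   `gene_map`, `expected_families`.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- 100  # all genes 100 residues; spans chosen to clear/fail c = 0.74
  row <- function(q, s, pident, qs, qe, ss, se, evalue) {
    sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f\t%d\t%d",
            q, s, pident, qe - qs + 1, 0L, 0L, qs, qe, ss, se,
            format(evalue, scientific = TRUE), 200, L, L)
  }
  aln <- c(
    # clique accept: a1-b1-c1 triangle -> one family
    row("a1", "b1", 90, 1, 95, 1, 95, 1e-80),
    row("b1", "c1", 88, 1, 92, 1, 92, 1e-70),
    row("a1", "c1", 85, 1, 90, 1, 90, 1e-60),
    # reciprocal duplicate of a1-b1 with worse E-value: must collapse
    row("b1", "a1", 90, 1, 95, 1, 95, 1e-75),
    # clique reject: a2-b2 strong, b2-c2 weaker, no a2-c2 edge
    row("a2", "b2", 92, 1, 96, 1, 96, 1e-50),
    row("b2", "c2", 80, 1, 85, 1, 85, 1e-30),
    # both-assigned skip: a3-b3 then c3-d3 seed families, b3-c3 skipped
    row("a3", "b3", 91, 1, 94, 1, 94, 1e-65),
    row("c3", "d3", 89, 1, 93, 1, 93, 1e-55),
    row("b3", "c3", 86, 1, 90, 1, 90, 1e-40),
    # paralogs p1, p2 (same genome) + q1: full triangle -> one family
    row("p1", "p2", 95, 1, 98, 1, 98, 1e-90),
    row("p1", "q1", 93, 1, 97, 1, 97, 1e-85),
    row("p2", "q1", 92, 1, 96, 1, 96, 1e-82),
    # distractors: below identity threshold; below coverage; self-hit
    row("s1", "a1", 50, 1, 95, 1, 95, 1e-20),
    row("s1", "b2", 90, 1, 60, 1, 60, 1e-25),
    row("s1", "s1", 100, 1, 100, 1, 100, 0))
  genes <- data.frame(
    gene_id = c("a1", "a2", "a3", "d3", "p1", "p2",
                "b1", "b2", "b3", "s1", "q1",
                "c1", "c2", "c3"),
    genome_id = rep(c("G1", "G2", "G3"), c(6, 5, 3)),
    stringsAsFactors = FALSE)
  # expected catalog under the greedy strict-clique rules (walked by hand,
  # families numbered in creation order, singletons in universe order):
  # F01 {p1,p2,q1}; F02 {a1,b1,c1}; F03 {a3,b3}; F04 {c3,d3}; F05 {a2,b2};
  # b3-c3 skipped (both assigned); c2 clique-rejected against {a2,b2}
  # (no c2-a2 edge); singletons F06 s1, F07 c2.
  expected <- data.frame(
    gene_id = c("p1", "p2", "q1", "a1", "b1", "c1", "a3", "b3",
                "c3", "d3", "a2", "b2", "s1", "c2"),
    family_id = c("F01", "F01", "F01", "F02", "F02", "F02", "F03", "F03",
                  "F04", "F04", "F05", "F05", "F06", "F07"),
    stringsAsFactors = FALSE)
  paths <- list(
    alignments = file.path(dir, "toy_alignments.tsv"),
    gene_map = file.path(dir, "toy_gene_map.tsv"),
    expected_families = file.path(dir, "toy_expected_families.tsv"))
  writeLines(aln, paths$alignments)
  con <- file(paths$gene_map, "w")
  write_meta(con, c(fixture = "toy"))
  writeLines(c("gene_id\tgenome_id",
               paste(genes$gene_id, genes$genome_id, sep = "\t")), con)
  close(con)
  con <- file(paths$expected_families, "w")
  write_meta(con, c(fixture = "toy"))
  writeLines(c("gene_id\tfamily_id",
               paste(expected$gene_id, expected$family_id, sep = "\t")), con)
  close(con)
  invisible(paths)
}
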