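write_aln <- function(lines, path = withr::local_tempfile(fileext = ".tsv",
                                                          .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

test_that("alignment parsing maps fields, drops self-hits, flags bad rows", {
  path <- write_aln(c(
    "gA\tgB\t80.00\t90\t10\t0\t1\t90\t5\t94\t1e-50\t200\t100\t100",
    "gA\tgA\t100.00\t100\t0\t0\t1\t100\t1\t100\t0\t300\t100\t100"))
  aln <- read_alignment_table(path)
  expect_equal(nrow(aln), 1)  # self-hit dropped
  expect_equal(aln$identity, 0.80)
  expect_equal(aln$q_len, 100)
  expect_equal(aln$s_len, 100)
  expect_equal(aln$evalue, 1e-50)

  # 12-column dialect requires a lengths table
  p12 <- write_aln("gA\tgB\t80.00\t90\t10\t0\t1\t90\t5\t94\t1e-50\t200")
  expect_error(read_alignment_table(p12), "qlen/slen")
  lens <- data.frame(gene_id = c("gA", "gB"), length = c(100, 120))
  aln12 <- read_alignment_table(p12, lengths = lens)
  expect_equal(aln12$s_len, 120)
  expect_error(read_alignment_table(p12, lengths = lens[1, ]), "gB")

  bad <- write_aln("gA\tgB\tnotanumber\t90\t10\t0\t1\t90\t5\t94\t1e-50\t200\t100\t100")
  expect_error(read_alignment_table(bad), "line")
  coords <- write_aln("gA\tgB\t80.00\t90\t10\t0\t90\t1\t5\t94\t1e-50\t200\t100\t100")
  expect_error(read_alignment_table(coords), "malformed")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(out <- read_alignment_table(empty), "empty")
  expect_equal(nrow(out), 0)
})

test_that("homology thresholds are strict and reciprocal hits collapse", {
  rec <- function(q, s, id, span, ev) {
    data.frame(query_id = q, subject_id = s, identity = id,
               q_start = 1, q_end = span, s_start = 1, s_end = span,
               evalue = ev, bitscore = 200, q_len = 100, s_len = 100)
  }
  records <- rbind(
    rec("a", "b", 0.80, 90, 1e-30),   # qualifies at i = c = 0.74
    rec("b", "a", 0.80, 90, 1e-50),   # reciprocal, better E-value
    rec("a", "c", 0.74, 90, 1e-40),   # identity exactly at bound: excluded
    rec("a", "d", 0.90, 74, 1e-40))   # coverage exactly at bound: excluded
  edges <- homology_edges(records, identity = 0.74, coverage = 0.74)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$gene_a, "a")
  expect_equal(edges$gene_b, "b")
  expect_equal(edges$evalue, 1e-50)  # best qualifying record kept
  expect_equal(edges$min_coverage, 0.90)

  # single qualifying record at looser thresholds
  edges2 <- homology_edges(records, identity = 0.7, coverage = 0.7)
  expect_equal(sort(paste(edges2$gene_a, edges2$gene_b)),
               c("a b", "a c", "a d"))
})

test_that("edge sets shrink monotonically as thresholds tighten", {
  set.seed(31)
  for (rep in 1:10) {
    records <- random_alignment_records(10, p_pair = 0.6)
    key <- function(e) paste(e$gene_a, e$gene_b)
    loose <- key(homology_edges(records, identity = 0.5, coverage = 0.5))
    for (th in list(c(0.6, 0.5), c(0.5, 0.7), c(0.7, 0.7), c(0.8, 0.8))) {
      tight <- key(homology_edges(records, identity = th[1], coverage = th[2]))
      expect_true(all(tight %in% loose))
    }
  }
})

test_that("strict-clique clustering follows the greedy walk-throughs", {
  ed <- function(a, b, ev) data.frame(gene_a = a, gene_b = b, evalue = ev,
                                      identity = 0.9, min_coverage = 0.9)
  # triangle: one family
  tri <- rbind(ed("a", "b", 1e-50), ed("b", "c", 1e-40), ed("a", "c", 1e-30))
  expect_equal(catalog_partition(cluster_families(tri, c("a", "b", "c"))),
               list(c("a", "b", "c")))
  # path: far end fails the clique test, becomes a singleton
  path <- rbind(ed("a", "b", 1e-50), ed("b", "c", 1e-30))
  expect_equal(catalog_partition(cluster_families(path, c("a", "b", "c"))),
               list(c("a", "b"), "c"))
  # both endpoints assigned: edge skipped, families never merge
  skip <- rbind(ed("a", "b", 1e-50), ed("c", "d", 1e-40), ed("b", "c", 1e-30))
  expect_equal(catalog_partition(cluster_families(skip, c("a", "b", "c", "d"))),
               list(c("a", "b"), c("c", "d")))
  # no edges at all: all singletons
  none <- cluster_families(ed("x", "y", 1)[0, ], c("a", "b"))
  expect_equal(length(unique(none$family_id)), 2)

  expect_error(cluster_families(ed("a", "zz", 1e-10), c("a", "b")),
               "outside the gene universe")
})

test_that("clustering matches an independent naive implementation", {
  set.seed(53)
  for (rep in 1:80) {
    inst <- random_edge_instance(n_genes = sample(4:12, 1))
    genes <- paste0("g", sprintf("%02d", seq_len(max(4, sample(4:12, 1)))))
    genes <- unique(c(genes, inst$gene_a, inst$gene_b))
    got <- catalog_partition(cluster_families(inst, genes))
    want <- canonical_partition(naive_cluster(inst, genes))
    expect_identical(got, want)
    # partition invariant: every gene in exactly one family
    expect_setequal(unlist(got), genes)
    expect_equal(sum(lengths(got)), length(genes))
  }
})

test_that("every multi-member output family is a clique", {
  set.seed(71)
  for (rep in 1:20) {
    inst <- random_edge_instance(n_genes = 10)
    genes <- paste0("g", sprintf("%02d", 1:10))
    cat <- cluster_families(inst, genes)
    has_edge <- paste(inst$gene_a, inst$gene_b)
    for (fam in split(cat$gene_id, cat$family_id)) {
      if (length(fam) >= 2) {
        prs <- utils::combn(sort(fam), 2)
        expect_true(all(paste(prs[1, ], prs[2, ]) %in% has_edge))
      }
    }
  }
})

test_that("clustering is deterministic", {
  set.seed(97)
  inst <- random_edge_instance(n_genes = 12)
  genes <- paste0("g", sprintf("%02d", 1:12))
  c1 <- cluster_families(inst, genes)
  c2 <- cluster_families(inst[sample(nrow(inst)), ], genes)  # shuffled input
  expect_identical(c1, c2)
})

test_that("genome family sets collapse paralogs and validate the map", {
  catalog <- data.frame(gene_id = c("a", "b", "e", "x"),
                        family_id = c("F1", "F1", "F3", "F9"))
  map <- data.frame(gene_id = c("a", "b", "e", "x"),
                    genome_id = c("G1", "G1", "G1", "G2"))
  sets <- genome_family_sets(catalog, map)
  expect_setequal(sets$G1, c("F1", "F3"))  # paralogs a, b collapse
  expect_equal(sets$G2, "F9")

  expect_error(genome_family_sets(catalog, map[-1, ]), "missing from")
  # a genome that appears in the map but holds no cataloged gene is dropped
  expect_warning(genome_family_sets(catalog, rbind(map,
    data.frame(gene_id = "zz", genome_id = "G3"))), "dropped")
})

test_that("tighter thresholds tend to raise family counts and fluidity", {
  # median-level tendency across random instances, not per-instance
  set.seed(123)
  n_fams_loose <- n_fams_tight <- phi_loose <- phi_tight <- numeric(20)
  for (r in 1:20) {
    grp <- clique_group(core = 6, u = c(2, 3, 2, 3), label = "t")
    # jitter identities so thresholds separate alignments
    grp$alignments$identity <- round(runif(nrow(grp$alignments), 0.55, 0.95), 2)
    est_at <- function(i, c) {
      e <- homology_edges(grp$alignments, i, c)
      cat <- cluster_families(e, grp$gene_map$gene_id)
      list(nf = length(unique(cat$family_id)),
           phi = fluidity(genome_family_sets(cat, grp$gene_map)))
    }
    lo <- est_at(0.5, 0.5); hi <- est_at(0.85, 0.85)
    n_fams_loose[r] <- lo$nf; n_fams_tight[r] <- hi$nf
    phi_loose[r] <- lo$phi; phi_tight[r] <- hi$phi
  }
  expect_gte(median(n_fams_tight), median(n_fams_loose))
  expect_gte(median(phi_tight), median(phi_loose))
})

test_that("family catalog TSV round-trips", {
  set.seed(5)
  inst <- random_edge_instance(8)
  genes <- paste0("g", sprintf("%02d", 1:8))
  cat1 <- cluster_families(inst, genes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_family_catalog(cat1, path, meta = c(note = "test"))
  back <- read_family_catalog(path)
  expect_equal(back$gene_id, cat1$gene_id)
  expect_equal(back$family_id, cat1$family_id)
})
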