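# Independent oracles: deliberately naive re-implementations used only to
# cross-check package results on small instances. They share no code with
# the package internals (set arithmetic instead of sparse matrices;
# adjacency matrices instead of hashed environments).

naive_pair_ratio <- function(a, b) {
  u_a <- length(setdiff(a, b))
  u_b <- length(setdiff(b, a))
  (u_a + u_b) / (length(a) + length(b))
}

naive_fluidity <- function(sets) {
  n <- length(sets)
  acc <- 0
  for (k in seq_len(n - 1)) {
    for (l in seq(k + 1, n)) {
      acc <- acc + naive_pair_ratio(sets[[k]], sets[[l]])
    }
  }
  2 / (n * (n - 1)) * acc
}

naive_loo <- function(sets, i) {
  n <- length(sets)
  acc <- 0
  for (k in seq_len(n - 1)) {
    for (l in seq(k + 1, n)) {
      if (k != i && l != i) {
        acc <- acc + naive_pair_ratio(sets[[k]], sets[[l]])
      }
    }
  }
  2 / ((n - 1) * (n - 2)) * acc
}

naive_jackknife <- function(sets) {
  n <- length(sets)
  phi <- naive_fluidity(sets)
  loo <- sapply(seq_len(n), function(i) naive_loo(sets, i))
  (n - 1) / n * sum((loo - phi)^2)
}

# random genome group: each of `fams` families enters each genome with
# probability p; empty genomes get one guaranteed family
random_sets <- function(n_genomes, fams = 30, p = 0.5) {
  universe <- paste0("fam", seq_len(fams))
  sets <- lapply(seq_len(n_genomes), function(i) {
    s <- universe[stats::runif(fams) < p]
    if (length(s) == 0) s <- sample(universe, 1)
    s
  })
  names(sets) <- paste0("G", seq_len(n_genomes))
  genome_sets(sets)
}

# naive greedy strict-clique clustering over an edge table, using a dense
# logical adjacency matrix and an integer label vector
naive_cluster <- function(edges, genes) {
  genes <- unique(genes)
  lab <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  adj <- matrix(FALSE, length(genes), length(genes),
                dimnames = list(genes, genes))
  if (nrow(edges) > 0) {
    o <- order(edges$evalue, -edges$identity, -edges$min_coverage,
               edges$gene_a, edges$gene_b)
    edges <- edges[o, , drop = FALSE]
    for (r in seq_len(nrow(edges))) {
      adj[edges$gene_a[r], edges$gene_b[r]] <- TRUE
      adj[edges$gene_b[r], edges$gene_a[r]] <- TRUE
    }
    nxt <- 0L
    for (r in seq_len(nrow(edges))) {
      a <- edges$gene_a[r]; b <- edges$gene_b[r]
      if (is.na(lab[a]) && is.na(lab[b])) {
        nxt <- nxt + 1L
        lab[c(a, b)] <- nxt
      } else if (xor(is.na(lab[a]), is.na(lab[b]))) {
        free <- if (is.na(lab[a])) a else b
        fid <- if (is.na(lab[a])) lab[b] else lab[a]
        members <- names(lab)[!is.na(lab) & lab == fid]
        if (all(adj[free, members])) lab[free] <- fid
      }
    }
  }
  for (g in genes) {
    if (is.na(lab[g])) lab[g] <- max(c(0L, lab), na.rm = TRUE) + 1L
  }
  lab
}

# canonical partition: list of sorted member vectors, ordered by first member
canonical_partition <- function(assignment) {
  # assignment: named vector gene -> family label (any label type)
  parts <- lapply(split(names(assignment), as.character(assignment)), sort)
  parts <- parts[order(vapply(parts, `[[`, character(1), 1))]
  unname(parts)
}

catalog_partition <- function(catalog) {
  canonical_partition(stats::setNames(catalog$family_id, catalog$gene_id))
}

# random edge instance over <= 12 genes; coarse E-value grid so ties occur
random_edge_instance <- function(n_genes = 8, p_edge = 0.45) {
  genes <- paste0("g", sprintf("%02d", seq_len(n_genes)))
  pairs <- t(utils::combn(genes, 2))
  pick <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[pick, , drop = FALSE]
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
             evalue = 10^(-sample(5:15, nrow(pairs), replace = TRUE)),
             identity = round(stats::runif(nrow(pairs), 0.75, 1), 2),
             min_coverage = round(stats::runif(nrow(pairs), 0.75, 1), 2),
             stringsAsFactors = FALSE)
}

# random alignment table (14-column dialect already parsed): spans and
# identities spread across [0.4, 1] so thresholds in [0.5, 0.8] bite
random_alignment_records <- function(n_genes = 10, p_pair = 0.5) {
  genes <- paste0("g", sprintf("%02d", seq_len(n_genes)))
  pairs <- t(utils::combn(genes, 2))
  pick <- stats::runif(nrow(pairs)) < p_pair
  pairs <- pairs[pick, , drop = FALSE]
  n <- nrow(pairs)
  len <- 100
  span <- sample(40:100, n, replace = TRUE)
  df <- data.frame(
    query_id = pairs[, 1], subject_id = pairs[, 2],
    identity = round(stats::runif(n, 0.4, 1), 2),
    q_start = 1, q_end = span, s_start = 1, s_end = span,
    evalue = 10^(-sample(5:40, n, replace = TRUE)),
    bitscore = 200, q_len = len, s_len = len,
    stringsAsFactors = FALSE)
  class(df) <- c("alignment_table", "data.frame")
  df
}

# alignment table + gene map for a group of genomes with `core` families
# shared by every genome (full per-family cliques at identity 0.95,
# coverage 0.96) and u[i] unique singleton genes in genome i; its fluidity
# under any threshold below 0.95/0.96 is mean over pairs of
# (u_i + u_j) / (2 * core + u_i + u_j)
clique_group <- function(core, u, label) {
  n <- length(u)
  genomes <- paste0(label, "_G", seq_len(n))
  gene <- character(0); genome <- character(0)
  rows <- character(0)
  ev <- 1e-60
  aln <- list()
  for (f in seq_len(core)) {
    ids <- paste0(label, "_f", f, "_", seq_len(n))
    gene <- c(gene, ids); genome <- c(genome, genomes)
    cmb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cmb))) {
      ev <- ev * 1.01
      aln[[length(aln) + 1]] <- data.frame(
        query_id = cmb[1, j], subject_id = cmb[2, j], identity = 0.95,
        q_start = 1, q_end = 96, s_start = 1, s_end = 96,
        evalue = ev, bitscore = 300, q_len = 100, s_len = 100,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n)) {
    if (u[i] > 0) {
      ids <- paste0(label, "_u", i, "_", seq_len(u[i]))
      gene <- c(gene, ids)
      genome <- c(genome, rep(genomes[i], u[i]))
    }
  }
  aln <- do.call(rbind, aln)
  class(aln) <- c("alignment_table", "data.frame")
  list(alignments = aln,
       gene_map = data.frame(gene_id = gene, genome_id = genome,
                             stringsAsFactors = FALSE),
       expected_phi = {
    pr <- utils::combn(u, 2)
    mean((pr[1, ] + pr[2, ]) / (2 * core + pr[1, ] + pr[2, ]))
  })
}
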