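#' Read a BLAST-style tabular alignment file
#'
#' Reads all-vs-all pairwise protein alignment results in the standard
#' 12-column tabular layout (query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, E-value, bit score), extended with the two gene lengths
#' `qlen` and `slen` as columns 13-14. If the file has only 12 columns a
#' `lengths` table (`gene_id`, `length`, e.g. from [read_gene_lengths()])
#' must supply the lengths instead. Percent identity is converted to a
#' fraction; self-alignments (query id equal to subject id) are dropped.
#'
#' @param path Path to the tab-separated alignment file (no header;
#'   `#`-prefixed comment lines allowed).
#' @param lengths Optional data frame with columns `gene_id` and `length`
#'   (residues), required when the file lacks the qlen/slen columns.
#' @return A data frame of class `alignment_table` with columns `query_id`,
#'   `subject_id`, `identity` (fraction), `q_start`, `q_end`, `s_start`,
#'   `s_end`, `q_len`, `s_len`, `evalue`, `bitscore`.
#' @export
read_alignment_table <- function(path, lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    warning("empty alignment file: ", path, call. = FALSE)
    return(empty_alignment_table())
  }
  raw <- utils::read.delim(text = lines, header = FALSE,
                           colClasses = "character")
  nc <- ncol(raw)
  if (nc != 12 && nc != 14) {
    stop("alignment file must have 12 standard columns (plus qlen, slen as ",
         "columns 13-14); found ", nc, " columns", call. = FALSE)
  }
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop("non-numeric ", name, " at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    v
  }
  df <- data.frame(
    query_id = raw[[1]], subject_id = raw[[2]],
    identity = num(3, "percent identity") / 100,
    q_start = num(7, "q_start"), q_end = num(8, "q_end"),
    s_start = num(9, "s_start"), s_end = num(10, "s_end"),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    stringsAsFactors = FALSE)
  if (nc == 14) {
    df$q_len <- num(13, "qlen")
    df$s_len <- num(14, "slen")
  } else {
    if (is.null(lengths)) {
      stop("alignment file has no qlen/slen columns; supply `lengths` ",
           "(a gene_id/length table, see read_gene_lengths())", call. = FALSE)
    }
    lut <- stats::setNames(as.numeric(lengths$length),
                           as.character(lengths$gene_id))
    df$q_len <- unname(lut[df$query_id])
    df$s_len <- unname(lut[df$subject_id])
    miss <- is.na(df$q_len) | is.na(df$s_len)
    if (any(miss)) {
      stop("no length for gene(s): ",
           paste(utils::head(unique(c(df$query_id[miss & is.na(df$q_len)],
                                      df$subject_id[miss & is.na(df$s_len)])), 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(!(df$q_start >= 1 & df$q_start <= df$q_end & df$q_end <= df$q_len &
                 df$s_start >= 1 & df$s_start <= df$s_end & df$s_end <= df$s_len &
                 df$identity >= 0 & df$identity <= 1 & df$evalue >= 0))
  if (length(bad)) {
    stop("malformed alignment coordinates at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  df <- df[df$query_id != df$subject_id, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("alignment_table", "data.frame")
  df
}

empty_alignment_table <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   identity = numeric(), q_start = numeric(),
                   q_end = numeric(), s_start = numeric(), s_end = numeric(),
                   evalue = numeric(), bitscore = numeric(),
                   q_len = numeric(), s_len = numeric(),
                   stringsAsFactors = FALSE)
  class(df) <- c("alignment_table", "data.frame")
  df
}

#' Read a gene-lengths TSV or derive lengths from a protein FASTA
#'
#' `read_gene_lengths()` reads a two-column `gene_id<TAB>length` table.
#' `gene_lengths_from_fasta()` reads protein sequences (requires the
#' Biostrings package) and returns their lengths in the same layout.
#'
#' @param path Input path.
#' @return Data frame with columns `gene_id`, `length`.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("gene_id", "length"),
                          colClasses = c("character", "numeric"))
  if (any(is.na(df$length) | df$length < 1)) {
    stop("invalid gene lengths in ", path, call. = FALSE)
  }
  df
}

#' @rdname read_gene_lengths
#' @export
gene_lengths_from_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("gene_lengths_from_fasta() requires the Biostrings package",
         call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  data.frame(gene_id = ids, length = Biostrings::width(aa),
             stringsAsFactors = FALSE)
}

#' Homology edges from alignments under identity/coverage thresholds
#'
#' A pair of genes is called homologous when a single alignment covers more
#' than fraction `coverage` of *each* gene's length and its identity exceeds
#' `identity` -- both bounds strict. Coverage of a gene is
#' `(end - start + 1) / length` of its aligned span. Reciprocal or repeated
#' records for the same unordered pair collapse to one edge, keeping the
#' qualifying record with the smallest E-value (ties broken by higher
#' identity, then higher minimum coverage).
#'
#' @param records An `alignment_table` from [read_alignment_table()].
#' @param identity Minimum identity fraction, exclusive bound, in \[0, 1).
#' @param coverage Minimum per-gene coverage fraction, exclusive bound, in
#'   \[0, 1\].
#' @return A data frame with one row per unordered gene pair: `gene_a`,
#'   `gene_b` (with `gene_a < gene_b`), `evalue`, `identity`,
#'   `min_coverage`.
#' @export
homology_edges <- function(records, identity = 0.74, coverage = 0.74) {
  if (!(identity >= 0 && identity < 1)) {
    stop("`identity` must lie in [0, 1)", call. = FALSE)
  }
  if (!(coverage >= 0 && coverage <= 1)) {
    stop("`coverage` must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(records) == 0) return(empty_edges())
  cov_q <- (records$q_end - records$q_start + 1) / records$q_len
  cov_s <- (records$s_end - records$s_start + 1) / records$s_len
  min_cov <- pmin(cov_q, cov_s)
  ok <- records$identity > identity & cov_q > coverage & cov_s > coverage
  if (!any(ok)) return(empty_edges())
  a <- pmin(records$query_id[ok], records$subject_id[ok])
  b <- pmax(records$query_id[ok], records$subject_id[ok])
  e <- data.frame(gene_a = a, gene_b = b,
                  evalue = records$evalue[ok],
                  identity = records$identity[ok],
                  min_coverage = min_cov[ok],
                  stringsAsFactors = FALSE)
  o <- order(e$evalue, -e$identity, -e$min_coverage, e$gene_a, e$gene_b)
  e <- e[o, , drop = FALSE]
  e <- e[!duplicated(paste(e$gene_a, e$gene_b, sep = "\r")), , drop = FALSE]
  rownames(e) <- NULL
  e
}

empty_edges <- function() {
  data.frame(gene_a = character(), gene_b = character(), evalue = numeric(),
             identity = numeric(), min_coverage = numeric(),
             stringsAsFactors = FALSE)
}

#' Cluster genes into families by greedy strict-clique agglomeration
#'
#' Edges are processed in order of increasing E-value (ties: higher
#' identity, then higher minimum coverage, then lexicographic pair), so
#' that weaker alignments cannot disrupt families seeded by stronger ones.
#' For each edge: if neither endpoint belongs to a family, the two genes
#' found a new family; if exactly one does, the free gene joins that family
#' only if it has a qualifying edge to *every* current member (the strict
#' clique requirement); if both are already assigned, the edge is skipped
#' (families never merge). Genes left unassigned become singleton families.
#' Every gene belongs to exactly one family and every multi-member family is
#' a clique in the homology graph.
#'
#' @param edges Edge table from [homology_edges()].
#' @param genes Character vector: the full gene universe (every edge
#'   endpoint must be included; genes without edges become singletons).
#' @return A `family_catalog`: data frame with columns `gene_id`,
#'   `family_id`, one row per gene.
#' @examples
#' edges <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
#'                     evalue = c(1e-50, 1e-40, 1e-30),
#'                     identity = 0.9, min_coverage = 0.9)
#' cluster_families(edges, c("a", "b", "c", "d"))
#' @export
cluster_families <- function(edges, genes) {
  genes <- unique(as.character(genes))
  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), genes)
    if (length(unknown)) {
      stop("edges reference genes outside the gene universe: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  fam_of <- new.env(parent = emptyenv(), hash = TRUE)
  members <- list()
  adj <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(edges) > 0) {
    o <- order(edges$evalue, -edges$identity, -edges$min_coverage,
               edges$gene_a, edges$gene_b)
    edges <- edges[o, , drop = FALSE]
    for (i in seq_len(nrow(edges))) {
      a <- edges$gene_a[i]; b <- edges$gene_b[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    for (i in seq_len(nrow(edges))) {
      a <- edges$gene_a[i]; b <- edges$gene_b[i]
      fa <- fam_of[[a]]; fb <- fam_of[[b]]
      if (is.null(fa) && is.null(fb)) {
        fid <- length(members) + 1L
        members[[fid]] <- c(a, b)
        fam_of[[a]] <- fid
        fam_of[[b]] <- fid
      } else if (is.null(fa) || is.null(fb)) {
        free <- if (is.null(fa)) a else b
        fid <- if (is.null(fa)) fb else fa
        if (all(members[[fid]] %in% adj[[free]])) {
          members[[fid]] <- c(members[[fid]], free)
          fam_of[[free]] <- fid
        }
      }
      # both assigned: skip; families are never merged
    }
  }
  nfam <- length(members)
  assignment <- character(length(genes))
  names(assignment) <- genes
  width <- max(1L, nchar(as.character(nfam + length(genes))))
  fmt <- paste0("F%0", width, "d")
  for (fid in seq_len(nfam)) {
    assignment[members[[fid]]] <- sprintf(fmt, fid)
  }
  nxt <- nfam
  for (g in genes) {
    if (!nzchar(assignment[[g]])) {
      nxt <- nxt + 1L
      assignment[[g]] <- sprintf(fmt, nxt)
    }
  }
  out <- data.frame(gene_id = genes, family_id = unname(assignment[genes]),
                    stringsAsFactors = FALSE)
  class(out) <- c("family_catalog", "data.frame")
  out
}

#' Genome family sets from a family catalog and a gene-to-genome map
#'
#' Collapses each genome's genes to the set of families they belong to;
#' within-genome paralogs therefore count once. Genomes listed in the map
#' but holding no cataloged gene are dropped with a warning.
#'
#' @param catalog `family_catalog` from [cluster_families()].
#' @param gene_map Data frame with columns `gene_id`, `genome_id` covering
#'   every gene of the catalog.
#' @return A [genome_sets] object.
#' @export
genome_family_sets <- function(catalog, gene_map) {
  lut <- stats::setNames(as.character(gene_map$genome_id),
                         as.character(gene_map$gene_id))
  genome <- lut[catalog$gene_id]
  if (anyNA(genome)) {
    stop("genes missing from the gene map: ",
         paste(utils::head(catalog$gene_id[is.na(genome)], 5),
               collapse = ", "), call. = FALSE)
  }
  sets <- lapply(split(catalog$family_id, genome), unique)
  unused <- setdiff(unique(as.character(gene_map$genome_id)), names(sets))
  if (length(unused)) {
    warning("genomes with no cataloged genes dropped: ",
            paste(unused, collapse = ", "), call. = FALSE)
  }
  genome_sets(sets)
}

#' Read or write a family catalog / gene map TSV
#'
#' The catalog layout is `gene_id<TAB>family_id` with a header line; the
#' gene map layout is `gene_id<TAB>genome_id`. Lines starting with `#` are
#' metadata.
#'
#' @param path File path.
#' @param catalog A `family_catalog`.
#' @param meta Optional named character vector of metadata header lines.
#' @return The catalog/map data frame for readers; `path` invisibly for the
#'   writer.
#' @export
read_family_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          colClasses = "character")
  if (!all(c("gene_id", "family_id") %in% names(df))) {
    stop("family catalog must have columns gene_id and family_id", call. = FALSE)
  }
  class(df) <- c("family_catalog", "data.frame")
  df
}

#' @rdname read_family_catalog
#' @export
write_family_catalog <- function(catalog, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  utils::write.table(catalog[, c("gene_id", "family_id")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_family_catalog
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          colClasses = "character")
  if (!all(c("gene_id", "genome_id") %in% names(df))) {
    stop("gene map must have columns gene_id and genome_id", call. = FALSE)
  }
  df
}
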