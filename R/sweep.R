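#' Sweep alignment thresholds and track fluidity rank orderings
#'
#' Re-runs the whole family-building pipeline for every point of an
#' inclusive (identity, coverage) grid: homology edges are recomputed,
#' genes re-clustered, genome family sets rebuilt and fluidity re-estimated
#' for each genome group. Fluidity magnitudes shift with the thresholds
#' (stricter thresholds split families, raising fluidity) but the
#' *ordering* of groups is typically stable; the sweep counts how often
#' each ordering occurs and runs pairwise z-tests at every grid point.
#'
#' @param groups Named list; each element is a list with components
#'   `alignments` (an `alignment_table`) and `gene_map` (a data frame with
#'   `gene_id`, `genome_id`). Each group needs at least 3 genomes for
#'   variances; smaller groups are dropped with a warning.
#' @param i_values,c_values Numeric vectors of identity and coverage
#'   thresholds, e.g. `seq(0.5, 0.8, by = 0.02)`.
#' @param alpha Per-pair significance level for the z-tests.
#' @return A `fluidity_sweep`: list with `grid` (long data frame: `i`, `c`,
#'   `group`, `phi`, `variance`, `n_genomes`), `orderings` (data frame
#'   `ordering`, `points`, `ties`), `significance` (list indexed by grid
#'   point label of [rank_significance()] results) and `alpha`.
#' @export
run_sweep <- function(groups, i_values, c_values, alpha = 0.05) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list", call. = FALSE)
  }
  if (length(i_values) < 1 || length(c_values) < 1 ||
      any(diff(i_values) <= 0) && length(i_values) > 1) {
    stop("threshold ranges must be non-empty and increasing", call. = FALSE)
  }
  keep <- vapply(groups, function(g) {
    length(unique(as.character(g$gene_map$genome_id))) >= 3
  }, logical(1))
  if (!all(keep)) {
    warning("groups with < 3 genomes dropped from the sweep: ",
            paste(names(groups)[!keep], collapse = ", "), call. = FALSE)
    groups <- groups[keep]
  }
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  grid_pts <- expand.grid(i = i_values, c = c_values,
                          KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  sig <- list()
  ordering <- character(nrow(grid_pts))
  tied <- logical(nrow(grid_pts))
  for (p in seq_len(nrow(grid_pts))) {
    iv <- grid_pts$i[p]; cv <- grid_pts$c[p]
    est <- lapply(names(groups), function(lab) {
      g <- groups[[lab]]
      estimate_at_point(g$alignments, g$gene_map, iv, cv, label = lab)
    })
    names(est) <- names(groups)
    rows[[p]] <- data.frame(
      i = iv, c = cv, group = names(groups),
      phi = vapply(est, `[[`, numeric(1), "phi"),
      variance = vapply(est, `[[`, numeric(1), "variance"),
      n_genomes = vapply(est, `[[`, numeric(1), "n_genomes"),
      row.names = NULL)
    ord <- ordering_string(vapply(est, `[[`, numeric(1), "phi"))
    ordering[p] <- ord$string
    tied[p] <- ord$tied
    sig[[sprintf("i=%g,c=%g", iv, cv)]] <- rank_significance(est, alpha = alpha)
  }
  tab <- table(ordering)
  ord_df <- data.frame(ordering = names(tab),
                       points = as.integer(tab),
                       ties = vapply(names(tab), function(o) {
                         any(tied[ordering == o])
                       }, logical(1)),
                       row.names = NULL)
  ord_df <- ord_df[order(-ord_df$points, ord_df$ordering), , drop = FALSE]
  rownames(ord_df) <- NULL
  structure(list(grid = do.call(rbind, rows), orderings = ord_df,
                 significance = sig, alpha = alpha),
            class = "fluidity_sweep")
}

# one grid point for one group: edges -> strict-clique families ->
# genome family sets -> fluidity estimate
estimate_at_point <- function(alignments, gene_map, identity, coverage,
                              label = NULL) {
  edges <- homology_edges(alignments, identity = identity,
                          coverage = coverage)
  catalog <- cluster_families(edges, genes = gene_map$gene_id)
  sets <- genome_family_sets(catalog, gene_map)
  estimate_fluidity(sets, label = label)
}

# descending-phi ordering string; exact ties joined with " = " and flagged
ordering_string <- function(phi) {
  labs <- names(phi)
  o <- order(-phi, labs)
  phi <- phi[o]; labs <- labs[o]
  sep <- ifelse(diff(phi) == 0, " = ", " > ")
  list(string = paste0(labs, c(sep, ""), collapse = ""),
       tied = any(diff(phi) == 0))
}

#' Pairwise significance matrix for a set of fluidity estimates
#'
#' Runs [compare_fluidity()] for every unordered pair of groups and
#' collects the z statistics, two-sided p-values and significance flags.
#'
#' @param estimates Named list of `fluidity_estimate` objects (>= 2, all
#'   with populated variances).
#' @param alpha Significance level for the `significant` flags.
#' @return A list with square matrices `z` (antisymmetric), `p`
#'   (symmetric) and logical `significant`, plus `alpha`. Diagonals are
#'   `NA`.
#' @export
rank_significance <- function(estimates, alpha = 0.05) {
  labs <- names(estimates)
  if (length(estimates) < 2 || is.null(labs)) {
    stop("need a named list of >= 2 estimates", call. = FALSE)
  }
  k <- length(estimates)
  z <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  p <- z
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      cmp <- compare_fluidity(estimates[[a]], estimates[[b]],
                              labels = c(labs[a], labs[b]))
      z[a, b] <- cmp$z
      z[b, a] <- -cmp$z
      p[a, b] <- p[b, a] <- cmp$p_value
    }
  }
  list(z = z, p = p, significant = p < alpha, alpha = alpha)
}

#' @export
print.fluidity_sweep <- function(x, ...) {
  np <- nrow(unique(x$grid[, c("i", "c")]))
  cat("fluidity_sweep:", np, "grid points,",
      length(unique(x$grid$group)), "groups\n")
  cat("rank orderings (phi descending):\n")
  print(x$orderings, row.names = FALSE)
  invisible(x)
}

#' Write sweep results to a directory of TSV files
#'
#' Writes `grid.tsv` (per-point, per-group estimates), `orderings.tsv`
#' and one `significance_i<i>_c<c>.tsv` per grid point (long pair format:
#' group_a, group_b, z, p, significant).
#'
#' @param sweep A `fluidity_sweep`.
#' @param dir Output directory (created if needed).
#' @param meta Optional named character vector of metadata header lines.
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir, meta = NULL) {
  stopifnot(inherits(sweep, "fluidity_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    write_meta(con, meta)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(sweep$grid, file.path(dir, "grid.tsv"))
  wt(sweep$orderings, file.path(dir, "orderings.tsv"))
  for (pt in names(sweep$significance)) {
    s <- sweep$significance[[pt]]
    labs <- rownames(s$z)
    pairs <- utils::combn(labs, 2)
    df <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     z = s$z[t(pairs)], p = s$p[t(pairs)],
                     significant = s$significant[t(pairs)])
    safe <- gsub("[=,]", "_", pt)
    wt(df, file.path(dir, paste0("significance_", safe, ".tsv")))
  }
  invisible(dir)
}
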