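#' Unique and total family counts for one genome pair
#'
#' For genomes k and l, returns the number of gene families unique to each
#' (`U_k`, `U_l`) and the total family counts (`M_k`, `M_l`). The pair ratio
#' `(U_k + U_l) / (M_k + M_l)` is the per-pair dissimilarity that genomic
#' fluidity averages.
#'
#' @param g_k,g_l Vectors of family identifiers (or single-genome elements of
#'   a [genome_sets] object). Both must be non-empty.
#' @param ids Character vector of length 2 with the genome ids (optional).
#' @return A list with elements `genome_k`, `genome_l`, `U_k`, `U_l`,
#'   `M_k`, `M_l` and `shared`. Note `M_k - U_k == M_l - U_l == shared`.
#' @examples
#' pair_counts(c("f1", "f2", "f3", "f4"), c("f1", "f2", "f3", "f5"))
#' @export
pair_counts <- function(g_k, g_l, ids = c("k", "l")) {
  g_k <- unique(as.character(g_k))
  g_l <- unique(as.character(g_l))
  if (length(g_k) == 0 || length(g_l) == 0) {
    stop("family sets must be non-empty", call. = FALSE)
  }
  shared <- length(intersect(g_k, g_l))
  list(genome_k = ids[[1]], genome_l = ids[[2]],
       U_k = length(g_k) - shared, U_l = length(g_l) - shared,
       M_k = length(g_k), M_l = length(g_l),
       shared = shared)
}

# N x N matrix of pairwise dissimilarity ratios (U_k+U_l)/(M_k+M_l),
# computed via a sparse family-by-genome incidence matrix: shared counts are
# a single cross-product, so large groups stay cheap.
pair_ratio_matrix <- function(sets) {
  sets <- as_genome_sets(sets)
  n <- length(sets)
  fam <- unlist(sets, use.names = FALSE)
  fidx <- match(fam, unique(fam))
  gidx <- rep.int(seq_len(n), lengths(sets))
  X <- Matrix::sparseMatrix(i = fidx, j = gidx, x = 1,
                            dims = c(max(fidx), n))
  S <- as.matrix(Matrix::crossprod(X))     # shared family counts
  M <- diag(S)                             # per-genome family counts
  tot <- outer(M, M, "+")
  R <- (tot - 2 * S) / tot
  dimnames(R) <- list(names(sets), names(sets))
  R
}

#' Genomic fluidity of a group of genomes
#'
#' Genomic fluidity is the average, over all genome pairs in the group, of
#' the ratio of unique to total gene families in the pair:
#' \deqn{\varphi = \frac{2}{N(N-1)} \sum_{k<l} \frac{U_k + U_l}{M_k + M_l}}
#' It is 0 when all genomes carry identical family sets and 1 when all pairs
#' are disjoint, and is invariant to genome order and family relabeling.
#'
#' @param sets A [genome_sets] object (or coercible named list) with at
#'   least two genomes.
#' @return The fluidity, a number in \[0, 1\].
#' @examples
#' g <- genome_sets(list(A = c("g1", "g2", "g3", "g4"),
#'                       B = c("g1", "g2", "g3", "g5"),
#'                       C = c("g1", "g2", "g6", "g7")))
#' fluidity(g)  # 5/12
#' @seealso [estimate_fluidity()] for the jackknife variance,
#'   [compare_fluidity()] for the two-group z-test.
#' @export
fluidity <- function(sets) {
  sets <- as_genome_sets(sets)
  if (length(sets) < 2) {
    stop("fluidity needs at least 2 genomes, got ", length(sets), call. = FALSE)
  }
  R <- pair_ratio_matrix(sets)
  mean(R[upper.tri(R)])
}

ratios_fluidity <- function(R) mean(R[upper.tri(R)])

ratios_loo <- function(R, i) {
  Ri <- R[-i, -i, drop = FALSE]
  mean(Ri[upper.tri(Ri)])
}

#' Leave-one-out fluidity
#'
#' The fluidity of the group with genome `i` removed, i.e. the average pair
#' ratio over the \eqn{(N-1)(N-2)/2} pairs not involving genome `i`. These
#' values drive the jackknife variance estimate.
#'
#' @inheritParams fluidity
#' @param i Index (or genome id) of the genome to drop; the group must have
#'   at least 3 genomes.
#' @return The leave-one-out fluidity, in \[0, 1\].
#' @export
fluidity_loo <- function(sets, i) {
  sets <- as_genome_sets(sets)
  if (length(sets) < 3) {
    stop("leave-one-out fluidity needs at least 3 genomes", call. = FALSE)
  }
  if (is.character(i)) i <- match(i, names(sets))
  if (is.na(i) || i < 1 || i > length(sets)) {
    stop("`i` does not identify a genome in the group", call. = FALSE)
  }
  ratios_loo(pair_ratio_matrix(sets), i)
}

#' Jackknife variance of the fluidity estimate
#'
#' The leave-one-out (jackknife) variance
#' \deqn{\hat\sigma^2 = \frac{N-1}{N} \sum_i (\hat\varphi_{(i)} - \hat\varphi)^2}
#' where \eqn{\hat\varphi_{(i)}} is the fluidity of the group without genome
#' i. Deviations are centered on the full-group estimate \eqn{\hat\varphi},
#' not on the mean of the leave-one-out values (see the methods vignette for
#' why this slightly conservative centering is used).
#'
#' @inheritParams fluidity
#' @return The variance estimate, a non-negative number.
#' @export
jackknife_variance <- function(sets) {
  sets <- as_genome_sets(sets)
  n <- length(sets)
  if (n < 3) {
    stop("jackknife variance needs at least 3 genomes, got ", n, call. = FALSE)
  }
  R <- pair_ratio_matrix(sets)
  phi <- ratios_fluidity(R)
  loo <- vapply(seq_len(n), function(i) ratios_loo(R, i), numeric(1))
  (n - 1) / n * sum((loo - phi)^2)
}

#' Estimate fluidity with its jackknife variance
#'
#' Bundles the fluidity point estimate, its jackknife variance and the
#' leave-one-out values into a `fluidity_estimate` object. With exactly two
#' genomes the point estimate is returned with the variance marked
#' unavailable (`NA`), since the jackknife needs at least three genomes.
#'
#' @inheritParams fluidity
#' @param label Optional group label carried into printing and comparisons.
#' @return A `fluidity_estimate`: list with `phi`, `variance`, `n_genomes`,
#'   `leave_one_out`, `genome_ids` and `label`.
#' @examples
#' g <- genome_sets(list(A = c("g1", "g2", "g3", "g4"),
#'                       B = c("g1", "g2", "g3", "g5"),
#'                       C = c("g1", "g2", "g6", "g7")))
#' estimate_fluidity(g)  # phi = 5/12, variance = 1/36
#' @export
estimate_fluidity <- function(sets, label = NULL) {
  sets <- as_genome_sets(sets)
  n <- length(sets)
  if (n < 2) {
    stop("fluidity needs at least 2 genomes, got ", n, call. = FALSE)
  }
  R <- pair_ratio_matrix(sets)
  phi <- ratios_fluidity(R)
  if (n >= 3) {
    loo <- vapply(seq_len(n), function(i) ratios_loo(R, i), numeric(1))
    v <- (n - 1) / n * sum((loo - phi)^2)
  } else {
    loo <- NULL
    v <- NA_real_
  }
  structure(list(phi = phi, variance = v, n_genomes = n,
                 leave_one_out = loo, genome_ids = names(sets),
                 label = label),
            class = "fluidity_estimate")
}

#' @export
print.fluidity_estimate <- function(x, ...) {
  lab <- if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  cat(sprintf("Genomic fluidity%s: phi = %.4f", lab, x$phi))
  if (is.na(x$variance)) {
    cat("  (variance unavailable: N = 2)\n")
  } else {
    cat(sprintf(" (sd = %.4f, jackknife), N = %d genomes\n",
                sqrt(x$variance), x$n_genomes))
  }
  invisible(x)
}

#' Write or read a fluidity estimate as JSON
#'
#' The JSON layout is `{"phi": ..., "variance": ..., "n_genomes": ...,
#' "leave_one_out": [...]}` plus the genome ids and optional label.
#'
#' @param x A `fluidity_estimate`.
#' @param path Output (input) path.
#' @return `path` invisibly for the writer; a `fluidity_estimate` for the
#'   reader.
#' @export
write_estimate_json <- function(x, path) {
  stopifnot(inherits(x, "fluidity_estimate"))
  jsonlite::write_json(
    list(phi = x$phi, variance = x$variance, n_genomes = x$n_genomes,
         leave_one_out = x$leave_one_out, genome_ids = x$genome_ids,
         label = x$label),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_estimate_json
#' @export
read_estimate_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(phi = as.numeric(j$phi),
                 variance = if (is.null(j$variance)) NA_real_ else as.numeric(j$variance),
                 n_genomes = as.integer(j$n_genomes),
                 leave_one_out = if (is.null(j$leave_one_out)) NULL else as.numeric(j$leave_one_out),
                 genome_ids = j$genome_ids,
                 label = j$label),
            class = "fluidity_estimate")
}

#' Convergence of fluidity under genome subsampling
#'
#' Draws, for each subsample size m, random subsets of m genomes (uniformly,
#' without replacement) and reports the mean fluidity across subsamples
#' together with a total standard deviation that combines the two sources of
#' uncertainty: the spread of estimates between subsamples and the sampling
#' variance of each estimate, taken as the mean within-subsample jackknife
#' variance. `total_sd = sqrt(var_between + mean_jackknife_var)`.
#'
#' @inheritParams fluidity
#' @param sizes Integer vector of subsample sizes, each in `3..N`.
#'   Defaults to `3:N`.
#' @param reps Number of random subsamples per size (at `m = N` only one
#'   distinct subsample exists and the between-subsample term is zero).
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return A data frame with columns `m`, `mean_phi`, `total_sd`, `n_reps`.
#' @export
subsample_convergence <- function(sets, sizes = NULL, reps = 50, seed = NULL) {
  sets <- as_genome_sets(sets)
  n <- length(sets)
  if (n < 3) stop("need at least 3 genomes", call. = FALSE)
  if (is.null(sizes)) sizes <- 3:n
  sizes <- as.integer(sizes)
  if (any(sizes < 3 | sizes > n)) {
    stop("subsample sizes must lie in 3..N (N = ", n, ")", call. = FALSE)
  }
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  R <- pair_ratio_matrix(sets)
  with_seed(seed, {
    out <- lapply(sizes, function(m) {
      nr <- if (m == n) 1L else as.integer(reps)
      phis <- numeric(nr)
      jvars <- numeric(nr)
      for (r in seq_len(nr)) {
        idx <- if (m == n) seq_len(n) else sample.int(n, m)
        Rm <- R[idx, idx, drop = FALSE]
        phi <- ratios_fluidity(Rm)
        loo <- vapply(seq_len(m), function(i) ratios_loo(Rm, i), numeric(1))
        phis[r] <- phi
        jvars[r] <- (m - 1) / m * sum((loo - phi)^2)
      }
      vb <- if (nr > 1) stats::var(phis) else 0
      data.frame(m = m, mean_phi = mean(phis),
                 total_sd = sqrt(vb + mean(jvars)), n_reps = nr)
    })
    do.call(rbind, out)
  })
}

#' Write a subsampling convergence table as TSV
#'
#' @param tab Data frame from [subsample_convergence()].
#' @param path Output path.
#' @param meta Optional named character vector of metadata header lines.
#' @return `path`, invisibly.
#' @export
write_convergence_tsv <- function(tab, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sample z-test for a fluidity difference
#'
#' Fluidity estimates are asymptotically normal (they are U-statistics), so
#' two groups are compared with
#' \deqn{z = \frac{\hat\varphi_1 - \hat\varphi_2}
#'                {\sqrt{\hat\sigma_1^2 + \hat\sigma_2^2}}}
#' using the jackknife variances, with a two-sided standard-normal p-value.
#'
#' @param a,b `fluidity_estimate` objects with populated variances.
#' @param labels Length-2 character vector naming the two groups; defaults
#'   to the estimates' own labels, else `"a"`/`"b"`.
#' @return A `fluidity_comparison`: list with `z`, `p_value`, `direction`
#'   (label of the larger estimate, or `"tie"`), the two estimates' `phi`,
#'   `variance` and `n_genomes`.
#' @examples
#' g1 <- genome_sets(list(x = c("a", "b"), y = c("a", "c"), z = c("a", "d")))
#' g2 <- genome_sets(list(x = c("a", "b"), y = c("a", "b"), z = c("a", "d")))
#' compare_fluidity(estimate_fluidity(g1), estimate_fluidity(g2))
#' @export
compare_fluidity <- function(a, b, labels = NULL) {
  stopifnot(inherits(a, "fluidity_estimate"), inherits(b, "fluidity_estimate"))
  if (is.null(labels)) {
    labels <- c(if (is.null(a$label)) "a" else a$label,
                if (is.null(b$label)) "b" else b$label)
  }
  if (is.na(a$variance) || is.na(b$variance)) {
    stop("both estimates need a jackknife variance (N >= 3 genomes)",
         call. = FALSE)
  }
  vsum <- a$variance + b$variance
  if (vsum == 0) {
    if (a$phi != b$phi) {
      stop("degenerate comparison: both variances are zero but the ",
           "estimates differ; the z-test is undefined", call. = FALSE)
    }
    z <- 0
  } else {
    z <- (a$phi - b$phi) / sqrt(vsum)
  }
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (z > 0) labels[[1]] else if (z < 0) labels[[2]] else "tie"
  structure(list(z = z, p_value = p, direction = direction,
                 labels = labels,
                 phi = c(a$phi, b$phi),
                 variance = c(a$variance, b$variance),
                 n_genomes = c(a$n_genomes, b$n_genomes)),
            class = "fluidity_comparison")
}

#' @export
print.fluidity_comparison <- function(x, ...) {
  cat(sprintf("Fluidity comparison %s (phi = %.4f) vs %s (phi = %.4f)\n",
              x$labels[1], x$phi[1], x$labels[2], x$phi[2]))
  cat(sprintf("  z = %.4f, two-sided p = %.4g", x$z, x$p_value))
  if (x$direction == "tie") cat("  (tie)\n")
  else cat(sprintf("  (larger: %s)\n", x$direction))
  invisible(x)
}

#' @rdname write_estimate_json
#' @param cmp A `fluidity_comparison`.
#' @export
write_comparison_json <- function(cmp, path) {
  stopifnot(inherits(cmp, "fluidity_comparison"))
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
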