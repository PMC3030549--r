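#' Specify a synthetic species by its pan/core/genome sizes
#'
#' A species template fixes the quantities a population's gene-frequency
#' distribution must honor: pan size `P` (total gene families), core size
#' `C` (families at frequency 1), expected genome size `G` (mean families
#' per genome), the frequency range `[f_min, f_max]` of accessory families
#' and the number `K` of accessory frequency classes.
#'
#' @param P Pan genome size (total family count).
#' @param C Core genome size (families present in every genome).
#' @param G Expected number of families per sampled genome, `C <= G <= P`.
#' @param f_min,f_max Rarest / most common accessory frequency,
#'   `0 < f_min <= f_max < 1`.
#' @param K Number of accessory frequency classes (>= 2).
#' @param label Species tag.
#' @return A `species_template` list.
#' @seealso [build_distribution()], [species_distribution()] for the
#'   built-in templates.
#' @export
species_template <- function(P, C, G, f_min, f_max, K = 40, label = "species") {
  if (!(C <= G && G <= P)) {
    stop("need C <= G <= P (got C=", C, ", G=", G, ", P=", P, ")",
         call. = FALSE)
  }
  if (P > C) {
    if (!(f_min > 0 && f_min <= f_max && f_max < 1)) {
      stop("need 0 < f_min <= f_max < 1", call. = FALSE)
    }
    if (K < 2) stop("need K >= 2 accessory classes", call. = FALSE)
  }
  structure(list(P = P, C = C, G = G, f_min = f_min, f_max = f_max,
                 K = as.integer(K), label = label),
            class = "species_template")
}

#' Build a gene-frequency distribution from a species template
#'
#' Constructs a compact class-based distribution: `C` families at frequency
#' 1 plus `K` accessory classes with frequencies log-spaced on
#' `[f_min, f_max]` and family counts proportional to `f^(-alpha)`. The
#' power-law exponent `alpha` is solved numerically so that the expected
#' genome size equals `G` while the total family count equals `P`. Counts
#' are rounded by largest remainder and then repaired by moving single
#' families between classes until the expected genome size is within 0.1%
#' of the accessory target `G - C` (the pan and core counts are exact by
#' construction). Large classes are never enumerated: the distribution is a
#' table of (frequency, count) rows.
#'
#' @param template A [species_template()].
#' @return A `gene_distribution`: data frame with columns `frequency`
#'   (strictly decreasing) and `families` (positive integer counts), with
#'   attributes `label` and `alpha`.
#' @examples
#' d <- build_distribution(species_template(100, 10, 50, 0.05, 0.95, K = 8))
#' sum(d$families)                      # pan size 100
#' sum(d$families * d$frequency)        # expected genome size ~50
#' @export
build_distribution <- function(template) {
  stopifnot(inherits(template, "species_template"))
  P <- template$P; C <- template$C; G <- template$G
  if (P == C) {
    # degenerate: everything core
    return(new_distribution(1, C, template$label, alpha = NA_real_))
  }
  A <- P - C
  Gacc <- G - C
  lo <- A * template$f_min
  hi <- A * template$f_max
  if (Gacc < lo || Gacc > hi) {
    stop("infeasible template: accessory genome mass G - C = ", Gacc,
         " must lie in [(P-C)*f_min, (P-C)*f_max] = [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  f <- exp(seq(log(template$f_max), log(template$f_min),
               length.out = template$K))
  n <- power_law_counts(A, Gacc, f)
  n <- repair_counts(n, f, Gacc, tol = 1e-3 * Gacc)
  keep <- n > 0
  new_distribution(c(1, f[keep]), c(C, n[keep]), template$label,
                   alpha = attr(n, "alpha"))
}

# counts n_j = total * w_j(alpha), w_j proportional to f_j^(-alpha),
# alpha solved so sum n_j f_j = mass; log-sum-exp keeps weights finite
# across many frequency decades. Largest-remainder rounding.
power_law_counts <- function(total, mass, f) {
  lf <- log(f)
  wts <- function(alpha) {
    lw <- -alpha * lf
    lw <- lw - max(lw)
    w <- exp(lw)
    w / sum(w)
  }
  h <- function(alpha) sum(total * wts(alpha) * f) - mass
  root <- stats::uniroot(h, c(-200, 200), tol = 1e-13)
  n_real <- total * wts(root$root)
  n <- floor(n_real)
  deficit <- total - sum(n)
  if (deficit > 0) {
    idx <- order(n_real - n, decreasing = TRUE)[seq_len(deficit)]
    n[idx] <- n[idx] + 1
  }
  attr(n, "alpha") <- root$root
  n
}

# move single families between classes (count-preserving) until the
# expected-size error is within tol; each move changes the mass by
# f_to - f_from, so pick the available pair that best cancels the error
repair_counts <- function(n, f, mass, tol) {
  alpha <- attr(n, "alpha")
  for (step in seq_len(20 * length(n))) {
    err <- sum(n * f) - mass
    if (abs(err) <= tol) break
    cand <- which(n > 0)
    best <- NULL; best_gain <- 0
    for (from in cand) {
      gain <- abs(err) - abs(err + f[seq_along(f)] - f[from])
      j <- which.max(gain)
      if (gain[j] > best_gain) {
        best <- c(from, j); best_gain <- gain[j]
      }
    }
    if (is.null(best)) break
    n[best[1]] <- n[best[1]] - 1
    n[best[2]] <- n[best[2]] + 1
  }
  attr(n, "alpha") <- alpha
  n
}

new_distribution <- function(frequency, families, label, alpha = NA_real_) {
  stopifnot(all(diff(frequency) < 0) || length(frequency) == 1,
            all(frequency > 0), all(frequency <= 1),
            all(families >= 1))
  d <- data.frame(frequency = frequency, families = families)
  attr(d, "label") <- label
  attr(d, "alpha") <- alpha
  class(d) <- c("gene_distribution", "data.frame")
  d
}

#' @export
print.gene_distribution <- function(x, ...) {
  cat(sprintf("gene_distribution [%s]: pan %s, core %s, E[genome] %.1f, %d classes\n",
              attr(x, "label"),
              format(sum(x$families), big.mark = ","),
              format(sum(x$families[x$frequency == 1]), big.mark = ","),
              sum(x$families * x$frequency), nrow(x)))
  cat(sprintf("  true fluidity %.4f\n", true_fluidity(x)))
  invisible(x)
}

#' Companion distribution with identical observables but a different pan
#'
#' Derives, from a base distribution, a new population whose pan and core
#' sizes differ radically while every property observable from a modest
#' genome sample is preserved. Three mass-conserving moves accomplish this:
#' all but `C` core families are relaxed to frequency `1 - core_relax`
#' (still present in essentially every sampled genome); `trim_mass`
#' expected genes are removed from the base's rarest class; and the same
#' mass is redistributed over however many ultra-rare tail families are
#' needed to reach pan size `P`, at frequencies in `[tail_f_min,
#' tail_f_max]`. Because a family at frequency f is seen in an n-genome
#' sample with probability ~ n*f when f << 1/n, rearranging mass among such
#' families leaves the expected gene-frequency spectrum and pan/core
#' rarefaction curves unchanged to first order -- which is precisely why
#' pan and core sizes cannot be inferred from samples.
#'
#' @param base A `gene_distribution` (e.g. `species_distribution("speciesA")`).
#' @param P Target pan size, larger than the base's pan size.
#' @param C Target core size, at most the base's core size.
#' @param core_relax Frequency deficit for demoted core families.
#' @param trim_mass Expected genes moved from the base's rarest class into
#'   the tail.
#' @param tail_f_max,tail_f_min Frequency range of the tail classes (both
#'   far below the inverse of any realistic sample size).
#' @param tail_K Number of tail classes.
#' @return A `gene_distribution` with pan `P` and core `C` exactly.
#' @export
companion_distribution <- function(base, P, C,
                                   core_relax = 1e-5, trim_mass = 0.5,
                                   tail_f_max = 1e-5, tail_f_min = 1e-9,
                                   tail_K = 20) {
  stopifnot(inherits(base, "gene_distribution"))
  base_core <- sum(base$families[base$frequency == 1])
  if (C > base_core) stop("target core exceeds the base core", call. = FALSE)
  if (P <= sum(base$families)) stop("target pan must exceed the base pan", call. = FALSE)
  acc <- base[base$frequency < 1, , drop = FALSE]
  if (nrow(acc) == 0 || min(acc$frequency) <= tail_f_max) {
    stop("base accessory frequencies must all exceed tail_f_max", call. = FALSE)
  }
  rarest <- nrow(acc)
  trim_n <- round(trim_mass / acc$frequency[rarest])
  if (trim_n >= acc$families[rarest]) {
    stop("trim_mass exceeds the rarest base class", call. = FALSE)
  }
  acc$families[rarest] <- acc$families[rarest] - trim_n
  demoted <- base_core - C
  tail_total <- P - C - demoted - sum(acc$families)
  tail_f <- exp(seq(log(tail_f_max), log(tail_f_min), length.out = tail_K))
  tail_n <- power_law_counts(tail_total, trim_mass, tail_f)
  keep <- tail_n > 0
  head_f <- c(1, if (demoted > 0) 1 - core_relax)
  head_n <- c(C, if (demoted > 0) demoted)
  new_distribution(c(head_f, acc$frequency, tail_f[keep]),
                   c(head_n, acc$families, tail_n[keep]),
                   label = paste0(attr(base, "label"), "-companion"),
                   alpha = attr(base, "alpha"))
}

#' Built-in species distributions
#'
#' Three reference populations, all with an expected genome size of 2000
#' families:
#' \describe{
#'   \item{speciesA}{pan 1e5, core 1e3; power-law accessory classes over
#'     frequencies 1e-4..0.99 (40 classes). True fluidity ~0.31.}
#'   \item{speciesB}{pan 1e7, core 10; built with
#'     [companion_distribution()] from speciesA, so its observable gene
#'     distribution is indistinguishable from speciesA's at realistic
#'     sample sizes even though its pan genome is 100-fold larger and its
#'     rarest families occur in fewer than 1 in 1e7 genomes.}
#'   \item{speciesC}{pan 1e5, core 1e3 (same as A) but a different
#'     frequency shape (1e-3..0.99, 30 classes); true fluidity ~0.39,
#'     more than 5 points above speciesA's, so the two are separable by
#'     the fluidity z-test from ~10 genomes.}
#' }
#'
#' @param name `"speciesA"`, `"speciesB"` or `"speciesC"`.
#' @return A `gene_distribution`.
#' @examples
#' true_fluidity(species_distribution("speciesA"))
#' @export
species_distribution <- function(name = c("speciesA", "speciesB", "speciesC")) {
  name <- match.arg(name)
  switch(name,
    speciesA = build_distribution(
      species_template(1e5, 1e3, 2000, 1e-4, 0.99, K = 40, label = "speciesA")),
    speciesB = {
      d <- companion_distribution(species_distribution("speciesA"),
                                  P = 1e7, C = 10)
      attr(d, "label") <- "speciesB"
      d
    },
    speciesC = build_distribution(
      species_template(1e5, 1e3, 2000, 1e-3, 0.99, K = 30, label = "speciesC")))
}

#' Closed-form true fluidity of a gene-frequency distribution
#'
#' Under independent per-family inclusion (each family enters each genome
#' with its population frequency f), the expected number of families unique
#' to one genome of a random pair is `sum n f (1 - f)` and the expected
#' genome size is `sum n f`; the population's fluidity is their ratio:
#' \deqn{\varphi = \frac{\sum_j n_j f_j (1 - f_j)}{\sum_j n_j f_j}}
#' This is the value that sample estimates converge to, and the dashed
#' reference against which unbiasedness is checked.
#'
#' @param d A `gene_distribution`.
#' @return The true fluidity, in \[0, 1).
#' @export
true_fluidity <- function(d) {
  stopifnot(inherits(d, "gene_distribution"))
  sum(d$families * d$frequency * (1 - d$frequency)) /
    sum(d$families * d$frequency)
}

#' Sample genomes from a gene-frequency distribution
#'
#' Each family enters each genome independently with its class frequency.
#' Classes are sampled sparsely: per genome and class, a binomial count of
#' present families is drawn and that many distinct family indices are
#' chosen uniformly, so classes with millions of families are never
#' enumerated. Family identities (`class.index`) are consistent across
#' genomes. Each genome uses its own deterministic substream derived from
#' `seed`, so genome g is identical whether 10 or 1000 genomes are drawn.
#'
#' @param d A `gene_distribution`.
#' @param n Number of genomes to sample.
#' @param seed Integer seed (required for reproducibility; `NULL` uses the
#'   current RNG stream).
#' @param prefix Genome id prefix; ids are `prefix1..prefixn`.
#' @return A [genome_sets] object of `n` genomes with expected size
#'   `sum(d$families * d$frequency)`.
#' @export
sample_genomes <- function(d, n, seed = NULL, prefix = "g") {
  stopifnot(inherits(d, "gene_distribution"), n >= 1)
  substreams <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  nf <- d$families
  ff <- d$frequency
  class_tag <- sprintf("c%02d.", seq_len(nrow(d)))
  sets <- vector("list", n)
  for (g in seq_len(n)) {
    sets[[g]] <- with_seed(substreams[g], {
      ids <- vector("list", nrow(d))
      for (j in seq_len(nrow(d))) {
        x <- if (ff[j] == 1) nf[j] else stats::rbinom(1L, nf[j], ff[j])
        if (x > 0) {
          idx <- if (x == nf[j]) seq_len(nf[j]) else sample.int(nf[j], x)
          ids[[j]] <- paste0(class_tag[j], idx)
        }
      }
      unlist(ids, use.names = FALSE)
    })
  }
  names(sets) <- paste0(prefix, seq_len(n))
  genome_sets(sets)
}

#' Gene frequency spectrum of a genome group
#'
#' Counts `g_k`: the number of gene families observed in exactly k of the n
#' genomes, for k = 1..n. The spectrum sums to the observed pan size.
#'
#' @inheritParams fluidity
#' @return A named integer vector of length n (`names` are k = 1..n).
#' @examples
#' g <- genome_sets(list(A = c("g1", "g2", "g3", "g4"),
#'                       B = c("g1", "g2", "g3", "g5"),
#'                       C = c("g1", "g2", "g6", "g7")))
#' gene_frequency_spectrum(g)  # g1 = 4, g2 = 1, g3 = 2
#' @export
gene_frequency_spectrum <- function(sets) {
  sets <- as_genome_sets(sets)
  n <- length(sets)
  occ <- table(unlist(sets, use.names = FALSE))
  g <- tabulate(occ, nbins = n)
  stats::setNames(as.integer(g), seq_len(n))
}

#' Pan and core rarefaction curves
#'
#' For random orderings of the genomes, tracks the observed pan size (union
#' of the first m family sets) and observed core size (their intersection)
#' as m grows, and summarizes mean and standard deviation across orderings.
#' Within every ordering the pan curve is non-decreasing and the core curve
#' non-increasing.
#'
#' @inheritParams fluidity
#' @param orderings Number of random genome orderings (>= 1).
#' @param seed Optional integer seed.
#' @param permutations Optional list of explicit orderings (integer index
#'   vectors or genome-id vectors); overrides `orderings`/`seed`.
#' @return A data frame with columns `m`, `pan_mean`, `pan_sd`,
#'   `core_mean`, `core_sd`, `n_orderings`.
#' @export
rarefaction_curves <- function(sets, orderings = 10, seed = NULL,
                               permutations = NULL) {
  sets <- as_genome_sets(sets)
  n <- length(sets)
  if (is.null(permutations)) {
    if (orderings < 1) stop("`orderings` must be >= 1", call. = FALSE)
    permutations <- with_seed(seed, {
      lapply(seq_len(orderings), function(i) sample.int(n))
    })
  } else {
    permutations <- lapply(permutations, function(p) {
      if (is.character(p)) p <- match(p, names(sets))
      if (anyNA(p) || !setequal(p, seq_len(n))) {
        stop("each permutation must order all genomes exactly once",
             call. = FALSE)
      }
      p
    })
  }
  pan <- matrix(0, length(permutations), n)
  core <- matrix(0, length(permutations), n)
  for (r in seq_along(permutations)) {
    p <- permutations[[r]]
    u <- sets[[p[1]]]
    v <- u
    pan[r, 1] <- length(u)
    core[r, 1] <- length(v)
    for (m in seq_len(n)[-1]) {
      u <- union(u, sets[[p[m]]])
      v <- intersect(v, sets[[p[m]]])
      pan[r, m] <- length(u)
      core[r, m] <- length(v)
    }
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(m = seq_len(n),
             pan_mean = colMeans(pan),
             pan_sd = apply(pan, 2, sd0),
             core_mean = colMeans(core),
             core_sd = apply(core, 2, sd0),
             n_orderings = length(permutations))
}

#' Write a spectrum or rarefaction table as TSV
#'
#' @param x A spectrum vector from [gene_frequency_spectrum()] or a data
#'   frame from [rarefaction_curves()].
#' @param path Output path.
#' @param meta Optional named character vector of metadata header lines.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(x, path, meta = NULL) {
  if (!is.data.frame(x)) {
    x <- data.frame(k = as.integer(names(x)), families = as.integer(x))
  }
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, meta)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
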