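abc_group <- genome_sets(list(A = c("g1", "g2", "g3", "g4"),
                              B = c("g1", "g2", "g3", "g5"),
                              C = c("g1", "g2", "g6", "g7")))

test_that("built distributions honor pan, core and expected-size constraints", {
  t1 <- species_template(100, 10, 50, 0.05, 0.95, K = 8)
  d <- build_distribution(t1)
  expect_equal(sum(d$families), 100)
  expect_equal(sum(d$families[d$frequency == 1]), 10)
  expect_lt(abs(sum(d$families * d$frequency) - 50), 0.001 * 40 + 1e-9)
  expect_true(all(diff(d$frequency) < 0))
  expect_true(all(d$families >= 1))

  # degenerate: everything core
  dd <- build_distribution(species_template(50, 50, 50, 0.1, 0.9))
  expect_equal(nrow(dd), 1)
  expect_equal(dd$frequency, 1)
  expect_equal(dd$families, 50)

  expect_error(species_template(100, 10, 200, 0.05, 0.95), "C <= G <= P")
  # accessory mass outside the reachable range
  expect_error(build_distribution(species_template(100, 10, 99, 0.05, 0.5)),
               "infeasible")
})

test_that("closed-form true fluidity behaves algebraically", {
  core_only <- build_distribution(species_template(30, 30, 30, 0.1, 0.9))
  expect_identical(true_fluidity(core_only), 0)

  # a single frequency class at f cancels to 1 - f regardless of count
  half <- structure(data.frame(frequency = 0.5, families = 1000),
                    class = c("gene_distribution", "data.frame"))
  expect_equal(true_fluidity(half), 0.5)
  tenth <- structure(data.frame(frequency = 0.9, families = 123),
                     class = c("gene_distribution", "data.frame"))
  expect_equal(true_fluidity(tenth), 0.1, tolerance = 1e-12)
})

test_that("sampled genomes follow the distribution and are reproducible", {
  # all-core distribution: every genome is the full pan genome
  core_only <- build_distribution(species_template(25, 25, 25, 0.1, 0.9))
  s <- sample_genomes(core_only, 3, seed = 1)
  expect_true(all(lengths(s) == 25))
  expect_identical(sort(s[[1]]), sort(s[[3]]))

  # binomial mean: single class f = 0.5, 1000 families, 200 genomes
  half <- structure(data.frame(frequency = 0.5, families = 1000),
                    class = c("gene_distribution", "data.frame"))
  attr(half, "label") <- "half"
  sh <- sample_genomes(half, 200, seed = 2)
  expect_lt(abs(mean(lengths(sh)) - 500), 3 * sqrt(1000 * 0.25 / 200))

  # determinism and substream consistency: genome g is the same whether
  # drawn as part of 5 or of 10 genomes
  d <- build_distribution(species_template(500, 50, 100, 0.01, 0.9, K = 10))
  a <- sample_genomes(d, 5, seed = 42)
  b <- sample_genomes(d, 10, seed = 42)
  expect_identical(unclass(a)[1:5], unclass(b)[1:5])
  expect_identical(sample_genomes(d, 5, seed = 42), a)
})

test_that("sampled fluidity estimates agree with the closed form", {
  d <- build_distribution(species_template(2000, 100, 300, 0.01, 0.95, K = 15))
  phi_true <- true_fluidity(d)
  s <- sample_genomes(d, 25, seed = 9)
  est <- estimate_fluidity(s)
  expect_lt(abs(est$phi - phi_true), 3 * sqrt(est$variance))
})

test_that("gene frequency spectrum counts occupancy classes", {
  g <- gene_frequency_spectrum(abc_group)
  expect_equal(unname(g), c(4, 1, 2))
  expect_equal(sum(g), 7)  # observed pan size

  single <- genome_sets(list(A = letters[1:5]))
  expect_equal(unname(gene_frequency_spectrum(single)), 5)

  same <- genome_sets(list(a = letters[1:6], b = letters[1:6],
                           c = letters[1:6]))
  expect_equal(unname(gene_frequency_spectrum(same)), c(0, 0, 6))
})

test_that("rarefaction curves track prefix unions and intersections", {
  rc <- rarefaction_curves(abc_group, permutations = list(c("A", "B", "C")))
  expect_equal(rc$pan_mean, c(4, 5, 7))
  expect_equal(rc$core_mean, c(4, 3, 2))

  same <- genome_sets(list(a = letters[1:6], b = letters[1:6],
                           c = letters[1:6]))
  rs <- rarefaction_curves(same, orderings = 3, seed = 1)
  expect_true(all(rs$pan_mean == 6) && all(rs$core_mean == 6))

  # monotone within every ordering; conservation with the spectrum
  set.seed(15)
  sets <- random_sets(8, fams = 40, p = 0.4)
  for (r in 1:5) {
    perm <- sample(8)
    one <- rarefaction_curves(sets, permutations = list(perm))
    expect_true(all(diff(one$pan_mean) >= 0))
    expect_true(all(diff(one$core_mean) <= 0))
    expect_equal(one$pan_mean[8], sum(gene_frequency_spectrum(sets)))
  }

  r1 <- rarefaction_curves(sets, orderings = 4, seed = 77)
  expect_identical(r1, rarefaction_curves(sets, orderings = 4, seed = 77))
})

test_that("companion distribution hides a huge pan behind identical observables", {
  base <- build_distribution(
    species_template(5000, 100, 150, 1e-4, 0.95, K = 20, label = "base"))
  comp <- companion_distribution(base, P = 1e6, C = 5, trim_mass = 0.01)
  expect_equal(sum(comp$families), 1e6)
  expect_equal(sum(comp$families[comp$frequency == 1]), 5)
  # expected genome size preserved within 0.1%
  g_base <- sum(base$families * base$frequency)
  expect_lt(abs(sum(comp$families * comp$frequency) - g_base), 1e-3 * g_base)
  # expected singleton count in a 50-genome sample matches to < 1%
  eg1 <- function(d, n) sum(d$families * n * d$frequency * (1 - d$frequency)^(n - 1))
  expect_lt(abs(eg1(comp, 50) - eg1(base, 50)) / eg1(base, 50), 0.01)
  expect_true(all(diff(comp$frequency) < 0))
})

test_that("built-in species match their published sizes", {
  dA <- species_distribution("speciesA")
  expect_equal(sum(dA$families), 1e5)
  expect_equal(sum(dA$families[dA$frequency == 1]), 1e3)
  dC <- species_distribution("speciesC")
  expect_equal(sum(dC$families), 1e5)
  # A and C share pan/core but differ in true fluidity by >= 5 points
  expect_gte(abs(true_fluidity(dA) - true_fluidity(dC)), 0.05)
})

test_that("genome sets membership TSV round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genome_sets(abc_group, path, meta = c(seed = 1))
  back <- read_genome_sets(path)
  expect_equal(lapply(back, sort), lapply(abc_group, sort))

  # presence/absence matrix layout
  pa <- withr::local_tempfile(fileext = ".tsv")
  fams <- sort(unique(unlist(abc_group)))
  mat <- t(sapply(abc_group, function(s) as.integer(fams %in% s)))
  df <- data.frame(genome_id = names(abc_group), mat, check.names = FALSE)
  colnames(df) <- c("genome_id", fams)
  write.table(df, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_genome_sets(pa, format = "matrix")
  expect_equal(lapply(back2, sort), lapply(abc_group, sort))
})
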