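test_that("generation is fully deterministic given a seed", {
  sc <- sim_scenario()
  a <- sample_dataset(sc, seed = 3)
  b <- sample_dataset(sc, seed = 3)
  c_ <- sample_dataset(sc, seed = 4)
  expect_identical(as.data.frame(a$genotypes), as.data.frame(b$genotypes))
  expect_identical(a$haplotypes$counts, b$haplotypes$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(as.data.frame(a$genotypes), as.data.frame(c_$genotypes)))
})

test_that("frequencies are conserved and sum to one", {
  sc <- sim_scenario()
  mp <- withr::with_seed(5, generate_source_metapopulation(sc))
  sums <- unlist(lapply(mp$pops, function(p) vapply(p, sum, numeric(1))))
  expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-12)
  # sampled gene counts: 2 per non-missing genotype
  ds <- sample_dataset(sc, seed = 5)
  genes <- allele_counts(ds$genotypes) |>
    dplyr::count(pop, locus, wt = count, name = "genes")
  nonmiss <- ds$genotypes |>
    dplyr::filter(!is.na(allele_1)) |>
    dplyr::count(pop, locus)
  expect_equal(genes$genes, 2L * nonmiss$n)
})

test_that("vanishing divergence_F collapses populations onto the ancestral pool", {
  sc <- sim_scenario(divergence_F = 1e-4)
  mp <- withr::with_seed(8, generate_source_metapopulation(sc))
  dev <- max(unlist(purrr::map2(
    mp$pops[["SRC1"]], mp$ancestral, ~ max(abs(.x - .y)))))
  expect_lt(dev, 0.05)
})

test_that("Balding-Nichols divergence reproduces its nominal FST", {
  # pairwise Weir-Cockerham theta between populations drifted at F
  # should average about F
  withr::local_seed(99)
  F <- 0.1
  sc <- sim_scenario(n_source_pops = 16, divergence_F = F,
                     sample_sizes = rep(100, 16), true_source = "SRC1")
  mp <- generate_source_metapopulation(sc)
  rows <- list()
  for (p in names(mp$pops)) {
    for (l in mp$loci) {
      fr <- mp$pops[[p]][[l]]
      g <- matrix(sample(as.integer(names(fr)), 200, TRUE, prob = fr), ncol = 2)
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, ind = sprintf("%s_%d", p, 1:100), locus = l,
        allele_1 = g[, 1], allele_2 = g[, 2])
    }
  }
  fm <- fst_matrix(genotype_table(do.call(rbind, rows)))
  expect_equal(mean(fm[lower.tri(fm)]), F, tolerance = 0.25)
})

test_that("a zero-drift introduction returns the founder gene pool exactly", {
  sc <- sim_scenario(true_N0 = 5, t = 0)
  mp <- withr::with_seed(2, generate_source_metapopulation(sc))
  intro <- withr::with_seed(3, simulate_introduction(mp$pops[["SRC9"]], sc))
  expect_identical(intro$freqs, intro$founder_freqs)
  multiples <- unlist(intro$freqs) * 10  # 2 * N0 = 10 gene copies
  expect_equal(multiples, round(multiples), tolerance = 1e-12)
})

test_that("alleles absent from the source never appear after founding", {
  sc <- sim_scenario()
  mp <- withr::with_seed(4, generate_source_metapopulation(sc))
  src <- mp$pops[[sc$true_source]]
  intro <- withr::with_seed(5, simulate_introduction(src, sc))
  for (l in names(src)) {
    expect_true(all(names(which(intro$freqs[[l]] > 0)) %in%
                      names(which(src[[l]] > 0))))
  }
})

test_that("founder-pool allele frequencies have binomial sampling variance", {
  # 2 N0 = 20 gene copies: var of a founder-pool frequency = p(1-p)/20
  withr::local_seed(17)
  p <- c(0.3, 0.7)
  draws <- stats::rmultinom(2000, 20, p)[1, ] / 20
  expect_equal(var(draws), 0.3 * 0.7 / 20, tolerance = 0.1)
  # and the package's founder step reproduces it
  sc <- sim_scenario(true_N0 = 10, t = 0)
  f1 <- replicate(2000, {
    simulate_introduction(list(L1 = c(`100` = 0.3, `102` = 0.7)), sc)$freqs[[1]][1]
  })
  expect_equal(var(f1), 0.3 * 0.7 / 20, tolerance = 0.1)
})

test_that("sampled allele frequencies converge to generating frequencies", {
  sc <- sim_scenario(n_source_pops = 2, n_loci = 2,
                     sample_sizes = c(10000, 10), true_source = "SRC1",
                     mito_sample_sizes = c(10, 10), missing_rate = 0)
  ds <- sample_dataset(sc, seed = 31)
  mp <- withr::with_seed(31, generate_source_metapopulation(sc))
  counts <- allele_counts(ds$genotypes)
  for (l in mp$loci) {
    fr <- mp$pops[["SRC1"]][[l]]
    obs <- counts[counts$pop == "SRC1" & counts$locus == l, ]
    est <- setNames(rep(0, length(fr)), names(fr))
    est[as.character(obs$allele)] <- obs$count / sum(obs$count)
    expect_lt(max(abs(est - fr)), 0.02)
  }
})

test_that("a population fixed for one allele yields only homozygotes", {
  sc <- sim_scenario(n_source_pops = 2, n_loci = 1, allele_range = c(6, 6),
                     sample_sizes = c(20, 20), true_source = "SRC1",
                     missing_rate = 0)
  mp <- withr::with_seed(1, generate_source_metapopulation(sc))
  mp$pops[["SRC1"]][[1]][] <- c(1, rep(0, length(mp$pops[["SRC1"]][[1]]) - 1))
  intro <- withr::with_seed(2, simulate_introduction(mp$pops[["SRC1"]], sc))
  expect_equal(unname(intro$freqs[[1]][1]), 1)
})

test_that("default scenario mirrors the intended study design", {
  sc <- sim_scenario()
  ds <- sample_dataset(sc, seed = 1)
  expect_equal(nlevels(ds$genotypes$locus), 7)
  expect_equal(ds$haplotypes$L, 759)
  expect_equal(nlevels(ds$genotypes$pop), 10)
  expect_equal(range(table(unique(ds$genotypes[c("pop", "ind")])$pop)),
               c(15, 124))
  f <- withr::local_tempdir()
  ds2 <- sample_dataset(sc, outdir = f, seed = 1)
  expect_true(all(file.exists(unlist(ds2$files))))
  truth <- jsonlite::read_json(ds2$files$truth, simplifyVector = TRUE)
  expect_equal(truth$true_N0, 10)
  expect_equal(truth$true_source, "SRC9")
  fa <- Biostrings::readDNAStringSet(ds2$files$fasta)
  expect_true(all(Biostrings::width(fa) == 759))
})

test_that("stronger bottlenecks leave less allelic richness", {
  richness <- vapply(c(2, 10, 50), function(N0) {
    mean(vapply(1:4, function(i) {
      ds <- sample_dataset(sim_scenario(true_N0 = N0), seed = 1000 * N0 + i)
      nd <- nuclear_diversity(ds$genotypes, g = 26)
      nd$A_R[nd$pop == "INTRO"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(richness[1] < richness[2])
  expect_true(richness[2] <= richness[3] + 0.2)  # small-sample wiggle allowed
})
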