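test_that("rarefied richness matches closed forms", {
  expect_equal(rarefied_allelic_richness(c(14), 14), 1.0)
  expect_equal(rarefied_allelic_richness(c(14), 5), 1.0)
  expect_equal(rarefied_allelic_richness(c(10, 3, 1), 14), 3.0)
  expect_equal(rarefied_allelic_richness(c(10, 3, 1), 2), 134 / 91,
               tolerance = 1e-12)
  expect_error(rarefied_allelic_richness(c(3, 2), 6), "exceeds")
})

test_that("rarefied richness equals exhaustive enumeration and is monotone in g", {
  withr::local_seed(42)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    counts <- as.vector(stats::rmultinom(1, sample(6:12, 1), rep(1 / k, k)))
    counts <- counts[counts > 0]
    N <- sum(counts)
    vals <- vapply(seq_len(N), function(g) rarefied_allelic_richness(counts, g),
                   numeric(1))
    g <- sample(seq_len(N), 1)
    expect_equal(vals[g], enum_rarefaction(counts, g), tolerance = 1e-12)
    expect_true(all(diff(vals) >= -1e-12))
    expect_equal(vals[N], length(counts))
  }
})

test_that("private allelic richness matches hand-computed hypergeometrics", {
  # focal {A:3, B:1}, other pop {A:4}, g = 2:
  # P(B in focal subsample) = 1 - C(3,2)/C(4,2) = 0.5; A is always elsewhere
  tbl <- data.frame(pop = c("F", "F", "O"), allele = c("A", "B", "A"),
                    count = c(3, 1, 4))
  expect_equal(private_allelic_richness(tbl, "F", 2), 0.5)
  # allele fixed in focal and absent elsewhere contributes exactly 1
  tbl2 <- data.frame(pop = c("F", "O"), allele = c("A", "B"), count = c(4, 4))
  expect_equal(private_allelic_richness(tbl2, "F", 2), 1)
  # allele fixed in another population contributes 0
  expect_equal(private_allelic_richness(tbl2, "O", 2), 1)  # B private to O
  tbl3 <- data.frame(pop = c("F", "O"), allele = c("A", "A"), count = c(4, 4))
  expect_equal(private_allelic_richness(tbl3, "F", 2), 0)
})

test_that("heterozygosity statistics match Nei's unbiased closed forms", {
  # monomorphic locus
  mono <- geno_from_mats(list(P = list(L1 = cbind(rep(1, 5), rep(1, 5)))))
  hs <- heterozygosity_stats(mono, "P")
  expect_equal(hs$Ho, 0)
  expect_equal(hs$He, 0)
  # five individuals all heterozygous A/B
  het <- geno_from_mats(list(P = list(L1 = cbind(rep(1, 5), rep(2, 5)))))
  hs <- heterozygosity_stats(het, "P")
  expect_equal(hs$Ho, 1)
  expect_equal(hs$He, (10 / 9) * 0.5, tolerance = 1e-12)
  # four individuals, allele counts A:7 B:1, one heterozygote
  m <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 2))
  hs <- heterozygosity_stats(geno_from_mats(list(P = list(L1 = m))), "P")
  expect_equal(hs$Ho, 0.25)
  expect_equal(hs$He, (8 / 7) * (1 - (49 + 1) / 64), tolerance = 1e-12)
  expect_equal(hs$He, 0.25, tolerance = 1e-12)
})

test_that("expected heterozygosity is invariant under allele relabeling", {
  withr::local_seed(7)
  m <- matrix(sample.int(4, 24, TRUE), ncol = 2)
  relab <- c(7, 2, 9, 4)[m]
  dim(relab) <- dim(m)
  a <- heterozygosity_stats(geno_from_mats(list(P = list(L1 = m))), "P")
  b <- heterozygosity_stats(geno_from_mats(list(P = list(L1 = relab))), "P")
  expect_equal(a$He, b$He)
  expect_equal(a$Ho, b$Ho)
  expect_true(a$He >= 0 && a$He < 1)
})

test_that("nuclear_diversity returns a coherent per-population table", {
  ds <- sample_dataset(sim_scenario(), seed = 13)
  nd <- nuclear_diversity(ds$genotypes, g = 26)
  expect_equal(nrow(nd), 10)
  expect_true(all(nd$P >= 0 & nd$P <= 1))
  expect_true(all(nd$Ho >= 0 & nd$Ho <= 1))
  expect_true(all(nd$He >= 0 & nd$He < 1))
  expect_true(all(nd$A_R <= nd$A + 1e-9))
  expect_true(all(nd$A_R >= 1))
  expect_true(all(nd$A_p >= 0))
  # the bottlenecked population has the lowest rarefied richness on average
  expect_lt(nd$A_R[nd$pop == "INTRO"], max(nd$A_R))
})

test_that("mitochondrial diversity matches closed forms", {
  seqs <- c(h1 = "AAAA", h2 = "AATA", h3 = "TTTA")
  hs1 <- haplotype_set(seqs, data.frame(pop = "P", haplotype = "h1", count = 5))
  d <- mito_diversity(hs1, "P")
  expect_equal(d$h, 0)
  expect_equal(d$pi, 0)
  # counts [12, 3]: h = (15/14)(1 - 0.8^2 - 0.2^2)
  hs2 <- haplotype_set(seqs, data.frame(pop = "P", haplotype = c("h1", "h2"),
                                        count = c(12, 3)))
  d2 <- mito_diversity(hs2, "P")
  expect_equal(d2$h, (15 / 14) * (1 - 0.64 - 0.04), tolerance = 1e-12)
  expect_equal(d2$n_H, 2)
  # two singleton sequences at distance d over length L: pi = d / L
  long1 <- paste(rep("A", 759), collapse = "")
  long2 <- paste(c(rep("A", 754), rep("T", 5)), collapse = "")
  hs3 <- haplotype_set(c(a = long1, b = long2),
                       data.frame(pop = "P", haplotype = c("a", "b"),
                                  count = c(1, 1)))
  d3 <- mito_diversity(hs3, "P")
  expect_equal(d3$pi, 5 / 759, tolerance = 1e-12)
  expect_error(mito_diversity(hs1, "missing_pop"))
})

test_that("private haplotypes are counted against all other populations", {
  seqs <- c(h1 = "AAAA", h2 = "AATA", h3 = "TTTA")
  hs <- haplotype_set(seqs, data.frame(
    pop = c("P1", "P1", "P2"), haplotype = c("h1", "h2", "h1"),
    count = c(3, 2, 4)))
  tab <- mito_diversity_table(hs)
  expect_equal(tab$n_pH[tab$pop == "P1"], 1)  # h2 only
  expect_equal(tab$n_pH[tab$pop == "P2"], 0)
})

test_that("between-population differences equal the brute-force pair average", {
  seqs <- c(h1 = "AAAAA", h2 = "AATAA", h3 = "TTTAA", h4 = "TTTTT")
  counts <- data.frame(
    pop = c("A", "A", "B", "B"),
    haplotype = c("h1", "h2", "h2", "h4"),
    count = c(3, 2, 1, 4))
  hs <- haplotype_set(seqs, counts)
  # enumerate every cross-population sequence pair
  a_list <- rep(c("h1", "h2"), c(3, 2))
  b_list <- rep(c("h2", "h4"), c(1, 4))
  brute <- mean(outer(a_list, b_list,
                      Vectorize(function(x, y) hs$diff[x, y])))
  expect_equal(between_population_differences(hs, "A", "B"), brute,
               tolerance = 1e-12)
  # single fixed haplotypes at distance 7 -> exactly 7
  s2 <- c(x = "AAAAAAA", y = "TTTTTTT")
  hs2 <- haplotype_set(s2, data.frame(pop = c("A", "B"),
                                      haplotype = c("x", "y"),
                                      count = c(6, 9)))
  expect_equal(between_population_differences(hs2, "A", "B"), 7)
  # identical distributions of one shared haplotype -> 0
  hs3 <- haplotype_set(s2, data.frame(pop = c("A", "B"),
                                      haplotype = c("x", "x"),
                                      count = c(5, 5)))
  expect_equal(between_population_differences(hs3, "A", "B"), 0)
})

test_that("self-comparison equals the uncorrected within-population mean", {
  seqs <- c(h1 = "AAAAA", h2 = "AATAA", h3 = "TTTAA")
  hs <- haplotype_set(seqs, data.frame(pop = "P",
                                       haplotype = c("h1", "h2", "h3"),
                                       count = c(2, 3, 5)))
  p <- c(2, 3, 5) / 10
  manual <- sum(outer(p, p) * hs$diff[c("h1", "h2", "h3"), c("h1", "h2", "h3")])
  expect_equal(between_population_differences(hs, "P", "P"), manual)
})
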