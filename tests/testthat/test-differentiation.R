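test_that("theta is 1 for fixed differences and matches the direct transcription", {
  fixed <- geno_from_mats(list(
    A = list(L1 = cbind(rep(1, 8), rep(1, 8))),
    B = list(L1 = cbind(rep(2, 8), rep(2, 8)))))
  expect_equal(pairwise_fst(fixed, "A", "B"), 1)

  withr::local_seed(11)
  for (i in 1:8) {
    mats <- random_toy_geno()
    geno <- geno_from_mats(mats)
    loci <- lapply(names(mats$A), function(l) list(mats$A[[l]], mats$B[[l]]))
    oracle <- wc_theta_direct(loci)
    if (is.nan(oracle)) next
    expect_equal(pairwise_fst(geno, "A", "B"), oracle, tolerance = 1e-10)
  }
})

test_that("theta is invariant to population order and allele relabeling", {
  withr::local_seed(3)
  mats <- random_toy_geno(n_loci = 3)
  geno <- geno_from_mats(mats)
  th <- pairwise_fst(geno, "A", "B")
  expect_equal(pairwise_fst(geno, "B", "A"), th)
  relab <- geno
  relab$allele_1 <- c(11L, 5L, 8L, 2L)[relab$allele_1]
  relab$allele_2 <- c(11L, 5L, 8L, 2L)[relab$allele_2]
  expect_equal(pairwise_fst(genotype_table(relab), "A", "B"), th)
})

test_that("theta is near zero for samples from one panmictic population", {
  withr::local_seed(23)
  n <- 500
  rows <- list()
  for (l in 1:5) {
    p <- stats::rgamma(6, 1)
    p <- p / sum(p)
    for (pop in c("A", "B")) {
      g <- matrix(sample.int(6, 2 * n, TRUE, prob = p), ncol = 2)
      rows[[length(rows) + 1]] <- data.frame(
        pop = pop, ind = sprintf("%s_%d", pop, 1:n), locus = paste0("L", l),
        allele_1 = g[, 1], allele_2 = g[, 2])
    }
  }
  th <- pairwise_fst(genotype_table(do.call(rbind, rows)), "A", "B")
  expect_lt(abs(th), 0.01)
})

test_that("theta is undefined (NA, flagged) without a usable locus", {
  mono <- geno_from_mats(list(
    A = list(L1 = cbind(rep(1, 5), rep(1, 5))),
    B = list(L1 = cbind(rep(1, 6), rep(1, 6)))))
  expect_warning(th <- pairwise_fst(mono, "A", "B"), "undefined")
  expect_true(is.na(th))
})

test_that("permutation test behaves at the null and at fixation", {
  fixed <- geno_from_mats(list(
    A = list(L1 = cbind(rep(1, 10), rep(1, 10))),
    B = list(L1 = cbind(rep(2, 10), rep(2, 10)))))
  res <- fst_permutation_test(fixed, "A", "B", reps = 999, seed = 2)
  expect_equal(res$p_value, 1 / 1000)
  # identical populations: p never 0, and not extreme
  withr::local_seed(5)
  m <- matrix(sample.int(3, 24, TRUE), ncol = 2)
  same <- geno_from_mats(list(A = list(L1 = m), B = list(L1 = m)))
  res2 <- fst_permutation_test(same, "A", "B", reps = 199, seed = 3)
  expect_gt(res2$p_value, 0.05)
  # determinism under seed
  expect_identical(
    fst_permutation_test(fixed, "A", "B", reps = 199, seed = 7),
    fst_permutation_test(fixed, "A", "B", reps = 199, seed = 7))
  expect_error(fst_permutation_test(fixed, "A", "B", reps = 10), "100")
})

test_that("chord distances follow the squared-chord closed forms", {
  # single locus, disjoint fixation -> 1
  disj <- geno_from_mats(list(
    A = list(L1 = cbind(rep(1, 6), rep(1, 6))),
    B = list(L1 = cbind(rep(2, 6), rep(2, 6)))))
  d <- chord_distance_matrix(disj)
  expect_equal(unname(d["A", "B"]), 1)
  # identical frequency vectors -> 0
  m <- rbind(c(1, 2), c(1, 2), c(1, 1), c(2, 2))
  same <- geno_from_mats(list(A = list(L1 = m), B = list(L1 = m)))
  expect_equal(unname(chord_distance_matrix(same)["A", "B"]), 0)
  expect_true(isSymmetric(unclass(chord_distance_matrix(same))))
})

test_that("NJ recovers the 4-taxon additive example with exact branch lengths", {
  d <- matrix(c(0, 2, 4, 5,
                2, 0, 4, 5,
                4, 4, 0, 5,
                5, 5, 5, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # split AB|CD present; pendant edges A=1, B=1, C=2, D=3, internal 1
  tip_edge <- function(tree, tip) {
    tree$edge.length[tree$edge[, 2] == match(tip, tree$tip.label)]
  }
  expect_equal(tip_edge(tr, "A"), 1)
  expect_equal(tip_edge(tr, "B"), 1)
  expect_equal(tip_edge(tr, "C"), 2)
  expect_equal(tip_edge(tr, "D"), 3)
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_equal(internal, 1)
})

test_that("three taxa give the unique unrooted topology", {
  d <- matrix(c(0, 3, 9, 3, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 1)
})

test_that("bootstrap support is 100% when every locus carries the same signal", {
  # four populations, strongly structured, identical at all loci
  base <- list(P1 = 1, P2 = 1, P3 = 2, P4 = 2)
  mats <- lapply(base, function(al) {
    m <- cbind(rep(al, 12), rep(al, 12))
    # one private second allele per group keeps loci polymorphic
    stats::setNames(lapply(1:5, function(l) m), paste0("L", 1:5))
  })
  # make groups distinguishable: P1/P2 fixed for 1, with P2 carrying a
  # shared variant; P3/P4 fixed for 2 with P4 carrying a variant
  mats$P2 <- lapply(mats$P2, function(m) { m[1, ] <- c(1, 3); m })
  mats$P4 <- lapply(mats$P4, function(m) { m[1, ] <- c(2, 4); m })
  geno <- geno_from_mats(mats)
  tr <- neighbor_joining_tree(geno, reps = 100, seed = 9)
  supports <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(supports == 100))
  # reproducible under the same seed
  tr2 <- neighbor_joining_tree(geno, reps = 100, seed = 9)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("NJ reproduces random additive trees (topology and lengths)", {
  withr::local_seed(31)
  for (i in 1:10) {
    nt <- sample(4:8, 1)
    tr0 <- ape::rtree(nt, rooted = FALSE,
                      br = function(n) stats::runif(n, 0.1, 2))
    d <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("assign_source ranks a zero-distance source first and reports ties", {
  withr::local_seed(8)
  m <- matrix(sample.int(4, 40, TRUE), ncol = 2)
  m2 <- matrix(sample.int(4, 40, TRUE), ncol = 2)
  geno <- geno_from_mats(list(S1 = list(L1 = m), S2 = list(L1 = m2),
                              INTRO = list(L1 = m)))
  fm <- fst_matrix(geno)
  rank_ <- assign_source(fm, "INTRO")
  expect_equal(rank_$source[1], "S1")
  # theta between two copies of the same sample is ~0; the unbiased
  # estimator may go slightly negative, never appreciably positive
  expect_lt(rank_$fst[1], 0.01)
  expect_gt(rank_$fst[1], -0.1)
  # exact ties share a rank
  geno2 <- geno_from_mats(list(S1 = list(L1 = m2), S2 = list(L1 = m2),
                               INTRO = list(L1 = m)))
  rank2 <- assign_source(fst_matrix(geno2), "INTRO")
  expect_equal(rank2$rank, c(1L, 1L))
})

test_that("true source ranks first in a default synthetic dataset", {
  ds <- sample_dataset(sim_scenario(), seed = 77)
  fm <- fst_matrix(ds$genotypes)
  rk <- assign_source(fm, "INTRO", mito_diff_matrix(ds$haplotypes))
  expect_equal(rk$source[1], ds$truth$true_source)
})
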