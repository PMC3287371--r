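# Independent oracles used to cross-check the package implementations.
# These deliberately use brute force / scalar arithmetic, never the
# package's own code paths.

# exhaustive rarefaction: average distinct alleles over all C(N, g)
# gene-copy subsamples
enum_rarefaction <- function(counts, g) {
  pool <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(pool), g)
  mean(apply(subs, 2, function(ix) length(unique(pool[ix]))))
}

# direct scalar transcription of the Weir & Cockerham (1984) variance
# components for one locus; pop_list = list of (n_i x 2) allele matrices
wc_components_direct <- function(pop_list) {
  r <- length(pop_list)
  n_i <- vapply(pop_list, nrow, integer(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(unlist(pop_list)))
  tot <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    p_i <- numeric(r)
    h_i <- numeric(r)
    for (i in seq_len(r)) {
      m <- pop_list[[i]]
      p_i[i] <- sum(m == al) / (2 * n_i[i])
      h_i[i] <- sum(m[, 1] != m[, 2] & (m[, 1] == al | m[, 2] == al)) / n_i[i]
    }
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    tot <- tot + c(a, b, hbar / 2)
  }
  tot
}

# multi-locus theta from the direct transcription: ratio of summed
# components over polymorphic loci
wc_theta_direct <- function(loci) {
  num <- 0
  den <- 0
  for (pop_list in loci) {
    if (length(unique(unlist(pop_list))) < 2) next
    comp <- wc_components_direct(pop_list)
    num <- num + comp[["a"]]
    den <- den + sum(comp)
  }
  num / den
}

# exhaustive P(exactly k distinct among N iid draws) for tiny cases
enum_distinct_pmf <- function(p, N, k) {
  grid <- as.matrix(expand.grid(rep(list(seq_along(p)), N)))
  probs <- apply(grid, 1, function(x) prod(p[x]))
  distinct <- apply(grid, 1, function(x) length(unique(x)))
  sum(probs[distinct == k])
}

# build a genotype tibble from a named list (pop) of named lists (locus)
# of (n x 2) allele matrices
geno_from_mats <- function(pop_mats) {
  rows <- list()
  for (p in names(pop_mats)) {
    loci <- pop_mats[[p]]
    n <- nrow(loci[[1]])
    ids <- sprintf("%s_%d", p, seq_len(n))
    for (l in names(loci)) {
      m <- loci[[l]]
      rows[[length(rows) + 1]] <- data.frame(
        pop = p, ind = ids, locus = l,
        allele_1 = m[, 1], allele_2 = m[, 2])
    }
  }
  genotype_table(do.call(rbind, rows))
}

# random two-population toy dataset for the FST dual-implementation check
random_toy_geno <- function(n_loci = 2, max_alleles = 4) {
  n <- c(A = sample(5:12, 1), B = sample(5:12, 1))
  mats <- list(A = list(), B = list())
  for (l in seq_len(n_loci)) {
    k <- sample(2:max_alleles, 1)
    for (p in c("A", "B")) {
      mats[[p]][[paste0("L", l)]] <-
        matrix(sample.int(k, 2 * n[[p]], replace = TRUE), ncol = 2)
    }
  }
  mats
}
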