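# ---- internal: fast per-locus genotype layout -------------------------------

# Align two (or more) populations' genotypes on a common individual index.
# Returns list(pop_idx, loci = list(locus -> list(a1, a2))) where a1/a2 are
# integer allele labels (NA = missing) of length n individuals.
geno_locus_data <- function(geno, pops) {
  sub <- geno[as.character(geno$pop) %in% pops, ]
  inds <- unique(sub$ind)
  pop_of <- sub$pop[match(inds, sub$ind)]
  pop_idx <- match(as.character(pop_of), pops)
  loci <- levels(geno$locus)
  per_locus <- lapply(loci, function(l) {
    sl <- sub[sub$locus == l, ]
    i <- match(sl$ind, inds)
    a1 <- rep(NA_integer_, length(inds))
    a2 <- rep(NA_integer_, length(inds))
    a1[i] <- sl$allele_1
    a2[i] <- sl$allele_2
    list(a1 = a1, a2 = a2)
  })
  names(per_locus) <- loci
  list(pop_idx = pop_idx, loci = per_locus, n = length(inds))
}

# Weir & Cockerham (1984) variance components for one locus, summed over
# alleles.  Returns c(a, b, c) and attr "usable" = FALSE when the locus is
# monomorphic across the populations or a population has no data.
wc_components_locus <- function(a1, a2, pop_idx, r) {
  keep <- !is.na(a1) & !is.na(pop_idx)
  a1 <- a1[keep]; a2 <- a2[keep]; pop_idx <- pop_idx[keep]
  out <- c(a = 0, b = 0, c = 0)
  n_i <- tabulate(pop_idx, nbins = r)
  if (any(n_i < 2)) return(structure(out, usable = FALSE))
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(structure(out, usable = FALSE))

  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pf <- factor(pop_idx, levels = seq_len(r))
  f1 <- factor(a1, levels = alleles)
  f2 <- factor(a2, levels = alleles)
  cnt <- table(pf, f1) + table(pf, f2)       # pop x allele gene counts
  p <- sweep(unclass(cnt), 1, 2 * n_i, "/")
  het <- a1 != a2
  hcnt <- table(pf[het], f1[het]) + table(pf[het], f2[het])
  h <- sweep(unclass(hcnt), 1, n_i, "/")     # freq of heterozygotes carrying a

  for (k in seq_along(alleles)) {
    pbar <- sum(n_i * p[, k]) / (r * nbar)
    s2 <- sum(n_i * (p[, k] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h[, k]) / (r * nbar)
    a_c <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_c <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_c <- hbar / 2
    out <- out + c(a_c, b_c, c_c)
  }
  structure(out, usable = TRUE)
}

theta_from_locus_data <- function(ld, pop_idx, r = 2) {
  comps <- vapply(ld$loci, function(l) {
    x <- wc_components_locus(l$a1, l$a2, pop_idx, r)
    c(x, usable = as.numeric(attr(x, "usable")))
  }, numeric(4))
  usable <- comps["usable", ] > 0
  if (!any(usable)) return(NA_real_)
  num <- sum(comps["a", usable])
  den <- sum(comps["a", usable] + comps["b", usable] + comps["c", usable])
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise Weir-Cockerham FST between two populations
#'
#' Multi-locus theta of Weir & Cockerham (1984): per-locus, per-allele
#' variance components are summed over alleles and loci and combined as
#' the ratio of summed components, \eqn{\hat\theta = \sum a / \sum (a + b
#' + c)} (the FSTAT convention).  Loci monomorphic across the two
#' populations carry no information and are excluded.
#'
#' @param geno A genotype tibble (see [genotype_table()]).
#' @param popA,popB Population ids.
#' @return The multi-locus theta, or `NA` (with a warning) when no locus
#'   is usable.
#' @export
pairwise_fst <- function(geno, popA, popB) {
  geno <- genotype_table(geno)
  pops <- c(popA, popB)
  if (!all(pops %in% levels(geno$pop))) abort("unknown population id")
  ld <- geno_locus_data(geno, pops)
  th <- theta_from_locus_data(ld, ld$pop_idx)
  if (is.na(th)) {
    warn(paste0("pairwise_fst: no usable polymorphic locus for ",
                popA, " vs ", popB, "; theta undefined"))
  }
  th
}

#' All-pairs FST matrix
#'
#' @param geno A genotype tibble.
#' @return Symmetric matrix of pairwise theta (class `dist_matrix`, kind
#'   `fst`), zero diagonal, `NA` where undefined.
#' @export
fst_matrix <- function(geno) {
  geno <- genotype_table(geno)
  pops <- levels(geno$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      ld <- geno_locus_data(geno, c(pops[i], pops[j]))
      m[i, j] <- m[j, i] <- theta_from_locus_data(ld, ld$pop_idx)
    }
  }
  structure(m, class = c("dist_matrix", "matrix"), kind = "fst")
}

#' Permutation test of pairwise FST
#'
#' Permutes whole multilocus genotypes (individuals) between the two
#' populations, recomputing theta each replicate.  The p-value uses the
#' add-one convention `p = (1 + #{theta_perm >= theta_obs}) / (reps + 1)`,
#' so it is never exactly zero.
#'
#' @param geno A genotype tibble.
#' @param popA,popB Population ids.
#' @param reps Number of permutations (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with `theta`, `p_value`, `reps`.
#' @export
fst_permutation_test <- function(geno, popA, popB, reps = 999, seed = NULL) {
  if (reps < 100) abort("use at least 100 permutations")
  geno <- genotype_table(geno)
  ld <- geno_locus_data(geno, c(popA, popB))
  obs <- theta_from_locus_data(ld, ld$pop_idx)
  if (is.na(obs)) abort("theta undefined for this pair; nothing to test")
  n1 <- sum(ld$pop_idx == 1)
  hits <- maybe_with_seed(seed, {
    sum(vapply(seq_len(reps), function(i) {
      idx <- rep(2L, ld$n)
      idx[sample.int(ld$n, n1)] <- 1L
      th <- theta_from_locus_data(ld, idx)
      !is.na(th) && th >= obs
    }, logical(1)))
  })
  tibble(theta = obs, p_value = (1 + hits) / (reps + 1), reps = reps)
}

# ---- chord distances and trees ----------------------------------------------

# per-locus squared-chord distances: array [locus, pop, pop];
# NA where a population has no genes at the locus
chord_by_locus <- function(geno) {
  counts <- allele_counts(geno)
  pops <- levels(geno$pop)
  loci <- levels(geno$locus)
  arr <- array(NA_real_, c(length(loci), length(pops), length(pops)),
               dimnames = list(loci, pops, pops))
  for (l in loci) {
    sub <- counts[counts$locus == l, ]
    alleles <- sort(unique(sub$allele))
    fr <- matrix(0, length(pops), length(alleles),
                 dimnames = list(pops, as.character(alleles)))
    tot <- setNames(rep(0, length(pops)), pops)
    for (p in pops) {
      s <- sub[sub$pop == p, ]
      tot[p] <- sum(s$count)
      if (tot[p] > 0) fr[p, match(s$allele, alleles)] <- s$count / tot[p]
    }
    sq <- sqrt(fr)
    d <- 1 - tcrossprod(sq)
    d[tot == 0, ] <- NA
    d[, tot == 0] <- NA
    diag(d) <- ifelse(tot > 0, 0, NA)
    arr[l, , ] <- d
  }
  arr
}

#' Cavalli-Sforza chord distance matrix
#'
#' Per-locus squared-chord distance \eqn{d_\ell = 1 - \sum_a \sqrt{x_a
#' y_a}} between allele-frequency vectors, averaged over loci.  Any
#' positive scaling of this distance leaves neighbor-joining topology
#' unchanged; the constant is fixed at 1.  Loci where a population has no
#' genes are dropped for the affected pairs (noted on the message
#' stream).
#'
#' @param geno A genotype tibble.
#' @return Symmetric matrix (class `dist_matrix`, kind `chord`).
#' @export
chord_distance_matrix <- function(geno) {
  geno <- genotype_table(geno)
  arr <- chord_by_locus(geno)
  if (anyNA(arr)) {
    ff_note("chord_distance_matrix: some population x locus cells have no ",
            "data; affected loci dropped pairwise")
  }
  m <- apply(arr, c(2, 3), mean, na.rm = TRUE)
  structure(m, class = c("dist_matrix", "matrix"), kind = "chord")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); any negative branch
#' length is clamped to zero with a note.  Exact on additive matrices.
#'
#' @param d Symmetric distance matrix with labelled rows/columns.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    ff_note("nj_tree: ", sum(tr$edge.length < 0),
            " negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Neighbor-joining population tree with locus bootstrap
#'
#' Builds the NJ tree on the chord distance matrix, then bootstraps loci
#' (resampling loci with replacement, recomputing distances and the tree)
#' and reports, for each internal branch of the point-estimate tree, the
#' percentage of pseudoreplicates containing the same bipartition.  With
#' few loci the attainable support values are coarse.
#'
#' @param geno A genotype tibble (>= 4 populations for internal branches).
#' @param reps Bootstrap pseudoreplicates (default 1000).
#' @param seed Optional integer seed.
#' @return A `phylo` tree whose `node.label` holds bootstrap percentages
#'   (root label `NA`), with attribute `reps`.
#' @export
neighbor_joining_tree <- function(geno, reps = 1000, seed = NULL) {
  geno <- genotype_table(geno)
  arr <- chord_by_locus(geno)
  point <- nj_tree(apply(arr, c(2, 3), mean, na.rm = TRUE))
  nloc <- dim(arr)[1]
  boot <- maybe_with_seed(seed, {
    lapply(seq_len(reps), function(i) {
      idx <- sample.int(nloc, nloc, replace = TRUE)
      nj_tree(apply(arr[idx, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE))
    })
  })
  counts <- ape::prop.clades(point, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supp <- round(100 * counts / reps, 1)
  supp[1] <- NA  # root of the unrooted representation: not a bipartition
  point$node.label <- supp
  attr(point, "reps") <- reps
  point
}

#' Rank candidate source populations for an introduced population
#'
#' Candidates are ranked by ascending FST against the introduced
#' population; exact ties are broken by mean mtDNA nucleotide differences
#' when supplied, and reported as ties in the `rank` column.  Undefined
#' FST entries rank last.
#'
#' @param fst FST matrix from [fst_matrix()].
#' @param introduced Label of the introduced population.
#' @param mito Optional mtDNA difference matrix from [mito_diff_matrix()].
#' @return Tibble `source`, `fst`, `mito_diff`, `rank`, ordered best
#'   first.
#' @export
assign_source <- function(fst, introduced, mito = NULL) {
  if (!introduced %in% rownames(fst)) abort("introduced population not in matrix")
  src <- setdiff(rownames(fst), introduced)
  out <- tibble(
    source = src,
    fst = as.numeric(fst[src, introduced]),
    mito_diff = if (is.null(mito)) NA_real_ else {
      as.numeric(mito[match(src, rownames(mito)), introduced])
    }
  )
  out <- out |> arrange(!is.finite(.data$fst), .data$fst, .data$mito_diff)
  finite_rank <- dplyr::min_rank(out$fst)
  finite_rank[!is.finite(out$fst)] <- NA_integer_
  out$rank <- finite_rank
  out
}
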