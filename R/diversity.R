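#' Rarefied allelic richness at one locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, computed from the hypergeometric probability that each allele
#' enters the subsample:
#' \deqn{A_R(g) = \sum_a \left[1 - \binom{N - N_a}{g} / \binom{N}{g}\right]}
#' where \eqn{N_a} is the gene count of allele \eqn{a} and \eqn{N = \sum_a
#' N_a}.  Evaluated in log-gamma arithmetic, so it is exact up to floating
#' point for any realistic counts.
#'
#' @param allele_counts Positive integer vector of per-allele gene counts.
#' @param g Subsample size in gene copies (`g <= sum(allele_counts)`).
#' @return The expected allele count, a number in `[1, length(allele_counts)]`.
#' @examples
#' rarefied_allelic_richness(c(10, 3, 1), g = 2) # 134/91
#' @export
rarefied_allelic_richness <- function(allele_counts, g) {
  N <- sum(allele_counts)
  if (g > N) abort("g exceeds the total gene count")
  if (g < 1) abort("g must be at least 1")
  sum(1 - exp(lchoose(N - allele_counts, g) - lchoose(N, g)))
}

#' Rarefied private allelic richness at one locus
#'
#' Expected number of alleles that appear in a `g`-gene subsample of the
#' focal population and in no other population's `g`-gene subsample:
#' for each allele, (hypergeometric probability of presence in the focal
#' subsample) x (product over other populations of the probability of
#' absence from theirs).
#'
#' @param all_pops_counts Data frame with columns `pop`, `allele`, `count`
#'   giving per-allele gene counts at one locus for every population.
#' @param focal Population id whose private richness is wanted.
#' @param g Subsample size in gene copies; must not exceed any
#'   population's gene count at the locus.
#' @return Expected count of private alleles (>= 0).
#' @export
private_allelic_richness <- function(all_pops_counts, focal, g) {
  x <- as_tibble(all_pops_counts)
  x$pop <- as.character(x$pop)
  if (!focal %in% x$pop) abort("focal population absent from counts")
  totals <- tapply(x$count, x$pop, sum)
  if (any(totals < g)) abort("g exceeds a population's gene count")
  foc <- x[x$pop == focal, ]
  others <- setdiff(names(totals), focal)
  p_absent <- function(pop_id, allele) {
    sub <- x[x$pop == pop_id, ]
    n_a <- sub$count[match(allele, sub$allele)]
    n_a[is.na(n_a)] <- 0
    exp(lchoose(totals[[pop_id]] - n_a, g) - lchoose(totals[[pop_id]], g))
  }
  present_foc <- 1 - p_absent(focal, foc$allele)
  absent_elsewhere <- rep(1, nrow(foc))
  for (o in others) {
    absent_elsewhere <- absent_elsewhere * p_absent(o, foc$allele)
  }
  sum(present_foc * absent_elsewhere)
}

#' Per-locus heterozygosity and allele-count statistics for one population
#'
#' Observed heterozygosity is the fraction of heterozygous genotypes;
#' expected heterozygosity uses Nei's unbiased small-sample estimator
#' \eqn{\hat H_E = \frac{2n}{2n-1}(1 - \sum_i p_i^2)} with `n` the
#' non-missing individuals at the locus.
#'
#' @param geno A genotype tibble (see [genotype_table()]).
#' @param population Population id.
#' @return Tibble with one row per locus: `locus`, `n` (non-missing
#'   individuals), `n_alleles`, `Ho`, `He`.  Loci with no data are
#'   dropped with a note.
#' @export
heterozygosity_stats <- function(geno, population) {
  sub <- geno[geno$pop == population, ]
  if (!nrow(sub)) abort(paste0("population not in table: ", population))
  out <- sub |>
    filter(!is.na(.data$allele_1)) |>
    group_by(.data$locus) |>
    summarise(
      n = n(),
      n_alleles = length(unique(c(.data$allele_1, .data$allele_2))),
      Ho = mean(.data$allele_1 != .data$allele_2),
      He = {
        p <- tabulate(factor(c(.data$allele_1, .data$allele_2)))
        p <- p / sum(p)
        nn <- n()
        (2 * nn / (2 * nn - 1)) * (1 - sum(p^2))
      },
      .groups = "drop"
    )
  dropped <- setdiff(levels(sub$locus), as.character(out$locus))
  if (length(dropped)) {
    ff_note("heterozygosity_stats: no data in ", population, " at ",
            paste(dropped, collapse = ", "), "; excluded")
  }
  out
}

#' Per-population nuclear diversity summary
#'
#' One row per population with the classic microsatellite summary
#' columns: sample size `n`, proportion of polymorphic loci `P`,
#' standardized private allelic richness `A_p` and allelic richness `A_R`
#' (both rarefied to `g` gene copies), mean observed allele count `A`
#' (with SD across loci), and mean observed/expected heterozygosity
#' `Ho`/`He` (with SD across loci).
#'
#' Loci where a population has fewer than `g` gene copies are excluded
#' from that population's `A_R` mean; loci where *any* population falls
#' below `g` are excluded from all `A_p` means (the usual rarefaction
#' convention).  Exclusions are noted on the message stream.
#'
#' @param geno A genotype tibble.
#' @param g Rarefaction size in gene copies (default 26).
#' @return A tibble with one row per population.
#' @export
nuclear_diversity <- function(geno, g = 26) {
  geno <- genotype_table(geno)
  counts <- allele_counts(geno)
  pops <- levels(geno$pop)
  loci <- levels(geno$locus)

  genes <- gene_counts(geno)
  # loci usable for A_p: every population must reach g genes
  ap_ok <- genes |>
    group_by(.data$locus) |>
    summarise(ok = all(.data$genes >= g) && n() == length(pops), .groups = "drop")
  ap_loci <- as.character(ap_ok$locus[ap_ok$ok])
  if (length(ap_loci) < length(loci)) {
    ff_note("nuclear_diversity: loci excluded from A_p (some population has < ",
            g, " genes): ", paste(setdiff(loci, ap_loci), collapse = ", "))
  }

  purrr::map(pops, function(p) {
    het <- heterozygosity_stats(geno, p)
    n_ind <- length(unique(geno$ind[geno$pop == p & !is.na(geno$allele_1)]))
    ar <- purrr::map_dbl(as.character(het$locus), function(l) {
      ct <- counts$count[counts$pop == p & counts$locus == l]
      if (sum(ct) < g) NA_real_ else rarefied_allelic_richness(ct, g)
    })
    if (anyNA(ar)) {
      ff_note("nuclear_diversity: ", p, ": ", sum(is.na(ar)),
              " locus(i) below ", g, " genes excluded from A_R")
    }
    ap <- purrr::map_dbl(ap_loci, function(l) {
      private_allelic_richness(
        counts[counts$locus == l, c("pop", "allele", "count")], p, g)
    })
    tibble(
      pop = p,
      n = n_ind,
      P = mean(het$n_alleles >= 2),
      A_p = if (length(ap)) mean(ap) else NA_real_,
      A_R = mean(ar, na.rm = TRUE),
      A = mean(het$n_alleles),
      A_sd = sd(het$n_alleles),
      Ho = mean(het$Ho),
      Ho_sd = sd(het$Ho),
      He = mean(het$He),
      He_sd = sd(het$He)
    )
  }) |>
    purrr::list_rbind() |>
    mutate(pop = factor(.data$pop, levels = pops))
}

#' Mitochondrial diversity for one population
#'
#' Haplotype diversity \eqn{h = \frac{n}{n-1}(1 - \sum_i p_i^2)} and
#' per-site nucleotide diversity \eqn{\pi = \frac{n}{n-1} \sum_{ij} p_i
#' p_j d_{ij} / L}, with the standard Nei/Tajima sampling variances for
#' the reported SDs.  Private haplotypes are counted against every other
#' population in the set.
#'
#' @param hapset A [haplotype_set()].
#' @param population Population id (mtDNA sample size must be >= 2).
#' @return One-row tibble: `pop`, `n`, `n_H`, `n_pH`, `h`, `h_sd`,
#'   `pi`, `pi_sd`.
#' @export
mito_diversity <- function(hapset, population) {
  ct <- hap_counts_one(hapset, population)
  n <- sum(ct)
  if (n < 2) abort("mito_diversity needs a sample of at least 2 sequences")
  p <- ct / n
  sp2 <- sum(p^2)
  h <- n / (n - 1) * (1 - sp2)
  # Nei (1987) eq. 8.12 sampling variance of h
  vh <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  d <- hapset$diff[names(ct), names(ct), drop = FALSE]
  pi_site <- (n / (n - 1)) * as.numeric(t(p) %*% d %*% p) / hapset$L
  # Tajima (1983) total variance of pi (per site), ARLEQUIN's convention
  vpi <- (n + 1) / (3 * (n - 1)) * pi_site / hapset$L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_site^2
  elsewhere <- unique(hapset$counts$haplotype[hapset$counts$pop != population])
  tibble(
    pop = population, n = n, n_H = length(ct),
    n_pH = sum(!names(ct) %in% elsewhere),
    h = h, h_sd = sqrt(max(vh, 0)),
    pi = pi_site, pi_sd = sqrt(max(vpi, 0))
  )
}

#' Mitochondrial diversity table for every population
#'
#' @param hapset A [haplotype_set()].
#' @return Tibble, one row per population (see [mito_diversity()]).
#' @export
mito_diversity_table <- function(hapset) {
  purrr::map(levels(hapset$counts$pop), ~ mito_diversity(hapset, .x)) |>
    purrr::list_rbind()
}

#' Mean pairwise nucleotide differences between two populations
#'
#' The frequency-weighted mean \eqn{\sum_{ij} p_i^A p_j^B d_{ij}} of raw
#' (not per-site) nucleotide differences over all cross-population
#' sequence pairs.  With `popA == popB` this is the uncorrected
#' within-population mean pairwise difference.
#'
#' @param hapset A [haplotype_set()].
#' @param popA,popB Population ids.
#' @return A single number (raw nucleotide differences).
#' @export
between_population_differences <- function(hapset, popA, popB) {
  ca <- hap_counts_one(hapset, popA)
  cb <- hap_counts_one(hapset, popB)
  pa <- ca / sum(ca)
  pb <- cb / sum(cb)
  d <- hapset$diff[names(ca), names(cb), drop = FALSE]
  as.numeric(t(pa) %*% d %*% pb)
}

#' Matrix of between-population mean nucleotide differences
#'
#' @param hapset A [haplotype_set()].
#' @return A symmetric numeric matrix (class `dist_matrix`, kind
#'   `mtdna_diff`) of raw mean pairwise differences, zero diagonal.
#' @export
mito_diff_matrix <- function(hapset) {
  pops <- levels(hapset$counts$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1)) {
      m[i, j] <- m[j, i] <- between_population_differences(hapset, pops[i], pops[j])
    }
  }
  structure(m, class = c("dist_matrix", "matrix"), kind = "mtdna_diff")
}
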