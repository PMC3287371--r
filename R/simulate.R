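#' Define a simulation scenario with known ground truth
#'
#' The default scenario emulates the sampling design of a typical
#' invasion-genetics study of a freshwater fish: nine candidate source
#' populations plus one introduced population founded from a known source
#' by a known number of individuals ten generations ago; seven
#' microsatellite loci with 6-48 alleles each; per-population sample
#' sizes between 15 and 124 individuals; and a 759-bp mtDNA locus with
#' small within-clade haplotype distances.  Source populations diverge
#' from a common ancestral gene pool under a Balding-Nichols model with
#' per-population drift parameter `divergence_F`, which for a pair of
#' populations is also (approximately) their expected pairwise FST; the
#' default 0.3 puts between-population FST in the 0.2-0.5 band typical of
#' strongly structured river-basin samples.
#'
#' @param n_source_pops Number of candidate source populations.
#' @param n_loci Number of microsatellite loci.
#' @param allele_range Range (min, max) of ancestral allele counts per
#'   locus; the realized count is drawn uniformly.
#' @param divergence_F Balding-Nichols drift parameter in (0, 1).
#' @param sample_sizes Genotyped individuals per source population
#'   (recycled to `n_source_pops`).
#' @param introduced_n Genotyped individuals in the introduced population.
#' @param mito_sample_sizes,introduced_mito_n mtDNA sample sizes.
#' @param true_source Label of the population the introduction came from.
#' @param true_N0 True founder number (diploid individuals).
#' @param K,r,t Post-founding logistic-growth demography (see
#'   [logistic_trajectory()]).
#' @param missing_rate Per-genotype missing-data probability.
#' @param mito List: `haps_per_pop`, alignment length `L`, substitutions
#'   separating population clades (`clade_subs`) and within-clade
#'   haplotypes (`within_subs`, sampled per haplotype).
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_source_pops = 9,
                         n_loci = 7,
                         allele_range = c(6, 48),
                         divergence_F = 0.3,
                         sample_sizes = c(28, 27, 68, 59, 71, 15, 33, 124, 66),
                         introduced_n = 71,
                         mito_sample_sizes = c(16, 24, 15, 16, 16, 15, 23, 31, 15),
                         introduced_mito_n = 15,
                         true_source = "SRC9",
                         true_N0 = 10,
                         K = 2000, r = 1.5, t = 10,
                         missing_rate = 0.02,
                         mito = list(haps_per_pop = 8, L = 759,
                                     clade_subs = 12, within_subs = 1:3)) {
  sc <- list(
    n_source_pops = as.integer(n_source_pops), n_loci = as.integer(n_loci),
    allele_range = as.integer(allele_range), divergence_F = divergence_F,
    sample_sizes = as.integer(rep_len(sample_sizes, n_source_pops)),
    introduced_n = as.integer(introduced_n),
    mito_sample_sizes = as.integer(rep_len(mito_sample_sizes, n_source_pops)),
    introduced_mito_n = as.integer(introduced_mito_n),
    pops = paste0("SRC", seq_len(n_source_pops)), introduced = "INTRO",
    true_source = true_source, true_N0 = as.integer(true_N0),
    K = K, r = r, t = as.integer(t),
    missing_rate = missing_rate, mito = mito
  )
  if (sc$true_N0 < 1) abort("true_N0 must be at least 1")
  if (sc$K < sc$true_N0) abort("K must be at least true_N0")
  if (sc$divergence_F <= 0 || sc$divergence_F >= 1) abort("divergence_F must lie in (0, 1)")
  if (sc$t < 0 || sc$r <= 0) abort("need t >= 0 and r > 0")
  if (any(c(sc$sample_sizes, sc$introduced_n,
            sc$mito_sample_sizes, sc$introduced_mito_n) <= 0)) {
    abort("sample sizes must be positive")
  }
  if (!sc$true_source %in% sc$pops) abort("true_source must be one of the source populations")
  if (sc$missing_rate < 0 || sc$missing_rate >= 1) abort("missing_rate must lie in [0, 1)")
  structure(sc, class = "sim_scenario")
}

#' Generate source-population allele frequencies
#'
#' Per locus, an ancestral frequency vector is drawn from a symmetric
#' Dirichlet(1); each source population's vector is then drawn from a
#' Balding-Nichols Dirichlet centred on the ancestral vector with
#' concentration `(1 - F) / F`, so `divergence_F` controls how far
#' populations drift apart (and approximates their expected pairwise
#' FST).
#'
#' @param scenario A [sim_scenario()].
#' @param seed Optional integer seed.
#' @return List with `loci` (names), `ancestral` (list of named
#'   frequency vectors; names are integer allele sizes), and `pops`
#'   (per-population lists of per-locus frequency vectors).
#' @export
generate_source_metapopulation <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  maybe_with_seed(seed, {
    loci <- sprintf("loc%d", seq_len(scenario$n_loci))
    conc <- (1 - scenario$divergence_F) / scenario$divergence_F
    ancestral <- lapply(loci, function(l) {
      k <- sample(scenario$allele_range[1]:scenario$allele_range[2], 1)
      sizes <- 100L + 2L * (seq_len(k) - 1L)
      setNames(rdirichlet_(1, 1, k = k)[, 1], sizes)
    })
    names(ancestral) <- loci
    pops <- lapply(scenario$pops, function(p) {
      f <- lapply(ancestral, function(anc) {
        setNames(rdirichlet_(1, anc * conc)[, 1], names(anc))
      })
      names(f) <- loci
      f
    })
    names(pops) <- scenario$pops
    list(loci = loci, ancestral = ancestral, pops = pops)
  })
}

#' Simulate the founding event and post-founding drift
#'
#' Draws a founder gene pool of `2 * true_N0` copies per locus from the
#' source frequencies, then applies `t` generations of Wright-Fisher
#' multinomial resampling with per-generation sizes from
#' [logistic_trajectory()].  There is no mutation, so alleles absent from
#' the source never appear.
#'
#' @param source_freqs Per-locus list of named source frequency vectors.
#' @param scenario A [sim_scenario()] (supplies `true_N0`, `K`, `r`, `t`).
#' @param seed Optional integer seed.
#' @return List: `freqs` (final per-locus frequencies),
#'   `founder_freqs` (gene-pool frequencies at generation 0) and
#'   `trajectory` (the realized size schedule).
#' @export
simulate_introduction <- function(source_freqs, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  traj <- logistic_trajectory(scenario$true_N0, scenario$K, scenario$r, scenario$t)
  maybe_with_seed(seed, {
    founder <- lapply(source_freqs, function(p) {
      f <- stats::rmultinom(1, 2L * traj[1], p)[, 1] / (2 * traj[1])
      setNames(f, names(p))
    })
    final <- lapply(founder, function(f0) {
      f <- matrix(f0, ncol = 1)
      if (length(traj) > 1) {
        for (g in 2:length(traj)) {
          f <- multinom_cols(2L * traj[g], f) / (2 * traj[g])
        }
      }
      setNames(f[, 1], names(f0))
    })
    list(freqs = final, founder_freqs = founder, trajectory = traj)
  })
}

# mtDNA haplotype pool: one random root sequence; each population gets its
# own clade (founder = root + clade_subs substitutions, haplotypes = founder
# + 1-3 substitutions), so within-clade distances are small and
# between-clade distances large
make_mito_pool <- function(scenario) {
  bases <- c("A", "C", "G", "T")
  L <- scenario$mito$L
  mutate_seq <- function(s, k) {
    pos <- sample.int(L, k)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1), character(1))
    s
  }
  root <- sample(bases, L, replace = TRUE)
  pool <- list()
  pop_seqs <- list()
  for (p in scenario$pops) {
    founder <- mutate_seq(root, scenario$mito$clade_subs)
    seqs <- c(list(founder), lapply(seq_len(scenario$mito$haps_per_pop - 1), function(i) {
      mutate_seq(founder, sample(scenario$mito$within_subs, 1))
    }))
    pop_seqs[[p]] <- vapply(seqs, paste, character(1), collapse = "")
  }
  all_seqs <- unique(unlist(pop_seqs))
  hap_ids <- sprintf("H%02d", seq_along(all_seqs))
  freqs <- lapply(pop_seqs, function(ss) {
    ids <- hap_ids[match(ss, all_seqs)]
    w <- rdirichlet_(1, 1, k = length(ss))[, 1]
    tapply(w, ids, sum)  # collapse duplicate haplotypes within the clade
  })
  list(sequences = setNames(all_seqs, hap_ids), pop_freqs = freqs)
}

#' Draw a full synthetic dataset with ground-truth sidecar
#'
#' Generates source allele frequencies, simulates the founding of the
#' introduced population, and samples diploid genotypes (two independent
#' gene copies per locus, Hardy-Weinberg assembly, with random missing
#' genotypes at `missing_rate`) and mtDNA haplotypes for every
#' population.  The introduced population's haplotype pool is the set
#' carried by its `true_N0` founders (post-founding drift of mtDNA
#' frequencies is not modelled, matching the assumption of the
#' mitochondrial estimator).
#'
#' @param scenario A [sim_scenario()].
#' @param outdir Optional directory; when given, writes `genotypes.gen`
#'   (Genepop), `haplotypes.fasta`, `popmap.tsv` and `truth.json`.
#' @param seed Optional integer seed; identical scenario + seed gives
#'   identical output.
#' @return A `sim_dataset` list: `genotypes` (genotype tibble),
#'   `haplotypes` ([haplotype_set()]), `truth` (ground-truth list) and
#'   `files` (paths, when written).
#' @export
sample_dataset <- function(scenario, outdir = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  maybe_with_seed(seed, {
    metapop <- generate_source_metapopulation(scenario)
    intro <- simulate_introduction(metapop$pops[[scenario$true_source]], scenario)

    all_freqs <- c(metapop$pops, setNames(list(intro$freqs), scenario$introduced))
    ns <- c(setNames(scenario$sample_sizes, scenario$pops),
            setNames(scenario$introduced_n, scenario$introduced))
    rows <- list()
    for (p in names(all_freqs)) {
      n <- ns[[p]]
      ids <- sprintf("%s_%d", p, seq_len(n))
      for (l in metapop$loci) {
        fr <- all_freqs[[p]][[l]]
        sizes <- as.integer(names(fr))
        g <- matrix(sample(sizes, 2 * n, replace = TRUE, prob = fr), ncol = 2)
        if (scenario$missing_rate > 0) {
          drop <- stats::runif(n) < scenario$missing_rate
          g[drop, ] <- NA_integer_
        }
        rows[[length(rows) + 1]] <- tibble(
          pop = p, ind = ids, locus = l, allele_1 = g[, 1], allele_2 = g[, 2])
      }
    }
    geno <- genotype_table(purrr::list_rbind(rows) |>
      mutate(pop = factor(.data$pop, levels = names(all_freqs)),
             locus = factor(.data$locus, levels = metapop$loci)))

    pool <- make_mito_pool(scenario)
    src_freq <- pool$pop_freqs[[scenario$true_source]]
    founder_haps <- sample(names(src_freq), scenario$true_N0,
                           replace = TRUE, prob = src_freq)
    intro_freq <- table(founder_haps) / scenario$true_N0
    mt_freqs <- c(pool$pop_freqs,
                  setNames(list(intro_freq), scenario$introduced))
    mt_ns <- c(setNames(scenario$mito_sample_sizes, scenario$pops),
               setNames(scenario$introduced_mito_n, scenario$introduced))
    counts <- purrr::imap(mt_freqs, function(fr, p) {
      ct <- stats::rmultinom(1, mt_ns[[p]], as.numeric(fr))[, 1]
      tibble(pop = p, haplotype = names(fr), count = ct)
    }) |> purrr::list_rbind() |> filter(.data$count > 0)
    counts$pop <- factor(counts$pop, levels = names(mt_freqs))
    used <- sort(unique(counts$haplotype))
    hapset <- haplotype_set(pool$sequences[used], counts)

    truth <- list(
      true_source = scenario$true_source, true_N0 = scenario$true_N0,
      K = scenario$K, r = scenario$r, t = scenario$t,
      divergence_F = scenario$divergence_F,
      trajectory = intro$trajectory,
      founder_haplotypes = sort(unique(founder_haps)),
      k_founder_haplotypes = length(unique(founder_haps)),
      k_observed_mito = length(unique(
        counts$haplotype[counts$pop == scenario$introduced]))
    )

    files <- NULL
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      files <- list(
        genepop = file.path(outdir, "genotypes.gen"),
        fasta = file.path(outdir, "haplotypes.fasta"),
        popmap = file.path(outdir, "popmap.tsv"),
        truth = file.path(outdir, "truth.json")
      )
      write_genepop(geno, files$genepop, title = "founderflow synthetic dataset")
      write_fasta_haplotypes(hapset, files$fasta, files$popmap)
      jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
    }
    structure(list(genotypes = geno, haplotypes = hapset,
                   truth = truth, files = files),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d populations, %d loci, true source %s, true N0 = %d\n",
    nlevels(x$genotypes$pop), nlevels(x$genotypes$locus),
    x$truth$true_source, x$truth$true_N0))
  invisible(x)
}
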