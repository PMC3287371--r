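#' Logistic effective-size trajectory after founding
#'
#' Continuous-logistic solution evaluated at integer generations and
#' rounded:
#' \deqn{N(g) = \mathrm{round}\!\left(\frac{K N_0 e^{r g}}{K + N_0 (e^{r g} - 1)}\right)}
#' with `N(0) = N0`.  Monotone non-decreasing and bounded by `K` for any
#' `r > 0`, unlike discrete Ricker updates which oscillate at high `r`.
#'
#' @param N0 Founder count (diploid individuals, `1 <= N0 <= K`).
#' @param K Effective carrying capacity.
#' @param r Intrinsic rate of increase per generation (> 0).
#' @param t Generations since founding (>= 0).
#' @return Integer vector `N(0), N(1), ..., N(t)` of length `t + 1`.
#' @examples
#' logistic_trajectory(10, K = 1000, r = 1, t = 10)
#' @export
logistic_trajectory <- function(N0, K, r, t) {
  if (N0 < 1 || N0 > K) abort("need 1 <= N0 <= K")
  if (r <= 0) abort("r must be positive")
  if (t < 0) abort("t must be non-negative")
  g <- 0:t
  N <- as.integer(round(K * N0 * exp(r * g) / (K + N0 * (exp(r * g) - 1))))
  N[1] <- as.integer(N0)
  N
}

# Wright-Fisher chain, vectorized over M replicate columns.
# p_src: source allele-frequency vector (length A);
# traj: per-generation diploid sizes N(0..t).
# Returns an A x M matrix of final-generation allele frequencies.
wf_final_freqs <- function(p_src, traj, M) {
  A <- length(p_src)
  counts <- stats::rmultinom(M, 2L * traj[1], p_src)  # founder gene pool
  freqs <- counts / (2 * traj[1])
  if (length(traj) > 1) {
    for (g in 2:length(traj)) {
      freqs <- multinom_cols(2L * traj[g], freqs) / (2 * traj[g])
    }
  }
  freqs
}

# systematic (stratified) resampling of normalized weights; unbiased,
# lower-variance replacement for multinomial resampling
systematic_resample <- function(w) {
  M <- length(w)
  u <- (stats::runif(1) + seq_len(M) - 1) / M
  pmin(findInterval(u, cumsum(w)) + 1L, M)
}

# colSums of C * log(F) treating 0 * log(0) as 0 (support is guarded by
# the proposal, so finite C > 0 entries always sit on F > 0)
xlogy_cols <- function(C, F) {
  lf <- log(F)
  lf[!is.finite(lf)] <- 0
  colSums(C * lf)
}

# Sequential Monte Carlo estimate of log P(observed counts | N0) for
# one locus.  M particles follow the founding-bottleneck Wright-Fisher
# chain with three variance-reduction devices, none of which biases the
# marginal-likelihood estimate:
#   * forced retention: chains that lose an allele observed in the
#     introduced sample contribute exactly zero, so the proposal plants
#     one copy of each observed allele at the founder draw and at every
#     resampling step, with the exact multinomial target/proposal ratio
#     carried in the particle weights;
#   * founder guidance: the founder remainder is proposed from a
#     (1 - guide) p_src + guide p_obs mixture, again exactly weighted;
#   * tempered lookahead: the multinomial probability of the observed
#     counts, raised to g/t, enters the potentials, and particles are
#     multinomially resampled each generation, so the particle cloud
#     concentrates on trajectories that can explain the data.  The
#     product of per-generation mean weights is the standard unbiased
#     SMC normalizing-constant estimator.
# Returns -Inf when 2*N0 < #observed alleles (the likelihood is zero).
loglik_locus_smc <- function(p_src, x_obs, traj, M, guide = 0.5) {
  A <- length(p_src)
  obs_idx <- which(x_obs > 0)
  A0 <- length(obs_idx)
  size0 <- 2L * traj[1]
  if (size0 < A0) return(-Inf)
  e <- numeric(A)
  e[obs_idx] <- 1
  tt <- length(traj) - 1L
  pmf_log <- function(F) dmultinom_cols(x_obs, F)

  p_obs <- x_obs / sum(x_obs)
  mix0 <- (1 - guide) * p_src + guide * p_obs
  counts <- stats::rmultinom(M, size0 - A0, mix0) + e
  logw <-
    (lgamma(size0 + 1) - colSums(lgamma(counts + 1)) +
       xlogy_cols(counts, matrix(p_src, A, M))) -
    (lgamma(size0 - A0 + 1) - colSums(lgamma(counts - e + 1)) +
       xlogy_cols(counts - e, matrix(mix0, A, M)))
  freqs <- counts / size0
  if (tt == 0L) {
    return(logsumexp(logw + pmf_log(freqs)) - log(M))
  }
  logZ <- 0
  alpha_prev <- 0
  phi_prev <- numeric(M)
  for (g in seq_len(tt)) {
    size <- 2L * traj[g + 1]
    counts <- multinom_cols(size - A0, freqs) + e
    logw <- logw + lgamma(size + 1) - lgamma(size - A0 + 1) -
      colSums(log(counts[obs_idx, , drop = FALSE])) +
      colSums(log(freqs[obs_idx, , drop = FALSE]))
    freqs <- counts / size
    alpha <- g / tt
    phi <- pmf_log(freqs)
    logw <- logw + alpha * phi - alpha_prev * phi_prev
    if (!is.finite(logsumexp(logw))) return(-Inf)
    alpha_prev <- alpha
    phi_prev <- phi
    # resample (systematic, low-variance) only when the effective
    # sample size drops below M / 2
    w <- exp(logw - max(logw))
    w <- w / sum(w)
    if (1 / sum(w^2) < M / 2 && g < tt) {
      idx <- systematic_resample(w)
      freqs <- freqs[, idx, drop = FALSE]
      phi_prev <- phi_prev[idx]
      logZ <- logZ + logsumexp(logw) - log(M)
      logw <- numeric(M)
    }
  }
  logZ + logsumexp(logw) - log(M)
}

# one multinomial draw per column of probmat (A x M), common size;
# sequential conditional-binomial decomposition keeps it vectorized in M
multinom_cols <- function(size, probmat) {
  A <- nrow(probmat)
  M <- ncol(probmat)
  out <- matrix(0, A, M)
  remaining <- rep.int(size, M)
  premain <- rep.int(1, M)
  for (a in seq_len(A - 1L)) {
    pa <- probmat[a, ]
    pr <- ifelse(premain > 0, pmin(pa / premain, 1), 0)
    draw <- stats::rbinom(M, remaining, pr)
    out[a, ] <- draw
    remaining <- remaining - draw
    premain <- pmax(premain - pa, 0)
  }
  out[A, ] <- remaining
  out
}

#' Simulate post-founding allele frequencies under the bottleneck model
#'
#' Draws a founder gene pool of `2 N0` copies from the source
#' frequencies, then resamples `2 N(g)` gene copies each generation along
#' the [logistic_trajectory()].  No mutation: an allele absent from the
#' source never appears.
#'
#' @param source_freqs A frequency vector for one locus, or a list of
#'   such vectors (one per locus).
#' @param N0,K,r,t Demographic model (see [logistic_trajectory()]).
#' @param seed Optional integer seed.
#' @return Final-generation frequency vector(s), matching the shape of
#'   `source_freqs`.
#' @export
simulate_post_founding_freqs <- function(source_freqs, N0, K, r, t, seed = NULL) {
  traj <- logistic_trajectory(N0, K, r, t)
  one <- function(p) {
    f <- wf_final_freqs(p, traj, 1L)[, 1]
    names(f) <- names(p)
    f
  }
  maybe_with_seed(seed, {
    if (is.list(source_freqs)) lapply(source_freqs, one) else one(source_freqs)
  })
}

# per-locus source/introduced gene counts over the allele union,
# with the +1 pseudocount for alleles unseen in the source sample
locus_count_pairs <- function(geno, source, introduced) {
  counts <- allele_counts(geno)
  loci <- levels(geno$locus)
  out <- list()
  excluded <- tibble(locus = character(0), reason = character(0))
  for (l in loci) {
    sc <- counts[counts$locus == l & counts$pop == source, ]
    ic <- counts[counts$locus == l & counts$pop == introduced, ]
    alleles <- sort(unique(c(sc$allele, ic$allele)))
    if (length(alleles) < 2) {
      excluded <- add_row(excluded, locus = l,
                          reason = "monomorphic across source and introduced")
      next
    }
    s <- setNames(rep(0, length(alleles)), alleles)
    i <- s
    s[as.character(sc$allele)] <- sc$count
    i[as.character(ic$allele)] <- ic$count
    novel <- i > 0 & s == 0
    if (any(novel)) {
      s[novel] <- 1
      ff_note("founder_likelihood: ", l, ": ", sum(novel),
              " allele(s) absent from the source sample given one ",
              "pseudocount copy")
    }
    out[[l]] <- list(source = s, introduced = i)
  }
  list(pairs = out, excluded = excluded)
}

# log multinomial probability of observed counts x (vector) for each
# frequency column of freqs (A x M); -Inf where an observed allele is
# lost.  Only alleles with x_a > 0 enter the sum (x_a = 0 terms are 0
# even when the replicate lost that allele).
dmultinom_cols <- function(x, freqs) {
  obs <- which(x > 0)
  const <- lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  const + as.numeric(crossprod(log(freqs[obs, , drop = FALSE]), x[obs]))
}

#' Monte Carlo likelihood of the effective founder number
#'
#' For each candidate founder number `N0`, the per-locus sampling
#' probability of the observed introduced-population allele counts —
#' the expectation, over founding-bottleneck + logistic-growth
#' Wright-Fisher trajectories, of the multinomial probability of those
#' counts under the final-generation allele frequencies — is estimated
#' with `M` particles by sequential Monte Carlo (forced retention of
#' observed alleles, a guided founder draw, and tempered lookahead
#' resampling; all exactly weighted, so the estimate is unbiased).  One
#' random substream per locus is reused across the whole grid (common
#' random numbers), so neighbouring `N0` values differ by parameter,
#' not noise.  Log-likelihoods are summed over loci; the MLE is the
#' grid argmax and the support limits are the extreme grid values
#' within 2 log-likelihood units of the maximum.
#'
#' Source allele frequencies are estimated from the source sample counts;
#' alleles observed in the introduced but not the source sample receive a
#' single pseudocount copy (source sampling error would otherwise force a
#' zero likelihood).  Loci monomorphic across both samples are excluded.
#'
#' @param geno A genotype tibble.
#' @param source,introduced Population ids for the assumed source and the
#'   introduced population.
#' @param K,r,t Demographic model held fixed during estimation (see
#'   [logistic_trajectory()]).
#' @param grid Candidate founder numbers (default `2:40`).
#' @param M Monte Carlo replicates per locus and grid point (>= 100).
#' @param seed Optional integer seed.
#' @return A `founder_fit` object; see [tidy.founder_fit()] and
#'   [glance.founder_fit()].
#' @export
founder_likelihood <- function(geno, source, introduced, K, r, t = 10,
                               grid = 2:40, M = 1000, seed = NULL) {
  if (M < 100) abort("M must be at least 100")
  if (!length(grid)) abort("empty founder grid")
  if (any(grid < 1) || any(grid > K)) abort("grid must satisfy 1 <= N0 <= K")
  geno <- genotype_table(geno)
  lp <- locus_count_pairs(geno, source, introduced)
  if (!length(lp$pairs)) abort("no polymorphic locus shared by the two samples")
  grid <- sort(unique(as.integer(grid)))

  loglik_mat <- maybe_with_seed(seed, {
    # common random numbers: each locus reuses one RNG substream across
    # the whole N0 grid, so grid points differ by parameter, not noise
    base <- sample.int(.Machine$integer.max - 1L, length(lp$pairs))
    vapply(grid, function(N0) {
      traj <- logistic_trajectory(N0, K, r, t)
      vapply(seq_along(lp$pairs), function(i) {
        pair <- lp$pairs[[i]]
        set.seed(base[i])
        loglik_locus_smc(pair$source / sum(pair$source), pair$introduced,
                         traj, M)
      }, numeric(1))
    }, numeric(length(lp$pairs)))
  })
  loglik_mat <- matrix(loglik_mat, nrow = length(lp$pairs),
                       dimnames = list(names(lp$pairs), grid))

  dead <- apply(loglik_mat, 1, function(x) all(!is.finite(x)))
  if (any(dead)) {
    ff_note("founder_likelihood: locus(i) with zero sampling probability ",
            "at every grid point excluded: ",
            paste(names(dead)[dead], collapse = ", "))
    lp$excluded <- add_row(lp$excluded, locus = names(dead)[dead],
                           reason = "zero Monte Carlo sampling probability")
    loglik_mat <- loglik_mat[!dead, , drop = FALSE]
  }
  if (!nrow(loglik_mat)) abort("all loci excluded; likelihood undefined")

  loglik <- colSums(loglik_mat)
  ok <- is.finite(loglik)
  if (!any(ok)) abort("log-likelihood is -Inf on the whole grid")
  mle <- grid[ok][which.max(loglik[ok])]
  within <- ok & loglik >= max(loglik[ok]) - 2
  structure(
    list(grid = grid, loglik = unname(loglik), mle = mle,
         support = c(lower = min(grid[within]), upper = max(grid[within])),
         per_locus = loglik_mat, excluded_loci = lp$excluded,
         K = K, r = r, t = t, M = M,
         source = source, introduced = introduced, seed = seed),
    class = "founder_fit"
  )
}

#' @export
print.founder_fit <- function(x, ...) {
  cat(sprintf(
    "<founder_fit> %s -> %s | K = %g, r = %g, t = %d, M = %d\n",
    x$source, x$introduced, x$K, x$r, x$t, x$M))
  cat(sprintf("  MLE founder number: %d (2-unit support %d-%d)\n",
              x$mle, x$support[["lower"]], x$support[["upper"]]))
  if (nrow(x$excluded_loci)) {
    cat("  excluded loci:",
        paste(x$excluded_loci$locus, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sweep the founder likelihood over a demographic grid
#'
#' Runs [founder_likelihood()] for every combination of carrying
#' capacity, intrinsic rate of increase and source population, producing
#' the classic estimate-versus-r table (one series per K).  Failed cells
#' are recorded and the sweep continues.
#'
#' @param geno A genotype tibble.
#' @param sources Character vector of assumed source populations.
#' @param introduced Introduced-population id.
#' @param K_values,r_values Demographic grids (defaults: the
#'   500-16,000 doubling series and r in 0.5-3).
#' @param t Generations since founding (default 10).
#' @param grid,M,seed As in [founder_likelihood()].
#' @return A `founder_sweep` object: tibble of per-cell results with the
#'   full fits in a list-column.
#' @export
demographic_sweep <- function(geno, sources, introduced,
                              K_values = c(500, 1000, 2000, 4000, 8000, 16000),
                              r_values = c(0.5, 1, 1.5, 2, 3),
                              t = 10, grid = 2:40, M = 1000, seed = NULL) {
  if (!length(K_values) || !length(r_values)) abort("empty demographic grid")
  cells <- tidyr::expand_grid(source = sources, K = K_values, r = r_values)
  fits <- maybe_with_seed(seed, {
    purrr::pmap(cells, function(source, K, r) {
      tryCatch(
        founder_likelihood(geno, source, introduced, K = K, r = r, t = t,
                           grid = grid, M = M, seed = NULL),
        error = function(e) conditionMessage(e)
      )
    })
  })
  cells$fit <- fits
  cells$mle <- purrr::map_dbl(fits, ~ if (inherits(.x, "founder_fit")) .x$mle else NA_real_)
  cells$support_lower <- purrr::map_dbl(fits, ~ if (inherits(.x, "founder_fit")) .x$support[["lower"]] else NA_real_)
  cells$support_upper <- purrr::map_dbl(fits, ~ if (inherits(.x, "founder_fit")) .x$support[["upper"]] else NA_real_)
  cells$error <- purrr::map_chr(fits, ~ if (is.character(.x)) .x else NA_character_)
  structure(list(cells = cells, introduced = introduced, t = t,
                 grid = grid, M = M, seed = seed),
            class = "founder_sweep")
}

#' @export
print.founder_sweep <- function(x, ...) {
  cat(sprintf("<founder_sweep> %d cell(s), introduced = %s, t = %d, M = %d\n",
              nrow(x$cells), x$introduced, x$t, x$M))
  print(x$cells |> select(!"fit"), ...)
  invisible(x)
}
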