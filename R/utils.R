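# shared internal helpers

# evaluate `code` under a temporary RNG state when `seed` is given;
# seed = NULL uses (and advances) the caller's RNG stream
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# n Dirichlet draws (columns) with parameter vector alpha (recycled to k)
rdirichlet_ <- function(n, alpha, k = length(alpha)) {
  alpha <- rep_len(alpha, k)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = k)
  # a gamma draw can underflow to 0 when alpha is tiny; keep columns valid
  cs <- colSums(x)
  bad <- cs == 0
  if (any(bad)) {
    x[, bad] <- 1 / k
    cs[bad] <- 1
  }
  sweep(x, 2, cs, "/")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# progress/exclusion notes; silence with options(founderflow.quiet = TRUE)
ff_note <- function(...) {
  if (isTRUE(getOption("founderflow.quiet", FALSE))) return(invisible(NULL))
  message(...)
  invisible(NULL)
}
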