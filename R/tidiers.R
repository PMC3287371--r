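#' Tidy a nuclear founder-number fit
#'
#' @param x A `founder_fit` from [founder_likelihood()].
#' @param ... Unused.
#' @return Tibble with one row per grid point: `N0`, `loglik`,
#'   `delta_loglik` (drop from the maximum), `in_support`.
#' @exportS3Method generics::tidy
#' @export
tidy.founder_fit <- function(x, ...) {
  tibble(
    N0 = x$grid,
    loglik = x$loglik,
    delta_loglik = max(x$loglik[is.finite(x$loglik)]) - x$loglik,
    in_support = x$grid >= x$support[["lower"]] & x$grid <= x$support[["upper"]] &
      is.finite(x$loglik)
  )
}

#' @rdname tidy.founder_fit
#' @exportS3Method generics::glance
#' @export
glance.founder_fit <- function(x, ...) {
  tibble(
    source = x$source, introduced = x$introduced,
    K = x$K, r = x$r, t = x$t, M = x$M,
    mle = x$mle,
    support_lower = x$support[["lower"]], support_upper = x$support[["upper"]],
    n_loci = nrow(x$per_locus), n_excluded = nrow(x$excluded_loci)
  )
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.founder_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$N0, y = .data$loglik)) +
    geom_line(colour = "grey40") +
    geom_point(aes(colour = .data$in_support), show.legend = FALSE) +
    labs(x = "candidate founder number N0", y = "log-likelihood",
         title = sprintf("Founder-number likelihood (%s -> %s)",
                         object$source, object$introduced),
         subtitle = sprintf("MLE %d, 2-unit support %d-%d",
                            object$mle, object$support[["lower"]],
                            object$support[["upper"]])) +
    theme_minimal()
}

#' Tidy a demographic sweep
#'
#' @param x A `founder_sweep` from [demographic_sweep()].
#' @param ... Unused.
#' @return Tibble with one row per (source, K, r) cell.
#' @exportS3Method generics::tidy
#' @export
tidy.founder_sweep <- function(x, ...) {
  x$cells |> select(!"fit")
}

#' @rdname tidy.founder_sweep
#' @exportS3Method generics::glance
#' @export
glance.founder_sweep <- function(x, ...) {
  ok <- !is.na(x$cells$mle)
  tibble(
    n_cells = nrow(x$cells), n_failed = sum(!ok),
    mle_min = min(x$cells$mle[ok]), mle_max = max(x$cells$mle[ok]),
    support_min = min(x$cells$support_lower[ok]),
    support_max = max(x$cells$support_upper[ok])
  )
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.founder_sweep <- function(object, ...) {
  d <- tidy(object) |> filter(!is.na(.data$mle))
  ggplot(d, aes(x = .data$r, y = .data$mle,
                colour = factor(.data$K), group = factor(.data$K))) +
    geom_line() +
    geom_point() +
    facet_wrap(~source) +
    labs(x = "assumed intrinsic rate of increase r",
         y = "ML founder number", colour = "K") +
    theme_minimal()
}

#' Tidy a mitochondrial founder fit
#'
#' @param x A `mito_founder_fit` from [mito_founder_estimate()].
#' @param ... Unused.
#' @return The probability curve: `N`, `prob_sim`, `prob_exact`.
#' @exportS3Method generics::tidy
#' @export
tidy.mito_founder_fit <- function(x, ...) {
  x$curve
}

#' @rdname tidy.mito_founder_fit
#' @exportS3Method generics::glance
#' @export
glance.mito_founder_fit <- function(x, ...) {
  tibble(
    k_observed = x$k_observed, n_source_haplotypes = length(x$source_counts),
    trials = x$trials, mle_N = x$mle_N,
    support_lower = x$support[["lower"]], support_upper = x$support[["upper"]],
    at_boundary = x$boundary
  )
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.mito_founder_fit <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(x = .data$N, y = .data$prob_sim)) +
    geom_col(fill = "grey70") +
    labs(x = "number of founders N",
         y = sprintf("P(exactly %d haplotypes among founders)",
                     object$k_observed),
         subtitle = sprintf("most likely N = %d", object$mle_N)) +
    scale_x_continuous(breaks = d$N) +
    theme_minimal()
  if (all(is.finite(d$prob_exact))) {
    p <- p + geom_point(aes(y = .data$prob_exact), colour = "black")
  }
  p
}

#' Long-format view of a distance matrix
#'
#' @param x A `dist_matrix` (from [fst_matrix()], [chord_distance_matrix()]
#'   or [mito_diff_matrix()]).
#' @param ... Unused.
#' @return Tibble `pop_a`, `pop_b`, `value`, `kind` (lower triangle).
#' @exportS3Method generics::tidy
#' @export
tidy.dist_matrix <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  tibble(
    pop_a = labs[idx[, "row"]], pop_b = labs[idx[, "col"]],
    value = x[idx], kind = attr(x, "kind") %||% "distance"
  )
}
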