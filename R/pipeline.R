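#' Analysis run configuration
#'
#' Bundles the tunable parameters of [run_full_analysis()] with the
#' conventional defaults: rarefaction to 26 gene copies, 1000 bootstrap
#' pseudoreplicates, 100,000 mitochondrial trials, candidate founder grid
#' 2-40, the K and r sweep grids, and 10 generations since founding.
#'
#' @param rarefaction_genes Gene copies for rarefied richness.
#' @param bootstrap_reps NJ bootstrap pseudoreplicates.
#' @param permutation_reps FST permutation replicates per pair (0 skips
#'   the permutation tests).
#' @param mito_trials Monte Carlo trials for the mitochondrial estimator.
#' @param founder_grid Candidate founder numbers.
#' @param K_values,r_values,t Demographic sweep.
#' @param M Monte Carlo replicates per likelihood evaluation.
#' @param n_top_sources Number of top-ranked sources carried into founder
#'   estimation.
#' @param seed Integer seed controlling every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(rarefaction_genes = 26, bootstrap_reps = 1000,
                       permutation_reps = 0, mito_trials = 1e5,
                       founder_grid = 2:40,
                       K_values = c(500, 1000, 2000, 4000, 8000, 16000),
                       r_values = c(0.5, 1, 1.5, 2, 3),
                       t = 10, M = 1000, n_top_sources = 3, seed = 1) {
  cfg <- list(rarefaction_genes = rarefaction_genes,
              bootstrap_reps = bootstrap_reps,
              permutation_reps = permutation_reps,
              mito_trials = mito_trials, founder_grid = founder_grid,
              K_values = K_values, r_values = r_values, t = t, M = M,
              n_top_sources = n_top_sources, seed = seed)
  if (any(c(cfg$rarefaction_genes, cfg$bootstrap_reps, cfg$mito_trials,
            cfg$M, cfg$n_top_sources) <= 0)) {
    abort("run_config counts must be positive")
  }
  if (min(cfg$founder_grid) < 1) abort("founder_grid minimum must be >= 1")
  structure(cfg, class = "run_config")
}

#' Run the full invasion-genetics analysis
#'
#' Executes, in order: nuclear and mitochondrial diversity summaries, the
#' FST and mtDNA distance matrices (with optional permutation tests), the
#' bootstrap NJ tree, source ranking, and — for the top-ranked candidate
#' sources — the nuclear demographic sweep and the mitochondrial founder
#' estimate.  Stage failures are recorded and dependent stages skipped;
#' the run is a pure function of `(geno, hapset, introduced, config)`.
#'
#' @param geno A genotype tibble.
#' @param hapset Optional [haplotype_set()]; when `NULL` the
#'   mitochondrial stages are marked skipped.
#' @param introduced Label of the introduced population.
#' @param config A [run_config()].
#' @return An `analysis_report` list with elements `nuclear_diversity`,
#'   `mito_diversity`, `fst`, `fst_tests`, `mito_diff`, `tree`,
#'   `source_ranking`, `nuclear_founders`, `mito_founder`, `skipped`
#'   (named reasons) and `provenance`.
#' @export
run_full_analysis <- function(geno, hapset = NULL, introduced,
                              config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  geno <- genotype_table(geno)
  if (!introduced %in% levels(geno$pop)) {
    abort("introduced population not present in genotype table")
  }
  report <- list()
  skipped <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      skipped[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  set.seed(config$seed)

  report$nuclear_diversity <- run_stage("nuclear_diversity",
    nuclear_diversity(geno, g = config$rarefaction_genes))
  report$mito_diversity <- if (is.null(hapset)) {
    skipped$mito_diversity <- "no mtDNA input"
    NULL
  } else {
    run_stage("mito_diversity", mito_diversity_table(hapset))
  }

  report$fst <- run_stage("fst", fst_matrix(geno))
  report$mito_diff <- if (is.null(hapset)) {
    skipped$mito_diff <- "no mtDNA input"
    NULL
  } else {
    run_stage("mito_diff", mito_diff_matrix(hapset))
  }
  report$fst_tests <- if (config$permutation_reps >= 100) {
    run_stage("fst_tests", {
      src <- setdiff(levels(geno$pop), introduced)
      purrr::map(src, function(s) {
        fst_permutation_test(geno, s, introduced,
                             reps = config$permutation_reps) |>
          mutate(source = s, .before = 1)
      }) |> purrr::list_rbind()
    })
  } else {
    skipped$fst_tests <- "permutation_reps below 100; tests not run"
    NULL
  }
  report$tree <- run_stage("tree",
    neighbor_joining_tree(geno, reps = config$bootstrap_reps))

  report$source_ranking <- if (is.null(report$fst)) {
    skipped$source_ranking <- "FST stage failed"
    NULL
  } else {
    run_stage("source_ranking",
      assign_source(report$fst, introduced, mito = report$mito_diff))
  }

  top <- NULL
  if (!is.null(report$source_ranking)) {
    top <- utils::head(report$source_ranking$source, config$n_top_sources)
  }
  report$nuclear_founders <- if (is.null(top)) {
    skipped$nuclear_founders <- "no source ranking available"
    NULL
  } else {
    run_stage("nuclear_founders",
      demographic_sweep(geno, sources = top, introduced = introduced,
                        K_values = config$K_values, r_values = config$r_values,
                        t = config$t, grid = config$founder_grid,
                        M = config$M))
  }
  report$mito_founder <- if (is.null(hapset)) {
    skipped$mito_founder <- "no mtDNA input"
    NULL
  } else if (is.null(top)) {
    skipped$mito_founder <- "no source ranking available"
    NULL
  } else {
    run_stage("mito_founder", {
      k_obs <- nrow(hapset$counts[hapset$counts$pop == introduced, ])
      pool <- hapset$counts |>
        filter(.data$pop %in% top) |>
        select("haplotype", "count")
      mito_founder_estimate(pool, k_observed = k_obs,
                            trials = config$mito_trials)
    })
  }

  report$skipped <- skipped
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("founderflow")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    introduced = introduced,
    n_populations = nlevels(geno$pop),
    n_loci = nlevels(geno$locus),
    timestamp = NA_character_  # left unset: reports must be byte-reproducible
  )
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  done <- setdiff(names(x), c("skipped", "provenance"))
  for (s in done) {
    cat(sprintf("  %-18s %s\n", s,
                if (is.null(x[[s]])) paste0("SKIPPED: ", x$skipped[[s]] %||% "?")
                else class(x[[s]])[1]))
  }
  if (!is.null(x$source_ranking)) {
    cat("  top-ranked source:", x$source_ranking$source[1], "\n")
  }
  invisible(x)
}

#' Write an analysis report (or individual results) to disk
#'
#' Emits CSV for the diversity tables and source ranking, a combined
#' Table-1-style CSV (FST below the diagonal, mean mtDNA differences
#' above, blank diagonal), Newick for the bootstrap NJ tree, and JSON for
#' the founder estimates.  Every write is noted on the message stream.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_results <- function(report, outdir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, 2) != 0) abort(paste0("cannot write to ", outdir))
  paths <- list()
  put_csv <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE)
    ff_note("write_results: wrote ", f)
    f
  }
  if (!is.null(report$nuclear_diversity)) {
    paths$nuclear_diversity <- put_csv(report$nuclear_diversity,
                                       "nuclear_diversity.csv")
  }
  if (!is.null(report$mito_diversity)) {
    paths$mito_diversity <- put_csv(report$mito_diversity, "mito_diversity.csv")
  }
  if (!is.null(report$fst)) {
    paths$differentiation <- {
      f <- file.path(outdir, "differentiation_matrix.csv")
      utils::write.csv(combined_distance_table(report$fst, report$mito_diff), f,
                       row.names = TRUE)
      ff_note("write_results: wrote ", f)
      f
    }
  }
  if (!is.null(report$fst_tests)) {
    paths$fst_tests <- put_csv(report$fst_tests, "fst_permutation_tests.csv")
  }
  if (!is.null(report$source_ranking)) {
    paths$source_ranking <- put_csv(report$source_ranking, "source_ranking.csv")
  }
  if (!is.null(report$tree)) {
    f <- file.path(outdir, "nj_tree.nwk")
    ape::write.tree(report$tree, f)
    ff_note("write_results: wrote ", f)
    paths$tree <- f
  }
  if (!is.null(report$nuclear_founders)) {
    paths$nuclear_founders_csv <- put_csv(tidy(report$nuclear_founders),
                                          "nuclear_founder_sweep.csv")
    f <- file.path(outdir, "nuclear_founder_fits.json")
    fits <- purrr::keep(report$nuclear_founders$cells$fit,
                        ~ inherits(.x, "founder_fit"))
    jsonlite::write_json(lapply(fits, founder_fit_json), f,
                         auto_unbox = TRUE, digits = NA)
    ff_note("write_results: wrote ", f)
    paths$nuclear_founders_json <- f
  }
  if (!is.null(report$mito_founder)) {
    f <- file.path(outdir, "mito_founder.json")
    mf <- report$mito_founder
    jsonlite::write_json(
      list(curve = mf$curve, k_observed = mf$k_observed, mle_N = mf$mle_N,
           support = as.list(mf$support), trials = mf$trials,
           note = "counts female-equivalent founders (maternal inheritance)"),
      f, auto_unbox = TRUE, digits = NA)
    ff_note("write_results: wrote ", f)
    paths$mito_founder <- f
  }
  f <- file.path(outdir, "provenance.json")
  jsonlite::write_json(c(report$provenance, list(skipped = report$skipped)),
                       f, auto_unbox = TRUE, digits = NA)
  paths$provenance <- f
  invisible(paths)
}

# Table-1-style combined matrix: FST below diagonal, mtDNA mean pairwise
# differences above, blank diagonal
combined_distance_table <- function(fst, mito = NULL) {
  labs <- rownames(fst)
  out <- matrix("", length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i > j) out[i, j] <- format(fst[i, j], digits = 6)
      if (i < j && !is.null(mito)) out[i, j] <- format(mito[i, j], digits = 6)
    }
  }
  out
}

# JSON-serializable view of a founder_fit (round-trips via read_founder_json)
founder_fit_json <- function(fit) {
  list(source = fit$source, introduced = fit$introduced,
       K = fit$K, r = fit$r, t = fit$t, M = fit$M,
       grid = fit$grid, loglik = fit$loglik, mle = fit$mle,
       support = as.list(fit$support),
       excluded_loci = fit$excluded_loci)
}

#' Read back founder-fit JSON written by [write_results()]
#'
#' @param path Path to `nuclear_founder_fits.json`.
#' @return List of per-cell lists with `grid`, `loglik`, `mle`, `support`.
#' @export
read_founder_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
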