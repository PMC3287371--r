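#' Build or validate a genotype table
#'
#' The package represents diploid multi-locus genotypes as a long tibble
#' with one row per individual x locus: columns `pop` (factor, population),
#' `ind` (character, individual id, unique within the table), `locus`
#' (factor), and integer allele labels `allele_1`, `allele_2` (`NA` =
#' missing).  A genotype with either allele missing is treated as wholly
#' missing at that locus, the convention of FSTAT-style tooling.
#'
#' @param x A data frame with columns `pop`, `ind`, `locus`, `allele_1`,
#'   `allele_2`.  `pop`/`locus` may be character (factor levels are then
#'   taken in order of appearance).
#' @return A validated genotype tibble.
#' @examples
#' gt <- genotype_table(data.frame(
#'   pop = "A", ind = c("A_1", "A_2"), locus = "loc1",
#'   allele_1 = c(101L, 101L), allele_2 = c(103L, NA)
#' ))
#' allele_counts(gt)
#' @export
genotype_table <- function(x) {
  need <- c("pop", "ind", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("genotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[need]
  if (!is.factor(x$pop)) x$pop <- factor(x$pop, levels = unique(as.character(x$pop)))
  if (!is.factor(x$locus)) x$locus <- factor(x$locus, levels = unique(as.character(x$locus)))
  x$ind <- as.character(x$ind)
  x$allele_1 <- as.integer(x$allele_1)
  x$allele_2 <- as.integer(x$allele_2)
  miss <- is.na(x$allele_1) | is.na(x$allele_2)
  x$allele_1[miss] <- NA_integer_
  x$allele_2[miss] <- NA_integer_
  pop_per_ind <- tapply(as.character(x$pop), x$ind, function(p) length(unique(p)))
  if (any(pop_per_ind > 1)) {
    abort(paste0("individual(s) assigned to more than one population: ",
                 paste(names(pop_per_ind)[pop_per_ind > 1][1:3], collapse = ", ")))
  }
  x
}

#' Tabulate allele counts per population and locus
#'
#' Counts gene copies (two per non-missing genotype) for every allele,
#' the elementary statistic behind allele frequencies, rarefaction and
#' F-statistics.
#'
#' @param geno A genotype tibble (see [genotype_table()]).
#' @return A tibble with columns `pop`, `locus`, `allele`, `count`.
#' @export
allele_counts <- function(geno) {
  geno |>
    filter(!is.na(.data$allele_1)) |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    count(.data$pop, .data$locus, .data$allele, name = "count")
}

# per-population, per-locus gene counts (2 x non-missing genotypes)
gene_counts <- function(geno) {
  geno |>
    group_by(.data$pop, .data$locus) |>
    summarise(genes = 2L * sum(!is.na(.data$allele_1)), .groups = "drop")
}

# named allele-frequency vector for one pop x locus (counts / genes)
allele_freqs_one <- function(counts_tbl, population, locus_id) {
  sub <- counts_tbl[counts_tbl$pop == population & counts_tbl$locus == locus_id, ]
  if (!nrow(sub)) return(numeric(0))
  setNames(sub$count / sum(sub$count), as.character(sub$allele))
}

#' Read a Genepop genotype file
#'
#' Parses the classic Genepop dialect: a title line, one locus name per
#' line (or a single comma-separated line), populations opened by a line
#' reading `pop` (case-insensitive), and individuals as
#' `id ,  a1a2 a1a2 ...` with 2- or 3-digit allele codes (auto-detected;
#' mixing widths in one file is an error).  Allele code `00`/`000` marks a
#' missing allele; a genotype with any missing allele is recorded as
#' wholly missing.
#'
#' Genepop has no population-name field.  Population labels are recovered
#' as the prefix before the final underscore when all individual ids in a
#' population share one (the convention [write_genepop()] emits);
#' otherwise populations are labelled `pop1`, `pop2`, ...
#'
#' @param path Path to a Genepop file.
#' @return A genotype tibble (see [genotype_table()]).
#' @export
read_genepop <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) < 3) abort("not a Genepop file: fewer than 3 lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) {
    abort("not a Genepop file: no 'pop' delimiter after the locus list")
  }
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  loci <- loci[loci != ""]
  if (!length(loci)) abort("no locus names found")

  width <- NULL
  pop_i <- 0L
  ids <- character(0)
  pops <- integer(0)
  a1 <- list()
  a2 <- list()
  for (i in seq(first_pop, length(lines))) {
    line <- lines[i]
    if (trimws(line) == "") next
    if (is_pop[i]) {
      pop_i <- pop_i + 1L
      next
    }
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0) {
      abort(sprintf("line %d: expected 'id , genotypes'", i))
    }
    id <- trimws(substr(line, 1, comma - 1))
    gts <- strsplit(trimws(substring(line, comma + 1)), "\\s+")[[1]]
    if (length(gts) != length(loci)) {
      abort(sprintf("line %d: %d genotype(s) for %d loci",
                    i, length(gts), length(loci)))
    }
    w <- unique(nchar(gts))
    if (length(w) != 1 || !(w %in% c(4L, 6L))) {
      abort(sprintf("line %d: unrecognized allele-code width", i))
    }
    w <- w / 2L
    if (is.null(width)) {
      width <- w
    } else if (width != w) {
      abort(sprintf("line %d: mixed 2- and 3-digit allele codes", i))
    }
    x1 <- as.integer(substr(gts, 1L, width))
    x2 <- as.integer(substr(gts, width + 1L, 2L * width))
    if (anyNA(x1) || anyNA(x2)) {
      abort(sprintf("line %d: non-numeric allele code", i))
    }
    x1[x1 == 0L] <- NA_integer_
    x2[x2 == 0L] <- NA_integer_
    k <- length(ids) + 1L
    ids[k] <- id
    pops[k] <- pop_i
    a1[[k]] <- x1
    a2[[k]] <- x2
  }
  if (!length(ids)) abort("no individuals found")

  pop_labels <- vapply(seq_len(pop_i), function(p) {
    pid <- ids[pops == p]
    pref <- unique(sub("_[^_]*$", "", pid))
    if (length(pref) == 1 && nzchar(pref) && all(grepl("_", pid))) {
      pref
    } else {
      paste0("pop", p)
    }
  }, character(1))
  if (anyDuplicated(pop_labels)) {
    pop_labels <- paste0("pop", seq_len(pop_i))
  }
  ids <- make.unique(ids, sep = "_dup")

  nl <- length(loci)
  genotype_table(tibble(
    pop = factor(pop_labels[rep(pops, each = nl)], levels = pop_labels),
    ind = rep(ids, each = nl),
    locus = factor(rep(loci, length(ids)), levels = loci),
    allele_1 = unlist(a1),
    allele_2 = unlist(a2)
  ))
}

#' Write a genotype table as a Genepop file
#'
#' Allele code width (2 or 3 digits) is chosen from the largest allele
#' label.  Individual ids are written as `<pop>_<id>` unless they already
#' carry the population prefix, so [read_genepop()] recovers population
#' labels and the write/read round trip is the identity on generator
#' output.
#'
#' @param geno A genotype tibble.
#' @param path Output file path.
#' @param title Title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, path, title = "founderflow genotypes") {
  geno <- genotype_table(geno)
  max_allele <- suppressWarnings(max(c(geno$allele_1, geno$allele_2), na.rm = TRUE))
  if (!is.finite(max_allele)) max_allele <- 1L
  if (max_allele > 999L) abort("allele labels above 999 cannot be Genepop-encoded")
  digits <- if (max_allele > 99L) 3L else 2L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    sprintf(paste0("%0", digits, "d"), a)
  }
  loci <- levels(geno$locus)
  out <- c(title, loci)
  for (p in levels(geno$pop)) {
    out <- c(out, "pop")
    sub <- geno[geno$pop == p, ]
    for (id in unique(sub$ind)) {
      g <- sub[sub$ind == id, ]
      g <- g[match(loci, as.character(g$locus)), ]
      id_out <- if (identical(sub("_[^_]*$", "", id), p)) id else paste(p, id, sep = "_")
      out <- c(out, paste0(id_out, " ,  ",
                           paste0(fmt(g$allele_1), fmt(g$allele_2), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
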