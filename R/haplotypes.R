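#' Build a haplotype set
#'
#' Bundles aligned mtDNA haplotypes with their per-population counts and
#' the pairwise nucleotide-difference matrix used by the diversity and
#' founder-number estimators.
#'
#' @param sequences Named character vector of equal-length aligned
#'   sequences (names are haplotype ids), or a data frame with columns
#'   `haplotype`, `sequence`.
#' @param counts Data frame with columns `pop`, `haplotype`, `count`.
#' @return An object of class `haplotype_set`: a list with elements
#'   `haplotypes` (tibble: haplotype, sequence), `counts` (tibble: pop,
#'   haplotype, count), `diff` (integer matrix of pairwise nucleotide
#'   differences) and `L` (alignment length).
#' @export
haplotype_set <- function(sequences, counts) {
  if (is.data.frame(sequences)) {
    haps <- as_tibble(sequences)[c("haplotype", "sequence")]
  } else {
    if (is.null(names(sequences))) {
      names(sequences) <- sprintf("H%02d", seq_along(sequences))
    }
    haps <- tibble(haplotype = names(sequences), sequence = unname(sequences))
  }
  haps$haplotype <- as.character(haps$haplotype)
  if (anyDuplicated(haps$haplotype)) abort("duplicated haplotype ids")
  lens <- nchar(haps$sequence)
  if (length(unique(lens)) != 1) abort("sequences are not all the same length")
  L <- lens[1]

  counts <- as_tibble(counts)[c("pop", "haplotype", "count")]
  if (!is.factor(counts$pop)) {
    counts$pop <- factor(counts$pop, levels = unique(as.character(counts$pop)))
  }
  counts$haplotype <- as.character(counts$haplotype)
  counts$count <- as.integer(counts$count)
  bad <- setdiff(counts$haplotype, haps$haplotype)
  if (length(bad)) abort(paste0("counts refer to unknown haplotype(s): ",
                                paste(bad[1:min(3, length(bad))], collapse = ", ")))
  if (any(counts$count < 0)) abort("negative haplotype counts")
  counts <- counts[counts$count > 0, ]

  structure(
    list(haplotypes = haps, counts = counts,
         diff = hap_diff_matrix(setNames(haps$sequence, haps$haplotype)),
         L = L),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes, %d bp, %d population(s)\n",
              nrow(x$haplotypes), x$L, nlevels(x$counts$pop)))
  tot <- x$counts |> count(.data$pop, wt = .data$count, name = "n")
  print(tot, ...)
  invisible(x)
}

# pairwise Hamming distances between aligned sequences; any differing
# characters (including gaps/ambiguity codes) count as a mismatch
hap_diff_matrix <- function(sequences) {
  H <- length(sequences)
  m <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  d <- matrix(0L, H, H, dimnames = list(names(sequences), names(sequences)))
  if (H >= 2) {
    for (i in 1:(H - 1)) {
      for (j in (i + 1):H) {
        d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  d
}

# named count vector for one population, aligned to the haplotype set
hap_counts_one <- function(hapset, population) {
  sub <- hapset$counts[hapset$counts$pop == population, ]
  if (!nrow(sub)) abort(paste0("population not in haplotype set: ", population))
  setNames(sub$count, sub$haplotype)
}

#' Read aligned haplotype sequences from FASTA plus a population map
#'
#' Identical sequences are collapsed to a single haplotype (ids `H01`,
#' `H02`, ... in order of first appearance) and counted per population.
#' The popmap is a two-column whitespace/tab-delimited file
#' (`record_id  population`), no header.
#'
#' @param fasta Path to an aligned FASTA file (equal-length records).
#' @param popmap Path to the two-column population map.
#' @return A [haplotype_set()].
#' @export
read_fasta_haplotypes <- function(fasta, popmap) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  sq <- as.character(seqs)
  if (length(unique(nchar(sq))) != 1) {
    abort("FASTA records differ in length; input must be pre-aligned")
  }
  pm <- utils::read.table(popmap, header = FALSE, col.names = c("id", "pop"),
                          colClasses = "character")
  missing_ids <- setdiff(ids, pm$id)
  if (length(missing_ids)) {
    abort(paste0("FASTA record(s) without popmap entry: ",
                 paste(missing_ids[1:min(3, length(missing_ids))], collapse = ", ")))
  }
  pops <- pm$pop[match(ids, pm$id)]
  if (any(grepl("[^ACGTacgt]", sq))) {
    ff_note("read_fasta_haplotypes: sequences contain gap/ambiguity codes; ",
            "they count as mismatches against any other character")
  }
  uniq <- unique(sq)
  hap_id <- sprintf("H%02d", seq_along(uniq))
  counts <- tibble(pop = factor(pops, levels = unique(pops)),
                   haplotype = hap_id[match(sq, uniq)]) |>
    count(.data$pop, .data$haplotype, name = "count")
  haplotype_set(setNames(uniq, hap_id), counts)
}

#' Write a haplotype set as FASTA + popmap (one record per sampled copy)
#'
#' @param hapset A [haplotype_set()].
#' @param fasta,popmap Output paths.
#' @return Invisibly, a list with both paths.
#' @export
write_fasta_haplotypes <- function(hapset, fasta, popmap) {
  counts <- hapset$counts
  recs <- counts[rep(seq_len(nrow(counts)), counts$count), ]
  recs$id <- paste0(as.character(recs$pop), "_m", stats::ave(
    rep(1L, nrow(recs)), recs$pop, FUN = seq_along))
  seqs <- setNames(hapset$haplotypes$sequence, hapset$haplotypes$haplotype)
  out <- Biostrings::DNAStringSet(seqs[recs$haplotype])
  names(out) <- recs$id
  Biostrings::writeXStringSet(out, fasta)
  utils::write.table(recs[c("id", "pop")], popmap, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta, popmap = popmap))
}
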