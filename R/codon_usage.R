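# Codon-usage statistics and background-dataset curation.
#
# The central statistic is the 4-vector of within-family fractions of the
# four Ala codons (GCT, GCC, GCA, GCG): a lineage-level fingerprint of a
# gene's origin that separates the Ala-rich antifreeze genes of the four
# fish groups even though their encoded peptides look alike.

ALL_CODONS <- names(Biostrings::GENETIC_CODE)

#' Count in-frame codons of a coding sequence
#'
#' A trailing partial codon is trimmed before counting. Codons containing `N`
#' are excluded from the counts and from the total (only the ambiguous codons
#' are removed, not the whole sequence).
#'
#' @param cds nucleotide string read in frame from its first base.
#' @param id optional source identifier recorded in the table.
#' @return an object of class `codon_usage_table`: list with `counts`
#'   (named integer vector over the 64 codons), `n_codons` (sum of counts)
#'   and `source_ids`.
#' @export
count_codons <- function(cds, id = character()) {
  cds <- normalize_nt(cds, what = "CDS")
  extra <- nchar(cds) %% 3
  if (extra > 0) cds <- substr(cds, 1, nchar(cds) - extra)
  if (nchar(cds) < 3) {
    stop("frame error: no complete codon after trimming", call. = FALSE)
  }
  n <- nchar(cds) / 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  counts <- integer(length(ALL_CODONS))
  names(counts) <- ALL_CODONS
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts, n_codons = sum(counts),
                 source_ids = as.character(id)),
            class = "codon_usage_table")
}

#' Pool codon tables and compute the Ala codon profile
#'
#' Fractions are within the Ala synonymous family: pooled counts of GCT, GCC,
#' GCA, GCG divided by the pooled Ala total. Pooling is order-invariant.
#'
#' @param tables a single `codon_usage_table` or a list of them.
#' @return an object of class `ala_profile`: list with `fractions` (named
#'   numeric 4-vector over GCT, GCC, GCA, GCG) and `n_ala`. When no Ala codon
#'   is present, fractions are all zero and `n_ala` is 0.
#' @export
ala_profile <- function(tables) {
  if (inherits(tables, "codon_usage_table")) tables <- list(tables)
  stopifnot(length(tables) > 0,
            all(vapply(tables, inherits, TRUE, "codon_usage_table")))
  pooled <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  ala <- pooled[ALA_CODONS]
  n_ala <- sum(ala)
  fractions <- if (n_ala > 0) ala / n_ala else stats::setNames(
    numeric(4), ALA_CODONS)
  structure(list(fractions = fractions, n_ala = as.integer(n_ala)),
            class = "ala_profile")
}

#' @export
print.ala_profile <- function(x, ...) {
  cat(sprintf("<ala_profile> n_ala=%d  %s\n", x$n_ala,
              paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
                    collapse = "  ")))
  invisible(x)
}

#' GC content of a nucleotide string, in percent
#'
#' `N` bases are ignored; an all-`N` (or empty) input is an error because the
#' content is undefined.
#'
#' @param nt nucleotide string.
#' @return percent GC in `[0, 100]`.
#' @export
gc_content <- function(nt) {
  nt <- normalize_nt(nt)
  v <- s2c(nt)
  v <- v[v != "N"]
  if (length(v) == 0) {
    stop("undefined GC content: no unambiguous bases", call. = FALSE)
  }
  100 * sum(v %in% c("G", "C")) / length(v)
}

#' Total-variation distance between two Ala codon profiles
#'
#' `0.5 * sum(|p_i - q_i|)`: 0 iff the fraction vectors are equal, 1 for
#' profiles concentrated on different codons. Symmetric and satisfies the
#' triangle inequality.
#'
#' @param p,q [ala_profile()] objects with `n_ala > 0`.
#' @return distance in `[0, 1]`.
#' @export
profile_distance <- function(p, q) {
  stopifnot(inherits(p, "ala_profile"), inherits(q, "ala_profile"))
  if (p$n_ala == 0 || q$n_ala == 0) {
    stop("profile_distance undefined for an empty (n_ala = 0) profile",
         call. = FALSE)
  }
  0.5 * sum(abs(p$fractions - q$fractions))
}

#' Percent identity from a global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment at match +1, mismatch -1 and a
#' linear gap penalty of -2 per base; identity is 100 x matched columns /
#' alignment columns (gap columns, including end gaps, count).
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap alignment scores; `gap` is the per-base cost.
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- normalize_nt(a)
  b <- normalize_nt(b)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = -gap)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / ncol_aln
}

#' Curate a background (non-AFP) coding-sequence set
#'
#' Mirrors the dataset-curation rules used for codon-usage baselines: within
#' each species, whenever two coding sequences share more than
#' `identity_threshold` percent DNA identity only the longest is retained
#' (greedy by descending length, ties broken by lexicographic id), and
#' sequences shorter than `min_codons` codons are excluded. Trailing partial
#' codons are trimmed before all checks (the reading frame is anchored at the
#' annotated CDS start, so only the trailing end can carry a partial codon).
#'
#' @param seqs list of [annotated_seq()] records, each with coding regions.
#' @param identity_threshold percent identity above which two sequences are
#'   considered redundant (default 65).
#' @param min_codons minimum CDS length in codons (default 50).
#' @return the surviving records, in input order. Idempotent.
#' @export
curate_background <- function(seqs, identity_threshold = 65, min_codons = 50) {
  if (length(seqs) == 0) return(seqs)
  cds <- vapply(seqs, function(rec) {
    x <- coding_sequence(rec)
    extra <- nchar(x) %% 3
    if (extra > 0) x <- substr(x, 1, nchar(x) - extra)
    x
  }, "")
  ids <- vapply(seqs, `[[`, "", "id")
  species <- vapply(seqs, function(r) {
    if (is.na(r$species)) "" else r$species
  }, "")
  long_enough <- nchar(cds) / 3 >= min_codons
  keep <- logical(length(seqs))
  for (sp in unique(species)) {
    idx <- which(species == sp & long_enough)
    if (length(idx) == 0) next
    # longest first; lexicographically smallest id wins ties
    idx <- idx[order(-nchar(cds[idx]), ids[idx])]
    kept <- integer(0)
    for (i in idx) {
      redundant <- any(vapply(kept, function(j) {
        pairwise_identity(cds[i], cds[j]) > identity_threshold
      }, TRUE))
      if (!redundant) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  seqs[keep]
}

#' Long-format codon usage table
#'
#' One row per codon with its amino acid, count and fraction within the
#' codon's synonymous family (0 where the family is unobserved); the layout
#' used by the package's TSV outputs.
#'
#' @param tbl a `codon_usage_table` from [count_codons()].
#' @param group optional group label repeated on every row.
#' @return `data.frame` with columns `group`, `codon`, `amino_acid`, `count`,
#'   `fraction_within_family`.
#' @export
codon_usage_long <- function(tbl, group = NA_character_) {
  stopifnot(inherits(tbl, "codon_usage_table"))
  aa <- unname(Biostrings::GENETIC_CODE[ALL_CODONS])
  fam_tot <- stats::ave(as.numeric(tbl$counts), aa, FUN = sum)
  frac <- ifelse(fam_tot > 0, tbl$counts / fam_tot, 0)
  out <- data.frame(group = group, codon = ALL_CODONS, amino_acid = aa,
                    count = as.integer(tbl$counts),
                    fraction_within_family = unname(frac),
                    stringsAsFactors = FALSE)
  out[order(out$amino_acid, out$codon), , drop = FALSE]
}
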