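# Alternative-reading-frame analysis of trinucleotide codon runs.
#
# A tandem run of one codon encodes a homopolymer in frame 0, but the five
# other reading frames (two shifted sense, three antisense) of the same run
# encode different homopolymers. Runs of Ala codons can therefore arise from
# frameshifted or antisense reading of runs rich in other residues (Gly, Pro,
# Leu, ...), which is the mechanistic route by which poly-Ala coding sequence
# can be seeded from pre-existing repetitive DNA such as trinucleotide
# microsatellites.

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Amino acids encoded by a codon run in the five alternative frames
#'
#' Products are computed on an infinite tandem repeat of the codon (two
#' copies suffice for every shifted codon). Frame `+1` discards the first
#' base of the repeat; antisense frames are read from the 5' end of the
#' reverse complement, frame 0 first.
#'
#' @param codon a trinucleotide over `{A,C,G,T}`.
#' @return object of class `frame_products`: list with `codon`, `sense_alt`
#'   (amino acids of sense frames +1 and +2) and `antisense` (amino acids of
#'   antisense frames 0, +1, +2); stop codons appear as `"*"`.
#' @export
alt_frame_products <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon)) {
    stop("codon must be 3 unambiguous bases (ACGT): ", codon, call. = FALSE)
  }
  rep2 <- paste0(codon, codon)
  rc2 <- revcomp(rep2)
  structure(list(
    codon = codon,
    sense_alt = c(translate_codon(substr(rep2, 2, 4)),
                  translate_codon(substr(rep2, 3, 5))),
    antisense = c(translate_codon(substr(rc2, 1, 3)),
                  translate_codon(substr(rc2, 2, 4)),
                  translate_codon(substr(rc2, 3, 5)))),
    class = "frame_products")
}

#' @export
print.frame_products <- function(x, ...) {
  aa3 <- function(a) {
    nm <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
            E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
            M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
            Y = "Tyr", V = "Val", `*` = "Stop", X = "Xaa")
    unname(nm[a])
  }
  cat(sprintf("%s\t%s\t%s\n", x$codon,
              paste(aa3(x$sense_alt), collapse = "/"),
              paste(aa3(x$antisense), collapse = "/")))
  invisible(x)
}

#' Find maximal tandem runs of one codon
#'
#' Maximal, non-extendable tandem repeats of `codon` at any sequence offset;
#' overlapping runs in different phases are reported separately.
#'
#' @param nt nucleotide string.
#' @param codon trinucleotide to search for.
#' @param min_run minimum number of repeat units (>= 2; default 4, a typical
#'   microsatellite-reporting threshold).
#' @return `data.frame` with columns `codon`, `start` (0-based), `n_repeats`
#'   and `frame_of_ala` (the frames of the run that yield poly-Ala,
#'   comma-separated; `NA` if none).
#' @export
find_codon_runs <- function(nt, codon, min_run = 4L) {
  nt <- normalize_nt(nt)
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3, min_run >= 2)
  L <- nchar(nt)
  empty <- data.frame(codon = character(), start = integer(),
                      n_repeats = integer(), frame_of_ala = character(),
                      stringsAsFactors = FALSE)
  if (L < 3 * min_run) return(empty)
  v <- s2c(nt)
  cv <- s2c(codon)
  occ <- which(v[seq_len(L - 2)] == cv[1] &
                 v[seq_len(L - 2) + 1L] == cv[2] &
                 v[seq_len(L - 2) + 2L] == cv[3]) - 1L   # 0-based starts
  if (length(occ) == 0) return(empty)
  is_occ <- logical(L)
  is_occ[occ + 1L] <- TRUE
  prev_occ <- occ >= 3 & is_occ[pmax(occ - 3L, 0L) + 1L]
  starts <- occ[!prev_occ]
  runs <- lapply(starts, function(s) {
    n <- 1L
    while (s + 3L * n <= L - 3L && is_occ[s + 3L * n + 1L]) n <- n + 1L
    c(s, n)
  })
  runs <- do.call(rbind, runs)
  keep <- runs[, 2] >= min_run
  if (!any(keep)) return(empty)
  runs <- runs[keep, , drop = FALSE]
  data.frame(codon = codon, start = as.integer(runs[, 1]),
             n_repeats = as.integer(runs[, 2]),
             frame_of_ala = ala_frame_of(codon),
             stringsAsFactors = FALSE)
}

# which of the six frames of a tandem repeat of `codon` encodes poly-Ala
ala_frame_of <- function(codon) {
  rep2 <- paste0(codon, codon)
  rc2 <- revcomp(rep2)
  frames <- c("sense+0" = codon,
              "sense+1" = substr(rep2, 2, 4),
              "sense+2" = substr(rep2, 3, 5),
              "antisense+0" = substr(rc2, 1, 3),
              "antisense+1" = substr(rc2, 2, 4),
              "antisense+2" = substr(rc2, 3, 5))
  hit <- names(frames)[frames %in% ALA_CODONS]
  if (length(hit) > 0) paste(hit, collapse = ",") else NA_character_
}

#' Scan a sequence for segments with poly-Ala coding potential
#'
#' Reports every maximal segment that translates to at least `min_ala`
#' consecutive Ala residues in at least one of the six reading frames
#' (three sense, three antisense of the reverse complement). Coordinates are
#' on the input (sense) strand. Note a maximal tract may mix synonymous Ala
#' codons, so segments are reported with their frame rather than a single
#' seeding codon.
#'
#' @param nt nucleotide string.
#' @param min_ala minimum run of Ala residues (default 6).
#' @return `data.frame` with columns `start`, `end` (0-based half-open nt
#'   coordinates of the Ala codons), `frame` (`"sense+0"` ...
#'   `"antisense+2"`) and `n_ala`.
#' @export
poly_ala_potential <- function(nt, min_ala = 6L) {
  nt <- normalize_nt(nt)
  L <- nchar(nt)
  scan_strand <- function(x, strand) {
    out <- list()
    for (f in 0:2) {
      ncod <- (nchar(x) - f) %/% 3
      if (ncod < min_ala) next
      codons <- substring(x, f + 3 * seq_len(ncod) - 2, f + 3 * seq_len(ncod))
      is_ala <- codons %in% ALA_CODONS
      r <- rle(is_ala)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      sel <- which(r$values & r$lengths >= min_ala)
      for (s in sel) {
        nt_start <- f + 3L * (starts[s] - 1L)       # 0-based on x
        nt_end <- f + 3L * ends[s]
        out[[length(out) + 1L]] <- data.frame(
          start = nt_start, end = nt_end,
          frame = sprintf("%s+%d", strand, f),
          n_ala = r$lengths[s], stringsAsFactors = FALSE)
      }
    }
    out
  }
  res <- scan_strand(nt, "sense")
  anti <- scan_strand(revcomp(nt), "antisense")
  # map antisense coordinates back to the sense strand
  anti <- lapply(anti, function(d) {
    new_start <- L - d$end
    d$end <- L - d$start
    d$start <- new_start
    d
  })
  out <- do.call(rbind, c(res, anti))
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      frame = character(), n_ala = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
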