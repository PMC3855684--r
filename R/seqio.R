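# Sequence and region I/O.
#
# One coordinate convention holds package-wide: 0-based, half-open [start, end),
# on the sense strand. Antisense is always computed on the fly, never stored.

REGION_KINDS <- c("five_prime_utr", "signal_peptide", "propeptide",
                  "mature_cds", "intron", "three_prime_utr")
CODING_KINDS <- c("signal_peptide", "propeptide", "mature_cds")
ALA_CODONS <- c("GCT", "GCC", "GCA", "GCG")

# split a sequence string into a character vector of single letters
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character strings over `{A,C,G,T,N}`.
#'
#' @param nt nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Uppercase, map RNA U to T, and validate the alphabet.
normalize_nt <- function(nt, what = "sequence") {
  nt <- chartr("u", "U", toupper(nt))
  nt <- gsub("U", "T", nt, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", nt)
  if (nchar(bad) > 0) {
    stop(sprintf("invalid character(s) in %s: %s", what,
                 paste(unique(s2c(bad)), collapse = " ")), call. = FALSE)
  }
  nt
}

#' Construct a region table
#'
#' Regions are typed intervals on a sequence: UTRs, coding segments
#' (signal peptide, propeptide, mature CDS) and introns. Coordinates are
#' 0-based, half-open.
#'
#' @param kind character vector of region kinds; one of `five_prime_utr`,
#'   `signal_peptide`, `propeptide`, `mature_cds`, `intron`,
#'   `three_prime_utr`.
#' @param start,end integer vectors, 0-based start (inclusive) and end
#'   (exclusive).
#' @param note free-text annotation, recycled.
#' @return a `data.frame` with columns `kind`, `start`, `end`, `note`,
#'   sorted by `start`.
#' @export
regions_df <- function(kind = character(), start = integer(),
                       end = integer(), note = "") {
  df <- data.frame(kind = as.character(kind),
                   start = as.integer(start),
                   end = as.integer(end),
                   note = rep_len(as.character(note), length(kind)),
                   stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

# Validate a region table, optionally against a known sequence length.
validate_regions <- function(regions, seq_len = NULL, id = "?") {
  if (is.null(regions) || nrow(regions) == 0) {
    return(regions_df())
  }
  stopifnot(all(c("kind", "start", "end") %in% names(regions)))
  unknown <- setdiff(unique(regions$kind), REGION_KINDS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown region kind(s) for '%s': %s", id,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  bad <- regions$start < 0 | regions$start >= regions$end
  if (!is.null(seq_len)) {
    bad <- bad | regions$end > seq_len
  }
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid region range for '%s': %s [%d, %d)", id,
                 regions$kind[i], regions$start[i], regions$end[i]),
         call. = FALSE)
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  if (nrow(regions) > 1) {
    for (i in seq_len(nrow(regions) - 1)) {
      if (regions$end[i] > regions$start[i + 1]) {
        stop(sprintf(
          "overlapping regions for '%s': %s [%d, %d) and %s [%d, %d)", id,
          regions$kind[i], regions$start[i], regions$end[i],
          regions$kind[i + 1], regions$start[i + 1], regions$end[i + 1]),
          call. = FALSE)
      }
    }
  }
  if (!"note" %in% names(regions)) regions$note <- ""
  rownames(regions) <- NULL
  regions[, c("kind", "start", "end", "note")]
}

#' Construct an annotated nucleotide sequence record
#'
#' @param id record identifier.
#' @param seq nucleotide string over `{A,C,G,T,N}`; lowercase and RNA `U`
#'   are normalized.
#' @param regions optional region table from [regions_df()].
#' @param species free-text species name.
#' @param group lineage label used for grouped analyses (e.g. `"sculpin"`,
#'   `"flounder"`, `"cunner"`, `"snailfish"`, or `"other"`).
#' @param source provenance: an accession or `"synthetic"`.
#' @return an object of class `afp_seq`.
#' @export
annotated_seq <- function(id, seq, regions = NULL, species = NA_character_,
                          group = "other", source = "") {
  seq <- normalize_nt(seq, what = sprintf("sequence '%s'", id))
  if (nchar(seq) == 0) stop("empty sequence for '", id, "'", call. = FALSE)
  regions <- validate_regions(regions, seq_len = nchar(seq), id = id)
  structure(list(id = as.character(id), species = species, group = group,
                 seq = seq, regions = regions, source = source),
            class = "afp_seq")
}

#' @export
print.afp_seq <- function(x, ...) {
  cat(sprintf("<afp_seq> %s (%d nt, group=%s, source=%s)\n",
              x$id, nchar(x$seq), x$group, x$source))
  if (nrow(x$regions) > 0) {
    for (i in seq_len(nrow(x$regions))) {
      cat(sprintf("  %-16s [%d, %d)\n", x$regions$kind[i],
                  x$regions$start[i], x$regions$end[i]))
    }
  }
  invisible(x)
}

#' Read a FASTA file into annotated sequence records
#'
#' Headers are truncated at the first whitespace to form ids; record order is
#' preserved. `U` is mapped to `T` and lowercase is uppercased. Records start
#' with an empty region table; see [read_regions()] and [attach_regions()].
#'
#' @param path FASTA file path.
#' @param source provenance string stored on each record (defaults to the
#'   file name).
#' @return list of [annotated_seq()] records.
#' @export
read_fasta <- function(path, source = basename(path)) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) NULL)
  if (is.null(set) || length(set) == 0) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate id(s) in FASTA file: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  recs <- lapply(seq_along(set), function(i) {
    annotated_seq(ids[i], as.character(set[[i]]), source = source)
  })
  names(recs) <- ids
  recs
}

#' Read a BED-like region annotation file
#'
#' Expects a headerless 4-column TSV: `seq_id`, `start` (0-based), `end`
#' (exclusive), `kind`. Ranges and within-id overlaps are validated; sequence
#' lengths are checked later, when regions are attached to records.
#'
#' @param path TSV file path.
#' @return named list mapping sequence id to a region `data.frame`.
#' @export
read_regions <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  if (ncol(tab) < 4) stop("expected 4 columns: seq_id, start, end, kind",
                          call. = FALSE)
  names(tab)[1:4] <- c("seq_id", "start", "end", "kind")
  out <- lapply(split(tab, tab$seq_id), function(d) {
    validate_regions(regions_df(d$kind, d$start, d$end), id = d$seq_id[1])
  })
  out[unique(tab$seq_id)]
}

#' Write region annotations back to a BED-like TSV
#'
#' Inverse of [read_regions()]: re-reading the written file reproduces the
#' same region tables.
#'
#' @param region_map named list of region tables (id -> regions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(region_map, path) {
  rows <- do.call(rbind, lapply(names(region_map), function(id) {
    r <- region_map[[id]]
    if (nrow(r) == 0) return(NULL)
    data.frame(seq_id = id, start = r$start, end = r$end, kind = r$kind,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach region annotations to sequence records
#'
#' @param seqs list of [annotated_seq()] records.
#' @param region_map named list from [read_regions()].
#' @return the records with regions validated against each sequence length.
#' @export
attach_regions <- function(seqs, region_map) {
  missing <- setdiff(names(region_map), vapply(seqs, `[[`, "", "id"))
  if (length(missing) > 0) {
    stop("regions refer to unknown sequence id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seqs, function(rec) {
    r <- region_map[[rec$id]]
    if (!is.null(r)) {
      rec$regions <- validate_regions(r, seq_len = nchar(rec$seq), id = rec$id)
    }
    rec
  })
}

#' Extract the concatenated sequence of all regions of one kind
#'
#' Regions of the requested kind are concatenated in coordinate order, so an
#' intron-split CDS comes back spliced.
#'
#' @param rec an [annotated_seq()] record.
#' @param kind region kind to extract.
#' @return nucleotide string.
#' @export
extract_region <- function(rec, kind) {
  kind <- match.arg(kind, REGION_KINDS)
  r <- rec$regions[rec$regions$kind == kind, , drop = FALSE]
  if (nrow(r) == 0) {
    stop(sprintf("region absent: '%s' has no %s region", rec$id, kind),
         call. = FALSE)
  }
  paste(substring(rec$seq, r$start + 1, r$end), collapse = "")
}

#' Concatenated coding sequence of a record
#'
#' Joins signal peptide, propeptide and mature CDS regions, in that order of
#' kinds and in coordinate order within each kind. This is the "full CDS"
#' used by the codon-usage analyses.
#'
#' @param rec an [annotated_seq()] record.
#' @return nucleotide string.
#' @export
coding_sequence <- function(rec) {
  present <- intersect(CODING_KINDS, unique(rec$regions$kind))
  if (length(present) == 0) {
    stop(sprintf("region absent: '%s' has no coding regions", rec$id),
         call. = FALSE)
  }
  paste(vapply(present, function(k) extract_region(rec, k), ""), collapse = "")
}

#' Construct a protein record
#'
#' @param id identifier.
#' @param seq amino-acid string (20 standard letters plus `X`); internal stop
#'   symbols are rejected.
#' @param provenance `"translated"` or `"direct"`.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, seq, provenance = c("direct", "translated")) {
  provenance <- match.arg(provenance)
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("empty protein sequence", call. = FALSE)
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", seq)
  if (nchar(bad) > 0) {
    stop("invalid amino-acid letter(s): ", paste(unique(s2c(bad)),
                                                 collapse = " "),
         call. = FALSE)
  }
  structure(list(id = as.character(id), seq = seq, provenance = provenance),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa, %s)\n%s\n",
              x$id, nchar(x$seq), x$provenance, x$seq))
  invisible(x)
}

#' Translate a coding sequence (standard genetic code)
#'
#' Codons containing `N` translate to `X`. A trailing stop codon is stripped;
#' an internal stop is an error reporting the codon position (1-based).
#'
#' @param cds in-frame nucleotide string, length divisible by 3.
#' @param id identifier for the resulting protein record.
#' @return a [protein_record()] with provenance `"translated"`.
#' @export
translate_cds <- function(cds, id = "translated") {
  cds <- normalize_nt(cds, what = "CDS")
  if (nchar(cds) %% 3 != 0) {
    stop(sprintf("frame error: CDS length %d is not divisible by 3",
                 nchar(cds)), call. = FALSE)
  }
  n <- nchar(cds) / 3
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[grepl("N", codons, fixed = TRUE)] <- "X"
  stops <- which(aa == "*")
  if (length(stops) > 0 && any(stops < n)) {
    stop(sprintf("premature stop codon at codon %d", min(stops[stops < n])),
         call. = FALSE)
  }
  if (length(stops) > 0) aa <- aa[-n]
  if (length(aa) == 0) stop("CDS encodes nothing but a stop codon",
                            call. = FALSE)
  protein_record(id, paste(aa, collapse = ""), "translated")
}

#' Translate the annotated coding regions of a record
#'
#' @param rec an [annotated_seq()] record with coding regions.
#' @param mature_only translate only the `mature_cds` region (default uses the
#'   full coding sequence: signal peptide + propeptide + mature CDS).
#' @return a [protein_record()].
#' @export
translate_record <- function(rec, mature_only = FALSE) {
  cds <- if (mature_only) extract_region(rec, "mature_cds") else
    coding_sequence(rec)
  translate_cds(cds, id = rec$id)
}
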