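# Helical / ice-binding feature annotation for Ala-rich antifreeze peptides.
#
# The short type I antifreeze proteins share a characteristic architecture:
# an 11-residue repeat with Thr at position i and Ala at i+4 and i+8 on the
# ice-binding face; i/i+4 acid-base pairs forming helix-stabilizing salt
# bridges off that face; an N-terminal acidic residue plus a nearby Pro/Gly
# capping the helix; and Pro/Gly otherwise confined to the termini. These
# scanners make each of those observations computable. Positions are 0-based
# in all machine output.

#' Alanine mole percent of a peptide
#'
#' `100 * #Ala / length`, the length counting every residue including the
#' initiator Met.
#'
#' @param p a [protein_record()].
#' @return percent in `[0, 100]`.
#' @export
ala_mol_percent <- function(p) {
  stopifnot(inherits(p, "protein_record"))
  v <- s2c(p$seq)
  100 * sum(v == "A") / length(v)
}

#' Best-phase Thr periodicity of a peptide
#'
#' For each phase `phi` in `[0, period)`, the slots are positions congruent
#' to `phi` modulo `period`; hits are slots holding Thr, and substitute hits
#' are slots holding an allowed substitute (Ile/Leu by default, the
#' replacements seen in naturally occurring isoforms). The best phase
#' maximizes hits + substitute hits, ties going to the smallest phase.
#'
#' @param p a [protein_record()] of length >= `period`.
#' @param period repeat length in residues (default 11).
#' @param allowed_substitutes residues counting as substitute hits.
#' @return list with `best_phase`, `n_hits`, `n_substitute`, `n_slots` and
#'   `score` (= `n_hits / n_slots` at the best phase; substitutes are not
#'   hits for the score).
#' @export
thr_periodicity <- function(p, period = 11L, allowed_substitutes = c("I", "L")) {
  stopifnot(inherits(p, "protein_record"))
  v <- s2c(p$seq)
  period <- as.integer(period)
  stopifnot(length(v) >= period)
  pos <- seq_along(v) - 1L
  best <- NULL
  for (phi in 0:(period - 1L)) {
    slots <- which(pos %% period == phi)
    hits <- sum(v[slots] == "T")
    subs <- sum(v[slots] %in% allowed_substitutes)
    cand <- list(best_phase = phi, n_hits = hits, n_substitute = subs,
                 n_slots = length(slots),
                 score = if (length(slots) > 0) hits / length(slots) else 0)
    if (is.null(best) || hits + subs > best$n_hits + best$n_substitute) {
      best <- cand
    }
  }
  best
}

#' Ice-binding i, i+4, i+8 triplets
#'
#' Emits `(i, i+4, i+8)` for every Thr at position `i` (0-based) whose
#' `i+4` and `i+8` residues are both Ala or Thr — the residues of the
#' ice-binding face of the 11-residue repeat. Ile/Leu substitutes at Thr
#' slots do not anchor triplets.
#'
#' @param p a [protein_record()].
#' @param period kept for interface symmetry; the triplet geometry itself is
#'   fixed at i, i+4, i+8.
#' @return `data.frame` with columns `i`, `i4`, `i8` (0-based positions).
#' @export
ice_binding_triplets <- function(p, period = 11L) {
  stopifnot(inherits(p, "protein_record"))
  v <- s2c(p$seq)
  i <- which(v == "T")
  i <- i[i + 8 <= length(v)]
  ok <- v[i + 4] %in% c("A", "T") & v[i + 8] %in% c("A", "T")
  i <- i[ok] - 1L
  data.frame(i = i, i4 = i + 4L, i8 = i + 8L)
}

#' i, i+4 salt bridge pairs
#'
#' All position pairs `(x, x+4)` where one residue is acidic (Asp/Glu) and
#' the other basic (Lys/Arg) — the separation most effective at stabilizing
#' an alpha helix. Overlapping pairs are all reported.
#'
#' @param p a [protein_record()].
#' @return `data.frame` with columns `pos1`, `pos2` (0-based, `pos2 = pos1+4`)
#'   and `orientation` (`"acid-first"` or `"base-first"`).
#' @export
salt_bridges <- function(p) {
  stopifnot(inherits(p, "protein_record"))
  v <- s2c(p$seq)
  acid <- v %in% c("D", "E")
  base <- v %in% c("K", "R")
  n <- length(v)
  if (n <= 4) {
    return(data.frame(pos1 = integer(), pos2 = integer(),
                      orientation = character()))
  }
  x <- seq_len(n - 4)
  af <- acid[x] & base[x + 4]
  bf <- base[x] & acid[x + 4]
  sel <- which(af | bf)
  data.frame(pos1 = sel - 1L, pos2 = sel + 3L,
             orientation = ifelse(af[sel], "acid-first", "base-first"),
             stringsAsFactors = FALSE)
}

#' N-terminal helix cap features
#'
#' Finds the first acidic residue (Asp/Glu) within `acid_window` residues
#' after the initiator Met (or from residue 0 when the peptide does not start
#' with Met), and the first Pro/Gly within `pg_window` residues — the
#' acid + Pro/Gly arrangement that caps the helix start and its dipole.
#'
#' @param p a [protein_record()].
#' @param acid_window,pg_window search window lengths in residues.
#' @return list with `acidic_pos` and `pg_pos` (0-based, or `NA` when
#'   absent).
#' @export
n_cap <- function(p, acid_window = 3L, pg_window = 8L) {
  stopifnot(inherits(p, "protein_record"))
  v <- s2c(p$seq)
  offset <- if (v[1] == "M") 1L else 0L
  first_in <- function(window, set) {
    if (offset > length(v) - 1L) return(NA_integer_)
    rng <- seq.int(offset, min(offset + window - 1L, length(v) - 1L))
    hit <- rng[v[rng + 1L] %in% set]
    if (length(hit) > 0) hit[1] else NA_integer_
  }
  list(acidic_pos = first_in(acid_window, c("D", "E")),
       pg_pos = first_in(pg_window, c("P", "G")))
}

#' Internal helix-breaking residues
#'
#' Positions of Pro/Gly away from both termini (`margin <= pos <
#' length - margin`). In the canonical short isoforms these are absent;
#' their presence marks the atypical, longer peptides.
#'
#' @param p a [protein_record()] with `length > 2 * margin`.
#' @param margin number of terminal residues exempted on each end.
#' @return integer vector of 0-based positions.
#' @export
internal_breakers <- function(p, margin = 5L) {
  stopifnot(inherits(p, "protein_record"))
  v <- s2c(p$seq)
  margin <- as.integer(margin)
  if (length(v) <= 2 * margin) {
    stop(sprintf("sequence too short (%d aa) for margin %d",
                 length(v), margin), call. = FALSE)
  }
  pos <- which(v %in% c("P", "G")) - 1L
  pos[pos >= margin & pos < length(v) - margin]
}

#' Full helix/ice-binding feature report for one peptide
#'
#' @param p a [protein_record()].
#' @param period repeat period for [thr_periodicity()].
#' @param margin terminal margin for [internal_breakers()]; reported as
#'   `NA` when the peptide is too short for the margin.
#' @return object of class `helix_feature_report`.
#' @export
helix_feature_report <- function(p, period = 11L, margin = 5L) {
  per <- thr_periodicity(p, period)
  brk <- tryCatch(internal_breakers(p, margin), error = function(e) NA)
  structure(list(id = p$id,
                 length = nchar(p$seq),
                 ala_mol_percent = ala_mol_percent(p),
                 thr_period = per,
                 motif_triplets = ice_binding_triplets(p, period),
                 salt_bridges = salt_bridges(p),
                 n_cap = n_cap(p),
                 internal_breakers = brk,
                 n_thr_substitutions = per$n_substitute),
            class = "helix_feature_report")
}

#' @export
print.helix_feature_report <- function(x, ...) {
  # human-readable text uses 1-based positions
  cat(sprintf("<helix_feature_report> %s: %d aa, %.1f mol%% Ala\n",
              x$id, x$length, x$ala_mol_percent))
  cat(sprintf("  period-11 phase %d: %d/%d Thr slots (score %.2f), %d substituted\n",
              x$thr_period$best_phase + 1L, x$thr_period$n_hits,
              x$thr_period$n_slots, x$thr_period$score,
              x$n_thr_substitutions))
  cat(sprintf("  %d ice-binding triplet(s), %d i/i+4 salt bridge(s)\n",
              nrow(x$motif_triplets), nrow(x$salt_bridges)))
  cap <- x$n_cap
  cat(sprintf("  N-cap: acidic %s, Pro/Gly %s; internal breakers: %s\n",
              if (is.na(cap$acidic_pos)) "none" else cap$acidic_pos + 1L,
              if (is.na(cap$pg_pos)) "none" else cap$pg_pos + 1L,
              if (length(x$internal_breakers) == 0) "none" else
                paste(x$internal_breakers + 1L, collapse = ",")))
  invisible(x)
}

#' Feature table for a set of peptides
#'
#' One row per record; list-valued fields are JSON-encoded so the table
#' round-trips through TSV.
#'
#' @param proteins list of [protein_record()] objects.
#' @return `data.frame`.
#' @export
features_table <- function(proteins) {
  rows <- lapply(proteins, function(p) {
    r <- helix_feature_report(p)
    data.frame(
      id = r$id, length = r$length, ala_mol_percent = r$ala_mol_percent,
      best_phase = r$thr_period$best_phase,
      period_score = r$thr_period$score,
      n_thr_substitutions = r$n_thr_substitutions,
      n_triplets = nrow(r$motif_triplets),
      triplets = as.character(jsonlite::toJSON(r$motif_triplets$i)),
      n_salt_bridges = nrow(r$salt_bridges),
      salt_bridges = as.character(jsonlite::toJSON(r$salt_bridges$pos1)),
      n_cap_acidic = r$n_cap$acidic_pos,
      n_cap_pg = r$n_cap$pg_pos,
      internal_breakers = as.character(jsonlite::toJSON(
        if (all(is.na(r$internal_breakers))) integer() else
          r$internal_breakers)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
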