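# Synthetic AFP-like gene families.
#
# The generator emulates the statistical structure the analyses rely on:
# Ala-rich mature peptides built from 11-residue Thr-faced repeats with an
# N-cap and an i/i+4 salt bridge; species-level Ala codon bias as the only
# deliberate codon signal (all other residues use uniform synonymous
# codons); paralog families descending from one ancestor whose 5' UTRs stay
# highly conserved while 3' UTRs accumulate indels and repeat-length
# variation; coding regions expanding and contracting in whole 33-nt repeat
# units; and GCC-leaning background gene sets. Every stochastic step is
# driven by the config seed and logged, so each paralog can be replayed
# byte-exactly from the ancestor.

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

SYN_CODONS <- split(names(Biostrings::GENETIC_CODE),
                    unname(Biostrings::GENETIC_CODE))

#' Configuration for the synthetic gene-family generator
#'
#' Defaults describe a sculpin-like family: GCG-dominant Ala codon usage,
#' a conserved 5' UTR (rarely hit by indels) and an indel-prone 3' UTR
#' carrying a GT microsatellite, with coding-region copy-number change in
#' whole 33-nt repeat units.
#'
#' @param seed integer seed driving all randomness.
#' @param n_repeats number of 11-residue repeats per mature peptide.
#' @param ala_bias length-4 probability vector over (GCT, GCC, GCA, GCG)
#'   for Ala codons of the AFP coding sequence.
#' @param background_bias Ala codon bias of background (non-AFP) genes;
#'   GCC-leaning by default.
#' @param utr5_len,utr3_len UTR lengths in nt (`utr5_len >= 20`).
#' @param point_mut_rate per-site substitution probability per paralog.
#' @param indel_rate expected indel events per 3' UTR per paralog.
#' @param utr5_indel_rate expected indel events per 5' UTR per paralog.
#' @param indel_len_range integer `(min, max)` indel length in nt.
#' @param repeat_cnv_prob probability that a paralog gains or loses one
#'   whole 33-nt repeat unit.
#' @param n_paralogs paralogs per family.
#' @param thr_sub_rate probability that a Thr slot carries an Ile/Leu
#'   substitute instead.
#' @param filler_sub_rate per-position probability of a non-Ala residue at
#'   the non-face, non-Thr positions of repeats after the first.
#' @param scenario `"homologous"` (one family from one ancestor) or
#'   `"convergent"` (independent groups).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_repeats = 3L,
                             ala_bias = c(GCT = 0.10, GCC = 0.10,
                                          GCA = 0.26, GCG = 0.54),
                             background_bias = c(GCT = 0.30, GCC = 0.38,
                                                 GCA = 0.18, GCG = 0.14),
                             utr5_len = 120L,
                             utr3_len = 350L,
                             point_mut_rate = 0.01,
                             indel_rate = 1.2,
                             utr5_indel_rate = 0.15,
                             indel_len_range = c(1L, 8L),
                             repeat_cnv_prob = 0.3,
                             n_paralogs = 6L,
                             thr_sub_rate = 0.05,
                             filler_sub_rate = 0.08,
                             scenario = c("homologous", "convergent")) {
  scenario <- match.arg(scenario)
  stopifnot(n_repeats >= 1, utr5_len >= 20, utr3_len >= 30,
            length(ala_bias) == 4, length(background_bias) == 4,
            abs(sum(ala_bias) - 1) < 1e-9,
            abs(sum(background_bias) - 1) < 1e-9,
            all(ala_bias >= 0), all(background_bias >= 0),
            point_mut_rate >= 0, point_mut_rate <= 1,
            indel_rate >= 0, utr5_indel_rate >= 0,
            length(indel_len_range) == 2,
            indel_len_range[1] >= 1,
            indel_len_range[1] <= indel_len_range[2],
            repeat_cnv_prob >= 0, repeat_cnv_prob <= 1,
            n_paralogs >= 1, thr_sub_rate >= 0, thr_sub_rate <= 1,
            filler_sub_rate >= 0, filler_sub_rate <= 1)
  names(ala_bias) <- ALA_CODONS
  names(background_bias) <- ALA_CODONS
  structure(list(seed = as.integer(seed), n_repeats = as.integer(n_repeats),
                 ala_bias = ala_bias, background_bias = background_bias,
                 utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len),
                 point_mut_rate = point_mut_rate, indel_rate = indel_rate,
                 utr5_indel_rate = utr5_indel_rate,
                 indel_len_range = as.integer(indel_len_range),
                 repeat_cnv_prob = repeat_cnv_prob,
                 n_paralogs = as.integer(n_paralogs),
                 thr_sub_rate = thr_sub_rate,
                 filler_sub_rate = filler_sub_rate,
                 scenario = scenario),
            class = "synthetic_config")
}

PEPTIDE_PREFIX <- c("M", "D", "A", "P", "A")
REPEAT_PHASE <- 5L   # Thr slots sit at positions 5, 16, 27, ... (0-based)
FILLER_RESIDUES <- c("S", "N", "K", "E", "D", "V")

# draws from the current RNG stream
.make_mature_peptide <- function(cfg) {
  reps <- lapply(seq_len(cfg$n_repeats), function(k) {
    r <- rep("A", 11)
    r[1] <- if (stats::runif(1) < cfg$thr_sub_rate)
      sample(c("I", "L"), 1) else "T"
    if (k == 1) {
      r[3] <- "E"       # i/i+4 salt bridge off the Thr face
      r[7] <- "K"
    } else {
      # offsets 4 and 8 (the i+4/i+8 face) stay Ala; cap at 2 substitutions
      cand <- c(2, 3, 4, 6, 7, 8, 10, 11)
      hit <- cand[stats::runif(length(cand)) < cfg$filler_sub_rate]
      if (length(hit) > 2) hit <- sample(hit, 2)
      for (x in hit) r[x] <- sample(FILLER_RESIDUES, 1)
    }
    r
  })
  protein_record("synthetic_peptide",
                 paste(c(PEPTIDE_PREFIX, unlist(reps)), collapse = ""),
                 "direct")
}

#' Generate one synthetic mature AFP-like peptide
#'
#' `MDAPA`-capped peptide of `n_repeats` 11-residue repeats with Thr slots
#' in a fixed phase, an i/i+4 Glu-Lys salt bridge off the Thr face and
#' Ala-dominated filler; Ala mole percent is above 50 by construction.
#'
#' @param cfg a [synthetic_config()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return a [protein_record()] with attribute `repeat_phase`.
#' @export
make_mature_peptide <- function(cfg, seed = cfg$seed) {
  p <- with_seed(seed, .make_mature_peptide(cfg))
  attr(p, "repeat_phase") <- REPEAT_PHASE
  p
}

.back_translate <- function(aa_seq, ala_bias) {
  v <- s2c(aa_seq)
  codons <- vapply(v, function(a) {
    if (a == "A") sample(ALA_CODONS, 1, prob = ala_bias)
    else {
      syn <- SYN_CODONS[[a]]
      if (is.null(syn)) stop("cannot back-translate residue: ", a,
                             call. = FALSE)
      if (length(syn) == 1) syn else sample(syn, 1)
    }
  }, "")
  paste(codons, collapse = "")
}

#' Back-translate a peptide with a chosen Ala codon bias
#'
#' Ala codons are drawn from `ala_bias`; every other residue draws uniformly
#' among its synonymous codons, so the Ala profile is the only deliberate
#' codon signal.
#'
#' @param p a [protein_record()] (or plain amino-acid string).
#' @param ala_bias length-4 probability vector over (GCT, GCC, GCA, GCG).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return nucleotide string with `translate_cds(.)` equal to the input.
#' @export
back_translate <- function(p, ala_bias, seed = NULL) {
  aa <- if (inherits(p, "protein_record")) p$seq else toupper(p)
  stopifnot(length(ala_bias) == 4, abs(sum(ala_bias) - 1) < 1e-9)
  if (is.null(seed)) .back_translate(aa, ala_bias)
  else with_seed(seed, .back_translate(aa, ala_bias))
}

.random_bases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# ---- event machinery -------------------------------------------------------

# state: list(seq = string, regions = data.frame)
apply_event <- function(state, ev) {
  L <- nchar(state$seq)
  r <- state$regions
  if (ev$op == "sub") {
    substr(state$seq, ev$pos + 1, ev$pos + 1) <- ev$alt
  } else if (ev$op == "ins") {
    len <- nchar(ev$seq)
    state$seq <- paste0(substr(state$seq, 1, ev$pos), ev$seq,
                        substr(state$seq, ev$pos + 1, L))
    grow <- r$start < ev$pos & ev$pos < r$end
    r$end[grow] <- r$end[grow] + len
    shift <- r$start >= ev$pos & !grow
    r$start[shift] <- r$start[shift] + len
    r$end[shift] <- r$end[shift] + len
    state$regions <- r
  } else if (ev$op == "del") {
    # deletions are always placed fully inside one region
    state$seq <- paste0(substr(state$seq, 1, ev$pos),
                        substr(state$seq, ev$pos + ev$len + 1, L))
    inside <- r$start <= ev$pos & ev$pos + ev$len <= r$end
    r$end[inside] <- r$end[inside] - ev$len
    after <- r$start >= ev$pos + ev$len
    r$start[after] <- r$start[after] - ev$len
    r$end[after] <- r$end[after] - ev$len
    state$regions <- r
  } else {
    stop("unknown event op: ", ev$op)
  }
  state
}

region_bounds <- function(state, kind) {
  r <- state$regions[state$regions$kind == kind, , drop = FALSE]
  if (nrow(r) == 0) NULL else c(r$start[1], r$end[1])
}

.make_ancestor <- function(cfg) {
  pep <- .make_mature_peptide(cfg)
  cds <- paste0(.back_translate(pep$seq, cfg$ala_bias), "TAA")
  gc5 <- stats::runif(1, 0.37, 0.44)
  gc3 <- stats::runif(1, 0.37, 0.44)
  utr5 <- paste(.random_bases(cfg$utr5_len, gc5), collapse = "")
  # shared in-frame stop 15 nt upstream of the start codon
  substr(utr5, cfg$utr5_len - 14, cfg$utr5_len - 12) <- "TAA"
  core <- .random_bases(cfg$utr3_len - 20, gc3)
  mid <- length(core) %/% 2
  utr3 <- paste(c(core[seq_len(mid)], rep(c("G", "T"), 10),
                  core[(mid + 1):length(core)]), collapse = "")
  seq <- paste0(utr5, cds, utr3)
  u5 <- cfg$utr5_len
  nc <- nchar(cds)
  regions <- regions_df(
    kind = c("five_prime_utr", "mature_cds", "three_prime_utr"),
    start = c(0L, u5, u5 + nc),
    end = c(u5, u5 + nc, nchar(seq)))
  list(seq = seq, regions = regions, peptide = pep)
}

# mutate one paralog, drawing from the current RNG stream; returns the new
# state plus the ordered event log that reproduces it
.mutate_paralog <- function(anc, cfg) {
  state <- list(seq = anc$seq, regions = anc$regions)
  events <- list()
  push <- function(ev) {
    events[[length(events) + 1L]] <<- ev
    state <<- apply_event(state, ev)
  }
  # 1. repeat copy-number change, in whole 33-nt units
  if (stats::runif(1) < cfg$repeat_cnv_prob) {
    cds <- region_bounds(state, "mature_cds")
    block0 <- cds[1] + 3L * length(PEPTIDE_PREFIX)
    k <- sample.int(cfg$n_repeats, 1) - 1L
    gain <- cfg$n_repeats == 1 || stats::runif(1) < 0.5
    if (gain) {
      unit <- substr(state$seq, block0 + 33L * k + 1L, block0 + 33L * (k + 1L))
      push(list(op = "ins", pos = block0 + 33L * (k + 1L), seq = unit))
    } else {
      push(list(op = "del", pos = block0 + 33L * k, len = 33L))
    }
  }
  # 2. point substitutions; CDS hits that would create an in-frame stop are
  #    skipped (purifying selection keeps every paralog translatable)
  L <- nchar(state$seq)
  hits <- which(stats::runif(L) < cfg$point_mut_rate) - 1L
  cds <- region_bounds(state, "mature_cds")
  for (pos in hits) {
    ref <- substr(state$seq, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    in_cds <- pos >= cds[1] && pos < cds[2] - 3L   # last codon is the stop
    if (in_cds) {
      c0 <- cds[1] + 3L * ((pos - cds[1]) %/% 3L)
      codon <- substr(state$seq, c0 + 1, c0 + 3)
      substr(codon, pos - c0 + 1, pos - c0 + 1) <- alt
      if (codon %in% c("TAA", "TAG", "TGA")) next
    }
    push(list(op = "sub", pos = pos, alt = alt))
  }
  # 3. UTR indels (the 3' UTR is far more indel-prone than the 5' UTR)
  for (utr in c("five_prime_utr", "three_prime_utr")) {
    rate <- if (utr == "five_prime_utr") cfg$utr5_indel_rate else
      cfg$indel_rate
    n_ev <- stats::rpois(1, rate)
    for (e in seq_len(n_ev)) {
      b <- region_bounds(state, utr)
      len <- sample(seq(cfg$indel_len_range[1], cfg$indel_len_range[2]), 1)
      if (stats::runif(1) < 0.5) {
        pos <- sample(seq(b[1] + 1L, b[2] - 1L), 1)
        push(list(op = "ins", pos = pos,
                  seq = paste(.random_bases(len), collapse = "")))
      } else if (b[2] - b[1] > len + 2L) {
        pos <- sample(seq(b[1] + 1L, b[2] - len - 1L), 1)
        push(list(op = "del", pos = pos, len = len))
      }
    }
  }
  list(state = state, events = events)
}

#' Simulate a homologous AFP-like paralog family
#'
#' One ancestral gene (5' UTR + CDS + 3' UTR, UTR GC content drawn uniformly
#' from 37-44%) gives rise to `n_paralogs` descendants, each receiving a
#' possible whole-repeat copy-number change, point substitutions and UTR
#' indels. Region annotations track every event, and the per-paralog event
#' log replays to the paralog byte-exactly (see [replay_family()]).
#'
#' @param cfg a [synthetic_config()] with `scenario = "homologous"`.
#' @param group group label stamped on each record.
#' @param id_prefix prefix for paralog ids.
#' @return list with `seqs` (list of [annotated_seq()] paralogs) and `truth`
#'   (class `family_truth`: ancestor state, per-paralog event logs, true
#'   repeat phase and Ala bias).
#' @export
make_family <- function(cfg, group = "other", id_prefix = "par") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$scenario != "homologous") {
    stop("make_family requires scenario = 'homologous'; use ",
         "make_convergent_groups() for independent groups", call. = FALSE)
  }
  .make_group(cfg, group = group, id_prefix = id_prefix)
}

.make_group <- function(cfg, group, id_prefix) {
  with_seed(cfg$seed, {
    anc <- .make_ancestor(cfg)
    paralogs <- vector("list", cfg$n_paralogs)
    logs <- vector("list", cfg$n_paralogs)
    for (p in seq_len(cfg$n_paralogs)) {
      mut <- .mutate_paralog(anc, cfg)
      id <- sprintf("%s%02d", id_prefix, p)
      paralogs[[p]] <- annotated_seq(id, mut$state$seq,
                                     regions = mut$state$regions,
                                     species = "synthetic",
                                     group = group, source = "synthetic")
      logs[[p]] <- mut$events
      names(paralogs)[p] <- id
      names(logs)[p] <- id
    }
    truth <- structure(list(ancestor = anc[c("seq", "regions")],
                            peptide = anc$peptide,
                            events = logs,
                            repeat_phase = REPEAT_PHASE,
                            ala_bias = cfg$ala_bias,
                            config = cfg),
                       class = "family_truth")
    list(seqs = paralogs, truth = truth)
  })
}

#' Replay a family's event logs on its ancestor
#'
#' @param truth a `family_truth` from [make_family()].
#' @return named list of nucleotide strings, one per paralog, reproducing
#'   the simulated sequences exactly.
#' @export
replay_family <- function(truth) {
  stopifnot(inherits(truth, "family_truth"))
  lapply(truth$events, function(log) {
    state <- truth$ancestor
    for (ev in log) state <- apply_event(state, ev)
    state$seq
  })
}

#' Simulate independent (convergent) AFP-like groups
#'
#' Each config produces an independent ancestor — unrelated UTRs drawn from
#' scratch and its own Ala codon bias — sharing only the peptide design
#' constraints. This is the null scenario against which shared ancestry is
#' judged.
#'
#' @param cfgs named list of [synthetic_config()] objects (>= 2), each with
#'   `scenario = "convergent"` and, typically, a distinct `ala_bias` and
#'   `seed`.
#' @return named list of group datasets, each as returned by the family
#'   simulator (`seqs` + `truth`).
#' @export
make_convergent_groups <- function(cfgs) {
  if (length(cfgs) < 2) {
    stop("need at least 2 groups for a convergent scenario", call. = FALSE)
  }
  stopifnot(all(vapply(cfgs, inherits, TRUE, "synthetic_config")))
  bad <- vapply(cfgs, function(c) c$scenario != "convergent", TRUE)
  if (any(bad)) {
    stop("all configs must have scenario = 'convergent'", call. = FALSE)
  }
  if (is.null(names(cfgs))) {
    names(cfgs) <- sprintf("group%d", seq_along(cfgs))
  }
  out <- lapply(names(cfgs), function(g) {
    .make_group(cfgs[[g]], group = g, id_prefix = paste0(g, "_"))
  })
  names(out) <- names(cfgs)
  out
}

#' Simulate a background (non-AFP) gene set
#'
#' Random coding sequences of 50-500 codons with uniform amino acids, Ala
#' codons drawn from `background_bias` and uniform synonymous codons
#' elsewhere. By construction the records pass [curate_background()]: all
#' are long enough and mutually non-redundant.
#'
#' @param cfg a [synthetic_config()].
#' @param n_genes number of genes (>= 1).
#' @param seed seed (defaults to `cfg$seed`).
#' @return list of [annotated_seq()] records whose single region is a
#'   `mature_cds` spanning the whole sequence.
#' @export
make_background_genes <- function(cfg, n_genes, seed = cfg$seed) {
  stopifnot(n_genes >= 1)
  aa20 <- setdiff(names(SYN_CODONS), "*")
  with_seed(seed, {
    lapply(seq_len(n_genes), function(g) {
      ncod <- sample(50:500, 1)
      aa <- c("M", sample(aa20, ncod - 1, replace = TRUE))
      nt <- paste0(.back_translate(paste(aa, collapse = ""),
                                   cfg$background_bias), "TAA")
      annotated_seq(sprintf("bg%03d", g), nt,
                    regions = regions_df("mature_cds", 0L, nchar(nt)),
                    species = "synthetic_background", group = "background",
                    source = "synthetic")
    })
  })
}
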