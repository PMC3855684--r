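---
title: "Diagnosing convergence in alanine-rich type I antifreeze protein genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing convergence in alanine-rich type I antifreeze protein genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpconverge)
```

## The scientific question

Type I antifreeze proteins (AFPs) are short, alanine-rich (>50 mol%) single
alpha-helices that keep fish blood liquid in icy seawater by adsorbing to
nascent ice crystals. Nearly identical-looking versions occur in four
distantly related lineages — flounders, sculpins, snailfishes and cunner —
that diverged long before polar ice sheets existed. Protein-level similarity
therefore poses a sharp question: are these genes homologs (descent, perhaps
with lateral transfer), or did unrelated progenitor helices converge on the
same solution?

The protein sequences cannot answer this. Almost every residue in a 37-aa
Ala-rich helix is functionally constrained: Ala is the strongest helix
former, Thr every 11th residue aligns a hydroxyl/methyl face with the ice
lattice (the *i*, *i*+4, *i*+8 motif with Ala at *i*+4 and *i*+8), acidic
N-terminal residues and a nearby Pro/Gly cap the helix dipole, and acid-base
pairs at *i*, *i*+4 form stabilizing salt bridges. Convergence on this
composition is expected. The discriminating evidence is at the nucleotide
level, where selection is weaker:

1. **Untranslated regions.** UTRs of true paralogs and recent orthologs stay
   recognizably similar; unrelated genes share nothing. Windowed dot-matrix
   comparison makes this visible and quantifiable.
2. **Synonymous codon usage.** An Ala-rich gene uses the four Ala codons
   (GCT, GCC, GCA, GCG) in proportions inherited from its progenitor. A
   shared origin predicts concordant biases; observed biases are GCT-peaked
   in cunner, GCC in flounder and snailfish, GCG in sculpin, while the
   non-AFP background of all four groups mildly prefers GCC.
3. **Gene architecture.** Intron presence and position are stable over the
   relevant timescales; sculpin AFP genes are intronless while flounder and
   cunner genes carry introns at different positions.
4. **Progenitor plausibility.** Because tandem Ala codon runs read in
   shifted or antisense frames encode runs of other residues (Leu/Cys and
   Ser/Ala/Gln for GCT, Pro/Arg and Gly/Ala/Arg for GCC, Arg/Gly and
   Arg/Ala/Pro for GCG), poly-Ala coding sequence can be seeded from
   pre-existing repetitive DNA — trinucleotide microsatellites or Gly-rich
   coding sequence — independently in each lineage.

The package implements each diagnostic and a simulator that generates gene
families with known ground truth, so the whole pipeline is testable without
any database access.

## The dot-matrix engine

`compute_dotplot()` marks a sense point at `(i, j)` when windows
`a[i, i+n)` and `b[j, j+n)` agree at `k` or more positions, and an
antisense point when `a`'s window agrees with the reverse complement of
`b`'s, reported in `b`'s sense coordinates so both modes share one matrix.
`N` never matches. Defaults follow the two comparison regimes: 9-of-10 for
within-family comparisons, 9-of-12 for cross-group comparisons. Maximal
diagonal runs of consecutive points are extracted as segments; sense
segments keep `j - i` constant, antisense segments keep `i + j` constant.

Implementation notes:

* Window counts are running sums along each diagonal, O(|a||b|) total. The
  test suite checks equivalence against two independent brute-force
  enumerations (a literal triple loop and a shifted-submatrix sum) on
  hundreds of random pairs.
* Points are assigned to annotated regions by the window midpoint
  (`start + floor(n/2)`), which minimizes misassignment at region
  boundaries.

### Quantifying UTR similarity

`utr_similarity_score()` reports the fraction of (unmasked) UTR positions
of sequence A covered by sense diagonal segments of at least `min_run`
consecutive windows whose window midpoints fall in UTR regions of both
sequences. Two numerical choices matter, and both were fixed from an
explicit null analysis rather than left to intuition:

* **Run threshold (`min_run = 10`).** At 9-of-12, two *unrelated* sequences
  produce window hits at a few per 10⁴ window pairs, and because adjacent
  windows share 11 of 12 comparisons a hit extends to a neighboring window
  with probability ≈ 0.45. Short runs (2–9 windows) are therefore expected
  background — these are the sporadic, insignificant short matches that a
  practiced eye discounts when reading a dot matrix. Requiring 10
  consecutive windows (a ≥ 21-nt conserved stretch) puts the null
  expectation of covered UTR sequence below ~1% while leaving conserved
  UTRs, which produce runs of dozens of windows, essentially at full
  coverage. Conserved UTR pairs score ≥ 0.95 even across a 30-nt indel,
  which breaks one diagonal into two long ones.
* **Simple-repeat masking.** Homopolymer and dinucleotide tracts of ≥ 10 nt
  (e.g. the GT microsatellites typical of these 3' UTRs) are masked from
  both numerator and denominator. Shared simple repeats generate long,
  perfect diagonals in genuinely unrelated sequences; they carry no
  phylogenetic signal, so they neither earn nor cost similarity.

## Codon usage

`count_codons()` tallies in-frame codons (codons containing `N` are dropped
from counts and totals), `ala_profile()` pools tables and returns the
within-family fractions of GCT, GCC, GCA, GCG, and `profile_distance()` is
the total-variation distance `0.5 * sum(|p - q|)` between two profiles —
0 for identical usage, 1 for biases concentrated on different codons.

Background (non-AFP) sets are curated by `curate_background()`: within a
species, whenever two CDSs share more than 65% global DNA identity only the
longest is kept (greedy by descending length, ties to the lexicographically
smaller id — the greedy rule, unlike pure single-link clustering, is
idempotent), and CDSs under 50 codons are dropped. Identity comes from
end-to-end Needleman–Wunsch alignment at match +1, mismatch −1, linear gap
−2 per base, with identity = matched columns / alignment columns (indel
columns count, which is the conservative choice for the >90% UTR-identity
claim). Codon profiles of annotated AFPs use the full coding sequence
(signal peptide + propeptide + mature CDS) by default; mature-only profiles
are available through `translate_record(..., mature_only = TRUE)` and
per-region extraction, so the choice is auditable.

## Helix features

`helix_feature_report()` bundles the scanners:

* `thr_periodicity()` scores each of the 11 phases by Thr occupancy of its
  slots; Ile/Leu count as substitutes toward choosing the best phase
  (naturally occurring isoforms carry such substitutions at two slots) but
  not toward the reported Thr score.
* `ice_binding_triplets()` emits `(i, i+4, i+8)` for Thr anchors whose
  `i+4`/`i+8` partners are Ala or Thr. Substituted (Ile/Leu) slots do not
  anchor triplets, since only Thr/Ala faces are credited with ice binding.
* `salt_bridges()` lists all acid/base pairs at separation 4, both
  orientations.
* `n_cap()` looks for the first Asp/Glu within 3 residues after Met1 and
  the first Pro/Gly within 8; `internal_breakers()` lists Pro/Gly more than
  5 residues from either terminus. The windows (3, 8) and margin (5) are
  configurable; the defaults classify the canonical short isoforms
  (MDAPA-type N-termini, breaker-free interiors) and the atypical snailfish
  peptide (internal Gly/Pro present) as described.

Positions are 0-based in machine-readable output and 1-based in printed
reports.

## Frame analysis

`alt_frame_products()` computes, from a two-copy window of an infinite
tandem repeat, the amino acids of the two shifted sense frames and the
three antisense frames ("+1" discards the first base; antisense frame 0 is
the reverse complement read from its 5' end). `find_codon_runs()` locates
maximal pure tandem repeats of a codon (default ≥ 4 units, a typical
microsatellite-reporting threshold; interrupted repeats are out of scope),
tagging each with every frame that would read it as poly-Ala.
`poly_ala_potential()` scans all six frames for segments encoding ≥ 6
consecutive Ala and is strand-symmetric by construction.

## The simulator

`make_family()` emulates the observed structure of a sculpin-like AFP
family; its defaults are the study conditions and are not tuned per test:

| parameter | default | rationale |
|---|---|---|
| `n_repeats` | 3 | short isoforms carry three 11-aa repeats (37–42 aa peptides) |
| `utr5_len`, `utr3_len` | 120, 350 nt | cDNA-scale UTRs; 3' UTR carries a 20-nt GT microsatellite |
| UTR GC | uniform 37–44% | the observed GC range of these flanking regions |
| `point_mut_rate` | 0.01/site | keeps intra-family 5' UTR identity > 90% (observed) |
| `indel_rate` (3' UTR) | 1.2 events/paralog | indels and repeat-length change are the norm in 3' UTRs |
| `utr5_indel_rate` | 0.15 | 5' UTRs are strongly conserved, sharing an in-frame stop 15 nt upstream of the start (reproduced by the generator) |
| `repeat_cnv_prob` | 0.3 | coding regions expand/contract in whole 33-nt repeat units via recombination in Ala-codon runs |
| `thr_sub_rate` | 0.05 | Ile/Leu substitution of Thr slots, as seen in real isoforms |
| `ala_bias` | (0.10, 0.10, 0.26, 0.54) | sculpin-like: GCG ≈ 52–55%, GCA ≈ 24–28% |
| `background_bias` | (0.30, 0.38, 0.18, 0.14) | the mild GCC > GCT preference of non-AFP genes |

Every mutational event is applied through a single event machine and
logged; `replay_family()` re-derives each paralog from the ancestor
byte-exactly, which the tests use as a ground-truth oracle. Point
substitutions that would create an in-frame stop inside the CDS are skipped
(purifying selection — every cloned isoform is an intact ORF). Non-Ala
codons are drawn uniformly among synonyms so the Ala profile is the only
deliberate codon signal. `make_convergent_groups()` builds independent
ancestors per group (the convergence null); `make_background_genes()`
produces 50–500-codon random CDSs that pass curation by construction.

What the simulator does *not* emulate: organism-specific codon usage
outside Ala, selection gradients along the gene, recombination mechanism
(repeat CNV is drawn, not mechanistically recombined), signal-peptide and
intron evolution, and phylogenetic tree structure within a family (all
paralogs descend independently from one ancestor). Passing tests therefore
demonstrate that the pipeline recovers planted signal under realistic noise
— not that real data are this clean.

## The convergence report

`run_report()` composes the modules over a grouped dataset: per-group
pooled Ala profiles (AFP and background), intron-count sets,
signal-peptide presence, mean helix features, and for each unordered group
pair a 9-of-12 dot matrix between group representatives (longest record),
the UTR similarity score, a CDS match density and the profile distance.
Three per-pair heuristic flags make the qualitative argument explicit:
`utr_dissimilar` (similarity < 0.1), `codon_bias_discordant` (profile
distance > 0.3) and `gene_structure_discordant` (differing intron-count
sets). They are deliberately labelled heuristics — the underlying argument
is a conjunction of qualitative observations, not a statistical test — and
all thresholds are `report_params()` arguments. `write_report()` emits
deterministic TSVs, ASCII dot matrices and a human-readable summary.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data:
families of 6 paralogs (~600-nt genes), 100-pair dotplot oracle sweeps at
lengths up to 200 nt, 100-CDS codon-bias recovery, 200-draw feature
recovery, and 25-replicate null-vs-family score comparisons (reduced UTR
lengths of 80 + 150 nt keep the replicated dotplots cheap). Degenerate
inputs are defined errors, not silent results: empty FASTA, duplicate ids,
overlapping or out-of-range regions, out-of-frame CDSs, internal stops,
all-`N` GC content, empty Ala profiles in `profile_distance()`, windows
longer than a sequence, UTR-less records in `utr_similarity_score()`.
Ties are deterministic throughout (smallest phase, lexicographically
smallest id, fixed frame order), so every pipeline output is reproducible
byte for byte under a fixed seed.

## Known limitations

* `pairwise_identity()` reports the identity of one optimal alignment;
  co-optimal alignments with different match counts are resolved by the
  aligner's internal tie-breaking.
* The UTR similarity score is asymmetric in its denominator (positions of
  A); the report always evaluates pairs in sorted group order, keeping
  outputs deterministic.
* Back-translation draws codons independently; it does not model
  dinucleotide or context effects.
* `back_translate()` takes a single Ala bias vector: non-Ala codons are
  uniform among synonyms by design, so a separate background bias parameter
  would be dead weight (background gene generation simply passes its own
  bias as `ala_bias`).
* Accession-based comparisons (real GenBank records) are supported through
  `read_fasta()`/`read_regions()` on user-supplied files but no network
  fetching is built in; all bundled validation is synthetic.
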