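test_that("generated mature peptides have the designed architecture", {
  cfg <- synthetic_config(seed = 1)
  p3 <- make_mature_peptide(cfg)
  expect_identical(nchar(p3$seq), 5L + 11L * 3L)
  expect_identical(substr(p3$seq, 1, 2), "MD")
  expect_identical(attr(p3, "repeat_phase"), 5L)

  p1 <- make_mature_peptide(synthetic_config(seed = 1, n_repeats = 1))
  expect_identical(nchar(p1$seq), 16L)
  expect_identical(n_cap(p1)$acidic_pos, 1L)
  expect_gte(nrow(salt_bridges(p1)), 1)
  expect_gt(ala_mol_percent(p1), 50)
})

test_that("peptides are Ala-rich with an intact Thr face over many draws", {
  cfg <- synthetic_config(seed = 99)
  for (s in 1:200) {
    p <- make_mature_peptide(cfg, seed = s)
    expect_gt(ala_mol_percent(p), 50)
    r <- thr_periodicity(p)
    # every Thr slot holds Thr or an allowed Ile/Leu substitute
    expect_gte((r$n_hits + r$n_substitute) / r$n_slots, 0.8)
    expect_gte(nrow(salt_bridges(p)), 1)
  }
})

test_that("back_translate honours the Ala bias and round-trips", {
  p <- protein_record("p", strrep("A", 50))
  nt <- back_translate(p, c(0, 0, 0, 1), seed = 8)
  expect_identical(nt, strrep("GCG", 50))

  big <- protein_record("p", strrep("A", 10000))
  nt2 <- back_translate(big, c(0.1, 0.1, 0.1, 0.7), seed = 8)
  prof <- ala_profile(count_codons(nt2))
  expect_true(all(abs(prof$fractions - c(0.1, 0.1, 0.1, 0.7)) < 0.02))

  pep <- make_mature_peptide(synthetic_config(seed = 3))
  nt3 <- back_translate(pep, c(0.25, 0.25, 0.25, 0.25), seed = 9)
  expect_identical(translate_cds(nt3)$seq, pep$seq)
})

test_that("families are deterministic and replay byte-exactly from the event log", {
  cfg <- synthetic_config(seed = 202)
  f1 <- make_family(cfg)
  f2 <- make_family(cfg)
  expect_identical(vapply(f1$seqs, `[[`, "", "seq"),
                   vapply(f2$seqs, `[[`, "", "seq"))
  expect_identical(f1$truth$events, f2$truth$events)

  replayed <- replay_family(f1$truth)
  expect_identical(replayed,
                   lapply(f1$seqs, `[[`, "seq")[names(replayed)])
})

test_that("a mutation-free family reproduces the ancestor exactly", {
  cfg <- synthetic_config(seed = 7, point_mut_rate = 0, indel_rate = 0,
                          utr5_indel_rate = 0, repeat_cnv_prob = 0,
                          n_paralogs = 3)
  fam <- make_family(cfg)
  for (rec in fam$seqs) {
    expect_identical(rec$seq, fam$truth$ancestor$seq)
    expect_identical(rec$regions, fam$truth$ancestor$regions)
  }
})

test_that("family paralogs keep conserved 5' UTRs and valid annotations", {
  fam <- make_family(synthetic_config(seed = 11))
  ids <- combn(length(fam$seqs), 2, function(ij) {
    pairwise_identity(extract_region(fam$seqs[[ij[1]]], "five_prime_utr"),
                      extract_region(fam$seqs[[ij[2]]], "five_prime_utr"))
  })
  expect_gt(mean(ids), 90)
  for (rec in fam$seqs) {
    # regions tile and the CDS still translates cleanly
    expect_identical(rec$regions$kind,
                     c("five_prime_utr", "mature_cds", "three_prime_utr"))
    expect_identical(rec$regions$end[3], nchar(rec$seq))
    p <- translate_record(rec, mature_only = TRUE)
    expect_gt(ala_mol_percent(p), 50)
  }
})

test_that("repeat copy-number events change the CDS in whole 33-nt units", {
  cfg <- synthetic_config(seed = 31, point_mut_rate = 0, indel_rate = 0,
                          utr5_indel_rate = 0, repeat_cnv_prob = 1,
                          n_paralogs = 8)
  fam <- make_family(cfg)
  anc_len <- diff(unlist(
    fam$truth$ancestor$regions[fam$truth$ancestor$regions$kind ==
                                 "mature_cds", c("start", "end")]))
  for (rec in fam$seqs) {
    r <- rec$regions[rec$regions$kind == "mature_cds", ]
    expect_true((r$end - r$start - anc_len) %in% c(-33L, 33L))
  }
})

test_that("convergent groups are independent in UTRs but share peptide design", {
  cfgs <- list(
    gct = synthetic_config(seed = 301, ala_bias = c(0.7, 0.1, 0.1, 0.1),
                           scenario = "convergent", n_paralogs = 2),
    gcc = synthetic_config(seed = 302, ala_bias = c(0.1, 0.7, 0.1, 0.1),
                           scenario = "convergent", n_paralogs = 2),
    gca = synthetic_config(seed = 303, ala_bias = c(0.1, 0.1, 0.7, 0.1),
                           scenario = "convergent", n_paralogs = 2),
    gcg = synthetic_config(seed = 304, ala_bias = c(0.1, 0.1, 0.1, 0.7),
                           scenario = "convergent", n_paralogs = 2))
  grp <- make_convergent_groups(cfgs)
  expect_identical(names(grp), names(cfgs))
  # pooled per-group profile argmax recovers each bias peak
  for (g in names(grp)) {
    tabs <- lapply(grp[[g]]$seqs, function(r) {
      count_codons(coding_sequence(r))
    })
    prof <- ala_profile(tabs)
    expect_identical(names(which.max(prof$fractions)),
                     names(which.max(cfgs[[g]]$ala_bias)))
  }
  expect_error(make_convergent_groups(cfgs[1]), "at least 2")
  expect_error(make_convergent_groups(list(a = synthetic_config(seed = 1),
                                           b = synthetic_config(seed = 2))),
               "convergent")
})

test_that("same seed with different bias gives identical peptide layouts", {
  cfgs <- list(
    a = synthetic_config(seed = 55, ala_bias = c(0.7, 0.1, 0.1, 0.1),
                         scenario = "convergent", n_paralogs = 1),
    b = synthetic_config(seed = 55, ala_bias = c(0.1, 0.1, 0.1, 0.7),
                         scenario = "convergent", n_paralogs = 1))
  grp <- make_convergent_groups(cfgs)
  pa <- translate_record(grp$a$seqs[[1]], mature_only = TRUE)
  pb <- translate_record(grp$b$seqs[[1]], mature_only = TRUE)
  expect_identical(pa$seq, pb$seq)
  expect_false(identical(extract_region(grp$a$seqs[[1]], "mature_cds"),
                         extract_region(grp$b$seqs[[1]], "mature_cds")))
})

test_that("homologous UTR similarity stochastically dominates the convergent null", {
  hom <- numeric(25)
  conv <- numeric(25)
  small <- function(seed, scenario) {
    synthetic_config(seed = seed, scenario = scenario, n_paralogs = 2,
                     utr5_len = 80, utr3_len = 150)
  }
  dp <- dotplot_params(12, 9)
  for (s in 1:25) {
    fam <- make_family(small(1000 + s, "homologous"))
    d <- compute_dotplot(fam$seqs[[1]], fam$seqs[[2]], dp)
    hom[s] <- utr_similarity_score(d, fam$seqs[[1]]$regions,
                                   fam$seqs[[2]]$regions)
    grp <- make_convergent_groups(list(
      a = small(2000 + s, "convergent"), b = small(3000 + s, "convergent")))
    ra <- grp$a$seqs[[1]]
    rb <- grp$b$seqs[[1]]
    d2 <- compute_dotplot(ra, rb, dp)
    conv[s] <- utr_similarity_score(d2, ra$regions, rb$regions)
  }
  w <- stats::wilcox.test(hom, conv, alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 1e-6)
})

test_that("background genes are GCC-leaning, deterministic and curation-proof", {
  cfg <- synthetic_config(seed = 77)
  bg <- make_background_genes(cfg, 12)
  expect_length(bg, 12)
  prof <- ala_profile(lapply(bg, function(r) {
    count_codons(coding_sequence(r))
  }))
  expect_identical(names(which.max(prof$fractions)), "GCC")
  expect_true(all(vapply(bg, function(r) {
    nchar(coding_sequence(r)) / 3 >= 50
  }, TRUE)))
  expect_length(curate_background(bg), 12)

  bg2 <- make_background_genes(cfg, 12)
  expect_identical(vapply(bg, `[[`, "", "seq"),
                   vapply(bg2, `[[`, "", "seq"))
  one <- make_background_genes(cfg, 1)
  expect_length(one, 1)
  expect_identical(one[[1]]$regions$kind, "mature_cds")
})
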