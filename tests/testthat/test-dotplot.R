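test_that("self-comparison gives a full main diagonal segment", {
  set.seed(2)
  a <- random_nt(60)
  res <- compute_dotplot(a, a, dotplot_params(10, 9, "sense"))
  main <- res$points[res$points$i == res$points$j, ]
  expect_identical(nrow(main), 51L)
  expect_true(all(main$n_matched == 10))
  seg <- res$segments[res$segments$diag == 0 & res$segments$mode == "sense", ]
  expect_identical(seg$length, 51L)
})

test_that("a GCG run is antisense-complementary to its reverse complement", {
  g <- strrep("GCG", 12)
  res <- compute_dotplot(g, revcomp(g), dotplot_params(12, 12, "antisense"))
  expect_gt(nrow(res$points), 0)
  expect_true(all(res$points$mode == "antisense"))
  # the full-length antisense diagonal is present
  expect_gte(max(res$segments$length), nchar(g) - 12 + 1 - 2)
})

test_that("N matches nothing in either mode", {
  a <- "ACGTACGTACGT"
  withN <- "ACGTACGTACGN"
  res <- compute_dotplot(a, withN, dotplot_params(12, 12, "sense"))
  expect_identical(nrow(res$points), 0L)
  res2 <- compute_dotplot(a, withN, dotplot_params(12, 11, "sense"))
  expect_identical(nrow(res2$points), 1L)
})

test_that("window shorter than either sequence is required", {
  expect_error(compute_dotplot("ACGT", "ACGTACGTACGT", dotplot_params(10, 9)),
               "shorter than window")
})

test_that("points match both brute-force enumerations on random pairs", {
  set.seed(13)
  for (r in 1:6) {
    a <- random_nt(sample(25:60, 1), c("A", "C", "G", "T", "N"))
    b <- random_nt(sample(25:60, 1), c("A", "C", "G", "T", "N"))
    for (nk in list(c(10, 9), c(12, 9))) {
      res <- compute_dotplot(a, b, dotplot_params(nk[1], nk[2]))
      for (mode in c("sense", "antisense")) {
        got <- sort_points(res$points[res$points$mode == mode, ])
        loops <- dotplot_bruteforce_loops(a, b, nk[1], nk[2], mode)
        loops$mode <- rep(mode, nrow(loops))
        shifted <- dotplot_bruteforce_shifted(a, b, nk[1], nk[2], mode)
        shifted$mode <- rep(mode, nrow(shifted))
        expect_identical(got, sort_points(loops))
        expect_identical(got, sort_points(shifted))
      }
    }
  }
})

test_that("sense points transpose under argument swap and antisense maps under the involution", {
  set.seed(29)
  a <- random_nt(80)
  b <- random_nt(70)
  n <- 12
  ab <- compute_dotplot(a, b, dotplot_params(n, 8))
  ba <- compute_dotplot(b, a, dotplot_params(n, 8))

  s_ab <- sort_points(ab$points[ab$points$mode == "sense", ])
  s_ba <- ba$points[ba$points$mode == "sense", c("j", "i", "mode", "n_matched")]
  names(s_ba) <- c("i", "j", "mode", "n_matched")
  expect_identical(s_ab, sort_points(s_ba))

  # antisense matching in b-sense coordinates is symmetric: window (i, j)
  # of (a, b) corresponds to window (j, i) of (b, a) because reverse
  # complementation is an involution
  x_ab <- ab$points[ab$points$mode == "antisense", ]
  x_ba <- ba$points[ba$points$mode == "antisense", ]
  mapped <- data.frame(i = x_ab$j, j = x_ab$i,
                       mode = rep("antisense", nrow(x_ab)),
                       n_matched = x_ab$n_matched)
  expect_identical(sort_points(mapped), sort_points(x_ba))
})

test_that("lowering k never removes points", {
  set.seed(37)
  a <- random_nt(90)
  b <- random_nt(90)
  p9 <- compute_dotplot(a, b, dotplot_params(12, 9))$points
  p8 <- compute_dotplot(a, b, dotplot_params(12, 8))$points
  key <- function(p) paste(p$i, p$j, p$mode)
  expect_true(all(key(p9) %in% key(p8)))
})

test_that("region_overlap assigns points by window midpoint", {
  # self-comparison of a record split into one UTR and one CDS: the main
  # diagonal tallies split exactly at the midpoint boundary
  set.seed(43)
  seqstr <- random_nt(60)
  regions <- regions_df(c("five_prime_utr", "mature_cds"), c(0, 30), c(30, 60))
  res <- compute_dotplot(seqstr, seqstr, dotplot_params(10, 10, "sense"))
  ov <- region_overlap(res, regions, regions)
  ov <- ov[ov$mode == "sense", ]
  diag_pts <- res$points[res$points$i == res$points$j, ]
  mids <- diag_pts$i + 5
  expect_identical(sum(ov$n_points), nrow(res$points))
  utr_utr <- ov$n_points[ov$kind_a == "five_prime_utr" &
                           ov$kind_b == "five_prime_utr"]
  expect_identical(sum(utr_utr), sum(mids < 30 &
                                       (diag_pts$j + 5) < 30))

  # all points inside CDS x CDS when sequences only match there
  a2 <- paste0(random_nt(30), strrep("GATTACA", 5))
  b2 <- paste0(strrep("GATTACA", 5), random_nt(30))
  ra <- regions_df(c("five_prime_utr", "mature_cds"), c(0, 30),
                   c(30, nchar(a2)))
  rb <- regions_df(c("mature_cds", "three_prime_utr"), c(0, 35),
                   c(35, nchar(b2)))
  res2 <- compute_dotplot(a2, b2, dotplot_params(12, 12, "sense"))
  ov2 <- region_overlap(res2, ra, rb)
  expect_true(all(ov2$kind_a == "mature_cds" & ov2$kind_b == "mature_cds"))
})

test_that("utr similarity is ~1 for identical UTRs, low for unrelated ones, intermediate with an indel", {
  set.seed(47)
  utr <- random_nt(200)
  cds <- strrep("GCT", 40)
  regions <- regions_df(c("five_prime_utr", "mature_cds"),
                        c(0, 200), c(200, 200 + nchar(cds)))
  same <- paste0(utr, cds)
  res <- compute_dotplot(same, same, dotplot_params(12, 9))
  expect_gte(utr_similarity_score(res, regions, regions), 0.95)

  other <- paste0(random_nt(200), cds)
  res2 <- compute_dotplot(same, other, dotplot_params(12, 9))
  expect_lt(utr_similarity_score(res2, regions, regions), 0.1)

  # one 30-nt deletion in the UTR: strictly between the extremes
  gapped <- paste0(substr(utr, 1, 100), substr(utr, 131, 200), cds)
  regions_g <- regions_df(c("five_prime_utr", "mature_cds"),
                          c(0, 170), c(170, 170 + nchar(cds)))
  res3 <- compute_dotplot(same, gapped, dotplot_params(12, 9))
  s3 <- utr_similarity_score(res3, regions, regions_g)
  expect_gt(s3, 0.5)
  expect_lt(s3, 0.95)

  no_utr <- regions_df("mature_cds", 0, nchar(same))
  expect_error(utr_similarity_score(res, no_utr, regions), "UTR")
})

test_that("render_text round-trips binned point presence", {
  set.seed(53)
  a <- random_nt(70)
  b <- random_nt(70)
  res <- compute_dotplot(a, b, dotplot_params(10, 7))
  for (bin in c(1L, 5L)) {
    m <- render_text(res, bin)
    expect_identical(dim(m), c((res$a_len - 10L) %/% bin + 1L,
                               (res$b_len - 10L) %/% bin + 1L))
    sense_cells <- unique(res$points[res$points$mode == "sense",
                                     c("i", "j")])
    for (idx in seq_len(nrow(sense_cells))) {
      ch <- m[sense_cells$i[idx] %/% bin + 1, sense_cells$j[idx] %/% bin + 1]
      expect_true(ch %in% c("+", "*"))
    }
    anti_cells <- unique(res$points[res$points$mode == "antisense",
                                    c("i", "j")])
    for (idx in seq_len(nrow(anti_cells))) {
      ch <- m[anti_cells$i[idx] %/% bin + 1, anti_cells$j[idx] %/% bin + 1]
      expect_true(ch %in% c("x", "*"))
    }
    # cells without any point render as "."
    expect_identical(sort(unique(as.vector(m))),
                     sort(unique(c(".", as.vector(m)))))
  }
  # empty result renders as all dots
  e <- compute_dotplot("AAAAAAAAAAAA", "CCCCCCCCCCCC",
                       dotplot_params(12, 9, "sense"))
  expect_true(all(render_text(e, 1) == "."))
})
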