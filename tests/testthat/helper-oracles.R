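# Independent oracles, deliberately naive and separate from the package's
# computational routes.

# Needleman-Wunsch with linear gaps, returning percent identity
# (matched columns / alignment columns) via explicit traceback.
nw_identity_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- S[i, j] + if (av[i] == bv[j]) match else mismatch
      S[i + 1, j + 1] <- max(sub, S[i, j + 1] + gap, S[i + 1, j] + gap)
    }
  }
  i <- n; j <- m; cols <- 0; matches <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      if (av[i] == bv[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  100 * matches / cols
}

# Literal triple-loop dot-matrix enumeration (0-based starts).
dotplot_bruteforce_loops <- function(a, b, n, k, mode = "sense") {
  av <- strsplit(a, "")[[1]]
  bv <- if (mode == "antisense") {
    strsplit(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(b))), "")[[1]]
  } else strsplit(b, "")[[1]]
  rows <- list()
  for (i in 0:(length(av) - n)) {
    for (j in 0:(length(bv) - n)) {
      cnt <- 0
      for (t in 1:n) {
        x <- av[i + t]; y <- bv[j + t]
        if (x != "N" && y != "N" && x == y) cnt <- cnt + 1
      }
      if (cnt >= k) {
        jj <- if (mode == "antisense") nchar(b) - n - j else j
        rows[[length(rows) + 1]] <- c(i, jj, cnt)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(i = integer(), j = integer(), n_matched = integer()))
  }
  m <- do.call(rbind, rows)
  data.frame(i = m[, 1], j = m[, 2], n_matched = m[, 3])
}

# Shifted-submatrix enumeration: window counts as the sum of n shifted
# copies of the full position-match matrix (no diagonal scanning).
dotplot_bruteforce_shifted <- function(a, b, n, k, mode = "sense") {
  av <- strsplit(a, "")[[1]]
  bv <- if (mode == "antisense") {
    strsplit(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(b))), "")[[1]]
  } else strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  M <- outer(av, bv, "==") & outer(av != "N", bv != "N", "&")
  W <- matrix(0L, la - n + 1, lb - n + 1)
  for (t in 0:(n - 1)) {
    W <- W + M[(1 + t):(la - n + 1 + t), (1 + t):(lb - n + 1 + t),
               drop = FALSE]
  }
  hit <- which(W >= k, arr.ind = TRUE)
  i <- hit[, 1] - 1L
  j <- hit[, 2] - 1L
  if (mode == "antisense") j <- lb - n - j
  data.frame(i = i, j = j, n_matched = as.integer(W[hit]))
}

# canonical ordering (and integer coercion) so point sets can be compared
# with identical()
sort_points <- function(p) {
  p <- p[order(p$mode, p$i, p$j), c("i", "j", "mode", "n_matched")]
  p$i <- as.integer(p$i)
  p$j <- as.integer(p$j)
  p$n_matched <- as.integer(p$n_matched)
  rownames(p) <- NULL
  p
}

# one-pass codon tally, independent of count_codons
codon_tally_oracle <- function(cds) {
  n <- nchar(cds) %/% 3
  out <- list()
  for (t in seq_len(n)) {
    cod <- substr(cds, 3 * t - 2, 3 * t)
    if (grepl("N", cod)) next
    out[[cod]] <- (if (is.null(out[[cod]])) 0L else out[[cod]]) + 1L
  }
  unlist(out)
}

random_nt <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
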