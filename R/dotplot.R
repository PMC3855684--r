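# Windowed k-of-n dot-matrix comparison.
#
# A sense point at (i, j) means windows a[i, i+n) and b[j, j+n) agree at >= k
# positions; an antisense point means a[i, i+n) agrees with the reverse
# complement of b at >= k positions, reported in b's sense coordinates so both
# modes plot on one matrix. N never matches in either mode. Diagonals of
# points are the visual signature of conserved runs; their presence in the
# untranslated regions is the homology signal this package quantifies.

DOT_MODES <- c("sense", "antisense")

#' Dot-matrix parameters
#'
#' @param window window length n (>= 1).
#' @param min_matches minimum matching bases k within a window (1 <= k <= n).
#' @param modes subset of `c("sense", "antisense")`.
#' @return validated parameter list of class `dotplot_params`.
#' @export
dotplot_params <- function(window = 12L, min_matches = 9L,
                           modes = c("sense", "antisense")) {
  window <- as.integer(window)
  min_matches <- as.integer(min_matches)
  modes <- match.arg(modes, DOT_MODES, several.ok = TRUE)
  stopifnot(window >= 1, min_matches >= 1, min_matches <= window)
  structure(list(window = window, min_matches = min_matches, modes = modes),
            class = "dotplot_params")
}

# All window pairs of a (rows) vs b (cols) with >= k matches, scanned one
# diagonal at a time with running window sums. Returns 0-based starts.
window_hits <- function(av, bv, n, k) {
  la <- length(av)
  lb <- length(bv)
  a_ok <- av != "N"
  b_ok <- bv != "N"
  res_i <- vector("list", la + lb - 1)
  res_j <- vector("list", la + lb - 1)
  res_m <- vector("list", la + lb - 1)
  slot <- 0L
  for (d in (-(la - n)):(lb - n)) {
    i0 <- max(0L, -d)                 # first a-position on this diagonal
    len <- min(la - i0, lb - (i0 + d))
    if (len < n) next
    ai <- (i0 + 1):(i0 + len)
    bi <- ai + d
    m <- (av[ai] == bv[bi]) & a_ok[ai] & b_ok[bi]
    cs <- cumsum(m)
    wins <- cs[n:len] - c(0, cs[seq_len(len - n)])
    hit <- which(wins >= k)
    if (length(hit) > 0) {
      slot <- slot + 1L
      res_i[[slot]] <- i0 + hit - 1L
      res_j[[slot]] <- i0 + d + hit - 1L
      res_m[[slot]] <- wins[hit]
    }
  }
  if (slot == 0L) {
    return(data.frame(i = integer(), j = integer(), n_matched = integer()))
  }
  data.frame(i = unlist(res_i[seq_len(slot)]),
             j = unlist(res_j[seq_len(slot)]),
             n_matched = as.integer(unlist(res_m[seq_len(slot)])))
}

# Maximal runs of consecutive points on one diagonal. Sense diagonals keep
# j - i constant with both indices increasing; antisense diagonals (in b's
# sense coordinates) keep i + j constant with j decreasing as i increases.
extract_segments <- function(points) {
  if (nrow(points) == 0) {
    return(data.frame(mode = character(), diag = integer(),
                      a_start = integer(), b_start = integer(),
                      length = integer()))
  }
  segs <- lapply(split(points, points$mode), function(p) {
    anti <- p$mode[1] == "antisense"
    d <- if (anti) p$i + p$j else p$j - p$i
    p <- p[order(d, p$i), , drop = FALSE]
    d <- if (anti) p$i + p$j else p$j - p$i
    new_run <- c(TRUE, diff(d) != 0 | diff(p$i) != 1)
    run_id <- cumsum(new_run)
    first <- !duplicated(run_id)
    data.frame(mode = p$mode[1],
               diag = d[first],
               a_start = p$i[first],
               b_start = p$j[first],
               length = as.integer(tabulate(run_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Compute a dot-matrix comparison of two nucleotide sequences
#'
#' @param a,b nucleotide strings (or [annotated_seq()] records).
#' @param params a [dotplot_params()] object.
#' @param a_id,b_id identifiers used in outputs; taken from the records when
#'   `a`/`b` are `afp_seq` objects.
#' @return an object of class `dotplot_result`: the parameters, sequence ids
#'   and lengths, a `points` data.frame (`i`, `j` 0-based window starts,
#'   `mode`, `n_matched`) and a `segments` data.frame of maximal diagonal
#'   runs (`mode`, `diag`, `a_start`, `b_start`, `length`).
#' @export
compute_dotplot <- function(a, b, params = dotplot_params(),
                            a_id = "A", b_id = "B") {
  if (inherits(a, "afp_seq")) { a_id <- a$id; a <- a$seq }
  if (inherits(b, "afp_seq")) { b_id <- b$id; b <- b$seq }
  a <- normalize_nt(a)
  b <- normalize_nt(b)
  n <- params$window
  k <- params$min_matches
  if (nchar(a) < n || nchar(b) < n) {
    stop(sprintf("sequence shorter than window (%d): |a|=%d, |b|=%d",
                 n, nchar(a), nchar(b)), call. = FALSE)
  }
  av <- s2c(a)
  bv <- s2c(b)
  pts <- list()
  if ("sense" %in% params$modes) {
    p <- window_hits(av, bv, n, k)
    if (nrow(p) > 0) p$mode <- "sense"
    pts$sense <- p
  }
  if ("antisense" %in% params$modes) {
    p <- window_hits(av, s2c(revcomp(b)), n, k)
    if (nrow(p) > 0) {
      p$j <- nchar(b) - n - p$j      # report in b's sense coordinates
      p$mode <- "antisense"
    }
    pts$antisense <- p
  }
  pts <- pts[vapply(pts, nrow, 0L) > 0]
  points <- if (length(pts) > 0) {
    out <- do.call(rbind, pts)
    rownames(out) <- NULL
    out[, c("i", "j", "mode", "n_matched")]
  } else {
    data.frame(i = integer(), j = integer(), mode = character(),
               n_matched = integer())
  }
  structure(list(params = params, a_id = a_id, b_id = b_id,
                 a_len = nchar(a), b_len = nchar(b),
                 a_seq = a, b_seq = b,
                 points = points, segments = extract_segments(points)),
            class = "dotplot_result")
}

#' @export
print.dotplot_result <- function(x, ...) {
  cat(sprintf(
    "<dotplot_result> %s (%d nt) vs %s (%d nt), window %d, min matches %d\n",
    x$a_id, x$a_len, x$b_id, x$b_len, x$params$window, x$params$min_matches))
  tab <- table(x$points$mode)
  cat(sprintf("  %d points (%s), %d segments\n", nrow(x$points),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$segments)))
  invisible(x)
}

# TRUE at 0-based positions lying inside a maximal period-1 or period-2
# tandem tract of at least min_len nt (homopolymers and dinucleotide
# microsatellites)
simple_repeat_mask <- function(v, min_len = 10L) {
  L <- length(v)
  mask <- logical(L)
  if (L < min_len) return(mask)
  p2 <- v[seq_len(L - 2)] == v[3:L]    # position repeats two later
  r <- rle(p2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (s in which(r$values & (r$lengths + 2L) >= min_len)) {
    mask[starts[s]:(ends[s] + 2L)] <- TRUE
  }
  mask
}

# kind of the region containing each 0-based position (or "unannotated")
region_kind_at <- function(regions, pos) {
  out <- rep("unannotated", length(pos))
  if (is.null(regions) || nrow(regions) == 0) return(out)
  for (r in seq_len(nrow(regions))) {
    inside <- pos >= regions$start[r] & pos < regions$end[r]
    out[inside] <- regions$kind[r]
  }
  out
}

#' Tally dot-matrix points by region pair
#'
#' Each point is assigned by the region containing its window midpoint
#' (`start + floor(window/2)`) on each sequence; points outside any region
#' tally under `"unannotated"`.
#'
#' @param res a [compute_dotplot()] result.
#' @param regions_a,regions_b region tables for the two sequences.
#' @return `data.frame` with columns `kind_a`, `kind_b`, `mode`, `n_points`.
#' @export
region_overlap <- function(res, regions_a, regions_b) {
  half <- res$params$window %/% 2
  p <- res$points
  if (nrow(p) == 0) {
    return(data.frame(kind_a = character(), kind_b = character(),
                      mode = character(), n_points = integer()))
  }
  ka <- region_kind_at(regions_a, p$i + half)
  kb <- region_kind_at(regions_b, p$j + half)
  agg <- stats::aggregate(list(n_points = rep(1L, nrow(p))),
                          by = list(kind_a = ka, kind_b = kb, mode = p$mode),
                          FUN = sum)
  agg[order(agg$kind_a, agg$kind_b, agg$mode), , drop = FALSE]
}

#' UTR similarity score from a dot-matrix result
#'
#' Fraction of UTR positions of sequence A covered by sense diagonal segments
#' of length >= `min_run` whose points have both window midpoints inside UTR
#' regions. Near 1 for conserved UTRs (up to window-edge loss), near 0 for
#' unrelated UTRs.
#'
#' @param res a [compute_dotplot()] result including sense mode.
#' @param regions_a,regions_b region tables; both must annotate at least one
#'   UTR.
#' @param min_run minimum segment length in windows (default 10). At the
#'   9-of-12 threshold, isolated window hits arise between unrelated
#'   sequences at a few per 10^4 window pairs and extend into short
#'   correlated runs, and a shared 20-nt simple-sequence repeat can by
#'   itself produce a 9-window run; requiring 10 consecutive windows
#'   excludes both, so only genuinely conserved stretches count as
#'   similarity.
#'   Simple-sequence repeats (maximal period-1/period-2 tandem tracts of at
#'   least 10 nt, e.g. the GT microsatellites common in these 3' UTRs) are
#'   masked out of both the covered and the total UTR positions: shared
#'   simple repeats produce long diagonals without being evidence of common
#'   descent, so they neither earn nor cost similarity.
#' @return fraction in `[0, 1]`.
#' @export
utr_similarity_score <- function(res, regions_a, regions_b, min_run = 10) {
  utr_kinds <- c("five_prime_utr", "three_prime_utr")
  utr_a <- regions_a[regions_a$kind %in% utr_kinds, , drop = FALSE]
  utr_b <- regions_b[regions_b$kind %in% utr_kinds, , drop = FALSE]
  if (nrow(utr_a) == 0 || nrow(utr_b) == 0) {
    stop("utr_similarity_score requires UTR regions on both records",
         call. = FALSE)
  }
  n <- res$params$window
  half <- n %/% 2
  segs <- res$segments[res$segments$mode == "sense" &
                         res$segments$length >= min_run, , drop = FALSE]
  utr_pos_a <- unlist(mapply(seq, utr_a$start, utr_a$end - 1,
                             SIMPLIFY = FALSE))
  masked <- simple_repeat_mask(s2c(res$a_seq))
  utr_pos_a <- utr_pos_a[!masked[utr_pos_a + 1]]
  if (length(utr_pos_a) == 0) {
    stop("all UTR positions of A are simple-sequence repeat", call. = FALSE)
  }
  covered <- logical(res$a_len)
  if (nrow(segs) > 0) {
    for (s in seq_len(nrow(segs))) {
      ii <- segs$a_start[s] + seq_len(segs$length[s]) - 1L
      jj <- segs$b_start[s] + seq_len(segs$length[s]) - 1L
      in_utr <- region_kind_at(utr_a, ii + half) != "unannotated" &
        region_kind_at(utr_b, jj + half) != "unannotated"
      for (t in which(in_utr)) {
        covered[(ii[t] + 1):(ii[t] + n)] <- TRUE
      }
    }
  }
  sum(covered[utr_pos_a + 1]) / length(utr_pos_a)
}

#' Render a dot-matrix result as a text matrix
#'
#' One character per `bin` x `bin` cell of window-start space: `.` no point,
#' `+` sense only, `x` antisense only, `*` both.
#'
#' @param res a [compute_dotplot()] result.
#' @param bin cell size in bases (>= 1).
#' @return character matrix (rows index A, columns index B).
#' @export
render_text <- function(res, bin = 1L) {
  bin <- as.integer(bin)
  stopifnot(bin >= 1)
  n <- res$params$window
  nr <- (res$a_len - n) %/% bin + 1L
  nc <- (res$b_len - n) %/% bin + 1L
  sense <- matrix(FALSE, nr, nc)
  anti <- matrix(FALSE, nr, nc)
  p <- res$points
  if (nrow(p) > 0) {
    ri <- p$i %/% bin + 1L
    ci <- p$j %/% bin + 1L
    s <- p$mode == "sense"
    sense[cbind(ri[s], ci[s])] <- TRUE
    anti[cbind(ri[!s], ci[!s])] <- TRUE
  }
  out <- matrix(".", nr, nc)
  out[sense & !anti] <- "+"
  out[anti & !sense] <- "x"
  out[sense & anti] <- "*"
  out
}

#' Write a rendered dot matrix to a text file
#'
#' @param res a [compute_dotplot()] result.
#' @param path output path.
#' @param bin cell size passed to [render_text()].
#' @return `path`, invisibly.
#' @export
write_dotplot_text <- function(res, path, bin = 1L) {
  m <- render_text(res, bin)
  writeLines(apply(m, 1, paste, collapse = ""), path)
  invisible(path)
}
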