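# Penalized changepoint segmentation (PELT-style exact search, Gaussian mean
# cost) with a minimum-probe rule. Deterministic for fixed input/parameters.

# exact penalized least-squares segmentation of one numeric vector by
# optimal partitioning (dynamic program over all admissible changepoints,
# vectorized over candidates). every segment is >= min_len points.
# returns integer vector of segment end indices (last index = n).
pelt_mean <- function(x, beta, min_len) {
  n <- length(x)
  min_len <- max(1L, as.integer(min_len))
  if (n < 2L * min_len) return(n)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  f <- rep(Inf, n + 1L)
  f[1L] <- -beta
  cp <- integer(n + 1L)       # last changepoint before t (0 = none)
  for (t in min_len:n) {
    s <- 0:(t - min_len)
    s <- s[s == 0L | s >= min_len]   # every segment honors min_len
    costs <- (s2[t + 1L] - s2[s + 1L]) -
      (s1[t + 1L] - s1[s + 1L])^2 / (t - s)
    tot <- f[s + 1L] + costs + beta
    best <- which.min(tot)
    f[t + 1L] <- tot[best]
    cp[t + 1L] <- s[best]
  }
  ends <- integer(0)
  t <- n
  while (t > 0L) { ends <- c(t, ends); t <- cp[t + 1L] }
  ends
}

default_penalty <- function(x) {
  sigma <- stats::mad(diff(x)) / sqrt(2)
  max(2 * sigma^2 * log(length(x)), 1e-12)
}

#' Segment a log2 (or folded-BAF) track into constant-signal pieces
#'
#' Runs an exact penalized changepoint search (optimal partitioning with
#' pruning, Gaussian mean cost) per chromosome. No emitted segment is shorter
#' than `min_probes` windows; a chromosome with fewer than `2 * min_probes`
#' windows is returned as a single segment. The default penalty is
#' `2 * sigma^2 * log(n)` per changepoint with `sigma` estimated robustly from
#' first differences, so segmentation is invariant to adding a constant to the
#' whole track.
#'
#' @param track a `log2_track` or any data.frame with columns `chrom`,
#'   `start`, `end` and the value column.
#' @param min_probes minimum windows per segment.
#' @param penalty per-changepoint penalty; `NULL` for the default.
#' @param value_col column to segment (default `"log2"`).
#' @return data.frame of class `cn_segments`: `chrom,start,end,n_windows,
#'   mean_log2,sd_log2,first,last` (`first`/`last` are row indices into
#'   `track`).
#' @export
segment_track <- function(track, min_probes = 10L, penalty = NULL,
                          value_col = "log2") {
  w <- as.data.frame(track)
  stopifnot(value_col %in% names(w), !is.unsorted(match(w$chrom, unique(w$chrom))))
  out <- list()
  offset <- 0L
  for (ch in unique(w$chrom)) {
    sel <- which(w$chrom == ch)
    x <- w[[value_col]][sel]
    beta <- if (is.null(penalty)) default_penalty(x) else penalty
    ends <- pelt_mean(x, beta, as.integer(min_probes))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = w$start[sel[starts]],
      end = w$end[sel[ends]],
      n_windows = ends - starts + 1L,
      mean_log2 = vapply(seq_along(ends),
                         function(i) mean(x[starts[i]:ends[i]]), 0),
      sd_log2 = vapply(seq_along(ends),
                       function(i) stats::sd(x[starts[i]:ends[i]]), 0),
      first = offset + starts, last = offset + ends,
      stringsAsFactors = FALSE)
    offset <- offset + length(sel)
  }
  segs <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  segs$sd_log2[is.na(segs$sd_log2)] <- 0
  structure(segs, class = c("cn_segments", "data.frame"))
}

#' Attach a folded-BAF summary to segments
#'
#' For each segment, computes the noise-corrected folded-BAF deviation
#' ([baf_deviation()]) over the informative sites falling inside it, plus the
#' number of supporting sites.
#'
#' @param segments a `cn_segments` table.
#' @param sites informative SNP sites (e.g. [select_informative_sites()])
#'   with `chrom`, `pos`, `baf_t` and depth columns.
#' @return `segments` with columns `mean_folded_baf`, `n_sites` added.
#' @export
annotate_segments_baf <- function(segments, sites) {
  dp <- if (all(c("a_depth_t", "b_depth_t") %in% names(sites))) {
    sites$a_depth_t + sites$b_depth_t
  } else NULL
  segments$mean_folded_baf <- NA_real_
  segments$n_sites <- 0L
  for (i in seq_len(nrow(segments))) {
    sel <- sites$chrom == segments$chrom[i] &
      sites$pos >= segments$start[i] & sites$pos < segments$end[i]
    segments$n_sites[i] <- sum(sel)
    if (any(sel)) {
      segments$mean_folded_baf[i] <-
        baf_deviation(sites$baf_t[sel], dp[sel])
    }
  }
  segments
}

#' Merge adjacent segments with indistinguishable states
#'
#' Abutting segments on the same chromosome are merged when their mean log2
#' values differ by less than `tol` and their folded-BAF states agree (both
#' missing, or differing by less than `baf_tol`). Merging repeats until a
#' fixed point, so the operation is idempotent.
#'
#' @param segments a `cn_segments` table (optionally BAF-annotated).
#' @param tol log2 tolerance for merging.
#' @param baf_tol folded-BAF tolerance for merging.
#' @return merged `cn_segments`.
#' @export
merge_adjacent <- function(segments, tol = 0.1, baf_tol = 0.1) {
  segs <- segments
  has_baf <- "mean_folded_baf" %in% names(segs)
  repeat {
    if (nrow(segs) < 2L) break
    merged <- FALSE
    i <- 1L
    while (i < nrow(segs)) {
      a <- segs[i, ]; b <- segs[i + 1L, ]
      same_baf <- !has_baf ||
        (is.na(a$mean_folded_baf) && is.na(b$mean_folded_baf)) ||
        (!is.na(a$mean_folded_baf) && !is.na(b$mean_folded_baf) &&
           abs(a$mean_folded_baf - b$mean_folded_baf) < baf_tol)
      if (a$chrom == b$chrom && a$end == b$start &&
          abs(a$mean_log2 - b$mean_log2) < tol && same_baf) {
        wts <- c(a$n_windows, b$n_windows)
        segs$end[i] <- b$end
        segs$n_windows[i] <- sum(wts)
        segs$mean_log2[i] <- stats::weighted.mean(
          c(a$mean_log2, b$mean_log2), wts)
        segs$last[i] <- b$last
        if (has_baf) {
          ns <- c(a$n_sites, b$n_sites)
          segs$n_sites[i] <- sum(ns)
          segs$mean_folded_baf[i] <- if (sum(ns) > 0) {
            stats::weighted.mean(c(a$mean_folded_baf, b$mean_folded_baf),
                                 ns, na.rm = TRUE)
          } else NA_real_
        }
        segs <- segs[-(i + 1L), ]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  rownames(segs) <- NULL
  segs
}

#' Cut a track at the union of two segmentations' breakpoints
#'
#' Joint log2 + folded-BAF segmentation: segments are re-derived from the
#' combined breakpoint set of the two input segmentations, so a change in
#' either signal starts a new segment.
#'
#' @param track the track both segmentations refer to.
#' @param segs_a,segs_b two `cn_segments` tables over `track`.
#' @param value_col column of `track` averaged per combined segment.
#' @return a `cn_segments` table on the combined breakpoints.
#' @export
combine_breakpoints <- function(track, segs_a, segs_b, value_col = "log2") {
  w <- as.data.frame(track)
  out <- list()
  for (ch in unique(w$chrom)) {
    sel <- which(w$chrom == ch)
    last_a <- segs_a$last[segs_a$chrom == ch]
    last_b <- segs_b$last[segs_b$chrom == ch]
    ends <- sort(unique(c(last_a, last_b))) - min(sel) + 1L
    ends <- ends[ends >= 1L & ends <= length(sel)]
    if (!length(ends) || max(ends) < length(sel)) {
      ends <- c(ends, length(sel))
    }
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    x <- w[[value_col]][sel]
    out[[ch]] <- data.frame(
      chrom = ch, start = w$start[sel[starts]], end = w$end[sel[ends]],
      n_windows = ends - starts + 1L,
      mean_log2 = vapply(seq_along(ends),
                         function(i) mean(x[starts[i]:ends[i]]), 0),
      sd_log2 = vapply(seq_along(ends), function(i) {
        v <- stats::sd(x[starts[i]:ends[i]]); if (is.na(v)) 0 else v
      }, 0),
      first = min(sel) - 1L + starts, last = min(sel) - 1L + ends,
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(out, list(make.row.names = FALSE))),
            class = c("cn_segments", "data.frame"))
}

#' Write segments as TSV
#' @param segments a `cn_segments` table.
#' @param path output file.
#' @export
write_segments <- function(segments, path) {
  cols <- intersect(c("chrom", "start", "end", "n_windows", "mean_log2",
                      "mean_folded_baf"), names(segments))
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
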