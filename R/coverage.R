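# Pseudo-CGH log2 ratio track from paired tumor/normal read counts.

#' Build read-count windows from per-position coverage
#'
#' Windows are defined on the *normal* sample: along each chromosome, a new
#' window closes as soon as it has accumulated `reads_per_window` normal
#' reads, so window width adapts to coverage (uniform coverage of 10 reads/bp
#' with the default 1000 reads per window gives exact 100 bp windows). Tumor
#' reads are counted inside the same intervals. The last window of a
#' chromosome is closed at the chromosome end even when under-filled and is
#' flagged `underfilled`.
#'
#' @param normal,tumor data.frames of per-position coverage with columns
#'   `chrom`, `pos` (0-based), `depth` (reads starting/assigned there).
#' @param reads_per_window normal reads per window (>= 1).
#' @return data.frame `chrom,start,end,n_normal,n_tumor,underfilled`;
#'   coordinates 0-based half-open.
#' @export
build_windows <- function(normal, tumor, reads_per_window = 1000L) {
  stopifnot(reads_per_window >= 1)
  need <- c("chrom", "pos", "depth")
  stopifnot(all(need %in% names(normal)), all(need %in% names(tumor)))
  if (!nrow(normal)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_normal = numeric(),
                      n_tumor = numeric(), underfilled = logical()))
  }
  out <- list()
  for (ch in unique(normal$chrom)) {
    nc <- normal[normal$chrom == ch, ]
    if (is.unsorted(nc$pos, strictly = FALSE)) {
      stop("normal coverage not sorted by position on ", ch)
    }
    tc <- tumor[tumor$chrom == ch, ]
    cum <- cumsum(nc$depth)
    brk_idx <- which(diff(c(0, cum %/% reads_per_window)) > 0)
    starts <- c(nc$pos[1], nc$pos[brk_idx] + 1)
    ends <- c(nc$pos[brk_idx] + 1, max(nc$pos, tc$pos) + 1)
    keep <- starts < ends
    starts <- starts[keep]; ends <- ends[keep]
    n <- length(starts)
    iv <- findInterval(nc$pos, starts)
    n_norm <- vapply(seq_len(n), function(i) sum(nc$depth[iv == i]), 0)
    ivt <- findInterval(tc$pos, starts)
    n_tum <- vapply(seq_len(n), function(i) sum(tc$depth[ivt == i]), 0)
    out[[ch]] <- data.frame(
      chrom = ch, start = starts, end = ends,
      n_normal = n_norm, n_tumor = n_tum,
      underfilled = n_norm < reads_per_window, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Compute the median-centered log2 ratio track
#'
#' For each window, `log2(n_tumor / n_normal)` minus the genome-wide median
#' (the median is taken over fully-filled windows only and is stored as the
#' `centering_offset` attribute). A diploid window (ratio 1:1) then sits at 0,
#' a 3:2 single-copy gain at 0.58 and a 1:2 heterozygous loss at -1, provided
#' most of the genome is unaltered. Windows with zero tumor reads are floored
#' at `floor` and flagged; windows with zero normal reads are dropped with a
#' warning.
#'
#' @param windows window count table (see [build_windows()] or
#'   [simulate_counts()]); an `underfilled` column is honored if present.
#' @param floor log2 value assigned when `n_tumor` is 0.
#' @return data.frame of class `log2_track` with added columns `log2`,
#'   `floored`; attributes `centering_offset`, `baseline_shift` (0 until
#'   [recenter_baseline()] is applied).
#' @export
compute_log2 <- function(windows, floor = -5) {
  w <- as.data.frame(windows)
  if (!"underfilled" %in% names(w)) w$underfilled <- FALSE
  if (any(w$n_normal == 0)) {
    warning(sum(w$n_normal == 0), " window(s) with zero normal reads dropped")
    w <- w[w$n_normal > 0, , drop = FALSE]
  }
  raw <- log2(w$n_tumor / w$n_normal)
  w$floored <- w$n_tumor == 0
  raw[w$floored] <- floor
  med <- stats::median(raw[!w$underfilled & !w$floored])
  w$log2 <- raw - med
  w$log2[w$floored] <- floor
  structure(w, class = c("log2_track", "data.frame"),
            centering_offset = med, baseline_shift = 0)
}

#' Expected centered log2 ratio of a copy-number state
#'
#' In a sample of purity `p` where a fraction `f` of tumor cells carries an
#' event with total copy number `c`, the expected tumor:normal ratio is
#' `(2(1 - p) + p((1 - f) * 2 + f * c)) / 2`, and the expected (diploid-
#' centered) log2 ratio is its log2. Normal-cell admixture and subclonality
#' both compress the signal toward 0: a clonal single-copy gain at purity 1
#' gives 0.585, a clonal heterozygous loss gives -1, and a homozygous loss in
#' half the cells gives -1 as well -- the depth degeneracy that only the BAF
#' can break.
#'
#' @param copy_state integer total copy number `c >= 0` of the event.
#' @param purity tumor-cell fraction `p` of the sample, in `[0, 1]`.
#' @param fraction fraction `f` of tumor cells carrying the event.
#' @return expected log2 ratio; `-Inf` when the expected copy is 0.
#' @export
expected_log2 <- function(copy_state, purity = 1, fraction = 1) {
  stopifnot(all(copy_state >= 0), all(purity >= 0 & purity <= 1),
            all(fraction >= 0 & fraction <= 1))
  total <- 2 * (1 - purity) + purity * ((1 - fraction) * 2 +
                                          fraction * copy_state)
  ifelse(total <= 0, -Inf, log2(total / 2))
}

#' Correct the log2 baseline for aneuploidy using the BAF track
#'
#' Median centering assumes most of the genome is copy-neutral; in a heavily
#' aneuploid genome the median can land inside altered territory and shift the
#' whole track. True diploid regions are recognizable because their
#' germline-het BAFs stay at 0.5. This function segments the track, looks for
#' segments whose site-level median folded BAF (`|BAF - 0.5|`) is below
#' `epsilon`, whose log2 standard deviation is unremarkable and that span at
#' least `min_span` windows, takes the longest qualifying span, and subtracts
#' its mean log2 from the whole track. If no span qualifies the track is
#' returned unchanged with a warning.
#'
#' @param track a `log2_track`.
#' @param baf_sites data.frame with `chrom`, `pos` and tumor BAF in `baf_t`
#'   (or `baf`).
#' @param epsilon tolerance on the median folded BAF of a diploid span.
#' @param min_span minimum number of windows in a qualifying span.
#' @param min_probes,penalty passed to [segment_track()].
#' @return the recentered `log2_track`; attribute `baseline_shift` records the
#'   subtracted value.
#' @export
recenter_baseline <- function(track, baf_sites, epsilon = 0.03,
                              min_span = 50L, min_probes = 10L,
                              penalty = NULL) {
  stopifnot(inherits(track, "log2_track"))
  baf <- if ("baf_t" %in% names(baf_sites)) baf_sites$baf_t else baf_sites$baf
  segs <- segment_track(track, min_probes = min_probes, penalty = penalty)
  med_fold <- vapply(seq_len(nrow(segs)), function(i) {
    sel <- baf_sites$chrom == segs$chrom[i] & baf_sites$pos >= segs$start[i] &
      baf_sites$pos < segs$end[i]
    if (!any(sel)) return(NA_real_)
    stats::median(abs(baf[sel] - 0.5))
  }, 0)
  sd_all <- stats::sd(track$log2[!track$floored])
  ok <- !is.na(med_fold) & med_fold < epsilon & segs$n_windows >= min_span &
    segs$sd_log2 <= 2 * sd_all
  if (!any(ok)) {
    warning("no diploid span with BAF near 0.5 found; baseline unchanged")
    return(track)
  }
  pick <- which(ok)[which.max(segs$n_windows[ok])]
  shift <- segs$mean_log2[pick]
  track$log2 <- track$log2 - shift
  attr(track, "baseline_shift") <- attr(track, "baseline_shift") + shift
  track
}

#' @export
plot.log2_track <- function(x, ylim = c(-3, 3), ...) {
  idx <- seq_len(nrow(x))
  graphics::plot(idx, pmax(pmin(x$log2, ylim[2]), ylim[1]), pch = 16,
                 cex = 0.3, col = "grey40", xlab = "window index",
                 ylab = "log2 ratio", ylim = ylim, ...)
  graphics::abline(h = 0, col = "red3")
  bounds <- cumsum(rle(as.character(x$chrom))$lengths)
  graphics::abline(v = bounds + 0.5, col = "grey80", lty = 3)
  invisible(x)
}

#' Write a log2 track as TSV (BED-compatible columns first)
#' @param track a `log2_track`.
#' @param path output file.
#' @export
write_log2_track <- function(track, path) {
  utils::write.table(
    track[, c("chrom", "start", "end", "n_normal", "n_tumor", "log2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
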