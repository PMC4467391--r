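# Classification of segments into copy-number events: graded loss/gain
# categories, clonal vs subclonal calls from joint log2 + BAF evidence, cell
# fraction estimates, two-level loss clustering and the subclonal
# homozygous-loss special case.

#' Classification thresholds for copy-number events
#'
#' All thresholds apply on the purity-corrected log2 scale (the log2 ratio a
#' pure sample would show, recovered via
#' `c_hat = (2^(log2+1) - 2(1 - p)) / p`). Gain grades (`CG` copy gain,
#' `HCG` high, `VHCG` very high, `EHCG` extreme) are binned by log2; a clonal
#' single-copy gain (log2 0.585) lands in HCG under the defaults. Losses are
#' called below `loss_max`; a purity-corrected copy estimate below
#' `hl_max_copy` triggers a homozygous-loss (`HL`) call. `complete_tol` is the
#' tolerance on the BAF-based `p*f` estimate for calling a loss complete
#' (`f = 1`, i.e. `p*f = purity`). `hl_baf_folded_max` is the folded-BAF
#' ceiling under which a deep loss counts as "BAF still at 0.5" for the
#' subclonal-HL rescue, and `min_separation` is the minimum log2 distance
#' between the two loss levels for two-level clustering to accept two levels.
#'
#' @param gain_min,hcg_min,vhcg_min,ehcg_min lower log2 edges of the gain
#'   grades.
#' @param loss_max log2 ceiling for calling a loss.
#' @param hl_max_copy purity-corrected copy number below which HL is called.
#' @param complete_tol tolerance for complete-vs-subclonal loss calls.
#' @param hl_baf_folded_max folded-BAF ceiling for the subclonal-HL rescue.
#' @param min_separation minimum log2 gap between loss levels.
#' @return named list of class `cn_thresholds`.
#' @export
cn_thresholds <- function(gain_min = 0.15, hcg_min = 0.55, vhcg_min = 1.0,
                          ehcg_min = 1.8, loss_max = -0.1,
                          hl_max_copy = 0.35, complete_tol = 0.1,
                          hl_baf_folded_max = 0.1, min_separation = 0.25) {
  stopifnot(gain_min < hcg_min, hcg_min < vhcg_min, vhcg_min < ehcg_min,
            loss_max < 0, hl_max_copy >= 0)
  structure(list(gain_min = gain_min, hcg_min = hcg_min,
                 vhcg_min = vhcg_min, ehcg_min = ehcg_min,
                 loss_max = loss_max, hl_max_copy = hl_max_copy,
                 complete_tol = complete_tol,
                 hl_baf_folded_max = hl_baf_folded_max,
                 min_separation = min_separation),
            class = "cn_thresholds")
}

# observed log2 -> log2 a pure, clonal sample would show
purity_corrected_log2 <- function(log2r, purity) {
  chat <- (2^(log2r + 1) - 2 * (1 - purity)) / purity
  ifelse(chat <= 0, -Inf, log2(chat / 2))
}

#' Estimate the aberrant cell fraction of a loss segment
#'
#' For a heterozygous loss, inverts the expected minor BAF
#' `m = (1 - p*f) / (2 - p*f)` to `p*f = (1 - 2m) / (1 - m)`; the log2-based
#' inversion `p*f = 2 - 2^(log2 + 1)` is returned alongside as a diagnostic.
#' For a homozygous loss the log2 route `p*f = 1 - 2^log2` is the estimate
#' (the BAF of the surviving cells stays near 0.5 and carries no fraction
#' signal). A minor BAF above 0.5 is impossible and is clipped with a warning.
#'
#' @param folded_baf folded BAF of the segment (`0.5 - minor`), may be `NA`.
#' @param mean_log2 segment mean log2 ratio.
#' @param kind `"het_loss"` or `"hom_loss"`.
#' @return list with `estimate` (the `p*f` estimate in `[0, 1]`),
#'   `baf_based`, `log2_based`.
#' @export
estimate_fraction <- function(folded_baf, mean_log2, kind = "het_loss") {
  kind <- match.arg(kind, c("het_loss", "hom_loss"))
  pf_log2 <- if (kind == "het_loss") 2 - 2^(mean_log2 + 1) else
    1 - 2^(mean_log2)
  pf_log2 <- min(max(pf_log2, 0), 1)
  pf_baf <- NA_real_
  if (!is.na(folded_baf) && kind == "het_loss") {
    m <- 0.5 - folded_baf
    if (m < 0) {
      warning("minor BAF above 0.5 is impossible; clipped to 0")
      m <- 0
    }
    pf_baf <- (1 - 2 * m) / (1 - m)
  }
  est <- if (!is.na(pf_baf)) pf_baf else pf_log2
  list(estimate = est, baf_based = pf_baf, log2_based = pf_log2)
}

classify_one <- function(chrom, start, end, mean_log2, folded, purity, th,
                         amplified_regions) {
  l2 <- purity_corrected_log2(mean_log2, purity)
  length_mb <- round((end - start) / 1e6, 2)
  row <- data.frame(chrom = chrom, start = start, end = end,
                    length_mb = length_mb, type = NA_character_,
                    clonality = NA_character_, est_fraction = NA_real_,
                    loss_level = NA_integer_, mean_log2 = mean_log2,
                    mean_folded_baf = folded, stringsAsFactors = FALSE)
  if (is.finite(l2) && l2 >= th$gain_min) {
    row$type <- if (l2 >= th$ehcg_min) "EHCG" else if (l2 >= th$vhcg_min)
      "VHCG" else if (l2 >= th$hcg_min) "HCG" else "CG"
    row$clonality <- "indeterminate"   # gains carry no clonality call
    return(row)
  }
  if (!is.finite(l2) || l2 <= th$loss_max) {
    chat <- (2^(mean_log2 + 1) - 2 * (1 - purity)) / purity
    if (chat < th$hl_max_copy) {
      row$type <- "HL"
      row$clonality <- "complete"
      row$est_fraction <- purity
      return(row)
    }
    row$type <- "LOH"
    if (!is.null(amplified_regions) && nrow(amplified_regions)) {
      inside <- amplified_regions$chrom == chrom &
        amplified_regions$start <= start + 1 &
        amplified_regions$end >= end - 1
      if (any(inside)) row$type <- "OCL"
    }
    est <- estimate_fraction(folded, mean_log2, "het_loss")
    row$est_fraction <- min(max(est$estimate, 0), 1)
    row$clonality <- if (is.na(folded)) "indeterminate" else
      if (row$est_fraction >= purity - th$complete_tol) "complete" else
        "subclonal"
    return(row)
  }
  NULL   # within the neutral band: no event
}

#' Classify segments into copy-number events
#'
#' Applies the event vocabulary: losses become `LOH` (or `OCL` when the
#' interval lies inside previously amplified territory supplied via
#' `amplified_regions`, or `HL` when the purity-corrected copy estimate is
#' near zero); gains are graded `CG`/`HCG`/`VHCG`/`EHCG` and always carry
#' clonality `indeterminate`, since the log2 ratio cannot distinguish a
#' moderate gain in all tumor cells from a strong gain in a subclone. Loss
#' clonality is `complete` when the BAF-based `p*f` estimate reaches the
#' sample purity within tolerance, `subclonal` below it, and `indeterminate`
#' without BAF support. Segments inside the neutral band yield no event.
#'
#' @param segments a `cn_segments` table, ideally BAF-annotated
#'   ([annotate_segments_baf()]).
#' @param purity tumor-cell fraction of the sample.
#' @param thresholds a [cn_thresholds()] configuration.
#' @param amplified_regions optional data.frame (`chrom,start,end`, bp) of
#'   gain territory from an earlier sample, used for `OCL` assignment.
#' @return data.frame of class `cn_events`: `chrom,start,end,length_mb,type,
#'   clonality,est_fraction,loss_level,mean_log2,mean_folded_baf`.
#' @export
classify_segments <- function(segments, purity = 1,
                              thresholds = cn_thresholds(),
                              amplified_regions = NULL) {
  folded <- if ("mean_folded_baf" %in% names(segments))
    segments$mean_folded_baf else rep(NA_real_, nrow(segments))
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    classify_one(segments$chrom[i], segments$start[i], segments$end[i],
                 segments$mean_log2[i], folded[i], purity, thresholds,
                 amplified_regions)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  ev <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  length_mb = numeric(), type = character(),
                  clonality = character(), est_fraction = numeric(),
                  loss_level = integer(), mean_log2 = numeric(),
                  mean_folded_baf = numeric(), stringsAsFactors = FALSE)
  structure(ev, class = c("cn_events", "data.frame"))
}

#' Assign Level 1 / Level 2 to loss events by two-level clustering
#'
#' Splits the mean log2 values of loss events into two clusters by the exact
#' 1-D two-means split (all sorted cut positions scanned). If the cluster
#' centers are closer than `min_separation` the losses form a single level
#' and all are Level 2 (complete). Otherwise the deeper cluster is Level 2
#' and the shallower Level 1 (subclonal) -- the two-subclone signature seen
#' when a catastrophic event deposits many losses in part of the population.
#'
#' @param events a `cn_events` table.
#' @param min_separation minimum log2 distance between level centers.
#' @return `events` with `loss_level` filled for loss rows.
#' @export
detect_loss_levels <- function(events, min_separation = 0.25) {
  loss <- which(events$type %in% c("LOH", "HL", "OCL"))
  if (!length(loss)) return(events)
  x <- events$mean_log2[loss]
  if (length(loss) == 1L) {
    events$loss_level[loss] <- 2L
    return(events)
  }
  ord <- order(x)
  xs <- x[ord]
  best <- NULL; best_ss <- Inf
  for (k in seq_len(length(xs) - 1L)) {
    lo <- xs[1:k]; hi <- xs[(k + 1):length(xs)]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) { best_ss <- ss; best <- k }
  }
  lo <- xs[1:best]; hi <- xs[(best + 1):length(xs)]
  if (abs(mean(hi) - mean(lo)) < min_separation) {
    events$loss_level[loss] <- 2L
  } else {
    deep <- x <= xs[best]           # deeper (more negative) = complete
    events$loss_level[loss] <- ifelse(deep, 2L, 1L)
  }
  events
}

#' Rescue subclonal homozygous losses hiding at Level-2 depth
#'
#' A loss at Level-2 depth whose folded BAF stays near 0 (BAF around 0.5)
#' cannot be a complete heterozygous loss: the depth is explained instead by
#' a *homozygous* loss in one subclone while the other subclone keeps both
#' alleles, whose balanced reads produce the 0.5 BAF. Such events are
#' reclassified `HL`, clonality `subclonal`, with the cell fraction from the
#' log2 depth under total copy 0: `p*f = 1 - 2^log2` (a log2 of -1 with BAF
#' 0.5 gives `p*f = 0.5`: the two subclones are about equally large).
#'
#' @param events a `cn_events` table with `loss_level` assigned.
#' @param thresholds a [cn_thresholds()] configuration.
#' @return `events` with qualifying rows reclassified.
#' @export
resolve_homozygous_subclonal <- function(events,
                                         thresholds = cn_thresholds()) {
  sel <- which(events$type == "LOH" & !is.na(events$loss_level) &
                 events$loss_level == 2L &
                 !is.na(events$mean_folded_baf) &
                 events$mean_folded_baf < thresholds$hl_baf_folded_max)
  for (i in sel) {
    events$type[i] <- "HL"
    events$clonality[i] <- "subclonal"
    events$est_fraction[i] <-
      estimate_fraction(NA, events$mean_log2[i], "hom_loss")$estimate
  }
  events
}

#' @export
print.cn_events <- function(x, ...) {
  cat("Copy-number events:", nrow(x), "(",
      sum(x$type %in% c("LOH", "HL", "OCL")), "loss,",
      sum(!x$type %in% c("LOH", "HL", "OCL")), "gain )\n")
  print.data.frame(utils::head(as.data.frame(x), 20), digits = 3)
  if (nrow(x) > 20) cat("...\n")
  invisible(x)
}
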