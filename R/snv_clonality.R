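# Somatic SNV filtering and cross-sample clonality tracking.

#' Filter somatic variant candidates with the fixed depth/BAF thresholds
#'
#' A candidate is retained when (i) the matched normal has depth >=
#' `min_normal_depth` and is homozygous reference (`normal BAF <
#' max_normal_baf`), (ii) it is not a known population SNP with allele
#' frequency above `max_pop_af`, and (iii) at least one tumor sample shows
#' both `alt_depth >= min_alt` and `BAF > min_baf`. The mutation is then
#' *noted present* in every sample whose BAF exceeds `presence_baf`, so a
#' variant discovered confidently in one stage is tracked at trace level in
#' the others. Candidates without normal data are rejected with reason
#' `no_normal`. The filter is row-order independent.
#'
#' @param calls long-format data.frame: one row per variant x tumor sample
#'   with columns `chrom,pos,ref,alt,sample,depth,alt_depth`, plus
#'   `normal_depth,normal_alt_depth` (or a precomputed `normal_baf`) and
#'   optionally `known_snp_af`.
#' @param min_normal_depth,max_normal_baf,min_alt,min_baf,presence_baf,max_pop_af
#'   filter thresholds.
#' @return object of class `somatic_calls`: list with `variants` (one row per
#'   retained variant), matrices `baf`, `alt`, `depth`, `presence`
#'   (variants x samples), `samples`, and `rejected` (variant table with a
#'   `reason` column).
#' @export
filter_somatic <- function(calls, min_normal_depth = 10L,
                           max_normal_baf = 0.02, min_alt = 3L,
                           min_baf = 0.15, presence_baf = 0.05,
                           max_pop_af = 0.01) {
  d <- as.data.frame(calls)
  need <- c("chrom", "pos", "ref", "alt", "sample", "depth", "alt_depth")
  stopifnot(all(need %in% names(d)))
  if (!"normal_depth" %in% names(d)) d$normal_depth <- NA_real_
  if (!"normal_alt_depth" %in% names(d)) d$normal_alt_depth <- NA_real_
  if (!"normal_baf" %in% names(d)) {
    d$normal_baf <- ifelse(!is.na(d$normal_depth) & d$normal_depth > 0,
                           d$normal_alt_depth / d$normal_depth, NA_real_)
  }
  if (!"known_snp_af" %in% names(d)) d$known_snp_af <- NA_real_
  d$baf <- ifelse(d$depth > 0, d$alt_depth / d$depth, 0)
  key <- paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  ukey <- sort(unique(key))
  samples <- unique(d$sample)
  idx <- function(col) {
    m <- matrix(NA_real_, length(ukey), length(samples),
                dimnames = list(ukey, samples))
    m[cbind(match(key, ukey), match(d$sample, samples))] <- d[[col]]
    m
  }
  baf <- idx("baf"); alt <- idx("alt_depth"); dp <- idx("depth")
  first <- d[!duplicated(key), ]
  first <- first[match(ukey, paste(first$chrom, first$pos, first$ref,
                                   first$alt, sep = ":")), ]
  variants <- first[, intersect(c("chrom", "pos", "ref", "alt", "annotation",
                                  "known_snp_af", "normal_depth",
                                  "normal_baf", "truth_clone"),
                                names(first))]
  rownames(variants) <- NULL
  reason <- rep(NA_character_, length(ukey))
  no_normal <- is.na(variants$normal_depth) | is.na(variants$normal_baf)
  reason[no_normal] <- "no_normal"
  bad_normal <- !no_normal & (variants$normal_depth < min_normal_depth |
                                variants$normal_baf >= max_normal_baf)
  reason[bad_normal] <- "normal_fails"
  pop <- !is.na(variants$known_snp_af) & variants$known_snp_af > max_pop_af
  reason[is.na(reason) & pop] <- "known_snp"
  confident <- rowSums(alt >= min_alt & baf > min_baf, na.rm = TRUE) > 0
  reason[is.na(reason) & !confident] <- "no_confident_sample"
  keep <- is.na(reason)
  presence <- baf > presence_baf
  presence[is.na(presence)] <- FALSE
  structure(list(
    variants = variants[keep, , drop = FALSE],
    baf = baf[keep, , drop = FALSE],
    alt = alt[keep, , drop = FALSE],
    depth = dp[keep, , drop = FALSE],
    presence = presence[keep, , drop = FALSE],
    samples = samples,
    rejected = cbind(variants[!keep, , drop = FALSE],
                     reason = reason[!keep])
  ), class = "somatic_calls")
}

#' @export
print.somatic_calls <- function(x, ...) {
  cat("Somatic calls:", nrow(x$variants), "retained variants across",
      length(x$samples), "samples (", nrow(x$rejected), "rejected )\n")
  invisible(x)
}

#' Per-variant presence matrix and membership-pattern counts
#'
#' Summarizes the cross-sample concordance of retained mutations: the boolean
#' presence matrix plus the count of every membership pattern (shared by all,
#' private to each sample, and every combination between), the numbers behind
#' a multi-sample Venn diagram.
#'
#' @param sc a `somatic_calls` object.
#' @return list with `presence` (logical matrix), `pattern_counts` (named
#'   integer vector; names are `+`-joined sample subsets), `shared_by_all`,
#'   and `private` (named count per sample).
#' @export
presence_matrix <- function(sc) {
  stopifnot(inherits(sc, "somatic_calls"))
  pres <- sc$presence
  pat <- apply(pres, 1, function(r) paste(sc$samples[r], collapse = "+"))
  pat[pat == ""] <- "(none)"
  counts <- table(pat)
  pattern_counts <- stats::setNames(as.integer(counts), names(counts))
  private <- vapply(sc$samples, function(s) {
    sum(pres[, s] & rowSums(pres) == 1L)
  }, 0L)
  list(presence = pres, pattern_counts = pattern_counts,
       shared_by_all = sum(rowSums(pres) == ncol(pres)),
       private = private)
}

#' Detect purification of subclonal mutations between two samples
#'
#' A mutation that is subclonal in an early sample (BAF inside
#' `subclonal_band`) but fully clonal heterozygous in a later one (BAF inside
#' `clonal_band`) marks the later lesion as descending from the early
#' subclone: the subclone's variants were "purified" to the whole population.
#' Only variants present in both samples are considered.
#'
#' @param sc a `somatic_calls` object.
#' @param early_sample,late_sample sample ids.
#' @param subclonal_band,clonal_band BAF intervals (default bracket the
#'   10-15% and 40-48% signatures of a subclone-seeded metastasis).
#' @return the flagged subset of `sc$variants` with `baf_early`, `baf_late`.
#' @export
detect_purification <- function(sc, early_sample, late_sample,
                                subclonal_band = c(0.05, 0.25),
                                clonal_band = c(0.35, 0.55)) {
  stopifnot(inherits(sc, "somatic_calls"),
            early_sample %in% sc$samples, late_sample %in% sc$samples)
  be <- sc$baf[, early_sample]; bl <- sc$baf[, late_sample]
  flag <- sc$presence[, early_sample] & sc$presence[, late_sample] &
    !is.na(be) & !is.na(bl) &
    be >= subclonal_band[1] & be <= subclonal_band[2] &
    bl >= clonal_band[1] & bl <= clonal_band[2]
  out <- sc$variants[flag, , drop = FALSE]
  out$baf_early <- be[flag]
  out$baf_late <- bl[flag]
  out
}

#' Mutation-frequency density and mode count for one sample
#'
#' Kernel density (Silverman bandwidth) of the BAFs of variants present in
#' `sample`, after excluding variants that overlap supplied copy-number
#' events (whose BAFs reflect copy state, not clone size). Modes are local
#' maxima with height at least `prominence` of the tallest peak: one mode is
#' consistent with a monoclonal population, two reveal a coexisting subclone.
#'
#' @param sc a `somatic_calls` object.
#' @param sample sample id.
#' @param exclude_events optional `cn_events`-like data.frame
#'   (`chrom,start,end` in bp) whose territory is excluded.
#' @param min_variants below this many usable variants the mode count is `NA`.
#' @param prominence minimum peak height relative to the maximum.
#' @return list with `baf` (used values), `density`, `modes` (BAF positions),
#'   `n_modes`.
#' @export
vaf_density <- function(sc, sample, exclude_events = NULL,
                        min_variants = 5L, prominence = 0.1) {
  stopifnot(inherits(sc, "somatic_calls"), sample %in% sc$samples)
  use <- sc$presence[, sample]
  if (!is.null(exclude_events) && nrow(exclude_events)) {
    v <- sc$variants
    inside <- vapply(seq_len(nrow(v)), function(i) {
      any(exclude_events$chrom == v$chrom[i] &
            exclude_events$start <= v$pos[i] &
            exclude_events$end > v$pos[i])
    }, TRUE)
    use <- use & !inside
  }
  baf <- sc$baf[use, sample]
  baf <- baf[!is.na(baf)]
  if (length(baf) < min_variants) {
    return(list(baf = baf, density = NULL, modes = numeric(),
                n_modes = NA_integer_))
  }
  dens <- stats::density(baf, bw = "nrd0", from = 0, to = 1)
  y <- dens$y
  cand <- which(diff(sign(diff(y))) == -2) + 1L
  cand <- cand[y[cand] >= prominence * max(y)]
  # prune ripples: keep a peak only if a valley at least `prominence` of the
  # maximum below it separates it from every taller accepted peak
  cand <- cand[order(y[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (p in cand) {
    ok <- TRUE
    for (q in peaks) {
      rng <- if (p < q) p:q else q:p
      if (min(y[rng]) > y[p] - prominence * max(y)) { ok <- FALSE; break }
    }
    if (ok) peaks <- c(peaks, p)
  }
  peaks <- sort(peaks)
  list(baf = baf, density = dens, modes = dens$x[peaks],
       n_modes = length(peaks))
}
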