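# B-allele frequencies at germline heterozygous known-SNP sites.

#' B-allele frequency
#'
#' `BAF = b / (a + b)`, the fraction of reads carrying the B (alternate)
#' allele. Undefined (NA) at zero total depth.
#'
#' @param a,b read depths of the A and B allele.
#' @return numeric in `[0, 1]`, `NA` where `a + b == 0`.
#' @export
compute_baf <- function(a, b) {
  stopifnot(all(a >= 0), all(b >= 0))
  tot <- a + b
  ifelse(tot > 0, b / tot, NA_real_)
}

#' Folded (mirrored) BAF
#'
#' `|BAF - 0.5|`: removes haplotype orientation so the magnitude of allelic
#' imbalance can be averaged across sites (0 at a balanced site, 0.5 at a
#' complete het loss).
#'
#' @param baf numeric BAF values.
#' @export
folded_baf <- function(baf) abs(baf - 0.5)

#' Select informative germline-heterozygous known-SNP sites
#'
#' Keeps sites that are annotated known SNPs, germline heterozygous, and
#' covered by at least `min_depth` reads in *both* tumor and normal. If the
#' table has no `germline_het` flag, heterozygosity is called from the normal
#' BAF falling inside `het_range` (at qualifying depth).
#'
#' @param sites data.frame with `a_depth_t,b_depth_t,a_depth_n,b_depth_n` and
#'   optionally `known_snp`, `germline_het`.
#' @param min_depth minimum total depth in each of tumor and normal.
#' @param het_range normal-BAF window used to call heterozygosity when no
#'   `germline_het` flag is supplied.
#' @return the filtered sites with added columns `baf_t`, `baf_n`,
#'   `folded_baf` (tumor) and `pass_filter` (all TRUE).
#' @export
select_informative_sites <- function(sites, min_depth = 30L,
                                     het_range = c(0.25, 0.75)) {
  s <- as.data.frame(sites)
  dp_t <- s$a_depth_t + s$b_depth_t
  dp_n <- s$a_depth_n + s$b_depth_n
  s$baf_t <- compute_baf(s$a_depth_t, s$b_depth_t)
  s$baf_n <- compute_baf(s$a_depth_n, s$b_depth_n)
  known <- if ("known_snp" %in% names(s)) s$known_snp else TRUE
  het <- if ("germline_het" %in% names(s)) s$germline_het else {
    !is.na(s$baf_n) & s$baf_n >= het_range[1] & s$baf_n <= het_range[2]
  }
  keep <- known & het & dp_t >= min_depth & dp_n >= min_depth &
    !is.na(s$baf_t)
  out <- s[keep, , drop = FALSE]
  out$folded_baf <- folded_baf(out$baf_t)
  out$pass_filter <- TRUE
  out
}

#' Expected BAF split under a copy-number event
#'
#' For a heterozygous loss of one haplotype carried by the fraction
#' `p * f` of all sequenced cells, the minor BAF mode is
#' `(1 - p*f) / (2 - p*f)` and the major mode its mirror `1 - minor`: a full
#' clonal loss at purity 1 splits to 0 and 1, while normal admixture or
#' subclonality pulls the split inward (the deviation from a 0/1 split
#' measures `p * f`). Balanced states (no event, balanced gain) stay at 0.5.
#'
#' @param purity tumor-cell fraction of the sample.
#' @param fraction fraction of tumor cells carrying the event.
#' @param kind `"het_loss"`, `"none"` or `"balanced_gain"`.
#' @return named numeric vector `c(minor=, major=)`.
#' @export
expected_baf <- function(purity, fraction, kind = "het_loss") {
  stopifnot(purity >= 0, purity <= 1, fraction >= 0, fraction <= 1)
  kind <- match.arg(kind, c("het_loss", "none", "balanced_gain"))
  if (kind != "het_loss") return(c(minor = 0.5, major = 0.5))
  pf <- purity * fraction
  minor <- (1 - pf) / (2 - pf)
  c(minor = minor, major = 1 - minor)
}

#' Noise-corrected folded-BAF deviation of a set of sites
#'
#' The raw mean of `|BAF - 0.5|` over sites is biased upward by binomial
#' sampling noise (folding rectifies noise), which matters exactly where
#' subtle allelic imbalance must be quantified. Since
#' `E[(BAF - 0.5)^2] = delta^2 + sigma^2` with `sigma^2 ~ 0.25 / depth` at a
#' (near-)balanced site, the deviation `delta` is recovered as
#' `sqrt(max(0, mean((BAF - 0.5)^2) - mean(0.25 / depth)))`.
#'
#' @param baf site BAFs.
#' @param depth site total depths (same length); if `NULL` no correction.
#' @return non-negative scalar deviation from 0.5 (`NA` if no sites).
#' @export
baf_deviation <- function(baf, depth = NULL) {
  baf <- baf[!is.na(baf)]
  if (!length(baf)) return(NA_real_)
  msq <- mean((baf - 0.5)^2)
  noise <- if (is.null(depth)) 0 else mean(0.25 / depth[depth > 0])
  sqrt(max(0, msq - noise))
}

#' Write a BAF track as TSV
#' @param sites output of [select_informative_sites()].
#' @param path output file.
#' @export
write_baf_track <- function(sites, path) {
  utils::write.table(
    sites[, c("chrom", "pos", "baf_t", "folded_baf", "pass_filter")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
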