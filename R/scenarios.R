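# Canned simulation scenarios: a four-stage nested progression mimicking the
# studied disease course, and a single-sample metastasis with two coexisting
# subclones. These fix the study conditions the rest of the package is
# exercised against.

#' Four-stage nested tumor progression scenario
#'
#' Two pre-invasive lesions, a primary tumor and an asynchronous metastasis
#' sharing one truncal clone, with stage-specific clones layered on top:
#' a side branch private to the second pre-invasive sample (point mutations
#' only), an invasive clone fixed in the primary, a metastasis-founder clone
#' that is subclonal (prevalence 0.3) in the primary and fixed in the
#' metastasis (carrying the mutations that appear "purified" there), a
#' metastasis clone adding complete events, and a late metastasis subclone
#' (prevalence 0.5) adding further subclonal losses. Purities are 0.75-0.85,
#' the histology floor of a curated tumor specimen. Copy events are nested
#' across stages, so the truth verdict is linear-consistent.
#'
#' @return list with `tree`, `cn_events`, `snvs`, `genome` and `stages`.
#' @export
demo_scenario <- function() {
  genome <- mini_genome(5)
  samples <- c("dcis1", "dcis2", "primary", "metastasis")
  clones <- c("A", "B", "A2", "P", "M0", "M1", "M2")
  parent <- c(A = NA, B = "A", A2 = "A", P = "A2", M0 = "P", M1 = "M0",
              M2 = "M1")
  prev <- rbind(
    dcis1 =      c(A = 1, B = 0,    A2 = 0,   P = 0, M0 = 0,   M1 = 0, M2 = 0),
    dcis2 =      c(A = 1, B = 0.55, A2 = 0.4, P = 0, M0 = 0,   M1 = 0, M2 = 0),
    primary =    c(A = 1, B = 0,    A2 = 1,   P = 1, M0 = 0.3, M1 = 0, M2 = 0),
    metastasis = c(A = 1, B = 0,    A2 = 1,   P = 1, M0 = 1,   M1 = 1, M2 = 0.5))
  purity <- c(dcis1 = 0.85, dcis2 = 0.80, primary = 0.75, metastasis = 0.80)
  tree <- clone_tree(clones, parent, prev, purity)
  mb <- 1e6
  ev <- rbind(
    cn_event_spec("chr1",  5 * mb, 20 * mb, "het_loss", "A",  allele = 1L),
    cn_event_spec("chr2", 10 * mb, 22 * mb, "het_loss", "A",  allele = 1L),
    cn_event_spec("chr3",  4 * mb, 12 * mb, "het_loss", "A",  allele = 2L),
    cn_event_spec("chr1", 35 * mb, 45 * mb, "gain",     "A",  copies = 4L, allele = 2L),
    cn_event_spec("chr4",  6 * mb, 12 * mb, "gain",     "A",  copies = 3L, allele = 1L),
    cn_event_spec("chr2", 30 * mb, 40 * mb, "het_loss", "A2", allele = 1L),
    cn_event_spec("chr4", 16 * mb, 24 * mb, "het_loss", "A2", allele = 2L),
    cn_event_spec("chr5",  2 * mb,  8 * mb, "gain",     "A2", copies = 5L, allele = 1L),
    cn_event_spec("chr3", 20 * mb, 32 * mb, "het_loss", "P",  allele = 1L),
    cn_event_spec("chr5", 13.5 * mb, 18 * mb, "gain",   "P",  copies = 4L, allele = 2L),
    cn_event_spec("chr1", 48 * mb, 58 * mb, "het_loss", "M0", allele = 2L),
    cn_event_spec("chr2", 44 * mb, 49 * mb, "het_loss", "M1", allele = 2L),
    cn_event_spec("chr3", 36 * mb, 39.5 * mb, "gain",   "M1", copies = 6L, allele = 1L),
    cn_event_spec("chr4",  0,       3 * mb, "gain",     "M1", copies = 3L, allele = 2L),
    cn_event_spec("chr1", 25 * mb, 31 * mb, "het_loss", "M2", allele = 2L),
    cn_event_spec("chr3", 14 * mb, 18 * mb, "het_loss", "M2", allele = 1L),
    cn_event_spec("chr5", 10 * mb, 11.5 * mb, "het_loss", "M2", allele = 1L))
  class(ev) <- c("cn_event_spec", "data.frame")
  # point mutations in copy-neutral territory only
  snvs <- rbind(
    snv_spec("chr2", seq(1, 9.4, length.out = 15) * mb, clone = "A"),
    snv_spec("chr1", seq(21, 24, length.out = 8) * mb, clone = "A"),
    snv_spec("chr3", 1.0 * mb, clone = "B"),
    snv_spec("chr4", seq(26, 29, length.out = 5) * mb, clone = "M0"),
    snv_spec("chr5", seq(19, 19.9, length.out = 10) * mb, clone = "M1"),
    snv_spec("chr3", seq(0.5, 3.4, length.out = 7) * mb, clone = "M1"))
  snvs$pos <- round(snvs$pos)
  class(snvs) <- c("snv_spec", "data.frame")
  list(tree = tree, cn_events = ev, snvs = snvs, genome = genome,
       stages = samples)
}

#' Single-sample metastasis scenario with two coexisting subclones
#'
#' One metastasis sample (purity 0.8) with a clonal background of
#' `n_clonal` heterozygous losses (Level 2, all tumor cells) and a late
#' subclone of prevalence `subclone_fraction` carrying `n_subclonal`
#' additional losses (Level 1) -- the two-level loss signature left by a
#' catastrophic burst of events in part of the population. Events are laid
#' out as 4 Mb intervals separated by 4 Mb of neutral territory.
#'
#' @param n_clonal,n_subclonal numbers of Level 2 / Level 1 losses.
#' @param subclone_fraction prevalence of the late subclone.
#' @param purity sample purity.
#' @return list with `tree`, `cn_events`, `genome`, `truth_level` (per event).
#' @export
metastasis_scenario <- function(n_clonal = 8L, n_subclonal = 17L,
                                subclone_fraction = 0.5, purity = 0.8) {
  genome <- mini_genome(8)
  tree <- clone_tree(
    clones = c("A", "S"), parent = c(A = NA, S = "A"),
    prevalence = matrix(c(1, subclone_fraction), 1, 2,
                        dimnames = list("metastasis", c("A", "S"))),
    purity = c(metastasis = purity))
  n <- n_clonal + n_subclonal
  slot_chrom <- character(n); slot_start <- numeric(n)
  slots_per_chrom <- floor(genome$length / 8e6)
  k <- 1L
  for (i in seq_len(nrow(genome))) {
    for (j in seq_len(slots_per_chrom[i])) {
      if (k > n) break
      slot_chrom[k] <- genome$chrom[i]
      slot_start[k] <- (j - 1) * 8e6 + 2e6
      k <- k + 1L
    }
  }
  if (k <= n) stop("genome too small for requested event count")
  clone <- rep(c("A", "S"), c(n_clonal, n_subclonal))
  ev <- cn_event_spec(slot_chrom, slot_start, slot_start + 4e6, "het_loss",
                      clone, allele = rep_len(c(1L, 2L), n))
  list(tree = tree, cn_events = ev, genome = genome,
       truth_level = ifelse(clone == "A", 2L, 1L))
}

#' Truth per-stage event presence and Mb totals for a scenario
#'
#' An event is present in a sample when its originating clone has positive
#' prevalence there; its full length counts toward the sample's gain or loss
#' total (subclonal and complete alike).
#'
#' @param scenario output of [demo_scenario()] or a compatible list.
#' @return list with `presence` (events x samples logical matrix) and
#'   `totals` (data.frame `stage, gained_mb, lost_mb, n_gain, n_loss`).
#' @export
scenario_truth <- function(scenario) {
  tree <- scenario$tree
  ev <- scenario$cn_events
  pres <- sapply(tree$samples, function(s)
    tree$prevalence[s, ev$clone] > 0)
  loss <- ev$kind %in% c("het_loss", "hom_loss")
  len <- (ev$end - ev$start) / 1e6
  tot <- data.frame(
    stage = tree$samples,
    gained_mb = colSums(len * pres * !loss),
    lost_mb = colSums(len * pres * loss),
    n_gain = colSums(pres & !loss), n_loss = colSums(pres & loss))
  rownames(tot) <- NULL
  list(presence = pres, totals = tot)
}
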