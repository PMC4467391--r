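# Clone-tree simulator: paired window counts, SNP allele counts, SNV tables.
# All draws go through a locally scoped RNG so callers' random state is
# untouched and a fixed seed reproduces outputs exactly.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

genome_windows <- function(genome, window_bp) {
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = window_bp)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + window_bp, genome$length[i]),
               stringsAsFactors = FALSE)
  }))
}

# overlap-weighted sum of prevalence * copy-delta per window for one sample
window_copy_delta <- function(windows, events, prev) {
  delta <- numeric(nrow(windows))
  if (!nrow(events)) return(delta)
  dlt <- event_copy_delta(events)
  for (k in seq_len(nrow(events))) {
    sel <- windows$chrom == events$chrom[k] &
      windows$end > events$start[k] & windows$start < events$end[k]
    if (!any(sel)) next
    ov <- pmin(windows$end[sel], events$end[k]) -
      pmax(windows$start[sel], events$start[k])
    w <- ov / (windows$end[sel] - windows$start[sel])
    delta[sel] <- delta[sel] + w * prev[events$clone[k]] * dlt[k]
  }
  delta
}

#' Simulate paired tumor/normal window read counts from a clone tree
#'
#' For every genomic window the expected total copy number in a sample is
#' `2(1 - p) + p * (2 + sum over events of prevalence * copy_delta)` where `p`
#' is the sample purity and prevalence is the fraction of tumor cells carrying
#' the event. Normal counts are Poisson around `depth`; tumor counts are
#' Poisson around `depth * copy / 2`, so a diploid window has expected
#' tumor:normal ratio 1, a clonal heterozygous loss at purity 1 has ratio 1/2,
#' and a het loss at prevalence 0.4 and purity 0.75 has expected copy
#' `2 - 0.75 * 0.4 = 1.7` (ratio 0.85).
#'
#' @param tree a [clone_tree()].
#' @param events a [cn_event_spec()] table (may have zero rows).
#' @param depth mean normal reads per window.
#' @param window_bp window size in bp.
#' @param genome data.frame (`chrom`, `length`), e.g. [mini_genome()].
#' @param seed integer seed; all output is reproducible for a fixed seed.
#' @return list of class `cn_sim_counts` with `counts` (per-sample list of
#'   data.frames `chrom,start,end,n_normal,n_tumor`) and `truth` (per-sample
#'   data.frames with `expected_copy` and `expected_ratio` per window).
#' @export
simulate_counts <- function(tree, events, depth = 1000, window_bp = 1e5,
                            genome = mini_genome(), seed = 1L) {
  stopifnot(inherits(tree, "clone_tree"), depth > 0, window_bp >= 1)
  check_event_conflicts(tree, events, genome)
  windows <- genome_windows(genome, window_bp)
  with_seed(seed, {
    counts <- list(); truth <- list()
    n_normal <- stats::rpois(nrow(windows), depth)
    for (s in tree$samples) {
      p <- tree$purity[[s]]
      prev <- stats::setNames(tree$prevalence[s, ], tree$clones)
      copy <- 2 * (1 - p) +
        p * (2 + window_copy_delta(windows, events, prev))
      n_tumor <- stats::rpois(nrow(windows), depth * copy / 2)
      counts[[s]] <- cbind(windows,
                           data.frame(n_normal = n_normal, n_tumor = n_tumor))
      truth[[s]] <- cbind(windows, data.frame(
        expected_copy = copy, expected_ratio = copy / 2))
    }
    structure(list(counts = counts, truth = truth, genome = genome,
                   window_bp = window_bp, depth = depth, seed = seed),
              class = "cn_sim_counts")
  })
}

#' @export
print.cn_sim_counts <- function(x, ...) {
  cat("Simulated paired counts:", length(x$counts), "samples,",
      nrow(x$counts[[1]]), "windows of", x$window_bp, "bp, depth",
      x$depth, "\n")
  invisible(x)
}

# expected copies of each parental haplotype at one site for one sample
site_haplotype_copies <- function(chrom, pos, events, prev, p) {
  h <- c(1, 1)
  if (nrow(events)) {
    sel <- which(events$chrom == chrom & events$start <= pos &
                   events$end > pos)
    for (k in sel) {
      pr <- prev[events$clone[k]]
      a <- events$allele[k]
      if (events$kind[k] == "het_loss") {
        h[a] <- h[a] - pr
      } else if (events$kind[k] == "hom_loss") {
        h <- h - pr
      } else {
        h[a] <- h[a] + pr * (events$copies[k] - 2)
      }
    }
  }
  (1 - p) * c(1, 1) + p * h
}

#' Simulate germline-heterozygous SNP allele counts
#'
#' Sites are placed uniformly over the genome. Every site is a germline
#' heterozygote at a known SNP position: one parental haplotype carries the B
#' (alternate) allele, assigned at random, so loss of either haplotype drives
#' the tumor BAF toward 0 or 1 symmetrically. Per sample, total site depth is
#' Poisson around `depth * total_copy / 2` and the B-allele depth is binomial
#' around the expected B-allele fraction given the copy events overlapping the
#' site. A site untouched by events has expected BAF 0.5; a clonal
#' heterozygous loss at purity 1 sends it to 0 or 1; a het loss with
#' `p * f = 0.5` leaves the minor mode at `(1 - 0.5)/(2 - 0.5) = 1/3`.
#'
#' Optional contamination fractions add sites that downstream filtering must
#' remove: germline homozygotes (`prop_hom`) and positions not annotated as
#' known SNPs (`prop_novel`).
#'
#' @inheritParams simulate_counts
#' @param n_sites number of SNP sites (> 0).
#' @param depth mean sequencing depth per site.
#' @param prop_hom,prop_novel fractions of homozygous / non-dbSNP sites.
#' @return list of class `snp_sim` with one data.frame per sample:
#'   `chrom,pos,ref,alt,a_depth_n,b_depth_n,a_depth_t,b_depth_t,known_snp,
#'   germline_het,truth_baf`.
#' @export
simulate_snp_counts <- function(tree, events, n_sites, depth = 120,
                                genome = mini_genome(), seed = 1L,
                                prop_hom = 0, prop_novel = 0) {
  if (n_sites <= 0) stop("n_sites must be positive")
  stopifnot(inherits(tree, "clone_tree"))
  check_event_conflicts(tree, events, genome)
  with_seed(seed, {
    ci <- sample.int(nrow(genome), n_sites, replace = TRUE,
                     prob = genome$length / sum(genome$length))
    pos <- floor(stats::runif(n_sites) * genome$length[ci])
    ord <- order(ci, pos)
    ci <- ci[ord]; pos <- pos[ord]
    b_hap <- sample(c(1L, 2L), n_sites, replace = TRUE)
    het <- stats::runif(n_sites) >= prop_hom
    known <- stats::runif(n_sites) >= prop_novel
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    out <- list()
    for (s in tree$samples) {
      p <- tree$purity[[s]]
      prev <- stats::setNames(tree$prevalence[s, ], tree$clones)
      ebaf <- numeric(n_sites); ecopy <- numeric(n_sites)
      for (i in seq_len(n_sites)) {
        h <- site_haplotype_copies(genome$chrom[ci[i]], pos[i], events,
                                   prev, p)
        ecopy[i] <- sum(h)
        ebaf[i] <- if (het[i]) h[b_hap[i]] / sum(h) else 0
      }
      dp_n <- stats::rpois(n_sites, depth)
      b_n <- stats::rbinom(n_sites, dp_n, ifelse(het, 0.5, 0))
      dp_t <- stats::rpois(n_sites, depth * ecopy / 2)
      b_t <- stats::rbinom(n_sites, dp_t, ebaf)
      out[[s]] <- data.frame(
        chrom = genome$chrom[ci], pos = pos, ref = ref, alt = alt,
        a_depth_n = dp_n - b_n, b_depth_n = b_n,
        a_depth_t = dp_t - b_t, b_depth_t = b_t,
        known_snp = known, germline_het = het, truth_baf = ebaf,
        stringsAsFactors = FALSE)
    }
    structure(out, class = c("snp_sim", "list"))
  })
}

#' Simulate somatic SNV read support across samples
#'
#' SNVs are heterozygous point mutations in copy-neutral territory: a variant
#' carried by a clone of prevalence `f` in a sample of purity `p` has expected
#' variant allele fraction `p * f / 2` (0.40 for a clonal variant at purity
#' 0.8; 0 where the clone is absent). Per sample, site depth is Poisson around
#' `depth` and alternate depth binomial around the expected VAF. The matched
#' normal is drawn at the same depth with alt probability `error_rate`.
#'
#' @inheritParams simulate_counts
#' @param snvs a [snv_spec()] table.
#' @param depth mean depth per site (deep-resequencing scale by default).
#' @param error_rate per-read alt error probability in the normal.
#' @return data.frame in long format: one row per variant x tumor sample with
#'   columns `chrom,pos,ref,alt,sample,depth,alt_depth,baf,normal_depth,
#'   normal_alt_depth,normal_baf,known_snp_af,annotation,truth_clone,
#'   truth_vaf`.
#' @export
simulate_snvs <- function(tree, snvs, depth = 377, seed = 1L,
                          error_rate = 0) {
  stopifnot(inherits(tree, "clone_tree"))
  if (!all(snvs$clone %in% tree$clones)) stop("SNV assigned to unknown clone")
  with_seed(seed, {
    n <- nrow(snvs)
    dp_n <- stats::rpois(n, depth)
    alt_n <- stats::rbinom(n, dp_n, error_rate)
    rows <- list()
    for (s in tree$samples) {
      p <- tree$purity[[s]]
      vaf <- p * tree$prevalence[s, snvs$clone] / 2
      dp <- stats::rpois(n, depth)
      alt <- stats::rbinom(n, dp, vaf)
      rows[[s]] <- data.frame(
        chrom = snvs$chrom, pos = snvs$pos, ref = snvs$ref, alt = snvs$alt,
        sample = s, depth = dp, alt_depth = alt,
        baf = ifelse(dp > 0, alt / dp, NA_real_),
        normal_depth = dp_n, normal_alt_depth = alt_n,
        normal_baf = ifelse(dp_n > 0, alt_n / dp_n, NA_real_),
        known_snp_af = NA_real_, annotation = "nonsynonymous",
        truth_clone = snvs$clone, truth_vaf = as.numeric(vaf),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
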