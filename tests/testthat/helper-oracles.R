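# Shared fixtures and independent oracles, built in code at test time.

# single-sample tree: root clone "A" (no events) plus clone "S" at prevalence
# `fraction` carrying one heterozygous loss; used for fraction-recovery tests
loss_scenario <- function(purity, fraction) {
  genome <- data.frame(chrom = c("chrA", "chrB"), length = c(30e6, 20e6))
  tree <- clone_tree(
    clones = c("A", "S"), parent = c(A = NA, S = "A"),
    prevalence = matrix(c(1, fraction), 1, 2,
                        dimnames = list("s1", c("A", "S"))),
    purity = c(s1 = purity))
  ev <- cn_event_spec("chrA", 5e6, 15e6, "het_loss", "S", allele = 1L)
  list(tree = tree, cn_events = ev, genome = genome)
}

# run the per-sample copy-number stages on a scenario and return the events
call_events <- function(scn, sample, seed, depth = 1000, window_bp = 1e5,
                        n_sites = 1000, snp_depth = 120) {
  sim <- simulate_counts(scn$tree, scn$cn_events, depth = depth,
                         window_bp = window_bp, genome = scn$genome,
                         seed = seed)
  snp <- simulate_snp_counts(scn$tree, scn$cn_events, n_sites = n_sites,
                             depth = snp_depth, genome = scn$genome,
                             seed = seed + 1L)
  track <- compute_log2(sim$counts[[sample]])
  sites <- select_informative_sites(snp[[sample]])
  segs <- annotate_segments_baf(segment_track(track), sites)
  ev <- classify_segments(segs, purity = scn$tree$purity[[sample]])
  detect_loss_levels(ev)
}

# random somatic-variant candidates straddling every filter threshold;
# expected labels are recomputed independently inside the tests
make_filter_candidates <- function(n = 200, seed = 11) {
  set.seed(seed)
  samples <- c("t1", "t2")
  normal_depth <- sample(5:60, n, replace = TRUE)
  normal_kind <- sample(c("clean", "noisy", "het"), n, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2))
  normal_p <- c(clean = 0, noisy = 0.05, het = 0.5)[normal_kind]
  normal_alt <- rbinom(n, normal_depth, normal_p)
  known_af <- sample(c(NA, 0.001, 0.05), n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.2))
  rows <- list()
  for (s in samples) {
    depth <- sample(20:400, n, replace = TRUE)
    baf_target <- sample(c(0, 0.02, 0.08, 0.16, 0.3, 0.5), n, replace = TRUE)
    alt <- rbinom(n, depth, baf_target)
    rows[[s]] <- data.frame(
      chrom = "chr1", pos = seq_len(n), ref = "C", alt = "T", sample = s,
      depth = depth, alt_depth = alt,
      normal_depth = normal_depth, normal_alt_depth = normal_alt,
      known_snp_af = known_af, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# uniform per-position coverage track
uniform_coverage <- function(chrom = "chr1", n_pos = 1000, depth = 10) {
  data.frame(chrom = rep_len(chrom, n_pos), pos = seq_len(n_pos) - 1L,
             depth = rep_len(depth, n_pos))
}
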