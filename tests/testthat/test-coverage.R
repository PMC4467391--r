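test_that("windows accumulate the requested normal read count", {
  nc <- uniform_coverage(n_pos = 1000, depth = 10)   # 10 reads/bp
  tc <- uniform_coverage(n_pos = 1000, depth = 10)
  w <- build_windows(nc, tc, reads_per_window = 1000)
  expect_true(all(w$end - w$start == 100))           # 1000/10 bp each
  expect_true(all(w$n_normal == 1000))
  expect_true(all(!w$underfilled))

  # degenerate bin: one window per covered position
  w1 <- build_windows(uniform_coverage(n_pos = 5, depth = 1),
                      uniform_coverage(n_pos = 5, depth = 1),
                      reads_per_window = 1)
  expect_equal(nrow(w1), 5)

  # a chromosome with too few reads yields a single flagged window
  w2 <- build_windows(uniform_coverage(n_pos = 50, depth = 1),
                      uniform_coverage(n_pos = 50, depth = 1),
                      reads_per_window = 1000)
  expect_equal(nrow(w2), 1)
  expect_true(w2$underfilled)

  # empty coverage -> empty track; unsorted input -> error
  expect_equal(nrow(build_windows(uniform_coverage(n_pos = 0),
                                  uniform_coverage(n_pos = 0))), 0)
  bad <- uniform_coverage(n_pos = 10)[c(3, 1, 2, 4:10), ]
  expect_error(build_windows(bad, uniform_coverage(n_pos = 10)),
               "not sorted")
})

test_that("log2 track reproduces the canonical ratio calibration", {
  w <- data.frame(chrom = "chr1", start = 0:9 * 100, end = 1:10 * 100,
                  n_normal = 1000, n_tumor = 1000)
  t0 <- compute_log2(w)
  expect_true(all(t0$log2 == 0))
  expect_equal(attr(t0, "centering_offset"), 0)

  # a minority 3:2 region sits at 0.58, a 1:2 region at -1
  w$n_tumor <- c(rep(1000, 6), 1500, 1500, 500, 500)
  tr <- compute_log2(w)
  expect_equal(tr$log2[1], 0)
  expect_equal(round(tr$log2[7], 2), 0.58)
  expect_equal(tr$log2[9], -1)

  # median of the track is zero before any baseline shift
  set.seed(1)
  w$n_tumor <- rpois(10, 800)
  expect_equal(median(compute_log2(w)$log2), 0)

  # zero tumor reads floored and flagged; zero normal reads dropped
  w$n_tumor <- c(0, rep(1000, 9))
  tf <- compute_log2(w, floor = -5)
  expect_equal(tf$log2[1], -5)
  expect_true(tf$floored[1])
  w$n_normal <- c(1000, 0, rep(1000, 8))
  expect_warning(td <- compute_log2(w), "zero normal reads")
  expect_equal(nrow(td), 9)
})

test_that("expected_log2 matches the purity/fraction algebra", {
  expect_equal(expected_log2(2, 0.3, 0.7), 0)             # identity
  expect_equal(round(expected_log2(3, 1, 1), 2), 0.58)    # 3:2 gain
  expect_equal(expected_log2(1, 1, 1), -1)                # 1:2 loss
  # homozygous-subclonal vs heterozygous-clonal degeneracy
  expect_equal(expected_log2(0, 1, 0.5), expected_log2(1, 1, 1))
  expect_identical(expected_log2(0, 1, 1), -Inf)

  # monotone in copy state; direction in p and f flips at c = 2
  cs <- 0:8
  expect_true(all(diff(expected_log2(cs, 0.8, 0.7)) > 0))
  ps <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(expected_log2(4, ps, 0.9)) > 0))
  expect_true(all(diff(expected_log2(1, ps, 0.9)) < 0))
  expect_true(all(diff(expected_log2(1, 0.9, ps)) < 0))
})

test_that("baseline recentering undoes an aneuploidy-shifted median", {
  # 60% of the genome carries a clonal het loss, so median centering lands
  # inside lost territory; truth-diploid windows must average 0 afterwards
  genome <- data.frame(chrom = c("chr1", "chr2"), length = c(30e6, 20e6))
  tree <- clone_tree("A", c(A = NA),
                     matrix(1, 1, 1, dimnames = list("s1", "A")),
                     c(s1 = 1))
  ev <- rbind(cn_event_spec("chr1", 0, 30e6, "het_loss", "A", allele = 1L))
  sim <- simulate_counts(tree, ev, depth = 2000, genome = genome, seed = 21)
  snp <- simulate_snp_counts(tree, ev, n_sites = 1500, depth = 400,
                             genome = genome, seed = 22)
  track <- compute_log2(sim$counts$s1)
  # pre-correction: diploid chr2 is centered off zero
  dip <- track$chrom == "chr2"
  expect_gt(abs(mean(track$log2[dip])), 0.3)
  sites <- select_informative_sites(snp$s1)
  fixed <- recenter_baseline(track, sites)
  expect_lt(abs(mean(fixed$log2[dip])), 0.02)
  expect_equal(attr(fixed, "baseline_shift"),
               -attr(fixed, "centering_offset"), tolerance = 0.05)

  # whole genome altered: warning, track unchanged
  ev2 <- rbind(
    cn_event_spec("chr1", 0, 30e6, "het_loss", "A", allele = 1L),
    cn_event_spec("chr2", 0, 20e6, "het_loss", "A", allele = 2L))
  sim2 <- simulate_counts(tree, ev2, depth = 2000, genome = genome, seed = 23)
  snp2 <- simulate_snp_counts(tree, ev2, n_sites = 1500, depth = 400,
                              genome = genome, seed = 24)
  track2 <- compute_log2(sim2$counts$s1)
  expect_warning(
    same <- recenter_baseline(track2, select_informative_sites(snp2$s1)),
    "baseline unchanged")
  expect_identical(same$log2, track2$log2)
})

test_that("noiseless counts round-trip to the expected log2 per copy state", {
  states <- data.frame(c = c(2, 1, 3, 4, 0), f = c(1, 1, 1, 0.5, 0.5))
  ratio <- 2^(expected_log2(states$c, 0.9, states$f))
  w <- data.frame(chrom = "chr1",
                  start = (0:99) * 100, end = (1:100) * 100,
                  n_normal = 1e6,
                  n_tumor = round(1e6 * rep(ratio, each = 20)))
  tr <- compute_log2(w)
  seg_means <- tapply(tr$log2, rep(seq_len(5), each = 20), mean)
  # median centering offset equals the diploid state's raw value here
  shift <- seg_means[1]
  expect_true(all(abs(
    (seg_means - shift) - expected_log2(states$c, 0.9, states$f)) < 0.01))
})
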