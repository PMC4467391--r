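seg_row <- function(mean_log2, folded = NA_real_, chrom = "chr1",
                    start = 0, end = 10e6, n = 100) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       n_windows = n, mean_log2 = mean_log2, sd_log2 = 0.05,
                       first = 1, last = n, mean_folded_baf = folded,
                       n_sites = 50L),
            class = c("cn_segments", "data.frame"))
}

test_that("segments classify into the event vocabulary", {
  # log2 -1 with a full BAF split: complete LOH at purity 1
  ev <- classify_segments(seg_row(-1, 0.5), purity = 1)
  expect_equal(ev$type, "LOH")
  expect_equal(ev$clonality, "complete")
  expect_equal(ev$est_fraction, 1, tolerance = 1e-6)

  # neutral segment: no event
  expect_equal(nrow(classify_segments(seg_row(0, 0.01))), 0)

  # subclonal loss: intermediate BAF split
  pf <- 0.5
  l <- expected_log2(1, 1, pf)
  fold <- 0.5 - expected_baf(1, pf)["minor"]
  ev2 <- classify_segments(seg_row(l, fold), purity = 1)
  expect_equal(ev2$type, "LOH")
  expect_equal(ev2$clonality, "subclonal")
  expect_equal(ev2$est_fraction, pf, tolerance = 1e-6)

  # missing BAF: category from log2 alone, clonality indeterminate
  ev3 <- classify_segments(seg_row(-1), purity = 1)
  expect_equal(ev3$type, "LOH")
  expect_equal(ev3$clonality, "indeterminate")

  # homozygous loss at depth floor
  ev4 <- classify_segments(seg_row(-4, 0.1), purity = 1)
  expect_equal(ev4$type, "HL")
  expect_equal(ev4$clonality, "complete")

  # gain grades are purity-corrected and never carry a clonality call
  for (cs in c(3, 4, 6, 9)) {
    for (p in c(1, 0.75)) {
      ev_g <- classify_segments(seg_row(expected_log2(cs, p, 1), 0.2),
                                purity = p)
      expect_equal(ev_g$clonality, "indeterminate")
      expect_equal(ev_g$type,
                   c(`3` = "HCG", `4` = "VHCG", `6` = "VHCG",
                     `9` = "EHCG")[[as.character(cs)]])
    }
  }

  # length in Mb at two decimals
  ev5 <- classify_segments(seg_row(-1, 0.5, start = 1e6, end = 4.456e6))
  expect_equal(ev5$length_mb, 3.46)
})

test_that("losses inside previously amplified territory become OCL", {
  amp <- data.frame(chrom = "chr1", start = 0, end = 20e6)
  ev <- classify_segments(seg_row(-0.6, 0.2, start = 2e6, end = 8e6),
                          purity = 1, amplified_regions = amp)
  expect_equal(ev$type, "OCL")
  ev2 <- classify_segments(seg_row(-0.6, 0.2, start = 2e6, end = 8e6),
                           purity = 1,
                           amplified_regions = data.frame(
                             chrom = "chr2", start = 0, end = 20e6))
  expect_equal(ev2$type, "LOH")
})

test_that("fraction estimation inverts the BAF and log2 algebra", {
  expect_equal(estimate_fraction(0.5, -1)$estimate, 1)        # m = 0
  expect_equal(estimate_fraction(0, -0.001)$estimate, 0)      # m = 0.5
  expect_equal(estimate_fraction(0.5 - 1 / 3, expected_log2(1, 1, 0.5))$estimate,
               0.5, tolerance = 1e-9)
  expect_warning(out <- estimate_fraction(0.6, -1), "impossible")
  expect_equal(out$estimate, 1)

  # log2-based inversion agrees with the BAF-based one on clean algebra
  for (pf in seq(0.1, 0.9, by = 0.2)) {
    est <- estimate_fraction(unname(0.5 - expected_baf(1, pf)["minor"]),
                             expected_log2(1, 1, pf))
    expect_equal(est$baf_based, pf, tolerance = 1e-9)
    expect_equal(est$log2_based, pf, tolerance = 1e-9)
  }
  # homozygous-loss route: p*f = 1 - 2^L
  expect_equal(estimate_fraction(NA, -1, "hom_loss")$estimate, 0.5)
})

test_that("two loss levels are recovered with correct membership", {
  set.seed(14)
  deep <- rnorm(12, -1, 0.03); shallow <- rnorm(8, -0.4, 0.03)
  segs <- do.call(rbind, lapply(c(deep, shallow), function(l)
    seg_row(l, 0.3)))
  class(segs) <- c("cn_segments", "data.frame")
  ev <- detect_loss_levels(classify_segments(segs, purity = 1))
  expect_equal(ev$loss_level, rep(c(2L, 1L), c(12, 8)))

  # single level: everything Level 2
  segs1 <- do.call(rbind, lapply(rnorm(10, -1, 0.03), function(l)
    seg_row(l, 0.45)))
  class(segs1) <- c("cn_segments", "data.frame")
  ev1 <- detect_loss_levels(classify_segments(segs1, purity = 1))
  expect_true(all(ev1$loss_level == 2L))
})

test_that("deep losses with balanced BAF become subclonal homozygous losses", {
  # log2 -1 but BAF still 0.5: HL in half the population, p*f = 0.5
  segs <- rbind(seg_row(-1, 0.02), seg_row(-1, 0.48, chrom = "chr2"))
  class(segs) <- c("cn_segments", "data.frame")
  ev <- detect_loss_levels(classify_segments(segs, purity = 1))
  ev <- resolve_homozygous_subclonal(ev)
  expect_equal(ev$type, c("HL", "LOH"))
  expect_equal(ev$clonality, c("subclonal", "complete"))
  expect_equal(ev$est_fraction[1], 0.5)

  # a shallow balanced dip below the call threshold yields no event at all
  expect_equal(nrow(classify_segments(seg_row(-0.05, 0.01), purity = 1)), 0)
})

test_that("aberrant cell fraction is recovered from simulated data", {
  scn <- loss_scenario(0.85, 0.6)
  ev <- call_events(scn, "s1", seed = 55)
  loss <- ev[ev$type == "LOH", ]
  expect_equal(nrow(loss), 1)
  expect_lt(abs(loss$est_fraction - 0.85 * 0.6), 0.05)
  # BAF-based and log2-based estimates agree internally
  est <- estimate_fraction(loss$mean_folded_baf, loss$mean_log2)
  expect_lt(abs(est$baf_based - est$log2_based), 0.1)
})
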