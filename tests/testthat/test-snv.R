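call_row <- function(pos, sample, depth, alt, normal_depth = 100,
                     normal_alt = 0, af = NA_real_) {
  data.frame(chrom = "chr1", pos = pos, ref = "C", alt = "T",
             sample = sample, depth = depth, alt_depth = alt,
             normal_depth = normal_depth, normal_alt_depth = normal_alt,
             known_snp_af = af, stringsAsFactors = FALSE)
}

test_that("somatic filter applies the fixed thresholds", {
  calls <- rbind(
    call_row(1, "t1", 100, 16), call_row(1, "t2", 100, 6),   # retained, both
    call_row(2, "t1", 100, 16, normal_alt = 3),              # normal BAF 0.03
    call_row(2, "t2", 100, 16, normal_alt = 3),
    call_row(3, "t1", 100, 16, normal_depth = 9),            # shallow normal
    call_row(3, "t2", 100, 0, normal_depth = 9),
    call_row(4, "t1", 100, 16, af = 0.05),                   # common SNP
    call_row(4, "t2", 100, 16, af = 0.05),
    call_row(5, "t1", 100, 10), call_row(5, "t2", 100, 8),   # no sample > 0.15
    call_row(6, "t1", 10, 2), call_row(6, "t2", 100, 40))    # 2 alt reads in t1
  sc <- filter_somatic(calls)
  expect_equal(sc$variants$pos, c(1, 6))
  expect_equal(unname(sc$presence["chr1:1:C:T", ]), c(TRUE, TRUE))
  expect_equal(unname(sc$presence["chr1:6:C:T", ]), c(TRUE, TRUE))
  expect_setequal(sc$rejected$reason,
                  c("normal_fails", "normal_fails", "known_snp",
                    "no_confident_sample"))
  # missing normal: rejected with its own reason code
  nn <- call_row(9, "t1", 100, 30)
  nn$normal_depth <- NA_real_; nn$normal_alt_depth <- NA_real_
  sc2 <- filter_somatic(nn)
  expect_equal(nrow(sc2$variants), 0)
  expect_equal(sc2$rejected$reason, "no_normal")
})

test_that("filter matches an independent re-application on 200 candidates", {
  calls <- make_filter_candidates(n = 200, seed = 11)
  sc <- filter_somatic(calls)
  # independent oracle: plain vectorized restatement of the thresholds
  by_pos <- split(calls, calls$pos)
  expected <- vapply(by_pos, function(d) {
    nb <- d$normal_alt_depth[1] / d$normal_depth[1]
    d$normal_depth[1] >= 10 && nb < 0.02 &&
      (is.na(d$known_snp_af[1]) || d$known_snp_af[1] <= 0.01) &&
      any(d$alt_depth >= 3 & d$alt_depth / d$depth > 0.15)
  }, TRUE)
  expect_setequal(sc$variants$pos, as.integer(names(by_pos))[expected])
  # germline heterozygous positions (normal BAF ~ 0.5) are never retained
  het_pos <- unique(calls$pos[calls$normal_alt_depth /
                                calls$normal_depth > 0.25])
  expect_length(intersect(sc$variants$pos, het_pos), 0)
  # order independence
  perm <- calls[sample(nrow(calls)), ]
  sc_perm <- filter_somatic(perm)
  expect_setequal(sc_perm$variants$pos, sc$variants$pos)
  expect_identical(sc_perm$presence[rownames(sc$presence), ], sc$presence)
})

test_that("presence patterns count every membership combination", {
  scn <- demo_scenario()
  raw <- simulate_snvs(scn$tree, scn$snvs, seed = 71)
  sc <- filter_somatic(raw)
  pm <- presence_matrix(sc)
  expect_equal(pm$shared_by_all, 23)
  expect_equal(unname(pm$pattern_counts["metastasis"]), 17)
  expect_equal(unname(pm$pattern_counts["dcis2"]), 1)
  expect_equal(unname(pm$pattern_counts["primary+metastasis"]), 5)
  expect_equal(unname(pm$private[c("dcis1", "primary")]), c(0L, 0L))

  # single sample: everything private
  one <- filter_somatic(raw[raw$sample == "metastasis", ])
  pm1 <- presence_matrix(one)
  expect_equal(sum(pm1$private), nrow(one$variants))
  # empty call set: zero counts
  pm0 <- presence_matrix(filter_somatic(raw[0, ]))
  expect_equal(pm0$shared_by_all, 0)
  expect_length(pm0$pattern_counts, 0)
})

test_that("purification flags subclonal-to-clonal variants only", {
  calls <- rbind(
    call_row(1, "early", 400, 48), call_row(1, "late", 400, 180),  # purified
    call_row(2, "early", 400, 180), call_row(2, "late", 400, 180), # clonal
    call_row(3, "early", 400, 0), call_row(3, "late", 400, 160))   # absent early
  sc <- filter_somatic(calls)
  out <- detect_purification(sc, "early", "late")
  expect_equal(out$pos, 1)
  expect_equal(out$baf_early, 0.12)
  expect_equal(out$baf_late, 0.45)

  # on the simulated cohort, the flags are exactly the metastasis-founder
  # clone's variants
  scn <- demo_scenario()
  raw <- simulate_snvs(scn$tree, scn$snvs, seed = 71)
  sc2 <- filter_somatic(raw)
  flagged <- detect_purification(sc2, "primary", "metastasis")
  expect_equal(nrow(flagged), 5)
  expect_true(all(flagged$truth_clone == "M0"))
  founders <- sc2$variants$truth_clone == "M0"
  expect_equal(sum(founders), 5)
})

test_that("VAF density separates monoclonal from two-clone samples", {
  scn <- demo_scenario()
  raw <- simulate_snvs(scn$tree, scn$snvs, seed = 71)
  sc <- filter_somatic(raw)
  # dcis1 carries only truncal variants: unimodal around p/2
  d1 <- vaf_density(sc, "dcis1")
  expect_equal(d1$n_modes, 1)
  expect_lt(abs(d1$modes - 0.425), 0.05)
  # the primary has a clonal peak and the founder subclone: bimodal
  dp <- vaf_density(sc, "primary")
  expect_equal(dp$n_modes, 2)
  # excluding variants inside copy-number events removes them from the density
  fake_ev <- data.frame(chrom = "chr2", start = 0, end = 50e6)
  dx <- vaf_density(sc, "dcis1", exclude_events = fake_ev)
  expect_lt(length(dx$baf), length(d1$baf))
  # too few usable variants: mode count undefined
  tiny <- filter_somatic(raw[raw$pos %in% raw$pos[1:2], ])
  expect_true(is.na(vaf_density(tiny, "dcis1")$n_modes))
})
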