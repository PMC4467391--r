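fixture_sets <- function() {
  suppressWarnings(read_event_table(progression_fixture_path()))$sets
}

test_that("per-sample totals reproduce the published event table", {
  sets <- fixture_sets()
  t1 <- totals(sets$dcis1)
  expect_equal(t1$gained_mb, 99.14)
  expect_equal(t1$lost_mb, 786.27)
  expect_equal(t1$n_gain, 11)
  expect_equal(t1$n_loss, 25)
  t2 <- totals(sets$dcis2)
  expect_equal(t2$gained_mb, 148.29)
  expect_equal(t2$lost_mb, 876.05)
  t3 <- totals(sets$primary)
  expect_equal(t3$gained_mb, 213.08)
  expect_equal(t3$lost_mb, 1014.93)
  t4 <- totals(sets$metastasis)
  expect_equal(t4$lost_mb, 1902.27)
  expect_equal(t4$n_loss, 52)
  expect_equal(t4$n_gain, 43)
  # empty set: all zeros
  t0 <- totals(sets$dcis1[0, ])
  expect_equal(unlist(t0), c(gained_mb = 0, lost_mb = 0, n_gain = 0,
                             n_loss = 0))
})

test_that("event matching honors chromosome, class and tolerance", {
  sets <- fixture_sets()
  m <- match_events(sets$dcis1, sets$dcis1)
  expect_equal(nrow(m$pairs), nrow(sets$dcis1))
  # every early event is retained in all later stages
  for (later in c("dcis2", "primary", "metastasis")) {
    expect_length(match_events(sets$dcis1, sets[[later]])$unmatched_a, 0)
  }
  # a 1 bp shift matches at 10 kb tolerance but not exactly
  shifted <- sets$dcis1
  shifted$start <- shifted$start + 1
  expect_gt(length(match_events(shifted, sets$dcis1, bp_tol = 0)$unmatched_a),
            0)
  expect_length(match_events(shifted, sets$dcis1, bp_tol = 1e4)$unmatched_a,
                0)
  # loss never matches gain territory
  loss_only <- sets$dcis1[sets$dcis1$type == "LOH", ]
  gain_only <- sets$dcis1[sets$dcis1$type %in% c("CG", "HCG", "VHCG",
                                                 "EHCG"), ]
  expect_equal(nrow(match_events(loss_only, gain_only, bp_tol = 1e9)$pairs),
               0)
})

test_that("Mb concordance matches the published percentages", {
  sets <- fixture_sets()
  expect_equal(round(concordance(sets$primary, sets$dcis1), 2), 72.10)
  expect_equal(round(concordance(sets$dcis2, sets$dcis1), 2), 86.44)
  expect_equal(concordance(sets$dcis1, sets$dcis1), 100)
  # disjoint sets: 0
  expect_equal(concordance(sets$dcis1,
                           sets$dcis1[0, ]), 0)
  # empty query: undefined
  expect_message(v <- concordance(sets$dcis1[0, ], sets$dcis1), "undefined")
  expect_true(is.na(v))
})

test_that("concordance is invariant to row order and to event splitting", {
  sets <- fixture_sets()
  q <- sets$primary
  ref <- sets$dcis1
  base <- concordance(q, ref)
  expect_equal(concordance(q[sample(nrow(q)), ], ref), base)
  # split the first event into two abutting halves of equal total length
  row <- q[1, ]
  mid <- (row$start + row$end) / 2
  split_rows <- rbind(row, row)
  split_rows$end[1] <- mid; split_rows$start[2] <- mid
  split_rows$length_mb <- split_rows$length_mb / 2
  q_split <- rbind(q[-1, ], split_rows)
  expect_equal(concordance(sample_event_set(q_split, "primary"), ref), base)
})

test_that("nested event sets classify as linear, private events as parallel", {
  sets <- fixture_sets()
  rep1 <- classify_progression(sets)
  expect_equal(rep1$verdict, "linear-consistent")
  expect_null(rep1$violations)
  expect_equal(unname(rep1$concordance[, "metastasis"]), rep(100, 4))
  # linearity implies monotone non-decreasing Mb totals across stages
  expect_true(all(diff(rep1$totals$gained_mb) >= 0))
  expect_true(all(diff(rep1$totals$lost_mb) >= 0))

  # one primary-private event flips the verdict and is listed
  q <- as.data.frame(sets$primary)
  extra <- q[1, ]
  extra$chrom <- "12"; extra$start <- 0; extra$end <- 10e6
  extra$length_mb <- 10; extra$type <- "LOH"
  sets2 <- sets
  sets2$primary <- sample_event_set(rbind(q, extra), "primary")
  rep2 <- classify_progression(sets2)
  expect_equal(rep2$verdict, "parallel-evidence")
  expect_equal(rep2$violations$chrom, "12")
  expect_equal(rep2$violations$stage, "primary")
  expect_equal(rep2$violations$missing_from, "metastasis")

  # a single sample is trivially linear-consistent
  rep3 <- classify_progression(sets["dcis1"])
  expect_equal(rep3$verdict, "linear-consistent")
})

test_that("acquisition stages give the cumulative Mb table", {
  sets <- fixture_sets()
  acq <- stage_acquisition(sets)
  expect_equal(acq$cumulative$cum_lost_mb[1], 786.27)
  expect_equal(acq$cumulative$cum_lost_mb[4], 1902.27)
  expect_equal(acq$cumulative$cum_gained_mb[1], 99.14)
  expect_equal(acq$cumulative$stage, names(sets))
  # an event only in the metastasis is acquired at the final stage
  met_only <- acq$events$first_stage[acq$events$chrom == "3"]
  expect_equal(met_only, "metastasis")
  # every DCIS 1 event is assigned to the first stage
  d1 <- fixture_sets()$dcis1
  m <- match_events(d1, acq$events[acq$events$first_stage == "dcis1", ])
  expect_length(m$unmatched_a, 0)
})
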