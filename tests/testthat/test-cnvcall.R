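flat_profile <- function(depth, n = 20L, chrom = "1") {
  start <- 1L + (seq_len(n) - 1L) * 200L
  data.frame(chrom = chrom, start = start, end = start + 119L,
             depth = rep_len(depth, n))
}

test_that("family reference is the per-target median on a common scale", {
  p <- flat_profile(100)
  # identical members: reference equals any one of them (normalized scale)
  ref <- build_family_reference(list(p, p, p))
  expect_equal(ref$ref_depth, rep(100, 20))
  expect_false(any(ref$masked))
  # single member: reference is that profile
  ref1 <- build_family_reference(list(p))
  expect_equal(ref1$ref_depth, ref$ref_depth)
  # an outlier member does not drag the reference off the median
  q <- flat_profile(100); q$depth[5] <- c(400)
  members <- list(flat_profile(100), flat_profile(110), q)
  ref <- build_family_reference(members)
  # at target 5 the normalized member depths are ~100, ~100, ~400
  expect_lt(abs(ref$ref_depth[5] - 100), 2)

  bad <- flat_profile(100); bad$start[3] <- bad$start[3] + 10L
  expect_error(build_family_reference(list(p, bad)), "row 3")
})

test_that("log2 ratios hit the analytic values and ignore global scale", {
  base <- flat_profile(400)
  ref <- build_family_reference(list(base, base))
  # identical test subject -> all ratios 0
  expect_equal(log2_ratios(base, ref)$log2_ratio, rep(0, 20))
  # half depth -> about -1; 1.5x -> about log2(1.5) = 0.585; depths are
  # rescaled by their median, so only a minority of targets is made aberrant
  partial <- base; partial$depth[1:5] <- 200
  expect_lt(abs(log2_ratios(partial, ref)$log2_ratio[1] - (-1)), 0.02)
  gain <- base; gain$depth[1:5] <- 600
  expect_lt(abs(log2_ratios(gain, ref)$log2_ratio[1] - log2(1.5)), 0.02)
  # doubling every depth (test and reference members) changes nothing
  ref2 <- build_family_reference(list(
    transform(base, depth = depth * 2), transform(base, depth = depth * 2)))
  gain2 <- gain; gain2$depth <- gain$depth * 2
  expect_equal(log2_ratios(gain2, ref2)$log2_ratio,
               log2_ratios(gain, ref)$log2_ratio)
})

test_that("threshold-merge segmentation calls the constructed track", {
  track <- flat_profile(1, n = 40L)[, c("chrom", "start", "end")]
  track$log2_ratio <- 0
  expect_equal(nrow(segment_and_call(track)), 0L)  # flat -> nothing

  # 10 consecutive targets at -1 amid zeros -> exactly one loss segment
  track$log2_ratio[11:20] <- -1
  segs <- segment_and_call(track, min_targets = 3)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$call, "loss")
  expect_equal(segs$n_targets, 10L)
  expect_equal(c(segs$start, segs$end), c(track$start[11], track$end[20]))

  # too-short runs are reverted to neutral
  track$log2_ratio <- 0; track$log2_ratio[5:6] <- 1
  expect_equal(nrow(segment_and_call(track, min_targets = 3)), 0L)

  # permuted target order gives identical calls after canonicalization
  track$log2_ratio <- 0; track$log2_ratio[11:20] <- -1
  perm <- track[sample(nrow(track)), ]
  expect_equal(segment_and_call(perm), segment_and_call(track))

  expect_error(segment_and_call(track, gain_threshold = -0.1), "thresholds")
})

test_that("planted CNVs are recovered with correct direction and no false calls", {
  sc <- cohort_scenario(n_families = 3L, n_sites = 50L, n_targets = 200L,
                        depth_dispersion = 0, twin_discordance_rate = 0,
                        seed = 3L)
  g <- generate_cohort(sc, withr::local_tempdir())
  truth <- g$truth$cnvs
  expect_equal(length(truth), 3L)
  for (tc in truth) {
    fam <- g$families[[tc$family_id]]
    proband_d <- read_depth_table(g$depth[[fam$proband]])
    healthy <- lapply(c(fam$cotwin, fam$father, fam$mother),
                      function(s) read_depth_table(g$depth[[s]]))
    segs <- call_family_cnvs(proband_d, healthy, subject = fam$proband)
    expect_equal(nrow(segs), 1L)   # exactly the planted event, nothing else
    expect_equal(segs$call, if (tc$copy_number < 2) "loss" else "gain")
    expect_equal(segs$chrom, tc$chrom)
    expect_lte(segs$start, tc$start)
    expect_gte(segs$end, tc$end)
    expect_gte(segs$n_targets, 3L)
  }
})
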