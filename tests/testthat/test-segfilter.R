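test_that("definitional segregation cases behave as stated", {
  fam <- make_quartet()
  cfg <- filter_config()
  # proband het with solid support, everyone else clean hom_ref -> retained
  calls <- quartet_calls(fam, 100, "het", "hom_ref", "hom_ref", "hom_ref")
  seg <- segregate_de_novo(calls, fam, cfg)
  expect_equal(seg$post_twinning$key, "1:100:A:T")
  expect_equal(nrow(seg$pre_twinning), 0L)

  # inherited variant: father het -> excluded
  calls <- quartet_calls(fam, 100, "het", "hom_ref", "het", "hom_ref")
  expect_equal(nrow(segregate_de_novo(calls, fam, cfg)$post_twinning), 0L)

  # co-twin carries alt reads above the carrier fraction -> excluded
  calls <- quartet_calls(fam, 100, "het", "hom_ref", "hom_ref", "hom_ref")
  calls$alt_depth[calls$sample == fam$cotwin] <- 3L  # 3/30 = 0.10 > 0.05
  expect_equal(nrow(segregate_de_novo(calls, fam, cfg)$post_twinning), 0L)

  # missing genotype in a non-proband member -> conservatively excluded
  calls <- quartet_calls(fam, 100, "het", "hom_ref", "hom_ref", "missing")
  expect_equal(nrow(segregate_de_novo(calls, fam, cfg)$post_twinning), 0L)

  # weak proband support fails the evidence thresholds
  calls <- quartet_calls(fam, 100, "het", "hom_ref", "hom_ref", "hom_ref")
  calls$alt_depth[calls$sample == fam$proband] <- 2L
  expect_equal(nrow(segregate_de_novo(calls, fam, cfg)$post_twinning), 0L)

  # member absent from calls -> error naming the role
  expect_error(segregate_de_novo(calls[calls$sample != fam$father, ], fam, cfg),
               "father")
})

test_that("pre-twinning de novo variants are flagged separately", {
  fam <- make_quartet()
  calls <- rbind(
    quartet_calls(fam, 100, "het", "het", "hom_ref", "hom_ref"),   # pre-twinning
    quartet_calls(fam, 200, "het", "hom_ref", "hom_ref", "hom_ref")) # post
  seg <- segregate_de_novo(calls, fam, filter_config())
  expect_equal(seg$post_twinning$pos, 200L)
  expect_equal(seg$pre_twinning$pos, 100L)
})

test_that("annotation filters implement the three criteria with provenance", {
  fam <- make_quartet()
  cfg <- filter_config()
  keys <- rbind(
    data.frame(chrom = "1", pos = 1:4 * 100L,
               ref = "A", alt = "T",
               key = paste0("1:", 1:4 * 100, ":A:T"),
               proband_gt = "het", proband_depth = 30L,
               proband_alt_depth = 15L, stringsAsFactors = FALSE))
  ann <- rbind(
    make_ann("1", 100, "A", "T", "G1", "missense", c(maf_exac = 0.15)),
    make_ann("1", 200, "A", "T", "G2", "synonymous"),
    make_ann("1", 300, "A", "T", "G3", "frameshift"),
    make_ann("1", 400, "A", "T", "G4", "missense",
             c(maf_1000g = 0.09, maf_exac = 0.10)))  # 0.10 is NOT > 0.10

  ev <- apply_annotation_filters(keys, ann, cfg, family_id = "FAM1")
  expect_setequal(ev$gene, c("G3", "G4"))
  expect_true(all(ev$prov_protein_altering == "pass" &
                    ev$prov_class_exclusion == "pass" &
                    ev$prov_population_maf == "pass"))

  rej <- rejected_events(ev)
  expect_setequal(rej$gene, c("G1", "G2"))
  expect_match(rej$prov_population_maf[rej$gene == "G1"], "maf_exac")
  expect_match(rej$prov_class_exclusion[rej$gene == "G2"], "synonymous")
  # the common variant fails only the frequency criterion
  expect_equal(rej$prov_protein_altering[rej$gene == "G1"], "pass")
})

test_that("unannotated keys are dropped with a count", {
  keys <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T",
                     key = "1:100:A:T", stringsAsFactors = FALSE)
  ann <- make_ann("2", 5, "G", "C", "GX", "missense")
  expect_message(ev <- apply_annotation_filters(keys, ann, filter_config()),
                 "1 unannotated")
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "n_unannotated"), 1L)
})

test_that("loosening the MAF threshold never removes events", {
  fam <- make_quartet()
  set.seed(31)
  keys <- data.frame(chrom = "1", pos = 1:30 * 10L, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  keys$key <- paste("1", keys$pos, "A", "T", sep = ":")
  ann <- do.call(rbind, lapply(seq_len(30), function(i)
    make_ann("1", i * 10, "A", "T", paste0("G", i),
             sample(functional_classes(), 1),
             setNames(runif(2, 0, 0.4), sample(twinseg:::maf_columns(), 2)))))
  prev <- -1L
  for (thr in c(0.05, 0.10, 0.20, 0.50, 1.0)) {
    ev <- apply_annotation_filters(keys, ann, filter_config(maf_threshold = thr))
    expect_gte(nrow(ev), prev)
    prev <- nrow(ev)
  }
})

test_that("segregation matches the naive per-site oracle on random cohorts", {
  fam <- make_quartet()
  cfg <- filter_config()
  set.seed(17)
  gts <- c("hom_ref", "het", "hom_alt", "missing")
  for (rep_i in 1:5) {
    calls <- do.call(rbind, lapply(1:120, function(p)
      quartet_calls(fam, p, sample(gts, 1, prob = c(.55, .25, .1, .1)),
                    sample(gts, 1, prob = c(.7, .15, .05, .1)),
                    sample(gts, 1, prob = c(.7, .15, .05, .1)),
                    sample(gts, 1, prob = c(.7, .15, .05, .1)),
                    depth = sample(c(3L, 10L, 40L), 1))))
    # random extra alt reads in hom_ref carriers exercise the fraction rule
    i <- calls$gt == "hom_ref"
    calls$alt_depth[i] <- rbinom(sum(i), calls$depth[i], 0.03)
    got <- sort(segregate_de_novo(calls, fam, cfg)$post_twinning$key)
    expect_equal(got, oracle_segregate(calls, fam, cfg))
  }
})

test_that("noise-free planted families are recovered exactly through run_family", {
  sc <- cohort_scenario(n_families = 2L, n_sites = 200L, n_targets = 60L,
                        cnv_plans = list(), depth_dispersion = 0,
                        twin_discordance_rate = 0, seed = 13L)
  g <- generate_cohort(sc, withr::local_tempdir())
  ann <- read_annotation_table(g$annotation)
  truth <- g$truth$dnms
  for (fid in names(g$families)) {
    ev <- run_family(g$vcf[[fid]], ann, g$families[[fid]])
    tk <- with(truth[truth$family_id == fid, ],
               paste(chrom, pos, ref, alt, sep = ":"))
    expect_setequal(ev$key, tk)
    cnt <- attr(ev, "stage_counts")
    expect_equal(unname(cnt["n_candidates"]),
                 unname(cnt["n_segregation_candidates"] - cnt["n_rejected_annotation"] -
                          cnt["n_unannotated"]))
    # evidence of all four members travels with each event
    expect_true(all(ev$cotwin_gt == "hom_ref" & ev$father_gt == "hom_ref" &
                      ev$mother_gt == "hom_ref"))
  }
})

test_that("a planted synonymous or common DNM is excluded with provenance", {
  spec <- data.frame(
    gene = c(NA, NA, NA),
    functional_class = c("missense", "synonymous", "missense"),
    maf_kind = c("absent", "absent", "common"),
    site_id = NA_character_, stringsAsFactors = FALSE)
  sc <- cohort_scenario(n_families = 1L, n_sites = 100L, n_targets = 60L,
                        n_planted_dnm_per_proband = 3L, planted_dnm_spec = spec,
                        cnv_plans = list(), depth_dispersion = 0,
                        twin_discordance_rate = 0, seed = 23L)
  g <- generate_cohort(sc, withr::local_tempdir())
  ev <- run_family(g$vcf[["FAM1"]], read_annotation_table(g$annotation),
                   g$families[["FAM1"]])
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$functional_class, "missense")
  rej <- rejected_events(ev)
  expect_equal(nrow(rej), 2L)
  syn <- rej[rej$functional_class == "synonymous", ]
  expect_match(syn$prov_class_exclusion, "fail")
  common <- rej[rej$functional_class == "missense", ]
  expect_match(common$prov_population_maf, "fail")
})
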