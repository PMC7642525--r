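scenario_small <- function(...) {
  args <- list(n_families = 2L, n_sites = 120L, n_targets = 60L,
               cnv_plans = list(), depth_dispersion = 0,
               twin_discordance_rate = 0, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_scenario, args)
}

test_that("scenario validation names the offending field", {
  expect_error(cohort_scenario(twin_discordance_rate = 1.5), "twin_discordance_rate")
  expect_error(cohort_scenario(n_families = -1), "n_families")
  expect_error(cohort_scenario(depth_mean = 0), "depth_mean")
  expect_error(cohort_scenario(planted_dnm_spec = data.frame(
    gene = NA, functional_class = "lincRNA", maf_kind = "rare",
    site_id = NA)), "functional_class")
  expect_error(generate_maf_profile("weird"), "weird")
})

test_that("MAF profiles match their kind by definition", {
  set.seed(1)
  for (i in 1:20) {
    expect_true(all(is.na(generate_maf_profile("absent"))))
    expect_true(all(generate_maf_profile("rare") <= 0.10))
    expect_gt(max(generate_maf_profile("common")), 0.10)
  }
})

test_that("zero discordance and zero planted DNMs give identical twin vectors", {
  sc <- scenario_small(n_planted_dnm_per_proband = 0L)
  g <- generate_cohort(sc, withr::local_tempdir())
  for (fam in g$families) {
    calls <- read_family_vcf(g$vcf[[fam$family_id]], fam)
    a <- calls[calls$sample == fam$proband, ]
    b <- calls[calls$sample == fam$cotwin, ]
    expect_equal(a$gt, b$gt)
  }
})

test_that("planted DNMs appear exactly as recorded in the truth table", {
  sc <- cohort_scenario(n_families = 6L, n_sites = 150L, n_targets = 60L,
                        cnv_plans = list(), depth_dispersion = 0,
                        twin_discordance_rate = 0, seed = 5L)
  g <- generate_cohort(sc, withr::local_tempdir())
  truth <- g$truth$dnms
  expect_equal(nrow(truth), 18L)  # 6 families x 3 planted
  ann <- read_annotation_table(g$annotation)
  for (fid in names(g$families)) {
    fam <- g$families[[fid]]
    calls <- read_family_vcf(g$vcf[[fid]], fam)
    key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
    tk <- with(truth[truth$family_id == fid, ],
               paste(chrom, pos, ref, alt, sep = ":"))
    expect_length(tk, 3L)
    for (k in tk) {
      site <- calls[key == k, ]
      expect_equal(site$gt[site$sample == fam$proband], "het")
      expect_equal(sort(site$gt[site$sample != fam$proband]),
                   rep("hom_ref", 3))
      expect_true(k %in% ann$key)  # every emitted allele is annotated
    }
  }
  # annotation covers every emitted site of every VCF
  calls <- read_family_vcf(g$vcf[["FAM1"]], g$families[["FAM1"]])
  key <- unique(paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"))
  expect_true(all(key %in% ann$key))
})

test_that("the same seed reproduces byte-identical outputs", {
  sc <- scenario_small()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generate_cohort(sc, d1)
  g2 <- generate_cohort(sc, d2)
  for (f in c("FAM1.vcf", "FAM2.vcf", "annotation.tsv", "pedigree.ped",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_identical(readLines(g1$depth[[1]]), readLines(g2$depth[[1]]))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(runif(1))
  generate_cohort(scenario_small(), withr::local_tempdir())
  expect_identical(runif(2), before[2:3])
})

test_that("twins are Mendelian-consistent with parents in noise-free mode", {
  sc <- scenario_small(n_planted_dnm_per_proband = 0L, n_sites = 400L)
  g <- generate_cohort(sc, withr::local_tempdir())
  fam <- g$families[["FAM1"]]
  calls <- read_family_vcf(g$vcf[["FAM1"]], fam)
  gt_num <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  wide <- split(gt_num[calls$gt], calls$sample)
  # transmitted allele count from a parent with genotype g is in
  # {floor(g/2) .. ceiling(g/2)}
  lo <- floor(wide[[fam$father]] / 2) + floor(wide[[fam$mother]] / 2)
  hi <- ceiling(wide[[fam$father]] / 2) + ceiling(wide[[fam$mother]] / 2)
  for (tw in c(fam$proband, fam$cotwin)) {
    expect_true(all(wide[[tw]] >= lo & wide[[tw]] <= hi))
  }
})
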