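test_that("the published six-family variant lists reproduce the recurrence table", {
  ev <- load_published_events()

  rv <- recurrent_variants(ev, min_families = 2)
  hoxa4 <- rv[rv$gene == "HOXA4", ]
  expect_equal(nrow(hoxa4), 1L)
  expect_equal(hoxa4$n_families, 3L)
  expect_equal(hoxa4$families, "II,III,V")
  expect_equal(hoxa4$hgvs_c, "c.920A>C")
  # sorted by recurrence: the triple-family hit leads
  expect_equal(rv$gene[1], "HOXA4")

  rg <- recurrent_genes(ev, min_families = 2)
  expect_equal(nrow(rg), 5L)
  expect_setequal(rg$gene, c("HOXA4", "MUC6", "CHST15", "TBX10", "AMER1"))
  expect_equal(sum(rg$n_variants), 7L)   # seven recurring mutations in total
  expect_equal(rg$n_variants[rg$gene == "MUC6"], 2L)
  expect_equal(rg$n_variants[rg$gene == "CHST15"], 2L)
  amer1 <- rv[rv$gene == "AMER1", ]
  expect_equal(amer1$n_families, 2L)
})

test_that("events from a single family can never recur", {
  ev <- load_published_events()
  one <- ev[ev$family_id == "II", ]
  expect_equal(nrow(recurrent_variants(one, 2)), 0L)
  expect_equal(nrow(recurrent_genes(one, 2)), 0L)
  # one gene, two variants, one family: still not recurrent
  g <- data.frame(family_id = "F1", gene = "G",
                  key = c("1:1:A:T", "1:2:A:T"), stringsAsFactors = FALSE)
  expect_equal(nrow(recurrent_genes(g, 2)), 0L)
})

test_that("recurrence matches the naive double-loop oracle on random events", {
  set.seed(41)
  for (rep_i in 1:5) {
    pos <- sample(1:25, 60, replace = TRUE)
    ev <- data.frame(
      family_id = sample(paste0("F", 1:6), 60, replace = TRUE),
      gene = paste0("G", pos %% 9),   # consistent key -> gene mapping
      key = paste0("1:", pos, ":A:T"),
      stringsAsFactors = FALSE)
    for (mf in 2:4) {
      expect_equal(sort(recurrent_variants(ev, mf)$key),
                   oracle_recurrent_keys(ev, mf))
      expect_equal(sort(recurrent_genes(ev, mf)$gene),
                   oracle_recurrent_genes(ev, mf))
      # raising min_families never adds entries
      expect_lte(nrow(recurrent_variants(ev, mf + 1)),
                 nrow(recurrent_variants(ev, mf)))
    }
    # variant-level recurrent keys all belong to gene-level recurrent genes
    rv <- recurrent_variants(ev, 2); rg <- recurrent_genes(ev, 2)
    expect_true(all(rv$gene %in% rg$gene))
    # singleton keys shuffled across families still never recur
    singletons <- ev[!duplicated(ev$key), ]
    singletons$family_id <- sample(singletons$family_id)
    expect_equal(nrow(recurrent_variants(singletons, 2)), 0L)
  }
})

test_that("the published CNV subject lists reproduce the CNV recurrence table", {
  fx <- load_published_cnvs()
  rc <- recurrent_cnv_genes(fx$segments, fx$genes, min_families = 2)
  expect_equal(nrow(rc), 3L)
  expect_setequal(rc$gene, c("UGT2B17", "OVOS", "KATNAL2"))
  expect_equal(rc$n_carriers[rc$gene == "UGT2B17"], 4L)
  expect_equal(rc$n_carriers[rc$gene == "KATNAL2"], 2L)
  expect_setequal(strsplit(rc$carriers[rc$gene == "OVOS"], ",")[[1]],
                  c("XH1535", "TWS06", "TWS18", "TWS22"))
})

test_that("CNV-gene overlap requires at least one shared base", {
  genes <- data.frame(gene = "G", chrom = "1", start = 1000L, end = 2000L)
  adjacent <- data.frame(subject = "S", family_id = "F1", chrom = "1",
                         start = 2001L, end = 3000L, call = "loss")
  touching <- adjacent; touching$start <- 2000L
  other_chrom <- adjacent; other_chrom$chrom <- "2"; other_chrom$start <- 1500L
  expect_equal(nrow(recurrent_cnv_genes(adjacent, genes, 1)), 0L)
  expect_equal(nrow(recurrent_cnv_genes(other_chrom, genes, 1)), 0L)
  got <- recurrent_cnv_genes(touching, genes, 1)
  expect_equal(got$gene, "G")
  expect_equal(got$direction, "loss")
  # gain in one family, loss in another -> mixed, both count
  two <- rbind(touching,
               data.frame(subject = "T", family_id = "F2", chrom = "1",
                          start = 900L, end = 1100L, call = "gain"))
  got <- recurrent_cnv_genes(two, genes, 2)
  expect_equal(got$direction, "mixed")
  expect_equal(got$n_families, 2L)
})
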