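# shared builders and independent oracles for the test suite

make_quartet <- function(fid = "FAM1") {
  quartet_family(fid, paste0(fid, "_twin_a"), paste0(fid, "_twin_b"),
                 paste0(fid, "_father"), paste0(fid, "_mother"))
}

# one genotype-call row
gcall <- function(sample, pos, gt, chrom = "1", ref = "A", alt = "T",
                  depth = 30L, alt_depth = NULL, gq = 99L) {
  if (is.null(alt_depth))
    alt_depth <- switch(gt, hom_ref = 0L, het = as.integer(depth / 2),
                        hom_alt = depth, missing = 0L)
  data.frame(sample = sample, chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = alt, gt = gt, depth = as.integer(depth),
             alt_depth = as.integer(alt_depth), gq = as.integer(gq),
             stringsAsFactors = FALSE)
}

# the four members' calls at one site
quartet_calls <- function(family, pos, pro, cot, fat, mot, ...) {
  rbind(gcall(family$proband, pos, pro, ...),
        gcall(family$cotwin, pos, cot, ...),
        gcall(family$father, pos, fat, ...),
        gcall(family$mother, pos, mot, ...))
}

# minimal annotation row(s)
make_ann <- function(chrom, pos, ref, alt, gene, functional_class,
                     maf = setNames(rep(NA_real_, 5), twinseg:::maf_columns())) {
  mafs <- setNames(rep(NA_real_, 5), twinseg:::maf_columns())
  mafs[names(maf)] <- maf
  norm <- normalize_variant_key(chrom, pos, ref, alt)
  cbind(data.frame(chrom = norm$chrom, pos = norm$pos, ref = norm$ref,
                   alt = norm$alt, gene = gene,
                   functional_class = functional_class,
                   hgvs_c = "c.1A>T", hgvs_p = "p.X1Y",
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(mafs)),
        data.frame(key = norm$key, stringsAsFactors = FALSE))
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "twinseg")
  stopifnot(nzchar(path))
  path
}

# per-family candidate lists of the published six-family cohort
load_published_events <- function() {
  ev <- read.delim(extdata("recurrent_variants_synthetic_coords.tsv"),
                   colClasses = "character")
  ev$pos <- as.integer(ev$pos)
  ev$key <- normalize_variant_key(ev$chrom, ev$pos, ev$ref, ev$alt)$key
  ev
}

load_published_cnvs <- function() {
  segs <- read.delim(extdata("recurrent_cnv_segments_synthetic_coords.tsv"))
  genes <- read.delim(extdata("recurrent_cnv_gene_intervals_synthetic_coords.tsv"))
  list(segments = segs, genes = genes)
}

# --- independent oracles -------------------------------------------------

# brute-force upper-tail hypergeometric by direct choose() summation
oracle_hypergeom <- function(M, m, N, n) {
  if (m == 0) return(1)
  total <- 0
  for (i in m:min(M, n)) {
    total <- total + choose(M, i) * choose(N - M, n - i)
  }
  total / choose(N, n)
}

# naive per-site segregation re-check (enumerates sites, applies each rule
# literally), independent of the vectorized implementation
oracle_segregate <- function(calls, family, config) {
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  out <- character(0)
  for (k in unique(key)) {
    site <- calls[key == k, ]
    g <- function(id) site[site$sample == id, ][1, ]
    pro <- g(family$proband); cot <- g(family$cotwin)
    fat <- g(family$father); mot <- g(family$mother)
    ok_pro <- !is.na(pro$sample) && pro$gt %in% c("het", "hom_alt") &&
      !is.na(pro$alt_depth) && pro$alt_depth >= config$min_proband_alt_depth &&
      !is.na(pro$depth) && pro$depth >= config$min_proband_depth
    clear <- function(x) {
      if (is.na(x$sample) || x$gt == "missing") return(FALSE)
      if (x$gt != "hom_ref") return(FALSE)
      frac <- if (is.na(x$depth) || x$depth == 0) 0 else x$alt_depth / x$depth
      frac <= config$max_carrier_alt_fraction
    }
    if (ok_pro && clear(cot) && clear(fat) && clear(mot)) out <- c(out, k)
  }
  sort(out)
}

# naive double-loop recurrence oracle
oracle_recurrent_keys <- function(events, min_families) {
  keys <- unique(events$key)
  keep <- character(0)
  for (k in keys) {
    fams <- unique(events$family_id[events$key == k])
    if (length(fams) >= min_families) keep <- c(keep, k)
  }
  sort(keep)
}

oracle_recurrent_genes <- function(events, min_families) {
  genes <- unique(events$gene)
  keep <- character(0)
  for (g in genes) {
    fams <- unique(events$family_id[events$gene == g])
    if (length(fams) >= min_families) keep <- c(keep, g)
  }
  sort(keep)
}
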