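#' Genotype concordance between co-twins
#'
#' Monozygosity check: compares the genotype category (hom_ref / het /
#' hom_alt) of the two twins at every site where both have a non-missing
#' genotype passing the quality and depth thresholds. Sites failing the
#' thresholds in either twin are excluded from the denominator. Monozygotic
#' co-twins are expected to agree at ~99.9% of SNV sites.
#'
#' @param calls Genotype-call table ([read_family_vcf()]).
#' @param family A [quartet_family()]; both twins must be present in `calls`.
#' @param min_gq Minimum genotype quality (default 20).
#' @param min_depth Minimum read depth (default 8).
#' @return A one-row data.frame (class `concordance_report`): `family_id`,
#'   `n_sites_compared`, `n_concordant`, `concordance` (NA, flagged
#'   undefined, when no site is comparable).
#' @export
twin_concordance <- function(calls, family, min_gq = 20, min_depth = 8) {
  for (role in c("proband", "cotwin")) {
    if (!family[[role]] %in% calls$sample)
      stop_twinseg("twin_concordance: sample for role '%s' (%s) absent from calls",
                   role, family[[role]])
  }
  usable <- function(id) {
    x <- calls[calls$sample == id, ]
    x <- x[x$gt != "missing" &
             !is.na(x$gq) & x$gq >= min_gq &
             !is.na(x$depth) & x$depth >= min_depth, ]
    x
  }
  a <- usable(family$proband)
  b <- usable(family$cotwin)
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  n <- length(common)
  conc <- sum(a$gt[match(common, ka)] == b$gt[match(common, kb)])
  structure(data.frame(family_id = family$family_id,
                       n_sites_compared = n,
                       n_concordant = conc,
                       concordance = if (n > 0) conc / n else NA_real_),
            class = c("concordance_report", "data.frame"))
}

#' Depth-coverage summary over capture targets
#'
#' @param depth_table Per-target depth table ([read_depth_table()]).
#' @param min_depth Coverage threshold (default 20 reads).
#' @return List with `mean_depth` (mean over targets) and
#'   `fraction_at_least_min` (fraction of targets with depth >= threshold).
#' @export
coverage_summary <- function(depth_table, min_depth = 20) {
  if (is.null(depth_table) || nrow(depth_table) == 0L)
    stop_twinseg("coverage_summary: depth table is empty")
  list(mean_depth = mean(depth_table$depth),
       fraction_at_least_min = mean(depth_table$depth >= min_depth))
}

#' Write a tab-separated QC report for a cohort
#'
#' @param reports List of concordance reports (one per family).
#' @param path Output path.
#' @param monozygosity_threshold Concordance at or above which a twin pair is
#'   declared monozygotic (default 0.99; a reporting convention, not a
#'   statistical test).
#' @return The combined report data.frame, invisibly.
#' @export
write_qc_report <- function(reports, path, monozygosity_threshold = 0.99) {
  rep <- do.call(rbind, lapply(reports, as.data.frame))
  rep$monozygotic <- !is.na(rep$concordance) &
    rep$concordance >= monozygosity_threshold
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
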