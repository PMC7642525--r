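#' Variants recurrent across unrelated families
#'
#' Groups candidate events by their normalized variant key; a variant recurs
#' when it is carried in at least `min_families` distinct families. Identity
#' is the (chrom, pos, ref, alt) key after multi-allelic splitting and
#' left-alignment — never the HGVS string, which is reporting-only.
#'
#' @param events data.frame of candidate events across families; must carry
#'   `family_id`, `key`, `gene` and (optionally) `hgvs_c`/`hgvs_p`.
#' @param min_families Minimum number of distinct families (default 2).
#' @return data.frame (`gene`, `key`, `hgvs_c`, `hgvs_p`, `families`
#'   comma-separated, `n_families`), sorted by `n_families` descending then
#'   gene.
#' @export
recurrent_variants <- function(events, min_families = 2L) {
  if (nrow(events) == 0L) return(empty_recurrent_variants())
  ev <- events[!duplicated(paste(events$family_id, events$key)), , drop = FALSE]
  grp <- split(ev, ev$key)
  rows <- lapply(grp, function(g) {
    fams <- sort(unique(g$family_id))
    data.frame(gene = g$gene[1], key = g$key[1],
               hgvs_c = if ("hgvs_c" %in% names(g)) g$hgvs_c[1] else NA_character_,
               hgvs_p = if ("hgvs_p" %in% names(g)) g$hgvs_p[1] else NA_character_,
               families = paste(fams, collapse = ","),
               n_families = length(fams),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_families >= min_families, , drop = FALSE]
  out <- out[order(-out$n_families, out$gene, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_recurrent_variants <- function() {
  data.frame(gene = character(), key = character(), hgvs_c = character(),
             hgvs_p = character(), families = character(),
             n_families = integer(), stringsAsFactors = FALSE)
}

#' Genes recurrent across unrelated families
#'
#' Gene-level recurrence: a gene recurs when candidate events in it — not
#' necessarily the same variant — occur in at least `min_families` distinct
#' families. The distinct variant keys per gene are reported, so a gene hit
#' by different mutations in different families is still counted once.
#'
#' @inheritParams recurrent_variants
#' @return data.frame (`gene`, `n_families`, `families`, `n_variants`,
#'   `variant_keys` comma-separated), sorted by `n_families` descending then
#'   gene.
#' @export
recurrent_genes <- function(events, min_families = 2L) {
  if (nrow(events) == 0L)
    return(data.frame(gene = character(), n_families = integer(),
                      families = character(), n_variants = integer(),
                      variant_keys = character(), stringsAsFactors = FALSE))
  grp <- split(events, events$gene)
  rows <- lapply(grp, function(g) {
    fams <- sort(unique(g$family_id))
    keys <- sort(unique(g$key))
    data.frame(gene = g$gene[1], n_families = length(fams),
               families = paste(fams, collapse = ","),
               n_variants = length(keys),
               variant_keys = paste(keys, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_families >= min_families, , drop = FALSE]
  out <- out[order(-out$n_families, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CNV-affected genes recurrent across unrelated families
#'
#' A gene is hit by a CNV call when any called gain/loss segment of a subject
#' overlaps the gene's interval by at least one base (1-based inclusive
#' coordinates on both sides). Recurrence is counted over distinct
#' *families*; carriers (subjects) are reported as well, since one family can
#' contribute several carriers. Direction is "gain", "loss", or "mixed" when
#' different families disagree; both directions count toward recurrence.
#'
#' @param cnv_calls data.frame of CNV segments: `subject`, `family_id`,
#'   `chrom`, `start`, `end`, `call` ("gain"/"loss").
#' @param gene_intervals data.frame: `gene`, `chrom`, `start`, `end`.
#' @param min_families Minimum number of distinct families (default 2).
#' @return data.frame (`gene`, `carriers` comma-separated, `n_carriers`,
#'   `families`, `n_families`, `direction`).
#' @export
recurrent_cnv_genes <- function(cnv_calls, gene_intervals, min_families = 2L) {
  empty <- data.frame(gene = character(), carriers = character(),
                      n_carriers = integer(), families = character(),
                      n_families = integer(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cnv_calls) == 0L || nrow(gene_intervals) == 0L) return(empty)
  seg_gr <- GenomicRanges::GRanges(
    sub("^chr", "", cnv_calls$chrom),
    IRanges::IRanges(cnv_calls$start, cnv_calls$end))
  gene_gr <- GenomicRanges::GRanges(
    sub("^chr", "", gene_intervals$chrom),
    IRanges::IRanges(gene_intervals$start, gene_intervals$end))
  # segments and genes may live on disjoint chromosome sets; that is not
  # worth a warning here
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(seg_gr, gene_gr, minoverlap = 1L))
  if (length(ov) == 0L) return(empty)
  hits <- data.frame(
    gene = gene_intervals$gene[S4Vectors::subjectHits(ov)],
    subject = cnv_calls$subject[S4Vectors::queryHits(ov)],
    family_id = cnv_calls$family_id[S4Vectors::queryHits(ov)],
    call = cnv_calls$call[S4Vectors::queryHits(ov)],
    stringsAsFactors = FALSE)
  rows <- lapply(split(hits, hits$gene), function(h) {
    fams <- sort(unique(h$family_id))
    subj <- sort(unique(h$subject))
    dirs <- unique(h$call)
    data.frame(gene = h$gene[1],
               carriers = paste(subj, collapse = ","),
               n_carriers = length(subj),
               families = paste(fams, collapse = ","),
               n_families = length(fams),
               direction = if (length(dirs) == 1L) dirs else "mixed",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_families >= min_families, , drop = FALSE]
  out <- out[order(-out$n_families, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
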