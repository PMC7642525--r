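#' Read a quartet family's multi-sample VCF into a genotype-call table
#'
#' Parses a VCF v4.2 file (via vcfR) and returns one row per sample per ALT
#' allele. Multi-allelic records are split into biallelic records with
#' per-allele alt depths; records whose FILTER is neither PASS nor "." are
#' dropped and counted. Variant representation is normalized on the way in:
#' chromosome names lose a leading "chr" and indel alleles are trimmed /
#' left-aligned (see [normalize_variant_key()]).
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param family A [quartet_family()]; all four member sample IDs must be
#'   present in the VCF, and an informative error names the missing role
#'   otherwise. Pass `NULL` to read all samples without the check.
#' @return A data.frame with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `gt` (hom_ref/het/hom_alt/missing), `depth`, `alt_depth`, `gq`.
#'   Attribute `n_filter_dropped` counts records removed by the FILTER rule.
#' @export
read_family_vcf <- function(path, family = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  if (!is.null(family)) {
    members <- family_members(family)
    absent <- members[!members %in% samples]
    if (length(absent))
      stop_twinseg("VCF '%s' lacks sample(s) for role(s): %s", path,
                   paste(sprintf("%s (%s)", names(absent), absent), collapse = ", "))
  }
  if (nrow(fix) == 0L) {
    out <- empty_calls()
    attr(out, "n_filter_dropped") <- 0L
    return(out)
  }

  filt <- fix[, "FILTER"]
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  n_dropped <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]) |
                 !nzchar(fix[, "REF"]) | !nzchar(fix[, "ALT"]))
  if (length(bad))
    stop_twinseg("malformed VCF record at data line %d of '%s'", bad[1], path)

  # vectorized fast path: biallelic records with one uniform GT:DP:AD:GQ-style
  # FORMAT (the common case for cohort-scale files)
  fmt1 <- unique(gt[, 1L])
  if (nrow(fix) > 0L && !any(grepl(",", fix[, "ALT"], fixed = TRUE)) &&
      length(fmt1) == 1L) {
    fast <- read_calls_fast(fix, gt, samples, pos, fmt1)
    if (!is.null(fast)) {
      if (n_dropped > 0L)
        message(sprintf("read_family_vcf: dropped %d record(s) with non-PASS FILTER",
                        n_dropped))
      attr(fast, "n_filter_dropped") <- n_dropped
      return(fast)
    }
  }

  rows <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt[r, 1L], ":", fixed = TRUE)[[1]]
    i_gt <- match("GT", fmt); i_dp <- match("DP", fmt)
    i_ad <- match("AD", fmt); i_gq <- match("GQ", fmt)
    if (is.na(i_gt))
      stop_twinseg("malformed VCF record at data line %d of '%s': no GT in FORMAT", r, path)
    per_sample <- strsplit(gt[r, -1L], ":", fixed = TRUE)
    rec <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      norm <- normalize_variant_key(fix[r, "CHROM"], pos[r], fix[r, "REF"], alts[k])
      cell <- function(parts, i) if (is.na(i) || length(parts) < i) NA_character_ else parts[[i]]
      gt_str <- vapply(per_sample, cell, "", i = i_gt)
      alleles <- strsplit(gt_str, "[/|]")
      category <- vapply(alleles, function(a) {
        if (length(a) == 0L || any(a == "." | is.na(a))) return("missing")
        copies <- sum(a == as.character(k))
        c("hom_ref", "het", "hom_alt")[copies + 1L]
      }, "")
      dp <- suppressWarnings(as.integer(vapply(per_sample, cell, "", i = i_dp)))
      ad_raw <- vapply(per_sample, cell, "", i = i_ad)
      ad <- vapply(strsplit(ad_raw, ",", fixed = TRUE), function(a) {
        if (length(a) <= k || is.na(a[1])) NA_integer_
        else suppressWarnings(as.integer(a[k + 1L]))
      }, NA_integer_)
      gq <- suppressWarnings(as.integer(vapply(per_sample, cell, "", i = i_gq)))
      rec[[k]] <- data.frame(sample = samples, chrom = norm$chrom, pos = norm$pos,
                             ref = norm$ref, alt = norm$alt, gt = category,
                             depth = dp, alt_depth = ad, gq = gq,
                             stringsAsFactors = FALSE)
    }
    rows[[r]] <- do.call(rbind, rec)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_dropped > 0L)
    message(sprintf("read_family_vcf: dropped %d record(s) with non-PASS FILTER", n_dropped))
  attr(out, "n_filter_dropped") <- n_dropped
  out
}

# Vectorized parser for biallelic records under a single FORMAT; returns
# NULL (falling back to the general parser) on ragged sample fields.
read_calls_fast <- function(fix, gt, samples, pos, fmt1) {
  fmt <- strsplit(fmt1, ":", fixed = TRUE)[[1]]
  i_gt <- match("GT", fmt); i_dp <- match("DP", fmt)
  i_ad <- match("AD", fmt); i_gq <- match("GQ", fmt)
  if (is.na(i_gt)) return(NULL)
  nf <- length(fmt)
  nr <- nrow(fix)
  norm <- normalize_variant_key(fix[, "CHROM"], pos, fix[, "REF"], fix[, "ALT"])
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    parts <- strsplit(gt[, s + 1L], ":", fixed = TRUE)
    if (!all(lengths(parts) == nf)) return(NULL)
    m <- matrix(unlist(parts), nrow = nf)
    gts <- m[i_gt, ]
    category <- rep("missing", nr)
    category[gts %in% c("0/0", "0|0")] <- "hom_ref"
    category[gts %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
    category[gts %in% c("1/1", "1|1")] <- "hom_alt"
    known <- gts %in% c("0/0", "0|0", "0/1", "1/0", "0|1", "1|0",
                        "1/1", "1|1", "./.", ".|.", ".")
    if (!all(known)) return(NULL)
    dp <- if (is.na(i_dp)) rep(NA_integer_, nr) else
      suppressWarnings(as.integer(m[i_dp, ]))
    ad <- if (is.na(i_ad)) rep(NA_integer_, nr) else
      suppressWarnings(as.integer(sub("^[^,]*,", "", m[i_ad, ])))
    gq <- if (is.na(i_gq)) rep(NA_integer_, nr) else
      suppressWarnings(as.integer(m[i_gq, ]))
    out[[s]] <- data.frame(sample = samples[s], chrom = norm$chrom,
                           pos = norm$pos, ref = norm$ref, alt = norm$alt,
                           gt = category, depth = dp, alt_depth = ad, gq = gq,
                           stringsAsFactors = FALSE)
  }
  # interleave to match the general parser's record-major row order
  res <- do.call(rbind, out)
  res <- res[as.vector(t(matrix(seq_len(nr * length(samples)),
                                nrow = nr))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(sample = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gt = character(),
             depth = integer(), alt_depth = integer(), gq = integer(),
             stringsAsFactors = FALSE)
}

#' Write a genotype-call table as a multi-sample VCF v4.2
#'
#' Inverse of [read_family_vcf()] for biallelic call tables: rows sharing a
#' (chrom, pos, ref, alt) key become one VCF record whose sample fields carry
#' GT:DP:AD:GQ. Sample column order follows first appearance in `calls`.
#'
#' @param calls A genotype-call data.frame as produced by [read_family_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(calls, path) {
  samples <- unique(calls$sample)
  ns <- length(samples)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")

  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  if (nrow(calls) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }

  cell <- paste(gt_code[calls$gt],
                ifelse(is.na(calls$depth), ".", as.character(calls$depth)),
                ifelse(is.na(calls$depth) | is.na(calls$alt_depth), ".",
                       paste0(calls$depth - calls$alt_depth, ",", calls$alt_depth)),
                ifelse(is.na(calls$gq), ".", as.character(calls$gq)),
                sep = ":")
  si <- match(calls$sample, samples)
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt, si)

  if (nrow(calls) %% ns == 0L &&
      identical(si[ord], rep_len(seq_len(ns), nrow(calls)))) {
    # complete table (every sample at every site): vectorized reshape
    first <- ord[seq(1L, length(ord), by = ns)]
    cellm <- matrix(cell[ord], nrow = ns)
    sample_cols <- lapply(seq_len(ns), function(s) cellm[s, ])
    lines <- paste(calls$chrom[first], calls$pos[first], ".",
                   calls$ref[first], calls$alt[first], ".", "PASS", ".",
                   "GT:DP:AD:GQ",
                   do.call(paste, c(sample_cols, list(sep = "\t"))),
                   sep = "\t")
  } else {
    ukey <- unique(key[ord])
    idx <- split(seq_len(nrow(calls)), key)
    lines <- vapply(ukey, function(k) {
      i <- idx[[k]]
      cells <- setNames(rep("./.:.:.:.", ns), samples)
      cells[calls$sample[i]] <- cell[i]
      paste(c(calls$chrom[i[1L]], calls$pos[i[1L]], ".", calls$ref[i[1L]],
              calls$alt[i[1L]], ".", "PASS", ".", "GT:DP:AD:GQ", cells),
            collapse = "\t")
    }, "")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
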