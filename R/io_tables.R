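#' Read an ANNOVAR-style per-variant annotation table
#'
#' Tab-separated with header. Required columns: chrom, pos, ref, alt, gene,
#' functional_class, hgvs_c, hgvs_p, and the five population-frequency
#' columns `maf_1000g`, `maf_hapmap_chb`, `maf_esp`, `maf_dbsnp`, `maf_exac`.
#' Optional in-silico prediction columns (sift, polyphen2, mutation_taster,
#' cadd) are carried through when present.
#'
#' Empty or "." MAF cells are parsed as absent (`NA`), never as zero — a
#' variant unseen by a database is not a variant at frequency 0 for filtering
#' purposes. Functional-class strings are mapped onto the closed vocabulary
#' through `class_synonyms`; unmapped values are rejected.
#'
#' @param path Path to the table.
#' @param class_synonyms Named character vector mapping input labels to
#'   canonical classes; defaults to [default_class_synonyms()].
#' @return A data.frame of annotated variants with normalized variant keys
#'   (column `key`).
#' @export
read_annotation_table <- function(path, class_synonyms = default_class_synonyms()) {
  ann <- read.delim(path, header = TRUE, colClasses = "character",
                    na.strings = c("NA", ".", ""))
  required <- c("chrom", "pos", "ref", "alt", "gene", "functional_class",
                "hgvs_c", "hgvs_p", maf_columns())
  miss <- setdiff(required, names(ann))
  if (length(miss))
    stop_twinseg("annotation table missing required column(s): %s",
                 paste(miss, collapse = ", "))

  unmapped <- setdiff(unique(ann$functional_class), names(class_synonyms))
  unmapped <- unmapped[!is.na(unmapped)]
  if (length(unmapped))
    stop_twinseg("annotation table contains unmapped functional class(es): %s",
                 paste(unmapped, collapse = ", "))
  ann$functional_class <- unname(class_synonyms[ann$functional_class])

  for (mc in maf_columns()) {
    v <- suppressWarnings(as.numeric(ann[[mc]]))
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop_twinseg("column '%s' contains frequencies outside [0,1]", mc)
    ann[[mc]] <- v
  }
  norm <- normalize_variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann$chrom <- norm$chrom; ann$pos <- norm$pos
  ann$ref <- norm$ref; ann$alt <- norm$alt
  ann$key <- norm$key
  ann
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated as name, description, then
#' member genes. Duplicate genes within a set are deduplicated; a line with
#' fewer than three fields (i.e. an empty set) is an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (pathway name -> gene symbols);
#'   descriptions kept as attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop_twinseg("GMT line %d: fewer than 3 fields (empty gene set?)", i)
    nm[i] <- f[1]; descs[i] <- f[2]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(nm))
    stop_twinseg("GMT contains duplicated set name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(setNames(sets, nm), descriptions = setNames(descs, nm))
}

#' Read a per-target read-depth table
#'
#' Tab-separated with header columns chrom, start, end, depth; coordinates
#' 1-based inclusive. Targets must be non-overlapping; they are sorted by
#' (chrom, start) on the way in.
#'
#' @param path Path to the depth table.
#' @param subject Optional subject ID recorded as attribute `"subject"`.
#' @return A data.frame (chrom, start, end, depth).
#' @export
read_depth_table <- function(path, subject = NULL) {
  d <- read.delim(path, header = TRUE)
  need <- c("chrom", "start", "end", "depth")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_twinseg("depth table missing required column(s): %s",
                 paste(miss, collapse = ", "))
  d$chrom <- sub("^chr", "", as.character(d$chrom))
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  validate_depth_profile(d)
  if (!is.null(subject)) attr(d, "subject") <- subject
  d
}

validate_depth_profile <- function(d) {
  if (nrow(d) == 0L) stop_twinseg("depth table is empty")
  if (any(d$depth < 0)) stop_twinseg("depth table contains negative depths")
  if (any(d$end < d$start)) stop_twinseg("depth table contains end < start")
  by_chr <- split(d, d$chrom)
  for (ch in by_chr) {
    if (nrow(ch) > 1L && any(ch$start[-1L] <= ch$end[-nrow(ch)]))
      stop_twinseg("depth table has overlapping targets on chrom %s", ch$chrom[1])
  }
  invisible(d)
}
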