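#' Normalize a variant representation into its identity key
#'
#' Recurrence matching across families must not be defeated by representation
#' differences, so every variant is reduced to a canonical
#' (chrom, pos, ref, alt) key: chromosome names are stripped of a leading
#' "chr", and indel alleles are trimmed/left-aligned by the standard
#' shift-left-while-prefix-equal rule operating on the allele strings alone
#' (no reference genome). Coordinates are 1-based inclusive throughout.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of reference / alternate alleles.
#' @return A data.frame with normalized `chrom`, `pos`, `ref`, `alt` and a
#'   collapsed string `key` ("chrom:pos:ref:alt").
#' @examples
#' normalize_variant_key("chr7", 100, "CAG", "CAGAG")  # right-trim, keep anchor
#' @export
normalize_variant_key <- function(chrom, pos, ref, alt) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  chrom <- sub("^chr", "", as.character(chrom))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(ref == alt)) stop_twinseg("ref and alt alleles must differ")
  # only records where both alleles have length > 1 can be trimmed
  for (i in which(nchar(ref) > 1L & nchar(alt) > 1L)) {
    la <- left_align_alleles(pos[i], ref[i], alt[i])
    pos[i] <- la$pos; ref[i] <- la$ref; alt[i] <- la$alt
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             key = paste(chrom, pos, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

# Shift-left normalization on allele strings only:
# 1) while both alleles start with the same base and both have length > 1,
#    drop the first base and advance pos (the shift-left rule) — doing this
#    first makes all paddings of a repeat-region indel converge;
# 2) then while both alleles end with the same base and both have length > 1,
#    drop the last base.
left_align_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_key_string <- function(df) {
  paste(sub("^chr", "", df$chrom), df$pos, df$ref, df$alt, sep = ":")
}
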