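#' Functional-class vocabulary
#'
#' The closed set of functional consequence classes the filters operate on.
#' Annotation sources use many spellings; [read_annotation_table()] maps them
#' onto this vocabulary via a synonym map.
#'
#' @return Character vector of the seven recognized classes.
#' @export
functional_classes <- function() {
  c("missense", "stopgain", "frameshift", "nonframeshift-indel",
    "splice-boundary", "synonymous", "intronic")
}

#' Default synonym map for annotation functional-class strings
#'
#' Maps ANNOVAR-style labels onto the closed vocabulary of
#' [functional_classes()]. Users can extend or override it when their
#' annotation source uses other spellings.
#'
#' @return Named character vector: names are input labels, values are
#'   canonical classes.
#' @export
default_class_synonyms <- function() {
  c("missense"                 = "missense",
    "nonsynonymous SNV"        = "missense",
    "missense SNV"             = "missense",
    "stopgain"                 = "stopgain",
    "stopgain SNV"             = "stopgain",
    "nonsense"                 = "stopgain",
    "frameshift"               = "frameshift",
    "frameshift insertion"     = "frameshift",
    "frameshift deletion"      = "frameshift",
    "frameshift substitution"  = "frameshift",
    "nonframeshift-indel"      = "nonframeshift-indel",
    "nonframeshift insertion"  = "nonframeshift-indel",
    "nonframeshift deletion"   = "nonframeshift-indel",
    "nonframeshift substitution" = "nonframeshift-indel",
    "splice-boundary"          = "splice-boundary",
    "splicing"                 = "splice-boundary",
    "splice site"              = "splice-boundary",
    "synonymous"               = "synonymous",
    "synonymous SNV"           = "synonymous",
    "intronic"                 = "intronic",
    "intron"                   = "intronic")
}

# the five population-frequency databases consulted by the MAF filter
maf_columns <- function() {
  c("maf_1000g", "maf_hapmap_chb", "maf_esp", "maf_dbsnp", "maf_exac")
}

# genotype categories of a diploid biallelic call
gt_levels <- function() c("hom_ref", "het", "hom_alt", "missing")

member_roles <- function() c("proband_twin", "cotwin", "father", "mother")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_twinseg <- function(...) stop(sprintf(...), call. = FALSE)
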