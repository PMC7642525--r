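#' Configuration of the segregation and annotation filters
#'
#' Encodes the three filter criteria applied to candidate de novo variants:
#' (1) keep protein-altering classes only (frameshift, nonframeshift indels,
#' missense, stopgain, intron-exon boundary); (2) exclude common variants
#' with frequency > `maf_threshold` (default 10%) in at least one of the five
#' population databases — a frequency that is absent (database never saw the
#' variant) never triggers exclusion; (3) exclude synonymous and intronic
#' classes. Read-evidence thresholds guard the segregation call itself.
#'
#' @param maf_threshold Exclude if any present population MAF exceeds this
#'   (strictly); default 0.10.
#' @param protein_altering_classes Classes retained by criterion (1).
#' @param excluded_classes Classes removed by criterion (3).
#' @param min_proband_alt_depth Minimum alt-supporting reads in the proband.
#' @param min_proband_depth Minimum total depth in the proband.
#' @param max_carrier_alt_fraction Maximum alt-allele read fraction tolerated
#'   in co-twin/parents before the variant is considered present in them
#'   (default 0.05; guards against allele dropout).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.10,
                          protein_altering_classes = c("frameshift",
                                                       "nonframeshift-indel",
                                                       "missense", "stopgain",
                                                       "splice-boundary"),
                          excluded_classes = c("synonymous", "intronic"),
                          min_proband_alt_depth = 4L,
                          min_proband_depth = 8L,
                          max_carrier_alt_fraction = 0.05) {
  if (is.na(maf_threshold) || maf_threshold <= 0 || maf_threshold > 1)
    stop_twinseg("filter_config: maf_threshold must be in (0, 1]")
  if (length(intersect(protein_altering_classes, excluded_classes)))
    stop_twinseg("filter_config: protein_altering_classes and excluded_classes must be disjoint")
  bad <- setdiff(c(protein_altering_classes, excluded_classes), functional_classes())
  if (length(bad))
    stop_twinseg("filter_config: unknown functional class(es): %s",
                 paste(bad, collapse = ", "))
  structure(list(maf_threshold = maf_threshold,
                 protein_altering_classes = protein_altering_classes,
                 excluded_classes = excluded_classes,
                 min_proband_alt_depth = as.integer(min_proband_alt_depth),
                 min_proband_depth = as.integer(min_proband_depth),
                 max_carrier_alt_fraction = max_carrier_alt_fraction),
            class = "filter_config")
}

#' Segregation screen for de novo variants in a quartet
#'
#' Post-twinning candidates are sites where the affected twin carries the
#' alternate allele (het or hom-alt, with sufficient read support) while the
#' co-twin and both parents are confidently hom-ref (non-missing genotype,
#' alt-read fraction at or below `max_carrier_alt_fraction`). Sites with a
#' missing genotype in any non-proband member are excluded (conservative).
#'
#' Variants present in *both* twins but absent from both parents are
#' pre-twinning de novo events: real mutations, but unable to explain twin
#' discordance. They are returned separately, not mixed into the candidates.
#'
#' @param calls Genotype-call table with all four members.
#' @param family A [quartet_family()].
#' @param config A [filter_config()].
#' @return List with two data.frames of variant keys (`chrom`, `pos`, `ref`,
#'   `alt`, `key`, proband evidence): `post_twinning` (the candidates) and
#'   `pre_twinning` (flagged separately).
#' @export
segregate_de_novo <- function(calls, family, config = filter_config()) {
  members <- family_members(family)
  for (i in seq_along(members)) {
    if (!members[[i]] %in% calls$sample)
      stop_twinseg("segregate_de_novo: sample for role '%s' (%s) absent from calls",
                   names(members)[i], members[[i]])
  }
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  tab <- function(id) {
    x <- calls[calls$sample == id, ]
    x$key <- key[calls$sample == id]
    x[!duplicated(x$key), ]
  }
  pro <- tab(family$proband); cot <- tab(family$cotwin)
  fat <- tab(family$father); mot <- tab(family$mother)

  keys <- pro$key
  mc <- match(keys, cot$key); mf <- match(keys, fat$key); mm <- match(keys, mot$key)

  carrier_clear <- function(x, m) {
    # confidently hom_ref: genotype present and alt evidence below threshold
    gt <- x$gt[m]
    frac <- ifelse(is.na(x$depth[m]) | x$depth[m] == 0, 0,
                   x$alt_depth[m] / x$depth[m])
    frac[is.na(frac)] <- 0
    !is.na(m) & !is.na(gt) & gt == "hom_ref" & frac <= config$max_carrier_alt_fraction
  }
  carrier_has <- function(x, m) {
    gt <- x$gt[m]
    !is.na(m) & !is.na(gt) & gt %in% c("het", "hom_alt")
  }

  pro_has <- pro$gt %in% c("het", "hom_alt") &
    !is.na(pro$alt_depth) & pro$alt_depth >= config$min_proband_alt_depth &
    !is.na(pro$depth) & pro$depth >= config$min_proband_depth

  post <- pro_has & carrier_clear(cot, mc) & carrier_clear(fat, mf) & carrier_clear(mot, mm)
  pre <- pro_has & carrier_has(cot, mc) & carrier_clear(fat, mf) & carrier_clear(mot, mm)

  take <- function(idx) {
    out <- pro[idx, c("chrom", "pos", "ref", "alt", "key",
                      "gt", "depth", "alt_depth")]
    names(out)[6:8] <- c("proband_gt", "proband_depth", "proband_alt_depth")
    rownames(out) <- NULL
    out
  }
  list(post_twinning = take(post), pre_twinning = take(pre))
}

#' Apply the functional-class and population-frequency filters
#'
#' Joins segregation-stage variant keys to their annotation and applies, in
#' order: the protein-altering inclusion criterion, the synonymous/intronic
#' exclusion criterion, and the common-variant frequency criterion (excluded
#' if any *present* database frequency exceeds `maf_threshold`). Keys without
#' an annotation row are dropped and counted. Every event — retained or
#' rejected — carries full per-filter provenance.
#'
#' @param keys data.frame of candidate keys (from [segregate_de_novo()]
#'   `$post_twinning`), with a `key` column.
#' @param annotations Annotation table ([read_annotation_table()]).
#' @param config A [filter_config()].
#' @param family_id Family label stamped onto the events.
#' @return A `candidate_events` data.frame of retained events (variant key,
#'   gene, class, HGVS, proband evidence, provenance columns `prov_*`).
#'   Rejected events with their provenance are in attribute `"rejected"`
#'   (see [rejected_events()]); the number of unannotated keys in attribute
#'   `"n_unannotated"`.
#' @export
apply_annotation_filters <- function(keys, annotations, config = filter_config(),
                                     family_id = NA_character_) {
  m <- match(keys$key, annotations$key)
  n_unann <- sum(is.na(m))
  if (n_unann > 0L)
    message(sprintf("apply_annotation_filters: dropped %d unannotated key(s)", n_unann))
  keys <- keys[!is.na(m), , drop = FALSE]
  ann <- annotations[m[!is.na(m)], , drop = FALSE]

  fc <- ann$functional_class
  pass_pa <- fc %in% config$protein_altering_classes
  pass_ex <- !fc %in% config$excluded_classes
  mafs <- as.matrix(ann[, maf_columns(), drop = FALSE])
  over <- !is.na(mafs) & mafs > config$maf_threshold
  pass_maf <- rowSums(over) == 0L

  detail_maf <- apply(over, 1L, function(r) {
    if (!any(r)) "all present MAFs <= threshold"
    else paste(colnames(over)[r], collapse = ",")
  })
  prov <- data.frame(
    prov_protein_altering = ifelse(pass_pa, "pass",
                                   paste0("fail: class ", fc, " not protein-altering")),
    prov_class_exclusion = ifelse(pass_ex, "pass",
                                  paste0("fail: class ", fc, " excluded")),
    prov_population_maf = ifelse(pass_maf, "pass",
                                 paste0("fail: >", config$maf_threshold, " in ", detail_maf)),
    stringsAsFactors = FALSE)

  events <- cbind(data.frame(family_id = rep(family_id, nrow(keys)),
                             stringsAsFactors = FALSE),
                  keys,
                  ann[, c("gene", "functional_class", "hgvs_c", "hgvs_p")],
                  prov)
  rownames(events) <- NULL
  keep <- pass_pa & pass_ex & pass_maf
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_events", "data.frame"),
            rejected = events[!keep, , drop = FALSE],
            n_unannotated = n_unann)
}

#' Events rejected by the annotation filters, with provenance
#'
#' @param x A `candidate_events` object from [apply_annotation_filters()].
#' @return data.frame of rejected events; the `prov_*` columns say which
#'   filter failed and why.
#' @export
rejected_events <- function(x) attr(x, "rejected")

#' Full per-family candidate screen
#'
#' Composition of [segregate_de_novo()] and [apply_annotation_filters()]:
#' reads the family VCF and annotation table, screens for post-twinning
#' candidates, applies the three annotation filters, and attaches the
#' genotype evidence of all four members to each retained event.
#'
#' @param vcf_path Path to the family's four-sample VCF.
#' @param annotations Annotation table, or a path to one.
#' @param family A [quartet_family()].
#' @param config A [filter_config()].
#' @return A `candidate_events` data.frame (see
#'   [apply_annotation_filters()]); per-stage record counts in attribute
#'   `"stage_counts"`; pre-twinning de novo keys in attribute
#'   `"pre_twinning"`.
#' @export
run_family <- function(vcf_path, annotations, family, config = filter_config()) {
  if (is.character(annotations)) annotations <- read_annotation_table(annotations)
  calls <- read_family_vcf(vcf_path, family)
  seg <- segregate_de_novo(calls, family, config)
  ev <- apply_annotation_filters(seg$post_twinning, annotations, config,
                                 family_id = family$family_id)
  ev2 <- attach_member_evidence(ev, calls, family)
  attr(ev2, "stage_counts") <- c(
    n_calls = nrow(calls),
    n_segregation_candidates = nrow(seg$post_twinning),
    n_pre_twinning = nrow(seg$pre_twinning),
    n_unannotated = attr(ev, "n_unannotated"),
    n_rejected_annotation = nrow(rejected_events(ev)),
    n_candidates = nrow(ev))
  attr(ev2, "pre_twinning") <- seg$pre_twinning
  ev2
}

attach_member_evidence <- function(events, calls, family) {
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  for (role in c("cotwin", "father", "mother")) {
    id <- family[[role]]
    sel <- calls$sample == id
    m <- match(events$key, key[sel])
    events[[paste0(role, "_gt")]] <- calls$gt[sel][m]
  }
  events
}
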