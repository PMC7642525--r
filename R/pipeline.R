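#' Assemble a run configuration for a generated or assembled cohort
#'
#' Convenience constructor for the [run_cohort()] configuration, typically
#' fed with the return value of [generate_cohort()]. All analysis thresholds
#' are surfaced here; defaults are the package defaults (MAF 0.10,
#' min_families 2, P < 0.05, q < 0.2).
#'
#' @param cohort List as returned by [generate_cohort()], or a list with
#'   elements `pedigree`, `vcf` (named by family), `annotation`, `depth`
#'   (named by subject), `gene_intervals`.
#' @param out_dir Output directory for the run.
#' @param gmt Optional path to a GMT file; enrichment is skipped when NULL.
#' @param filter,qc,cnv,enrich Named lists overriding individual settings of
#'   the corresponding stage.
#' @return A `run_config` list.
#' @export
cohort_config <- function(cohort, out_dir, gmt = NULL, filter = list(),
                          qc = list(), cnv = list(), enrich = list()) {
  merge_defaults <- function(user, defaults) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop_twinseg("unknown setting(s): %s", paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  structure(list(
    pedigree = cohort$pedigree,
    vcf = cohort$vcf,
    annotation = cohort$annotation,
    depth = cohort$depth,
    gene_intervals = cohort$gene_intervals,
    gmt = gmt,
    out_dir = out_dir,
    filter = merge_defaults(filter, as.list(unclass(filter_config()))),
    qc = merge_defaults(qc, list(min_gq = 20, min_depth = 8,
                                 monozygosity_threshold = 0.99)),
    cnv = merge_defaults(cnv, list(min_targets = 3L, gain_threshold = 0.3,
                                   loss_threshold = -0.3, pseudocount = 1)),
    enrich = merge_defaults(enrich, list(min_recurrent_families = 2L,
                                         p_threshold = 0.05,
                                         q_threshold = 0.2,
                                         min_families_recurrence = 2L))),
    class = "run_config")
}

#' Read a YAML run configuration
#'
#' Same structure as [cohort_config()]; file paths are interpreted relative
#' to the YAML file's directory unless absolute.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  absolutize <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(grepl("^/", p), p, file.path(base, p))
    names(out) <- names(p)
    out
  }
  for (f in c("pedigree", "annotation", "gene_intervals", "gmt"))
    cfg[[f]] <- absolutize(cfg[[f]])
  cfg$vcf <- absolutize(unlist(cfg$vcf))
  cfg$depth <- absolutize(unlist(cfg$depth))
  cohort_config(cfg, out_dir = cfg$out_dir %||% file.path(base, "run"),
                gmt = cfg$gmt,
                filter = cfg$filter %||% list(), qc = cfg$qc %||% list(),
                cnv = cfg$cnv %||% list(), enrich = cfg$enrich %||% list())
}

#' Run the full cohort analysis
#'
#' Executes the stages in order — monozygosity QC, per-family segregation
#' and annotation filtering, cross-family recurrence (variants and genes),
#' family-reference CNV calling with CNV-gene recurrence, and (when a GMT is
#' configured) pathway enrichment — writing tab-separated result tables and
#' a JSON run manifest with per-stage record counts under
#' `config$out_dir`. The analysis is deterministic: identical inputs and
#' configuration reproduce identical outputs.
#'
#' @param config A `run_config` from [cohort_config()] /
#'   [read_run_config()], or a path to a YAML configuration.
#' @return Invisibly, a list of the result tables (`qc`, `candidates`,
#'   `rejected`, `recurrent_variants`, `recurrent_genes`, `cnv_segments`,
#'   `recurrent_cnv_genes`, `enrichment`, `manifest`).
#' @export
run_cohort <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  inputs <- c(config$pedigree, config$annotation, config$gene_intervals,
              config$gmt, config$vcf, config$depth)
  missing_files <- inputs[!file.exists(inputs)]
  if (length(missing_files))
    stop_twinseg("run_cohort: missing input file(s): %s",
                 paste(missing_files, collapse = ", "))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, fam, expr) {
    tryCatch(expr, error = function(e)
      stop_twinseg("stage '%s'%s failed: %s", name,
                   if (is.na(fam)) "" else paste0(" (family ", fam, ")"),
                   conditionMessage(e)))
  }
  tsv <- function(x, file) {
    write.table(x, file.path(out_dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    file
  }

  families <- stage("pedigree", NA, read_pedigree(config$pedigree))
  ann <- stage("annotation", NA, read_annotation_table(config$annotation))
  fcfg <- do.call(filter_config, config$filter)

  qc_reports <- list()
  events <- list(); rejected <- list(); pre_twinning <- list()
  counts <- list()
  for (fam in families) {
    fid <- fam$family_id
    calls <- stage("read_vcf", fid, read_family_vcf(config$vcf[[fid]], fam))
    qc_reports[[fid]] <- stage("twinqc", fid,
      twin_concordance(calls, fam, min_gq = config$qc$min_gq,
                       min_depth = config$qc$min_depth))
    seg <- stage("segregate", fid, segregate_de_novo(calls, fam, fcfg))
    ev <- stage("annotation_filters", fid,
      apply_annotation_filters(seg$post_twinning, ann, fcfg, family_id = fid))
    ev <- attach_member_evidence(ev, calls, fam)
    events[[fid]] <- as.data.frame(ev)
    rejected[[fid]] <- rejected_events(ev)
    pre_twinning[[fid]] <- seg$pre_twinning
    counts[[fid]] <- list(
      records_in = nrow(calls) / 4,
      segregation_candidates = nrow(seg$post_twinning),
      pre_twinning = nrow(seg$pre_twinning),
      unannotated_dropped = attr(ev, "n_unannotated"),
      rejected_by_annotation_filters = nrow(rejected_events(ev)),
      candidates_out = nrow(ev))
  }
  qc_tab <- write_qc_report(qc_reports, file.path(out_dir, "qc_report.tsv"),
                            config$qc$monozygosity_threshold)
  candidates <- do.call(rbind, c(events, list(make.row.names = FALSE)))
  rejected_tab <- do.call(rbind, c(rejected, list(make.row.names = FALSE)))
  tsv(candidates, "candidates.tsv")
  tsv(rejected_tab, "candidates_rejected.tsv")

  min_fam <- config$enrich$min_families_recurrence
  rec_var <- stage("recurrence", NA, recurrent_variants(candidates, min_fam))
  rec_gene <- stage("recurrence", NA, recurrent_genes(candidates, min_fam))
  tsv(rec_var, "recurrent_variants.tsv")
  tsv(rec_gene, "recurrent_genes.tsv")

  segs <- list()
  for (fam in families) {
    fid <- fam$family_id
    proband_d <- stage("cnv", fid,
      read_depth_table(config$depth[[fam$proband]], fam$proband))
    healthy <- lapply(c(fam$cotwin, fam$father, fam$mother), function(s)
      read_depth_table(config$depth[[s]], s))
    s <- stage("cnv", fid, call_family_cnvs(
      proband_d, healthy, subject = fam$proband,
      min_targets = config$cnv$min_targets,
      gain_threshold = config$cnv$gain_threshold,
      loss_threshold = config$cnv$loss_threshold,
      pseudocount = config$cnv$pseudocount))
    if (nrow(s)) s$family_id <- fid
    else s$family_id <- character(0)
    segs[[fid]] <- s
  }
  cnv_segments <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
  tsv(cnv_segments, "cnv_segments.tsv")
  gene_iv <- read.delim(config$gene_intervals,
                        colClasses = c(gene = "character", chrom = "character"))
  rec_cnv <- stage("cnv_recurrence", NA,
    recurrent_cnv_genes(cnv_segments, gene_iv, min_fam))
  tsv(rec_cnv, "recurrent_cnv_genes.tsv")

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    pathways <- stage("enrich", NA, read_gmt(config$gmt))
    gene_sets <- lapply(events, function(e) unique(e$gene))
    enrichment <- stage("enrich", NA, enrich_families(
      gene_sets, pathways,
      min_recurrent_families = config$enrich$min_recurrent_families,
      p_threshold = config$enrich$p_threshold,
      q_threshold = config$enrich$q_threshold))
    tsv(as.data.frame(enrichment), "enrichment.tsv")
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serializable_config(config), cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("twinseg")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stage_counts = counts,
    n_families = length(families),
    n_candidates = nrow(candidates),
    n_recurrent_variants = nrow(rec_var),
    n_recurrent_genes = nrow(rec_gene),
    n_cnv_segments = nrow(cnv_segments),
    n_recurrent_cnv_genes = nrow(rec_cnv),
    n_pathways_tested = if (is.null(enrichment)) 0L else nrow(enrichment))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(qc = qc_tab, candidates = candidates,
                 rejected = rejected_tab, pre_twinning = pre_twinning,
                 recurrent_variants = rec_var, recurrent_genes = rec_gene,
                 cnv_segments = cnv_segments, recurrent_cnv_genes = rec_cnv,
                 enrichment = enrichment, manifest = manifest))
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$vcf <- as.list(cfg$vcf)
  cfg$depth <- as.list(cfg$depth)
  cfg
}
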