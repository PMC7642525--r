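#' Describe a synthetic discordant-twin cohort
#'
#' A `cohort_scenario` fixes every parameter of the synthetic-cohort
#' generator: cohort size, exome site count, germline heterozygosity,
#' the co-twin discordance rate (somatic mosaicism between twins), the
#' planted post-twinning de novo mutations, the read-depth law, the exome
#' capture target grid, and the planted CNVs. Identical scenarios with
#' identical seeds produce byte-identical output files.
#'
#' Defaults mirror the study design the package addresses: six quartet
#' families, co-twin genotype concordance of 99.9% (discordance rate 1e-3),
#' mean target depth 387.6x with negative-binomial dispersion 0.1.
#'
#' @param n_families Number of quartet families (default 6).
#' @param n_sites Number of background (germline) exome variant sites.
#' @param germline_het_rate Per-site probability that a parent is
#'   heterozygous; parents are hom-alt with a quarter of that probability.
#' @param twin_discordance_rate Per-site probability that the co-twins'
#'   germline genotype is perturbed in one twin (models somatic mosaicism).
#' @param n_planted_dnm_per_proband Post-twinning de novo mutations planted
#'   heterozygous in each affected twin (absent in co-twin and parents).
#' @param planted_dnm_spec data.frame with columns `gene`, `functional_class`,
#'   `maf_kind` (absent/rare/common) and `site_id`; recycled to
#'   `n_planted_dnm_per_proband` rows per family. A non-NA `site_id` pins the
#'   mutation to one cohort-wide site shared by every family that plants it
#'   (for recurrence experiments); NA means a family-private site.
#' @param depth_mean Mean per-target and per-site read depth.
#' @param depth_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 switches off all depth noise
#'   (deterministic depths and allele depths).
#' @param n_targets Number of exome capture targets in the depth tables.
#' @param cnv_plans List of [planted_cnv()] records; `NULL` for the default
#'   plan (a recurrent heterozygous deletion in families 1-2 and a
#'   single-copy gain in family 3, sized to span >= 8 targets).
#' @param seed Integer RNG seed.
#' @return A validated object of class `cohort_scenario`.
#' @seealso [generate_cohort()]
#' @export
cohort_scenario <- function(n_families = 6L,
                            n_sites = 2000L,
                            germline_het_rate = 0.3,
                            twin_discordance_rate = 0.001,
                            n_planted_dnm_per_proband = 3L,
                            planted_dnm_spec = default_planted_dnm_spec(),
                            depth_mean = 387.6,
                            depth_dispersion = 0.1,
                            n_targets = 400L,
                            cnv_plans = NULL,
                            seed = 1L) {
  sc <- structure(list(n_families = as.integer(n_families),
                       n_sites = as.integer(n_sites),
                       germline_het_rate = germline_het_rate,
                       twin_discordance_rate = twin_discordance_rate,
                       n_planted_dnm_per_proband = as.integer(n_planted_dnm_per_proband),
                       planted_dnm_spec = planted_dnm_spec,
                       depth_mean = depth_mean,
                       depth_dispersion = depth_dispersion,
                       n_targets = as.integer(n_targets),
                       cnv_plans = cnv_plans,
                       seed = as.integer(seed)),
                  class = "cohort_scenario")
  if (is.null(sc$cnv_plans)) sc$cnv_plans <- default_cnv_plans(sc)
  validate_scenario(sc)
}

default_planted_dnm_spec <- function() {
  data.frame(gene = NA_character_,
             functional_class = c("missense", "stopgain", "frameshift"),
             maf_kind = c("rare", "absent", "absent"),
             site_id = NA_character_,
             stringsAsFactors = FALSE)
}

validate_scenario <- function(sc) {
  chk_count <- function(x, field) {
    if (length(x) != 1L || is.na(x) || x < 0L)
      stop_twinseg("invalid scenario: field '%s' must be a count >= 0", field)
  }
  chk_rate <- function(x, field) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop_twinseg("invalid scenario: field '%s' must be a rate in [0,1]", field)
  }
  chk_count(sc$n_families, "n_families")
  chk_count(sc$n_sites, "n_sites")
  chk_count(sc$n_planted_dnm_per_proband, "n_planted_dnm_per_proband")
  chk_count(sc$n_targets, "n_targets")
  chk_rate(sc$germline_het_rate, "germline_het_rate")
  chk_rate(sc$twin_discordance_rate, "twin_discordance_rate")
  if (is.na(sc$depth_mean) || sc$depth_mean <= 0)
    stop_twinseg("invalid scenario: field 'depth_mean' must be > 0")
  if (is.na(sc$depth_dispersion) || sc$depth_dispersion < 0)
    stop_twinseg("invalid scenario: field 'depth_dispersion' must be >= 0")
  if (is.na(sc$seed))
    stop_twinseg("invalid scenario: field 'seed' must be an integer")
  spec <- sc$planted_dnm_spec
  if (!is.data.frame(spec) ||
      !all(c("gene", "functional_class", "maf_kind", "site_id") %in% names(spec)))
    stop_twinseg(paste("invalid scenario: field 'planted_dnm_spec' must be a",
                       "data.frame with columns gene, functional_class, maf_kind, site_id"))
  if (sc$n_planted_dnm_per_proband > 0L && nrow(spec) == 0L)
    stop_twinseg("invalid scenario: field 'planted_dnm_spec' is empty but DNMs are requested")
  if (!all(spec$functional_class %in% functional_classes()))
    stop_twinseg("invalid scenario: field 'planted_dnm_spec' has unknown functional_class")
  if (!all(spec$maf_kind %in% c("absent", "rare", "common")))
    stop_twinseg("invalid scenario: field 'planted_dnm_spec' has unknown maf_kind")
  for (p in sc$cnv_plans) {
    if (!inherits(p, "planted_cnv"))
      stop_twinseg("invalid scenario: field 'cnv_plans' must contain planted_cnv objects")
    if (p$family > sc$n_families)
      stop_twinseg("invalid scenario: field 'cnv_plans' references family %d of %d",
                   p$family, sc$n_families)
  }
  sc
}

#' Plan a CNV to plant in the synthetic cohort
#'
#' @param family Family index (1-based) in the scenario.
#' @param carrier Member role carrying the CNV (usually "proband_twin").
#' @param chrom,start,end 1-based inclusive interval of the event.
#' @param copy_number Integer copy number; 2 is the diploid baseline and is
#'   rejected (1 = heterozygous loss, 3 = single-copy gain, 0 = homozygous
#'   loss, ...).
#' @param overlapping_genes Gene symbols whose synthetic intervals will
#'   overlap the event.
#' @return Object of class `planted_cnv`.
#' @export
planted_cnv <- function(family, carrier, chrom, start, end, copy_number,
                        overlapping_genes = character()) {
  if (start > end) stop_twinseg("planted_cnv: start must be <= end")
  if (copy_number == 2L || copy_number < 0L)
    stop_twinseg("planted_cnv: copy_number must be a non-negative integer != 2")
  if (!carrier %in% member_roles())
    stop_twinseg("planted_cnv: unknown carrier role '%s'", carrier)
  structure(list(family = as.integer(family), carrier = carrier,
                 chrom = sub("^chr", "", as.character(chrom)),
                 start = as.integer(start), end = as.integer(end),
                 copy_number = as.integer(copy_number),
                 overlapping_genes = as.character(overlapping_genes)),
            class = "planted_cnv")
}

# Default CNV plan: a recurrent het deletion (families 1 and 2) and a gain
# (family 3), each spanning 8 consecutive targets of the synthetic grid.
default_cnv_plans <- function(sc) {
  plans <- list()
  grid <- target_grid(sc$n_targets)
  span <- function(chrom, i1, i2) {
    g <- grid[grid$chrom == chrom, ]
    c(g$start[i1], g$end[i2])
  }
  if (sc$n_families >= 1L && sum(grid$chrom == "1") >= 58L) {
    iv <- span("1", 51L, 58L)
    plans <- c(plans, list(
      planted_cnv(1L, "proband_twin", "1", iv[1], iv[2], 1L, "CNVGENE_A")))
    if (sc$n_families >= 2L)
      plans <- c(plans, list(
        planted_cnv(2L, "proband_twin", "1", iv[1], iv[2], 1L, "CNVGENE_A")))
  }
  if (sc$n_families >= 3L && sum(grid$chrom == "2") >= 28L) {
    iv <- span("2", 21L, 28L)
    plans <- c(plans, list(
      planted_cnv(3L, "proband_twin", "2", iv[1], iv[2], 3L, "CNVGENE_B")))
  }
  plans
}

# Exome capture target grid: 120 bp targets every 200 bp, split between
# chromosomes 1 and 2.
target_grid <- function(n_targets) {
  n1 <- ceiling(n_targets / 2)
  n2 <- n_targets - n1
  mk <- function(chrom, n) {
    if (n == 0L) return(NULL)
    start <- 1L + (seq_len(n) - 1L) * 200L
    data.frame(chrom = chrom, start = start, end = start + 119L,
               stringsAsFactors = FALSE)
  }
  rbind(mk("1", n1), mk("2", n2))
}

#' Generate a five-database population-frequency profile
#'
#' The frequency columns mimic the five databases consulted by the common-
#' variant filter (1000 Genomes, HapMap CHB, ESP, dbSNP, ExAC).
#'
#' @param kind "absent" (unseen in all five databases -> all missing),
#'   "rare" (present everywhere at <= 0.10) or "common" (> 0.10 in at least
#'   one database).
#' @return Named numeric vector of length 5 (NA = absent).
#' @export
generate_maf_profile <- function(kind) {
  cols <- maf_columns()
  switch(kind,
    absent = setNames(rep(NA_real_, 5L), cols),
    rare   = setNames(round(runif(5L, 1e-4, 0.08), 5), cols),
    common = {
      v <- round(runif(5L, 0.01, 0.45), 5)
      v[sample.int(5L, 1L)] <- round(runif(1L, 0.12, 0.6), 5)
      setNames(v, cols)
    },
    stop_twinseg("generate_maf_profile: unknown kind '%s'", kind))
}

#' Generate a synthetic quartet cohort with known ground truth
#'
#' Writes, under `dir`: one VCF v4.2 per family (four samples, GT:DP:AD:GQ),
#' a cohort-wide annotation table covering every emitted ALT allele, one
#' read-depth table per subject, a pedigree file with twin roles, a synthetic
#' gene-interval table for CNV-to-gene mapping, and a JSON truth table of
#' planted DNMs and CNVs.
#'
#' The germline model: each parent is independently heterozygous with
#' probability `germline_het_rate` (hom-alt with a quarter of it); twins
#' share one Mendelian draw from the parents; with probability
#' `twin_discordance_rate` per site one randomly chosen twin's genotype is
#' perturbed to a different category (somatic mosaicism — such sites may
#' legitimately violate Mendelian consistency). Planted de novo mutations
#' are heterozygous in the affected twin only, at sites where the whole
#' family is otherwise hom-ref.
#'
#' @param scenario A [cohort_scenario()].
#' @param dir Output directory (created if needed).
#' @return List with `dir`, per-family `vcf` paths, `pedigree`, `annotation`,
#'   per-subject `depth` paths, `gene_intervals`, `truth_json`, the in-memory
#'   `truth` list and the `families` list of [quartet_family()] objects.
#' @export
generate_cohort <- function(scenario, dir) {
  validate_scenario(scenario)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # localize RNG state so generation is reproducible and side-effect free
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(scenario$seed)

  fam_ids <- sprintf("FAM%d", seq_len(scenario$n_families))
  families <- lapply(fam_ids, function(f)
    quartet_family(f, paste0(f, "_twin_a"), paste0(f, "_twin_b"),
                   paste0(f, "_father"), paste0(f, "_mother")))
  names(families) <- fam_ids

  sites <- build_site_catalog(scenario, fam_ids)
  ann <- sites$annotation
  truth_dnms <- sites$truth_dnms

  vcf_paths <- setNames(file.path(dir, paste0(fam_ids, ".vcf")), fam_ids)
  for (fi in seq_along(fam_ids)) {
    calls <- simulate_family_calls(scenario, sites, fi, families[[fi]])
    write_genotype_vcf(calls, vcf_paths[[fi]])
  }

  ann_path <- file.path(dir, "annotation.tsv")
  write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")

  ped_path <- file.path(dir, "pedigree.ped")
  write_pedigree(families, ped_path)

  depth <- write_depth_tables(scenario, families, dir)

  gi_path <- file.path(dir, "gene_intervals.tsv")
  write.table(gene_interval_table(scenario), gi_path, sep = "\t",
              quote = FALSE, row.names = FALSE)

  truth <- list(
    dnms = truth_dnms,
    cnvs = lapply(scenario$cnv_plans, function(p) {
      fam <- families[[p$family]]
      c(unclass(p)[c("chrom", "start", "end", "copy_number")],
        list(family_id = fam$family_id, carrier_role = p$carrier,
             carrier = family_members(fam)[[role_key(p$carrier)]],
             overlapping_genes = p$overlapping_genes))
    }))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  list(dir = dir, vcf = vcf_paths, pedigree = ped_path, annotation = ann_path,
       depth = depth, gene_intervals = gi_path, truth_json = truth_path,
       truth = truth, families = families)
}

role_key <- function(role) {
  c(proband_twin = "proband", cotwin = "cotwin",
    father = "father", mother = "mother")[[role]]
}

# Cohort-wide variant-site catalog: background germline sites (positions
# below 6e7) plus planted DNM sites (shared or family-private, positions
# above 7e7 so they never collide), with one annotation row per unique site
# and a (family, pos) map recording which family carries which planted site.
build_site_catalog <- function(sc, fam_ids) {
  n <- sc$n_sites
  chroms <- as.character(1:22)
  chrom <- sort(rep(chroms, length.out = n))
  pos <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(6e7L, length(i)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  gene <- sprintf("GENE%04d", ceiling(seq_len(n) / 20))
  class_p <- c(missense = 0.30, synonymous = 0.30, intronic = 0.25,
               `splice-boundary` = 0.04, stopgain = 0.03,
               frameshift = 0.05, `nonframeshift-indel` = 0.03)
  fclass <- if (n > 0)
    sample(names(class_p), n, replace = TRUE, prob = class_p) else character()
  maf_kind <- if (n > 0)
    sample(c("common", "rare", "absent"), n, replace = TRUE,
           prob = c(0.5, 0.45, 0.05)) else character()

  cols <- c("chrom", "pos", "ref", "alt", "gene", "functional_class",
            "maf_kind", "planted", "site_id")
  germline <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         gene = gene, functional_class = fclass,
                         maf_kind = maf_kind, planted = FALSE,
                         site_id = NA_character_,
                         stringsAsFactors = FALSE)

  planted <- planted_site_table(sc, fam_ids)        # one row per family x DNM
  uplanted <- planted[!duplicated(planted$pos), cols, drop = FALSE]
  sites <- rbind(germline[cols], uplanted)
  sites <- indelize(sites)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  m <- match(planted$pos, sites$pos)   # planted positions are cohort-unique
  truth_dnms <- data.frame(family_id = fam_ids[planted$family_idx],
                           chrom = sites$chrom[m], pos = sites$pos[m],
                           ref = sites$ref[m], alt = sites$alt[m],
                           gene = sites$gene[m],
                           functional_class = sites$functional_class[m],
                           maf_kind = sites$maf_kind[m],
                           site_id = planted$site_id,
                           stringsAsFactors = FALSE)

  list(sites = sites, annotation = annotate_sites(sites),
       truth_dnms = truth_dnms,
       planted_map = data.frame(family_idx = planted$family_idx,
                                pos = planted$pos))
}

planted_site_table <- function(sc, fam_ids) {
  k <- sc$n_planted_dnm_per_proband
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), gene = character(),
                      functional_class = character(), maf_kind = character(),
                      planted = logical(), family_idx = integer(),
                      site_id = character(), stringsAsFactors = FALSE)
  if (k == 0L || sc$n_families == 0L) return(empty)
  spec <- sc$planted_dnm_spec[rep_len(seq_len(nrow(sc$planted_dnm_spec)), k), ,
                              drop = FALSE]
  # shared sites get one coordinate for the whole cohort
  shared_ids <- unique(spec$site_id[!is.na(spec$site_id)])
  shared_pos <- setNames(70000000L + seq_along(shared_ids) * 1000L, shared_ids)
  shared_allele <- lapply(setNames(shared_ids, shared_ids), function(id)
    sample(c("A", "C", "G", "T"), 2L))
  rows <- list()
  counter <- 0L
  for (fi in seq_len(sc$n_families)) {
    for (j in seq_len(k)) {
      sid <- spec$site_id[j]
      if (!is.na(sid)) {
        p <- shared_pos[[sid]]
        al <- shared_allele[[sid]]
        g <- if (is.na(spec$gene[j])) paste0("DNMG_", sid) else spec$gene[j]
      } else {
        counter <- counter + 1L
        p <- 80000000L + counter * 1000L
        al <- sample(c("A", "C", "G", "T"), 2L)
        g <- if (is.na(spec$gene[j])) sprintf("DNMG_%s_%d", fam_ids[fi], j) else spec$gene[j]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "1", pos = p, ref = al[1], alt = al[2], gene = g,
        functional_class = spec$functional_class[j], maf_kind = spec$maf_kind[j],
        planted = TRUE, family_idx = fi, site_id = sid,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Give indel-class sites indel alleles (simple anchored ins/del). The extra
# bases and the ins/del choice are derived from the position, not the RNG,
# so a site shared across families always gets identical alleles.
indelize <- function(sites) {
  bases <- c("A", "C", "G", "T")
  is_indel <- sites$functional_class %in% c("frameshift", "nonframeshift-indel")
  for (i in which(is_indel)) {
    anchor <- sites$ref[i]
    extra_n <- if (sites$functional_class[i] == "frameshift") 1L else 3L
    p <- sites$pos[i]
    extra <- paste(bases[(p + seq_len(extra_n)) %% 4L + 1L], collapse = "")
    if (p %% 2L == 0L) {                        # deletion
      sites$ref[i] <- paste0(anchor, extra)
      sites$alt[i] <- anchor
    } else {                                    # insertion
      sites$alt[i] <- paste0(anchor, extra)
      sites$ref[i] <- anchor
    }
  }
  sites
}

annotate_sites <- function(sites) {
  n <- nrow(sites)
  # vectorized equivalent of generate_maf_profile() over all sites
  maf <- matrix(NA_real_, n, 5L, dimnames = list(NULL, maf_columns()))
  i_rare <- which(sites$maf_kind == "rare")
  maf[i_rare, ] <- round(matrix(runif(length(i_rare) * 5L, 1e-4, 0.08),
                                ncol = 5L), 5)
  i_common <- which(sites$maf_kind == "common")
  maf[i_common, ] <- round(matrix(runif(length(i_common) * 5L, 0.01, 0.45),
                                  ncol = 5L), 5)
  maf[cbind(i_common, sample.int(5L, length(i_common), replace = TRUE))] <-
    round(runif(length(i_common), 0.12, 0.6), 5)
  hgvs_c <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                   sprintf("c.%d%s>%s", sites$pos %% 3000L + 1L, sites$ref, sites$alt),
            ifelse(nchar(sites$ref) > nchar(sites$alt),
                   sprintf("c.%ddel%s", sites$pos %% 3000L + 1L, substr(sites$ref, 2L, nchar(sites$ref))),
                   sprintf("c.%dins%s", sites$pos %% 3000L + 1L, substr(sites$alt, 2L, nchar(sites$alt)))))
  hgvs_p <- ifelse(sites$functional_class %in% c("intronic", "splice-boundary"),
                   NA_character_, sprintf("p.X%dY", sites$pos %% 1000L + 1L))
  pred <- function(levels_) sample(levels_, n, replace = TRUE)
  cbind(sites[c("chrom", "pos", "ref", "alt", "gene", "functional_class")],
        data.frame(hgvs_c = hgvs_c, hgvs_p = hgvs_p, stringsAsFactors = FALSE),
        as.data.frame(maf),
        data.frame(sift = pred(c("D", "T")),
                   polyphen2 = pred(c("D", "P", "B")),
                   mutation_taster = pred(c("D", "N")),
                   cadd = round(runif(n, 0, 40), 2),
                   stringsAsFactors = FALSE))
}

# Draw the four members' genotype vectors for one family and attach depths.
simulate_family_calls <- function(sc, sites_obj, fam_idx, family) {
  sites <- sites_obj$sites
  n <- nrow(sites)
  map <- sites_obj$planted_map
  own_planted <- sites$pos %in% map$pos[map$family_idx == fam_idx] & sites$planted
  bg <- !sites$planted

  gdraw <- function() {
    h <- sc$germline_het_rate
    sample(0:2, n, replace = TRUE, prob = c(1 - h - h / 4, h, h / 4))
  }
  father <- ifelse(bg, gdraw(), 0L)
  mother <- ifelse(bg, gdraw(), 0L)
  transmit <- function(g) ifelse(g == 2L, 1L,
                          ifelse(g == 1L, rbinom(n, 1L, 0.5), 0L))
  twin_germ <- transmit(father) + transmit(mother)
  proband <- twin_germ
  cotwin <- twin_germ

  # somatic mosaicism: perturb one twin's category at background sites
  flip <- bg & (runif(n) < sc$twin_discordance_rate)
  if (any(flip)) {
    which_twin <- runif(sum(flip)) < 0.5
    shift <- sample(1:2, sum(flip), replace = TRUE)
    newg <- (twin_germ[flip] + shift) %% 3L
    proband[flip][which_twin] <- newg[which_twin]
    cotwin[flip][!which_twin] <- newg[!which_twin]
  }
  proband[own_planted] <- 1L    # the post-twinning event itself

  members <- family_members(family)
  gmat <- cbind(proband = proband, cotwin = cotwin, father = father, mother = mother)
  calls <- vector("list", 4L)
  for (j in seq_len(4L)) {
    g <- gmat[, j]
    if (sc$depth_dispersion == 0) {
      dp <- rep(as.integer(round(sc$depth_mean)), n)
      ad <- ifelse(g == 2L, dp, ifelse(g == 1L, as.integer(round(dp / 2)), 0L))
    } else {
      dp <- pmax(1L, rnbinom(n, mu = sc$depth_mean, size = 1 / sc$depth_dispersion))
      ad <- ifelse(g == 2L, dp, ifelse(g == 1L, rbinom(n, dp, 0.5), 0L))
    }
    calls[[j]] <- data.frame(sample = unname(members[j]), chrom = sites$chrom,
                             pos = sites$pos, ref = sites$ref, alt = sites$alt,
                             gt = c("hom_ref", "het", "hom_alt")[g + 1L],
                             depth = as.integer(dp), alt_depth = as.integer(ad),
                             gq = 99L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

write_pedigree <- function(families, path) {
  rows <- lapply(families, function(f) {
    data.frame(family_id = f$family_id,
               individual_id = c(f$proband, f$cotwin, f$father, f$mother),
               father_id = c(f$father, f$father, "0", "0"),
               mother_id = c(f$mother, f$mother, "0", "0"),
               sex = c("0", "0", "1", "2"),
               phenotype = c("2", "1", "1", "1"),
               role = member_roles(),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

write_depth_tables <- function(sc, families, dir) {
  grid <- target_grid(sc$n_targets)
  depth_dir <- file.path(dir, "depth")
  if (!dir.exists(depth_dir)) dir.create(depth_dir)
  paths <- character(0)
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    members <- family_members(fam)
    for (role in member_roles()) {
      subject <- members[[role_key(role)]]
      if (sc$depth_dispersion == 0) {
        dp <- rep(round(sc$depth_mean), nrow(grid))
      } else {
        dp <- rnbinom(nrow(grid), mu = sc$depth_mean, size = 1 / sc$depth_dispersion)
      }
      for (p in sc$cnv_plans) {
        if (p$family == fi && p$carrier == role) {
          hit <- grid$chrom == p$chrom & grid$start <= p$end & grid$end >= p$start
          dp[hit] <- round(dp[hit] * p$copy_number / 2)
        }
      }
      d <- cbind(grid, depth = as.integer(dp))
      path <- file.path(depth_dir, paste0(subject, ".depth.tsv"))
      write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[subject] <- path
    }
  }
  paths
}

# Synthetic gene intervals for CNV-gene overlap: each planted CNV's genes at
# the planted interval, plus untouched filler genes.
gene_interval_table <- function(sc) {
  rows <- list()
  for (p in sc$cnv_plans) {
    for (g in p$overlapping_genes) {
      rows[[g]] <- data.frame(gene = g, chrom = p$chrom,
                              start = p$start, end = p$end,
                              stringsAsFactors = FALSE)
    }
  }
  grid <- target_grid(sc$n_targets)
  far <- max(grid$end) + 100000L
  fillers <- data.frame(gene = sprintf("CNVGENE_F%d", 1:3), chrom = "1",
                        start = far + (0:2) * 5000L,
                        end = far + (0:2) * 5000L + 2000L,
                        stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, unname(rows)), fillers)
  rownames(out) <- NULL
  out
}
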