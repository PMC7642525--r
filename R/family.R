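#' Define a quartet family
#'
#' The unit of segregation analysis: the affected twin (proband), the
#' unaffected co-twin, and the two parents. All four sample IDs must be
#' distinct.
#'
#' @param family_id Family identifier.
#' @param proband,cotwin,father,mother Sample IDs of the four members.
#' @return An object of class `quartet_family`.
#' @export
quartet_family <- function(family_id, proband, cotwin, father, mother) {
  ids <- c(proband = proband, cotwin = cotwin, father = father, mother = mother)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop_twinseg("all four member sample IDs must be non-empty")
  if (anyDuplicated(ids))
    stop_twinseg("family '%s': the four member sample IDs must be distinct", family_id)
  structure(list(family_id = as.character(family_id),
                 proband = proband, cotwin = cotwin,
                 father = father, mother = mother),
            class = "quartet_family")
}

#' @export
print.quartet_family <- function(x, ...) {
  cat(sprintf("quartet family %s: proband=%s cotwin=%s father=%s mother=%s\n",
              x$family_id, x$proband, x$cotwin, x$father, x$mother))
  invisible(x)
}

family_members <- function(family) {
  c(proband = family$proband, cotwin = family$cotwin,
    father = family$father, mother = family$mother)
}

#' Read a pedigree file with twin roles
#'
#' PED-like tab-separated file with columns family_id, individual_id,
#' father_id, mother_id, sex, phenotype, role; `role` is one of
#' proband_twin, cotwin, father, mother.
#'
#' @param path Path to the pedigree file.
#' @return A list of [quartet_family()] objects, one per family, named by
#'   family ID; the raw table is attached as attribute `"table"`.
#' @export
read_pedigree <- function(path) {
  ped <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("family_id", "individual_id", "role")
  miss <- setdiff(need, names(ped))
  if (length(miss))
    stop_twinseg("pedigree file missing required column(s): %s",
                 paste(miss, collapse = ", "))
  bad <- setdiff(unique(ped$role), member_roles())
  if (length(bad))
    stop_twinseg("pedigree contains unknown role(s): %s", paste(bad, collapse = ", "))
  fams <- lapply(split(ped, ped$family_id), function(p) {
    pick <- function(role) {
      id <- p$individual_id[p$role == role]
      if (length(id) != 1L)
        stop_twinseg("family '%s': expected exactly one member with role '%s'",
                     p$family_id[1], role)
      id
    }
    quartet_family(p$family_id[1], pick("proband_twin"), pick("cotwin"),
                   pick("father"), pick("mother"))
  })
  structure(fams[order(names(fams))], table = ped)
}
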