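#' Upper-tail hypergeometric enrichment probability
#'
#' The enrichment statistic for a pathway holding `M` of the `N` universe
#' genes when `m` of the `n` candidate genes fall in it:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}}
#' i.e. the probability of observing at least `m` candidate genes in the
#' pathway under uniform sampling of `n` genes from `N`. Computed by direct
#' summation of the upper tail in log-space (terms
#' `exp(lchoose(M,i) + lchoose(N-M,n-i) - lchoose(N,n))`), which is
#' numerically safe for small tails where literal `1 - sum` would lose all
#' precision; binomial coefficients with impossible arguments contribute 0.
#'
#' Vectorized over all four arguments.
#'
#' @param M Genes in the pathway.
#' @param m Candidate genes in the pathway.
#' @param N Genes in the union of all pathways.
#' @param n Candidate genes within that union.
#' @return Probability in \[0, 1\]; exactly 1 when `m = 0`.
#' @export
hypergeom_tail <- function(M, m, N, n) {
  len <- max(length(M), length(m), length(N), length(n))
  M <- rep_len(as.numeric(M), len); m <- rep_len(as.numeric(m), len)
  N <- rep_len(as.numeric(N), len); n <- rep_len(as.numeric(n), len)
  bad <- is.na(M) | is.na(m) | is.na(N) | is.na(n) |
    m < 0 | M < 0 | n < 0 | N < 0 | m > M | m > n | M > N | n > N
  if (any(bad))
    stop_twinseg("hypergeom_tail: arguments must satisfy 0 <= m <= min(M, n), M <= N, n <= N")
  vapply(seq_len(len), function(j) {
    if (m[j] == 0) return(1)
    i <- seq(m[j], min(M[j], n[j]))
    p <- sum(exp(lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
                   lchoose(N[j], n[j])))
    min(max(p, 0), 1)
  }, numeric(1))
}

#' Pathway enrichment of candidate genes across families
#'
#' Two-step procedure. First the recurrence criterion: per family, a pathway
#' is "hit" when it contains at least one of that family's candidate genes;
#' only pathways hit in at least `min_recurrent_families` families are
#' tested. Second, each tested pathway is scored with [hypergeom_tail()]
#' on the pooled (union) candidate set, with Benjamini-Hochberg q-values
#' computed over the tested pathways only. A pathway is significant when
#' `P < p_threshold` and `q < q_threshold` (defaults 0.05 and 0.2).
#'
#' The gene universe `N` is the union of all pathway genes; candidate genes
#' outside every pathway are excluded from both `n` and the per-pathway
#' counts (their number is reported in attribute `"n_outside_universe"`).
#' Per-family P values for the tested pathways are attached as attribute
#' `"per_family"` for transparency.
#'
#' @param family_gene_sets Named list: family ID -> character vector of
#'   candidate gene symbols.
#' @param pathways Named list of gene sets, e.g. from [read_gmt()].
#' @param min_recurrent_families Recurrence criterion (default 2).
#' @param p_threshold,q_threshold Significance thresholds.
#' @return data.frame (`pathway`, `M`, `m`, `N`, `n`, `P`, `q`,
#'   `families_hit`, `n_families_hit`, `significant`), one row per tested
#'   pathway, sorted by `P`.
#' @export
enrich_families <- function(family_gene_sets, pathways,
                            min_recurrent_families = 2L,
                            p_threshold = 0.05, q_threshold = 0.2) {
  if (length(pathways) == 0L)
    stop_twinseg("enrich_families: empty pathway collection")
  universe <- unique(unlist(pathways, use.names = FALSE))
  N <- length(universe)
  pooled <- unique(unlist(family_gene_sets, use.names = FALSE))
  n_outside <- sum(!pooled %in% universe)
  pooled <- intersect(pooled, universe)
  n <- length(pooled)

  hit_mat <- vapply(family_gene_sets, function(genes)
    vapply(pathways, function(pw) any(genes %in% pw), logical(1)),
    logical(length(pathways)))
  hit_mat <- matrix(hit_mat, nrow = length(pathways),
                    dimnames = list(names(pathways), names(family_gene_sets)))
  n_hit <- rowSums(hit_mat)
  tested <- names(pathways)[n_hit >= min_recurrent_families]

  empty <- data.frame(pathway = character(), M = integer(), m = integer(),
                      N = integer(), n = integer(), P = numeric(),
                      q = numeric(), families_hit = character(),
                      n_families_hit = integer(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (length(tested) == 0L)
    return(structure(empty, per_family = NULL, n_outside_universe = n_outside))

  M <- vapply(pathways[tested], length, integer(1))
  m <- vapply(pathways[tested], function(pw) sum(pooled %in% pw), integer(1))
  P <- hypergeom_tail(M, m, N, n)
  q <- p.adjust(P, method = "BH")
  fams_hit <- vapply(tested, function(pw)
    paste(colnames(hit_mat)[hit_mat[pw, ]], collapse = ","), "")

  out <- data.frame(pathway = tested, M = M, m = m, N = N, n = n,
                    P = P, q = q, families_hit = fams_hit,
                    n_families_hit = n_hit[tested],
                    significant = P < p_threshold & q < q_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$P, out$pathway), , drop = FALSE]
  rownames(out) <- NULL

  per_family <- do.call(rbind, lapply(names(family_gene_sets), function(f) {
    cand <- intersect(unique(family_gene_sets[[f]]), universe)
    mf <- vapply(pathways[tested], function(pw) sum(cand %in% pw), integer(1))
    data.frame(family_id = f, pathway = tested, m = mf,
               n = length(cand),
               P = hypergeom_tail(M, mf, N, length(cand)),
               stringsAsFactors = FALSE)
  }))
  structure(out, per_family = per_family, n_outside_universe = n_outside)
}
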