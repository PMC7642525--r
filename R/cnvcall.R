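#' Build a within-family normal reference for CNV calling
#'
#' Copy number in the affected twin is judged against a reference built from
#' the healthy members of the same family (co-twin and parents), mirroring
#' the family-reference idea of read-depth CNV callers. Each member's depth
#' vector is first normalized to a common scale (median per-target depth =
#' 100), then the per-target median across members becomes the reference;
#' the per-target spread (MAD) is recorded and zero-median targets are
#' masked.
#'
#' @param profiles List of depth tables ([read_depth_table()]), one per
#'   healthy member, on identical target grids.
#' @return data.frame (`chrom`, `start`, `end`, `ref_depth`, `spread`,
#'   `masked`), class `cnv_reference`.
#' @export
build_family_reference <- function(profiles) {
  if (length(profiles) < 1L)
    stop_twinseg("build_family_reference: need at least one healthy member")
  grid <- profiles[[1]][, c("chrom", "start", "end")]
  for (i in seq_along(profiles)) {
    g <- profiles[[i]][, c("chrom", "start", "end")]
    if (nrow(g) != nrow(grid) || !isTRUE(all.equal(g, grid, check.attributes = FALSE))) {
      bad <- if (nrow(g) != nrow(grid)) 1L else
        which(g$chrom != grid$chrom | g$start != grid$start | g$end != grid$end)[1]
      stop_twinseg("build_family_reference: member %d target grid mismatch at row %d (%s:%s-%s vs %s:%s-%s)",
                   i, bad, g$chrom[bad], g$start[bad], g$end[bad],
                   grid$chrom[bad], grid$start[bad], grid$end[bad])
    }
  }
  normed <- vapply(profiles, function(p) normalize_depth(p$depth), numeric(nrow(grid)))
  normed <- matrix(normed, nrow = nrow(grid))
  ref_depth <- apply(normed, 1L, median)
  spread <- apply(normed, 1L, mad)
  out <- cbind(grid, data.frame(ref_depth = ref_depth, spread = spread,
                                masked = ref_depth == 0))
  structure(out, class = c("cnv_reference", "data.frame"))
}

# scale a depth vector so its median per-target depth is 100; invariant to
# multiplying all depths by a constant
normalize_depth <- function(depth, scale_to = 100) {
  md <- median(depth)
  if (md == 0) stop_twinseg("depth profile has zero median depth")
  depth / md * scale_to
}

#' Per-target log2 copy ratios of a test subject against a family reference
#'
#' Both tracks are on the normalized scale of [build_family_reference()];
#' the ratio at a target is `log2((test + c) / (reference + c))` with
#' pseudocount `c` stabilizing low-coverage targets. Masked (zero-median)
#' reference targets are excluded. 0 means diploid, about -1 a heterozygous
#' loss, about +0.585 a single-copy gain (3 copies).
#'
#' @param proband Depth table of the test subject (same grid as the
#'   reference).
#' @param reference A `cnv_reference` from [build_family_reference()].
#' @param pseudocount Stabilizing constant c (default 1 read).
#' @return data.frame (`chrom`, `start`, `end`, `log2_ratio`), class
#'   `cnv_ratio_track`.
#' @export
log2_ratios <- function(proband, reference, pseudocount = 1) {
  g <- proband[, c("chrom", "start", "end")]
  gr <- reference[, c("chrom", "start", "end")]
  if (nrow(g) != nrow(gr) || !isTRUE(all.equal(g, gr, check.attributes = FALSE)))
    stop_twinseg("log2_ratios: proband target grid does not match the reference grid")
  keep <- !reference$masked
  if (!any(keep))
    stop_twinseg("log2_ratios: all reference targets are masked")
  test <- normalize_depth(proband$depth)
  ratio <- log2((test[keep] + pseudocount) / (reference$ref_depth[keep] + pseudocount))
  out <- cbind(g[keep, , drop = FALSE], data.frame(log2_ratio = ratio))
  rownames(out) <- NULL
  structure(out, class = c("cnv_ratio_track", "data.frame"))
}

#' Segment a log2 ratio track and call gains and losses
#'
#' Transparent threshold-plus-merge segmentation: each target is classified
#' gain (ratio > `gain_threshold`), loss (ratio < `loss_threshold`) or
#' neutral; consecutive same-state targets on one chromosome are merged;
#' gain/loss segments spanning fewer than `min_targets` targets are
#' discarded (reverted to neutral). Targets are canonicalized to
#' (chrom, start) order first, so input order does not matter.
#'
#' @param track A `cnv_ratio_track` from [log2_ratios()].
#' @param min_targets Minimum targets per reported segment (default 3).
#' @param gain_threshold,loss_threshold Log2-ratio thresholds (defaults
#'   +0.3 / -0.3; must satisfy loss < 0 < gain).
#' @param subject Optional subject ID stamped onto the segments.
#' @return data.frame of called segments (`subject`, `chrom`, `start`,
#'   `end`, `n_targets`, `mean_log2_ratio`, `call`); zero rows when the
#'   track is flat.
#' @export
segment_and_call <- function(track, min_targets = 3L, gain_threshold = 0.3,
                             loss_threshold = -0.3, subject = NA_character_) {
  if (!(loss_threshold < 0 && 0 < gain_threshold))
    stop_twinseg("segment_and_call: thresholds must satisfy loss < 0 < gain")
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  state <- ifelse(track$log2_ratio > gain_threshold, "gain",
           ifelse(track$log2_ratio < loss_threshold, "loss", "neutral"))
  run_id <- cumsum(c(TRUE, state[-1] != state[-length(state)] |
                       track$chrom[-1] != track$chrom[-nrow(track)]))
  segs <- lapply(split(seq_len(nrow(track)), run_id), function(i) {
    st <- state[i[1]]
    if (st == "neutral" || length(i) < min_targets) return(NULL)
    data.frame(subject = subject, chrom = track$chrom[i[1]],
               start = track$start[i[1]], end = track$end[i[length(i)]],
               n_targets = length(i),
               mean_log2_ratio = mean(track$log2_ratio[i]),
               call = st, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(subject = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_targets = integer(), mean_log2_ratio = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Family CNV screen: reference, ratios, segmentation in one call
#'
#' Builds the within-family reference from the healthy members, computes the
#' affected twin's log2 ratio track and calls segments. Sex chromosomes are
#' processed like autosomes but flagged with a message, since quartets mix
#' sexes and no ploidy correction is applied.
#'
#' @param proband_profile Depth table of the affected twin.
#' @param healthy_profiles List of depth tables of the healthy members.
#' @param subject Subject ID for the output segments.
#' @param min_targets,gain_threshold,loss_threshold,pseudocount Passed to
#'   [segment_and_call()] / [log2_ratios()].
#' @return Called segments as in [segment_and_call()]; the ratio track is in
#'   attribute `"track"`.
#' @export
call_family_cnvs <- function(proband_profile, healthy_profiles,
                             subject = NA_character_, min_targets = 3L,
                             gain_threshold = 0.3, loss_threshold = -0.3,
                             pseudocount = 1) {
  if (any(proband_profile$chrom %in% c("X", "Y")))
    message("call_family_cnvs: sex-chromosome targets processed without ploidy correction")
  ref <- build_family_reference(healthy_profiles)
  track <- log2_ratios(proband_profile, ref, pseudocount = pseudocount)
  segs <- segment_and_call(track, min_targets = min_targets,
                           gain_threshold = gain_threshold,
                           loss_threshold = loss_threshold, subject = subject)
  attr(segs, "track") <- track
  segs
}
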