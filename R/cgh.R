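# Array-CGH probe simulation and segmentation.
#
# Probe log2 ratios of test vs reference DNA sit near 0 for two copies,
# log2(1/2) = -1 for one copy and log2(3/2) ~ 0.585 for three.  The
# proprietary aberration statistic of the commercial analysis software is
# replaced by a documented threshold-and-merge segmentation; the operative
# consecutive-probe filter (at least ten probes inside densely covered
# genes, five elsewhere) is applied as stated.

#' Simulate an aCGH probe track
#'
#' Evenly spaced probes across a region; each probe's expected log2 ratio
#' is `log2(cn/2)` for the copy-number segment containing it (background
#' copy number 2 elsewhere) plus Gaussian noise.
#'
#' @param region_length Length of the tiled region in bp.
#' @param segments `data.frame` with columns `start`, `end`, `cn`
#'   (copy number in 1..3) for aberrant segments; may be empty.
#' @param probe_spacing Distance between adjacent probes in bp.
#' @param noise_sd Gaussian noise SD on log2 ratios.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `probe`, `position`, `log2`.
#' @export
simulate_cgh <- function(region_length, segments = NULL, probe_spacing = 100L,
                         noise_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- seq.int(from = as.integer(probe_spacing %/% 2L),
                 to = as.integer(region_length), by = as.integer(probe_spacing))
  cn <- rep(2, length(pos))
  if (!is.null(segments) && nrow(segments) > 0L) {
    if (any(segments$cn < 1 | segments$cn > 3)) {
      stop("segment copy numbers must be in 1..3")
    }
    for (i in seq_len(nrow(segments))) {
      inside <- pos >= segments$start[i] & pos <= segments$end[i]
      cn[inside] <- segments$cn[i]
    }
  }
  lr <- log2(cn / 2)
  if (noise_sd > 0) lr <- lr + stats::rnorm(length(pos), 0, noise_sd)
  data.frame(probe = sprintf("p%05d", seq_along(pos)), position = pos,
             log2 = lr, stringsAsFactors = FALSE)
}

#' Segment aCGH probes into copy-number aberrations
#'
#' Simplified segmentation: probes whose |log2| exceeds `z_threshold` times
#' a robust background SD (estimated from first differences of adjacent
#' probes) are flagged; consecutive flagged probes of the same sign are
#' merged, bridging up to `gap_tolerance` unflagged probes; segments with
#' fewer than `min_probes_gene` flagged probes inside `gene_regions` (or
#' `min_probes_genome` elsewhere) are discarded.  Segment coordinates are
#' the positions of the first and last flagged probe.
#'
#' @param probes `data.frame` with `position` and `log2`, sorted by
#'   position (unsorted input is an error).
#' @param gene_regions Optional `data.frame` with `start`, `end` marking
#'   densely covered gene regions subject to the stricter probe minimum.
#' @param z_threshold Flagging threshold in background-SD units.
#' @param min_probes_gene Minimum consecutive probes for segments
#'   overlapping a gene region (default 10).
#' @param min_probes_genome Minimum elsewhere (default 5).
#' @param gap_tolerance Unflagged probes bridged when merging a run.
#' @return A `data.frame` of segments: `start`, `end`, `n_probes`,
#'   `mean_log2`, `state` (`"loss"`/`"gain"`), `cn_estimate`, `iscn`.
#' @export
segment_cgh <- function(probes, gene_regions = NULL, z_threshold = 4,
                        min_probes_gene = 10L, min_probes_genome = 5L,
                        gap_tolerance = 2L) {
  if (is.unsorted(probes$position, strictly = FALSE)) {
    stop("probes must be sorted by coordinate")
  }
  x <- probes$log2
  # noise SD from first differences of adjacent probes: robust both to
  # outliers and to the copy-number segments themselves (which only
  # contribute two boundary differences each)
  bg_sd <- if (length(x) >= 2L) stats::mad(diff(x)) / sqrt(2) else 0
  thr <- z_threshold * bg_sd
  sgn <- ifelse(abs(x) > thr, sign(x), 0)
  empty <- data.frame(start = integer(), end = integer(),
                      n_probes = integer(), mean_log2 = numeric(),
                      state = character(), cn_estimate = integer(),
                      iscn = character(), stringsAsFactors = FALSE)
  if (all(sgn == 0)) return(empty)
  flagged <- which(sgn != 0)
  # merge flagged runs of the same sign across gaps of <= gap_tolerance
  runs <- list()
  cur_start <- flagged[1L]; cur_end <- flagged[1L]; cur_sign <- sgn[flagged[1L]]
  for (i in flagged[-1L]) {
    if (sgn[i] == cur_sign && i - cur_end - 1L <= gap_tolerance) {
      cur_end <- i
    } else {
      runs[[length(runs) + 1L]] <- c(cur_start, cur_end, cur_sign)
      cur_start <- i; cur_end <- i; cur_sign <- sgn[i]
    }
  }
  runs[[length(runs) + 1L]] <- c(cur_start, cur_end, cur_sign)
  out <- empty
  for (r in runs) {
    i1 <- r[1L]; i2 <- r[2L]
    # the consecutive-probe filter counts aberrant probes, so a bridged
    # gap (or a lone outlier attached across one) cannot rescue a segment
    n_pr <- sum(sgn[i1:i2] == r[3L])
    seg_start <- probes$position[i1]; seg_end <- probes$position[i2]
    in_gene <- FALSE
    if (!is.null(gene_regions) && nrow(gene_regions) > 0L) {
      in_gene <- any(gene_regions$start <= seg_end &
                       gene_regions$end >= seg_start)
    }
    min_req <- if (in_gene) min_probes_gene else min_probes_genome
    if (n_pr < min_req) next
    m <- mean(probes$log2[i1:i2])
    cn_est <- max(0L, as.integer(round(2 * 2^m)))
    out <- rbind(out, data.frame(
      start = seg_start, end = seg_end, n_probes = n_pr, mean_log2 = m,
      state = if (r[3L] > 0) "gain" else "loss",
      cn_estimate = cn_est,
      iscn = iscn_string(seg_start, seg_end, cn_est, band = "locus"),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
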