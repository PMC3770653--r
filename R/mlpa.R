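# MLPA dosage-quotient screening.
#
# MLPA reports one amplification-peak area per probe; normalized dosage
# ratios of ~0.5 / 1.0 / 1.5 indicate one, two or three copies of the
# probed exon.  Samples with a dosage value below 0.7 or above 1.2 are
# confirmed in a second independent reaction before an aberration is
# reported.

#' Simulate MLPA peak-area tables
#'
#' One test sample with the given per-exon copy numbers plus `n_controls`
#' diploid controls, each run in two independent reactions.  Per-probe peak
#' area = probe efficiency x (copy number / 2) x sample loading factor x
#' lognormal noise (`exp(rnorm(0, noise_sd))`).  A block of reference
#' probes (exon label `"REF"`, always two copies) emulates the kit's
#' control probes and carries the normalization.
#'
#' @param copy_number_by_exon Named integer vector (names = exon labels,
#'   values in 0..3) for the test sample.
#' @param n_controls Number of diploid control samples (>= 3).
#' @param noise_sd Lognormal scatter of individual peak areas.
#' @param seed Optional integer seed.
#' @param n_reference_probes Number of always-diploid reference probes.
#' @param sample_id Identifier of the test sample.
#' @return A long-format `data.frame` with columns `sample`, `reaction`
#'   (1 or 2), `probe`, `exon`, `area`.
#' @export
simulate_mlpa <- function(copy_number_by_exon, n_controls = 5L,
                          noise_sd = 0.05, seed = NULL,
                          n_reference_probes = 8L, sample_id = "S1") {
  if (!is.null(seed)) set.seed(seed)
  cn <- as.integer(copy_number_by_exon)
  if (any(is.na(cn)) || any(cn < 0L) || any(cn > 3L)) {
    stop("copy numbers must be integers in {0,1,2,3}")
  }
  if (n_controls < 3L) stop("need at least 3 control samples in a batch")
  exons <- names(copy_number_by_exon)
  if (is.null(exons)) exons <- sprintf("E%d", seq_along(cn))
  probes <- c(sprintf("P_%s", exons), sprintf("REF%02d", seq_len(n_reference_probes)))
  exon_of <- c(exons, rep("REF", n_reference_probes))
  cn_test <- c(cn, rep(2L, n_reference_probes))
  efficiency <- stats::rlnorm(length(probes), meanlog = log(1000), sdlog = 0.3)
  samples <- c(sample_id, sprintf("C%02d", seq_len(n_controls)))
  rows <- list()
  for (s in seq_along(samples)) {
    cn_s <- if (s == 1L) cn_test else rep(2L, length(probes))
    for (r in 1:2) {
      loading <- stats::rlnorm(1L, meanlog = 0, sdlog = 0.2)
      noise <- if (noise_sd > 0) exp(stats::rnorm(length(probes), 0, noise_sd)) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples[s], reaction = r, probe = probes, exon = exon_of,
        area = efficiency * (cn_s / 2) * loading * noise,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Normalize MLPA peak areas into dosage ratios
#'
#' Within each reaction, every sample's peak areas are first divided by the
#' sample's summed reference-probe area (or the summed area over all probes
#' when no probes carry the exon label `"REF"`), then each probe's relative
#' value is divided by the median of that quantity across the batch
#' samples.  The batch median makes the reference robust to a single
#' aberrant sample, but a batch in which *all* samples carry the same
#' deletion self-normalizes to 1.0 -- a known screening blind spot.
#'
#' @param peaks Long `data.frame` with columns `sample`, `reaction`,
#'   `probe`, `exon`, `area` (as from [simulate_mlpa()]).
#' @return A `data.frame` with columns `sample`, `reaction`, `probe`,
#'   `exon`, `ratio`.
#' @export
normalize_mlpa <- function(peaks) {
  stopifnot(all(c("sample", "reaction", "probe", "exon", "area") %in%
                  names(peaks)))
  if (length(unique(peaks$sample)) < 3L) {
    stop("batch normalization needs at least 3 samples")
  }
  zero <- tapply(peaks$area, peaks$probe, function(a) all(a == 0))
  if (any(zero)) {
    stop(sprintf("probe(s) with zero total area across the batch: %s",
                 paste(names(zero)[zero], collapse = ", ")))
  }
  out <- list()
  for (r in unique(peaks$reaction)) {
    sub <- peaks[peaks$reaction == r, , drop = FALSE]
    ref_probes <- unique(sub$probe[sub$exon == "REF"])
    rel <- do.call(rbind, lapply(split(sub, sub$sample), function(d) {
      denom <- if (length(ref_probes) > 0L) {
        sum(d$area[d$probe %in% ref_probes])
      } else sum(d$area)
      if (denom == 0) stop(sprintf("sample %s has zero total area", d$sample[1]))
      d$rel <- d$area / denom
      d
    }))
    med <- tapply(rel$rel, rel$probe, stats::median)
    rel$ratio <- rel$rel / med[rel$probe]
    out[[length(out) + 1L]] <-
      rel[, c("sample", "reaction", "probe", "exon", "ratio")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call per-exon dosage states from two independent reactions
#'
#' State thresholds follow the screening protocol: a ratio strictly below
#' `low` is a deletion, strictly above `high` a duplication (exact boundary
#' values call normal).  An aberration is reported (confirmed) only when
#' both reactions agree on the same non-normal state; reactions that
#' straddle a threshold yield a normal call flagged as discordant, and a
#' probe missing from one reaction is reported unconfirmed with a warning.
#'
#' @param profile_r1,profile_r2 Ratio `data.frame`s for one sample's two
#'   reactions (columns `probe`, `exon`, `ratio`); reference probes
#'   (`exon == "REF"`) are ignored.
#' @param low,high Dosage thresholds (defaults 0.7 and 1.2).
#' @return A `data.frame` with columns `exon`, `state`, `ratio_r1`,
#'   `ratio_r2`, `confirmed`, `discordant`.
#' @export
call_dosage <- function(profile_r1, profile_r2, low = 0.7, high = 1.2) {
  state_of <- function(x) {
    ifelse(is.na(x), NA_character_,
           ifelse(x < low, "deletion", ifelse(x > high, "duplication", "normal")))
  }
  p1 <- profile_r1[profile_r1$exon != "REF", , drop = FALSE]
  p2 <- profile_r2[profile_r2$exon != "REF", , drop = FALSE]
  m <- merge(p1[, c("probe", "exon", "ratio")],
             p2[, c("probe", "ratio")],
             by = "probe", all = TRUE, suffixes = c("_r1", "_r2"))
  # restore reaction-1 probe order
  m <- m[order(match(m$probe, p1$probe)), , drop = FALSE]
  if (any(is.na(m$exon))) {
    miss <- m$probe[is.na(m$exon)]
    m$exon[is.na(m$exon)] <-
      p2$exon[match(miss, p2$probe)]
  }
  s1 <- state_of(m$ratio_r1); s2 <- state_of(m$ratio_r2)
  missing <- is.na(s1) | is.na(s2)
  if (any(missing)) {
    warning(sprintf("probe(s) missing in one reaction: %s",
                    paste(m$probe[missing], collapse = ", ")))
  }
  agree_aberrant <- !missing & s1 == s2 & s1 != "normal"
  state <- ifelse(agree_aberrant, s1, "normal")
  discordant <- !missing & s1 != s2
  data.frame(exon = m$exon, state = state,
             ratio_r1 = m$ratio_r1, ratio_r2 = m$ratio_r2,
             confirmed = agree_aberrant,
             discordant = discordant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Segment exon-level dosage calls into candidate rearrangement intervals
#'
#' Maximal runs of consecutive confirmed same-state exons become candidate
#' large-rearrangement intervals; singleton runs are allowed.
#'
#' @param calls `data.frame` from [call_dosage()], ordered by exon (or
#'   reordered via `exon_order`).
#' @param exon_order Optional character vector giving gene exon order.
#' @return A `data.frame` with `state`, `exon_from`, `exon_to`, `n_exons`
#'   and a compact `label` such as `"E11-16 del"`.
#' @export
segment_exon_calls <- function(calls, exon_order = NULL) {
  if (!is.null(exon_order)) {
    calls <- calls[match(exon_order, calls$exon), , drop = FALSE]
    calls <- calls[!is.na(calls$exon), , drop = FALSE]
  }
  eff <- ifelse(calls$confirmed, calls$state, "normal")
  r <- rle(eff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "normal"
  if (!any(keep)) {
    return(data.frame(state = character(), exon_from = character(),
                      exon_to = character(), n_exons = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  from <- calls$exon[starts[keep]]
  to <- calls$exon[ends[keep]]
  lab <- ifelse(from == to,
                sprintf("%s %s", from, substr(r$values[keep], 1, 3)),
                sprintf("%s-%s %s", from, sub("^E", "", to),
                        substr(r$values[keep], 1, 3)))
  data.frame(state = r$values[keep], exon_from = from, exon_to = to,
             n_exons = r$lengths[keep], label = lab,
             stringsAsFactors = FALSE)
}
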