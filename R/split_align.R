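# Split-read breakpoint detection.
#
# A chimeric read is one whose two parts align to two discrete reference
# regions; reads accumulating at the same pair of regions define a
# rearrangement junction.  The aligner is a substitution-only seed-and-
# extend: the read prefix and, independently, the read suffix are anchored
# by a near-exact terminal seed and extended while the cumulative mismatch
# rate stays within budget.  For a candidate chimera the exact cut is then
# refined by minimizing total mismatches over all split positions, the
# chimeric and fully-contained interpretations are compared by mismatch
# count (a junction inside a diverged repeat pair is alignable end-to-end
# at elevated mismatch rate, so containment alone is not decisive), and
# the winning junction is leftmost-normalized against the reference so
# that reads supporting the same event report identical coordinates
# regardless of where inside a microhomology stretch their individual
# alignments end.

# Prepared reference context shared across reads: raw bytes plus a k-mer
# position index for seed lookup.
.ref_context <- function(ref_string, k) {
  n <- nchar(ref_string)
  if (n < k) stop("reference shorter than the seed length")
  kmers <- substring(ref_string, seq_len(n - k + 1L), k:n)
  idx <- list2env(split(seq_len(n - k + 1L), kmers), hash = TRUE)
  list(string = ref_string, raw = charToRaw(ref_string), n = n, k = k,
       index = idx)
}

# Positions (1-based) where `seed` occurs with at most `mm` mismatches.
# Exact hits are returned when present; single-mismatch variants are tried
# only when the exact lookup fails (a seed carrying a read error).
.seed_hits <- function(seed, ctx, mm) {
  hits <- ctx$index[[seed]]
  if (!is.null(hits)) return(hits)
  if (mm < 1L) return(integer(0))
  k <- ctx$k
  ch <- strsplit(seed, "")[[1]]
  out <- integer(0)
  for (p in seq_len(k)) {
    for (b in setdiff(DNA_BASES, ch[p])) {
      v <- ch; v[p] <- b
      h <- ctx$index[[paste(v, collapse = "")]]
      if (!is.null(h)) out <- c(out, h)
    }
  }
  sort(unique(out))
}

# Maximal prefix extension of read_raw against the reference starting at
# ref pos s; returns length after trimming trailing mismatches.
.extend_prefix <- function(read_raw, ref_raw, s, rate) {
  L <- length(read_raw); n <- length(ref_raw)
  len <- min(L, n - s + 1L)
  if (len < 1L) return(0L)
  cmp <- read_raw[seq_len(len)] != ref_raw[s:(s + len - 1L)]
  mism <- cumsum(cmp)
  ok <- which(mism <= rate * seq_len(len))
  if (length(ok) == 0L) return(0L)
  e <- max(ok)
  while (e > 0L && cmp[e]) e <- e - 1L
  e
}

# Maximal suffix (backward) extension ending at ref pos ref_end.
.extend_suffix <- function(read_raw, ref_raw, ref_end, rate) {
  L <- length(read_raw)
  len <- min(L, ref_end)
  if (len < 1L) return(0L)
  cmp <- read_raw[seq(L, L - len + 1L)] != ref_raw[seq(ref_end, ref_end - len + 1L)]
  mism <- cumsum(cmp)
  ok <- which(mism <= rate * seq_len(len))
  if (length(ok) == 0L) return(0L)
  f <- max(ok)
  while (f > 0L && cmp[f]) f <- f - 1L
  f
}

# Seed one read end and pick the best extension among hits.
.anchor <- function(read, read_raw, ctx, rate, side) {
  L <- length(read_raw); k <- ctx$k
  seed <- if (side == "prefix") substr(read, 1L, k) else
    substr(read, L - k + 1L, L)
  hits <- .seed_hits(seed, ctx, floor(k * rate))
  if (length(hits) == 0L) {
    return(list(pos = NA_integer_, ext = 0L, ambiguous = FALSE))
  }
  exts <- if (side == "prefix") {
    vapply(hits, function(s) .extend_prefix(read_raw, ctx$raw, s, rate), 0L)
  } else {
    vapply(hits, function(s)
      .extend_suffix(read_raw, ctx$raw, s + k - 1L, rate), 0L)
  }
  best <- max(exts)
  ties <- hits[exts == best]
  # distinct placements with equally long extensions cannot be assigned
  list(pos = ties[1L], ext = best, ambiguous = length(unique(ties)) > 1L)
}

# Core single-orientation alignment.  Returns a list whose `status` is one
# of "contained", "chimeric", "partial", "ambiguous", "unaligned".
.align_one_orientation <- function(read, ctx, min_anchor, rate,
                                   min_sv_distance, max_insertion) {
  read_raw <- charToRaw(read)
  L <- length(read_raw); n <- ctx$n
  ref_raw <- ctx$raw

  count_mism <- function(s) sum(read_raw != ref_raw[s:(s + L - 1L)])

  pre <- .anchor(read, read_raw, ctx, rate, "prefix")
  contained_pos <- NA_integer_; contained_mism <- NA_integer_
  if (!is.na(pre$pos) && !pre$ambiguous && pre$ext == L) {
    contained_pos <- pre$pos
    contained_mism <- count_mism(pre$pos)
    if (contained_mism <= 1L) {
      # essentially exact end-to-end placement: no chimeric interpretation
      # can beat it by the required margin
      return(list(status = "contained", p1 = contained_pos, e = L,
                  mism = contained_mism))
    }
  }
  suf <- .anchor(read, read_raw, ctx, rate, "suffix")
  if (is.na(contained_pos) && !is.na(suf$pos) && !suf$ambiguous &&
      suf$ext == L) {
    q_start <- suf$pos + ctx$k - L
    if (q_start >= 1L) {
      contained_pos <- q_start
      contained_mism <- count_mism(q_start)
    }
  }

  finish_contained <- function() {
    if (!is.na(contained_pos) && contained_mism <= rate * L) {
      list(status = "contained", p1 = contained_pos, e = L,
           mism = contained_mism)
    } else if (is.na(pre$pos) && is.na(suf$pos)) {
      list(status = "unaligned")
    } else if (pre$ambiguous || suf$ambiguous) {
      list(status = "ambiguous")
    } else {
      list(status = "partial")
    }
  }

  if (is.na(pre$pos) || is.na(suf$pos) || pre$ambiguous || suf$ambiguous ||
      pre$ext < min_anchor || suf$ext < min_anchor) {
    return(finish_contained())
  }

  p1 <- pre$pos; e <- pre$ext
  ref_end <- suf$pos + ctx$k - 1L
  f <- suf$ext
  s2 <- L - f + 1L
  dS <- ref_end - L                      # suffix diagonal: read i -> ref dS + i
  if (dS + 1L == p1) return(finish_contained())  # same diagonal

  # mismatch profiles along the two diagonals
  lenA <- min(L, n - p1 + 1L)
  cmpA <- read_raw[seq_len(lenA)] != ref_raw[p1:(p1 + lenA - 1L)]
  A <- c(0L, cumsum(cmpA))               # A[c+1] = mismatches in read[1..c]
  i0 <- max(1L, 1L - dS); i1 <- min(L, n - dS)
  cmpB <- read_raw[i0:i1] != ref_raw[(dS + i0):(dS + i1)]
  Brev <- c(rev(cumsum(rev(cmpB))), 0L)  # Brev[j] = mism in read[(i0+j-1)..i1]
  Bfrom <- function(i) Brev[max(i, i0) - i0 + 1L]

  # joint search over both cut points: the read is prefix(1..c1) + inserted
  # bases (possibly none) + suffix(c2..L), minimizing prefix-diagonal plus
  # suffix-diagonal mismatches with an affine insertion penalty (0.5 to
  # open, 0.5 per inserted base); ties prefer the shorter insertion, then
  # the leftmost cut.  Searching both cuts jointly (rather than trusting
  # where the independent extensions stopped) matters because an extension
  # can overrun through a short insertion or microhomology within its
  # mismatch budget, and the gap penalty stops junction-adjacent read
  # errors from being hidden inside a spurious "insertion".
  c1_hi <- min(lenA, L - min_anchor)
  if (min_anchor > c1_hi) return(finish_contained())
  c2_cap <- L - min_anchor + 1L
  Bvec <- rep(Inf, L + 1L)
  Bvec[i0:i1] <- Brev[seq_len(i1 - i0 + 1L)]
  gap_pen <- c(0, 0.5 + 0.5 * seq_len(max_insertion))
  best <- NULL
  for (c1 in min_anchor:c1_hi) {
    w2 <- (c1 + 1L):min(c1 + 1L + max_insertion, c2_cap)
    costs <- A[c1 + 1L] + Bvec[w2] + gap_pen[seq_along(w2)]
    k <- which.min(costs)                # first index: shortest insertion
    ins_len <- w2[k] - c1 - 1L
    if (is.null(best) || costs[k] < best$cost ||
        (costs[k] == best$cost && ins_len < best$ins_len)) {
      best <- list(cost = costs[k], c1 = c1, c2 = w2[k], ins_len = ins_len,
                   mism = A[c1 + 1L] + Bvec[w2[k]])
    }
  }
  if (is.null(best) || !is.finite(best$cost)) return(finish_contained())
  chim_mism <- best$mism
  bp5 <- p1 + best$c1 - 1L
  bp3 <- dS + best$c2
  ins <- if (best$c2 > best$c1 + 1L) {
    substr(read, best$c1 + 1L, best$c2 - 1L)
  } else ""
  if (chim_mism > rate * L) return(finish_contained())
  # model comparison: a contained placement within budget wins unless the
  # split interpretation removes at least two mismatches
  if (!is.na(contained_pos) && contained_mism <= rate * L &&
      chim_mism + 2L > contained_mism) {
    return(finish_contained())
  }

  jn <- normalize_junction(ctx$string, bp5, bp3, ins)
  if (jn$bp3 > jn$bp5) {
    if (jn$bp3 - jn$bp5 - 1L <= min_sv_distance && !nzchar(jn$ins)) {
      return(finish_contained())         # small gap: not an SV junction
    }
    type <- "deletion"
  } else {
    if (jn$bp5 - jn$bp3 + 1L <= min_sv_distance) {
      return(finish_contained())
    }
    type <- "duplication"
  }
  list(status = "chimeric", type = type,
       p1 = p1, e = e, q1 = dS + s2, f = f, s2 = s2,
       bp5 = jn$bp5, bp3 = jn$bp3, ins = jn$ins, cut_mism = chim_mism)
}

.align_both_orientations <- function(read, ctx, min_anchor, rate,
                                     min_sv_distance, max_insertion) {
  res <- .align_one_orientation(read, ctx, min_anchor, rate,
                                min_sv_distance, max_insertion)
  strand <- "+"; oriented <- read
  if (!res$status %in% c("contained", "chimeric")) {
    rc_read <- revcomp(read)
    rc <- .align_one_orientation(rc_read, ctx, min_anchor, rate,
                                 min_sv_distance, max_insertion)
    if (rc$status %in% c("contained", "chimeric") ||
        (res$status == "unaligned" && rc$status != "unaligned")) {
      res <- rc; strand <- "-"; oriented <- rc_read
    }
  }
  res$strand <- strand
  res$oriented <- oriented
  res
}

#' Split-align a single read against a reference locus
#'
#' Seed-and-extend from both read ends; the read is chimeric when the two
#' anchors place at least `min_anchor` bases each at reference loci
#' separated by more than `min_sv_distance` (deletion junction) or with the
#' suffix mapping upstream of the prefix (tandem-duplication junction), and
#' the split interpretation beats any full-length placement on mismatch
#' count.  Reads fully contained in the reference are non-chimeric.  Both
#' read orientations are tried; ambiguous anchors (several equally good
#' placements) reject the read rather than assigning it silently.
#'
#' @param read A DNA string (one read).
#' @param locus A `reference_locus`.
#' @param min_anchor Minimum anchored bases per segment (also the seed
#'   k-mer length).
#' @param max_mismatch_rate Mismatch-rate budget for extension.
#' @param min_sv_distance Minimum separation between the two reference
#'   segments for a junction call.
#' @param max_insertion Longest untemplated junction insertion considered.
#' @return A list with at least `status` (`"contained"`, `"chimeric"`,
#'   `"partial"`, `"ambiguous"` or `"unaligned"`), `strand`, and for
#'   chimeric reads the leftmost-normalized junction (`bp5`, `bp3`, `ins`,
#'   `type`), or `NULL` when the read cannot be placed at all.
#' @export
split_align <- function(read, locus, min_anchor = 20L,
                        max_mismatch_rate = 0.05, min_sv_distance = 100L,
                        max_insertion = 50L) {
  read <- toupper(as.character(read))
  if (nchar(read) < 2L * min_anchor) {
    stop("read length must be >= 2 * min_anchor")
  }
  ctx <- .ref_context(locus$sequence, as.integer(min_anchor))
  res <- .align_both_orientations(read, ctx, min_anchor, max_mismatch_rate,
                                  min_sv_distance, max_insertion)
  if (res$status == "unaligned") return(NULL)
  res
}

#' Split-align a set of reads
#'
#' Vectorized driver over [split_align()] sharing the reference k-mer index
#' across reads.
#'
#' @inheritParams split_align
#' @param reads Named character vector of reads.
#' @return A `data.frame` with one row per read: `read_id`, `status`,
#'   `is_chimeric`, `strand`, `type`, junction coordinates `bp5`/`bp3`
#'   (leftmost-normalized, locus-local), `ins`, segment bookkeeping columns
#'   and the plus-strand oriented read sequence (`oriented`).
#' @export
split_align_reads <- function(reads, locus, min_anchor = 20L,
                              max_mismatch_rate = 0.05,
                              min_sv_distance = 100L, max_insertion = 50L) {
  ctx <- .ref_context(locus$sequence, as.integer(min_anchor))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(reads))
  ids <- sub("\\s.*$", "", ids)
  nr <- length(reads)
  status <- character(nr); strand <- character(nr); type <- rep(NA_character_, nr)
  bp5 <- rep(NA_integer_, nr); bp3 <- rep(NA_integer_, nr)
  ins <- rep(NA_character_, nr)
  s1s <- rep(NA_integer_, nr); s1l <- rep(NA_integer_, nr)
  s2s <- rep(NA_integer_, nr); s2l <- rep(NA_integer_, nr)
  s2r <- rep(NA_integer_, nr)
  oriented <- character(nr)
  for (i in seq_len(nr)) {
    res <- .align_both_orientations(toupper(reads[[i]]), ctx, min_anchor,
                                    max_mismatch_rate, min_sv_distance,
                                    max_insertion)
    status[i] <- res$status
    strand[i] <- res$strand
    oriented[i] <- res$oriented
    if (res$status == "chimeric") {
      type[i] <- res$type; bp5[i] <- res$bp5; bp3[i] <- res$bp3
      ins[i] <- res$ins
      s1s[i] <- res$p1; s1l[i] <- res$e
      s2s[i] <- res$q1; s2l[i] <- res$f; s2r[i] <- res$s2
    } else if (res$status == "contained") {
      s1s[i] <- res$p1; s1l[i] <- res$e
    }
  }
  data.frame(read_id = ids, status = status,
             is_chimeric = status == "chimeric", strand = strand,
             type = type, bp5 = bp5, bp3 = bp3, ins = ins,
             seg1_ref_start = s1s, seg1_len = s1l,
             seg2_ref_start = s2s, seg2_len = s2l, seg2_read_start = s2r,
             oriented = oriented, stringsAsFactors = FALSE)
}

#' Cluster chimeric reads into breakpoint candidates
#'
#' Single-linkage clustering of the leftmost-normalized `(bp5, bp3)` pairs:
#' two chimeric reads are linked when both coordinates lie within `tol` bp.
#' Clusters with fewer than `min_support` reads are discarded; reads
#' accumulating in two discrete regions thus define one candidate junction
#' per distinct event, and no read contributes to more than one cluster.
#'
#' @param alignments `data.frame` from [split_align_reads()].
#' @param tol Linkage tolerance in bp.
#' @param min_support Minimum supporting reads per cluster.
#' @return A list of clusters; each is a list with `bp5`, `bp3` (medians of
#'   member junctions), `type`, `ins` (modal insertion), `support` and
#'   `members` (read ids).  Empty input gives an empty list.
#' @export
cluster_chimeras <- function(alignments, tol = 10L, min_support = 3L) {
  chim <- alignments[alignments$is_chimeric %in% TRUE, , drop = FALSE]
  if (nrow(chim) == 0L) return(list())
  n <- nrow(chim)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  ord <- order(chim$bp5, chim$bp3)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      i <- ord[a]
      for (b in (a + 1L):n) {
        j <- ord[b]
        if (chim$bp5[j] - chim$bp5[i] > tol) break
        if (chim$type[i] == chim$type[j] &&
            abs(chim$bp3[i] - chim$bp3[j]) <= tol) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    if (length(idx) < min_support) next
    ins_tab <- table(chim$ins[idx])
    out[[length(out) + 1L]] <- list(
      bp5 = as.integer(round(stats::median(chim$bp5[idx]))),
      bp3 = as.integer(round(stats::median(chim$bp3[idx]))),
      type = names(sort(table(chim$type[idx]), decreasing = TRUE))[1L],
      ins = names(sort(ins_tab, decreasing = TRUE))[1L],
      support = length(idx),
      members = chim$read_id[idx])
  }
  if (length(out) > 1L) {
    out <- out[order(vapply(out, `[[`, 0L, "bp5"))]
  }
  out
}

#' Summarize breakpoint clusters as a table
#' @param clusters List from [cluster_chimeras()].
#' @return A `data.frame` with one row per cluster.
#' @export
clusters_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(bp5 = integer(), bp3 = integer(), type = character(),
                      ins = character(), support = integer()))
  }
  data.frame(
    bp5 = vapply(clusters, `[[`, 0L, "bp5"),
    bp3 = vapply(clusters, `[[`, 0L, "bp3"),
    type = vapply(clusters, `[[`, "", "type"),
    ins = vapply(clusters, `[[`, "", "ins"),
    support = vapply(clusters, `[[`, 0L, "support"),
    stringsAsFactors = FALSE
  )
}

#' Reconstruct the junction consensus for a breakpoint cluster
#'
#' Member reads are stacked in the suffix-alignment diagonal frame (which
#' is invariant to where each read's own alignment happened to end inside a
#' microhomology stretch) and a majority-vote consensus is taken per
#' column, reported over about `flank` bp on each side of the join.
#'
#' @param cluster One cluster from [cluster_chimeras()].
#' @param alignments The alignment `data.frame` the cluster came from.
#' @param flank Half-width of the reported window in bp.
#' @return List with `consensus` (DNA string), `d_start` (the
#'   suffix-diagonal coordinate of its first base: for columns at or beyond
#'   the junction this is the reference coordinate) and `coverage`.
#' @export
reconstruct_junction <- function(cluster, alignments, flank = 150L) {
  rows <- alignments[alignments$read_id %in% cluster$members &
                       alignments$is_chimeric %in% TRUE, , drop = FALSE]
  if (nrow(rows) == 0L) stop("cluster has no member alignments")
  w1 <- cluster$bp3 - flank
  w2 <- cluster$bp3 + flank - 1L
  W <- w2 - w1 + 1L
  counts <- matrix(0L, nrow = 4L, ncol = W, dimnames = list(DNA_BASES, NULL))
  for (i in seq_len(nrow(rows))) {
    dS <- rows$seg2_ref_start[i] - rows$seg2_read_start[i]
    L <- nchar(rows$oriented[i])
    istart <- max(1L, w1 - dS); iend <- min(L, w2 - dS)
    if (istart > iend) next
    cols <- (istart:iend) + dS - w1 + 1L
    ch <- strsplit(substr(rows$oriented[i], istart, iend), "")[[1]]
    keep <- ch %in% DNA_BASES
    if (!all(keep)) { ch <- ch[keep]; cols <- cols[keep] }
    idx <- cbind(match(ch, DNA_BASES), cols)
    counts[idx] <- counts[idx] + 1L
  }
  cov <- colSums(counts)
  nz <- which(cov > 0L)
  if (length(nz) == 0L) stop("no read coverage across the junction window")
  lo <- min(nz); hi <- max(nz)
  counts <- counts[, lo:hi, drop = FALSE]
  cons <- DNA_BASES[apply(counts, 2L, which.max)]
  list(consensus = paste(cons, collapse = ""),
       d_start = w1 + lo - 1L,
       coverage = cov[lo:hi])
}
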