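# Junction annotation: exact breakpoints, microhomology, insertions,
# repeat overlap, mechanism classification, sizes and nomenclature.

# Longest common prefix length of ref[a..] and ref[b..] (raw compare).
.lcp_len <- function(ref_raw, a, b) {
  n <- length(ref_raw)
  len <- min(n - a + 1L, n - b + 1L)
  if (len < 1L) return(0L)
  neq <- ref_raw[a:(a + len - 1L)] != ref_raw[b:(b + len - 1L)]
  if (!any(neq)) len else which.max(neq) - 1L
}

# Longest common suffix length of ref[..a] and ref[..b].
.lcs_len <- function(ref_raw, a, b) {
  len <- min(a, b)
  if (len < 1L) return(0L)
  neq <- ref_raw[seq(a, a - len + 1L)] != ref_raw[seq(b, b - len + 1L)]
  if (!any(neq)) len else which.max(neq) - 1L
}

#' Microhomology at a deletion junction
#'
#' For a deletion joining `ref[..bp5]` to `ref[bp3..]` (retained-base
#' convention), the microhomology length is the maximal window over which
#' the junction can be shifted while reconstructing the identical derived
#' allele: the longest common suffix of the two sequences ending at the 5'
#' and 3' joins plus the longest common prefix of the sequences starting
#' after them.  Breakpoints are reported leftmost-normalized within the
#' ambiguity interval; the microhomology sequence is taken from the
#' reference.
#'
#' @param locus A `reference_locus` (or plain DNA string).
#' @param bp5 Last retained base before the join (1-based, local).
#' @param bp3 First retained base after the join.
#' @return List with `length`, `seq`, leftmost-normalized `bp5` and `bp3`,
#'   and `ambiguity` (the closed interval of admissible 5' cut positions).
#' @export
compute_microhomology <- function(locus, bp5, bp3) {
  seq <- if (inherits(locus, "reference_locus")) locus$sequence else locus
  n <- nchar(seq)
  bp5 <- as.integer(bp5); bp3 <- as.integer(bp3)
  if (bp5 < 1L || bp3 > n || bp5 >= bp3) {
    stop("require 1 <= bp5 < bp3 <= locus length")
  }
  ref_raw <- charToRaw(seq)
  k1 <- .lcs_len(ref_raw, bp5, bp3 - 1L)
  k1 <- min(k1, bp5 - 0L)               # cannot shift past the locus start
  k2 <- if (bp5 + 1L <= n && bp3 <= n) .lcp_len(ref_raw, bp5 + 1L, bp3) else 0L
  mh <- k1 + k2
  bp5_left <- bp5 - k1
  bp3_left <- bp3 - k1
  mh_seq <- if (mh > 0L) substr(seq, bp3_left, bp3_left + mh - 1L) else ""
  list(length = mh, seq = mh_seq, bp5 = bp5_left, bp3 = bp3_left,
       ambiguity = c(bp5_left, bp5_left + mh))
}

#' Size of a deletion (or any 1-based inclusive interval)
#'
#' @param start,end First and last affected base, 1-based inclusive.
#' @return `end - start + 1`.
#' @export
deletion_size <- function(start, end) {
  if (any(start > end)) stop("require start <= end")
  as.integer(end - start + 1)
}

#' Repeat element containing a coordinate
#'
#' @param coordinate A single 1-based position.
#' @param repeat_track A repeat track `data.frame` (sorted by start).
#' @return The one-row `data.frame` of the containing element (endpoints
#'   inclusive), or `NULL` when the coordinate lies in unique sequence.
#' @export
overlap_repeats <- function(coordinate, repeat_track) {
  if (nrow(repeat_track) == 0L) return(NULL)
  hit <- which(repeat_track$start <= coordinate & repeat_track$end >= coordinate)
  if (length(hit) == 0L) return(NULL)
  repeat_track[hit[1L], , drop = FALSE]
}

#' Classify the mutational mechanism of a junction
#'
#' NAHR (nonallelic homologous recombination) requires substantial junction
#' microhomology *and* both breakpoints inside same-orientation repeat
#' elements of the same superfamily (e.g. two Alu copies); the location of
#' a breakpoint at an Alu sequence alone is not a proxy for NAHR.  NHEJ is
#' called for junctions with little or no homology regardless of repeat
#' context.  Intermediate homology, or homology without qualifying repeats,
#' is left unclassified.
#'
#' @param microhomology_len Junction microhomology in bp.
#' @param repeat5,repeat3 One-row repeat-track `data.frame`s (or `NULL`)
#'   for the elements containing the 5' and 3' breakpoints.
#' @param min_homology Minimum microhomology for NAHR (default 10 bp; the
#'   NAHR junctions motivating the default carry 15-48 bp).
#' @param short_homology_cap Junctions with less homology than this are
#'   NHEJ (default 5 bp).
#' @return `"NAHR"`, `"NHEJ"` or `"unclassified"`.
#' @export
classify_mechanism <- function(microhomology_len, repeat5 = NULL,
                               repeat3 = NULL, min_homology = 10L,
                               short_homology_cap = 5L) {
  mh <- as.integer(microhomology_len)
  if (is.na(mh)) mh <- 0L
  reps_qualify <- !is.null(repeat5) && !is.null(repeat3) &&
    nrow(repeat5) == 1L && nrow(repeat3) == 1L &&
    repeat_superfamily(repeat5$family) == repeat_superfamily(repeat3$family) &&
    repeat5$strand == repeat3$strand
  if (mh >= min_homology && reps_qualify) return("NAHR")
  if (mh < short_homology_cap) return("NHEJ")
  "unclassified"
}

# Shorten the second coordinate of a pos1_pos2 pair by dropping the digits
# it shares with pos1 (keeping at least two), e.g. 47694485/47694486 -> "86".
.short_pos <- function(p1, p2) {
  s1 <- as.character(p1); s2 <- as.character(p2)
  if (nchar(s1) != nchar(s2)) return(s2)
  ch1 <- strsplit(s1, "")[[1]]; ch2 <- strsplit(s2, "")[[1]]
  d <- which(ch1 != ch2)
  if (length(d) == 0L) return(s2)
  start <- min(d[1L], nchar(s2) - 1L)
  substr(s2, start, nchar(s2))
}

#' Format deletion/duplication nomenclature
#'
#' Returns both the compact dialect used in clinical reports of this kind
#' (deletion: `g.{start}-{end}del{size}`; duplication-with-insertion: a
#' bracketed allele describing the junction insertion and the inserted
#' head-to-tail copy) and a standard HGVS-style genomic description.
#'
#' @param event_type `"deletion"` or `"duplication"`.
#' @param start,end First and last affected base (genomic, 1-based
#'   inclusive).
#' @param inserted_seq Untemplated junction insertion (duplications).
#' @param ref_id Sequence identifier used for the inserted copy in the
#'   duplication allele string (e.g. an Ensembl gene id).
#' @return List with `paper_style` and `hgvs` strings.
#' @export
format_nomenclature <- function(event_type = c("deletion", "duplication"),
                                start, end, inserted_seq = "",
                                ref_id = "locus") {
  event_type <- match.arg(event_type)
  if (is.null(start) || is.null(end) || any(is.na(c(start, end)))) {
    stop(paste("breakpoints unresolved: use bounded MLPA-style notation",
               "(e.g. \"c.212-?_366+?del\") instead of genomic coordinates"))
  }
  start <- as.numeric(start); end <- as.numeric(end)
  size <- deletion_size(start, end)
  if (event_type == "deletion") {
    paper <- sprintf("g.%d-%ddel%d", start, end, size)
    hgvs <- if (start == end) sprintf("g.%ddel", start) else
      sprintf("g.%d_%ddel", start, end)
  } else {
    p <- end                              # insertion point: after the 3' copy end
    p2s <- .short_pos(p, p + 1)
    if (nzchar(inserted_seq)) {
      paper <- sprintf("g.[%d_%sins%s;%d_%sins%s:g.%d_%d]",
                       p, p2s, inserted_seq, p, p2s, ref_id, start, end)
      hgvs <- sprintf("g.[%d_%dins%s;%d_%ddup]",
                      p, p + 1, inserted_seq, start, end)
    } else {
      paper <- sprintf("g.[%d_%sins%s:g.%d_%d]", p, p2s, ref_id, start, end)
      hgvs <- sprintf("g.%d_%ddup", start, end)
    }
  }
  list(paper_style = paper, hgvs = hgvs)
}

#' ISCN-style copy-number segment string
#' @param start,end Genomic coordinates of the segment.
#' @param n Copy number.
#' @param band Cytogenetic band label.
#' @return e.g. `"arr 2p21 (47705272-47705637)x3"`.
#' @export
iscn_string <- function(start, end, n, band = "2p21") {
  sprintf("arr %s (%d-%d)x%d", band, start, end, n)
}

#' Repeat content of a locus
#'
#' @param repeat_track Repeat track `data.frame`.
#' @param locus A `reference_locus` (or an integer locus length).
#' @return List with `masked_fraction` (union of element bases over locus
#'   length; overlapping elements counted once) and `counts`, a named
#'   integer vector of element counts per repeat class.
#' @export
repeat_content <- function(repeat_track, locus) {
  len <- if (inherits(locus, "reference_locus")) locus_length(locus) else
    as.integer(locus)
  classes <- c("SINE", "LINE", "LTR", "DNA")
  counts <- stats::setNames(integer(length(classes)), classes)
  if (nrow(repeat_track) > 0L) {
    tb <- table(factor(repeat_track$class, levels = classes))
    counts[names(tb)] <- as.integer(tb)
    ir <- IRanges::reduce(IRanges::IRanges(repeat_track$start,
                                           repeat_track$end))
    masked <- sum(IRanges::width(ir))
  } else {
    masked <- 0L
  }
  list(masked_fraction = masked / len, counts = counts)
}

#' Resolve the exact junction from a cluster consensus
#'
#' The error-corrected junction consensus is re-anchored on the reference
#' with *exact* matching: the maximal exact extension of its start gives
#' the rightmost admissible 5' breakpoint and the maximal exact backward
#' extension of its tail the leftmost admissible 3' breakpoint.  Their
#' overlap is the junction microhomology; a gap between them is an
#' untemplated insertion.  The reported junction is leftmost-normalized.
#'
#' @param locus A `reference_locus`.
#' @param junction List from [reconstruct_junction()] (`consensus`,
#'   `d_start`).
#' @param min_tail Minimum exactly matching consensus tail/head required.
#' @return List with `bp5`, `bp3` (retained-base convention, leftmost-
#'   normalized), `microhomology_len`, `microhomology_seq`,
#'   `inserted_seq`, `ambiguity` and `event_type`.
#' @export
resolve_junction <- function(locus, junction, min_tail = 20L) {
  ref <- locus$sequence
  ref_raw <- charToRaw(ref)
  n <- length(ref_raw)
  C <- junction$consensus
  C_raw <- charToRaw(C)
  LC <- length(C_raw)
  d_start <- as.integer(junction$d_start)

  # leftmost admissible 3' breakpoint: maximal exactly matching tail along
  # the suffix diagonal (consensus position k <-> ref position d_start+k-1)
  kmin <- max(1L, 2L - d_start)
  kmax <- min(LC, n - d_start + 1L)
  if (kmax < kmin) stop("consensus window lies outside the reference")
  cmp <- C_raw[kmin:kmax] != ref_raw[(d_start + kmin - 1L):(d_start + kmax - 1L)]
  last_mm <- if (any(cmp)) max(which(cmp)) + kmin - 1L else kmin - 1L
  t <- last_mm + 1L                      # consensus index of first suffix base
  if (kmax - t + 1L < min_tail) stop("consensus tail anchors < min_tail bases")
  B3min <- d_start + t - 1L

  # anchor the consensus head on the reference and extend exactly
  head_len <- min(25L, t - 1L)
  if (head_len < 15L) stop("consensus head too short to anchor")
  hits <- Biostrings::start(
    Biostrings::matchPattern(substr(C, 1L, head_len),
                             Biostrings::DNAString(ref)))
  if (length(hits) == 0L) stop("consensus head does not match the reference")
  exts <- vapply(hits, function(a) .lcp_raw(C_raw, ref_raw, a), 0L)
  a <- hits[which.max(exts)]
  j <- max(exts)
  B5max <- a + j - 1L

  if (t > j + 1L) {
    ins <- substr(C, j + 1L, t - 1L)
    jn <- normalize_junction(ref, B5max, B3min, ins)
    list(bp5 = jn$bp5, bp3 = jn$bp3, microhomology_len = 0L,
         microhomology_seq = "", inserted_seq = jn$ins,
         ambiguity = c(jn$bp5, jn$bp5),
         event_type = if (jn$bp3 > jn$bp5) "deletion" else "duplication")
  } else {
    h <- j - t + 1L
    bp5 <- B5max - h
    bp3 <- B3min
    if (bp3 > bp5) {
      mh <- compute_microhomology(locus, bp5, bp3)
      list(bp5 = mh$bp5, bp3 = mh$bp3, microhomology_len = mh$length,
           microhomology_seq = mh$seq, inserted_seq = "",
           ambiguity = mh$ambiguity, event_type = "deletion")
    } else {
      jn <- normalize_junction(ref, bp5, bp3, "")
      list(bp5 = jn$bp5, bp3 = jn$bp3, microhomology_len = h,
           microhomology_seq = if (h > 0L)
             substr(ref, jn$bp3, jn$bp3 + h - 1L) else "",
           inserted_seq = "", ambiguity = c(jn$bp5, jn$bp5 + h),
           event_type = "duplication")
    }
  }
}

# exact common prefix of a consensus and ref[a..]
.lcp_raw <- function(C_raw, ref_raw, a) {
  len <- min(length(C_raw), length(ref_raw) - a + 1L)
  if (len < 1L) return(0L)
  neq <- C_raw[seq_len(len)] != ref_raw[a:(a + len - 1L)]
  if (!any(neq)) len else which.max(neq) - 1L
}

#' Annotate a resolved junction as a rearrangement call
#'
#' Converts a resolved junction into a typed event with affected interval,
#' size, repeat-element overlap at both breakpoints, mechanism class,
#' nomenclature (local coordinates are lifted to genomic ones via the locus
#' offset) and a rule-based pathogenicity flag: events overlapping at least
#' one annotated exon are flagged as disrupting the transcript, purely
#' intronic events are not, and a co-occurrence note can be attached.
#'
#' @param locus A `reference_locus`.
#' @param junction List from [resolve_junction()].
#' @param support Supporting read count.
#' @param exons Optional `data.frame` with `start`, `end`, `label`
#'   (locus-local coordinates) for pathogenicity annotation.
#' @param min_homology,short_homology_cap Passed to [classify_mechanism()].
#' @param ref_id Identifier for duplication allele strings.
#' @return A one-row `data.frame` (class `rearrangement_call`) with event
#'   type, local and genomic coordinates, size, microhomology, insertion,
#'   repeats, mechanism, nomenclature and pathogenicity columns.
#' @export
annotate_rearrangement <- function(locus, junction, support = NA_integer_,
                                   exons = NULL, min_homology = 10L,
                                   short_homology_cap = 5L,
                                   ref_id = NULL) {
  if (is.null(ref_id)) ref_id <- locus$name
  if (junction$event_type == "deletion") {
    start <- junction$bp5 + 1L; end <- junction$bp3 - 1L
  } else {
    start <- junction$bp3; end <- junction$bp5
  }
  r5 <- overlap_repeats(start, locus$repeats)
  r3 <- overlap_repeats(end, locus$repeats)
  mech <- classify_mechanism(junction$microhomology_len, r5, r3,
                             min_homology, short_homology_cap)
  g_start <- start + locus$offset - 1L
  g_end <- end + locus$offset - 1L
  nomen <- format_nomenclature(junction$event_type, g_start, g_end,
                               inserted_seq = junction$inserted_seq,
                               ref_id = ref_id)
  path_flag <- NA
  path_note <- ""
  if (!is.null(exons)) {
    hit <- exons$start <= end & exons$end >= start
    if (any(hit)) {
      path_flag <- TRUE
      path_note <- sprintf("disrupts exon(s) %s",
                           paste(exons$label[hit], collapse = ","))
    } else {
      path_flag <- FALSE
      path_note <- "no exon overlap (intronic); assess co-occurrence"
    }
  }
  out <- data.frame(
    event_type = junction$event_type,
    start = start, end = end, size = deletion_size(start, end),
    genomic_start = g_start, genomic_end = g_end,
    microhomology_len = junction$microhomology_len,
    microhomology_seq = junction$microhomology_seq,
    inserted_seq = junction$inserted_seq,
    repeat5 = if (is.null(r5)) NA_character_ else r5$family,
    repeat3 = if (is.null(r3)) NA_character_ else r3$family,
    strand5 = if (is.null(r5)) NA_character_ else r5$strand,
    strand3 = if (is.null(r3)) NA_character_ else r3$strand,
    mechanism = mech,
    nomenclature_paper_style = nomen$paper_style,
    nomenclature_hgvs = nomen$hgvs,
    support = support,
    pathogenic_flag = path_flag,
    pathogenic_note = path_note,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rearrangement_call", class(out))
  out
}

#' Write rearrangement calls as VCF 4.2 symbolic SV records
#'
#' @param calls `data.frame` of calls from [annotate_rearrangement()]
#'   (rows may be concatenated with `rbind`).
#' @param path Output VCF path.
#' @param locus The `reference_locus` the calls refer to.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, locus) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", locus$name, locus_length(locus)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
    "##INFO=<ID=HOMSEQ,Number=1,Type=String,Description=\"Microhomology sequence\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Untemplated junction insertion\">",
    "##INFO=<ID=MECH,Number=1,Type=String,Description=\"Proposed mechanism\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    svtype <- if (calls$event_type[i] == "deletion") "DEL" else "DUP"
    svlen <- if (svtype == "DEL") -calls$size[i] else calls$size[i]
    pos <- calls$start[i] - 1L
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;HOMLEN=%d;MECH=%s",
                    svtype, calls$end[i], svlen,
                    calls$microhomology_len[i], calls$mechanism[i])
    if (nzchar(calls$microhomology_seq[i])) {
      info <- paste0(info, ";HOMSEQ=", calls$microhomology_seq[i])
    }
    if (nzchar(calls$inserted_seq[i])) {
      info <- paste0(info, ";INSSEQ=", calls$inserted_seq[i])
    }
    writeLines(sprintf("%s\t%d\t%s\t%s\t<%s>\t.\tPASS\t%s",
                       locus$name, pos, sprintf("sv%d", i),
                       substr(locus$sequence, pos, pos), svtype, info), con)
  }
  invisible(path)
}
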