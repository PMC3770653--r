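# Planting rearranged alleles with known truth.
#
# Truth records describe events by the affected interval, matching the
# convention of printed deletion designations: bp5 = first affected
# (deleted / duplicated) base, bp3 = last affected base, both 1-based
# locus-local coordinates.  The internal junction representation used by
# the mapper and annotator instead stores retained bases (last base kept
# before the join, first base kept after it); `truth_junction()` converts.

#' Leftmost-normalize a junction representation
#'
#' A junction writes the derived allele as
#' `ref[1..bp5] + ins + ref[bp3..n]` (deletions have `bp3 > bp5`; tandem
#' head-to-tail duplications have `bp3 <= bp5`, the duplicated interval
#' being `[bp3, bp5]`).  When flanks share sequence the same allele admits
#' several `(bp5, bp3, ins)` triples; this function shifts the junction as
#' far left as possible, the package-wide canonical form: first any
#' inserted bases templated from the adjacent reference are absorbed into
#' the flanks (minimal insertion), then a residual blunt junction is
#' shifted to its leftmost admissible position.
#'
#' @param sequence Reference sequence (character) or a `reference_locus`.
#' @param bp5 Last retained base before the join (1-based).
#' @param bp3 First retained base after the join (1-based).
#' @param ins Inserted sequence at the join (possibly empty).
#' @return List with normalized `bp5`, `bp3`, `ins`.
#' @export
normalize_junction <- function(sequence, bp5, bp3, ins = "") {
  if (inherits(sequence, "reference_locus")) sequence <- sequence$sequence
  n <- nchar(sequence)
  bp5 <- as.integer(bp5); bp3 <- as.integer(bp3)
  # absorb templated insertion bases into the flanks (tail first, then
  # head, until neither applies): the representation with the shortest
  # untemplated insertion is canonical
  while (nzchar(ins)) {
    k <- nchar(ins)
    if (bp3 >= 2L && substr(ins, k, k) == substr(sequence, bp3 - 1L, bp3 - 1L)) {
      ins <- substr(ins, 1L, k - 1L); bp3 <- bp3 - 1L
    } else if (bp5 + 1L <= n &&
               substr(ins, 1L, 1L) == substr(sequence, bp5 + 1L, bp5 + 1L)) {
      ins <- substr(ins, 2L, k); bp5 <- bp5 + 1L
    } else break
  }
  if (!nzchar(ins)) {
    while (bp5 >= 1L && bp3 >= 2L &&
           substr(sequence, bp5, bp5) == substr(sequence, bp3 - 1L, bp3 - 1L)) {
      bp5 <- bp5 - 1L; bp3 <- bp3 - 1L
    }
  }
  list(bp5 = bp5, bp3 = bp3, ins = ins)
}

#' Construct a truth record for a planted rearrangement
#'
#' @param event_type `"deletion"` or `"duplication"`.
#' @param bp5,bp3 First and last affected base (deleted or duplicated
#'   interval), 1-based locus-local coordinates.
#' @param planted_microhomology Junction microhomology length in bp.
#' @param inserted_seq Untemplated insertion at the junction (or `""`).
#' @param mechanism_label `"NAHR"` or `"NHEJ"`.
#' @return A list of class `truth_record`.
#' @export
truth_record <- function(event_type, bp5, bp3, planted_microhomology = 0L,
                         inserted_seq = "", mechanism_label = "NHEJ") {
  event_type <- match.arg(event_type, c("deletion", "duplication"))
  mechanism_label <- match.arg(mechanism_label, c("NAHR", "NHEJ"))
  bp5 <- as.integer(bp5); bp3 <- as.integer(bp3)
  if (event_type == "deletion" && bp5 >= bp3) {
    stop("deletion truth requires bp5 < bp3")
  }
  if (planted_microhomology > 0L && nzchar(inserted_seq)) {
    stop("microhomology and an untemplated insertion are mutually exclusive")
  }
  structure(list(event_type = event_type, bp5 = bp5, bp3 = bp3,
                 planted_microhomology = as.integer(planted_microhomology),
                 inserted_seq = toupper(inserted_seq),
                 mechanism_label = mechanism_label),
            class = "truth_record")
}

#' Junction (retained-base) coordinates of a truth record
#'
#' @param truth A `truth_record`.
#' @return List with `bp5` (last retained base before the join), `bp3`
#'   (first retained base after it) and `ins`.
#' @export
truth_junction <- function(truth) {
  if (truth$event_type == "deletion") {
    list(bp5 = truth$bp5 - 1L, bp3 = truth$bp3 + 1L, ins = truth$inserted_seq)
  } else {
    # tandem head-to-tail: allele = ref[1..bp3] + ins + ref[bp5..n]
    list(bp5 = truth$bp3, bp3 = truth$bp5, ins = truth$inserted_seq)
  }
}

#' Derive the rearranged allele from a locus and truth records
#'
#' Events are applied along a walk of the reference: at each junction the
#' walk emits sequence up to the last retained base, then the insertion,
#' then resumes at the first retained base (which lies upstream for
#' duplications).  Multiple non-nested events on one allele are supported.
#'
#' @param locus A `reference_locus`.
#' @param truths A single `truth_record` or a list of them.
#' @return The derived allele as a character string.
#' @export
derive_allele <- function(locus, truths) {
  if (inherits(truths, "truth_record")) truths <- list(truths)
  jx <- lapply(truths, truth_junction)
  ord <- order(vapply(jx, `[[`, 0L, "bp5"))
  jx <- jx[ord]
  seqs <- character(0)
  cur <- 1L
  n <- locus_length(locus)
  for (j in jx) {
    if (j$bp5 < cur - 1L) stop("overlapping/nested events are not supported")
    seqs <- c(seqs, substr(locus$sequence, cur, j$bp5), j$ins)
    cur <- j$bp3
  }
  seqs <- c(seqs, substr(locus$sequence, cur, n))
  paste(seqs, collapse = "")
}

# Replace a single base so it differs from every base in `avoid`.
force_mismatch <- function(seq_chars, pos, avoid) {
  if (seq_chars[pos] %in% avoid) {
    choices <- setdiff(DNA_BASES, unique(c(avoid, seq_chars[pos])))
    if (length(choices) == 0L) choices <- setdiff(DNA_BASES, seq_chars[pos])
    seq_chars[pos] <- choices[1L]
  }
  seq_chars
}

#' Plant a rearrangement in a reference locus
#'
#' Three request kinds are supported, mirroring the junction architectures
#' seen at repeat-dense disease loci:
#'
#' * **NAHR deletion** (`mechanism = "NAHR"`): the request names two
#'   same-orientation planted repeats (`repeat5`, `repeat3`, row indices in
#'   `locus$repeats`) and a `microhomology` length.  A stretch of that
#'   length is copied from the 5' element into the 3' element so the two
#'   share an identical window, and the deletion joins through it; the
#'   bases flanking the window are forced to differ so the recovered
#'   microhomology equals the planted value exactly.
#' * **NHEJ deletion** (`mechanism = "NHEJ"`, `event = "deletion"`): a blunt
#'   join of `bp5..bp3` (first..last deleted base), or a join with an
#'   untemplated `inserted_seq`.  Bases adjacent to the junction inside the
#'   deleted interval are edited so the flanks share no identity (the
#'   planted junction is unambiguous and truly blunt).
#' * **Tandem duplication** (`event = "duplication"`): a head-to-tail copy
#'   of `bp5..bp3` with an optional `inserted_seq` at the junction.
#'
#' Because NAHR/NHEJ planting may edit reference bases, the (possibly
#' modified) locus is returned alongside the allele; truth coordinates are
#' leftmost-normalized so parameter-recovery comparisons are well defined.
#'
#' @param locus A `reference_locus`.
#' @param event `"deletion"` or `"duplication"`.
#' @param mechanism `"NAHR"` or `"NHEJ"`.
#' @param repeat5,repeat3 Row indices into `locus$repeats` (NAHR only).
#' @param microhomology Microhomology length to plant (NAHR only).
#' @param bp5,bp3 First and last affected base (NHEJ deletion and
#'   duplication requests).
#' @param inserted_seq Untemplated junction insertion.
#' @return List with elements `locus` (possibly edited), `allele`
#'   (character) and `truth` (a `truth_record`).
#' @export
plant_rearrangement <- function(locus, event = c("deletion", "duplication"),
                                mechanism = c("NHEJ", "NAHR"),
                                repeat5 = NULL, repeat3 = NULL,
                                microhomology = 0L,
                                bp5 = NULL, bp3 = NULL, inserted_seq = "") {
  event <- match.arg(event)
  mechanism <- match.arg(mechanism)
  n <- locus_length(locus)
  inserted_seq <- toupper(inserted_seq)

  if (mechanism == "NAHR") {
    if (event != "deletion") stop("NAHR planting is defined for deletions")
    if (is.null(repeat5) || is.null(repeat3)) {
      stop("an NAHR request must name two planted repeats (repeat5, repeat3)")
    }
    r5 <- locus$repeats[repeat5, ]; r3 <- locus$repeats[repeat3, ]
    if (r5$strand != r3$strand ||
        repeat_superfamily(r5$family) != repeat_superfamily(r3$family)) {
      stop(paste("NAHR requires two same-orientation elements of the same",
                 "repeat family; recombined elements must be directed in the",
                 "same orientation"))
    }
    if (r5$end >= r3$start) stop("repeat5 must lie upstream of repeat3")
    h <- as.integer(microhomology)
    elen <- min(r5$end - r5$start, r3$end - r3$start) + 1L
    if (h < 1L || h > elen - 4L) {
      stop(sprintf("planted microhomology must be in [1, %d] for these elements",
                   elen - 4L))
    }
    # offset of the shared window inside each element; keep one base margin
    # on both sides for the forced boundary mismatches
    o <- if (elen - h - 2L >= 2L) sample(2:(elen - h - 2L), 1L) else 2L
    p5s <- r5$start + o; p5e <- p5s + h - 1L
    p3s <- r3$start + o; p3e <- p3s + h - 1L
    chars <- strsplit(locus$sequence, "")[[1]]
    chars[p3s:p3e] <- chars[p5s:p5e]
    chars <- force_mismatch(chars, p3s - 1L, chars[p5s - 1L])
    chars <- force_mismatch(chars, p3e + 1L, chars[p5e + 1L])
    locus$sequence <- paste(chars, collapse = "")
    truth <- truth_record("deletion", bp5 = p5s, bp3 = p3s - 1L,
                          planted_microhomology = h,
                          mechanism_label = "NAHR")
  } else if (event == "deletion") {
    bp5 <- as.integer(bp5); bp3 <- as.integer(bp3)
    if (is.null(bp5) || is.null(bp3) || bp5 >= bp3) {
      stop("an NHEJ deletion request needs bp5 < bp3 (first/last deleted base)")
    }
    if (bp5 < 2L || bp3 > n - 1L || bp3 - bp5 < 10L) {
      stop("deletion must be interior to the locus and span >= 10 bp")
    }
    chars <- strsplit(locus$sequence, "")[[1]]
    # junction: ...chars[bp5-1] | ins | chars[bp3+1]...  Edit deleted-interval
    # bases adjacent to the junction so flanks share no identity and the
    # representation is canonical (no junction shift, no insertion rotation).
    avoid5 <- chars[bp5 - 1L]            # base kept just before the join
    avoid3 <- chars[bp3 + 1L]            # base kept just after the join
    if (nzchar(inserted_seq)) {
      i1 <- substr(inserted_seq, 1L, 1L)
      ik <- substr(inserted_seq, nchar(inserted_seq), nchar(inserted_seq))
      chars <- force_mismatch(chars, bp5, c(i1, avoid3))
      chars <- force_mismatch(chars, bp3, c(ik, avoid5))
    } else {
      chars <- force_mismatch(chars, bp5, avoid3)
      chars <- force_mismatch(chars, bp3, avoid5)
    }
    locus$sequence <- paste(chars, collapse = "")
    truth <- truth_record("deletion", bp5 = bp5, bp3 = bp3,
                          inserted_seq = inserted_seq,
                          mechanism_label = "NHEJ")
  } else {
    bp5 <- as.integer(bp5); bp3 <- as.integer(bp3)
    if (is.null(bp5) || is.null(bp3) || bp5 >= bp3) {
      stop("a duplication request needs bp5 < bp3 (duplicated interval)")
    }
    if (bp5 < 2L || bp3 > n - 1L) stop("duplicated interval must be interior")
    truth <- truth_record("duplication", bp5 = bp5, bp3 = bp3,
                          inserted_seq = inserted_seq,
                          mechanism_label = "NHEJ")
  }

  allele <- derive_allele(locus, truth)
  # store the canonical (leftmost) representation in the truth record
  j <- truth_junction(truth)
  jn <- normalize_junction(locus$sequence, j$bp5, j$bp3, j$ins)
  if (truth$event_type == "deletion") {
    truth$bp5 <- jn$bp5 + 1L; truth$bp3 <- jn$bp3 - 1L
  } else {
    truth$bp5 <- jn$bp3; truth$bp3 <- jn$bp5
  }
  truth$inserted_seq <- jn$ins
  list(locus = locus, allele = allele, truth = truth)
}
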