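# Reference loci and repeat annotation tracks.
#
# Coordinates are 1-based inclusive throughout the package; conversion to
# half-open BED happens only at I/O.

# A ~300 bp AluY-like consensus used for all planted SINE elements.  Any
# fixed primate Alu consensus works here: planted copies are diverged per
# base, so only the length scale and self-similarity structure matter.
ALU_CONSENSUS <- paste0(
  "GGCCGGGCGCGGTGGCTCACGCCTGTAATCCCAGCACTTTGGGAGGCCGAGGCGGGCGGATCACGAGG",
  "TCAGGAGATCGAGACCATCCTGGCTAACACGGTGAAACCCCGTCTCTACTAAAAATACAAAAAATTAG",
  "CCGGGCGTGGTGGCGGGCGCCTGTAGTCCCAGCTACTCGGGAGGCTGAGGCAGGAGAATGGCGTGAAC",
  "CCGGGAGGCGGAGCTTGCAGTGAGCCGAGATCGCGCCACTGCACTCCAGCCTGGGCGACAGAGCGAGA",
  "CTCCGTCTCAAAAAAAAAAAAAAAAAAA"
)

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a reference locus
#'
#' A reference locus bundles a DNA sequence with a 1-based genomic offset
#' (the genomic coordinate of its first base) and a repeat annotation track.
#'
#' @param name Locus name (used as the FASTA header / BED chromosome).
#' @param sequence Uppercase DNA string over the alphabet A, C, G, T, N.
#' @param offset Genomic coordinate (1-based) of the first base.
#' @param repeats Repeat track `data.frame` as returned by [repeat_track()].
#' @return An object of class `reference_locus`.
#' @export
reference_locus <- function(name, sequence, offset = 1L,
                            repeats = repeat_track()) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("locus sequence must have length >= 1")
  if (grepl("[^ACGTN]", sequence)) {
    stop("locus sequence contains characters outside {A,C,G,T,N}")
  }
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) stop("offset must be a 1-based coordinate (>= 1)")
  validate_repeat_track(repeats, nchar(sequence))
  structure(
    list(name = as.character(name), offset = offset,
         sequence = sequence, repeats = repeats),
    class = "reference_locus"
  )
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus> %s: %d bp (offset %d), %d repeat elements\n",
              x$name, nchar(x$sequence), x$offset, nrow(x$repeats)))
  invisible(x)
}

#' Length of a reference locus in base pairs
#' @param locus A `reference_locus`.
#' @return Integer length.
#' @export
locus_length <- function(locus) nchar(locus$sequence)

#' Build a repeat annotation track
#'
#' @param family Repeat family names (e.g. `"AluY"`, `"AluSx"`, `"L1"`).
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param class Repeat class: `"SINE"`, `"LINE"`, `"LTR"` or `"DNA"`.
#' @return A `data.frame` with one row per element, sorted by start.
#' @export
repeat_track <- function(family = character(), start = integer(),
                         end = integer(), strand = character(),
                         class = character()) {
  df <- data.frame(
    family = as.character(family), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    class = as.character(class), stringsAsFactors = FALSE
  )
  df[order(df$start), , drop = FALSE]
}

validate_repeat_track <- function(track, locus_len = NULL) {
  stopifnot(is.data.frame(track),
            all(c("family", "start", "end", "strand", "class") %in% names(track)))
  if (nrow(track) == 0L) return(invisible(track))
  if (any(track$start > track$end)) stop("repeat elements must have start <= end")
  if (!all(track$strand %in% c("+", "-"))) stop("repeat strand must be '+' or '-'")
  if (!is.null(locus_len) &&
      (any(track$start < 1L) || any(track$end > locus_len))) {
    stop("repeat elements must lie within the locus")
  }
  invisible(track)
}

#' Superfamily of a repeat element family name
#'
#' Collapses the Alu subfamilies (AluY, AluSx, AluSp, ...) onto `"Alu"`;
#' other family names are returned unchanged.  Mechanism classification
#' treats two elements as homology partners when their superfamilies agree,
#' since NAHR between e.g. an AluY and an AluSp copy is routinely observed.
#'
#' @param family Character vector of family names.
#' @return Character vector of superfamily names.
#' @export
repeat_superfamily <- function(family) {
  ifelse(grepl("^Alu", family), "Alu", family)
}

#' Generate a random repeat-dense reference locus
#'
#' Background sequence is uniform random DNA; `n_repeats` Alu-like elements
#' (copies of a fixed ~300 bp consensus, mutated per base with probability
#' `repeat_divergence` and placed on a random strand) are planted at
#' non-overlapping positions.  Annotation coordinates in the returned track
#' are exact.
#'
#' @param length Locus length in bp (>= 2000).
#' @param n_repeats Number of elements to plant.
#' @param repeat_divergence Per-base substitution probability in `[0, 0.3]`.
#' @param seed Optional integer seed for reproducibility.
#' @param families Pool of SINE family labels assigned at random.
#' @param offset Genomic offset of the locus.
#' @param name Locus name.
#' @return A `reference_locus` whose `$repeats` track annotates the planted
#'   elements.
#' @export
generate_reference <- function(length, n_repeats, repeat_divergence = 0.05,
                               seed = NULL,
                               families = c("AluY", "AluSx", "AluSp",
                                            "AluJb", "AluSz"),
                               offset = 1L, name = "locus") {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  n_repeats <- as.integer(n_repeats)
  if (length < 2000L) stop("locus length must be >= 2000 bp")
  if (repeat_divergence < 0 || repeat_divergence > 0.3) {
    stop("repeat_divergence must lie in [0, 0.3]")
  }
  elen <- nchar(ALU_CONSENSUS)
  if (n_repeats * elen > length) {
    stop(sprintf(
      "cannot place %d non-overlapping %d bp elements in a %d bp locus (max %d)",
      n_repeats, elen, length, length %/% elen))
  }
  seq_chars <- sample(DNA_BASES, length, replace = TRUE)
  track <- repeat_track()
  if (n_repeats > 0L) {
    # stars-and-bars: uniform non-overlapping placement of n equal elements
    slack <- length - n_repeats * elen
    cuts <- sort(sample.int(slack + n_repeats, n_repeats))
    # start_i = (cuts_i - i) + (i-1)*elen + 1
    starts <- (cuts - seq_len(n_repeats)) + (seq_len(n_repeats) - 1L) * elen + 1L
    strands <- sample(c("+", "-"), n_repeats, replace = TRUE)
    fams <- sample(families, n_repeats, replace = TRUE)
    cons <- strsplit(ALU_CONSENSUS, "")[[1]]
    for (i in seq_len(n_repeats)) {
      el <- cons
      if (repeat_divergence > 0) {
        hit <- runif(elen) < repeat_divergence
        if (any(hit)) {
          el[hit] <- vapply(el[hit],
                            function(b) sample(setdiff(DNA_BASES, b), 1L),
                            character(1))
        }
      }
      if (strands[i] == "-") el <- rev(chartr("ACGT", "TGCA", el))
      seq_chars[starts[i]:(starts[i] + elen - 1L)] <- el
    }
    track <- repeat_track(family = fams, start = starts,
                          end = starts + elen - 1L, strand = strands,
                          class = rep("SINE", n_repeats))
  }
  reference_locus(name = name, sequence = paste(seq_chars, collapse = ""),
                  offset = offset, repeats = track)
}

## ---- sequence utilities ----------------------------------------------------

#' Reverse-complement a DNA string
#' @param x Character vector of DNA strings.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---- FASTA -----------------------------------------------------------------

#' Write a locus (or any named set of sequences) to FASTA
#' @param locus A `reference_locus`, or a named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(locus, path) {
  if (inherits(locus, "reference_locus")) {
    seqs <- stats::setNames(locus$sequence, locus$name)
  } else {
    seqs <- locus
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a reference locus from FASTA
#' @param path FASTA file with a single record.
#' @param offset Genomic offset of the first base.
#' @param repeats Optional repeat track.
#' @return A `reference_locus`.
#' @export
read_locus_fasta <- function(path, offset = 1L, repeats = repeat_track()) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single-record FASTA for a locus")
  reference_locus(name = sub("\\s.*$", "", names(ss)[1]),
                  sequence = as.character(ss[[1]]),
                  offset = offset, repeats = repeats)
}

## ---- repeat track I/O ------------------------------------------------------

#' Write a repeat track as BED6
#'
#' BED is half-open 0-based; the track's 1-based inclusive coordinates are
#' converted on output.  Strand goes in column 6, `family` in the name
#' column, and the repeat class is carried as `class:family` when
#' `keep_class` is set.
#'
#' @param track Repeat track `data.frame`.
#' @param path Output file.
#' @param chrom Chromosome/locus name for column 1.
#' @return `path`, invisibly.
#' @export
write_repeat_bed <- function(track, path, chrom = "locus") {
  df <- data.frame(chrom = chrom, start = track$start - 1L, end = track$end,
                   name = paste(track$class, track$family, sep = ":"),
                   score = 0L, strand = track$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a repeat track from BED6
#' @param path BED file written by [write_repeat_bed()] (or any BED6 whose
#'   name column is `class:family` or a bare family name).
#' @return A repeat track `data.frame`.
#' @export
read_repeat_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  nm <- strsplit(df[[4]], ":", fixed = TRUE)
  cls <- vapply(nm, function(x) if (length(x) == 2L) x[1] else "SINE", "")
  fam <- vapply(nm, function(x) x[length(x)], "")
  repeat_track(family = fam, start = df[[2]] + 1L, end = df[[3]],
               strand = df[[6]], class = cls)
}

#' Write a repeat track in RepeatMasker `.out` layout
#'
#' Emits the classic fixed-column annotation table (three header lines, then
#' one row per element) so downstream tools expecting RepeatMasker output can
#' consume synthetic tracks.
#'
#' @param track Repeat track `data.frame`.
#' @param path Output file.
#' @param chrom Query sequence name.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(track, path, chrom = "locus") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query       matching repeat            position in repeat",
    "score   div. del. ins.  sequence  begin end      (left)   repeat     class/family  begin  end    (left)   ID",
    ""), con)
  for (i in seq_len(nrow(track))) {
    writeLines(sprintf(
      "%5d %6.1f %4.1f %4.1f  %s %7d %7d (%d) %s %-10s %-13s %6d %6d (%d) %4d",
      1000L, 5.0, 0.0, 0.0, chrom, track$start[i], track$end[i], 0L,
      ifelse(track$strand[i] == "+", "+", "C"),
      track$family[i],
      paste0(track$class[i], "/", repeat_superfamily(track$family[i])),
      1L, track$end[i] - track$start[i] + 1L, 0L, i), con)
  }
  invisible(path)
}

#' Read a repeat track from RepeatMasker `.out` format
#' @param path A RepeatMasker annotation file.
#' @return A repeat track `data.frame`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(repeat_track())
  fields <- strsplit(trimws(lines), "\\s+")
  get <- function(i) vapply(fields, `[[`, "", i)
  cls <- sub("/.*$", "", get(11L))
  repeat_track(family = get(10L), start = as.integer(get(6L)),
               end = as.integer(get(7L)),
               strand = ifelse(get(9L) == "C", "-", "+"), class = cls)
}
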