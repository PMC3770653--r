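# Amplicon read simulation (substitution errors only, constant quality).
#
# Emulates long-amplicon pyrosequencing reads spanning rearrangement
# junctions: ~400 bp uniform-start reads at high depth.  Homopolymer indel
# errors, the hallmark artifact of real 454 chemistry, are deliberately out
# of scope: the mapper handles substitutions only and documents that
# limitation.

#' Simulate uniform-start reads from an allele
#'
#' Read count is `round(length(allele) * depth / read_length)`; start
#' positions are uniform, half of the reads (in expectation) are
#' reverse-complemented, and each base is substituted independently with
#' probability `error_rate`.  Deterministic under `seed`.
#'
#' @param allele DNA string to sequence.
#' @param read_length Read length in bp.
#' @param depth Mean fold-coverage.
#' @param error_rate Per-base substitution probability.
#' @param seed Optional integer seed.
#' @param both_strands Simulate reads from both strands (default `TRUE`).
#' @param prefix Read-name prefix.
#' @return A named character vector of read sequences; names carry the
#'   read id, 1-based start position on the allele and strand
#'   (`"<prefix>_<i> pos=<start> strand=<+/->"`).
#' @export
simulate_reads <- function(allele, read_length = 400L, depth = 30,
                           error_rate = 0, seed = NULL,
                           both_strands = TRUE, prefix = "read") {
  if (!is.null(seed)) set.seed(seed)
  allele <- toupper(as.character(allele))
  L <- nchar(allele)
  read_length <- as.integer(read_length)
  if (read_length > L) stop("read_length exceeds allele length")
  if (depth < 1) stop("depth must be >= 1")
  n <- max(1L, as.integer(round(L * depth / read_length)))
  starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
  reads <- substring(allele, starts, starts + read_length - 1L)
  if (error_rate > 0) {
    nerr <- stats::rbinom(n, read_length, error_rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(read_length, nerr[i])
      ch <- strsplit(reads[i], "")[[1]]
      ch[pos] <- vapply(ch[pos],
                        function(b) sample(setdiff(DNA_BASES, b), 1L),
                        character(1))
      reads[i] <- paste(ch, collapse = "")
    }
  }
  strands <- rep("+", n)
  if (both_strands) {
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    strands[flip] <- "-"
  }
  names(reads) <- sprintf("%s_%05d pos=%d strand=%s",
                          prefix, seq_len(n), starts, strands)
  reads
}

#' Write reads to FASTQ with a constant quality line
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @param quality_char Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ss <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(l) strrep(quality_char, l), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read sequences from FASTQ (or FASTA)
#' @param path Input file.
#' @param format `"fastq"` or `"fasta"`.
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  ss <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(ss), names(ss))
}
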