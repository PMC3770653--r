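# End-to-end convenience wrapper: reads -> split alignment -> clustering ->
# junction consensus -> exact resolution -> annotated calls.

#' Map and annotate rearrangements from reads
#'
#' Runs the full breakpoint-mapping pipeline against one locus: split-align
#' every read, cluster chimeric reads into breakpoint candidates,
#' reconstruct each cluster's junction consensus, resolve exact
#' (leftmost-normalized) breakpoints and annotate mechanism, repeats and
#' nomenclature.
#'
#' @param locus A `reference_locus`.
#' @param reads Named character vector of reads.
#' @param min_anchor,max_mismatch_rate,min_sv_distance Passed to
#'   [split_align_reads()].
#' @param tol,min_support Passed to [cluster_chimeras()].
#' @param exons Optional exon `data.frame` for pathogenicity flags.
#' @param min_homology,short_homology_cap Mechanism thresholds.
#' @return List with `calls` (a `data.frame`, one row per event),
#'   `clusters` and `alignments`.
#' @export
map_rearrangements <- function(locus, reads, min_anchor = 20L,
                               max_mismatch_rate = 0.05,
                               min_sv_distance = 100L, tol = 10L,
                               min_support = 3L, exons = NULL,
                               min_homology = 10L, short_homology_cap = 5L) {
  aln <- split_align_reads(reads, locus, min_anchor = min_anchor,
                           max_mismatch_rate = max_mismatch_rate,
                           min_sv_distance = min_sv_distance)
  clusters <- cluster_chimeras(aln, tol = tol, min_support = min_support)
  calls <- NULL
  for (cl in clusters) {
    cons <- reconstruct_junction(cl, aln)
    jx <- tryCatch(resolve_junction(locus, cons), error = function(e) NULL)
    if (is.null(jx)) next
    call <- annotate_rearrangement(locus, jx, support = cl$support,
                                   exons = exons,
                                   min_homology = min_homology,
                                   short_homology_cap = short_homology_cap)
    calls <- if (is.null(calls)) call else rbind(calls, call)
  }
  if (is.null(calls)) {
    calls <- annotate_empty_calls()
  }
  list(calls = calls, clusters = clusters, alignments = aln)
}

annotate_empty_calls <- function() {
  data.frame(event_type = character(), start = integer(), end = integer(),
             size = integer(), genomic_start = integer(),
             genomic_end = integer(), microhomology_len = integer(),
             microhomology_seq = character(), inserted_seq = character(),
             repeat5 = character(), repeat3 = character(),
             strand5 = character(), strand3 = character(),
             mechanism = character(), nomenclature_paper_style = character(),
             nomenclature_hgvs = character(), support = integer(),
             pathogenic_flag = logical(), pathogenic_note = character(),
             stringsAsFactors = FALSE)
}
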