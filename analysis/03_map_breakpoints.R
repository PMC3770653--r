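#!/usr/bin/env Rscript

# Step 3: split-read breakpoint mapping.
#
# Long-amplicon reads (400 bp, 30x, 1% substitution error) are simulated
# from each planted allele of step 1 and mapped back to the locus.
# Chimeric reads -- those matching two discrete reference regions -- are
# clustered into breakpoint candidates; each cluster's junction consensus
# is reconstructed by majority vote.  Requires results/ from step 1.

library(rearrangemap)

locus <- read_locus_fasta("results/locus.fasta", offset = 47630108L,
                          repeats = read_repeat_bed("results/repeats.bed"))
alleles <- read_reads("results/alleles.fasta", format = "fasta")
truth <- utils::read.delim("results/truth.tsv")

all_clusters <- list()
for (k in seq_along(alleles)) {
  nm <- sub("^allele_", "", names(alleles)[k])
  reads <- simulate_reads(alleles[[k]], read_length = 400, depth = 30,
                          error_rate = 0.01, seed = 300L + k,
                          prefix = nm)
  aln <- split_align_reads(reads, locus)
  cl <- cluster_chimeras(aln)
  tab <- clusters_table(cl)
  if (nrow(tab)) tab$event <- nm
  all_clusters[[nm]] <- tab
  message(sprintf(
    "%-6s: %d reads (%d chimeric) -> %d cluster(s): %s", nm, length(reads),
    sum(aln$is_chimeric), length(cl),
    paste(sprintf("%d/%d (n=%d)", tab$bp5, tab$bp3, tab$support),
          collapse = "; ")))
  # junction consensus for downstream annotation
  for (i in seq_along(cl)) {
    cons <- reconstruct_junction(cl[[i]], aln)
    writeLines(c(sprintf(">%s_cluster%d d_start=%d support=%d",
                         nm, i, cons$d_start, cl[[i]]$support),
                 cons$consensus),
               sprintf("results/junction_%s_%d.fasta", nm, i))
  }
}
clusters <- do.call(rbind, all_clusters)
utils::write.table(clusters, "results/breakpoint_clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/breakpoint_clusters.tsv and junction consensus FASTAs")
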