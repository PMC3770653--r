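#!/usr/bin/env Rscript

# Step 1: build the synthetic study locus and plant rearranged alleles.
#
# A 40 kb repeat-dense locus (genomic offset matching the GRCh37 MSH2
# region) stands in for the real gene.  Three allele architectures seen in
# the clinical cohort are planted with known truth: an Alu-mediated NAHR
# deletion with substantial junction microhomology (confined to the first
# 18 kb), a blunt NHEJ deletion at 20.0-22.5 kb, and a head-to-tail tandem
# duplication of 26-31 kb with a short untemplated junction insertion.
# NAHR/NHEJ planting edits a handful of reference bases to make the truth
# junctions unambiguous, so events are planted sequentially on one locus
# and every allele is re-derived from the final edited sequence.  Outputs:
# locus FASTA, repeat track (BED + RepeatMasker layout), allele FASTA and
# a truth table under results/.

library(rearrangemap)

dir.create("results", showWarnings = FALSE)
set.seed(101)

loc <- generate_reference(40000, 30, 0.05, seed = 101,
                          offset = 47630108L, name = "msh2_synthetic")
rc <- repeat_content(loc$repeats, loc)
message(sprintf("locus: %d bp, %d repeat elements, %.2f%% masked",
                locus_length(loc), nrow(loc$repeats),
                100 * rc$masked_fraction))

tr <- loc$repeats
pair <- NULL
for (i in seq_len(nrow(tr) - 1L)) {
  for (j in (i + 1L):nrow(tr)) {
    if (tr$strand[i] == tr$strand[j] && tr$start[j] - tr$end[i] >= 3000 &&
        tr$start[i] >= 1000 && tr$end[j] <= 18000) { pair <- c(i, j); break }
  }
  if (!is.null(pair)) break
}
stopifnot(!is.null(pair))

ev1 <- plant_rearrangement(loc, event = "deletion", mechanism = "NAHR",
                           repeat5 = pair[1], repeat3 = pair[2],
                           microhomology = 24)
ev2 <- plant_rearrangement(ev1$locus, event = "deletion", mechanism = "NHEJ",
                           bp5 = 20000, bp3 = 22470)
ev3 <- plant_rearrangement(ev2$locus, event = "duplication",
                           bp5 = 26000, bp3 = 31000,
                           inserted_seq = "AAACAAT")
final_locus <- ev3$locus
truths <- list(nahr = ev1$truth, nhej = ev2$truth, dup = ev3$truth)
alleles <- vapply(truths, function(t) derive_allele(final_locus, t), "")

truth <- do.call(rbind, lapply(names(truths), function(nm) {
  t <- truths[[nm]]
  data.frame(event = nm, event_type = t$event_type, bp5 = t$bp5,
             bp3 = t$bp3, size = t$bp3 - t$bp5 + 1L,
             microhomology = t$planted_microhomology,
             inserted_seq = t$inserted_seq, mechanism = t$mechanism_label)
}))
print(truth)

write_fasta(final_locus, "results/locus.fasta")
write_repeat_bed(final_locus$repeats, "results/repeats.bed",
                 chrom = final_locus$name)
write_repeatmasker_out(final_locus$repeats, "results/repeats.out",
                       chrom = final_locus$name)
write_fasta(stats::setNames(alleles, sprintf("allele_%s", names(truths))),
            "results/alleles.fasta")
utils::write.table(truth, "results/truth.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("wrote results/locus.fasta, repeats.bed, repeats.out, alleles.fasta, truth.tsv")
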