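# Synthetic locus, planted rearrangements and simulators.

test_that("generate_reference plants exact, recomputable repeat annotation", {
  loc0 <- generate_reference(20000, 0, 0, seed = 1)
  expect_equal(nrow(loc0$repeats), 0L)
  expect_equal(repeat_content(loc0$repeats, loc0)$masked_fraction, 0)

  loc <- generate_reference(20000, 10, 0.05, seed = 7)
  expect_equal(nrow(loc$repeats), 10L)
  expect_true(all(loc$repeats$end <= locus_length(loc)))
  # non-overlapping placement
  expect_true(all(diff(loc$repeats$start) >
                    (loc$repeats$end - loc$repeats$start)[-10]))
  # masked fraction recomputable by brute-force base counting
  rc <- repeat_content(loc$repeats, loc)
  expect_equal(rc$masked_fraction,
               oracle_masked_fraction(loc$repeats, locus_length(loc)))
  expect_equal(unname(rc$counts["SINE"]), 10L)

  # determinism under a fixed seed
  loc2 <- generate_reference(20000, 10, 0.05, seed = 7)
  expect_identical(loc$sequence, loc2$sequence)
  expect_identical(loc$repeats, loc2$repeats)

  expect_error(generate_reference(2000, 100, 0, seed = 1), "max")
  expect_error(generate_reference(1000, 0, 0), ">= 2000")
})

test_that("planted deletions have the exact requested size and self-consistent truth", {
  loc <- generate_reference(20000, 0, 0, seed = 11)
  pl <- plant_rearrangement(loc, event = "deletion", mechanism = "NHEJ",
                            bp5 = 1000, bp3 = 3470)
  # size oracle: end - start + 1 deleted bases
  expect_equal(nchar(pl$allele), locus_length(loc) - 2471L)
  expect_equal(pl$truth$bp3 - pl$truth$bp5 + 1L, 2471L)
  expect_identical(derive_allele(pl$locus, pl$truth), pl$allele)

  # duplication with an untemplated insertion at the head-to-tail junction
  set.seed(2)
  locd <- generate_reference(40000, 0, 0, seed = 12)
  dup <- plant_rearrangement(locd, event = "duplication",
                             bp5 = 4000, bp3 = 35607, inserted_seq = "AAACAAT")
  # the allele carries the requested 31,608 bp interval head-to-tail with
  # the untemplated insertion between the two copies
  interval <- substr(locd$sequence, 4000, 35607)
  expect_equal(nchar(interval), 31608L)
  expect_true(grepl(paste0(interval, "AAACAAT", interval),
                    dup$allele, fixed = TRUE))
  # the stored truth is the canonical (minimal-insertion, leftmost) form
  # and regenerates the identical allele
  expect_identical(derive_allele(dup$locus, dup$truth), dup$allele)
})

test_that("NAHR planting yields exactly the requested junction microhomology", {
  set.seed(5)
  loc <- generate_reference(20000, 12, 0.05, seed = 5)
  pair <- pick_nahr_pair(loc$repeats, len = locus_length(loc))
  expect_false(is.null(pair))
  pl <- plant_rearrangement(loc, event = "deletion", mechanism = "NAHR",
                            repeat5 = pair[1], repeat3 = pair[2],
                            microhomology = 48)
  expect_identical(derive_allele(pl$locus, pl$truth), pl$allele)
  j <- truth_junction(pl$truth)
  # brute-force junction-shift oracle recovers the planted value exactly
  orc <- oracle_microhomology(pl$locus$sequence, j$bp5, j$bp3)
  expect_equal(orc$mh, 48L)
  expect_equal(orc$bp5_left, j$bp5)

  # opposite-strand or cross-family requests are refused
  opp <- which(loc$repeats$strand != loc$repeats$strand[pair[1]])
  if (length(opp) > 0) {
    expect_error(
      plant_rearrangement(loc, event = "deletion", mechanism = "NAHR",
                          repeat5 = min(pair[1], opp[1]),
                          repeat3 = max(pair[1], opp[1]), microhomology = 20),
      "orientation")
  }
})

test_that("simulate_reads matches its sampling model", {
  loc <- generate_reference(5000, 0, 0, seed = 3)
  allele <- loc$sequence
  reads <- simulate_reads(allele, read_length = 400, depth = 30,
                          error_rate = 0, seed = 3)
  expect_equal(length(reads), 375L)  # round(5000 * 30 / 400)
  # zero error rate: every read is an exact substring of the allele (either
  # strand)
  fwd <- vapply(reads, function(r) grepl(r, allele, fixed = TRUE), FALSE)
  rev <- vapply(revcomp(reads), function(r) grepl(r, allele, fixed = TRUE),
                FALSE)
  expect_true(all(fwd | rev))

  # error rate: observed mismatch fraction within 3 SE of the target
  reads_e <- simulate_reads(allele, 400, 30, error_rate = 0.01, seed = 9,
                            both_strands = FALSE)
  starts <- as.integer(sub(".*pos=(\\d+).*", "\\1", names(reads_e)))
  mism <- mapply(function(r, s) {
    sum(charToRaw(r) != charToRaw(substr(allele, s, s + 399L)))
  }, reads_e, starts)
  p_hat <- sum(mism) / (length(reads_e) * 400)
  se <- sqrt(0.01 * 0.99 / (length(reads_e) * 400))
  expect_lt(abs(p_hat - 0.01), 3 * se)

  # junction occupancy: at depth >= 20 some read always covers any interior
  # position (here the midpoint standing in for a junction)
  reads_j <- simulate_reads(allele, 400, 20, 0, seed = 13)
  st <- as.integer(sub(".*pos=(\\d+).*", "\\1", names(reads_j)))
  jpos <- 2500L
  expect_gt(sum(st <= jpos & st + 399L >= jpos), 0L)

  expect_error(simulate_reads(substr(allele, 1, 100), read_length = 400),
               "exceeds")
  expect_identical(simulate_reads(allele, 400, 5, 0.01, seed = 21),
                   simulate_reads(allele, 400, 5, 0.01, seed = 21))
})

test_that("FASTQ and repeat-track round trips preserve content", {
  loc <- generate_reference(3000, 4, 0.05, seed = 8)
  reads <- simulate_reads(loc$sequence, 100, 5, 0, seed = 1)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_reads(fq)
  expect_equal(unname(back), unname(reads))

  bed <- tempfile(fileext = ".bed")
  write_repeat_bed(loc$repeats, bed)
  expect_equal(read_repeat_bed(bed), loc$repeats)

  rmo <- tempfile(fileext = ".out")
  write_repeatmasker_out(loc$repeats, rmo)
  rm_track <- read_repeatmasker_out(rmo)
  expect_equal(rm_track[, c("family", "start", "end", "strand", "class")],
               loc$repeats[, c("family", "start", "end", "strand", "class")])

  fa <- tempfile(fileext = ".fa")
  write_fasta(loc, fa)
  loc2 <- read_locus_fasta(fa, offset = loc$offset, repeats = loc$repeats)
  expect_identical(loc2$sequence, loc$sequence)
})

test_that("simulated MLPA tables follow exact dosage arithmetic without noise", {
  cn <- stats::setNames(rep(2L, 16), sprintf("E%d", 1:16))
  peaks <- simulate_mlpa(cn, n_controls = 4, noise_sd = 0, seed = 2)
  ratios <- normalize_mlpa(peaks)
  expect_true(all(abs(ratios$ratio - 1) < 1e-12))

  cn["E7"] <- 1L
  peaks <- simulate_mlpa(cn, n_controls = 4, noise_sd = 0, seed = 2)
  ratios <- normalize_mlpa(peaks)
  r7 <- ratios$ratio[ratios$sample == "S1" & ratios$probe == "P_E7"]
  expect_equal(r7, c(0.5, 0.5))

  # duplicated exon under mild noise is called in both reactions
  cn <- stats::setNames(rep(2L, 16), sprintf("E%d", 1:16))
  cn["E3"] <- 3L
  peaks <- simulate_mlpa(cn, n_controls = 5, noise_sd = 0.05, seed = 4)
  ratios <- normalize_mlpa(peaks)
  s1 <- ratios[ratios$sample == "S1", ]
  calls <- call_dosage(s1[s1$reaction == 1, ], s1[s1$reaction == 2, ])
  e3 <- calls[calls$exon == "E3", ]
  expect_equal(e3$state, "duplication")
  expect_true(e3$confirmed)
})

test_that("simulated cohorts follow their sampling model", {
  quiet <- simulate_cohort(phenotype_rates = list(
    lgr = c(CRC = 0, EC = 0), point = c(CRC = 0, EC = 0)), seed = 1)
  expect_false(any(quiet$affected))

  big <- simulate_cohort(n_carrier_families = 400, n_point_families = 0,
                         phenotype_rates = list(lgr = c(CRC = 0.55),
                                                point = c(CRC = 0.42)),
                         seed = 2)
  n <- nrow(big)
  p_hat <- mean(big$affected)
  expect_lt(abs(p_hat - 0.55), 3 * sqrt(0.55 * 0.45 / n))

  expect_identical(simulate_cohort(seed = 3), simulate_cohort(seed = 3))
})

test_that("simulated aCGH probe tracks are exact without noise", {
  flat <- simulate_cgh(20000, NULL, probe_spacing = 100, noise_sd = 0)
  expect_true(all(flat$log2 == 0))

  seg <- data.frame(start = 5000, end = 6500, cn = 1)
  probes <- simulate_cgh(20000, seg, probe_spacing = 100, noise_sd = 0)
  shifted <- probes$position >= 5000 & probes$position <= 6500
  expect_gte(sum(shifted), 10L)
  expect_true(all(probes$log2[shifted] == -1))
  expect_true(all(probes$log2[!shifted] == 0))
})
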