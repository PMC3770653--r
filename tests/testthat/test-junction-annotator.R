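# Microhomology, sizes, repeat overlap, mechanism and nomenclature.

test_that("compute_microhomology matches the exhaustive junction-shift oracle", {
  loc <- generate_reference(10000, 10, 0.05, seed = 19)
  seq <- loc$sequence

  # flanks sharing no bases: a junction forced blunt by planting
  pl <- plant_rearrangement(loc, event = "deletion", mechanism = "NHEJ",
                            bp5 = 2000, bp3 = 4000)
  j <- truth_junction(pl$truth)
  mh0 <- compute_microhomology(pl$locus, j$bp5, j$bp3)
  expect_equal(mh0$length, 0L)
  expect_equal(mh0$seq, "")

  # random breakpoint pairs against the brute-force oracle
  set.seed(101)
  for (i in 1:200) {
    bp5 <- sample(300:8000, 1)
    bp3 <- bp5 + sample(60:1800, 1)
    got <- compute_microhomology(loc, bp5, bp3)
    orc <- oracle_microhomology(seq, bp5, bp3)
    expect_equal(got$length, orc$mh)
    expect_equal(got$bp5, orc$bp5_left)
    expect_equal(got$bp3, orc$bp3_left)
    # leftmost normalization is idempotent and preserves the allele
    again <- compute_microhomology(loc, got$bp5, got$bp3)
    expect_equal(again[c("length", "bp5", "bp3")],
                 got[c("length", "bp5", "bp3")])
    expect_identical(oracle_allele(seq, got$bp5, got$bp3),
                     oracle_allele(seq, bp5, bp3))
  }

  expect_error(compute_microhomology(loc, 5000, 4000), "bp5 < bp3")
  expect_error(compute_microhomology(loc, 0, 4000), "bp5 < bp3")
})

test_that("deletion_size follows 1-based inclusive arithmetic", {
  expect_equal(deletion_size(47654696, 47659152), 4457L)
  expect_equal(deletion_size(47696844, 47715548), 18705L)
  expect_equal(deletion_size(47649352, 47726190), 76839L)
  expect_equal(deletion_size(47672050, 47680329), 8280L)
  expect_equal(deletion_size(47694636, 47697106), 2471L)
  expect_equal(deletion_size(5, 5), 1L)
  expect_error(deletion_size(10, 5), "start <= end")
})

test_that("overlap_repeats returns the containing element inclusively", {
  track <- repeat_track(family = c("AluSx", "AluY"), start = c(100, 900),
                        end = c(399, 1199), strand = c("+", "-"),
                        class = c("SINE", "SINE"))
  expect_equal(overlap_repeats(250, track)$family, "AluSx")
  expect_equal(overlap_repeats(100, track)$family, "AluSx")  # inclusive ends
  expect_equal(overlap_repeats(399, track)$family, "AluSx")
  expect_null(overlap_repeats(500, track))
  expect_null(overlap_repeats(250, repeat_track()))
})

test_that("classify_mechanism follows the homology + same-orientation repeat rule", {
  el <- function(fam, strand) repeat_track(fam, 1, 300, strand, "SINE")
  expect_equal(classify_mechanism(24, el("AluY", "+"), el("AluSp", "+")),
               "NAHR")
  expect_equal(classify_mechanism(0, el("AluSx", "+"), NULL), "NHEJ")
  expect_equal(classify_mechanism(0, NULL, NULL), "NHEJ")
  # homology without qualifying repeats, or intermediate homology, stays open
  expect_equal(classify_mechanism(30, NULL, NULL), "unclassified")
  expect_equal(classify_mechanism(30, el("AluY", "+"), el("AluY", "-")),
               "unclassified")
  expect_equal(classify_mechanism(7, el("AluY", "+"), el("AluY", "+")),
               "unclassified")
  # a breakpoint inside an Alu is not a proxy for NAHR
  expect_equal(classify_mechanism(2, el("AluY", "+"), el("AluY", "+")),
               "NHEJ")
})

test_that("format_nomenclature emits the clinical dialect and HGVS forms", {
  del <- format_nomenclature("deletion", 47654696, 47659152)
  expect_equal(del$paper_style, "g.47654696-47659152del4457")
  expect_equal(del$hgvs, "g.47654696_47659152del")

  one <- format_nomenclature("deletion", 123456, 123456)
  expect_equal(one$paper_style, "g.123456-123456del1")
  expect_equal(one$hgvs, "g.123456del")

  dup <- format_nomenclature("duplication", 47662877, 47694485,
                             inserted_seq = "AAACAAT",
                             ref_id = "ENSG00000095002")
  expect_equal(
    dup$paper_style,
    "g.[47694485_86insAAACAAT;47694485_86insENSG00000095002:g.47662877_47694485]")
  expect_equal(dup$hgvs,
               "g.[47694485_47694486insAAACAAT;47662877_47694485dup]")

  expect_error(format_nomenclature("deletion", NA, 100), "c.212-\\?_366\\+\\?del")
})

test_that("repeat_content counts union bases and per-class elements", {
  empty <- repeat_content(repeat_track(), 1000)
  expect_equal(empty$masked_fraction, 0)
  expect_true(all(empty$counts == 0))

  # overlapping elements are counted once in the masked fraction
  track <- repeat_track(family = c("AluY", "AluY", "L1"),
                        start = c(100, 200, 600), end = c(299, 399, 899),
                        strand = c("+", "+", "-"),
                        class = c("SINE", "SINE", "LINE"))
  rc <- repeat_content(track, 1000)
  expect_equal(rc$masked_fraction, (300 + 300) / 1000)  # 100-399 union, 600-899
  expect_equal(unname(rc$counts[c("SINE", "LINE")]), c(2L, 1L))

  loc <- generate_reference(20000, 10, 0.05, seed = 7)
  expect_equal(repeat_content(loc$repeats, loc)$masked_fraction,
               oracle_masked_fraction(loc$repeats, locus_length(loc)))
})

test_that("annotated calls carry genomic coordinates, mechanism and pathogenicity", {
  set.seed(77)
  loc <- generate_reference(20000, 12, 0.05, seed = 77, offset = 47630108L)
  pair <- pick_nahr_pair(loc$repeats, len = locus_length(loc))
  pl <- plant_rearrangement(loc, event = "deletion", mechanism = "NAHR",
                            repeat5 = pair[1], repeat3 = pair[2],
                            microhomology = 24)
  j <- truth_junction(pl$truth)
  mh <- compute_microhomology(pl$locus, j$bp5, j$bp3)
  jx <- list(bp5 = mh$bp5, bp3 = mh$bp3, microhomology_len = mh$length,
             microhomology_seq = mh$seq, inserted_seq = "",
             ambiguity = mh$ambiguity, event_type = "deletion")
  exons <- data.frame(start = c(1000, 18000), end = c(1200, 18200),
                      label = c("E1", "E2"))
  call <- annotate_rearrangement(pl$locus, jx, support = 12, exons = exons)
  expect_equal(call$mechanism, "NAHR")
  expect_equal(call$size, pl$truth$bp3 - pl$truth$bp5 + 1L)
  expect_equal(call$genomic_start, call$start + 47630108L - 1L)
  expect_match(call$nomenclature_paper_style, "^g\\.\\d+-\\d+del\\d+$")
  expect_type(call$pathogenic_flag, "logical")

  vcf <- tempfile(fileext = ".vcf")
  write_calls_vcf(call, vcf, pl$locus)
  lines <- readLines(vcf)
  expect_true(any(grepl("SVTYPE=DEL", lines)))
  expect_true(any(grepl(sprintf("HOMLEN=%d", call$microhomology_len), lines)))
})
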