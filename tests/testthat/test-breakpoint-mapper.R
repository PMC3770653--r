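# Split-read alignment, chimera clustering and junction consensus.

make_deletion_fixture <- function(seed = 17, del5 = 3000, del3 = 5470,
                                  n_repeats = 6) {
  loc <- generate_reference(10000, n_repeats, 0.05, seed = seed)
  plant_rearrangement(loc, event = "deletion", mechanism = "NHEJ",
                      bp5 = del5, bp3 = del3)
}

test_that("exact substring reads are non-chimeric; junction reads are chimeric", {
  set.seed(1)
  pl <- make_deletion_fixture()
  loc <- pl$locus

  plain <- substr(loc$sequence, 501, 900)
  a <- split_align(plain, loc)
  expect_equal(a$status, "contained")
  expect_false(isTRUE(a$is_chimeric))

  # read spanning the deletion junction with 200 bp on each side
  j <- truth_junction(pl$truth)
  read <- paste0(substr(loc$sequence, j$bp5 - 199, j$bp5),
                 substr(loc$sequence, j$bp3, j$bp3 + 199))
  ch <- split_align(read, loc)
  expect_equal(ch$status, "chimeric")
  expect_equal(ch$type, "deletion")
  expect_equal(ch$bp5, j$bp5)
  expect_equal(ch$bp3, j$bp3)

  # brute-force oracle over all split positions agrees on a small fixture
  small_ref <- substr(loc$sequence, j$bp5 - 600, j$bp3 + 600)
  off <- j$bp5 - 600 - 1L
  orc <- oracle_split(read, small_ref)
  expect_equal(orc$mism, 0L)
  norm <- normalize_junction(small_ref, orc$bp5, orc$bp3)
  expect_equal(norm$bp5 + off, ch$bp5)
  expect_equal(norm$bp3 + off, ch$bp3)

  # duplication junction: suffix maps upstream of prefix
  locd <- generate_reference(10000, 0, 0, seed = 23)
  dup <- plant_rearrangement(locd, event = "duplication",
                             bp5 = 3000, bp3 = 7000, inserted_seq = "AAACAAT")
  jd <- truth_junction(dup$truth)  # leftmost-normalized insertion junction
  rd <- paste0(substr(locd$sequence, jd$bp5 - 195, jd$bp5), jd$ins,
               substr(locd$sequence, jd$bp3, jd$bp3 + 197))
  chd <- split_align(rd, locd)
  expect_equal(chd$status, "chimeric")
  expect_equal(chd$type, "duplication")
  expect_lt(chd$bp3, chd$bp5)  # suffix locus upstream of prefix locus
  expect_equal(chd$bp5, jd$bp5)
  expect_equal(chd$bp3, jd$bp3)
  expect_equal(chd$ins, jd$ins)

  expect_error(split_align(substr(loc$sequence, 1, 30), loc), "min_anchor")
})

test_that("chimera clustering applies support thresholds and separates events", {
  set.seed(7)
  pl <- make_deletion_fixture()
  reads <- simulate_reads(pl$allele, 400, 25, 0, seed = 2)
  aln <- split_align_reads(reads, pl$locus)
  cl <- cluster_chimeras(aln, tol = 10, min_support = 3)
  expect_equal(length(cl), 1L)
  expect_gte(cl[[1]]$support, 10L)
  j <- truth_junction(pl$truth)
  expect_equal(cl[[1]]$bp5, j$bp5)
  expect_equal(cl[[1]]$bp3, j$bp3)

  # below min_support nothing is reported
  few <- aln[aln$is_chimeric, ][1:2, ]
  expect_equal(length(cluster_chimeras(few, min_support = 3)), 0L)
  expect_equal(length(cluster_chimeras(aln[0, ])), 0L)

  # no read contributes to more than one cluster
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)

  # two planted events on one allele give two clusters
  loc <- generate_reference(20000, 0, 0, seed = 31)
  t_del <- truth_record("deletion", 3000, 5600, mechanism_label = "NHEJ")
  t_dup <- truth_record("duplication", 9000, 15000, inserted_seq = "TTGAC",
                        mechanism_label = "NHEJ")
  allele <- derive_allele(loc, list(t_del, t_dup))
  reads2 <- simulate_reads(allele, 400, 25, 0, seed = 3)
  aln2 <- split_align_reads(reads2, loc)
  cl2 <- cluster_chimeras(aln2)
  expect_equal(length(cl2), 2L)
  expect_setequal(vapply(cl2, `[[`, "", "type"), c("deletion", "duplication"))
})

test_that("chimera detection is strand-symmetric", {
  set.seed(9)
  pl <- make_deletion_fixture(seed = 41)
  reads <- simulate_reads(pl$allele, 400, 25, 0, seed = 4,
                          both_strands = FALSE)
  aln_f <- split_align_reads(reads, pl$locus)
  aln_r <- split_align_reads(revcomp(reads), pl$locus)
  cf <- clusters_table(cluster_chimeras(aln_f))
  cr <- clusters_table(cluster_chimeras(aln_r))
  expect_equal(cf[, c("bp5", "bp3", "type", "support")],
               cr[, c("bp5", "bp3", "type", "support")])
})

test_that("junction consensus equals the true allele sequence", {
  set.seed(3)
  pl <- make_deletion_fixture(seed = 55)
  j <- truth_junction(pl$truth)
  true_window <- function(flank) {
    paste0(substr(pl$locus$sequence, j$bp5 - flank + 1, j$bp5),
           substr(pl$locus$sequence, j$bp3, j$bp3 + flank - 1))
  }

  reads0 <- simulate_reads(pl$allele, 400, 25, 0, seed = 5)
  aln0 <- split_align_reads(reads0, pl$locus)
  cl0 <- cluster_chimeras(aln0)[[1]]
  cons0 <- reconstruct_junction(cl0, aln0)
  expect_true(grepl(true_window(120), cons0$consensus, fixed = TRUE))

  # 1% substitution errors, support >= 10: majority vote recovers the truth
  reads1 <- simulate_reads(pl$allele, 400, 30, 0.01, seed = 6)
  aln1 <- split_align_reads(reads1, pl$locus)
  cl1 <- cluster_chimeras(aln1)[[1]]
  expect_gte(cl1$support, 10L)
  cons1 <- reconstruct_junction(cl1, aln1)
  expect_true(grepl(true_window(120), cons1$consensus, fixed = TRUE))
})
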