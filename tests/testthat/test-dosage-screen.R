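# MLPA normalization / dosage calling and aCGH segmentation.

make_peaks <- function(areas_by_sample, ref_area = 1000) {
  # areas_by_sample: named list sample -> named numeric vector probe -> area;
  # eight constant reference probes are appended to carry the normalization
  rows <- list()
  for (s in names(areas_by_sample)) {
    for (r in 1:2) {
      a <- areas_by_sample[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, reaction = r,
        probe = c(names(a), sprintf("REF%02d", 1:8)),
        exon = c(names(a), rep("REF", 8)),
        area = c(unname(a), rep(ref_area, 8)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("normalize_mlpa is exact on closed-form toy batches", {
  base <- stats::setNames(rep(100, 10), sprintf("E%d", 1:10))
  identical_batch <- make_peaks(list(A = base, B = base, C = base, D = base))
  r <- normalize_mlpa(identical_batch)
  expect_true(all(r$ratio == 1))

  # one sample with probe E7 halved: ratio exactly 0.5 for that probe
  halved <- base; halved["E7"] <- 50
  batch <- make_peaks(list(A = halved, B = base, C = base, D = base))
  r <- normalize_mlpa(batch)
  expect_equal(unique(r$ratio[r$sample == "A" & r$probe == "E7"]), 0.5)
  expect_true(all(r$ratio[r$sample == "A" & r$probe != "E7"] == 1))

  # screening blind spot: a batch where every sample carries the deletion
  # self-normalizes to 1.0
  blind <- make_peaks(list(A = halved, B = halved, C = halved))
  r <- normalize_mlpa(blind)
  expect_true(all(r$ratio == 1))

  # scale invariance: scaling one sample's areas leaves its ratios unchanged
  scaled <- make_peaks(list(A = halved * 7, B = base, C = base, D = base))
  scaled$area[scaled$sample == "A" & scaled$exon == "REF"] <- 7000
  expect_equal(normalize_mlpa(scaled)$ratio, normalize_mlpa(batch)$ratio)

  zero <- batch; zero$area[zero$probe == "E3"] <- 0
  expect_error(normalize_mlpa(zero), "E3")
  expect_error(normalize_mlpa(batch[batch$sample %in% c("A", "B"), ]),
               "3 samples")
})

test_that("call_dosage applies strict 0.7/1.2 thresholds with two-reaction confirmation", {
  prof <- function(ratios) data.frame(probe = names(ratios),
                                      exon = names(ratios),
                                      ratio = unname(ratios),
                                      stringsAsFactors = FALSE)
  r1 <- prof(c(E1 = 0.50, E2 = 1.50, E3 = 0.69, E4 = 1.0, E5 = 0.7, E6 = 1.2))
  r2 <- prof(c(E1 = 0.48, E2 = 1.45, E3 = 0.75, E4 = 1.0, E5 = 0.7, E6 = 1.2))
  calls <- call_dosage(r1, r2)
  expect_equal(calls$state,
               c("deletion", "duplication", "normal", "normal", "normal",
                 "normal"))
  expect_equal(calls$confirmed, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # threshold-straddling reaction pair is flagged discordant
  expect_true(calls$discordant[calls$exon == "E3"])
  # exact boundary values call normal (strict inequalities)
  expect_false(calls$discordant[calls$exon == "E5"])

  # missing probe in one reaction: unconfirmed with a warning
  expect_warning(calls2 <- call_dosage(r1, r2[r2$probe != "E2", ]), "E2")
  expect_false(calls2$confirmed[calls2$exon == "E2"])
})

test_that("segment_exon_calls produces maximal runs with compact labels", {
  mk <- function(states, confirmed = TRUE) {
    data.frame(exon = sprintf("E%d", seq_along(states)), state = states,
               confirmed = rep(confirmed, length.out = length(states)),
               stringsAsFactors = FALSE)
  }
  st <- rep("normal", 16)
  st[11:16] <- "deletion"
  seg <- segment_exon_calls(mk(st))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$label, "E11-16 del")

  st <- rep("normal", 16); st[7] <- "deletion"
  expect_equal(segment_exon_calls(mk(st))$label, "E7 del")

  expect_equal(nrow(segment_exon_calls(mk(rep("normal", 16)))), 0L)

  # unconfirmed aberrations do not seed intervals
  st <- rep("normal", 16); st[5] <- "duplication"
  expect_equal(nrow(segment_exon_calls(mk(st, confirmed = FALSE))), 0L)
})

test_that("segment_cgh applies the consecutive-probe filters", {
  flat <- simulate_cgh(30000, NULL, 100, noise_sd = 0)
  expect_equal(nrow(segment_cgh(flat)), 0L)

  gene <- data.frame(start = 1, end = 30000)
  # 12 consecutive in-gene gain probes pass the 10-probe filter...
  seg12 <- data.frame(start = 10010, end = 11190, cn = 3)
  p12 <- simulate_cgh(30000, seg12, 100, noise_sd = 0.05, seed = 1)
  out12 <- segment_cgh(p12, gene_regions = gene)
  expect_equal(nrow(out12), 1L)
  expect_equal(out12$state, "gain")
  expect_equal(out12$cn_estimate, 3L)
  # ...the same gain over 8 probes is filtered out
  seg8 <- data.frame(start = 10010, end = 10790, cn = 3)
  p8 <- simulate_cgh(30000, seg8, 100, noise_sd = 0.05, seed = 1)
  expect_equal(nrow(segment_cgh(p8, gene_regions = gene)), 0L)
  # ...but passes the genome-wide 5-probe minimum outside gene regions
  expect_equal(nrow(segment_cgh(p8)), 1L)

  shuffled <- p12[sample(nrow(p12)), ]
  expect_error(segment_cgh(shuffled), "sorted")

  # output never contains a segment below the applicable minimum
  set.seed(33)
  for (rep in 1:20) {
    pr <- simulate_cgh(20000, data.frame(start = 8000, end = 9500, cn = 1),
                       100, noise_sd = 0.15)
    out <- segment_cgh(pr, gene_regions = data.frame(start = 1, end = 20000))
    if (nrow(out) > 0) expect_true(all(out$n_probes >= 10))
  }
})

test_that("segment_cgh recovers planted segment boundaries", {
  seg <- data.frame(start = 8010, end = 9490, cn = 1)  # 15 probes at 100 bp
  pr <- simulate_cgh(20000, seg, 100, noise_sd = 0.1, seed = 5)
  out <- segment_cgh(pr, gene_regions = data.frame(start = 1, end = 20000))
  expect_equal(nrow(out), 1L)
  expect_equal(out$state, "loss")
  expect_lte(abs(out$start - 8050), 100)  # first probe inside the segment
  expect_lte(abs(out$end - 9450), 100)
})
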