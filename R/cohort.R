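# Cohort-level frequencies and genotype-phenotype summaries.
#
# The cohort table is individual-level: one row per mutation carrier with
# family id, clinical criteria class (Amsterdam I or II), mutation class
# (point mutation vs large genomic rearrangement), a family-level
# pathogenicity flag and a tumor-history string "TYPE,age;TYPE,age;...".
# An individual is affected iff the tumor history is non-empty.

#' Round half-up to a fixed number of decimals
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values (ties away from zero for positive input).
#' @export
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Parse tumor-history strings
#' @param tumors Character vector, each `"TYPE,age;TYPE,age"` or `""`.
#' @return A list of `data.frame`s with columns `type`, `age`.
#' @export
parse_tumors <- function(tumors) {
  lapply(tumors, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(type = character(), age = numeric()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
    data.frame(type = trimws(vapply(parts, `[[`, "", 1L)),
               age = as.numeric(vapply(parts, function(p)
                 if (length(p) > 1L) p[2L] else NA_character_, "")),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a carrier cohort
#'
#' One row per carrier individual across `n_carrier_families` families with
#' a pathogenic rearrangement and `n_point_families` families with a point
#' mutation.  Tumor indicators are independent Bernoulli draws per
#' individual with class-specific rates; ages at diagnosis are normal.
#'
#' @param n_carrier_families Families carrying a rearrangement.
#' @param n_point_families Families carrying a point mutation.
#' @param phenotype_rates Named list with elements `lgr` and `point`, each
#'   a named vector of per-individual tumor rates (e.g.
#'   `c(CRC = 0.55, EC = 0.11)`).
#' @param mean_members Mean carriers per family (>= 1).
#' @param age_mean,age_sd Age-at-diagnosis distribution.
#' @param frac_ams1 Probability a family meets Amsterdam I (vs II).
#' @param seed Optional integer seed.
#' @return Individual-level cohort `data.frame`.
#' @export
simulate_cohort <- function(n_carrier_families = 9L, n_point_families = 74L,
                            phenotype_rates = list(
                              lgr = c(CRC = 0.55, EC = 0.11),
                              point = c(CRC = 0.42, EC = 0.14)),
                            mean_members = 3, age_mean = 43, age_sd = 12,
                            frac_ams1 = 48 / 83, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build <- function(n_fam, class, rates, fam_offset) {
    rows <- list()
    for (f in seq_len(n_fam)) {
      fam <- sprintf("F%03d", fam_offset + f)
      criteria <- if (stats::runif(1) < frac_ams1) "AMS I" else "AMS II"
      members <- 1L + stats::rpois(1L, max(0, mean_members - 1))
      for (m in seq_len(members)) {
        tum <- character(0)
        for (tt in names(rates)) {
          if (stats::runif(1) < rates[[tt]]) {
            age <- max(18L, round(stats::rnorm(1, age_mean, age_sd)))
            tum <- c(tum, sprintf("%s,%d", tt, age))
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = fam, individual_id = sprintf("%s.%d", fam, m),
          criteria = criteria, mutation_class = class, carrier = TRUE,
          pathogenic = TRUE, affected = length(tum) > 0L,
          tumors = paste(tum, collapse = ";"), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  rbind(build(n_carrier_families, "LGR", phenotype_rates$lgr, 0L),
        build(n_point_families, "point", phenotype_rates$point, 1000L))
}

#' Build an individual-level cohort from class margins
#'
#' Deterministically constructs a cohort whose per-class counts (affected,
#' healthy, individuals with colorectal or endometrial cancer, individuals
#' with more than one tumor, mean age at first diagnosis) match the given
#' margins exactly, for re-deriving summary tables from published counts.
#'
#' @param margins `data.frame` with columns `class` (`"point"`/`"LGR"`),
#'   `affected`, `healthy`, `crc`, `ec`, `multi_tumor`, `mean_age`.
#' @return Individual-level cohort `data.frame`.
#' @export
cohort_from_counts <- function(margins) {
  rows <- list()
  for (i in seq_len(nrow(margins))) {
    m <- margins[i, ]
    both <- m$crc + m$ec - m$affected
    if (both < 0L) stop("margins imply fewer tumor carriers than affected")
    crc_only <- m$crc - both
    ec_only <- m$ec - both
    extra_multi <- m$multi_tumor - both
    if (extra_multi < 0L || extra_multi > crc_only) {
      stop("multi-tumor margin not representable with CRC second tumors")
    }
    n_aff <- m$affected
    # symmetric ages around the target mean keep the average exact
    ages <- rep(m$mean_age, n_aff)
    if (n_aff >= 2L) {
      k <- n_aff %/% 2L
      ages[seq_len(k)] <- m$mean_age - 5
      ages[n_aff - seq_len(k) + 1L] <- m$mean_age + 5
    }
    tum <- character(n_aff)
    idx <- 1L
    for (j in seq_len(both)) {
      tum[idx] <- sprintf("CRC,%d;EC,%d", as.integer(ages[idx]),
                          as.integer(ages[idx]) + 3L); idx <- idx + 1L
    }
    for (j in seq_len(extra_multi)) {
      tum[idx] <- sprintf("CRC,%d;CRC,%d", as.integer(ages[idx]),
                          as.integer(ages[idx]) + 4L); idx <- idx + 1L
    }
    for (j in seq_len(crc_only - extra_multi)) {
      tum[idx] <- sprintf("CRC,%d", as.integer(ages[idx])); idx <- idx + 1L
    }
    for (j in seq_len(ec_only)) {
      tum[idx] <- sprintf("EC,%d", as.integer(ages[idx])); idx <- idx + 1L
    }
    n <- n_aff + m$healthy
    rows[[i]] <- data.frame(
      family_id = sprintf("%s_fam", m$class),
      individual_id = sprintf("%s_%03d", m$class, seq_len(n)),
      criteria = "AMS I", mutation_class = m$class, carrier = TRUE,
      pathogenic = TRUE,
      affected = c(rep(TRUE, n_aff), rep(FALSE, m$healthy)),
      tumors = c(tum, rep("", m$healthy)), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Rearrangement frequencies in the screened population
#'
#' Computes the fraction of families with a pathogenic large rearrangement
#' among all families, among all alterations found at the locus, and per
#' clinical criteria class, each as a percentage rounded half-up to one
#' decimal.
#'
#' @param cohort Individual-level cohort `data.frame` of rearrangement
#'   carrier families (point-mutation families, if present, are ignored).
#' @param n_families_total Families screened in the population.
#' @param n_ams1,n_ams2 Amsterdam I / II family counts among them.
#' @param n_locus_alterations Total pathogenic alterations found at the
#'   locus (point mutations plus rearrangements).
#' @return List with integer counts (`n_lgr`, `n_lgr_ams1`, `n_lgr_ams2`)
#'   and percentages (`pct_of_families`, `pct_of_locus_alterations`,
#'   `pct_ams1`, `pct_ams2`).
#' @export
lgr_frequencies <- function(cohort, n_families_total = 83L, n_ams1 = 48L,
                            n_ams2 = 35L, n_locus_alterations = 44L) {
  if (any(c(n_families_total, n_ams1, n_ams2, n_locus_alterations) == 0L)) {
    stop("zero denominator in frequency computation")
  }
  lgr <- cohort[cohort$mutation_class == "LGR" & cohort$pathogenic, ,
                drop = FALSE]
  fam <- unique(lgr[, c("family_id", "criteria")])
  n_lgr <- nrow(fam)
  n1 <- sum(fam$criteria == "AMS I")
  n2 <- sum(fam$criteria == "AMS II")
  list(n_lgr = n_lgr, n_lgr_ams1 = n1, n_lgr_ams2 = n2,
       pct_of_families = round_half_up(100 * n_lgr / n_families_total, 1L),
       pct_of_locus_alterations =
         round_half_up(100 * n_lgr / n_locus_alterations, 1L),
       pct_ams1 = round_half_up(100 * n1 / n_ams1, 1L),
       pct_ams2 = round_half_up(100 * n2 / n_ams2, 1L))
}

#' Genotype-phenotype summary table
#'
#' Pure counting by mutation class: affected/healthy, individuals with one
#' vs more than one tumor, individuals developing colorectal (CRC) or
#' endometrial (EC) cancer, and mean age at first diagnosis.
#' Tumor-frequency percentages are reported as integer percent,
#' floor-rounded.
#'
#' @param cohort Individual-level cohort `data.frame`.
#' @return List with `counts` (a `data.frame`, one row per metric, one
#'   column per class), `tables` (2x2 matrices for association tests) and
#'   `ages` (numeric vectors of age at first diagnosis per class).
#' @export
phenotype_table <- function(cohort) {
  classes <- c("point", "LGR")
  tl <- parse_tumors(cohort$tumors)
  n_tumors <- vapply(tl, nrow, 0L)
  affected <- n_tumors > 0L
  has_crc <- vapply(tl, function(d) any(d$type == "CRC"), FALSE)
  has_ec <- vapply(tl, function(d) any(d$type == "EC"), FALSE)
  first_age <- vapply(tl, function(d)
    if (nrow(d) > 0L) min(d$age, na.rm = TRUE) else NA_real_, 0)
  one <- function(cls) {
    k <- cohort$mutation_class == cls
    n_aff <- sum(affected & k); n_healthy <- sum(!affected & k)
    n_tot <- n_aff + n_healthy
    c(affected = n_aff, healthy = n_healthy,
      one_tumor = sum(k & n_tumors == 1L),
      multi_tumor = sum(k & n_tumors > 1L),
      crc = sum(k & has_crc), ec = sum(k & has_ec),
      pct_crc = if (n_tot > 0L) floor(100 * sum(k & has_crc) / n_tot) else 0,
      pct_ec = if (n_tot > 0L) floor(100 * sum(k & has_ec) / n_tot) else 0,
      mean_age = if (any(k & affected))
        mean(first_age[k & affected]) else NA_real_)
  }
  cnt <- vapply(classes, one, numeric(9L))
  counts <- data.frame(metric = rownames(cnt), point = cnt[, "point"],
                       LGR = cnt[, "LGR"], row.names = NULL,
                       stringsAsFactors = FALSE)
  two_by_two <- function(a, b) {
    m <- matrix(c(a, b), nrow = 2L, byrow = TRUE,
                dimnames = list(c("point", "LGR"), NULL))
    m
  }
  g <- function(metric, cls) cnt[metric, cls]
  tables <- list(
    affected_vs_healthy = two_by_two(
      c(g("affected", "point"), g("healthy", "point")),
      c(g("affected", "LGR"), g("healthy", "LGR"))),
    one_vs_multi_tumor = two_by_two(
      c(g("one_tumor", "point"), g("multi_tumor", "point")),
      c(g("one_tumor", "LGR"), g("multi_tumor", "LGR"))),
    crc = two_by_two(
      c(g("crc", "point"),
        g("affected", "point") + g("healthy", "point") - g("crc", "point")),
      c(g("crc", "LGR"),
        g("affected", "LGR") + g("healthy", "LGR") - g("crc", "LGR"))),
    ec = two_by_two(
      c(g("ec", "point"),
        g("affected", "point") + g("healthy", "point") - g("ec", "point")),
      c(g("ec", "LGR"),
        g("affected", "LGR") + g("healthy", "LGR") - g("ec", "LGR"))))
  ages <- list(
    point = first_age[cohort$mutation_class == "point" & affected],
    LGR = first_age[cohort$mutation_class == "LGR" & affected])
  list(counts = counts, tables = tables, ages = ages)
}

#' Association tests on 2x2 contingency tables
#'
#' The primary method is the chi-square test with continuity correction;
#' the uncorrected chi-square and Fisher's exact test are reported
#' alongside for transparency.  When any expected cell count falls below 1
#' only Fisher's exact test is reported, with a note.  An optional
#' two-sample equal-variance t-test compares ages between classes.
#'
#' @param tables Named list of 2x2 matrices (as from [phenotype_table()]).
#' @param ages Optional named list of two numeric vectors for the age
#'   comparison.
#' @return A `data.frame` with columns `comparison`, `method`,
#'   `statistic`, `p_value`, `note`; the row with
#'   `method == "chisq_corrected"` (or `"fisher"` for sparse tables) is the
#'   primary result per comparison.
#' @export
association_tests <- function(tables, ages = NULL) {
  rows <- list()
  add <- function(comparison, method, statistic, p, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, method = method, statistic = statistic,
      p_value = p, note = note, stringsAsFactors = FALSE)
  }
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (any(tab < 0)) stop("negative cell count")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    fis <- stats::fisher.test(tab)
    if (any(expected < 1)) {
      add(nm, "fisher", NA_real_, fis$p.value,
          "expected cell < 1: Fisher's exact test only")
      next
    }
    cc <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    un <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    add(nm, "chisq_corrected", unname(cc$statistic), cc$p.value)
    add(nm, "chisq_uncorrected", unname(un$statistic), un$p.value)
    add(nm, "fisher", NA_real_, fis$p.value)
  }
  if (!is.null(ages) && length(ages) == 2L &&
      all(lengths(ages) >= 2L) &&
      stats::sd(unlist(ages)) > 0) {
    tt <- stats::t.test(ages[[1L]], ages[[2L]], var.equal = TRUE)
    add("age_at_first_diagnosis", "t_equal_var",
        unname(tt$statistic), tt$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
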