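# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive string operations and exhaustive scans and
# share no code with the package internals they check.

# Derived allele for a junction in retained-base convention.
oracle_allele <- function(seq, bp5, bp3, ins = "") {
  n <- nchar(seq)
  paste0(substr(seq, 1, bp5), ins, substr(seq, bp3, n))
}

# Exhaustive junction-shift scan: microhomology length is the number of
# alternative (bp5+k, bp3+k) pairs producing the identical allele, minus
# one; also reports the leftmost admissible bp5.
oracle_microhomology <- function(seq, bp5, bp3, window = 200L) {
  base <- oracle_allele(seq, bp5, bp3)
  n <- nchar(seq)
  ks <- seq(-min(window, bp5), min(window, n - bp3 + 1L))
  valid <- vapply(ks, function(k)
    identical(oracle_allele(seq, bp5 + k, bp3 + k), base), FALSE)
  stopifnot(!valid[1L], !valid[length(valid)])  # window wide enough
  list(mh = sum(valid) - 1L,
       bp5_left = bp5 + min(ks[valid]),
       bp3_left = bp3 + min(ks[valid]))
}

# Two-sided Fisher exact p by exhaustive hypergeometric tail enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force split-read oracle: over every cut position, place the read
# prefix and suffix independently at their minimum-mismatch reference
# offsets and return the cut minimizing total mismatches.  O(L^2 * n);
# only usable on small fixtures.
oracle_split <- function(read, ref, min_anchor = 20L) {
  L <- nchar(read); n <- nchar(ref)
  rr <- charToRaw(read); fr <- charToRaw(ref)
  best <- NULL
  for (cut in min_anchor:(L - min_anchor)) {
    pre <- rr[1:cut]; suf <- rr[(cut + 1):L]
    pm <- vapply(1:(n - cut + 1L), function(s)
      sum(pre != fr[s:(s + cut - 1L)]), 0L)
    sm <- vapply(1:(n - (L - cut) + 1L), function(s)
      sum(suf != fr[s:(s + L - cut - 1L)]), 0L)
    tot <- min(pm) + min(sm)
    if (is.null(best) || tot < best$mism) {
      best <- list(cut = cut, mism = tot,
                   bp5 = which.min(pm) + cut - 1L,
                   bp3 = which.min(sm))
    }
  }
  best
}

# Per-base masked-fraction count from a repeat track.
oracle_masked_fraction <- function(track, len) {
  mask <- logical(len)
  for (i in seq_len(nrow(track))) {
    mask[track$start[i]:track$end[i]] <- TRUE
  }
  mean(mask)
}

# Pick a same-strand ordered repeat pair suitable for NAHR planting, or
# NULL if the track has none.
pick_nahr_pair <- function(track, min_gap = 700L, margin = 400L, len = NULL) {
  n <- nrow(track)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (track$strand[i] == track$strand[j] &&
          track$start[j] - track$end[i] >= min_gap &&
          track$start[i] >= margin &&
          (is.null(len) || track$end[j] <= len - margin)) {
        return(c(i, j))
      }
    }
  }
  NULL
}
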