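# Independent brute-force oracles used to validate the production engines.
# These deliberately share no search code with the package: the seed oracle
# walks every anti-diagonal, the structure oracles enumerate every admissible
# pair set and score it with the package's re-scoring functions.

# Watson-Crick only (seed stage).
wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# Watson-Crick or G:U wobble (thermodynamic stages).
thermo_pair <- function(a, b) {
  wc_pair(a, b) | (a == "G" & b == "U") | (a == "U" & b == "G")
}

# Naive O(n*m) diagonal scan: every maximal run of >= b consecutive WC pairs
# between the miRNA (5'->3') and target read antiparallel.
naive_seed_scan <- function(mirna, target, b) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  t <- strsplit(target, "", fixed = TRUE)[[1]]
  M <- length(m); Tn <- length(t)
  rows <- list()
  for (cc in 0:(M + Tn - 2)) {       # anti-diagonal: i + j == cc
    i_lo <- max(0L, cc - (Tn - 1L))
    i_hi <- min(M - 1L, cc)
    run_start <- NA_integer_
    for (i in i_lo:(i_hi + 1L)) {
      ok <- i <= i_hi && wc_pair(m[i + 1L], t[cc - i + 1L])
      if (ok && is.na(run_start)) run_start <- i
      if (!ok && !is.na(run_start)) {
        len <- i - run_start
        if (len >= b) {
          rows[[length(rows) + 1L]] <- c(
            target_start = cc - (i - 1L), target_end = cc - run_start + 1L,
            mirna_start = run_start, mirna_end = i, length = len)
        }
        run_start <- NA_integer_
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(target_start = integer(), target_end = integer(),
                      mirna_start = integer(), mirna_end = integer(),
                      length = integer()))
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- out[order(out$target_start, out$mirna_start, out$target_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# All antiparallel non-crossing intermolecular pair sets between sequences
# m and w (character vectors), as a list of 2-column 0-based matrices.
enumerate_duplex_structures <- function(m, w) {
  M <- length(m); W <- length(w)
  rec <- function(i_min, j_max) {
    acc <- list(matrix(integer(), 0, 2))
    if (i_min >= M || j_max < 0) return(acc)
    for (i in i_min:(M - 1L)) {
      for (j in j_max:0) {
        if (!thermo_pair(m[i + 1L], w[j + 1L])) next
        for (tail in rec(i + 1L, j - 1L)) {
          acc[[length(acc) + 1L]] <- rbind(c(i, j), tail)
        }
      }
    }
    acc
  }
  rec(0L, W - 1L)
}

# Brute-force duplex MFE: min score over every enumerated structure.
brute_duplex_mfe <- function(mirna, site, model) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  w <- strsplit(site, "", fixed = TRUE)[[1]]
  best <- Inf
  for (p in enumerate_duplex_structures(m, w)) {
    if (nrow(p) == 0) next
    e <- score_duplex(p, mirna, site, model)
    if (e < best) best <- e
  }
  best
}

# All non-crossing intramolecular pair sets with >= 3 unpaired hairpin bases
# (every pair spans >= 4), as 2-column 0-based matrices.
enumerate_fold_structures <- function(s) {
  n <- length(s)
  rec <- function(i, j) {
    if (j - i < 4L) return(list(matrix(integer(), 0, 2)))
    acc <- rec(i + 1L, j)                       # i unpaired
    for (k in (i + 4L):j) {
      if (!thermo_pair(s[i + 1L], s[k + 1L])) next
      inner <- rec(i + 1L, k - 1L)
      outer <- if (k + 1L <= j) rec(k + 1L, j) else list(matrix(integer(), 0, 2))
      for (a in inner) for (b in outer) {
        acc[[length(acc) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    acc
  }
  rec(0L, n - 1L)
}

# Brute-force fold MFE: min score over every enumerated structure (empty
# structure scores 0, so the result is never positive).
brute_fold_mfe <- function(seq, model) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  best <- 0
  for (p in enumerate_fold_structures(s)) {
    if (nrow(p) == 0) next
    e <- score_structure(p, seq, model)
    if (e < best) best <- e
  }
  best
}

# Random RNA string helper for property tests.
rand_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# GC fraction of a sequence string.
gc_fraction <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(ch %in% c("G", "C"))
}

# Dinucleotide count table of a sequence string.
dinuc_counts <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) return(table(character()))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# Site-set nesting: every site in `a` has a same-miRNA/target/strand site in
# `b` whose footprint overlaps it.
sites_nested_in <- function(a, b) {
  if (nrow(a) == 0) return(TRUE)
  all(vapply(seq_len(nrow(a)), function(r) {
    cand <- b[b$mirna_id == a$mirna_id[r] & b$target_id == a$target_id[r] &
                b$strand == a$strand[r], , drop = FALSE]
    any(cand$site_start < a$site_end[r] & cand$site_end > a$site_start[r])
  }, logical(1)))
}
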