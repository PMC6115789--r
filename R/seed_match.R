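#' Build an exact k-mer index over a target sequence
#'
#' Maps every length-`b` substring of the target (windows containing `N` are
#' excluded, since `N` never pairs) to the sorted 0-based start positions at
#' which it occurs. The index is the "quick match" data structure: looking up
#' each length-`b` window of the reverse complement of a miRNA retrieves every
#' target location where at least `b` consecutive Watson-Crick pairs can form.
#' Unlike a heuristic similarity search, the scan is exact and provably
#' complete.
#'
#' @param target A target sequence (character scalar or `RNAString`).
#' @param b Seed length (consecutive perfect matches); must be at least 4.
#' @return A `match_index` object (environment-backed hash plus metadata).
#' @examples
#' idx <- build_match_index("ACGUACGU", b = 4)
#' idx$env[["ACGU"]]  # 0 4
#' @export
build_match_index <- function(target, b) {
  b <- check_seed_length(b)
  target <- as_residues(target)
  n <- nchar(target)
  if (n < b) stop("target shorter than the seed length b = ", b)
  starts0 <- 0:(n - b)
  kmers <- substring(target, starts0 + 1L, starts0 + b)
  keep <- !grepl("N", kmers, fixed = TRUE)
  env <- list2env(split(starts0[keep], kmers[keep]),
                  hash = TRUE, parent = emptyenv())
  # cache the residues for maximal extension (key cannot collide: all k-mer
  # keys are length-b strings over A C G U)
  env[[".target_chars"]] <- strsplit(target, "", fixed = TRUE)[[1]]
  structure(list(env = env, b = b, target_len = n),
            class = "match_index")
}

check_seed_length <- function(b) {
  b <- as.integer(b)
  if (length(b) != 1L || is.na(b) || b < 4L) {
    stop("seed length b must be a single integer >= 4")
  }
  b
}

#' Find all maximal seed matches between a miRNA and a target
#'
#' Finds every maximal run of consecutive Watson-Crick base pairs (A:U, G:C;
#' no G:U wobble, no `N`) of length at least `b` between the miRNA and the
#' target read antiparallel. Each length-`b` window of the miRNA's reverse
#' complement is looked up in the target k-mer index and every hit is extended
#' in both directions to maximality; runs reached from several windows are
#' reported once.
#'
#' Coordinates are 0-based half-open: `target_start/target_end` on the target
#' forward strand, `mirna_start/mirna_end` on the miRNA 5'->3'. The miRNA 5'
#' end pairs toward the target 3' end, so the position of a run on the miRNA
#' is the reverse-complement image of its position on the target.
#'
#' @param mirna A mature miRNA sequence (character scalar or `RNAString`).
#' @param target A target sequence, or `NULL` if `index` is given.
#' @param b Minimum run length (seed); default 7.
#' @param index Optional prebuilt [build_match_index()] for the target (must
#'   have the same `b`); when scanning many miRNAs against one target, build
#'   the index once.
#' @return A data frame with columns `target_start`, `target_end`,
#'   `mirna_start`, `mirna_end`, `length`, sorted by
#'   `(target_start, mirna_start, target_end)`; zero rows when no run of
#'   length `b` exists.
#' @export
find_seed_matches <- function(mirna, target = NULL, b = 7L, index = NULL) {
  b <- check_seed_length(b)
  mirna <- as_residues(mirna)
  if (is.null(index)) {
    if (is.null(target)) stop("supply a target sequence or a match index")
    target <- as_residues(target)
    if (nchar(target) < b) return(empty_seed_matches())
    index <- build_match_index(target, b)
  } else {
    if (!inherits(index, "match_index")) stop("index must be a match_index")
    if (index$b != b) stop("index was built with b = ", index$b,
                           ", not b = ", b)
  }

  m_len <- nchar(mirna)
  if (m_len < b) return(empty_seed_matches())
  rc <- reverse_complement(mirna)
  rc_ch <- strsplit(rc, "", fixed = TRUE)[[1]]
  # target characters are needed for maximal extension
  t_ch <- get_index_target_chars(index)
  t_len <- index$target_len

  seen <- new.env(hash = TRUE, parent = emptyenv())
  rows <- list()
  for (p in 0:(m_len - b)) {
    key <- substr(rc, p + 1L, p + b)
    if (grepl("N", key, fixed = TRUE)) next
    hits <- index$env[[key]]
    if (is.null(hits)) next
    for (s in hits) {
      # extend the run [p, p+b) on rc / [s, s+b) on target to maximality
      ps <- p; ss <- s
      while (ps > 0L && ss > 0L && rc_ch[ps] == t_ch[ss] &&
             rc_ch[ps] != "N") { ps <- ps - 1L; ss <- ss - 1L }
      pe <- p + b; se <- s + b
      while (pe < m_len && se < t_len && rc_ch[pe + 1L] == t_ch[se + 1L] &&
             rc_ch[pe + 1L] != "N") { pe <- pe + 1L; se <- se + 1L }
      tag <- paste0(ss - ps, ":", ss)   # (diagonal, maximal extent) key
      if (!is.null(seen[[tag]])) next
      seen[[tag]] <- TRUE
      rows[[length(rows) + 1L]] <- c(ss, se, m_len - pe, m_len - ps,
                                     pe - ps)
    }
  }
  if (!length(rows)) return(empty_seed_matches())
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("target_start", "target_end", "mirna_start", "mirna_end",
                  "length")
  out <- out[order(out$target_start, out$mirna_start, out$target_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_seed_matches <- function() {
  data.frame(target_start = integer(), target_end = integer(),
             mirna_start = integer(), mirna_end = integer(),
             length = integer())
}

# The extension step needs the target residues, cached by the index builder.
get_index_target_chars <- function(index) {
  ch <- index$env[[".target_chars"]]
  if (is.null(ch)) stop("match index lacks cached target residues")
  ch
}
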