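# Encode residues for the C++ engines: A=0 C=1 G=2 U=3 N=4.
encode_bases <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(ch, c("A", "C", "G", "U"))
  code[is.na(code)] <- 5L
  code - 1L
}

# Loop tables with disallowed sizes as +Inf, ready for C++.
finite_table <- function(v) {
  v[is.na(v)] <- Inf
  v
}

# Hairpin initiation for sizes 1..n with logarithmic extrapolation.
hairpin_table <- function(model, n) {
  tab <- finite_table(model$hairpin)
  k <- length(tab)
  if (n <= k) return(tab[seq_len(n)])
  c(tab, tab[k] + model$lxc * log((k + 1):n / k))
}

pair_symbol <- function(pt) {
  c("|", "|", ":", ":", "|", "|")[pt]  # WC '|', wobble ':'
}

#' Score an explicit miRNA-target duplex structure
#'
#' Recomputes the nearest-neighbor free energy of an intermolecular duplex
#' from its pair list: duplex initiation, stacking increments for adjacent
#' pairs, bulge/internal-loop penalties (with asymmetry) between non-adjacent
#' pairs, and a terminal AU/GU penalty at every helix end (duplex ends and
#' pairs flanking a loop). This is the scoring oracle against which the
#' dynamic-programming result of [hybridize()] is verifiable.
#'
#' @param pairs Two-column matrix of 0-based `(mirna_pos, target_pos)` pairs,
#'   strictly increasing in `mirna_pos` and strictly decreasing in
#'   `target_pos` (antiparallel, non-crossing). A zero-row matrix denotes the
#'   empty duplex.
#' @param mirna,site The two sequences (character or `RNAString`); positions
#'   in `pairs` index into these.
#' @param model An [energy_model][load_energy_model()].
#' @return Free energy in kcal/mol; `Inf` for the empty duplex.
#' @export
score_duplex <- function(pairs, mirna, site, model = load_energy_model()) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0) return(Inf)
  mirna <- as_residues(mirna)
  site <- as_residues(site)
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  w <- strsplit(site, "", fixed = TRUE)[[1]]

  i <- pairs[, 1]; j <- pairs[, 2]
  if (any(i < 0 | i >= length(m) | j < 0 | j >= length(w))) {
    stop("invalid duplex structure: pair position out of bounds")
  }
  if (nrow(pairs) > 1 && (any(diff(i) <= 0) || any(diff(j) >= 0))) {
    stop("invalid duplex structure: pairs must be antiparallel and non-crossing")
  }
  pt <- pair_type(m[i + 1], w[j + 1])
  if (any(pt == 0)) stop("invalid duplex structure: disallowed base pair")

  au <- function(t) if (t >= 3) model$terminal_au else 0
  e <- model$duplex_init + au(pt[1]) + au(pt[nrow(pairs)])
  if (nrow(pairs) > 1) {
    for (k in seq_len(nrow(pairs) - 1)) {
      l1 <- i[k + 1] - i[k] - 1L
      l2 <- j[k] - j[k + 1] - 1L
      if (l1 == 0 && l2 == 0) {
        e <- e + model$stack[pt[k], pair_type(w[j[k + 1] + 1], m[i[k + 1] + 1])]
      } else {
        if (l1 + l2 > model$max_loop) {
          stop("invalid duplex structure: loop larger than max_loop")
        }
        loop <- if (l1 == 0 || l2 == 0) {
          loop_energy(model, "bulge", l1 + l2)
        } else {
          internal_loop_energy(model, l1, l2)
        }
        e <- e + loop + au(pt[k]) + au(pt[k + 1])
      }
    }
  }
  unname(e)
}

as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0)) {
    return(matrix(integer(), 0, 2))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must be a two-column matrix")
  storage.mode(pairs) <- "integer"
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2])) {
    stop("invalid structure: a position is used by more than one pair")
  }
  pairs
}

#' Minimum-free-energy miRNA-target hybrid duplex
#'
#' Computes the minimum-free-energy intermolecular structure between a miRNA
#' and a target window under the nearest-neighbor model, restricted to the
#' standard hybridization model: no intramolecular pairs within either
#' strand, non-crossing antiparallel pairs (Watson-Crick and G:U wobble),
#' and loops limited to stacks, bulges and internal loops of total unpaired
#' size at most `model$max_loop`. Solved by dynamic programming over
#' (miRNA position, window position) with deterministic traceback; the
#' returned energy always equals [score_duplex()] of the returned pairs.
#'
#' @param mirna Mature miRNA sequence, 5'->3'.
#' @param target Target sequence (forward strand).
#' @param window Integer vector `c(start, end)`: 0-based half-open interval
#'   of `target` to hybridize against (at most 200 nt; the seed scan already
#'   localizes candidate sites).
#' @param model An [energy_model][load_energy_model()].
#' @param mirna_id,target_id Optional identifiers carried into the result.
#' @return An object of class `hybrid_duplex`: list with `mirna_id`,
#'   `target_id`, `mfe` (kcal/mol; `Inf` if no pair is possible), `pairs`
#'   (0-based `(mirna_pos, target_pos)` matrix, target positions on the
#'   forward strand of the full target), `site_start`/`site_end` (0-based
#'   half-open duplex footprint on the target), and the three alignment
#'   strings `mirna_aln` (5'->3'), `pair_aln` (`|` Watson-Crick, `:` G:U)
#'   and `target_aln` (3'->5').
#' @examples
#' hybridize("ACGUACGUACGUACGUACGUAC",
#'           reverse_complement("ACGUACGUACGUACGUACGUAC"), c(0, 22))
#' @export
hybridize <- function(mirna, target, window = NULL,
                      model = load_energy_model(),
                      mirna_id = NA_character_, target_id = NA_character_) {
  mirna <- as_residues(mirna)
  target <- as_residues(target)
  if (is.null(window)) window <- c(0L, nchar(target))
  window <- as.integer(window)
  if (length(window) != 2 || window[1] < 0 || window[2] <= window[1] ||
      window[2] > nchar(target)) {
    stop("window must be a valid 0-based half-open interval on the target")
  }
  if (window[2] - window[1] > 200L) {
    stop("hybridization window longer than 200 nt; narrow the site window")
  }
  site <- substr(target, window[1] + 1L, window[2])

  res <- .duplex_dp(encode_bases(mirna), encode_bases(site),
                    model$stack, finite_table(model$bulge),
                    finite_table(model$internal),
                    model$ninio_per_nt, model$ninio_max, model$terminal_au,
                    model$duplex_init, model$max_loop)
  pairs <- res$pairs
  if (nrow(pairs)) {
    aln <- render_duplex_alignment(mirna, site, pairs)
    footprint <- c(window[1] + min(pairs[, 2]), window[1] + max(pairs[, 2]) + 1L)
    pairs[, 2] <- pairs[, 2] + window[1]
  } else {
    aln <- list(mirna = "", pair = "", target = "")
    footprint <- c(NA_integer_, NA_integer_)
  }
  structure(list(mirna_id = mirna_id, target_id = target_id,
                 site_start = footprint[1], site_end = footprint[2],
                 window_start = window[1], window_end = window[2],
                 pairs = pairs, mfe = res$mfe,
                 mirna_aln = aln$mirna, pair_aln = aln$pair,
                 target_aln = aln$target),
            class = "hybrid_duplex")
}

# Three-line rendering of the duplex footprint; miRNA on top 5'->3', target
# underneath 3'->5', loops padded with '-'.
render_duplex_alignment <- function(mirna, site, pairs) {
  m <- strsplit(mirna, "", fixed = TRUE)[[1]]
  w <- strsplit(site, "", fixed = TRUE)[[1]]
  i <- pairs[, 1] + 1L; j <- pairs[, 2] + 1L   # 1-based
  top <- m[i[1]]
  mid <- pair_symbol(pair_type(m[i[1]], w[j[1]]))
  bot <- w[j[1]]
  if (nrow(pairs) > 1) {
    for (k in seq_len(nrow(pairs) - 1)) {
      mg <- if (i[k + 1] - i[k] > 1) m[(i[k] + 1):(i[k + 1] - 1)] else character()
      wg <- if (j[k] - j[k + 1] > 1) w[(j[k] - 1):(j[k + 1] + 1)] else character()
      gap <- max(length(mg), length(wg))
      if (gap > 0) {
        top <- paste0(top, paste(c(mg, rep("-", gap - length(mg))), collapse = ""))
        mid <- paste0(mid, strrep(" ", gap))
        bot <- paste0(bot, paste(c(wg, rep("-", gap - length(wg))), collapse = ""))
      }
      top <- paste0(top, m[i[k + 1]])
      mid <- paste0(mid, pair_symbol(pair_type(m[i[k + 1]], w[j[k + 1]])))
      bot <- paste0(bot, w[j[k + 1]])
    }
  }
  list(mirna = top, pair = mid, target = bot)
}

#' @export
print.hybrid_duplex <- function(x, ...) {
  cat("miRNA-target hybrid duplex\n")
  if (!is.na(x$mirna_id)) cat("  miRNA:", x$mirna_id, "\n")
  if (!is.na(x$target_id)) cat("  target:", x$target_id, "\n")
  if (is.finite(x$mfe)) {
    cat(sprintf("  mfe: %.2f kcal/mol  site: [%d, %d)\n",
                x$mfe, x$site_start, x$site_end))
    cat("  5' ", x$mirna_aln, " 3' (miRNA)\n", sep = "")
    cat("     ", x$pair_aln, "\n", sep = "")
    cat("  3' ", x$target_aln, " 5' (target)\n", sep = "")
  } else {
    cat("  no admissible base pair (mfe = +Inf)\n")
  }
  invisible(x)
}

#' Does a duplex pass the minimum-free-energy cutoff?
#'
#' @param duplex A [hybridize()] result (or a bare mfe value).
#' @param e Cutoff in kcal/mol (default -25). The comparison is inclusive:
#'   `mfe <= e` passes, so a duplex exactly at the cutoff is kept; a pairless
#'   duplex (`mfe = Inf`) never passes.
#' @return Logical.
#' @export
passes_energy_cutoff <- function(duplex, e = -25) {
  mfe <- if (inherits(duplex, "hybrid_duplex")) duplex$mfe else as.numeric(duplex)
  is.finite(mfe) & mfe <= e
}
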