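#' Minimum-free-energy fold of the target region around a site
#'
#' Folds the local target window (the site extended by `flank` nucleotides on
#' each side, clipped to the sequence ends) and reports its minimum free
#' energy, a proxy for how much intramolecular structure competes with miRNA
#' binding at the site. The model admits hairpin loops (at least 3 unpaired
#' bases), stacks, bulges, internal loops (total unpaired size at most
#' `model$max_loop`) and multibranch loops scored by a linear model
#' (closing offset + per-branch + per-unpaired-base terms). The empty
#' structure scores 0, so the result is never positive. Zuker-style dynamic
#' programming with a deterministic traceback (co-optimal structures resolve
#' in the fixed scan order stack, then interior, then hairpin, then
#' multibranch, smaller loop offsets first).
#'
#' @param target Target sequence (forward strand).
#' @param site Integer `c(start, end)`: 0-based half-open site interval.
#' @param flank Window extension on each side of the site (default 70 nt).
#' @param model An [energy_model][load_energy_model()].
#' @param target_id Optional identifier carried into the result.
#' @return An object of class `fold_result`: list with `target_id`,
#'   `window_start`, `window_end` (0-based half-open), `fold_mfe` (kcal/mol,
#'   always <= 0) and `pair_map` (0-based two-column matrix of intramolecular
#'   pairs, positions on the full target).
#' @export
fold_local <- function(target, site, flank = 70L,
                       model = load_energy_model(),
                       target_id = NA_character_) {
  target <- as_residues(target)
  site <- as.integer(site)
  flank <- as.integer(flank)
  if (flank < 0) stop("flank must be >= 0")
  n <- nchar(target)
  if (length(site) != 2 || site[1] < 0 || site[2] <= site[1] || site[2] > n) {
    stop("site must be a valid 0-based half-open interval on the target")
  }
  ws <- max(0L, site[1] - flank)
  we <- min(n, site[2] + flank)
  if (we - ws > 300L) {
    stop("folding window longer than 300 nt; reduce the flank")
  }
  window <- substr(target, ws + 1L, we)

  res <- .fold_dp(encode_bases(window), model$stack,
                  finite_table(model$bulge), finite_table(model$internal),
                  hairpin_table(model, max(nchar(window), 3L)),
                  model$ml_close, model$ml_branch, model$ml_unpaired,
                  model$ninio_per_nt, model$ninio_max, model$terminal_au,
                  model$max_loop)
  pairs <- res$pairs
  if (nrow(pairs)) pairs <- pairs + ws
  structure(list(target_id = target_id, window_start = ws, window_end = we,
                 site_start = site[1], site_end = site[2],
                 fold_mfe = res$mfe, pair_map = pairs),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("local fold: window [%d, %d), mfe %.2f kcal/mol, %d pairs\n",
              x$window_start, x$window_end, x$fold_mfe, nrow(x$pair_map)))
  invisible(x)
}

#' Score an explicit intramolecular secondary structure
#'
#' Recomputes the nearest-neighbor free energy of a secondary structure from
#' its pair list by loop decomposition: hairpins, stacks, bulges, internal
#' loops (with asymmetry), multibranch loops under the linear model, and
#' terminal AU/GU penalties at every helix end (including hairpin closings,
#' multiloop branches and exterior-loop branches). The scoring oracle for
#' [fold_local()].
#'
#' @param pairs Two-column matrix of 0-based `(i, j)` pairs, `i < j`; a
#'   zero-row matrix is the empty structure.
#' @param seq The folded sequence.
#' @param model An [energy_model][load_energy_model()].
#' @return Free energy in kcal/mol (0 for the empty structure).
#' @export
score_structure <- function(pairs, seq, model = load_energy_model()) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0) return(0)
  s <- strsplit(as_residues(seq), "", fixed = TRUE)[[1]]
  i <- pmin(pairs[, 1], pairs[, 2])
  j <- pmax(pairs[, 1], pairs[, 2])
  if (any(i < 0 | j >= length(s))) stop("invalid structure: position out of bounds")
  if (any(j - i < 4)) stop("invalid structure: hairpin loop smaller than 3")
  pos <- c(i, j)
  if (anyDuplicated(pos)) stop("invalid structure: position used twice")
  ord <- order(i)
  i <- i[ord]; j <- j[ord]
  k <- length(i)
  # parent = enclosing pair with the smallest span; crossing check on the way
  parent <- rep(0L, k)
  for (a in seq_len(k)) {
    best <- 0L; span <- Inf
    for (b in seq_len(k)) {
      if (a == b) next
      if (i[b] < i[a] && j[b] > j[a]) {           # b encloses a
        if (j[b] - i[b] < span) { span <- j[b] - i[b]; best <- b }
      } else if (i[b] > i[a] && j[b] < j[a]) {    # b inside a
      } else if (j[b] < i[a] || i[b] > j[a]) {    # disjoint
      } else {
        stop("invalid structure: crossing pairs")
      }
    }
    parent[a] <- best
  }
  pt <- pair_type(s[i + 1], s[j + 1])
  if (any(pt == 0)) stop("invalid structure: disallowed base pair")
  au <- function(t) ifelse(t >= 3, model$terminal_au, 0)

  e <- 0
  for (a in seq_len(k)) {
    ch <- which(parent == a)
    ch <- ch[order(i[ch])]
    if (length(ch) == 0) {                       # hairpin
      e <- e + loop_energy(model, "hairpin", j[a] - i[a] - 1) + au(pt[a])
    } else if (length(ch) == 1) {                # stack / bulge / internal
      b <- ch
      l1 <- i[b] - i[a] - 1L
      l2 <- j[a] - j[b] - 1L
      if (l1 == 0 && l2 == 0) {
        e <- e + model$stack[pt[a], pair_type(s[j[b] + 1], s[i[b] + 1])]
      } else {
        if (l1 + l2 > model$max_loop) {
          stop("invalid structure: internal loop larger than max_loop")
        }
        loop <- if (l1 == 0 || l2 == 0) {
          loop_energy(model, "bulge", l1 + l2)
        } else {
          internal_loop_energy(model, l1, l2)
        }
        e <- e + loop + au(pt[a]) + au(pt[b])
      }
    } else {                                     # multibranch loop
      unpaired <- (j[a] - i[a] - 1L) - sum(j[ch] - i[ch] + 1L)
      e <- e + model$ml_close + model$ml_branch + au(pt[a]) +
        sum(model$ml_branch + au(pt[ch])) +
        model$ml_unpaired * unpaired
    }
  }
  # exterior loop: one AU/GU penalty per top-level branch
  e <- e + sum(au(pt[parent == 0L]))
  unname(e)
}

#' Accessibility summary of a folded site
#'
#' Summarizes a [fold_local()] result for reporting: the fraction of site
#' positions left unpaired in the MFE structure, and the window folding
#' energy. Deterministic given the fold's fixed traceback order.
#'
#' @param fold A `fold_result` whose window contains `site`.
#' @param site Integer `c(start, end)` 0-based half-open; defaults to the
#'   site the fold was computed around.
#' @return List with `unpaired_fraction` and `fold_mfe`.
#' @export
site_accessibility_report <- function(fold, site = NULL) {
  stopifnot(inherits(fold, "fold_result"))
  if (is.null(site)) site <- c(fold$site_start, fold$site_end)
  site <- as.integer(site)
  if (site[1] < fold$window_start || site[2] > fold$window_end) {
    stop("site interval must lie within the folded window")
  }
  pos <- site[1]:(site[2] - 1L)
  paired <- unique(as.vector(fold$pair_map))
  list(unpaired_fraction = mean(!(pos %in% paired)),
       fold_mfe = fold$fold_mfe)
}
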