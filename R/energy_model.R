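#' Load a nearest-neighbor RNA free-energy model
#'
#' Reads a plain-text tabular parameter file (Gibbs free-energy increments at
#' 37 degrees C, kcal/mol) into an `energy_model` object shared by the duplex
#' hybridization engine ([hybridize()]) and the local folding engine
#' ([fold_local()]). The package ships a versioned Turner-style parameter set
#' (`rna_nn_dg37_v1.tsv`) which is used when `path` is `NULL`.
#'
#' The file holds four record types: `stack` (6x6 table over the allowed pair
#' alphabet AU, UA, GC, CG, GU, UG; `key1` is the outer pair read 5'->3',
#' `key2` the adjacent inner pair read reversed), `bulge` / `internal` /
#' `hairpin` loop initiation penalties by loop size, and `misc` scalars:
#' intermolecular duplex initiation (`duplex_init`), the per-helix-end AU/GU
#' closure penalty (`terminal_au`), the multibranch-loop linear model
#' (`ml_close`, `ml_branch`, `ml_unpaired`), internal-loop asymmetry
#' (`ninio_per_nt`, capped at `ninio_max`), the largest internal/bulge loop
#' (`max_loop`) and the logarithmic loop-size extrapolation coefficient
#' (`lxc`): sizes beyond the tabulated range score
#' `dg(max_tabulated) + lxc * log(size / max_tabulated)`.
#'
#' @param path Path to a parameter file, or `NULL` for the shipped default.
#' @return An object of class `energy_model`: a list with elements `stack`
#'   (named 6x6 matrix), `bulge`, `internal`, `hairpin` (numeric vectors
#'   indexed by loop size), the `misc` scalars, and `version` (file basename).
#' @examples
#' model <- load_energy_model()
#' model$stack["GC", "GC"]  # 5'-GC-3' / 3'-CG-5' stack
#' @export
load_energy_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rna_nn_dg37_v1.tsv", package = "mirtarp",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("energy parameter file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "numeric"))
  need <- c("record", "key1", "key2", "dg")
  if (!all(need %in% names(tab))) {
    stop("malformed energy parameter file (need columns ",
         paste(need, collapse = ", "), "): ", path)
  }

  pr <- PAIR_TYPES
  st <- tab[tab$record == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pr, pr))
  stack[cbind(st$key1, st$key2)] <- st$dg
  if (anyNA(stack)) stop("incomplete stack table in ", path)

  size_table <- function(rec) {
    x <- tab[tab$record == rec, ]
    sizes <- as.integer(x$key1)
    out <- rep(NA_real_, max(sizes))
    out[sizes] <- x$dg
    out
  }
  misc <- tab[tab$record == "misc", ]
  scalars <- stats::setNames(misc$dg, misc$key1)
  need_sc <- c("duplex_init", "terminal_au", "ml_close", "ml_branch",
               "ml_unpaired", "ninio_per_nt", "ninio_max", "max_loop", "lxc")
  missing_sc <- setdiff(need_sc, names(scalars))
  if (length(missing_sc)) {
    stop("missing misc parameters in ", path, ": ",
         paste(missing_sc, collapse = ", "))
  }

  model <- c(
    list(stack = stack,
         bulge = size_table("bulge"),
         internal = size_table("internal"),
         hairpin = size_table("hairpin"),
         version = basename(path)),
    as.list(scalars[need_sc])
  )
  model$max_loop <- as.integer(model$max_loop)
  class(model) <- "energy_model"
  validate_energy_model(model)
  model
}

# Allowed pair alphabet, fixed order shared with the C++ engines.
PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

validate_energy_model <- function(model) {
  stopifnot(is.matrix(model$stack), identical(dim(model$stack), c(6L, 6L)))
  for (rec in c("bulge", "internal", "hairpin")) {
    if (all(is.na(model[[rec]]))) stop("empty ", rec, " table")
  }
  # bulge/internal penalties must be non-decreasing beyond short-loop
  # irregularities (hairpins are allowed small-size structure, e.g. the
  # favorable size-8 initiation)
  for (rec in c("bulge", "internal")) {
    v <- model[[rec]]
    tail_v <- v[seq(6, length(v))]
    if (is.unsorted(tail_v[!is.na(tail_v)])) {
      stop(rec, " penalties decrease beyond size 6")
    }
  }
  if (model$max_loop < 1) stop("max_loop must be >= 1")
  invisible(model)
}

#' @export
print.energy_model <- function(x, ...) {
  cat("RNA nearest-neighbor energy model (dG37, kcal/mol)\n")
  cat("  parameter set:", x$version, "\n")
  cat("  duplex initiation:", x$duplex_init,
      " terminal AU/GU:", x$terminal_au, "\n")
  cat("  max internal/bulge loop:", x$max_loop,
      " multiloop (close/branch/unpaired):",
      x$ml_close, x$ml_branch, x$ml_unpaired, "\n")
  invisible(x)
}

#' Loop initiation free energy with logarithmic extrapolation
#'
#' Looks up the initiation penalty for a hairpin, bulge or internal loop of a
#' given size; sizes beyond the tabulated range are extrapolated with the
#' model's `lxc` coefficient.
#'
#' @param model An [energy_model][load_energy_model()].
#' @param type One of `"hairpin"`, `"bulge"`, `"internal"`.
#' @param size Loop size in unpaired nucleotides (total of both sides for
#'   internal loops).
#' @return Free energy in kcal/mol (`Inf` for sizes below the physical
#'   minimum of the loop type).
#' @export
loop_energy <- function(model, type = c("hairpin", "bulge", "internal"),
                        size) {
  type <- match.arg(type)
  tab <- model[[type]]
  n <- length(tab)
  vapply(as.integer(size), function(s) {
    if (s < 1 || (s <= n && is.na(tab[s]))) return(Inf)
    if (s <= n) tab[s] else tab[n] + model$lxc * log(s / n)
  }, numeric(1))
}

# Pair type code for bases a, b (characters); 0 if not an allowed pair.
# Codes follow PAIR_TYPES order: CG=1 GC=2 GU=3 UG=4 AU=5 UA=6.
pair_type <- function(a, b) {
  key <- paste0(a, b)
  m <- match(key, PAIR_TYPES)
  ifelse(is.na(m), 0L, m)
}

# Stack increment for consecutive pairs (a1:b1) then (a2:b2) along a helix
# (a-strand 5'->3'); inner pair is looked up reversed, matching the table
# encoding.
stack_energy <- function(model, a1, b1, a2, b2) {
  p <- pair_type(a1, b1)
  q <- pair_type(b2, a2)
  if (p == 0L || q == 0L) return(Inf)
  model$stack[p, q]
}

# Terminal AU/GU helix-end penalty for pair (a, b); 0 for GC/CG.
au_end_penalty <- function(model, a, b) {
  if (pair_type(a, b) %in% c(3L, 4L, 5L, 6L)) model$terminal_au else 0
}

# Internal (non-bulge) loop penalty with asymmetry term.
internal_loop_energy <- function(model, l1, l2) {
  loop_energy(model, "internal", l1 + l2) +
    min(model$ninio_max, abs(l1 - l2) * model$ninio_per_nt)
}
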