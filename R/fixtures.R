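# Run code under a seeded, restored RNG so fixture generation never disturbs
# the caller's random stream.
with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_rna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic miRNA/target fixture with planted sites
#'
#' Produces a set of random mature miRNAs (20-24 nt), a set of random target
#' sequences, and a truth table of sites planted into the targets. A
#' `perfect` plant is the exact reverse complement of a miRNA; a `mismatched`
#' plant carries 1-3 point substitutions; a `bulged` plant carries a 1-2 nt
#' insertion on the target side. Planted intervals never overlap on a
#' target. The background is i.i.d. at the requested GC fraction, so every
#' stage of the pipeline can be exercised against known ground truth without
#' any external download. Regeneration with the same seed reproduces
#' identical sequences and truth.
#'
#' @param n_mirnas,n_targets Numbers of miRNA and target records.
#' @param target_len Length of each target (nt).
#' @param n_planted Total number of planted sites.
#' @param gc GC fraction of miRNAs and background, in (0, 1).
#' @param plant_types Types to draw from: subset of
#'   `c("perfect", "mismatched", "bulged")`.
#' @param min_gap Minimum separation (nt) between planted intervals on the
#'   same target (default 40, so the assessment windows of distinct planted
#'   sites stay disjoint at the default `site_flank` of 15 and each site is
#'   reported individually).
#' @param rng_seed Integer seed; the generator is deterministic given it.
#' @param dir If not `NULL`, also write `mirnas.fa`, `targets.fa` and
#'   `truth.tsv` into this directory.
#' @return List with `mirnas` and `targets`
#'   ([Biostrings::RNAStringSet]) and `truth` (data frame with columns
#'   `mirna_id`, `target_id`, `strand`, `site_start`, `site_end`,
#'   `plant_type`; 0-based half-open coordinates), plus the generation
#'   parameters as attribute `params`.
#' @examples
#' fx <- generate_fixture(n_mirnas = 2, n_targets = 1, target_len = 300,
#'                        n_planted = 2, rng_seed = 1)
#' fx$truth
#' @export
generate_fixture <- function(n_mirnas, n_targets, target_len, n_planted,
                             gc = 0.5, plant_types = "perfect",
                             min_gap = 40L, rng_seed = 1L, dir = NULL) {
  stopifnot(n_mirnas >= 1, n_targets >= 1, target_len >= 30)
  if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
  plant_types <- match.arg(plant_types,
                           c("perfect", "mismatched", "bulged"),
                           several.ok = TRUE)
  with_rng_seed(rng_seed, {
    mirna_ids <- sprintf("mir-%03d", seq_len(n_mirnas))
    mirnas <- vapply(seq_len(n_mirnas),
                     function(i) random_rna(sample(20:24, 1), gc),
                     character(1))
    names(mirnas) <- mirna_ids
    target_ids <- sprintf("target-%03d", seq_len(n_targets))
    targets <- vapply(seq_len(n_targets),
                      function(i) random_rna(target_len, gc), character(1))
    names(targets) <- target_ids

    occupied <- lapply(seq_len(n_targets), function(i) IRanges::IRanges())
    truth <- empty_fixture_truth()
    if (n_planted > 0) {
      for (p in seq_len(n_planted)) {
        type <- if (length(plant_types) == 1) plant_types else
          sample(plant_types, 1)
        placed <- FALSE
        for (attempt in seq_len(200)) {
          m <- sample.int(n_mirnas, 1)
          t <- sample.int(n_targets, 1)
          site <- plant_sequence(mirnas[m], type)
          if (nchar(site) > target_len) next
          start0 <- sample.int(target_len - nchar(site) + 1L, 1) - 1L
          iv <- IRanges::IRanges(start0 + 1L, start0 + nchar(site))
          if (length(IRanges::findOverlaps(iv, occupied[[t]],
                                           maxgap = min_gap))) next
          occupied[[t]] <- c(occupied[[t]], iv)
          substr(targets[t], start0 + 1L, start0 + nchar(site)) <- site
          truth <- rbind(truth, data.frame(
            mirna_id = mirna_ids[m], target_id = target_ids[t],
            strand = "+", site_start = start0,
            site_end = start0 + nchar(site), plant_type = type,
            stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place ", n_planted, " non-overlapping sites; ",
               "increase target_len or n_targets")
        }
      }
      truth <- truth[order(truth$target_id, truth$site_start), , drop = FALSE]
      rownames(truth) <- NULL
    }

    mi <- Biostrings::RNAStringSet(mirnas)
    tg <- Biostrings::RNAStringSet(targets)
    out <- list(mirnas = mi, targets = tg, truth = truth)
    attr(out, "params") <- list(n_mirnas = n_mirnas, n_targets = n_targets,
                                target_len = target_len,
                                n_planted = n_planted, gc = gc,
                                plant_types = plant_types,
                                min_gap = min_gap, rng_seed = rng_seed)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(mi, file.path(dir, "mirnas.fa"))
      write_fasta(tg, file.path(dir, "targets.fa"))
      write_fixture_truth(truth, file.path(dir, "truth.tsv"))
    }
    out
  })
}

empty_fixture_truth <- function() {
  data.frame(mirna_id = character(), target_id = character(),
             strand = character(), site_start = integer(),
             site_end = integer(), plant_type = character(),
             stringsAsFactors = FALSE)
}

# Build the target-side sequence of a planted site from a miRNA.
plant_sequence <- function(mirna, type) {
  site <- reverse_complement(unname(mirna))
  if (type == "perfect") return(site)
  ch <- strsplit(site, "", fixed = TRUE)[[1]]
  if (type == "mismatched") {
    k <- sample(1:3, 1)
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
    return(paste(ch, collapse = ""))
  }
  # bulged: 1-2 nt insertion on the target side, away from the ends
  k <- sample(1:2, 1)
  p <- sample(2:(length(ch) - 1), 1)
  ins <- paste(sample(c("A", "C", "G", "U"), k, replace = TRUE), collapse = "")
  paste0(paste(ch[1:p], collapse = ""), ins,
         paste(ch[(p + 1):length(ch)], collapse = ""))
}

#' Write / read a fixture truth table
#'
#' @param truth A truth table from [generate_fixture()].
#' @param path TSV path.
#' @return `path` invisibly, or the parsed truth table.
#' @export
write_fixture_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixture_truth
#' @export
read_fixture_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- names(empty_fixture_truth())
  if (!identical(names(tab), need)) stop("not a fixture truth table: ", path)
  tab
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random permutation of a sequence that preserves its exact dinucleotide
#' multiset (and hence mononucleotide composition), via a random Eulerian
#' path on the dinucleotide transition multigraph (Altschul-Erickson). Used
#' to build negative-control targets in which seed-level signal is destroyed
#' but composition is retained.
#'
#' @param seq Sequence (character scalar or `RNAString`), length >= 2.
#' @param rng_seed Integer seed; the shuffle is deterministic given it.
#' @return The shuffled sequence as a character scalar.
#' @export
shuffle_preserving_dinucleotides <- function(seq, rng_seed = 1L) {
  s <- strsplit(as_residues(seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 2) stop("sequence must have length >= 2")
  with_rng_seed(rng_seed, {
    verts <- unique(s)
    edges <- lapply(stats::setNames(verts, verts),
                    function(v) s[which(s[-n] == v) + 1L])
    last_v <- s[n]
    # choose a random "last out-edge" per vertex; accept when these edges
    # form an arborescence into the path's final vertex
    repeat {
      last_edge <- vapply(verts, function(v) {
        if (v == last_v || !length(edges[[v]])) NA_character_
        else sample(edges[[v]], 1)
      }, character(1))
      ok <- TRUE
      for (v in verts) {
        if (v == last_v || !length(edges[[v]])) next
        cur <- v
        hops <- 0L
        while (cur != last_v && hops <= length(verts)) {
          cur <- last_edge[[cur]]
          hops <- hops + 1L
          if (is.na(cur)) break
        }
        if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # permute the remaining out-edges, placing the chosen last edge last
    for (v in verts) {
      ev <- edges[[v]]
      if (!length(ev)) next
      if (!is.na(last_edge[[v]])) {
        ev <- ev[-match(last_edge[[v]], ev)]
        edges[[v]] <- c(sample_perm(ev), last_edge[[v]])
      } else {
        edges[[v]] <- sample_perm(ev)
      }
    }
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1] <- s[1]
    cur <- s[1]
    for (i in 2:n) {
      nxt <- edges[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

# sample() without the surprising scalar behavior.
sample_perm <- function(x) {
  if (length(x) <= 1) x else sample(x)
}
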