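#' Pipeline configuration
#'
#' Bundles and validates the tunable parameters of the prediction pipeline.
#' The two science-facing parameters keep their conventional flag names:
#' `b`, the number of consecutive Watson-Crick base matches required to seed
#' a candidate site (default 7), and `e`, the duplex minimum-free-energy
#' cutoff in kcal/mol (default -25; sites with `mfe <= e` are kept).
#'
#' @param b Seed length (consecutive base matches), integer >= 4.
#' @param e Duplex MFE cutoff, kcal/mol, <= 0.
#' @param site_flank Target window extension beyond the seed on each side
#'   before duplex assessment (default 15 nt, enough for a full ~22-nt miRNA
#'   with bulges).
#' @param fold_flank Window extension around the reported site for the local
#'   accessibility fold (default 70 nt).
#' @param both_strands Also scan the reverse complement of each target and
#'   report hits with strand `"-"` (default `FALSE`).
#' @param accessibility Compute the local folding energy per site
#'   (default `TRUE`).
#' @param energy_params Path to an energy parameter file, or `NULL` for the
#'   shipped set.
#' @param rng_seed Seed used only by the fixture generator.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(b = 7L, e = -25, site_flank = 15L,
                            fold_flank = 70L, both_strands = FALSE,
                            accessibility = TRUE, energy_params = NULL,
                            rng_seed = NULL) {
  cfg <- list(b = check_seed_length(b), e = as.numeric(e),
              site_flank = as.integer(site_flank),
              fold_flank = as.integer(fold_flank),
              both_strands = isTRUE(both_strands),
              accessibility = isTRUE(accessibility),
              energy_params = energy_params,
              rng_seed = rng_seed)
  if (is.na(cfg$e) || cfg$e > 0) stop("energy cutoff e must be <= 0 kcal/mol")
  if (cfg$site_flank < 0) stop("site_flank must be >= 0")
  if (cfg$fold_flank < 0) stop("fold_flank must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any argument of [pipeline_config()] (same names);
#' unspecified values keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown configuration keys in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Predict miRNA target sites
#'
#' Runs the full prediction flow for every miRNA against every target, on the
#' forward strand (and the reverse strand if configured): exact seed scan for
#' runs of at least `b` consecutive Watson-Crick pairs; extension of each
#' seed by `site_flank` on both sides (clipped at the sequence ends); merging
#' of overlapping windows of the same (miRNA, target, strand) so each merged
#' window yields at most one reported site; minimum-free-energy hybridization
#' of the miRNA against each window; retention of duplexes with
#' `mfe <= e`; and local accessibility folding of the region around each
#' retained site. The same machinery serves both prediction directions --
#' host miRNAs against viral genomes and viral miRNAs against host
#' transcripts -- only the `origin` tag differs.
#'
#' @param mirnas Mature miRNAs: an `RNAStringSet` from [mirna_records()] (the
#'   `origin` metadata column is carried into the report) or a named
#'   character vector (origin defaults to `"host"`).
#' @param targets Target sequences: `RNAStringSet` or named character vector.
#' @param config A [pipeline_config()].
#' @return A data frame of target sites (columns as in [write_sites_tsv()]),
#'   sorted by `(target_id, site_start, mirna_id)`, with an attribute
#'   `stage_counts` recording seeds found, merged windows assessed, and
#'   sites reported. Coordinates are 0-based half-open on the target forward
#'   strand; `local_fold_mfe_kcal_mol` is `NA` when accessibility is
#'   disabled. An empty result is valid (zero rows).
#' @export
predict_targets <- function(mirnas, targets, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  mi <- as_sequence_table(mirnas, default_origin = "host")
  tg <- as_sequence_table(targets)
  if (nrow(mi) == 0) stop("empty miRNA set")
  if (nrow(tg) == 0) stop("empty target set")
  model <- load_energy_model(config$energy_params)

  rows <- list()
  n_seeds <- 0L; n_windows <- 0L
  strands <- if (config$both_strands) c("+", "-") else "+"
  for (t in seq_len(nrow(tg))) {
    t_len <- nchar(tg$seq[t])
    for (strand in strands) {
      scan_seq <- if (strand == "+") tg$seq[t] else reverse_complement(tg$seq[t])
      if (t_len < config$b) next
      idx <- build_match_index(scan_seq, config$b)
      for (m in seq_len(nrow(mi))) {
        seeds <- find_seed_matches(mi$seq[m], b = config$b, index = idx)
        if (nrow(seeds) == 0) next
        n_seeds <- n_seeds + nrow(seeds)
        win <- IRanges::reduce(IRanges::IRanges(
          start = pmax(0L, seeds$target_start - config$site_flank) + 1L,
          end = pmin(t_len, seeds$target_end + config$site_flank)))
        n_windows <- n_windows + length(win)
        for (k in seq_along(win)) {
          ws <- IRanges::start(win)[k] - 1L
          we <- IRanges::end(win)[k]
          in_win <- seeds$target_start < we & seeds$target_end > ws
          seed_len <- max(seeds$length[in_win])
          dup <- hybridize_window(mi$seq[m], scan_seq, c(ws, we), model,
                                  mirna_len = nchar(mi$seq[m]),
                                  site_flank = config$site_flank)
          if (!passes_energy_cutoff(dup, config$e)) next
          ss <- dup$site_start; se <- dup$site_end
          if (strand == "-") { tmp <- ss; ss <- t_len - se; se <- t_len - tmp }
          fold_mfe <- NA_real_
          if (config$accessibility) {
            fr <- fold_local(scan_seq, c(dup$site_start, dup$site_end),
                             flank = config$fold_flank, model = model)
            fold_mfe <- fr$fold_mfe
          }
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = mi$id[m], mirna_origin = mi$origin[m],
            target_id = tg$id[t], strand = strand,
            site_start = ss, site_end = se,
            seed_length = seed_len,
            duplex_mfe_kcal_mol = dup$mfe,
            local_fold_mfe_kcal_mol = fold_mfe,
            mirna_aln = dup$mirna_aln, pair_aln = dup$pair_aln,
            target_aln = dup$target_aln, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_sites()
  out <- sort_sites(out)
  rownames(out) <- NULL
  attr(out, "stage_counts") <- c(seeds = n_seeds, windows = n_windows,
                                 sites = nrow(out))
  out
}

# Hybridize one merged window. Windows longer than the 200-nt engine limit
# (possible when many seed windows chain, e.g. low-complexity targets) are
# tiled with overlapping 200-nt sub-windows and the lowest-mfe duplex is
# reported, preserving "one site per merged window".
hybridize_window <- function(mirna, target, window, model, mirna_len,
                             site_flank) {
  if (window[2] - window[1] <= 200L) {
    return(hybridize(mirna, target, window, model))
  }
  overlap <- min(199L, mirna_len + 2L * site_flank)
  step <- 200L - overlap
  starts <- seq(window[1], window[2] - 1L, by = step)
  best <- NULL
  for (s in starts) {
    e <- min(window[2], s + 200L)
    if (e - s < mirna_len %/% 2L) break
    d <- hybridize(mirna, target, c(s, e), model)
    if (is.null(best) || d$mfe < best$mfe) best <- d
    if (e == window[2]) break
  }
  best
}

# Normalize miRNA/target inputs to a data.frame(id, seq, origin).
as_sequence_table <- function(x, default_origin = NA_character_) {
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("character sequence sets must be named")
    }
    seqs <- unname(vapply(x, function(s) {
      v <- normalize_residues(s)
      if (is.na(v)) stop("sequence contains characters outside A C G U N / T")
      v
    }, character(1)))
    return(data.frame(id = names(x), seq = seqs,
                      origin = default_origin, stringsAsFactors = FALSE))
  }
  if (methods::is(x, "XStringSet")) {
    origin <- S4Vectors::mcols(x)$origin %||% default_origin
    return(data.frame(id = names(x), seq = as.character(x),
                      origin = origin, stringsAsFactors = FALSE))
  }
  stop("unsupported sequence container: ", class(x)[1])
}

#' Batch prediction from FASTA files
#'
#' Reads a miRNA FASTA and a target FASTA, runs [predict_targets()], and
#' writes the site report (TSV, optionally GFF3) plus a run log recording the
#' parameters, input record counts, per-stage site counts and runtime. A run
#' with zero passing sites is a success (header-only TSV): screening a new
#' genome and finding nothing is a valid result, distinct from failure.
#'
#' @param mirna_file,target_file Paths to multi-FASTA inputs.
#' @param config A [pipeline_config()].
#' @param out_prefix Output path prefix; writes `<prefix>.sites.tsv`,
#'   `<prefix>.log` and optionally `<prefix>.sites.gff3`.
#' @param origin Origin tag for the miRNA set: `"host"` or `"virus"`.
#' @param gff3 Also write a GFF3 report.
#' @param quiet Suppress the log echo to the console.
#' @return Invisibly, a list with the site table (`sites`), the stage counts
#'   (`counts`) and the paths written (`files`).
#' @export
run_batch <- function(mirna_file, target_file, config = pipeline_config(),
                      out_prefix = "mirtarp_run", origin = c("host", "virus"),
                      gff3 = FALSE, quiet = FALSE) {
  origin <- match.arg(origin)
  t0 <- Sys.time()
  mirnas <- mirna_records(read_fasta(mirna_file), origin = origin)
  targets <- read_fasta(target_file)
  sites <- predict_targets(mirnas, targets, config)
  counts <- attr(sites, "stage_counts")

  tsv <- paste0(out_prefix, ".sites.tsv")
  write_sites_tsv(sites, tsv)
  files <- c(tsv = tsv)
  if (gff3) {
    gff <- paste0(out_prefix, ".sites.gff3")
    write_sites_gff3(sites, gff)
    files <- c(files, gff3 = gff)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_lines <- c(
    sprintf("mirtarp run: b=%d e=%.2f site_flank=%d fold_flank=%d strands=%s accessibility=%s",
            config$b, config$e, config$site_flank, config$fold_flank,
            if (config$both_strands) "+/-" else "+",
            if (config$accessibility) "on" else "off"),
    sprintf("inputs: %d miRNA record(s) [%s], %d target record(s)",
            length(mirnas), origin, length(targets)),
    sprintf("stages: %d seed match(es), %d merged window(s), %d duplex(es) passing",
            counts["seeds"], counts["windows"], counts["sites"]),
    sprintf("%d sites reported", nrow(sites)),
    sprintf("elapsed: %.1f s", elapsed))
  log_file <- paste0(out_prefix, ".log")
  writeLines(log_lines, log_file)
  files <- c(files, log = log_file)
  if (!quiet) message(paste(log_lines, collapse = "\n"))
  invisible(list(sites = sites, counts = counts, files = files))
}
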