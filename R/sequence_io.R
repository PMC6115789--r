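#' Read and normalize a multi-FASTA file
#'
#' Parses a FASTA file of RNA or DNA sequences and normalizes every record to
#' the uppercase RNA alphabet (`T` becomes `U`). The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as a
#' description. Duplicate ids are made unique with a numeric suffix
#' (`x`, `x_2`, ...) and a warning. Records containing characters outside
#' `A C G U N` (or `T`/lowercase equivalents) are dropped with a warning
#' naming the record -- they are never silently masked.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::RNAStringSet] in file order; `names()` hold the ids
#'   and the `description` metadata column the rest of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1 an example", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(raw) == 0) stop("no FASTA records in ", path)

  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")

  seqs <- normalize_residues(as.character(raw))
  bad <- is.na(seqs)
  if (any(bad)) {
    warning("dropped ", sum(bad), " record(s) with non-ACGUNT characters: ",
            paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  if (all(bad)) stop("no parseable FASTA records in ", path)
  ids <- ids[!bad]; desc <- desc[!bad]; seqs <- seqs[!bad]

  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate FASTA ids made unique: ", paste(dup, collapse = ", "),
            call. = FALSE)
    ids <- make_unique_ids(ids)
  }

  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

# Uppercase, T->U; NA for sequences with characters outside the RNA alphabet
# or of zero length.
normalize_residues <- function(x) {
  x <- chartr("T", "U", toupper(x))
  ok <- nzchar(x) & !grepl("[^ACGUN]", x)
  x[!ok] <- NA_character_
  x
}

# x, x, x -> x, x_2, x_3 (deterministic, file order).
make_unique_ids <- function(ids) {
  counts <- list()
  vapply(ids, function(id) {
    n <- (counts[[id]] %||% 0L) + 1L
    counts[[id]] <<- n
    if (n == 1L) id else paste0(id, "_", n)
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write sequences to a FASTA file
#'
#' @param x A named character vector or [Biostrings::RNAStringSet] (a
#'   `description` metadata column, if present, is appended to the header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- Biostrings::RNAStringSet(x)
  }
  hdr <- names(x)
  if (is.null(hdr)) stop("sequences must be named")
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc)) {
    hdr <- ifelse(nzchar(desc), paste(hdr, desc), hdr)
  }
  y <- x
  names(y) <- hdr
  Biostrings::writeXStringSet(y, path)
  invisible(path)
}

#' Reverse complement of an RNA sequence
#'
#' RNA complement (A-U, G-C, N-N), reversed. An involution:
#' `reverse_complement(reverse_complement(x))` equals `x`.
#'
#' @param x A character vector of RNA sequences (uppercase `A C G U N`) or a
#'   [Biostrings::RNAStringSet]/`RNAString`.
#' @return Same type as the input.
#' @examples
#' reverse_complement("AAGG")  # "CCUU"
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    comp <- chartr("ACGUN", "UGCAN", x)
    return(vapply(comp, function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE))
  }
  Biostrings::reverseComplement(x)
}

# Coerce a single sequence argument (character scalar, RNAString, or a
# length-1 RNAStringSet) to a plain residue string.
as_residues <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single sequence")
    s <- normalize_residues(x)
    if (is.na(s)) stop("sequence contains characters outside A C G U N / T")
    return(s)
  }
  if (methods::is(x, "XStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(as.character(x)[[1]])
  }
  as.character(x)
}

#' Tag mature miRNA records with their origin
#'
#' Validates mature-miRNA lengths and attaches the origin (host or virus) that
#' determines the prediction direction. Records shorter than 10 nt are dropped
#' with a warning; lengths outside the typical mature range 15--30 nt are kept
#' with a warning. The origin is always set explicitly by the caller, never
#' guessed from the id.
#'
#' @param x An [Biostrings::RNAStringSet] (e.g. from [read_fasta()]).
#' @param origin `"host"` or `"virus"`.
#' @return The validated `RNAStringSet` with an `origin` metadata column.
#' @export
mirna_records <- function(x, origin = c("host", "virus")) {
  origin <- match.arg(origin)
  if (is.character(x)) x <- Biostrings::RNAStringSet(x)
  len <- Biostrings::width(x)
  too_short <- len < 10L
  if (any(too_short)) {
    warning("dropped ", sum(too_short), " miRNA record(s) shorter than 10 nt: ",
            paste(names(x)[too_short], collapse = ", "), call. = FALSE)
    x <- x[!too_short]; len <- len[!too_short]
  }
  if (length(x) == 0) stop("no usable miRNA records")
  atypical <- len < 15L | len > 30L
  if (any(atypical)) {
    warning(sum(atypical), " miRNA record(s) outside the typical 15-30 nt ",
            "mature length: ", paste(names(x)[atypical], collapse = ", "),
            call. = FALSE)
  }
  S4Vectors::mcols(x)$origin <- origin
  x
}

# Column order of the sites table / TSV report.
SITE_COLUMNS <- c("mirna_id", "mirna_origin", "target_id", "strand",
                  "site_start", "site_end", "seed_length",
                  "duplex_mfe_kcal_mol", "local_fold_mfe_kcal_mol",
                  "mirna_aln", "pair_aln", "target_aln")

#' An empty target-site table
#'
#' @return A zero-row data frame with the standard site report columns.
#' @export
empty_sites <- function() {
  data.frame(mirna_id = character(), mirna_origin = character(),
             target_id = character(), strand = character(),
             site_start = integer(), site_end = integer(),
             seed_length = integer(),
             duplex_mfe_kcal_mol = numeric(),
             local_fold_mfe_kcal_mol = numeric(),
             mirna_aln = character(), pair_aln = character(),
             target_aln = character(), stringsAsFactors = FALSE)
}

sort_sites <- function(sites) {
  sites[order(sites$target_id, sites$site_start, sites$mirna_id), ,
        drop = FALSE]
}

#' Write predicted target sites to TSV
#'
#' One header line plus one row per site, sorted by
#' `(target_id, site_start, mirna_id)`. Coordinates are 0-based half-open on
#' the forward strand of the target; energies are printed with two decimals
#' (`NA` when the accessibility step was skipped).
#'
#' @param sites A site table as returned by [predict_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  stopifnot(all(SITE_COLUMNS %in% names(sites)))
  out <- sort_sites(sites)[, SITE_COLUMNS, drop = FALSE]
  out$duplex_mfe_kcal_mol <- sprintf("%.2f", out$duplex_mfe_kcal_mol)
  out$local_fold_mfe_kcal_mol <- ifelse(
    is.na(out$local_fold_mfe_kcal_mol), "NA",
    sprintf("%.2f", out$local_fold_mfe_kcal_mol))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(SITE_COLUMNS, collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a target-site TSV written by [write_sites_tsv()]
#'
#' @param path Path to the TSV report.
#' @return A site table (data frame) with typed columns.
#' @export
read_sites_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(mirna_aln = "character",
                                          pair_aln = "character",
                                          target_aln = "character"))
  if (!identical(names(tab), SITE_COLUMNS)) {
    stop("not a site TSV (unexpected columns): ", path)
  }
  if (nrow(tab) == 0) return(empty_sites())
  tab
}

#' Write predicted target sites as GFF3
#'
#' Coordinates are converted to the 1-based inclusive GFF3 convention; the
#' score column carries the duplex minimum free energy.
#'
#' @inheritParams write_sites_tsv
#' @return `path`, invisibly.
#' @export
write_sites_gff3 <- function(sites, path) {
  out <- sort_sites(sites)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(out)) {
    attrs <- sprintf(
      "ID=site%0*d;mirna_id=%s;mirna_origin=%s;seed_length=%d;local_fold_mfe=%s",
      nchar(nrow(out)), seq_len(nrow(out)), out$mirna_id, out$mirna_origin,
      out$seed_length,
      ifelse(is.na(out$local_fold_mfe_kcal_mol), "NA",
             sprintf("%.2f", out$local_fold_mfe_kcal_mol)))
    writeLines(paste(out$target_id, "mirtarp", "miRNA_target_site",
                     out$site_start + 1L, out$site_end,
                     sprintf("%.2f", out$duplex_mfe_kcal_mol),
                     out$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}
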