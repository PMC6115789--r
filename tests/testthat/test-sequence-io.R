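write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

test_that("read_fasta normalizes to the uppercase RNA alphabet", {
  fa <- write_tmp_fasta(c(">m1 some description", "acgt"))
  x <- read_fasta(fa)
  expect_length(x, 1)
  expect_identical(names(x), "m1")
  expect_identical(as.character(x)[[1]], "ACGU")
  expect_identical(S4Vectors::mcols(x)$description, "some description")
  # idempotent: re-normalizing changes nothing
  y <- mirtarp:::normalize_residues(as.character(x))
  expect_identical(unname(y), unname(as.character(x)))
})

test_that("duplicate ids get a deterministic numeric suffix with a warning", {
  fa <- write_tmp_fasta(c(">x", "AAAA", ">x", "CCCC"))
  expect_warning(x <- read_fasta(fa), "duplicate")
  expect_identical(names(x), c("x", "x_2"))
})

test_that("records with alien characters are dropped loudly, not masked", {
  fa <- write_tmp_fasta(c(">bad", "ACGX", ">good", "ACGU"))
  expect_warning(x <- read_fasta(fa), "bad")
  expect_identical(names(x), "good")
})

test_that("missing or unparseable files raise errors", {
  expect_error(read_fasta(tempfile()), "not found")
  fa <- write_tmp_fasta(c("no header", "ACGU"))
  expect_error(suppressWarnings(read_fasta(fa)))
  # a file whose only record is invalid is a format error
  fa2 <- write_tmp_fasta(c(">only", "QQQQ"))
  expect_error(suppressWarnings(read_fasta(fa2)), "no parseable")
})

test_that("FASTA writing round-trips record sets exactly", {
  fa <- write_tmp_fasta(c(">a first", "ACGUACGU", ">b", "GGGCCCAAUU"))
  x <- read_fasta(fa)
  out <- tempfile(fileext = ".fa")
  write_fasta(x, out)
  y <- read_fasta(out)
  expect_identical(as.character(x), as.character(y))
  expect_identical(S4Vectors::mcols(x)$description,
                   S4Vectors::mcols(y)$description)
})

test_that("reverse_complement matches the pairing table and is an involution", {
  expect_identical(reverse_complement("ACGU"), "ACGU")
  expect_identical(reverse_complement("AAGG"), "CCUU")
  expect_identical(reverse_complement("ANU"), "ANU")
  set.seed(11)
  for (i in 1:25) {
    s <- rand_rna(sample(5:40, 1))
    rc <- reverse_complement(s)
    expect_identical(nchar(rc), nchar(s))
    expect_identical(reverse_complement(rc), s)
  }
})

test_that("miRNA record validation enforces mature-length rules", {
  x <- Biostrings::RNAStringSet(c(ok = "ACGUACGUACGUACGUACGUAC",
                                  short = "ACGUA",
                                  atypical = "ACGUACGUACGU"))
  expect_warning(expect_warning(y <- mirna_records(x, "virus"), "shorter"),
                 "typical")
  expect_identical(names(y), c("ok", "atypical"))
  expect_identical(unique(S4Vectors::mcols(y)$origin), "virus")
  expect_error(suppressWarnings(
    mirna_records(Biostrings::RNAStringSet(c(a = "ACG")), "host")))
})

make_site_row <- function(start = 5L, end = 27L, mfe = -30.25, fold = -12.5) {
  data.frame(mirna_id = "mir-1", mirna_origin = "host", target_id = "t1",
             strand = "+", site_start = start, site_end = end,
             seed_length = 8L, duplex_mfe_kcal_mol = mfe,
             local_fold_mfe_kcal_mol = fold,
             mirna_aln = "ACGU", pair_aln = "||||", target_aln = "UGCA",
             stringsAsFactors = FALSE)
}

test_that("site TSV: header-only when empty, exact coordinates otherwise", {
  f <- tempfile(fileext = ".tsv")
  write_sites_tsv(empty_sites(), f)
  expect_identical(length(readLines(f)), 1L)

  write_sites_tsv(make_site_row(), f)
  lines <- readLines(f)
  expect_length(lines, 2)
  fields <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  expect_identical(fields[5:6], c("5", "27"))
  expect_identical(fields[8], "-30.25")  # two decimals
})

test_that("site TSV round-trips through read_sites_tsv", {
  sites <- rbind(make_site_row(5L, 27L, -30.25, -12.5),
                 make_site_row(100L, 121L, -26.5, NA))
  f <- tempfile(fileext = ".tsv")
  write_sites_tsv(sites, f)
  back <- read_sites_tsv(f)
  expect_identical(back$site_start, sites$site_start)
  expect_identical(back$site_end, sites$site_end)
  expect_identical(back$mirna_aln, sites$mirna_aln)
  expect_equal(back$duplex_mfe_kcal_mol, sites$duplex_mfe_kcal_mol)
  expect_true(is.na(back$local_fold_mfe_kcal_mol[2]))
  # writing the parsed table again is byte-identical
  f2 <- tempfile(fileext = ".tsv")
  write_sites_tsv(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("GFF3 export converts to 1-based inclusive coordinates", {
  f <- tempfile(fileext = ".gff3")
  write_sites_gff3(make_site_row(5L, 27L), f)
  lines <- readLines(f)
  expect_identical(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  expect_identical(fields[3], "miRNA_target_site")
  expect_identical(fields[4:5], c("6", "27"))
  expect_identical(fields[6], "-30.25")
  expect_match(fields[9], "mirna_id=mir-1")
})
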