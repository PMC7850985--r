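make_records <- function(up, psms, symbols = NULL) {
  n <- length(up)
  if (is.null(symbols)) symbols <- sprintf("GENE%d", seq_len(n))
  data.frame(
    accession = sprintf("ACC%d", seq_len(n)),
    gene_symbol = symbols,
    unique_peptides = as.integer(up),
    psms = as.integer(psms),
    is_bait = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("parser reads well-formed tables and reports bad rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Accession\tGene Symbol\t# Unique Peptides\t# PSMs",
    "P1\tGAPDH\t5\t12"
  ), path)
  rec <- parse_identifications(path)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$gene_symbol, "GAPDH")
  expect_equal(rec$psms, 12L)
  expect_false(rec$is_bait)

  writeLines(c(
    "Accession\tGene Symbol\t# Unique Peptides\t# PSMs",
    "P1\tGAPDH\t5\t12",
    "P2\tENO1\tNA\t4"
  ), path)
  expect_error(parse_identifications(path), "row\\(s\\) 2")

  # internally inconsistent: peptides but no PSMs
  writeLines(c(
    "Accession\tGene Symbol\t# Unique Peptides\t# PSMs",
    "P1\tGAPDH\t5\t0"
  ), path)
  expect_error(parse_identifications(path), "zero PSMs")

  expect_error(
    parse_identifications(path, columns = c(accession = "Accession")),
    "gene_symbol"
  )
})

test_that("parser round-trips the synthetic generator at study scale", {
  gen <- generate_identifications(672, pass_fraction = 347 / 672, seed = 5)
  path <- write_id_table(gen$records)
  rec <- parse_identifications(path)
  expect_equal(nrow(rec), 672L)
  expect_equal(rec$unique_peptides, gen$records$unique_peptides)
  expect_equal(rec$psms, gen$records$psms)
})

test_that("filter applies both thresholds at the documented boundary", {
  rec <- make_records(up = c(2, 1, 2, 3, 1), psms = c(2, 10, 1, 50, 1))
  parts <- filter_identifications(rec)
  expect_equal(parts$kept$gene_symbol, c("GENE1", "GENE4"))
  expect_equal(parts$removed$gene_symbol, c("GENE2", "GENE3", "GENE5"))
})

test_that("kept/removed partition the input and respect monotonicity", {
  gen <- generate_identifications(100, pass_fraction = 0.5, seed = 7)
  parts <- filter_identifications(gen$records)
  expect_equal(nrow(parts$kept), gen$pass_count)
  expect_equal(nrow(parts$kept) + nrow(parts$removed), 100L)
  expect_length(intersect(parts$kept$accession, parts$removed$accession), 0)
  # order preserved within each list
  expect_equal(parts$kept$accession,
               gen$records$accession[gen$records$accession %in%
                                       parts$kept$accession])

  # raising either threshold never grows `kept`
  for (th in list(evidence_thresholds(3, 2), evidence_thresholds(2, 3),
                  evidence_thresholds(5, 5))) {
    stricter <- filter_identifications(gen$records, th)
    expect_true(all(stricter$kept$accession %in% parts$kept$accession))
  }

  # determinism
  again <- filter_identifications(gen$records)
  expect_identical(parts, again)

  # empty input -> two empty frames
  empty <- filter_identifications(gen$records[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$removed), 0L)
})

test_that("strict per-peptide mode uses the peptide-level table", {
  rec <- make_records(up = c(2, 2), psms = c(10, 10))
  # GENE1 has two strong peptides; GENE2 has one strong, one weak
  peptides <- data.frame(
    accession = c("ACC1", "ACC1", "ACC2", "ACC2"),
    peptide = c("AAA", "BBB", "CCC", "DDD"),
    psms = c(5L, 5L, 9L, 1L),
    stringsAsFactors = FALSE
  )
  parts <- filter_identifications(rec, peptide_table = peptides)
  expect_equal(parts$kept$gene_symbol, "GENE1")
  expect_equal(parts$removed$gene_symbol, "GENE2")
})

test_that("duplicate gene symbols collapse to the highest-PSM record", {
  rec <- make_records(up = c(3, 4, 2), psms = c(5, 20, 7),
                      symbols = c("DUP", "DUP", "OTHER"))
  expect_message(out <- collapse_gene_duplicates(rec), "DUP")
  expect_equal(nrow(out), 2L)
  expect_equal(out$psms[out$gene_symbol == "DUP"], 20L)
})

test_that("bait addition appends once and warns on re-addition", {
  rec <- make_records(up = c(3, 4), psms = c(5, 20))
  out <- add_bait(rec, "P35247", "SFTPD")
  expect_equal(nrow(out), 3L)
  expect_true(out$is_bait[out$gene_symbol == "SFTPD"])
  expect_warning(out2 <- add_bait(out, "P35247", "SFTPD"), "already present")
  expect_identical(out2, out)
  # empty list + bait -> singleton
  single <- add_bait(rec[0, ], "P35247", "SFTPD")
  expect_equal(nrow(single), 1L)
})

test_that("generator pass fractions 0 and 1 are exact", {
  all_pass <- generate_identifications(40, 1, seed = 2)
  expect_equal(nrow(filter_identifications(all_pass$records)$kept), 40L)
  none_pass <- generate_identifications(40, 0, seed = 2)
  expect_equal(nrow(filter_identifications(none_pass$records)$kept), 0L)
})
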