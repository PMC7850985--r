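#' Default column mapping for protein identification tables
#'
#' Maps the internal field names to the column headers used by typical
#' Proteome Discoverer style exports.
#'
#' @return Named character vector: internal field -> column header.
#' @export
default_id_columns <- function() {
  c(
    accession       = "Accession",
    gene_symbol     = "Gene Symbol",
    unique_peptides = "# Unique Peptides",
    psms            = "# PSMs"
  )
}

#' Evidence thresholds for protein identification filtering
#'
#' Thresholds applied to the spectral evidence of each identified protein:
#' the number of unique peptides and the total number of peptide-spectrum
#' matches (PSMs). The defaults (2 and 2) are the conventional two-peptide
#' rule with at least two PSMs.
#'
#' @param min_unique_peptides Minimum number of unique peptides (>= 1).
#' @param min_psms Minimum total PSM count (>= 1). In strict per-peptide mode
#'   (see [filter_identifications()]) this is instead the minimum PSM count
#'   each qualifying peptide must reach.
#' @return An object of class `evidence_thresholds`.
#' @export
evidence_thresholds <- function(min_unique_peptides = 2L, min_psms = 2L) {
  min_unique_peptides <- as.integer(min_unique_peptides)
  min_psms <- as.integer(min_psms)
  if (is.na(min_unique_peptides) || min_unique_peptides < 1L) {
    stop("`min_unique_peptides` must be a positive integer", call. = FALSE)
  }
  if (is.na(min_psms) || min_psms < 1L) {
    stop("`min_psms` must be a positive integer", call. = FALSE)
  }
  structure(
    list(min_unique_peptides = min_unique_peptides, min_psms = min_psms),
    class = "evidence_thresholds"
  )
}

#' Parse a protein identification table
#'
#' Reads a delimited text export of protein identifications (one row per
#' protein, with accession, gene symbol, unique-peptide count and PSM count)
#' into a data frame of protein records. Rows with unparseable counts are
#' reported as errors with their row numbers, never silently dropped.
#'
#' Rows claiming at least one unique peptide but zero PSMs are internally
#' inconsistent (every peptide identification rests on at least one
#' spectrum match) and are rejected at parse time.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param columns Named character vector mapping the fields `accession`,
#'   `gene_symbol`, `unique_peptides` and `psms` (optionally `search_score`)
#'   to column headers; see [default_id_columns()].
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param collapse_duplicates Collapse rows sharing a gene symbol, keeping
#'   the one with the highest PSM count (network nodes are gene symbols).
#' @return A data frame with columns `accession`, `gene_symbol`,
#'   `unique_peptides`, `psms`, optionally `search_score`, and `is_bait`
#'   (all `FALSE` at parse time).
#' @export
parse_identifications <- function(path,
                                  columns = default_id_columns(),
                                  sep = NULL,
                                  collapse_duplicates = TRUE) {
  required <- c("accession", "gene_symbol", "unique_peptides", "psms")
  missing_map <- setdiff(required, names(columns))
  if (length(missing_map) > 0) {
    stop("column mapping lacks field(s): ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character", fileEncoding = "UTF-8")
  for (field in required) {
    if (!columns[[field]] %in% names(raw)) {
      stop("input lacks mapped column '", columns[[field]], "' (field ",
           field, ")", call. = FALSE)
    }
  }

  parse_count <- function(x, what) {
    x <- trimws(x)
    n <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(n) | n < 0 | n != floor(n))
    if (length(bad) > 0) {
      stop("non-integer ", what, " count in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    as.integer(n)
  }

  records <- data.frame(
    accession       = trimws(raw[[columns[["accession"]]]]),
    gene_symbol     = trimws(raw[[columns[["gene_symbol"]]]]),
    unique_peptides = parse_count(raw[[columns[["unique_peptides"]]]],
                                  "unique-peptide"),
    psms            = parse_count(raw[[columns[["psms"]]]], "PSM"),
    stringsAsFactors = FALSE
  )
  if ("search_score" %in% names(columns) &&
      columns[["search_score"]] %in% names(raw)) {
    records$search_score <-
      suppressWarnings(as.numeric(raw[[columns[["search_score"]]]]))
  }
  empty_sym <- which(records$gene_symbol == "" | is.na(records$gene_symbol))
  if (length(empty_sym) > 0) {
    stop("empty gene symbol in row(s) ", paste(empty_sym, collapse = ", "),
         call. = FALSE)
  }
  inconsistent <- which(records$unique_peptides >= 1L & records$psms < 1L)
  if (length(inconsistent) > 0) {
    stop("row(s) ", paste(inconsistent, collapse = ", "),
         " report unique peptides but zero PSMs", call. = FALSE)
  }
  records$is_bait <- FALSE
  if (collapse_duplicates) {
    records <- collapse_gene_duplicates(records)
  }
  records
}

#' Collapse duplicate gene symbols, keeping the highest-PSM record
#'
#' Isoform accessions mapping to one gene symbol would create duplicate
#' network nodes; the record with the most PSMs is kept per symbol
#' (original input order preserved otherwise).
#'
#' @param records Protein record data frame.
#' @return De-duplicated data frame.
#' @export
collapse_gene_duplicates <- function(records) {
  if (nrow(records) < 2L) return(records)
  dup_syms <- unique(records$gene_symbol[duplicated(records$gene_symbol)])
  if (length(dup_syms) == 0) return(records)
  drop <- logical(nrow(records))
  for (sym in dup_syms) {
    idx <- which(records$gene_symbol == sym)
    keep <- idx[which.max(records$psms[idx])]
    drop[setdiff(idx, keep)] <- TRUE
  }
  message(sum(drop), " duplicate record(s) collapsed for ",
          length(dup_syms), " gene symbol(s): ",
          paste(dup_syms, collapse = ", "))
  records[!drop, , drop = FALSE]
}

#' Filter protein identifications by spectral evidence
#'
#' Partitions protein records into those meeting the evidence thresholds and
#' those that do not. The default (protein-level) contract keeps a record
#' when `unique_peptides >= min_unique_peptides` and
#' `psms >= min_psms`. When a peptide-level table is supplied, a strict
#' per-peptide mode is applied instead: a protein is kept when at least
#' `min_unique_peptides` of its unique peptides each carry `min_psms` or
#' more PSMs.
#'
#' @param records Protein record data frame from [parse_identifications()].
#' @param thresholds An [evidence_thresholds()] object.
#' @param peptide_table Optional data frame with columns `accession`,
#'   `peptide`, `psms` giving per-peptide PSM counts; activates strict mode.
#' @return A list with elements `kept` and `removed`, each a data frame;
#'   together they partition the input, preserving input order.
#' @export
filter_identifications <- function(records,
                                   thresholds = evidence_thresholds(),
                                   peptide_table = NULL) {
  stopifnot(inherits(thresholds, "evidence_thresholds"))
  if (nrow(records) == 0L) {
    return(list(kept = records, removed = records))
  }
  if (is.null(peptide_table)) {
    pass <- records$unique_peptides >= thresholds$min_unique_peptides &
      records$psms >= thresholds$min_psms
  } else {
    stopifnot(all(c("accession", "peptide", "psms") %in% names(peptide_table)))
    strong <- peptide_table[peptide_table$psms >= thresholds$min_psms, ,
                            drop = FALSE]
    strong <- strong[!duplicated(paste(strong$accession, strong$peptide)), ,
                     drop = FALSE]
    n_strong <- table(strong$accession)
    counts <- as.integer(n_strong[records$accession])
    counts[is.na(counts)] <- 0L
    pass <- counts >= thresholds$min_unique_peptides
  }
  list(
    kept    = records[pass, , drop = FALSE],
    removed = records[!pass, , drop = FALSE]
  )
}

#' Add the bait protein to a record list
#'
#' Affinity-purification baits are not always identified in their own pull
#' down; this appends the bait record so it can participate in the network.
#' The bait is flagged (`is_bait = TRUE`) so downstream ranking can include
#' or exclude it.
#'
#' @param records Protein record data frame.
#' @param accession Bait accession (e.g. `"P35247"`).
#' @param gene_symbol Bait gene symbol (e.g. `"SFTPD"`).
#' @param unique_peptides,psms Evidence counts to record for the bait
#'   (defaults 0; the bait is typically added without MS evidence).
#' @return The record data frame with the bait appended, or unchanged (with
#'   a warning) when the symbol is already present.
#' @export
add_bait <- function(records, accession, gene_symbol,
                     unique_peptides = 0L, psms = 0L) {
  if (gene_symbol %in% records$gene_symbol) {
    warning("bait '", gene_symbol, "' already present; records unchanged",
            call. = FALSE)
    return(records)
  }
  bait <- data.frame(
    accession = accession, gene_symbol = gene_symbol,
    unique_peptides = as.integer(unique_peptides), psms = as.integer(psms),
    stringsAsFactors = FALSE
  )
  if ("search_score" %in% names(records)) bait$search_score <- NA_real_
  bait$is_bait <- TRUE
  out <- rbind(records, bait[, names(records), drop = FALSE])
  rownames(out) <- NULL
  out
}
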