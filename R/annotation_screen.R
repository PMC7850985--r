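#' Default truthy/falsy token dialect for annotation tables
#'
#' Printed annotation tables typically flag membership with a check mark and
#' absence with an "x"; machine exports use yes/no or 0/1.
#'
#' @return List with character vectors `truthy` and `falsy`.
#' @export
default_annotation_dialect <- function() {
  list(
    truthy = c("\u2713", "\u2714", "yes", "y", "true", "TRUE", "1"),
    falsy  = c("x", "X", "no", "n", "false", "FALSE", "0")
  )
}

#' Parse a boolean annotation table
#'
#' Reads a delimited table whose first column holds gene symbols and whose
#' remaining columns are annotation criteria with truthy/falsy tokens.
#' Empty cells parse to `NA` — "unannotated", a third state distinct from
#' `FALSE`, because database lookups are incomplete and a silent `FALSE`
#' would fabricate a negative.
#'
#' @param path Path to a TSV/CSV file with a header row naming the criteria.
#' @param dialect Token dialect; see [default_annotation_dialect()].
#' @param sep Field separator; `NULL` auto-detects tab vs comma.
#' @param provenance Optional named character vector mapping criterion names
#'   to source labels, attached as the `"provenance"` attribute.
#' @return Data frame: column `gene_symbol` plus one logical column per
#'   criterion (`TRUE`/`FALSE`/`NA`).
#' @export
parse_annotations <- function(path, dialect = default_annotation_dialect(),
                              sep = NULL, provenance = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("annotation table needs >= 2 columns", call. = FALSE)
  symbols <- trimws(raw[[1]])
  dups <- unique(symbols[duplicated(symbols)])
  if (length(dups) > 0) {
    stop("duplicate gene symbol row(s): ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(gene_symbol = symbols, stringsAsFactors = FALSE)
  for (col in names(raw)[-1]) {
    tok <- trimws(raw[[col]])
    val <- rep(NA, length(tok))
    val[tok %in% dialect$truthy] <- TRUE
    val[tok %in% dialect$falsy] <- FALSE
    unknown <- which(!(tok %in% c(dialect$truthy, dialect$falsy)) & tok != "")
    if (length(unknown) > 0) {
      stop("unmapped token(s) in column '", col, "', row(s) ",
           paste(unknown, collapse = ", "), ": ",
           paste(unique(tok[unknown]), collapse = ", "), call. = FALSE)
    }
    out[[col]] <- as.logical(val)
  }
  attr(out, "provenance") <- provenance
  out
}

#' Write an annotation table
#'
#' Inverse of [parse_annotations()] with the default dialect: `TRUE` becomes
#' a check mark, `FALSE` an `x`, `NA` an empty cell.
#'
#' @param annotations Annotation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  for (col in names(out)[-1]) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "\u2713", "x"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Screen a shortlist against annotation criteria
#'
#' Computes, over the shortlisted proteins: the per-criterion count of
#' annotated-true members, the running intersection counts along the
#' conjunction (each prefix of the criterion list), and the final
#' candidates — shortlist members annotated `TRUE` for every criterion in
#' the conjunction, ordered by cumulative rank. Symbols missing from the
#' annotation table (or with `NA` flags) are counted as unannotated and can
#' never become candidates.
#'
#' @param shortlist Either a character vector of gene symbols (in rank
#'   order) or a rank-table data frame with columns `node` and
#'   `cumulative_rank` (e.g. from [shortlist_top_fraction()]).
#' @param annotations Annotation data frame from [parse_annotations()].
#' @param conjunction Ordered character vector of criterion names to
#'   intersect; defaults to every criterion in the table.
#' @return An object of class `candidate_report`: a list with elements
#'   `shortlist`, `criterion_counts`, `unannotated_counts`,
#'   `intersection_counts`, `final_candidates` (data frame `node`,
#'   `cumulative_rank`), `conjunction` and `provenance`.
#' @export
screen_candidates <- function(shortlist, annotations, conjunction = NULL) {
  if (is.data.frame(shortlist)) {
    stopifnot(all(c("node", "cumulative_rank") %in% names(shortlist)))
    nodes <- shortlist$node
    ranks <- shortlist$cumulative_rank
  } else {
    nodes <- as.character(shortlist)
    ranks <- seq_along(nodes)
  }
  criteria <- setdiff(names(annotations), "gene_symbol")
  if (is.null(conjunction)) conjunction <- criteria
  unknown <- setdiff(conjunction, criteria)
  if (length(unknown) > 0) {
    stop("unknown criterion(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(criteria, collapse = ", "), call. = FALSE)
  }

  idx <- match(nodes, annotations$gene_symbol)
  flags <- vapply(criteria, function(cr) {
    v <- annotations[[cr]][idx]   # NA where symbol missing from table
    v
  }, logical(length(nodes)))
  if (length(nodes) == 1) flags <- matrix(flags, nrow = 1,
                                          dimnames = list(NULL, criteria))

  criterion_counts <- vapply(criteria,
                             function(cr) sum(flags[, cr], na.rm = TRUE),
                             integer(1))
  unannotated_counts <- vapply(criteria,
                               function(cr) sum(is.na(flags[, cr])),
                               integer(1))

  keep <- rep(TRUE, length(nodes))
  intersection_counts <- integer(length(conjunction))
  names(intersection_counts) <- vapply(
    seq_along(conjunction),
    function(i) paste(conjunction[seq_len(i)], collapse = " & "),
    character(1))
  for (i in seq_along(conjunction)) {
    cr <- conjunction[i]
    keep <- keep & !is.na(flags[, cr]) & flags[, cr]
    intersection_counts[i] <- sum(keep)
  }

  final <- data.frame(node = nodes[keep], cumulative_rank = ranks[keep],
                      stringsAsFactors = FALSE)
  final <- final[order(final$cumulative_rank, final$node), , drop = FALSE]
  rownames(final) <- NULL

  structure(list(
    shortlist = nodes,
    criterion_counts = criterion_counts,
    unannotated_counts = unannotated_counts,
    intersection_counts = intersection_counts,
    final_candidates = final,
    conjunction = conjunction,
    provenance = attr(annotations, "provenance")
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Candidate screen over", length(x$shortlist), "shortlisted proteins\n")
  cat("Per-criterion counts (true / unannotated):\n")
  for (cr in names(x$criterion_counts)) {
    src <- if (!is.null(x$provenance) && cr %in% names(x$provenance)) {
      paste0(" [", x$provenance[[cr]], "]")
    } else ""
    cat(sprintf("  %-28s %3d / %d%s\n", cr, x$criterion_counts[[cr]],
                x$unannotated_counts[[cr]], src))
  }
  cat("Conjunction:", paste(x$conjunction, collapse = " & "), "\n")
  cat("Intersection counts:\n")
  for (nm in names(x$intersection_counts)) {
    cat(sprintf("  %-60s %3d\n", nm, x$intersection_counts[[nm]]))
  }
  if (nrow(x$final_candidates) == 0) {
    cat("Final candidates: none\n")
  } else {
    cat("Final candidates:",
        paste(sprintf("%s (cumulative rank %s)", x$final_candidates$node,
                      x$final_candidates$cumulative_rank), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a candidate report
#'
#' Emits a per-criterion count TSV, an intersection TSV and a final
#' candidate TSV next to each other.
#'
#' @param report A `candidate_report` from [screen_candidates()].
#' @param prefix Path prefix; files `<prefix>_criteria.tsv`,
#'   `<prefix>_intersections.tsv`, `<prefix>_candidates.tsv` are written.
#' @return Character vector of the paths written, invisibly.
#' @export
write_candidate_report <- function(report, prefix) {
  crit <- data.frame(
    criterion = names(report$criterion_counts),
    n_true = as.integer(report$criterion_counts),
    n_unannotated = as.integer(report$unannotated_counts),
    provenance = if (is.null(report$provenance)) "" else
      as.character(report$provenance[names(report$criterion_counts)]),
    stringsAsFactors = FALSE
  )
  inter <- data.frame(
    conjunction_prefix = names(report$intersection_counts),
    n = as.integer(report$intersection_counts),
    stringsAsFactors = FALSE
  )
  paths <- paste0(prefix, c("_criteria.tsv", "_intersections.tsv",
                            "_candidates.tsv"))
  utils::write.table(crit, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(inter, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(report$final_candidates, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
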