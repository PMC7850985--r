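#' Pipeline configuration
#'
#' Collects every tunable choice of the prioritization pipeline so a run can
#' record and reproduce them: the spectral-evidence thresholds, the STRING
#' confidence cutoff, the shortlist fraction, bait handling, and the
#' screening conjunction.
#'
#' @param min_unique_peptides,min_psms Evidence thresholds; see
#'   [evidence_thresholds()].
#' @param min_confidence STRING combined-score cutoff on the 0-1 scale
#'   (default 0.4, the "medium confidence" convention).
#' @param fraction Shortlist fraction in (0, 1] (default 0.05).
#' @param include_bait Keep the bait in the ranked list (default `FALSE`;
#'   the bait always participates in the network topology).
#' @param conjunction Ordered criterion names for the candidate screen;
#'   `NULL` uses every criterion in the annotation table.
#' @param bait_accession,bait_symbol Bait identifiers; `NULL` disables bait
#'   addition.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_unique_peptides = 2L,
                            min_psms = 2L,
                            min_confidence = 0.4,
                            fraction = 0.05,
                            include_bait = FALSE,
                            conjunction = NULL,
                            bait_accession = NULL,
                            bait_symbol = NULL) {
  thresholds <- evidence_thresholds(min_unique_peptides, min_psms)
  if (min_confidence < 0 || min_confidence > 1) {
    stop("`min_confidence` must lie in [0, 1]", call. = FALSE)
  }
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    min_unique_peptides = thresholds$min_unique_peptides,
    min_psms = thresholds$min_psms,
    min_confidence = min_confidence,
    fraction = fraction,
    include_bait = isTRUE(include_bait),
    conjunction = conjunction,
    bait_accession = bait_accession,
    bait_symbol = bait_symbol
  ), class = "pipeline_config")
}

#' Run the full prioritization pipeline
#'
#' Chains every stage: parse and filter the identification table, add the
#' bait, read the STRING-style edge list, induce the subnetwork on the
#' filtered node set, score every node (degree, clustering, betweenness,
#' closeness, perturbation, disruption), aggregate the three analysis ranks
#' into the cumulative rank, shortlist the top fraction, and screen the
#' shortlist against the annotation table. All intermediate tables are
#' written to `output_dir` along with a run manifest (effective config,
#' input checksums, package version). On any stage error the partial
#' outputs are removed and the error is re-signalled with the stage name.
#'
#' @param identifications_file Protein identification TSV/CSV.
#' @param edges_file STRING-style edge list.
#' @param annotations_file Annotation TSV/CSV.
#' @param config A [pipeline_config()].
#' @param output_dir Directory for outputs (created if needed).
#' @return The final [screen_candidates()] report, invisibly; its
#'   attributes `rank_table`, `shortlist` and `scores` carry the
#'   intermediate tables.
#' @export
run_pipeline <- function(identifications_file, edges_file, annotations_file,
                         config = pipeline_config(),
                         output_dir = tempfile("netprio_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(identifications_file, edges_file, annotations_file)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written) > 0) unlink(written), add = TRUE)
  emit <- function(path) { written <<- c(written, path); path }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- evidence filter ------------------------------------------------------
  records <- stage("parse_identifications",
                   parse_identifications(identifications_file))
  parts <- stage("filter_identifications",
                 filter_identifications(
                   records,
                   evidence_thresholds(config$min_unique_peptides,
                                       config$min_psms)))
  kept <- parts$kept
  message("evidence filter: ", nrow(records), " in / ", nrow(kept),
          " kept / ", nrow(parts$removed), " removed")
  if (!is.null(config$bait_symbol)) {
    kept <- stage("add_bait",
                  add_bait(kept, config$bait_accession, config$bait_symbol))
  }
  write_identifications(kept, emit(file.path(output_dir, "kept.tsv")))
  write_identifications(parts$removed,
                        emit(file.path(output_dir, "removed.tsv")))

  # -- network --------------------------------------------------------------
  network <- stage("read_string_edges",
                   read_string_edges(edges_file,
                                     min_confidence = config$min_confidence))
  network <- stage("induce_subnetwork",
                   induce_subnetwork(network, kept$gene_symbol))
  write_edges(network, emit(file.path(output_dir, "network.tsv")))
  message("network: ", igraph::vcount(network), " nodes, ",
          igraph::ecount(network), " edges")

  # -- scoring and ranking --------------------------------------------------
  scores <- stage("score_nodes", score_nodes(network))
  write_score_table(scores, emit(file.path(output_dir, "scores.tsv")))
  ranks <- stage("rank_nodes",
                 rank_nodes(scores, bait = config$bait_symbol,
                            include_bait = config$include_bait))
  write_rank_table(ranks, emit(file.path(output_dir, "ranks.tsv")))
  short <- stage("shortlist_top_fraction",
                 shortlist_top_fraction(ranks, config$fraction))
  write_rank_table(short, emit(file.path(output_dir, "shortlist.tsv")))
  message("shortlist: ", nrow(short), " of ", nrow(ranks), " nodes (top ",
          config$fraction * 100, "%)")

  # -- candidate screen -----------------------------------------------------
  annotations <- stage("parse_annotations",
                       parse_annotations(annotations_file))
  report <- stage("screen_candidates",
                  screen_candidates(short, annotations,
                                    conjunction = config$conjunction))
  paths <- write_candidate_report(report,
                                  file.path(output_dir, "candidates"))
  written <- c(written, paths)

  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(c(identifications = identifications_file,
                                     edges = edges_file,
                                     annotations = annotations_file))),
    package_version = as.character(utils::packageVersion("netprio")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest,
                       emit(file.path(output_dir, "manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  ok <- TRUE
  attr(report, "rank_table") <- ranks
  attr(report, "shortlist") <- short
  attr(report, "scores") <- scores
  attr(report, "output_dir") <- output_dir
  invisible(report)
}
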