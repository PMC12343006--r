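.SCHEMA_VERSION <- "1.0"

.store_tables <- c("genes", "representative_exons", "matches_local",
                   "matches_global", "reconciled_matches", "expansions",
                   "expansion_members", "tandemness_pairs", "interdependence",
                   "failures")

#' Persist pipeline results to a relational store
#'
#' Writes every result table of an `exdup_results` object into a single
#' directory as TSV files plus a `manifest.json` describing the schema
#' version, the run id, the full parameter snapshot and the tool version —
#' one self-describing relational store per run. Writing is idempotent per
#' `run_id` (re-writing the same run replaces it); attempting to write into a
#' store with a different schema version is an error.
#'
#' @param results An `exdup_results` object.
#' @param path Store directory (created if needed).
#' @param run_id Identifier of this run (default `"run1"`).
#' @param input_paths Optional character vector of input file paths recorded
#'   in the manifest.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, run_id = "run1", input_paths = character(0)) {
  stopifnot(inherits(results, "exdup_results"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  mpath <- file.path(path, "manifest.json")
  if (file.exists(mpath)) {
    old <- jsonlite::read_json(mpath)
    if (!identical(old$schema_version, .SCHEMA_VERSION))
      stop("existing store has schema version ", old$schema_version,
           ", this package writes ", .SCHEMA_VERSION)
  }
  m <- results$matches
  loc <- m[m$source == "local", , drop = FALSE]
  glo <- m[m$source == "global", , drop = FALSE]
  tabs <- list(
    genes = results$genes,
    representative_exons = results$representative_exons,
    matches_local = loc[, setdiff(names(loc), c("cluster_id", "rt_start",
                                                "rt_end", "reading_frame")),
                        drop = FALSE],
    matches_global = glo[, setdiff(names(glo), c("cluster_id", "rt_start",
                                                 "rt_end", "reading_frame")),
                         drop = FALSE],
    reconciled_matches = m,
    expansions = results$expansions,
    expansion_members = results$expansion_members,
    tandemness_pairs = results$tandem_pairs,
    interdependence = results$interdependence,
    failures = results$failures
  )
  for (nm in names(tabs)) {
    df <- tabs[[nm]]
    utils::write.table(df, file.path(path, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  manifest <- list(
    schema_version = .SCHEMA_VERSION,
    run_id = run_id,
    tool_version = results$run_info$tool_version,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_paths = as.list(input_paths),
    parameters = unclass(results$params),
    tables = as.list(.store_tables)
  )
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a results store back into memory
#'
#' Inverse of [write_results()]: reconstructs an `exdup_results` object
#' (including the parameter snapshot) from a store directory. Classification,
#' intervals and parameters round-trip losslessly.
#'
#' @param path Store directory.
#' @return An `exdup_results` object.
#' @export
read_results <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", path)
  manifest <- jsonlite::read_json(mpath)
  if (!identical(manifest$schema_version, .SCHEMA_VERSION))
    stop("store schema version ", manifest$schema_version,
         " is not supported (expected ", .SCHEMA_VERSION, ")")
  rd <- function(nm) {
    f <- file.path(path, paste0(nm, ".tsv"))
    if (!file.exists(f)) stop("store is missing table '", nm, "'")
    utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = NA, na.strings = "NA")
  }
  p <- manifest$parameters
  params <- search_params(evalue_cutoff = p$evalue_cutoff,
                          query_coverage = p$query_coverage,
                          self_hit = p$self_hit,
                          min_exon_length = p$min_exon_length,
                          exon_overlap = p$exon_overlap,
                          target_overlap = p$target_overlap,
                          pair_ratio = p$pair_ratio, identity = p$identity,
                          aligned_fraction = p$aligned_fraction,
                          mode = p$mode, backend = p$backend,
                          max_hsps = p$max_hsps)
  out <- list(
    genes = rd("genes"),
    representative_exons = rd("representative_exons"),
    matches = rd("reconciled_matches"),
    expansions = rd("expansions"),
    expansion_members = rd("expansion_members"),
    tandem_pairs = rd("tandemness_pairs"),
    interdependence = rd("interdependence"),
    failures = rd("failures"),
    params = params,
    run_info = list(tool_version = manifest$tool_version,
                    n_genes = nrow(rd("genes")),
                    n_failed = nrow(rd("failures")))
  )
  class(out) <- "exdup_results"
  out
}

#' Export simplified CSV views of a results store
#'
#' Writes three summary CSVs (RFC 4180 quoting, deterministic row order by
#' gene id and coordinates): `full_length_events.csv` (reconciled full-length
#' matches), `matches.csv` (every match with its class) and `expansions.csv`.
#' Re-exporting produces byte-identical files.
#'
#' @param x An `exdup_results` object or a store directory path.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
export_csv <- function(x, out_dir) {
  res <- if (inherits(x, "exdup_results")) x else read_results(x)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  m <- res$matches
  ord <- function(df, cols) df[do.call(order, df[cols]), , drop = FALSE]
  views <- list(
    full_length_events = if (nrow(m))
      ord(m[m$match_class == "full_length",
            c("gene_id", "q_start", "q_end", "rt_start", "rt_end", "source",
              "protein_identity"), drop = FALSE],
          c("gene_id", "q_start", "q_end", "rt_start", "rt_end"))
      else m,
    matches = if (nrow(m)) ord(m, c("gene_id", "q_start", "q_end", "t_start", "t_end"))
              else m,
    expansions = if (nrow(res$expansions))
      ord(res$expansions, c("gene_id", "expansion_id")) else res$expansions
  )
  paths <- character(0)
  for (nm in names(views)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    df <- views[[nm]]
    rownames(df) <- NULL
    utils::write.csv(df, f, row.names = FALSE, quote = TRUE, na = "NA",
                     eol = "\n")
    paths <- c(paths, f)
  }
  paths
}
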