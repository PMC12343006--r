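#' Run the full exon-duplication pipeline
#'
#' For every gene: select representative exons, run the local and/or global
#' similarity search, classify matches against the exon/intron architecture,
#' reconcile overlapping targets and assign reading frames, promote partial
#' matches confirmed by the global search, build the match graph, extract
#' expansions, and classify tandemness and transcript interdependence.
#' Genes are processed independently (optionally in parallel); a failure in
#' one gene is quarantined in the `failures` table and does not abort the
#' run. Results are identical for any worker count.
#'
#' @param annotation Either a named list of `gene_model` objects or the path
#'   to a GFF3/GTF file.
#' @param genome Path to the genome FASTA (ignored when `annotation` is a
#'   list of gene models).
#' @param params A [search_params()] object.
#' @param workers Number of parallel workers (forked; the unit of work is one
#'   gene).
#' @param hard_mask Passed to [load_annotation()].
#' @return An object of class `exdup_results`: a list of data.frames
#'   (`genes`, `representative_exons`, `matches`, `expansions`,
#'   `expansion_members`, `tandem_pairs`, `interdependence`, `failures`) plus
#'   `params` and `run_info`.
#' @export
run_exon_duplication_search <- function(annotation, genome = NULL,
                                        params = search_params(),
                                        workers = 1L, hard_mask = FALSE) {
  stopifnot(inherits(params, "search_params"), workers >= 1L)
  genes <- if (is.list(annotation) && all(vapply(annotation, inherits, TRUE, "gene_model")))
    annotation
  else
    load_annotation(annotation, genome, hard_mask = hard_mask)

  worker <- function(g) {
    tryCatch(list(ok = TRUE, res = .process_gene(g, params)),
             error = function(e) list(ok = FALSE, gene_id = g$gene_id,
                                      error = conditionMessage(e)))
  }
  res_list <- if (workers > 1L)
    parallel::mclapply(genes, worker, mc.cores = workers, mc.preschedule = TRUE)
  else
    lapply(genes, worker)

  ok <- vapply(res_list, function(x) isTRUE(x$ok), TRUE)
  failures <- data.frame(
    gene_id = vapply(res_list[!ok], function(x) x$gene_id, ""),
    error = vapply(res_list[!ok], function(x) x$error, ""))
  parts <- lapply(res_list[ok], function(x) x$res)
  bind <- function(field) {
    dfs <- lapply(parts, function(p) p[[field]])
    out <- do.call(rbind, dfs)
    if (is.null(out)) out <- data.frame()
    rownames(out) <- NULL
    out
  }
  out <- list(
    genes = bind("gene"),
    representative_exons = bind("rep_exons"),
    matches = bind("matches"),
    expansions = bind("expansions"),
    expansion_members = bind("expansion_members"),
    tandem_pairs = bind("tandem_pairs"),
    interdependence = bind("interdependence"),
    failures = failures,
    params = params,
    run_info = list(tool_version = as.character(utils::packageVersion("exdup")),
                    n_genes = length(genes), n_failed = sum(!ok))
  )
  class(out) <- "exdup_results"
  out
}

.process_gene <- function(gene, params) {
  exons <- select_representative_exons(gene, params$min_exon_length,
                                       params$exon_overlap)
  matches <- run_search(gene, params, exons)
  matches <- .classify_matches(matches, gene, params$query_coverage)
  matches <- reconcile_targets(matches, gene, params$target_overlap)
  glob <- matches[matches$source == "global", , drop = FALSE]
  matches <- promote_partial_to_full(matches, glob, params$target_overlap)

  graph <- build_match_graph(exons, matches)
  exps <- find_expansions(graph)
  coding <- gene_coding_exons(gene)

  exp_df <- data.frame(gene_id = character(0), expansion_id = integer(0),
                       k = integer(0), event_count = integer(0),
                       full_length_only = logical(0))
  mem_df <- data.frame(gene_id = character(0), expansion_id = integer(0),
                       start = integer(0), end = integer(0))
  tand_df <- data.frame(gene_id = character(0), expansion_id = integer(0),
                        pred_start = integer(0), pred_end = integer(0),
                        succ_start = integer(0), succ_end = integer(0),
                        tandem = logical(0))
  int_df <- data.frame(gene_id = character(0), expansion_id = integer(0),
                       group_type = character(0), members = character(0),
                       class = character(0))
  for (e in exps) {
    exp_df <- rbind(exp_df, data.frame(gene_id = gene$gene_id,
                                       expansion_id = e$expansion_id, k = e$k,
                                       event_count = e$event_count,
                                       full_length_only = e$full_length_only))
    mem_df <- rbind(mem_df, data.frame(gene_id = gene$gene_id,
                                       expansion_id = e$expansion_id,
                                       start = e$vertices$start,
                                       end = e$vertices$end))
    if (e$full_length_only) {
      tp <- classify_tandemness(e, coding)
      if (nrow(tp))
        tand_df <- rbind(tand_df, cbind(data.frame(gene_id = gene$gene_id,
                                                   expansion_id = e$expansion_id), tp))
      cls <- tryCatch(classify_interdependence(gene, e$vertices),
                      error = function(err) NA_character_)
      int_df <- rbind(int_df, data.frame(
        gene_id = gene$gene_id, expansion_id = e$expansion_id,
        group_type = "expansion",
        members = paste(.iv_key(e$vertices$start, e$vertices$end), collapse = ","),
        class = cls))
      # every full-length pair connected within the expansion
      if (e$k > 2L) {
        for (i in seq_len(nrow(e$vertices) - 1L)) {
          for (j in (i + 1L):nrow(e$vertices)) {
            pair <- e$vertices[c(i, j), , drop = FALSE]
            pcls <- tryCatch(classify_interdependence(gene, pair),
                             error = function(err) NA_character_)
            int_df <- rbind(int_df, data.frame(
              gene_id = gene$gene_id, expansion_id = e$expansion_id,
              group_type = "pair",
              members = paste(.iv_key(pair$start, pair$end), collapse = ","),
              class = pcls))
          }
        }
      }
    }
  }
  list(
    gene = data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                      strand = gene$strand, start = gene$start, end = gene$end,
                      n_transcripts = length(gene$transcripts)),
    rep_exons = if (nrow(exons$exons))
      data.frame(gene_id = gene$gene_id, start = exons$exons$start,
                 end = exons$exons$end)
    else data.frame(gene_id = character(0), start = integer(0), end = integer(0)),
    matches = matches, expansions = exp_df, expansion_members = mem_df,
    tandem_pairs = tand_df, interdependence = int_df
  )
}

#' @export
print.exdup_results <- function(x, ...) {
  cat("Exon duplication search results\n")
  cat("  genes processed:   ", nrow(x$genes), "\n")
  cat("  quarantined genes: ", nrow(x$failures), "\n")
  cat("  matches:           ", nrow(x$matches), "\n")
  if (nrow(x$matches)) {
    tb <- table(x$matches$match_class)
    cat("    by class:        ",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  cat("  expansions:        ", nrow(x$expansions),
      " (full-length:", sum(x$expansions$full_length_only %||% logical(0)), ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.exdup_results <- function(object, ...) {
  print(object)
  if (nrow(object$interdependence)) {
    cat("  interdependence (expansion groups):\n")
    tb <- table(object$interdependence$class[
      object$interdependence$group_type == "expansion"])
    for (nm in names(tb)) cat("    ", nm, ": ", tb[[nm]], "\n", sep = "")
  }
  if (nrow(object$tandem_pairs))
    cat("  tandem pairs: ", sum(object$tandem_pairs$tandem), "/",
        nrow(object$tandem_pairs), "\n")
  invisible(object)
}
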