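.iv_key <- function(s, e) paste0(s, "-", e)

#' Build the per-gene directed match graph
#'
#' Vertices are the distinct intervals among the representative exons and the
#' reconciled targets (compared by exact coordinates, so a target snapped to
#' an annotated exon merges with that exon's vertex). Each local match
#' contributes one directed edge query -> reconciled target; global matches
#' are reciprocal and contribute edges in both directions. Self-loops (query
#' reconciled onto itself) are dropped.
#'
#' @param exons A `representative_exons` set.
#' @param reconciled Reconciled matches data.frame (see
#'   [reconcile_targets()]).
#' @return An `igraph` directed graph; vertex attributes `start`, `end`;
#'   edge attributes `match_class`, `source`.
#' @export
build_match_graph <- function(exons, reconciled) {
  vs <- data.frame(start = c(exons$exons$start, reconciled$rt_start),
                   end = c(exons$exons$end, reconciled$rt_end))
  vs <- unique(vs)
  vs <- .sort_intervals(vs)
  name <- .iv_key(vs$start, vs$end)
  g <- igraph::make_empty_graph(n = nrow(vs), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = name)
  g <- igraph::set_vertex_attr(g, "start", value = vs$start)
  g <- igraph::set_vertex_attr(g, "end", value = vs$end)
  if (nrow(reconciled)) {
    from <- .iv_key(reconciled$q_start, reconciled$q_end)
    to <- .iv_key(reconciled$rt_start, reconciled$rt_end)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    cls <- reconciled$match_class[keep]; src <- reconciled$source[keep]
    # query exons of matches may themselves be absent from the vertex table
    # only if never a representative; guard by adding missing vertices
    missing <- setdiff(unique(c(from, to)), name)
    if (length(missing)) {
      sm <- as.integer(sub("-.*", "", missing))
      em <- as.integer(sub(".*-", "", missing))
      g <- igraph::add_vertices(g, length(missing), name = missing,
                                start = sm, end = em)
    }
    bidir <- src == "global"
    ef <- c(rbind(from, to), rbind(to[bidir], from[bidir]))
    g <- igraph::add_edges(g, ef,
           match_class = c(cls, cls[bidir]), source = c(src, src[bidir]))
  }
  g
}

#' Extract expansions from a match graph
#'
#' An expansion is a connected component of the undirected projection of the
#' match graph, excluding isolated vertices: a family of mutually related
#' exon copies arising from repeated duplication. The size `k` of an
#' expansion counts its vertices; assuming no multi-exon duplication, the
#' number of duplication events in the family is `k - 1`. An expansion is
#' *full-length* when every edge in the component derives from a full-length
#' match.
#'
#' @param graph Directed match graph from [build_match_graph()].
#' @return List of expansions; each a list with `expansion_id`, `vertices`
#'   (data.frame `start`, `end`, sorted), `k`, `event_count`,
#'   `full_length_only`.
#' @export
find_expansions <- function(graph) {
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(match_class = "first",
                                                     source = "first"))
  comp <- igraph::components(und)
  out <- list()
  for (k in seq_len(comp$no)) {
    vid <- which(comp$membership == k)
    if (length(vid) < 2L) next
    sub <- igraph::induced_subgraph(graph, vid)
    vs <- data.frame(start = igraph::vertex_attr(sub, "start"),
                     end = igraph::vertex_attr(sub, "end"))
    vs <- .sort_intervals(vs); rownames(vs) <- NULL
    cls <- igraph::edge_attr(sub, "match_class")
    out[[length(out) + 1L]] <- list(
      expansion_id = length(out) + 1L, vertices = vs, k = nrow(vs),
      event_count = nrow(vs) - 1L,
      full_length_only = length(cls) > 0L && all(cls == "full_length"))
  }
  out
}

#' Tandemness of the events within a full-length expansion
#'
#' Sorts the expansion's exons by `(start, end)`, forms consecutive
#' predecessor-successor pairs, and calls a pair tandem when no complete exon
#' lies between the two: the gene's coding exons are clustered with
#' [cluster_intervals()] at cutoff 0 and the pair must fall in consecutive
#' clusters.
#'
#' @param expansion An expansion (from [find_expansions()]) with
#'   `full_length_only = TRUE`.
#' @param all_coding_exons data.frame of all coding exons of the gene
#'   (see [gene_coding_exons()]).
#' @return data.frame with columns `pred_start`, `pred_end`, `succ_start`,
#'   `succ_end`, `tandem`.
#' @export
classify_tandemness <- function(expansion, all_coding_exons) {
  if (!isTRUE(expansion$full_length_only))
    stop("tandemness is defined for full-length expansions only")
  ids <- interval_cluster_ids(all_coding_exons, 0)
  # position of an expansion exon = cluster of the coding exon it overlaps most
  pos_of <- function(s, e) {
    r <- .overlap_ratio_vec(s, e, all_coding_exons$start, all_coding_exons$end)
    if (max(r) == 0) return(NA_integer_)
    ids[which.max(r)]
  }
  vs <- expansion$vertices
  pos <- vapply(seq_len(nrow(vs)), function(i) pos_of(vs$start[i], vs$end[i]), 0L)
  n <- nrow(vs)
  if (n < 2L) return(data.frame(pred_start = integer(0), pred_end = integer(0),
                                succ_start = integer(0), succ_end = integer(0),
                                tandem = logical(0)))
  i <- seq_len(n - 1L)
  data.frame(pred_start = vs$start[i], pred_end = vs$end[i],
             succ_start = vs$start[i + 1L], succ_end = vs$end[i + 1L],
             tandem = !is.na(pos[i]) & !is.na(pos[i + 1L]) &
                      abs(pos[i + 1L] - pos[i]) == 1L)
}

#' Transcript interdependence of a group of duplicate exons
#'
#' Classifies how a group of duplicated exons co-occurs across the gene's
#' transcripts. A duplicate is "in" a transcript when some CDS interval of
#' that transcript overlaps it by an [overlap_ratio()] of at least
#' `membership_overlap` (tolerating minor isoform boundary variation).
#' Classes: `obligate` — every duplicate in every transcript; `exclusive` —
#' no transcript contains two or more of the duplicates; `flexible` — every
#' transcript carries at least one duplicate without an obligate or exclusive
#' pattern. When at least one transcript lacks the group entirely, the class
#' is `optional_*`, sub-classified over only the transcripts that carry at
#' least one duplicate.
#'
#' @param gene A `gene_model`.
#' @param duplicate_group data.frame (`start`, `end`) of at least two
#'   exon-coordinate intervals (intronic matches are excluded from
#'   interdependence classification).
#' @param membership_overlap Overlap-ratio threshold for transcript
#'   membership (default 0.9).
#' @return One of `"obligate"`, `"exclusive"`, `"flexible"`,
#'   `"optional_obligate"`, `"optional_exclusive"`, `"optional_flexible"`.
#' @export
classify_interdependence <- function(gene, duplicate_group, membership_overlap = 0.9) {
  duplicate_group <- as.data.frame(duplicate_group)
  if (nrow(duplicate_group) < 2L)
    stop("interdependence needs a group of at least two duplicates")
  txn <- names(gene$transcripts)
  present <- matrix(FALSE, length(txn), nrow(duplicate_group),
                    dimnames = list(txn, NULL))
  for (t in seq_along(txn)) {
    tx <- gene$transcripts[[t]]
    for (d in seq_len(nrow(duplicate_group))) {
      r <- .overlap_ratio_vec(duplicate_group$start[d], duplicate_group$end[d],
                              tx$start, tx$end)
      present[t, d] <- any(r >= membership_overlap)
    }
  }
  .interdependence_from_matrix(present)
}

# classification from a transcripts x duplicates presence matrix
.interdependence_from_matrix <- function(present) {
  has_any <- rowSums(present) > 0L
  optional <- any(!has_any)
  sub <- present[has_any, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no transcript contains any member of the duplicate group")
  cls <- if (all(sub)) "obligate"
         else if (all(rowSums(sub) <= 1L)) "exclusive"
         else "flexible"
  if (optional) paste0("optional_", cls) else cls
}
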