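#' Classify a match against the gene's exon/intron architecture
#'
#' Assigns one of four classes to a (query, target) match, evaluated in the
#' precedence order full_length > partial > inter_boundary > intronic:
#'
#' * `full_length` — the aligned query fraction reaches `te` and the target
#'   covers at least `te` of some annotated exon's length.
#' * `partial` — the target lies inside an annotated exon or encompasses one,
#'   and coverage reaches `te` for the query exon or for the annotated exon
#'   but not for both.
#' * `inter_boundary` — query coverage reaches `te`, every overlapped exon is
#'   covered below `te`, and the target spans both exonic and intronic
#'   sequence.
#' * `intronic` — at least `te` of the target lies in intron space.
#'
#' Annotated exons are the union of CDS intervals over all transcripts, not
#' only the representatives.
#'
#' @param query,target Length-2 vectors `c(start, end)`, genomic coordinates.
#' @param q_cov Aligned query fraction of the match.
#' @param annotated_exons data.frame (`start`, `end`): all coding exons of the
#'   gene.
#' @param intron_space data.frame (`start`, `end`): the gene span minus the
#'   exon space.
#' @param te Coverage threshold (the search's `query_coverage`).
#' @return One of `"full_length"`, `"partial"`, `"inter_boundary"`,
#'   `"intronic"`, or `"unclassified"` when no rule applies.
#' @export
classify_match <- function(query, target, q_cov, annotated_exons, intron_space, te) {
  stopifnot(target[1] <= target[2])
  t_len <- .interval_len(target[1], target[2])
  ex <- annotated_exons
  ov_ex <- if (nrow(ex)) pmax(0, pmin(target[2], ex$end) - pmax(target[1], ex$start) + 1)
           else numeric(0)
  ex_cov <- if (nrow(ex)) ov_ex / .interval_len(ex$start, ex$end) else numeric(0)
  touches <- ov_ex > 0
  q_ok <- q_cov >= te

  if (q_ok && any(ex_cov >= te)) return("full_length")

  # partial: target within an exon or encompassing one, coverage met for
  # exactly one of query / exon
  if (any(touches)) {
    inside <- ex$start <= target[1] & ex$end >= target[2]
    engulfs <- target[1] <= ex$start & target[2] >= ex$end
    for (k in which(touches & (inside | engulfs))) {
      if (xor(q_ok, ex_cov[k] >= te)) return("partial")
    }
  }

  ex_total <- sum(ov_ex[touches])
  intr_ov <- if (nrow(intron_space))
    sum(pmax(0, pmin(target[2], intron_space$end) - pmax(target[1], intron_space$start) + 1))
  else 0

  if (q_ok && any(touches) && all(ex_cov[touches] < te) && ex_total > 0 && intr_ov > 0)
    return("inter_boundary")

  if (intr_ov >= te * t_len) return("intronic")
  "unclassified"
}

# classify every row of a matches data.frame for one gene
.classify_matches <- function(matches, gene, te) {
  ex <- gene_coding_exons(gene)
  intr <- .intron_space(gene)
  if (nrow(matches) == 0L) {
    matches$match_class <- character(0)
    return(matches)
  }
  if (any(matches$t_start < gene$start | matches$t_end > gene$end))
    stop("match target outside the span of gene ", gene$gene_id)
  matches$match_class <- vapply(seq_len(nrow(matches)), function(i) {
    classify_match(c(matches$q_start[i], matches$q_end[i]),
                   c(matches$t_start[i], matches$t_end[i]),
                   matches$aligned_query_fraction[i], ex, intr, te)
  }, "")
  # a global match is by construction a full-exon duplication event
  matches$match_class[matches$source == "global"] <- "full_length"
  # a full-length duplication is reciprocal; no other class is
  matches$reciprocal <- matches$match_class == "full_length"
  matches
}

#' Assign the reading frame of a target sequence
#'
#' Translates `target_nt` in frames 0, 1, 2, globally aligns each translation
#' to the query exon peptide (whose frame is known), and returns the frame
#' with the highest alignment identity; ties go to the lowest frame index.
#'
#' @param query_pep Query exon peptide (character or `AAString`).
#' @param target_nt Target nucleotide sequence (character), length >= 3.
#' @return Integer frame in `{0, 1, 2}`, with attribute `identity`.
#' @export
assign_reading_frame <- function(query_pep, target_nt) {
  stopifnot(nchar(as.character(target_nt)) >= 3L)
  if (is.character(query_pep)) query_pep <- Biostrings::AAString(query_pep)
  B62 <- .blosum62()
  trans <- lapply(0:2, function(f) .translate_frame(as.character(target_nt), f))
  ok <- !vapply(trans, is.null, TRUE)
  ids <- rep(-Inf, 3L)
  if (any(ok)) {
    als <- Biostrings::pairwiseAlignment(Biostrings::AAStringSet(trans[ok]),
             query_pep, substitutionMatrix = B62, gapOpening = .GAP_OPEN,
             gapExtension = .GAP_EXT, type = "global")
    ids[ok] <- vapply(seq_len(sum(ok)),
                      function(i) .alignment_stats(als[i])$identity, 0)
  }
  f <- which.max(ids) - 1L  # which.max takes the first maximum: lowest frame
  structure(f, identity = ids[f + 1L])
}

#' Reconcile overlapping target intervals
#'
#' Clusters the target intervals of a gene's matches with
#' [cluster_intervals()] at cutoff `ct` and replaces each target by its
#' cluster's reconciled interval: clusters composed of full-length matches
#' snap to the annotated exon that maps to the targets (highest
#' [overlap_ratio()] with the cluster's merged footprint; ties to the
#' shortest exon), other clusters take the target of the most significant
#' member (lowest E-value, then largest aligned query fraction, then earliest
#' target). Every input match appears exactly once in the output with its
#' `cluster_id`, reconciled target (`rt_start`, `rt_end`) and reading frame;
#' reconciled matches may still overlap. The operation is idempotent.
#'
#' @param matches Classified matches data.frame for one gene (needs a
#'   `match_class` column; see [classify_match()]).
#' @param gene The `gene_model` the matches belong to.
#' @param ct Target overlap cutoff.
#' @return The matches data.frame with columns `cluster_id`, `rt_start`,
#'   `rt_end`, `reading_frame` added.
#' @export
reconcile_targets <- function(matches, gene, ct = 0.9) {
  if (is.null(matches$match_class))
    stop("matches must be classified before reconciliation")
  if (nrow(matches) == 0L) {
    matches$cluster_id <- integer(0)
    matches$rt_start <- integer(0); matches$rt_end <- integer(0)
    matches$reading_frame <- integer(0)
    return(matches)
  }
  ex <- gene_coding_exons(gene)
  ids <- interval_cluster_ids(data.frame(start = matches$t_start, end = matches$t_end), ct)
  matches$cluster_id <- ids
  matches$rt_start <- NA_integer_; matches$rt_end <- NA_integer_
  for (k in unique(ids)) {
    sel <- which(ids == k)
    cl <- matches[sel, , drop = FALSE]
    if (all(cl$match_class == "full_length") && nrow(ex) > 0L) {
      foot <- c(min(cl$t_start), max(cl$t_end))
      r <- .overlap_ratio_vec(foot[1], foot[2], ex$start, ex$end)
      if (max(r) > 0) {
        cand <- which(r == max(r))
        lens <- .interval_len(ex$start[cand], ex$end[cand])
        best <- cand[order(lens, ex$start[cand], ex$end[cand])][1L]
        matches$rt_start[sel] <- ex$start[best]
        matches$rt_end[sel] <- ex$end[best]
        next
      }
    }
    ev <- cl$evalue; ev[is.na(ev)] <- Inf
    o <- order(ev, -cl$aligned_query_fraction, cl$t_start, cl$t_end)[1L]
    matches$rt_start[sel] <- cl$t_start[o]
    matches$rt_end[sel] <- cl$t_end[o]
  }
  matches$reading_frame <- vapply(seq_len(nrow(matches)), function(i) {
    pep <- .exon_peptide(gene, matches$q_start[i], matches$q_end[i])
    if (is.null(pep)) return(NA_integer_)
    tnt <- gene_sequence(gene, matches$rt_start[i], matches$rt_end[i])
    if (nchar(tnt) < 3L) return(NA_integer_)
    as.integer(assign_reading_frame(pep, tnt))
  }, 0L)
  matches
}

#' Promote partial local matches confirmed by the global search
#'
#' A local match classified as partial whose (query, target) pair of
#' representative exons also appears as a retained global match is a
#' full-exon duplication event and is reclassified `full_length`. Pair
#' identity requires the local query to coincide with one global endpoint and
#' the reconciled target to be contained in the other endpoint's exon (or to
#' encompass it) by at least `ct` of the shorter of the two; mere overlap
#' with an unrelated pair does not promote.
#'
#' @param reconciled Reconciled local matches data.frame (see
#'   [reconcile_targets()]).
#' @param global_matches Global matches data.frame.
#' @param ct Overlap cutoff used to identify the target with a global exon.
#' @return `reconciled` with promoted `match_class` values.
#' @export
promote_partial_to_full <- function(reconciled, global_matches, ct = 0.9) {
  if (nrow(reconciled) == 0L || nrow(global_matches) == 0L) return(reconciled)
  # containment ratio: overlap relative to the shorter of the two intervals;
  # a partial target sits inside (or engulfs) its exon, so min-overlap would
  # never fire here
  contain <- function(a, b) {
    ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1
    if (ov <= 0) return(0)
    ov / min(a[2] - a[1] + 1, b[2] - b[1] + 1)
  }
  for (i in which(reconciled$match_class == "partial" & reconciled$source == "local")) {
    q <- c(reconciled$q_start[i], reconciled$q_end[i])
    t <- c(reconciled$rt_start[i], reconciled$rt_end[i])
    for (j in seq_len(nrow(global_matches))) {
      g1 <- c(global_matches$q_start[j], global_matches$q_end[j])
      g2 <- c(global_matches$t_start[j], global_matches$t_end[j])
      hit <- (all(q == g1) && contain(t, g2) >= ct) ||
             (all(q == g2) && contain(t, g1) >= ct)
      if (hit) {
        reconciled$match_class[i] <- "full_length"
        reconciled$reciprocal[i] <- TRUE
        break
      }
    }
  }
  reconciled
}
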