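#' Minimum interval overlap ratio
#'
#' Overlap of two closed genomic intervals, measured relative to the longer
#' interval: `length(intersection) / max(length(i1), length(i2))`, or 0 when
#' the intervals are disjoint. Interval lengths are closed-interval lengths,
#' `end - start + 1`. The ratio is symmetric and lies in `[0, 1]`; it equals 1
#' only for identical intervals.
#'
#' @param i1,i2 Closed intervals as length-2 numeric vectors `c(start, end)`
#'   with `start <= end`, 1-based inclusive coordinates.
#' @return A single number in `[0, 1]`.
#' @examples
#' overlap_ratio(c(1, 10), c(6, 20))  # 5 / 15
#' @export
overlap_ratio <- function(i1, i2) {
  stopifnot(length(i1) == 2L, length(i2) == 2L, i1[1] <= i1[2], i2[1] <= i2[2])
  ov <- min(i1[2], i2[2]) - max(i1[1], i2[1]) + 1
  if (ov <= 0) return(0)
  ov / max(i1[2] - i1[1] + 1, i2[2] - i2[1] + 1)
}

# vectorized overlap ratio of (s1,e1) against (s2,e2); same definition
.overlap_ratio_vec <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  r <- ov / pmax(e1 - s1 + 1, e2 - s2 + 1)
  r[ov <= 0] <- 0
  r
}

.interval_len <- function(s, e) e - s + 1

# canonical deterministic order: by start, then end
.sort_intervals <- function(df) df[order(df$start, df$end), , drop = FALSE]

#' Deterministic clustering of genomic intervals
#'
#' Partitions a set of closed intervals by a single-linkage sweep: intervals
#' are sorted by `(start, end)` and an interval joins the currently open
#' cluster when its [overlap_ratio()] with the most recently added member is
#' strictly greater than `cutoff`; otherwise it opens a new cluster. The
#' partition is therefore the set of maximal runs, in sorted order, whose
#' consecutive members overlap by more than `cutoff` — identical to the
#' transitive closure of the consecutive-pair overlap relation, and invariant
#' under permutation of the input.
#'
#' @param intervals data.frame with integer columns `start`, `end`
#'   (1-based, inclusive). Zero rows allowed.
#' @param cutoff Overlap-ratio cutoff in `[0, 1]`; membership uses strict
#'   inequality, so `cutoff = 1` yields singletons and `cutoff = 0` merges any
#'   chain of overlapping intervals.
#' @return A list of clusters in sorted order. Each cluster is a list with
#'   `members` (data.frame, sorted by `(start, end)`) and `representative`
#'   (`c(start, end)` of the shortest member; ties broken by `(start, end)`
#'   order).
#' @seealso [interval_cluster_ids()] for per-input cluster labels.
#' @export
cluster_intervals <- function(intervals, cutoff) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff < 0 || cutoff > 1)
    stop("`cutoff` must be a single value in [0, 1]")
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) return(list())
  ids <- interval_cluster_ids(intervals, cutoff)
  ord <- order(intervals$start, intervals$end)
  out <- list()
  for (k in unique(ids[ord])) {
    m <- .sort_intervals(intervals[ids == k, c("start", "end"), drop = FALSE])
    rownames(m) <- NULL
    len <- .interval_len(m$start, m$end)
    rep_i <- which(len == min(len))[1L]  # members already in (start, end) order
    out[[length(out) + 1L]] <- list(
      members = m,
      representative = c(start = m$start[rep_i], end = m$end[rep_i])
    )
  }
  out
}

#' Cluster labels for intervals, in input order
#'
#' Same partition as [cluster_intervals()], returned as an integer cluster id
#' per input row; ids are numbered 1, 2, ... along the sorted order.
#'
#' @inheritParams cluster_intervals
#' @return Integer vector of length `nrow(intervals)`.
#' @export
interval_cluster_ids <- function(intervals, cutoff) {
  intervals <- as.data.frame(intervals)
  n <- nrow(intervals)
  if (n == 0L) return(integer(0))
  ord <- order(intervals$start, intervals$end)
  s <- intervals$start[ord]; e <- intervals$end[ord]
  id_sorted <- integer(n)
  id_sorted[1L] <- 1L
  if (n > 1L) {
    link <- .overlap_ratio_vec(s[-n], e[-n], s[-1L], e[-1L]) > cutoff
    id_sorted[-1L] <- 1L + cumsum(!link)
  }
  ids <- integer(n)
  ids[ord] <- id_sorted
  ids
}

#' Select the representative exons of a gene
#'
#' Pools the CDS intervals of all transcripts of a gene, collapses duplicate
#' coordinates, drops exons not longer than `l` nucleotides, clusters the
#' remainder with [cluster_intervals()] at cutoff `ce`, and takes the shortest
#' member of each cluster as its representative (maximizing alignment
#' coverage in the downstream search). With `ce = 0` the representatives are
#' pairwise non-overlapping; with `ce = 1` every length-passing exon is
#' admitted.
#'
#' @param gene A `gene_model` (see [load_annotation()]).
#' @param l Minimum exon length in nucleotides; exons must satisfy
#'   `length > l` (strict).
#' @param ce Exon overlap-ratio cutoff in `[0, 1]` for clustering.
#' @return An object of class `representative_exons`: a list with `gene_id`,
#'   `exons` (data.frame `start`, `end`, sorted), `l` and `ce`.
#' @export
select_representative_exons <- function(gene, l = 30L, ce = 0.9) {
  stopifnot(inherits(gene, "gene_model"))
  cds <- gene_coding_exons(gene)
  cds <- cds[.interval_len(cds$start, cds$end) > l, , drop = FALSE]
  if (nrow(cds) == 0L) {
    message("gene ", gene$gene_id, ": no exon longer than l = ", l)
    exons <- data.frame(start = integer(0), end = integer(0))
  } else {
    cl <- cluster_intervals(cds, ce)
    exons <- data.frame(
      start = vapply(cl, function(x) unname(x$representative["start"]), 0),
      end = vapply(cl, function(x) unname(x$representative["end"]), 0)
    )
    exons <- .sort_intervals(exons)
    rownames(exons) <- NULL
  }
  structure(list(gene_id = gene$gene_id, exons = exons, l = l, ce = ce),
            class = "representative_exons")
}

#' @export
print.representative_exons <- function(x, ...) {
  cat("Representative exons for gene", x$gene_id, "\n")
  cat("  n =", nrow(x$exons), " (l =", x$l, "nt, ce =", x$ce, ")\n")
  if (nrow(x$exons)) print(x$exons)
  invisible(x)
}

#' All distinct coding-exon intervals of a gene
#'
#' Union of the CDS intervals over all transcripts, deduplicated by exact
#' coordinates and sorted by `(start, end)`.
#'
#' @param gene A `gene_model`.
#' @return data.frame with columns `start`, `end`.
#' @export
gene_coding_exons <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  cds <- do.call(rbind, lapply(gene$transcripts, function(tx) tx[, c("start", "end")]))
  cds <- unique(cds)
  cds <- .sort_intervals(cds)
  rownames(cds) <- NULL
  cds
}

# complement of the coding-exon space within the gene span, as intervals
.intron_space <- function(gene) {
  ex <- gene_coding_exons(gene)
  if (nrow(ex) == 0L)
    return(data.frame(start = gene$start, end = gene$end))
  ir <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
  gaps <- IRanges::setdiff(IRanges::IRanges(gene$start, gene$end), ir)
  data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps))
}
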