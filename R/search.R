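#' Search parameters for the duplication search
#'
#' Bundles every threshold governing a run. All fractional cutoffs are in
#' `[0, 1]`. Defaults are the package's implementation defaults; every value
#' can be overridden here or on the command line.
#'
#' @param evalue_cutoff E-value cutoff for local matches (pairwise search
#'   space: query exon vs its gene). Default `1e-3`.
#' @param query_coverage `te`, minimum fraction of the query exon that must be
#'   aligned for a local match; also drives match classification. Default 0.9.
#' @param self_hit `ts`: local hits whose target overlaps the query by an
#'   [overlap_ratio()] of at least `ts` are discarded as self-matches.
#'   Default 0.5.
#' @param min_exon_length `l`, minimum representative-exon length in nt
#'   (strict; exons must be longer). Default 30.
#' @param exon_overlap `ce`, overlap cutoff for representative-exon
#'   clustering. Default 0.9.
#' @param target_overlap `ct`, overlap cutoff for target-interval
#'   reconciliation. Default 0.9.
#' @param pair_ratio `tp`: a pair of representative exons enters the global
#'   search only when shorter/longer length ratio is strictly greater than
#'   `tp`. Default 0.7.
#' @param identity `ti`, minimum protein alignment identity for a global
#'   match. Default 0.4.
#' @param aligned_fraction `ta`, minimum fraction of alignment columns that
#'   are non-gap in both sequences for a global match. Default 0.9.
#' @param mode One of `"local"`, `"global"`, `"both"`.
#' @param backend `"builtin"` (six-frame translated Smith-Waterman with
#'   Karlin-Altschul E-values; no external software) or `"external"`
#'   (a tblastx-compatible executable on the PATH).
#' @param max_hsps Maximum local hits collected per query/frame combination
#'   before the iterative masking stops. Default 6.
#' @return An object of class `search_params` (a validated list).
#' @export
search_params <- function(evalue_cutoff = 1e-3, query_coverage = 0.9,
                          self_hit = 0.5, min_exon_length = 30L,
                          exon_overlap = 0.9, target_overlap = 0.9,
                          pair_ratio = 0.7, identity = 0.4,
                          aligned_fraction = 0.9,
                          mode = c("both", "local", "global"),
                          backend = c("builtin", "external"),
                          max_hsps = 6L) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  fracs <- c(query_coverage = query_coverage, self_hit = self_hit,
             exon_overlap = exon_overlap, target_overlap = target_overlap,
             pair_ratio = pair_ratio, identity = identity,
             aligned_fraction = aligned_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractional thresholds must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (evalue_cutoff <= 0) stop("`evalue_cutoff` must be positive")
  structure(list(evalue_cutoff = evalue_cutoff, query_coverage = query_coverage,
                 self_hit = self_hit, min_exon_length = as.integer(min_exon_length),
                 exon_overlap = exon_overlap, target_overlap = target_overlap,
                 pair_ratio = pair_ratio, identity = identity,
                 aligned_fraction = aligned_fraction, mode = mode,
                 backend = backend, max_hsps = as.integer(max_hsps)),
        class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat("Duplication search parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

.empty_matches <- function() {
  data.frame(gene_id = character(0), q_start = integer(0), q_end = integer(0),
             t_start = integer(0), t_end = integer(0), source = character(0),
             evalue = numeric(0), protein_identity = numeric(0),
             dna_identity = numeric(0), aligned_query_fraction = numeric(0),
             reciprocal = logical(0))
}

# translate a nucleotide string in frame f (0,1,2); trailing partial codon
# dropped; ambiguity -> X, stops -> *
.translate_frame <- function(nt, f = 0L) {
  n <- nchar(nt) - f
  n <- 3L * (n %/% 3L)
  if (n < 3L) return(NULL)
  Biostrings::translate(Biostrings::DNAString(substring(nt, f + 1L, f + n)),
                        if.fuzzy.codon = "X", no.init.codon = TRUE)
}

# identity / aligned-fraction bookkeeping from a PairwiseAlignments object:
# identity over columns non-gap in both; aligned fraction = such columns /
# total alignment columns
.alignment_stats <- function(al) {
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  both <- a != "-" & b != "-"
  n_both <- sum(both)
  list(identity = if (n_both) sum(a[both] == b[both]) / n_both else 0,
       aligned_fraction = if (length(a)) n_both / length(a) else 0)
}

# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1),
# the standard values used by protein BLAST
.KA_LAMBDA <- 0.267
.KA_K <- 0.041
.GAP_OPEN <- 11
.GAP_EXT <- 1

.ka_evalue <- function(score, m_aa, n_aa) .KA_K * m_aa * n_aa * exp(-.KA_LAMBDA * score)

# Six-frame translations of the gene in strand space, with the mapping from
# amino-acid positions back to strand-space nucleotide intervals.
.subject_frames <- function(strand_seq) {
  L <- nchar(strand_seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(strand_seq)))
  frames <- list()
  for (f in 0:2) {
    aa <- .translate_frame(strand_seq, f)
    if (!is.null(aa))
      frames[[length(frames) + 1L]] <- list(aa = aa, f = f, rev = FALSE, L = L)
    aar <- .translate_frame(rc, f)
    if (!is.null(aar))
      frames[[length(frames) + 1L]] <- list(aa = aar, f = f, rev = TRUE, L = L)
  }
  frames
}

# aa interval [p1, p2] in a subject frame -> strand-space nt interval
.frame_aa_to_nt <- function(fr, p1, p2) {
  s <- fr$f + 3L * (p1 - 1L) + 1L
  e <- fr$f + 3L * p2
  if (!fr$rev) c(s, e) else c(fr$L - e + 1L, fr$L - s + 1L)
}

#' Local duplication search: representative exons vs the whole gene
#'
#' Queries each representative exon, translated, against the full gene
#' sequence (introns included) and returns local similarity matches. With the
#' built-in backend, each query frame (3) is aligned against each of the six
#' translation frames of the gene by Smith-Waterman (BLOSUM62, gap 11/1);
#' further co-optimal copies are recovered by masking each hit and
#' re-aligning. E-values use Karlin-Altschul statistics with the pairwise
#' search space (query length x gene length, in residues). Matches must
#' satisfy `evalue <= evalue_cutoff` and an aligned query fraction of at least
#' `query_coverage`; hits whose target overlaps the query interval by
#' `self_hit` or more are self-matches and are dropped. With the external
#' backend the same contract is fulfilled by a tblastx-compatible executable.
#'
#' @param gene A `gene_model`.
#' @param exons A `representative_exons` set for the gene.
#' @param params A [search_params()] object.
#' @return A matches data.frame (one row per match) with columns `gene_id`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `source`, `evalue`,
#'   `protein_identity`, `dna_identity`, `aligned_query_fraction`,
#'   `reciprocal`. Target coordinates are genomic.
#' @export
local_search <- function(gene, exons, params = search_params()) {
  stopifnot(inherits(gene, "gene_model"), inherits(exons, "representative_exons"))
  if (nrow(exons$exons) == 0L) return(.empty_matches())
  if (params$backend == "external") return(.local_search_tblastx(gene, exons, params))
  .local_search_builtin(gene, exons, params)
}

.local_search_builtin <- function(gene, exons, params) {
  strand_seq <- .gene_strand_seq(gene)
  frames <- .subject_frames(strand_seq)
  n_aa <- nchar(strand_seq) / 3
  B62 <- .blosum62()

  # each query exon is translated once, in its annotated coding frame; the
  # subject side is translated in all six frames, so any duplicate copy --
  # frame-shifted or inverted -- is still reachable. All queries are aligned
  # against a subject frame in one batched call on the first, unmasked pass.
  qmeta <- list()
  qseqs <- list()
  for (i in seq_len(nrow(exons$exons))) {
    qs <- exons$exons$start[i]; qe <- exons$exons$end[i]
    q_nt <- gene_sequence(gene, qs, qe)
    qf <- .exon_phase(gene, qs, qe)
    q_aa <- .translate_frame(q_nt, qf)
    if (is.null(q_aa)) next
    qmeta[[length(qmeta) + 1L]] <- list(qs = qs, qe = qe,
                                        q_len = nchar(q_nt), qf = qf)
    qseqs[[length(qseqs) + 1L]] <- q_aa
  }
  if (length(qseqs) == 0L) return(.empty_matches())
  qset <- Biostrings::AAStringSet(qseqs)
  rows <- list()
  emit <- function(al_p, al_s, al, meta, fr, ev) {
    # al_p / al_s: pattern and subject ranges of one alignment
    t_strand <- .frame_aa_to_nt(fr, IRanges::start(al_s), IRanges::end(al_s))
    t_gen <- .strand_to_genomic(gene, t_strand[1L], t_strand[2L])
    q_cov <- 3 * (IRanges::end(al_p) - IRanges::start(al_p) + 1) / meta$q_len
    if (q_cov < params$query_coverage) return(NULL)
    if (overlap_ratio(c(meta$qs, meta$qe), t_gen) >= params$self_hit) return(NULL)
    st <- .alignment_stats(al)
    data.frame(gene_id = gene$gene_id, q_start = meta$qs, q_end = meta$qe,
               t_start = t_gen[1L], t_end = t_gen[2L], source = "local",
               evalue = ev, protein_identity = st$identity,
               dna_identity = NA_real_,
               aligned_query_fraction = min(1, q_cov), reciprocal = FALSE)
  }
  for (fr in frames) {
    als <- Biostrings::pairwiseAlignment(qset, fr$aa,
             substitutionMatrix = B62, gapOpening = .GAP_OPEN,
             gapExtension = .GAP_EXT, type = "local")
    scs <- Biostrings::score(als)
    evs <- .ka_evalue(scs, vapply(qmeta, function(m) ceiling(m$q_len / 3), 0), n_aa)
    for (k in which(is.finite(scs) & scs > 0 & evs <= params$evalue_cutoff)) {
      al <- als[k]
      ev <- evs[k]
      subj <- fr$aa
      for (iter in seq_len(params$max_hsps)) {
        p_rng <- Biostrings::pattern(al)
        s_rng <- Biostrings::subject(al)
        r <- emit(p_rng, s_rng, al, qmeta[[k]], fr, ev)
        if (!is.null(r)) rows[[length(rows) + 1L]] <- r
        if (iter == params$max_hsps) break
        # mask the found region and look for further copies
        ss <- IRanges::start(s_rng); es <- IRanges::end(s_rng)
        Biostrings::subseq(subj, ss, es) <-
          Biostrings::AAString(strrep("X", es - ss + 1L))
        al <- Biostrings::pairwiseAlignment(qset[[k]], subj,
                substitutionMatrix = B62, gapOpening = .GAP_OPEN,
                gapExtension = .GAP_EXT, type = "local")
        sc <- Biostrings::score(al)
        ev <- .ka_evalue(sc, ceiling(qmeta[[k]]$q_len / 3), n_aa)
        if (!is.finite(sc) || sc <= 0 || ev > params$evalue_cutoff) break
      }
    }
  }
  .dedup_local(do.call(rbind, c(list(.empty_matches()), rows)))
}

# the same target can be found from several query/subject frame combinations;
# keep the most significant hit per (query, near-identical target) pair
.dedup_local <- function(m) {
  if (nrow(m) < 2L) return(m)
  m <- m[order(m$q_start, m$q_end, m$evalue, -m$aligned_query_fraction,
               m$t_start, m$t_end), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (m$q_start[i] == m$q_start[j] && m$q_end[i] == m$q_end[j] &&
          .overlap_ratio_vec(m$t_start[i], m$t_end[i], m$t_start[j], m$t_end[j]) > 0.8) {
        keep[i] <- FALSE
        break
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  rownames(m) <- NULL
  m
}

.local_search_tblastx <- function(gene, exons, params) {
  exe <- Sys.which("tblastx")
  if (exe == "")
    stop("external backend requested but no tblastx-compatible executable found on PATH")
  strand_seq <- .gene_strand_seq(gene)
  td <- tempfile("exdup_blast_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qfa <- file.path(td, "q.fa"); sfa <- file.path(td, "s.fa")
  qn <- sprintf("q%d", seq_len(nrow(exons$exons)))
  writeLines(paste0(">", qn, "\n",
                    vapply(seq_len(nrow(exons$exons)), function(i)
                      gene_sequence(gene, exons$exons$start[i], exons$exons$end[i]), "")),
             qfa)
  writeLines(c(">gene", strand_seq), sfa)
  out <- system2(exe, c("-query", qfa, "-subject", sfa,
                        "-evalue", format(params$evalue_cutoff, scientific = TRUE),
                        "-outfmt", shQuote("6 qseqid qstart qend sstart send evalue pident qlen")),
                 stdout = TRUE)
  if (length(out) == 0L) return(.empty_matches())
  tb <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("qseqid", "qstart", "qend", "sstart",
                                        "send", "evalue", "pident", "qlen"))
  rows <- list()
  for (k in seq_len(nrow(tb))) {
    i <- match(tb$qseqid[k], qn)
    qs <- exons$exons$start[i]; qe <- exons$exons$end[i]
    t_strand <- sort(c(tb$sstart[k], tb$send[k]))
    t_gen <- .strand_to_genomic(gene, t_strand[1L], t_strand[2L])
    q_cov <- (abs(tb$qend[k] - tb$qstart[k]) + 1) / tb$qlen[k]
    if (q_cov < params$query_coverage) next
    if (overlap_ratio(c(qs, qe), t_gen) >= params$self_hit) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$gene_id, q_start = qs, q_end = qe,
      t_start = t_gen[1L], t_end = t_gen[2L], source = "local",
      evalue = tb$evalue[k], protein_identity = tb$pident[k] / 100,
      dna_identity = NA_real_, aligned_query_fraction = min(1, q_cov),
      reciprocal = FALSE)
  }
  .dedup_local(do.call(rbind, c(list(.empty_matches()), rows)))
}

# reading-frame offset for translating an exon: the annotated GFF phase when a
# transcript carries this exact CDS interval, else the frame with fewest stops
.exon_phase <- function(gene, start, end) {
  for (tx in gene$transcripts) {
    hit <- which(tx$start == start & tx$end == end & !is.na(tx$phase))
    if (length(hit)) return(tx$phase[hit[1L]] %% 3L)
  }
  nt <- gene_sequence(gene, start, end)
  stops <- vapply(0:2, function(f) {
    aa <- .translate_frame(nt, f)
    if (is.null(aa)) return(Inf)
    sum(strsplit(as.character(aa), "")[[1L]] == "*")
  }, 0)
  (which.min(stops) - 1L) %% 3L
}

# exon peptide in its annotated frame, or NULL when the translation has an
# internal stop codon
.exon_peptide <- function(gene, start, end) {
  ph <- .exon_phase(gene, start, end)
  aa <- .translate_frame(gene_sequence(gene, start, end), ph)
  if (is.null(aa)) return(NULL)
  ch <- strsplit(as.character(aa), "")[[1L]]
  if (any(ch[-length(ch)] == "*")) return(NULL)
  if (ch[length(ch)] == "*") aa <- Biostrings::subseq(aa, 1L, length(aa) - 1L)
  if (length(aa) == 0L) NULL else aa
}

#' Global duplication search over representative exon pairs
#'
#' Aligns pairs of representative exons whose shorter/longer length ratio is
#' strictly greater than `pair_ratio`, both as nucleotide sequences and as
#' peptides (each exon translated in its annotated frame). A match is emitted
#' when the protein alignment identity reaches `identity` and the fraction of
#' alignment columns aligned in both sequences reaches `aligned_fraction`.
#' Global matches are reciprocal by construction. Pairs whose peptide contains
#' an internal stop codon in the annotated frame are skipped with a warning.
#'
#' @inheritParams local_search
#' @return A matches data.frame (see [local_search()]); `source = "global"`,
#'   `reciprocal = TRUE`, `dna_identity` filled, `evalue = NA`.
#' @export
global_search <- function(gene, exons, params = search_params()) {
  stopifnot(inherits(gene, "gene_model"), inherits(exons, "representative_exons"))
  ex <- exons$exons
  if (nrow(ex) < 2L) return(.empty_matches())
  B62 <- .blosum62()
  nuc <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  peps <- lapply(seq_len(nrow(ex)), function(i) .exon_peptide(gene, ex$start[i], ex$end[i]))
  lens <- .interval_len(ex$start, ex$end)

  pairs <- which(upper.tri(matrix(0, nrow(ex), nrow(ex))), arr.ind = TRUE)
  ratio <- pmin(lens[pairs[, 1]], lens[pairs[, 2]]) /
           pmax(lens[pairs[, 1]], lens[pairs[, 2]])
  pairs <- pairs[ratio > params$pair_ratio, , drop = FALSE]
  if (nrow(pairs) == 0L) return(.empty_matches())
  bad <- vapply(seq_len(nrow(pairs)), function(k)
    is.null(peps[[pairs[k, 1]]]) || is.null(peps[[pairs[k, 2]]]), TRUE)
  if (any(bad)) {
    for (k in which(bad))
      warning("gene ", gene$gene_id, ": exon pair (",
              ex$start[pairs[k, 1]], "-", ex$end[pairs[k, 1]], ", ",
              ex$start[pairs[k, 2]], "-", ex$end[pairs[k, 2]],
              ") skipped: not translatable in annotated frame")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(.empty_matches())

  # elementwise batched global alignments over all retained pairs
  pals <- Biostrings::pairwiseAlignment(
            Biostrings::AAStringSet(peps[pairs[, 1]]),
            Biostrings::AAStringSet(peps[pairs[, 2]]),
            substitutionMatrix = B62, gapOpening = .GAP_OPEN,
            gapExtension = .GAP_EXT, type = "global")
  pst <- lapply(seq_len(nrow(pairs)), function(k) .alignment_stats(pals[k]))
  keep <- vapply(pst, function(s)
    s$identity >= params$identity && s$aligned_fraction >= params$aligned_fraction,
    TRUE)
  if (!any(keep)) return(.empty_matches())
  pairs <- pairs[keep, , drop = FALSE]
  pst <- pst[keep]
  nals <- Biostrings::pairwiseAlignment(
            Biostrings::DNAStringSet(vapply(pairs[, 1], function(i)
              gene_sequence(gene, ex$start[i], ex$end[i]), "")),
            Biostrings::DNAStringSet(vapply(pairs[, 2], function(i)
              gene_sequence(gene, ex$start[i], ex$end[i]), "")),
            substitutionMatrix = nuc, gapOpening = 5, gapExtension = 2,
            type = "global")
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    data.frame(gene_id = gene$gene_id, q_start = ex$start[i], q_end = ex$end[i],
               t_start = ex$start[j], t_end = ex$end[j], source = "global",
               evalue = NA_real_, protein_identity = pst[[k]]$identity,
               dna_identity = .alignment_stats(nals[k])$identity,
               aligned_query_fraction = pst[[k]]$aligned_fraction,
               reciprocal = TRUE)
  })
  do.call(rbind, c(list(.empty_matches()), rows))
}

#' Run the duplication search for one gene
#'
#' Dispatches over `params$mode`: the local search, the global search, or
#' both (local results first, then global; duplicate query/target pairs from
#' the two sources are both retained and resolved later by classification
#' precedence).
#'
#' @inheritParams local_search
#' @param exons Optional `representative_exons`; computed from `params` when
#'   missing.
#' @return A matches data.frame.
#' @export
run_search <- function(gene, params = search_params(), exons = NULL) {
  if (is.null(exons))
    exons <- select_representative_exons(gene, params$min_exon_length,
                                         params$exon_overlap)
  loc <- if (params$mode %in% c("local", "both")) local_search(gene, exons, params)
         else .empty_matches()
  glo <- if (params$mode %in% c("global", "both")) global_search(gene, exons, params)
         else .empty_matches()
  out <- rbind(loc, glo)
  rownames(out) <- NULL
  out
}
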