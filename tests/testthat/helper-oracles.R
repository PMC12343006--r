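# Independent oracles and fixture builders used across the suite.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rand_orf <- function(n_codons) {
  cods <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  cods <- setdiff(cods, c("TAA", "TAG", "TGA"))
  paste(sample(cods, n_codons, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Brute-force clustering oracle: reachability closure (boolean matrix powers)
# of the consecutive-in-sorted-order overlap relation. Returns cluster ids in
# input order.
oracle_cluster_ids <- function(df, cutoff) {
  n <- nrow(df)
  if (n == 0L) return(integer(0))
  ord <- order(df$start, df$end)
  s <- df$start[ord]; e <- df$end[ord]
  adj <- diag(TRUE, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (i >= n) break
    if (overlap_ratio(c(s[i], e[i]), c(s[i + 1L], e[i + 1L])) > cutoff)
      adj[i, i + 1L] <- adj[i + 1L, i] <- TRUE
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n); nc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { nc <- nc + 1L; comp[reach[i, ]] <- nc }
  }
  out <- integer(n)
  out[ord] <- comp
  out
}

# normalize a labelling to a canonical partition (list of sorted index sets)
as_partition <- function(ids) {
  unname(lapply(split(seq_along(ids), ids), sort))[order(
    vapply(split(seq_along(ids), ids), min, 0L))]
}

# Brute-force connected components by edge-relaxation (undirected)
oracle_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      if (comp[a] != comp[b]) {
        m <- min(comp[a], comp[b])
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Interdependence classification straight from the definitions, over a
# transcripts x duplicates presence matrix
oracle_interdependence <- function(P) {
  has_any <- rowSums(P) > 0L
  classify <- function(S) {
    if (all(S)) "obligate"
    else if (all(rowSums(S) <= 1L)) "exclusive"
    else "flexible"
  }
  if (any(!has_any)) paste0("optional_", classify(P[has_any, , drop = FALSE]))
  else classify(P)
}

# Build a gene_model from an ordered list of blocks. Each block is
# list(seq = <nt string>, exon = TRUE/FALSE). Returns the gene with an
# attribute "blocks": data.frame(start, end, exon) in genomic coordinates.
# Default transcript t1 carries every exon block; `transcripts` may map
# transcript names to exon-block ordinals instead.
build_gene <- function(blocks, transcripts = NULL, gene_id = "g1",
                       chrom = "chr1", strand = "+", offset = 1000L) {
  pos <- offset + 1L
  iv <- data.frame(start = integer(0), end = integer(0), exon = logical(0))
  for (b in blocks) {
    len <- nchar(b$seq)
    iv <- rbind(iv, data.frame(start = pos, end = pos + len - 1L,
                               exon = isTRUE(b$exon)))
    pos <- pos + len
  }
  seq <- paste(vapply(blocks, `[[`, "", "seq"), collapse = "")
  ex <- iv[iv$exon, , drop = FALSE]
  if (is.null(transcripts)) transcripts <- list(t1 = seq_len(nrow(ex)))
  txs <- lapply(transcripts, function(idx)
    data.frame(start = ex$start[idx], end = ex$end[idx], phase = 0L))
  g <- gene_model(gene_id, chrom, strand, c(offset + 1L, pos - 1L), txs, seq)
  attr(g, "blocks") <- iv
  g
}

# A gene with one source exon and one exact copy: `where` controls whether
# the copy is annotated ("exon") or buried in an intron ("intronic").
dup_gene <- function(n_codons = 50L, where = c("exon", "intronic"),
                     copy_seq = NULL, gene_id = "g1") {
  where <- match.arg(where)
  src <- rand_orf(n_codons)
  copy <- if (is.null(copy_seq)) src else copy_seq
  other <- rand_orf(40L)
  if (where == "exon") {
    blocks <- list(list(seq = src, exon = TRUE),
                   list(seq = paste0("GT", rand_dna(296), "AG"), exon = FALSE),
                   list(seq = copy, exon = TRUE),
                   list(seq = paste0("GT", rand_dna(296), "AG"), exon = FALSE),
                   list(seq = other, exon = TRUE))
  } else {
    blocks <- list(list(seq = src, exon = TRUE),
                   list(seq = paste0("GT", rand_dna(150), copy, rand_dna(150), "AG"),
                        exon = FALSE),
                   list(seq = other, exon = TRUE))
  }
  g <- build_gene(blocks, gene_id = gene_id)
  bl <- attr(g, "blocks")
  if (where == "exon") {
    attr(g, "src") <- c(bl$start[1], bl$end[1])
    attr(g, "copy") <- c(bl$start[3], bl$end[3])
  } else {
    attr(g, "src") <- c(bl$start[1], bl$end[1])
    ist <- bl$start[2] + 2L + 150L
    attr(g, "copy") <- c(ist, ist + nchar(copy) - 1L)
  }
  g
}

# overlap ratio of each (s[i], e[i]) against a fixed interval iv
.iv_overlap <- function(s, e, iv) {
  if (length(s) == 0L) return(numeric(0))
  vapply(seq_along(s), function(i) overlap_ratio(c(s[i], e[i]), iv), 0)
}

# run the pipeline on a list of genes with default-ish parameters
run_quiet <- function(genes, params = search_params(), workers = 1L) {
  suppressWarnings(suppressMessages(
    run_exon_duplication_search(genes, params = params, workers = workers)))
}
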