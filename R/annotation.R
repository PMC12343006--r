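#' Construct a gene model
#'
#' Low-level constructor used by [load_annotation()] and by the simulator;
#' useful directly when building genes programmatically (e.g. in tests).
#' Coordinates are 1-based inclusive genomic coordinates throughout; they are
#' never strand-flipped. Sequence access through [gene_sequence()] is the only
#' place strand is applied.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param span `c(start, end)` of the gene on the chromosome.
#' @param transcripts Named list; each element a data.frame with columns
#'   `start`, `end` and optionally `phase` (GFF frame attribute, 0/1/2 or NA)
#'   giving the transcript's CDS intervals. Intervals within a transcript must
#'   be non-overlapping; they are sorted by `(start, end)`.
#' @param chrom_seq Nucleotide sequence of the *gene span* (plus strand of the
#'   chromosome, positions `span[1]..span[2]`), as a character string.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, span, transcripts, chrom_seq) {
  stopifnot(strand %in% c("+", "-"), length(span) == 2L, span[1] <= span[2],
            length(transcripts) >= 1L, nchar(chrom_seq) == span[2] - span[1] + 1)
  transcripts <- lapply(transcripts, function(tx) {
    tx <- as.data.frame(tx)
    if (is.null(tx$phase)) tx$phase <- NA_integer_
    tx <- tx[order(tx$start, tx$end), , drop = FALSE]
    rownames(tx) <- NULL
    if (nrow(tx) == 0L) stop("transcript with no CDS interval")
    if (nrow(tx) > 1L && any(tx$start[-1L] <= tx$end[-nrow(tx)]))
      stop("overlapping CDS intervals within one transcript of gene ", gene_id)
    if (any(tx$start < span[1] | tx$end > span[2]))
      stop("CDS interval outside gene span for gene ", gene_id)
    tx
  })
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = as.integer(span[1]), end = as.integer(span[2]),
                 transcripts = transcripts, seq = toupper(chrom_seq)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene", x$gene_id, " ", x$chrom, ":", x$start, "-", x$end,
      " (", x$strand, "), ", length(x$transcripts), " transcript(s)\n", sep = "")
  for (nm in names(x$transcripts))
    cat("  ", nm, ": ", nrow(x$transcripts[[nm]]), " CDS\n", sep = "")
  invisible(x)
}

#' Nucleotide sequence of a genomic interval, on the gene's strand
#'
#' Returns the 5'-to-3' sequence of `[start, end]` as read on the gene's
#' coding strand: for minus-strand genes this is the reverse complement of
#' the plus-strand chromosome sequence of the interval. Coordinates remain
#' genomic (plus-strand) in either case, and the returned string always has
#' `end - start + 1` characters.
#'
#' @param gene A `gene_model`.
#' @param start,end 1-based inclusive genomic coordinates within the gene span.
#' @return Character string.
#' @export
gene_sequence <- function(gene, start, end) {
  stopifnot(inherits(gene, "gene_model"), start >= gene$start, end <= gene$end,
            start <= end)
  s <- substring(gene$seq, start - gene$start + 1, end - gene$start + 1)
  if (nchar(s) != end - start + 1)
    stop("gene ", gene$gene_id, ": stored sequence does not cover ",
         start, "-", end)
  if (gene$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# gene sequence in "strand space": full span, 5'->3' on the coding strand.
# position p in strand space maps to genomic coordinates via .strand_to_genomic().
.gene_strand_seq <- function(gene) gene_sequence(gene, gene$start, gene$end)

# convert an interval [p1, p2] (1-based along the strand-space sequence)
# back to genomic coordinates
.strand_to_genomic <- function(gene, p1, p2) {
  if (gene$strand == "+") c(gene$start + p1 - 1L, gene$start + p2 - 1L)
  else c(gene$end - p2 + 1L, gene$end - p1 + 1L)
}

# genomic interval -> strand-space interval
.genomic_to_strand <- function(gene, g1, g2) {
  if (gene$strand == "+") c(g1 - gene$start + 1L, g2 - gene$start + 1L)
  else c(gene$end - g2 + 1L, gene$end - g1 + 1L)
}

.sniff_format <- function(path) {
  if (grepl("\\.(gtf)(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
}

#' Load gene models from an annotation and a genome
#'
#' Parses a GFF3 or GTF annotation (gene / mRNA or transcript / CDS features)
#' together with a FASTA genome into a list of [gene_model()] objects. Only
#' CDS features are retained: genes annotated without any CDS are skipped with
#' a warning. GTF files are mapped onto the parent model through their
#' `gene_id` / `transcript_id` attributes. Soft-masked (lowercase) sequence is
#' uppercased by default; `hard_mask = TRUE` converts it to `N` instead, which
#' removes masked regions from the similarity search.
#'
#' @param annotation_path Path to a GFF3 or GTF file (optionally gzipped);
#'   format chosen by file extension.
#' @param genome_path Path to a FASTA file (optionally gzipped/bgzipped).
#' @param hard_mask Replace soft-masked nucleotides with `N` (default FALSE).
#' @return A named list of `gene_model` objects (names = gene ids).
#' @export
load_annotation <- function(annotation_path, genome_path, hard_mask = FALSE) {
  stopifnot(file.exists(annotation_path), file.exists(genome_path))
  fmt <- .sniff_format(annotation_path)
  gr <- rtracklayer::import(annotation_path, format = fmt)
  # BStringSet preserves case, which encodes soft-masking
  genome <- Biostrings::readBStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- as.character(genome)
  if (hard_mask) seqs <- gsub("[acgtn]", "N", seqs) else seqs <- toupper(seqs)

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (fmt == "gtf") {
    df$id <- NA_character_
    df$parent <- NA_character_
    df$gene_id <- as.character(mc$gene_id)
    df$tx_id <- if (!is.null(mc$transcript_id)) as.character(mc$transcript_id) else NA_character_
    df$id[df$type == "gene"] <- df$gene_id[df$type == "gene"]
    tx_rows <- df$type %in% c("mRNA", "transcript")
    df$id[tx_rows] <- df$tx_id[tx_rows]
    df$parent[tx_rows] <- df$gene_id[tx_rows]
    df$parent[df$type == "CDS"] <- df$tx_id[df$type == "CDS"]
  } else {
    df$id <- if (!is.null(mc$ID)) as.character(mc$ID) else NA_character_
    par <- mc$Parent
    df$parent <- vapply(seq_along(gr), function(i) {
      p <- par[[i]]
      if (length(p) == 0L) NA_character_ else as.character(p[1L])
    }, "")
  }
  df$phase <- if (!is.null(mc$phase)) suppressWarnings(as.integer(as.character(mc$phase)))
              else NA_integer_

  genes <- df[df$type == "gene", , drop = FALSE]
  txs <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (any(is.na(cds$parent) | cds$parent == ""))
    stop("CDS feature without a parent transcript link (rows: ",
         paste(utils::head(which(is.na(cds$parent) | cds$parent == "")), collapse = ", "), ")")
  if (nrow(txs) && any(is.na(txs$parent) | txs$parent == ""))
    stop("mRNA/transcript feature without a parent gene link (ids: ",
         paste(utils::head(txs$id[is.na(txs$parent) | txs$parent == ""]), collapse = ", "), ")")
  orphan <- !(cds$parent %in% txs$id)
  if (any(orphan))
    stop("CDS feature references unknown transcript '", cds$parent[orphan][1L], "'")

  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    gtx <- txs[txs$parent == gid, , drop = FALSE]
    tx_list <- list()
    for (j in seq_len(nrow(gtx))) {
      tcds <- cds[cds$parent == gtx$id[j], , drop = FALSE]
      if (nrow(tcds) == 0L) next
      tx_list[[gtx$id[j]]] <- data.frame(start = tcds$start, end = tcds$end,
                                         phase = tcds$phase)
    }
    if (length(tx_list) == 0L) {
      warning("gene ", gid, " has no CDS-bearing transcript; skipped")
      next
    }
    if (!genes$chrom[i] %in% names(seqs))
      stop("gene ", gid, " references chromosome '", genes$chrom[i],
           "' absent from the genome FASTA")
    chrom_seq <- substring(seqs[[genes$chrom[i]]], genes$start[i], genes$end[i])
    out[[gid]] <- gene_model(gid, genes$chrom[i],
                             ifelse(genes$strand[i] %in% c("+", "-"), genes$strand[i], "+"),
                             c(genes$start[i], genes$end[i]), tx_list, chrom_seq)
  }
  out
}

#' Write gene models back to GFF3
#'
#' Round-trip utility: serializes gene / mRNA / CDS features with parent
#' links, 1-based inclusive coordinates, so that re-parsing with
#' [load_annotation()] reproduces the same interval sets.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, paste(g$chrom, "exdup", "gene", g$start, g$end, ".",
                            g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"))
    for (tn in names(g$transcripts)) {
      tx <- g$transcripts[[tn]]
      lines <- c(lines, paste(g$chrom, "exdup", "mRNA", min(tx$start), max(tx$end),
                              ".", g$strand, ".",
                              paste0("ID=", tn, ";Parent=", g$gene_id), sep = "\t"))
      for (k in seq_len(nrow(tx))) {
        ph <- if (is.na(tx$phase[k])) "." else tx$phase[k]
        lines <- c(lines, paste(g$chrom, "exdup", "CDS", tx$start[k], tx$end[k],
                                ".", g$strand, ph,
                                paste0("ID=cds-", tn, "-", k, ";Parent=", tn), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
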