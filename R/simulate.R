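.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic-genome simulator
#'
#' Describes a synthetic genome of multi-exon protein-coding genes into which
#' full-length and intronic exon-duplication events are planted across a
#' ladder of evolutionary distances (expected nucleotide substitutions per
#' site). Defaults give a desk-scale genome with events pooled evenly over
#' distances 0.2-2.0.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Inclusive range `c(min, max)` of base exons per gene.
#' @param exon_length Range of exon lengths in nt (rounded to whole codons).
#' @param intron_length Range of intron lengths in nt.
#' @param n_full_length_events Number of planted full-length (annotated)
#'   duplications.
#' @param n_intronic_events Number of planted intronic (unannotated)
#'   duplications.
#' @param distances Evolutionary distances (expected substitutions/site);
#'   events are assigned to distances in even rotation.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param omega Optional nonsynonymous acceptance probability. `NULL`
#'   (default) mutates copies under a uniform substitution (JC69-style)
#'   process: intronic copies unconstrained, annotated copies conditioned
#'   only on containing no in-frame stop codon (a CDS annotation must stay
#'   translatable). A numeric `omega` in (0, 1] switches to a codon-aware
#'   purifying-selection process in which synonymous substitutions are always
#'   accepted and nonsynonymous ones with probability `omega`, for
#'   sensitivity analysis of divergence that conserves the protein.
#' @param min_intron_flank Minimum intact intron flank (nt) on each side of
#'   an intronic insertion.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 25L, exons_per_gene = c(4L, 6L),
                              exon_length = c(102L, 300L),
                              intron_length = c(200L, 1000L),
                              n_full_length_events = 20L,
                              n_intronic_events = 20L,
                              distances = c(0.2, 0.5, 1.0, 1.5, 2.0),
                              seed = 1L, omega = NULL,
                              min_intron_flank = 50L) {
  stopifnot(n_genes > 0, all(exons_per_gene >= 2), all(exon_length >= 30),
            all(intron_length >= 2 * min_intron_flank + 20),
            n_full_length_events >= 0, n_intronic_events >= 0,
            all(distances > 0), length(seed) == 1L)
  if (!is.null(omega)) stopifnot(omega > 0, omega <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 n_full_length_events = as.integer(n_full_length_events),
                 n_intronic_events = as.integer(n_intronic_events),
                 distances = distances, seed = as.integer(seed),
                 omega = omega, min_intron_flank = as.integer(min_intron_flank)),
            class = "simulation_config")
}

.rand_orf <- function(n_codons) {
  codons <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = "")
  codons <- setdiff(codons, .STOPS)
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

.rand_intron <- function(len) {
  stopifnot(len >= 8)
  paste0("GT", paste(sample(.BASES, len - 4, replace = TRUE), collapse = ""), "AG")
}

# uniform substitution process: each site substituted with the JC69
# probability of being in a different state after distance d
.jc_mutate <- function(seq, d) {
  v <- strsplit(seq, "")[[1]]
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- runif(length(v)) < p
  if (any(hit))
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(.BASES, b), 1L), "")
  paste(v, collapse = "")
}

# same process, conditioned on the frame-0 translation containing no stop
# codon (annotated copies must remain valid CDS); stop codons created by the
# draw are re-drawn at their mutated positions
.jc_mutate_orf <- function(seq, d) {
  out <- .jc_mutate(seq, d)
  v <- strsplit(out, "")[[1]]
  orig <- strsplit(seq, "")[[1]]
  n_cod <- length(v) %/% 3L
  for (ci in seq_len(n_cod)) {
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    guard <- 0L
    while (paste(v[idx], collapse = "") %in% .STOPS) {
      mut <- idx[v[idx] != orig[idx]]
      if (length(mut) == 0L) break  # cannot happen: source codons are non-stop
      p <- if (length(mut) == 1L) mut else sample(mut, 1L)
      v[p] <- sample(setdiff(.BASES, orig[p]), 1L)
      guard <- guard + 1L
      if (guard > 100L) stop("stop-codon rejection did not converge")
    }
  }
  paste(v, collapse = "")
}

# codon-aware purifying-selection process: sequential single-nucleotide
# proposals; synonymous accepted, nonsynonymous accepted w.p. omega, stops
# rejected; runs until ~ d * L substitutions have been accepted
.purifying_mutate <- function(seq, d, omega) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  target <- rpois(1L, d * L)
  translate1 <- function(cod) as.character(
    Biostrings::translate(Biostrings::DNAString(cod), no.init.codon = TRUE))
  acc <- 0L; tries <- 0L
  while (acc < target && tries < 200L * target + 1000L) {
    tries <- tries + 1L
    p <- sample.int(L, 1L)
    new <- sample(setdiff(.BASES, v[p]), 1L)
    ci <- (p - 1L) %/% 3L
    idx <- (3L * ci + 1L):(3L * ci + 3L)
    if (max(idx) > L) { # trailing partial codon: neutral
      v[p] <- new; acc <- acc + 1L; next
    }
    old_cod <- paste(v[idx], collapse = "")
    w <- v; w[p] <- new
    new_cod <- paste(w[idx], collapse = "")
    if (new_cod %in% .STOPS) next
    syn <- translate1(old_cod) == translate1(new_cod)
    if (syn || runif(1L) < omega) { v[p] <- new; acc <- acc + 1L }
  }
  paste(v, collapse = "")
}

#' Simulate an annotated genome with planted exon duplications
#'
#' Builds `n_genes` protein-coding genes from random open-reading-frame exons
#' (whole codons, no internal stops) separated by random introns with
#' canonical GT..AG ends, concatenated on one chromosome with intergenic
#' spacers. For each planted event a source exon of the gene is copied,
#' mutated to the event's evolutionary distance (see
#' [simulation_config()]), and inserted into an intron: full-length events
#' become new annotated CDS exons (in all of the gene's transcripts, or a
#' random subset covering at least one), intronic events are placed
#' mid-intron, unannotated, with at least `min_intron_flank` nt of intact
#' intron on both sides. At most one event is planted per intron; a
#' configuration with more events than intron slots is an error. The entire
#' construction is deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created); FASTA, GFF3 and a tab-separated
#'   truth table are written there.
#' @return List with `fasta`, `gff`, `truth_path` (file paths), `truth`
#'   (data.frame: `gene_id`, `src_start`, `src_end`, `ins_start`, `ins_end`,
#'   `event_type`, `distance`) and `genes` (list of `gene_model`).
#' @export
simulate_genome <- function(config, dir = tempfile("exdup_sim_")) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2],
                 config$n_genes, replace = TRUE)
  slots <- data.frame(gene = rep(seq_len(config$n_genes), n_ex - 1L))
  slots$intron <- unlist(lapply(n_ex - 1L, seq_len))
  n_events <- config$n_full_length_events + config$n_intronic_events
  if (n_events > nrow(slots))
    stop("infeasible geometry: ", n_events, " events but only ", nrow(slots),
         " intron slots; increase n_genes or exons_per_gene")
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  events <- data.frame(
    gene = slots$gene[seq_len(n_events)],
    intron = slots$intron[seq_len(n_events)],
    event_type = rep(c("full_length", "intronic"),
                     c(config$n_full_length_events, config$n_intronic_events)))
  events$distance <- rep_len(config$distances, n_events)

  rlen <- function(rg) sample(rg[1]:rg[2], 1L)
  genes <- list()
  truth <- list()
  chrom_parts <- character(0)
  offset <- 0L
  chrom <- "chrsim"
  for (gi in seq_len(config$n_genes)) {
    gid <- sprintf("gene%03d", gi)
    ex_seqs <- lapply(seq_len(n_ex[gi]), function(i)
      .rand_orf(rlen(config$exon_length) %/% 3L))
    in_seqs <- lapply(seq_len(n_ex[gi] - 1L), function(i)
      .rand_intron(rlen(config$intron_length)))
    ev <- events[events$gene == gi, , drop = FALSE]

    # blocks: type "exon" (annotated), "ins_exon" (annotated copy),
    # "intron", "ins_intronic" (unannotated copy inside an intron)
    blocks <- list()
    for (i in seq_len(n_ex[gi])) {
      blocks[[length(blocks) + 1L]] <- list(type = "exon", seq = ex_seqs[[i]],
                                            src = i, ev = NA_integer_)
      if (i == n_ex[gi]) break
      evi <- which(ev$intron == i)
      iseq <- in_seqs[[i]]
      if (length(evi) == 0L) {
        blocks[[length(blocks) + 1L]] <- list(type = "intron", seq = iseq,
                                              src = NA, ev = NA_integer_)
      } else {
        e <- ev[evi[1L], ]
        src_i <- sample.int(n_ex[gi], 1L)
        src_seq <- ex_seqs[[src_i]]
        copy <- if (!is.null(config$omega))
          .purifying_mutate(src_seq, e$distance, config$omega)
        else if (e$event_type == "full_length") .jc_mutate_orf(src_seq, e$distance)
        else .jc_mutate(src_seq, e$distance)
        half <- nchar(iseq) %/% 2L
        left <- substring(iseq, 1L, half)
        right <- substring(iseq, half + 1L, nchar(iseq))
        if (e$event_type == "full_length") {
          # split the intron into two canonical introns around the new exon
          left <- paste0(substring(left, 1L, nchar(left) - 2L), "AG")
          right <- paste0("GT", substring(right, 3L))
          blocks[[length(blocks) + 1L]] <- list(type = "intron", seq = left,
                                                src = NA, ev = NA_integer_)
          blocks[[length(blocks) + 1L]] <- list(type = "ins_exon", seq = copy,
                                                src = src_i,
                                                ev = as.integer(rownames(e)))
          blocks[[length(blocks) + 1L]] <- list(type = "intron", seq = right,
                                                src = NA, ev = NA_integer_)
        } else {
          blocks[[length(blocks) + 1L]] <- list(type = "intron",
                                                seq = paste0(left, copy, right),
                                                src = NA, ev = NA_integer_,
                                                ins_at = nchar(left),
                                                ins_len = nchar(copy),
                                                ins_src = src_i,
                                                ins_ev = as.integer(rownames(e)))
        }
      }
    }

    spacer <- paste(sample(.BASES, 500L, replace = TRUE), collapse = "")
    chrom_parts <- c(chrom_parts, spacer)
    offset <- offset + 500L
    gene_start <- offset + 1L

    pos <- gene_start
    ann <- list()       # annotated exon intervals in order
    src_iv <- vector("list", n_ex[gi])
    for (b in blocks) {
      len <- nchar(b$seq)
      iv <- c(pos, pos + len - 1L)
      if (b$type == "exon") {
        ann[[length(ann) + 1L]] <- iv
        src_iv[[b$src]] <- iv
      } else if (b$type == "ins_exon") {
        ann[[length(ann) + 1L]] <- iv
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, src_block = b$src, ins_start = iv[1], ins_end = iv[2],
          event_type = "full_length",
          distance = events$distance[b$ev], stringsAsFactors = FALSE)
      } else if (!is.null(b$ins_len)) {
        ins <- c(pos + b$ins_at, pos + b$ins_at + b$ins_len - 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, src_block = b$ins_src, ins_start = ins[1],
          ins_end = ins[2], event_type = "intronic",
          distance = events$distance[b$ins_ev], stringsAsFactors = FALSE)
      }
      pos <- pos + len
    }
    gene_end <- pos - 1L
    gene_seq <- paste(vapply(blocks, `[[`, "", "seq"), collapse = "")
    chrom_parts <- c(chrom_parts, gene_seq)
    offset <- gene_end

    # resolve truth source coordinates now that exon intervals are known
    for (k in seq_along(truth)) {
      if (truth[[k]]$gene_id == gid && is.null(truth[[k]]$src_start)) {
        s <- src_iv[[truth[[k]]$src_block]]
        truth[[k]]$src_start <- s[1]; truth[[k]]$src_end <- s[2]
      }
    }

    ann_df <- data.frame(start = vapply(ann, `[`, 0, 1),
                         end = vapply(ann, `[`, 0, 2), phase = 0L)
    txs <- list(t1 = ann_df)
    if (runif(1L) < 0.5 && nrow(ann_df) > 2L) {
      keep <- runif(nrow(ann_df)) < 0.8
      if (!any(keep)) keep[1L] <- TRUE
      txs$t2 <- ann_df[keep, , drop = FALSE]
    }
    names(txs) <- paste0(gid, ".", seq_along(txs))
    genes[[gid]] <- gene_model(gid, chrom, "+", c(gene_start, gene_end),
                               txs, gene_seq)
  }
  chrom_parts <- c(chrom_parts, paste(sample(.BASES, 500L, replace = TRUE),
                                      collapse = ""))
  truth <- do.call(rbind, truth)
  truth <- truth[, c("gene_id", "src_start", "src_end", "ins_start", "ins_end",
                     "event_type", "distance")]
  rownames(truth) <- NULL

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  seq <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(seq) <- chrom
  Biostrings::writeXStringSet(seq, fasta, width = 80L)
  gff <- file.path(dir, "annotation.gff3")
  write_gff3(genes, gff)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, gff = gff, truth_path = truth_path, truth = truth,
       genes = genes)
}

#' Score recovery of planted duplication events
#'
#' A truth event is recovered when some reconciled match of its gene has a
#' compatible class and overlaps the inserted interval by at least
#' `min_overlap` ([overlap_ratio()]): full-length events must be recovered as
#' full-length (query or reconciled-target side), intronic events as intronic
#' or inter-boundary matches (reconciled-target side).
#'
#' @param truth Truth data.frame from [simulate_genome()] (or its TSV read
#'   back).
#' @param results An `exdup_results` object or a results-store directory.
#' @param min_overlap Minimum overlap ratio (default 0.9).
#' @return A `recovery_report`: list with `per_stratum` (rows per event type
#'   x distance) and `pooled` (rows per event type), each with `total`,
#'   `recovered`, `rate`.
#' @export
score_recovery <- function(truth, results, min_overlap = 0.9) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty truth set")
  res <- if (inherits(results, "exdup_results")) results else read_results(results)
  m <- res$matches
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    ins <- c(truth$ins_start[i], truth$ins_end[i])
    gm <- m[m$gene_id == truth$gene_id[i], , drop = FALSE]
    if (nrow(gm) == 0L) next
    if (truth$event_type[i] == "full_length") {
      fl <- gm[gm$match_class == "full_length", , drop = FALSE]
      hit[i] <- any(.overlap_ratio_vec(fl$rt_start, fl$rt_end, ins[1], ins[2]) >= min_overlap |
                    .overlap_ratio_vec(fl$q_start, fl$q_end, ins[1], ins[2]) >= min_overlap)
    } else {
      it <- gm[gm$match_class %in% c("intronic", "inter_boundary"), , drop = FALSE]
      hit[i] <- any(.overlap_ratio_vec(it$rt_start, it$rt_end, ins[1], ins[2]) >= min_overlap |
                    .overlap_ratio_vec(it$t_start, it$t_end, ins[1], ins[2]) >= min_overlap)
    }
  }
  per <- aggregate(cbind(recovered = hit) ~ event_type + distance,
                   data = cbind(truth, hit = hit), FUN = sum)
  tot <- aggregate(cbind(total = rep(1L, nrow(truth))) ~ event_type + distance,
                   data = truth, FUN = sum)
  per <- merge(per, tot, by = c("event_type", "distance"))
  per$rate <- per$recovered / per$total
  per <- per[order(per$event_type, per$distance), , drop = FALSE]
  rownames(per) <- NULL
  pooled <- aggregate(cbind(recovered = hit) ~ event_type,
                      data = cbind(truth, hit = hit), FUN = sum)
  ptot <- as.data.frame(table(truth$event_type), stringsAsFactors = FALSE)
  names(ptot) <- c("event_type", "total")
  pooled <- merge(pooled, ptot, by = "event_type")
  pooled$rate <- pooled$recovered / pooled$total
  structure(list(per_stratum = per, pooled = pooled,
                 min_overlap = min_overlap),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery of planted exon-duplication events (min overlap ",
      x$min_overlap, ")\n", sep = "")
  cat("Pooled:\n")
  print(x$pooled, row.names = FALSE)
  cat("By distance:\n")
  print(x$per_stratum, row.names = FALSE)
  invisible(x)
}
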