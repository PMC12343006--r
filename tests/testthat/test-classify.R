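# match classification, target reconciliation, reading frames, promotion

exons_fix <- data.frame(start = c(100, 500), end = c(199, 599))
introns_fix <- data.frame(start = c(1, 200, 600), end = c(99, 499, 1000))

test_that("match classes follow the boundary rules", {
  # aligned region covers the query and an annotated exon entirely
  expect_equal(classify_match(c(100, 199), c(500, 599), 1.0,
                              exons_fix, introns_fix, 0.9), "full_length")
  # target entirely inside an intron
  expect_equal(classify_match(c(100, 199), c(700, 799), 1.0,
                              exons_fix, introns_fix, 0.9), "intronic")
  # target inside an annotated exon, but covering only half of it
  expect_equal(classify_match(c(100, 199), c(500, 549), 1.0,
                              exons_fix, introns_fix, 0.9), "partial")
  # target straddling an exon boundary, covering 40/100 of the exon
  expect_equal(classify_match(c(100, 199), c(560, 659), 1.0,
                              exons_fix, introns_fix, 0.9), "inter_boundary")
  # the same straddling target with enough exon coverage stays full-length
  expect_equal(classify_match(c(100, 199), c(505, 650), 1.0,
                              exons_fix, introns_fix, 0.9), "full_length")
  # a target encompassing a whole exon with low query coverage is partial
  expect_equal(classify_match(c(100, 199), c(480, 620), 0.5,
                              exons_fix, introns_fix, 0.9), "partial")
})

# gene fixture for reconciliation: annotated exons [100,201] (an ORF, the
# query) and [500,599]; everything else intronic/flanking
make_rec_gene <- function() {
  seq <- paste0(rand_dna(99), rand_orf(34), rand_dna(298), rand_dna(100),
                rand_dna(601))
  gene_model("gR", "chr1", "+", c(1, nchar(seq)),
             list(t1 = data.frame(start = c(100, 500), end = c(201, 599),
                                  phase = 0L)),
             seq)
}

mk_match <- function(g, q, t, class, evalue = 1e-20, source = "local") {
  data.frame(gene_id = g$gene_id, q_start = q[1], q_end = q[2],
             t_start = t[1], t_end = t[2], source = source, evalue = evalue,
             protein_identity = 0.9, dna_identity = NA_real_,
             aligned_query_fraction = 1.0,
             reciprocal = class == "full_length", match_class = class)
}

test_that("reconciliation snaps full-length clusters to the annotated exon", {
  set.seed(201)
  g <- make_rec_gene()
  m <- mk_match(g, c(100, 201), c(505, 590), "full_length")
  r <- reconcile_targets(m, g, 0.9)
  expect_equal(c(r$rt_start, r$rt_end), c(500, 599))
  expect_equal(r$cluster_id, 1L)
})

test_that("other clusters take the most significant member's target", {
  set.seed(202)
  g <- make_rec_gene()
  m <- rbind(mk_match(g, c(100, 201), c(700, 790), "intronic", evalue = 1e-30),
             mk_match(g, c(100, 201), c(705, 799), "intronic", evalue = 1e-10))
  # overlap ratio 86/95 > 0.9: one cluster; both take the 1e-30 member's target
  r <- reconcile_targets(m, g, 0.9)
  expect_equal(unique(r$cluster_id), 1L)
  expect_equal(r$rt_start, c(700, 700))
  expect_equal(r$rt_end, c(790, 790))
  # disjoint targets reconcile to themselves
  m2 <- rbind(mk_match(g, c(100, 201), c(700, 750), "intronic"),
              mk_match(g, c(100, 201), c(900, 950), "intronic"))
  r2 <- reconcile_targets(m2, g, 0.9)
  expect_equal(r2$rt_start, r2$t_start)
  expect_equal(r2$rt_end, r2$t_end)
  expect_equal(length(unique(r2$cluster_id)), 2L)
})

test_that("reconciliation is idempotent", {
  set.seed(203)
  g <- make_rec_gene()
  m <- rbind(mk_match(g, c(100, 201), c(505, 590), "full_length"),
             mk_match(g, c(100, 201), c(700, 790), "intronic", evalue = 1e-30),
             mk_match(g, c(100, 201), c(705, 799), "intronic", evalue = 1e-10))
  r1 <- reconcile_targets(m, g, 0.9)
  m2 <- r1
  m2$t_start <- r1$rt_start; m2$t_end <- r1$rt_end
  r2 <- reconcile_targets(m2[names(m)], g, 0.9)
  expect_equal(r2$rt_start, r1$rt_start)
  expect_equal(r2$rt_end, r1$rt_end)
})

test_that("reading frames are recovered for all three frame shifts", {
  set.seed(204)
  orf <- rand_orf(40)
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  f0 <- assign_reading_frame(pep, orf)
  expect_equal(as.integer(f0), 0L)
  expect_equal(attr(f0, "identity"), 1.0)
  expect_equal(as.integer(assign_reading_frame(pep, paste0("G", orf))), 1L)
  expect_equal(as.integer(assign_reading_frame(pep, paste0("GA", orf))), 2L)
  # random target: low identity but a deterministic answer
  rnd <- rand_dna(120)
  r1 <- assign_reading_frame(pep, rnd)
  r2 <- assign_reading_frame(pep, rnd)
  expect_identical(as.integer(r1), as.integer(r2))
  expect_true(as.integer(r1) %in% 0:2)
  expect_lt(attr(r1, "identity"), 0.5)
})

test_that("partial local matches with a global counterpart are promoted", {
  set.seed(205)
  g <- make_rec_gene()
  partial <- mk_match(g, c(100, 201), c(505, 590), "partial")
  rec <- reconcile_targets(partial, g, 0.9)
  glob <- mk_match(g, c(100, 201), c(500, 599), "full_length", evalue = NA,
                   source = "global")
  out <- promote_partial_to_full(rec, glob, 0.9)
  expect_equal(out$match_class, "full_length")
  expect_true(out$reciprocal)

  # without a counterpart the class is unchanged
  out2 <- promote_partial_to_full(rec, glob[0, , drop = FALSE], 0.9)
  expect_equal(out2$match_class, "partial")

  # an intronic match is never promoted, even when a global match overlaps it
  intr <- reconcile_targets(mk_match(g, c(100, 201), c(700, 790), "intronic"), g, 0.9)
  out3 <- promote_partial_to_full(intr, glob, 0.9)
  expect_equal(out3$match_class, "intronic")
})

test_that("targets outside the gene span violate the classification contract", {
  set.seed(206)
  g <- make_rec_gene()
  m <- mk_match(g, c(100, 201), c(g$end + 50, g$end + 120), "intronic")
  m$match_class <- NULL
  expect_error(exdup:::.classify_matches(m, g, 0.9), "outside the span")
})
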