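# local (translated) and global duplication searches

test_that("an exact intronic copy of an exon is found at full coverage", {
  set.seed(101)
  g <- dup_gene(50, "intronic")
  ex <- select_representative_exons(g, 30, 0.9)
  m <- local_search(g, ex, search_params())
  src <- attr(g, "src"); copy <- attr(g, "copy")
  hit <- m[m$q_start == src[1] & m$q_end == src[2] &
           .iv_overlap(m$t_start, m$t_end, copy) >= 0.9, , drop = FALSE]
  expect_gte(nrow(hit), 1)
  expect_true(all(hit$evalue < 1e-10))
  expect_true(any(hit$aligned_query_fraction >= 0.99))
})

test_that("self-matches are suppressed by the self-hit threshold", {
  set.seed(102)
  g <- dup_gene(50, "intronic")
  ex <- select_representative_exons(g, 30, 0.9)
  p <- search_params()
  m <- local_search(g, ex, p)
  for (i in seq_len(nrow(m)))
    expect_lt(overlap_ratio(c(m$q_start[i], m$q_end[i]),
                            c(m$t_start[i], m$t_end[i])), p$self_hit)
})

test_that("identical annotated exons give a perfect global match", {
  set.seed(103)
  g <- dup_gene(40, "exon")
  ex <- select_representative_exons(g, 30, 0.9)
  m <- global_search(g, ex, search_params())
  expect_gte(nrow(m), 1)
  best <- m[which.max(m$protein_identity), ]
  expect_equal(best$protein_identity, 1.0)
  expect_equal(best$aligned_query_fraction, 1.0)
  expect_true(all(m$reciprocal))
})

test_that("the pair-length gate is strict: ratio equal to tp is not aligned", {
  set.seed(104)
  # identical 90-nt prefix exon vs 100-nt exon: ratio exactly 0.9
  long <- rand_orf(33)                       # 99 nt
  short <- substring(long, 1, 90)
  blocks <- list(list(seq = short, exon = TRUE),
                 list(seq = paste0("GT", rand_dna(200), "AG"), exon = FALSE),
                 list(seq = long, exon = TRUE))
  g <- build_gene(blocks)
  ex <- select_representative_exons(g, 30, 0.9)
  expect_equal(nrow(global_search(g, ex, search_params(pair_ratio = 90 / 99))), 0)
  # loosening the gate admits the pair
  expect_gt(nrow(global_search(g, ex, search_params(pair_ratio = 0.5,
                                                    aligned_fraction = 0.8))), 0)
})

test_that("unrelated random exons never reach the global identity cutoff", {
  set.seed(105)
  hits <- 0L
  for (k in 1:40) {
    blocks <- list(list(seq = rand_orf(50), exon = TRUE),
                   list(seq = paste0("GT", rand_dna(150), "AG"), exon = FALSE),
                   list(seq = rand_orf(50), exon = TRUE))
    g <- build_gene(blocks)
    ex <- select_representative_exons(g, 30, 0.9)
    hits <- hits + nrow(global_search(g, ex, search_params(identity = 0.4)))
  }
  expect_equal(hits, 0L)
})

test_that("search mode restricts the sources and unions them in mode both", {
  set.seed(106)
  g <- dup_gene(45, "exon")
  p_local <- search_params(mode = "local")
  p_global <- search_params(mode = "global")
  p_both <- search_params(mode = "both")
  ml <- run_search(g, p_local)
  mg <- run_search(g, p_global)
  mb <- run_search(g, p_both)
  expect_true(all(ml$source == "local"))
  expect_true(all(mg$source == "global"))
  expect_equal(nrow(mb), nrow(ml) + nrow(mg))
  # single-exon gene: no pairs for the global search
  g1 <- build_gene(list(list(seq = rand_orf(60), exon = TRUE)))
  expect_equal(nrow(run_search(g1, p_global)), 0)
})

test_that("global search is symmetric under exon-pair order reversal", {
  set.seed(107)
  g <- dup_gene(45, "exon")
  ex <- select_representative_exons(g, 30, 0.9)
  ex_rev <- ex
  ex_rev$exons <- ex$exons[rev(seq_len(nrow(ex$exons))), , drop = FALSE]
  m1 <- global_search(g, ex, search_params())
  m2 <- global_search(g, ex_rev, search_params())
  key <- function(m) {
    a <- pmin(m$q_start, m$t_start); b <- pmax(m$q_end, m$t_end)
    sort(paste(a, b, round(m$protein_identity, 10)))
  }
  expect_identical(key(m1), key(m2))
})

test_that("sensitivity is monotone in the thresholds", {
  set.seed(108)
  g <- dup_gene(45, "intronic",
                copy_seq = local({  # a mildly diverged copy
                  s <- strsplit(rand_orf(45), "")[[1]]
                  i <- sample(seq_along(s), 20)
                  s[i] <- sapply(s[i], function(b) sample(setdiff(BASES, b), 1))
                  paste(s, collapse = "")
                }))
  ex <- select_representative_exons(g, 30, 0.9)
  strict <- local_search(g, ex, search_params(evalue_cutoff = 1e-6,
                                              query_coverage = 0.95))
  loose <- local_search(g, ex, search_params(evalue_cutoff = 1e-2,
                                             query_coverage = 0.7))
  k <- function(m) paste(m$q_start, m$q_end, m$t_start, m$t_end)
  expect_true(all(k(strict) %in% k(loose)))

  gx <- dup_gene(45, "exon")
  exx <- select_representative_exons(gx, 30, 0.9)
  gs <- global_search(gx, exx, search_params(identity = 0.9, aligned_fraction = 0.95))
  gl <- global_search(gx, exx, search_params(identity = 0.2, aligned_fraction = 0.5))
  expect_true(all(k(gs) %in% k(gl)))
})

test_that("builtin and external translated-search backends agree on exact copies", {
  skip_if(Sys.which("tblastx") == "", "no tblastx-compatible executable on PATH")
  set.seed(109)
  g <- dup_gene(60, "intronic")
  ex <- select_representative_exons(g, 30, 0.9)
  copy <- attr(g, "copy")
  mb <- local_search(g, ex, search_params(backend = "builtin"))
  me <- local_search(g, ex, search_params(backend = "external"))
  tb <- mb[.iv_overlap(mb$t_start, mb$t_end, copy) > 0.8, , drop = FALSE]
  te <- me[.iv_overlap(me$t_start, me$t_end, copy) > 0.8, , drop = FALSE]
  expect_gte(nrow(tb), 1); expect_gte(nrow(te), 1)
  expect_lte(abs(tb$t_start[1] - te$t_start[1]), 3)
  expect_lte(abs(tb$t_end[1] - te$t_end[1]), 3)
})
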