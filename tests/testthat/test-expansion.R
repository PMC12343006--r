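# match graphs, expansions, tandemness, transcript interdependence

# minimal builders for graph-level tests (no sequences needed)
rep_set <- function(iv) {
  structure(list(gene_id = "g", exons = iv, l = 30L, ce = 0.9),
            class = "representative_exons")
}

rmatch <- function(q, t, class = "full_length",
                   source = if (class == "full_length") "global" else "local") {
  data.frame(gene_id = "g", q_start = q[1], q_end = q[2], t_start = t[1],
             t_end = t[2], source = source, evalue = 1e-20,
             protein_identity = 0.9, dna_identity = NA_real_,
             aligned_query_fraction = 1, reciprocal = source == "global",
             match_class = class, cluster_id = 1L, rt_start = t[1],
             rt_end = t[2], reading_frame = 0L)
}

test_that("the match graph encodes direction and reciprocity", {
  ex <- rep_set(data.frame(start = c(10, 100), end = c(50, 140)))
  # no matches: only isolated representative vertices
  g0 <- build_match_graph(ex, rmatch(c(1, 2), c(3, 4))[0, ])
  expect_equal(igraph::vcount(g0), 2)
  expect_equal(igraph::ecount(g0), 0)
  # one local match: one directed edge
  g1 <- build_match_graph(ex, rmatch(c(10, 50), c(200, 240), "intronic"))
  expect_equal(igraph::vcount(g1), 3)
  expect_equal(igraph::ecount(g1), 1)
  # one global match: bidirectional
  g2 <- build_match_graph(ex, rmatch(c(10, 50), c(100, 140)))
  expect_equal(igraph::ecount(g2), 2)
  expect_true(igraph::are_adjacent(g2, "10-50", "100-140"))
  expect_true(igraph::are_adjacent(g2, "100-140", "10-50"))
})

test_that("expansions are connected components excluding isolated vertices", {
  ex <- rep_set(data.frame(start = c(10, 100, 200, 400, 500),
                           end = c(50, 140, 240, 440, 540)))
  # chain A->B, B->C plus an unrelated pair D<->E: two expansions
  rm <- rbind(rmatch(c(10, 50), c(100, 140), "intronic"),
              rmatch(c(100, 140), c(200, 240), "intronic"),
              rmatch(c(400, 440), c(500, 540)))
  exps <- find_expansions(build_match_graph(ex, rm))
  expect_length(exps, 2)
  ks <- sort(vapply(exps, `[[`, 0L, "k"))
  expect_equal(ks, c(2L, 3L))
  expect_equal(vapply(exps, `[[`, 0L, "event_count"),
               vapply(exps, `[[`, 0L, "k") - 1L)
  fl <- vapply(exps, `[[`, TRUE, "full_length_only")
  expect_equal(sort(fl), c(FALSE, TRUE))
  # empty graph
  expect_length(find_expansions(build_match_graph(ex, rm[0, ])), 0)
})

test_that("expansion extraction agrees with brute-force components", {
  set.seed(301)
  for (trial in 1:500) {
    n <- sample(2:20, 1)
    iv <- data.frame(start = 10L * seq_len(n), end = 10L * seq_len(n) + 5L)
    n_e <- sample(0:min(12, n * (n - 1) / 2), 1)
    rm_rows <- list()
    edges <- matrix(0L, 0, 2)
    if (n_e > 0) {
      for (k in seq_len(n_e)) {
        ab <- sample.int(n, 2)
        cls <- sample(c("full_length", "intronic", "partial"), 1)
        rm_rows[[k]] <- rmatch(c(iv$start[ab[1]], iv$end[ab[1]]),
                               c(iv$start[ab[2]], iv$end[ab[2]]), cls)
        edges <- rbind(edges, sort(ab))
      }
    }
    rm <- do.call(rbind, c(list(rmatch(c(1, 2), c(3, 4))[0, ]), rm_rows))
    exps <- find_expansions(build_match_graph(rep_set(iv), rm))
    # oracle: relax edges to components, drop isolated vertices
    comp <- oracle_components(n, edges)
    in_edge <- seq_len(n) %in% as.vector(edges)
    expected <- unname(lapply(split(seq_len(n)[in_edge], comp[in_edge]), sort))
    expected <- expected[order(vapply(expected, min, 0L))]
    got <- lapply(exps, function(e)
      sort(match(e$vertices$start, iv$start)))
    got <- got[order(vapply(got, min, 0L))]
    expect_equal(got, expected)
  }
})

test_that("tandemness is decided by consecutive coding-exon clusters", {
  coding <- data.frame(start = c(10, 100, 200, 400), end = c(50, 140, 240, 440))
  mk_exp <- function(iv) list(expansion_id = 1L, vertices = iv, k = nrow(iv),
                              event_count = nrow(iv) - 1L, full_length_only = TRUE)
  # adjacent duplicates: tandem
  t1 <- classify_tandemness(mk_exp(data.frame(start = c(10, 100), end = c(50, 140))),
                            coding)
  expect_true(t1$tandem)
  # a complete exon (cluster 2) lies between clusters 1 and 3
  t2 <- classify_tandemness(mk_exp(data.frame(start = c(10, 200), end = c(50, 240))),
                            coding)
  expect_false(t2$tandem)
  # k = 3 expansion at cluster positions 1, 2, 4
  t3 <- classify_tandemness(mk_exp(data.frame(start = c(10, 100, 400),
                                              end = c(50, 140, 440))), coding)
  expect_equal(t3$tandem, c(TRUE, FALSE))
  expect_equal(nrow(t3), 2)  # pairs <= k - 1
  # tandemness is undefined for non-full-length expansions
  bad <- mk_exp(data.frame(start = c(10, 100), end = c(50, 140)))
  bad$full_length_only <- FALSE
  expect_error(classify_tandemness(bad, coding), "full-length")
})

# gene with duplicates e1, e2 and a filler exon; transcripts built per pattern
interdep_gene <- function(pattern) {
  # pattern: T x 2 logical matrix (transcripts x duplicates)
  e1 <- c(101, 200); e2 <- c(301, 400); filler <- c(501, 600)
  txs <- lapply(seq_len(nrow(pattern)), function(t) {
    iv <- data.frame(start = 501, end = 600)
    if (pattern[t, 1]) iv <- rbind(iv, data.frame(start = 101, end = 200))
    if (pattern[t, 2]) iv <- rbind(iv, data.frame(start = 301, end = 400))
    iv
  })
  names(txs) <- paste0("t", seq_len(nrow(pattern)))
  gene_model("gI", "chr1", "+", c(1, 700), txs, strrep("A", 700))
}

test_that("interdependence matches its illustrative cases", {
  grp <- data.frame(start = c(101, 301), end = c(200, 400))
  expect_equal(classify_interdependence(
    interdep_gene(matrix(c(TRUE, TRUE, TRUE, TRUE), 2)), grp), "obligate")
  expect_equal(classify_interdependence(
    interdep_gene(matrix(c(TRUE, FALSE, FALSE, TRUE), 2)), grp), "exclusive")
  expect_equal(classify_interdependence(
    interdep_gene(matrix(c(TRUE, TRUE, TRUE, FALSE), 2)), grp), "flexible")
  expect_equal(classify_interdependence(
    interdep_gene(matrix(c(TRUE, FALSE, TRUE, FALSE), 2)), grp), "optional_obligate")
  expect_error(classify_interdependence(
    interdep_gene(matrix(TRUE, 1, 2)), grp[1, , drop = FALSE]), "at least two")
})

test_that("interdependence is total and exclusive over all membership patterns", {
  grp <- data.frame(start = c(101, 301), end = c(200, 400))
  classes6 <- c("obligate", "exclusive", "flexible",
                "optional_obligate", "optional_exclusive", "optional_flexible")
  for (T in 1:4) {
    pats <- expand.grid(rep(list(c(FALSE, TRUE)), 2 * T))
    for (r in seq_len(nrow(pats))) {
      P <- matrix(as.logical(unlist(pats[r, ])), nrow = T)
      if (any(colSums(P) == 0)) next  # a duplicate absent everywhere
      got <- classify_interdependence(interdep_gene(P), grp)
      expect_true(got %in% classes6)
      expect_identical(got, oracle_interdependence(P))
      # the three non-optional classes partition full-coverage patterns
      if (all(rowSums(P) >= 1))
        expect_true(got %in% classes6[1:3])
      else
        expect_true(startsWith(got, "optional_"))
    }
  }
})
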