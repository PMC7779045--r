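# Co-variation scoring: concatenation, weighting, MI-APC, mfDCA, ranking
# and the inter/intra filtering rules.

test_that("concatenation joins shared species and records segments", {
  a <- toy_alignment(c("MKLV", "MKLA", "MKIV"),
                     species = c("Homo sapiens", "Bos taurus", "Mus musculus"),
                     protein = "MT-ND1")
  b <- toy_alignment(c("WYTRAA", "WYTRAC", "WYSRAC"),
                     species = c("Homo sapiens", "Bos taurus", "Mus musculus"),
                     protein = "MT-CO1")
  cc <- concatenate_alignments(list(a, b))
  expect_equal(n_columns(cc), 10L)
  expect_equal(cc$segments$protein, c("MT-ND1", "MT-CO1"))
  expect_equal(cc$segments$start, c(1L, 5L))
  expect_equal(cc$segments$end, c(4L, 10L))
  expect_equal(cc$seqs[cc$ref], "MKLVWYTRAA")
  # only species present in all inputs survive
  b2 <- toy_alignment(c("WYTRAA", "WYTRAC"),
                      species = c("Homo sapiens", "Bos taurus"),
                      protein = "MT-CO1")
  cc2 <- concatenate_alignments(list(a, b2))
  expect_setequal(cc2$species, c("Homo sapiens", "Bos taurus"))
  # no overlap at all is an error
  c3 <- toy_alignment(c("AAAA", "CCCC"),
                      species = c("Rattus norvegicus", "Gallus gallus"))
  expect_error(concatenate_alignments(list(a, c3)), "not present|no species")
})

test_that("duplicate species rows resolve to the one closest to human", {
  a <- toy_alignment(c("AAAA", "AAAT", "TTTT"),
                     ids = c("h", "x1", "x2"),
                     species = c("Homo sapiens", "Bos taurus", "Bos taurus"),
                     protein = "P1")
  b <- toy_alignment(c("CCCC", "CCCC"), ids = c("h", "x"),
                     species = c("Homo sapiens", "Bos taurus"),
                     protein = "P2")
  cc <- concatenate_alignments(list(a, b))
  expect_equal(cc$seqs[cc$species == "Bos taurus"], "AAATCCCC")
})

test_that("sequence weights follow the inverse-redundancy rule", {
  same <- toy_alignment(rep("MKLVMKLVML", 4))
  w <- sequence_weights(same)
  expect_equal(as.numeric(w), rep(0.25, 4))
  expect_equal(attr(w, "Meff"), 1)
  distinct <- toy_alignment(c("AAAAAAAAAA", "CCCCCCCCCC", "DDDDDDDDDD"))
  expect_equal(as.numeric(sequence_weights(distinct)), rep(1, 3))
  mix <- toy_alignment(c("AAAAAAAAAA", "AAAAAAAAAA", "WWWWWWWWWW"))
  wm <- sequence_weights(mix)
  expect_equal(as.numeric(wm), c(0.5, 0.5, 1))
  expect_equal(attr(wm, "Meff"), 2)
})

test_that("perfectly coupled binary columns give 1 bit before APC", {
  aln <- toy_alignment(c(rep("AC", 4), rep("CA", 4)))
  m <- mi_apc(aln, pseudocount = 0, weights = rep(1, 8))
  expect_equal(m$raw[1, 2], 1)
  expect_equal(m$raw[2, 1], 1)
})

test_that("independent uniform columns give near-zero MI at large n", {
  set.seed(5)
  seqs <- paste0(sample(c("A", "C"), 4000, replace = TRUE),
                 sample(c("A", "C"), 4000, replace = TRUE))
  aln <- toy_alignment(seqs, species = c("Homo sapiens",
                                         sprintf("Species sp%04d", 1:3999)))
  m <- mi_apc(aln, pseudocount = 0, weights = rep(1, 4000))
  expect_lt(m$raw[1, 2], 0.005)
})

test_that("MI and DCA matrices are symmetric with NA diagonals and DI >= 0", {
  sim <- simulate_alignment(60, 12, divergence = 0.5, seed = 8)
  m1 <- mi_apc(sim$alignment)
  m2 <- mfdca(sim$alignment)
  for (m in list(m1, m2)) {
    expect_true(all(is.na(diag(m$scores))))
    off <- m$scores; diag(off) <- 0
    expect_equal(off, t(off))
  }
  di <- m2$scores; diag(di) <- 0
  expect_true(all(di >= 0))
})

test_that("iid columns give small DI; a planted pair attains the maximum", {
  # background DI is pure sampling noise and shrinks with depth; at 1000
  # i.i.d. uniform sequences it sits well below the planted-signal scale
  set.seed(20)
  m0 <- matrix(sample(AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY",
                                           "")[[1]], 8000, TRUE), 1000, 8)
  iid <- toy_alignment(apply(m0, 1, paste, collapse = ""),
                       species = c("Homo sapiens",
                                   sprintf("Species sp%04d", 1:999)))
  d0 <- mfdca(iid)$scores
  expect_lt(max(d0, na.rm = TRUE), 0.1)
  sim1 <- simulate_alignment(150, 10, divergence = 0.6,
                             coupled_pairs = data.frame(i = 2, j = 7,
                                                        strength = 0.9),
                             seed = 22)
  d1 <- mfdca(sim1$alignment)$scores
  expect_equal(d1[2, 7], max(d1, na.rm = TRUE))
  expect_gt(d1[2, 7], 2 * max(d1[-c(2, 7), -c(2, 7)], na.rm = TRUE))
})

test_that("both scorers are permutation-equivariant", {
  sim <- simulate_alignment(40, 8, divergence = 0.5, seed = 13)
  aln <- sim$alignment
  set.seed(99)
  perm_rows <- c(1L, sample(2:40))                # keep the reference first
  aln_r <- protein_alignment(aln$ids[perm_rows], aln$seqs[perm_rows],
                             aln$species[perm_rows], aln$ids[1L],
                             protein = aln$protein)
  cols <- sample(8)
  mat <- as.matrix(aln)
  aln_c <- protein_alignment(aln$ids,
                             apply(mat[, cols, drop = FALSE], 1L, paste,
                                   collapse = ""),
                             aln$species, aln$ids[1L], protein = aln$protein)
  for (scorer in list(mi_apc, mfdca)) {
    base <- scorer(aln)$scores
    expect_equal(scorer(aln_r)$scores, base, tolerance = 1e-7)
    expect_equal(scorer(aln_c)$scores, base[cols, cols], tolerance = 1e-7)
  }
})

test_that("top_pairs ranks by score with deterministic positional tie-breaks", {
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 5
  sc[1, 3] <- sc[3, 1] <- 3
  sc[2, 3] <- sc[3, 2] <- 1
  m <- make_score_matrix(sc)
  tp <- top_pairs(m, 2)
  expect_equal(tp$score, c(5, 3))
  expect_equal(tp$position_a, c(1, 1))
  expect_equal(tp$position_b, c(2, 3))
  # n beyond the pair count returns everything
  expect_equal(nrow(top_pairs(m, 100)), 3L)
  # ties resolve by (protein_a, position_a, position_b)
  tie <- matrix(2, 4, 4)
  mt <- make_score_matrix(tie)
  tpt <- top_pairs(mt, 3)
  expect_equal(tpt$position_a, c(1, 1, 1))
  expect_equal(tpt$position_b, c(2, 3, 4))
  # top-n lists are nested
  for (n1 in 1:5) {
    a <- top_pairs(mt, n1); b <- top_pairs(mt, n1 + 1L)
    expect_true(all(paste(a$position_a, a$position_b) %in%
                      paste(b$position_a, b$position_b)))
  }
})

test_that("columns gapped in the human reference never enter the ranking", {
  aln <- toy_alignment(c("AC-G", "ACTG", "CATG", "AGTC", "CCAG"))
  m <- mi_apc(aln, pseudocount = 0.1)
  tp <- top_pairs(m, 100)
  expect_false(any(tp$column_a == 3 | tp$column_b == 3))
  # positions map through the gap: column 4 is human position 3
  expect_equal(tp$position_b[tp$column_b == 4][1], 3)
})

test_that("inter/intra filters partition pairs disjointly", {
  pairs <- data.frame(
    protein_a = c("MT-ND1", "MT-ND2", "MT-ND2", "MT-ND1"),
    position_a = c(5, 10, 11, 7),
    protein_b = c("MT-ND2", "MT-ND2", "MT-ND2", "MT-ND1"),
    position_b = c(9, 30, 31, 20),
    column_a = 1:4, column_b = 5:8,
    method = "MI_APC", score = c(4, 3, 2, 1),
    klass = NA_character_, stringsAsFactors = FALSE)
  inter <- filter_inter(pairs)
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$klass, "inter")
  intra <- filter_intra(pairs, "MT-ND1")
  expect_equal(nrow(intra), 2L)
  expect_true(all(intra$klass == "intra"))
  # the two classes never share a pair
  expect_length(intersect(paste(inter$column_a, inter$column_b),
                          paste(intra$column_a, intra$column_b)), 0)
  expect_equal(nrow(filter_inter(pairs[0, ])), 0L)
  expect_equal(nrow(filter_intra(pairs[0, ])), 0L)
})

test_that("combine_methods reports union size |a|+|b| and flags common pairs", {
  mk <- function(pa, qa, pb, qb, method, score = 1) {
    data.frame(protein_a = pa, position_a = qa, protein_b = pb,
               position_b = qb, column_a = NA, column_b = NA,
               method = method, score = score, klass = "inter",
               stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, Map(mk, "P1", 1:3, "P2", 1:3, "MI_APC"))
  b <- do.call(rbind, Map(mk, "P1", 4:5, "P2", 4:5, "mfDCA"))
  cb <- combine_methods(a, b)
  expect_equal(nrow(cb$union), 5L)
  expect_equal(nrow(cb$common), 0L)
  # identical lists: every pair is common and the union keeps both copies
  cb2 <- combine_methods(a, transform(a, method = "mfDCA"))
  expect_equal(nrow(cb2$union), 6L)
  expect_equal(nrow(cb2$common), 3L)
  expect_true(all(cb2$union$in_common))
  b3 <- rbind(b, mk("P1", 2, "P2", 2, "mfDCA"))
  cb3 <- combine_methods(a, b3)
  expect_equal(nrow(cb3$common), 1L)
  expect_equal(sum(cb3$union$in_common), 2L)
})

test_that("score matrices round-trip through their TSV with header block", {
  sim <- simulate_alignment(30, 6, divergence = 0.4, seed = 31)
  m <- mi_apc(sim$alignment)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(m, f)
  m2 <- read_score_matrix(f)
  expect_equal(m2$method, m$method)
  expect_equal(m2$scores, m$scores, tolerance = 1e-12)
  expect_equal(m2$segments, m$segments)
  expect_equal(m2$column_map$position, m$column_map$position)
  expect_equal(m2$params$pseudocount, m$params$pseudocount)
})

test_that("the I-COMS dialect adapter feeds the TOP-N selection", {
  lab <- c("MT-ND1_1", "MT-ND1_2", "MT-CO1_1", "MT-CO1_2")
  sc <- matrix(0, 4, 4, dimnames = list(lab, lab))
  sc[1, 3] <- sc[3, 1] <- 9
  sc[1, 2] <- sc[2, 1] <- 7
  sc[3, 4] <- sc[4, 3] <- 5
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(sc, f, sep = "\t", quote = FALSE)
  m <- read_icoms_matrix(f, method = "cMI")
  expect_equal(m$column_map$protein,
               c("MT-ND1", "MT-ND1", "MT-CO1", "MT-CO1"))
  tp <- top_pairs(m, 3)
  expect_equal(tp$score, c(9, 7, 5))
  inter <- filter_inter(tp)
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$protein_a, "MT-ND1")
  expect_equal(inter$protein_b, "MT-CO1")
  intra <- filter_intra(tp, "MT-ND1")
  expect_equal(nrow(intra), 1L)
  expect_equal(intra$protein_a, "MT-CO1")
  expect_error(read_icoms_matrix(f, method = "cMI",
                                 label_pattern = "^(ZZZ)([0-9]+)$"),
               "unparseable")
})

test_that("bundle reproduction aggregates per-method counts over matrix runs", {
  dir <- withr::local_tempdir()
  lab <- c("MT-ND1_1", "MT-ND1_2", "MT-CO1_1", "MT-CO1_2")
  write_run <- function(name, hot) {
    sc <- matrix(0, 4, 4, dimnames = list(lab, lab))
    for (h in hot) sc[h[1], h[2]] <- sc[h[2], h[1]] <- h[3]
    write.table(sc, file.path(dir, name), sep = "\t", quote = FALSE)
  }
  # cMI run: 2 inter pairs; mfDCA run: 2 inter pairs, 1 shared with cMI
  write_run("run1_cMI.tsv", list(c(1, 3, 9), c(2, 4, 8), c(1, 2, 1)))
  write_run("run1_mfDCA.tsv", list(c(1, 3, 6), c(1, 4, 5), c(3, 4, 2)))
  counts <- reproduce_icoms_counts(dir, top_n = 2)
  expect_equal(counts$inter$cmi, 2L)
  expect_equal(counts$inter$mfdca, 2L)
  expect_equal(counts$inter$union, 4L)
  expect_equal(counts$inter$common, 1L)
  expect_error(reproduce_icoms_counts(file.path(dir, "nope")), "not found")
})

test_that("planted coupled pairs are ranked above background by both methods", {
  planted <- data.frame(i = c(4, 11, 18, 27), j = c(33, 22, 39, 8),
                        strength = 0.9)
  sim <- simulate_alignment(300, 40, divergence = 0.6,
                            coupled_pairs = planted, seed = 77)
  w <- sequence_weights(sim$alignment)
  expect_gte(attr(w, "Meff"), 200)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  truth_keys <- key(planted$i, planted$j)
  for (scorer in list(mi_apc, mfdca)) {
    tp <- top_pairs(scorer(sim$alignment), n = choose(40, 2))
    lab <- key(tp$column_a, tp$column_b) %in% truth_keys
    expect_gte(ranking_auc(tp$score, lab), 0.9)
  }
})
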