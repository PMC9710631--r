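test_that("coefficients reproduce their formulas on worked examples", {
  expect_equal(conditional_probability(pair_counts(10, 10, 10)), 1)
  expect_equal(conditional_probability(pair_counts(8, 5, 2)), 0.25)
  expect_equal(conditional_probability(pair_counts(8, 5, 0)), 0)
  expect_equal(dice_coefficient(pair_counts(6, 6, 6)), 1)
  expect_equal(dice_coefficient(pair_counts(4, 6, 2)), 0.4)
  expect_equal(dice_coefficient(pair_counts(4, 6, 0)), 0)
  expect_equal(otsuka_ochiai(pair_counts(9, 9, 9)), 1)
  expect_equal(otsuka_ochiai(pair_counts(4, 9, 3)), 0.5)
})

test_that("degenerate counts are rejected", {
  expect_error(pair_counts(3, 5, 4), "f_ab")
  expect_error(pair_counts(3, 5, 2, n_docs = 4), "n_docs")
  expect_error(conditional_probability(pair_counts(0, 5, 0)), "undefined")
  expect_error(otsuka_ochiai(pair_counts(0, 0, 0)), "undefined")
  expect_error(dice_coefficient(pair_counts(0, 0, 0)), "undefined")
})

test_that("otsuka-ochiai equals cosine similarity of incidence vectors", {
  set.seed(21)
  for (i in seq_len(50)) {
    n <- 30L
    a <- sample(c(TRUE, FALSE), n, replace = TRUE)
    b <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(a) || !any(b)) next
    counts <- pair_counts(sum(a), sum(b), sum(a & b), n)
    cosine <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(otsuka_ochiai(counts), cosine)
  }
})

test_that("coefficient bounds, symmetry and AM-GM ordering hold under fuzz", {
  set.seed(22)
  for (i in seq_len(500)) {
    f_a <- sample(1:50, 1L)
    f_b <- sample(1:50, 1L)
    f_ab <- sample(0:min(f_a, f_b), 1L)
    c_xy <- pair_counts(f_a, f_b, f_ab)
    c_yx <- pair_counts(f_b, f_a, f_ab)
    d <- dice_coefficient(c_xy)
    k <- otsuka_ochiai(c_xy)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_gte(k, 0); expect_lte(k, 1)
    expect_equal(d, dice_coefficient(c_yx))
    expect_equal(k, otsuka_ochiai(c_yx))
    expect_lte(d, k + 1e-15)
    if (f_a == f_b) expect_equal(d, k) else if (f_ab > 0) expect_lt(d, k)
  }
})

test_that("coefficients are monotone in f_ab at fixed marginals", {
  f_a <- 12L; f_b <- 20L
  for (fn in list(conditional_probability, dice_coefficient,
                  otsuka_ochiai)) {
    vals <- vapply(0:12, function(j) fn(pair_counts(f_a, f_b, j)),
                   numeric(1L))
    expect_true(all(diff(vals) > 0))
  }
})

# a small fixed corpus for the code-level tests
assoc_fixture <- function() {
  corpus <- structure(list(
    pmid = as.character(1:10),
    stems = list(c("Va", "Vb"), c("Va", "Vc"), c("Va"), c("Vb", "Vc"),
                 c("Vc"), c("Va", "Vb", "Vc"), c("Vd"), c("Vd", "Va"),
                 c("Vb"), c("Vc", "Vd"))),
    class = "abstract_corpus")
  dictionary <- data.frame(
    code = c("X00001", "X00001", "Y00001", "Z00001"),
    kind = c("C", "C", "C", "C"),
    term = c("Va", "Vd", "Vb", "Vc"),
    stems = c("Va", "Vd", "Vb", "Vc"),
    stringsAsFactors = FALSE)
  class(dictionary) <- c("term_dictionary", "data.frame")
  list(corpus = corpus, dictionary = dictionary,
       index = build_index(corpus, dictionary))
}

test_that("code pair distance max-pools over term pairs", {
  fx <- assoc_fixture()
  # X terms {Va, Vd}, Y term {Vb}: f(Va)=5, f(Vd)=3, f(Vb)=4,
  # f(Va&Vb)=2, f(Vd&Vb)=0 -> max K = 2/sqrt(20)
  e <- code_pair_distance("X00001", "Y00001", fx$index, fx$dictionary)
  expect_equal(e$coefficient, 2 / sqrt(20))
  expect_equal(e$distance, -log(2 / sqrt(20)))
  expect_identical(e$best_term_x, "Va")
  expect_identical(e$best_term_y, "Vb")
  expect_identical(e$pmids, "1,6")
  expect_equal(e$f_ab, 2L)
})

test_that("self-similarity gives zero distance; disjoint gives +Inf", {
  fx <- assoc_fixture()
  self <- code_pair_distance("Y00001", "Y00001", fx$index, fx$dictionary)
  expect_equal(self$coefficient, 1)
  expect_equal(self$distance, 0)
  # a term with empty posting only
  dict2 <- rbind(fx$dictionary,
                 data.frame(code = "W00001", kind = "C", term = "Vz",
                            stems = "Vz"))
  class(dict2) <- c("term_dictionary", "data.frame")
  idx2 <- build_index(fx$corpus, dict2)
  far <- code_pair_distance("W00001", "Y00001", idx2, dict2)
  expect_equal(far$coefficient, 0)
  expect_identical(far$distance, Inf)
  expect_error(code_pair_distance("NOPE", "Y00001", fx$index,
                                  fx$dictionary), "NOPE")
})

test_that("conditional edges carry both directions", {
  fx <- assoc_fixture()
  e <- code_pair_distance("Y00001", "Z00001", fx$index, fx$dictionary,
                          method = "conditional")
  # f(Vb)=4, f(Vc)=5, joint=2
  expect_equal(e$coefficient, 2 / 4)
  expect_equal(e$coefficient_yx, 2 / 5)
  expect_equal(e$distance, -log(0.5))
  expect_equal(e$distance_yx, -log(0.4))
})

test_that("edge set equals the dense all-pairs oracle", {
  set.seed(23)
  for (i in seq_len(20)) {
    toy <- random_toy_corpus(25L, toy_vocab(6L), 5L)
    idx <- build_index(toy$corpus, toy$dictionary)
    edges <- build_edge_set(index = idx, dictionary = toy$dictionary)
    codes <- unique(toy$dictionary$code)
    dense <- list()
    for (a in seq_len(length(codes) - 1L)) {
      for (b in (a + 1L):length(codes)) {
        e <- code_pair_distance(codes[a], codes[b], idx, toy$dictionary)
        if (e$f_ab >= 1L) dense[[length(dense) + 1L]] <- e
      }
    }
    dense <- do.call(rbind, dense)
    if (is.null(dense)) {
      expect_equal(nrow(edges), 0L)
    } else {
      dense <- dense[order(dense$code_x, dense$code_y), , drop = FALSE]
      rownames(dense) <- NULL
      expect_equal(as.data.frame(edges), dense, ignore_attr = TRUE)
    }
  }
})

test_that("min_support filters single-paper links", {
  fx <- assoc_fixture()
  e1 <- build_edge_set(index = fx$index, dictionary = fx$dictionary,
                       min_support = 1L)
  e3 <- build_edge_set(index = fx$index, dictionary = fx$dictionary,
                       min_support = 3L)
  expect_true(all(e3$f_ab >= 3L))
  expect_lt(nrow(e3), nrow(e1))
  expect_error(build_edge_set(index = fx$index,
                              dictionary = fx$dictionary,
                              min_support = 0L), "min_support")
})

test_that("edge tables round-trip through TSV", {
  fx <- assoc_fixture()
  edges <- build_edge_set(index = fx$index, dictionary = fx$dictionary)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(edges, path)
  back <- read_edges(path)
  expect_identical(attr(back, "method"), "otsuka_ochiai")
  expect_equal(as.data.frame(back), as.data.frame(edges),
               ignore_attr = TRUE)
})
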