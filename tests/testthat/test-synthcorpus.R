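tiny_spec <- function(n = 200L, seed = 1L) {
  corpus_spec(
    n_abstracts = n,
    codes = data.frame(code = c("H00001", "K00001", "D00001"),
                       kind = c("H", "K", "D"), stringsAsFactors = FALSE),
    synonyms = list(H00001 = c("covira syndrome" = 1),
                    K00001 = c("vexokinase" = 1),
                    D00001 = c("niravir" = 1)),
    marginal_probs = c(H00001 = 0.2, K00001 = 0.2, D00001 = 0.15),
    pair_probs = data.frame(x = c("H00001", "K00001"),
                            y = c("K00001", "D00001"),
                            p = c(0.1, 0.05), stringsAsFactors = FALSE),
    chain = c("H00001", "K00001", "D00001"),
    noise_vocab_size = 60L, seed = seed)
}

test_that("inconsistent specs are rejected before any writing", {
  base <- tiny_spec()
  expect_error(corpus_spec(
    100L, base$codes, base$synonyms,
    c(H00001 = 0.05, K00001 = 0.2, D00001 = 0.15),
    base$pair_probs), "exceeds a marginal")
  expect_error(corpus_spec(
    100L, base$codes, base$synonyms,
    c(H00001 = 0.9, K00001 = 0.9, D00001 = 0.9),
    base$pair_probs), "exceeds 1")
  bad_w <- base$synonyms
  bad_w$H00001 <- c("covira syndrome" = 0.7)
  expect_error(corpus_spec(100L, base$codes, bad_w, base$marginal_probs,
                           base$pair_probs), "sum to 1")
  shared <- base$synonyms
  shared$D00001 <- c("vexokinase" = 1)   # same stem as K00001's term
  expect_error(corpus_spec(100L, base$codes, shared, base$marginal_probs,
                           base$pair_probs), "share a stem")
})

test_that("expected coefficients follow the closed forms", {
  spec <- tiny_spec()
  expect_equal(expected_coefficient(spec, "H00001", "K00001"),
               0.1 / sqrt(0.2 * 0.2))
  expect_equal(expected_coefficient(spec, "K00001", "D00001", "dice"),
               2 * 0.05 / (0.2 + 0.15))
  expect_equal(expected_coefficient(spec, "K00001", "D00001",
                                    "conditional"), 0.05 / 0.2)
  # no planted joint -> zero
  expect_equal(expected_coefficient(spec, "H00001", "D00001"), 0)
  # worked example: marginals 0.04/0.09, joint 0.03 -> K = 0.5
  sp2 <- corpus_spec(
    100L,
    data.frame(code = c("C00001", "C00002"), kind = "C"),
    list(C00001 = c(alphin = 1), C00002 = c(betol = 1)),
    c(C00001 = 0.04, C00002 = 0.09),
    data.frame(x = "C00001", y = "C00002", p = 0.03))
  expect_equal(expected_coefficient(sp2, "C00001", "C00002"), 0.5)
  # synonym weights attenuate the max-pooled coefficient
  sp3 <- corpus_spec(
    100L,
    data.frame(code = c("C00001", "C00002"), kind = "C"),
    list(C00001 = c(alphin = 0.8, atester = 0.2),
         C00002 = c(betol = 1)),
    c(C00001 = 0.04, C00002 = 0.09),
    data.frame(x = "C00001", y = "C00002", p = 0.03))
  expect_equal(expected_coefficient(sp3, "C00001", "C00002"),
               0.5 * sqrt(0.8))
  expect_error(expected_coefficient(sp2, "C00001", "NOPE"), "marginal")
})

test_that("generation is reproducible and files parse back", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- tiny_spec()
  g1 <- generate_corpus(spec, d1)
  g2 <- generate_corpus(spec, d2)
  expect_identical(readLines(g1$pubmed_xml), readLines(g2$pubmed_xml))
  expect_identical(readLines(g1$kegg_flat), readLines(g2$kegg_flat))
  corpus <- parse_pubmed_xml(g1$pubmed_xml)
  expect_equal(length(corpus$pmid), spec$n_abstracts)
  recs <- parse_kegg_flatfile(g1$kegg_flat)
  expect_identical(recs$code, spec$codes$code)
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_corpus(spec, withr::local_tempdir()))
  expect_identical(rnorm(3), before)
})

test_that("planted marginals and joints are recovered from counts", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec(n = 2000L, seed = 8L)
  g <- generate_corpus(spec, dir)
  corpus <- parse_pubmed_xml(g$pubmed_xml)
  dict <- build_dictionary(parse_kegg_flatfile(g$kegg_flat))
  idx <- build_index(corpus, dict)
  n <- idx$doc_count
  for (cd in spec$codes$code) {
    key <- dict$stems[dict$code == cd][1L]
    f <- term_frequency(idx, key)
    m <- spec$marginal_probs[[cd]]
    expect_lt(abs(f / n - m), 3 * sqrt(m * (1 - m) / n) + 1e-9,
              label = cd)
  }
  # empirical code-level K within 3 sigma of the spec's expectation
  for (i in seq_len(nrow(spec$pair_probs))) {
    x <- spec$pair_probs$x[i]
    y <- spec$pair_probs$y[i]
    e <- code_pair_distance(x, y, idx, dict)
    ek <- expected_coefficient(spec, x, y)
    band <- 3 * ek * expected_distance_se(spec, x, y)
    expect_lt(abs(e$coefficient - ek), band, label = paste(x, y))
  }
  # zero-joint pairs truly never co-occur
  far <- code_pair_distance("H00001", "D00001", idx, dict)
  expect_equal(far$f_ab, 0L)
})

test_that("the ground truth table carries the implied coefficients", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec()
  g <- generate_corpus(spec, dir)
  expect_true(file.exists(g$truth_tsv))
  truth <- read.delim(g$truth_tsv)
  expect_equal(truth$k_otsuka_ochiai,
               vapply(seq_len(nrow(truth)), function(i) {
                 expected_coefficient(spec, truth$x[i], truth$y[i])
               }, numeric(1L)))
})

test_that("chain expectation combines edge distances and their noise", {
  spec <- tiny_spec()
  ec <- expected_chain_distance(spec)
  k1 <- expected_coefficient(spec, "H00001", "K00001")
  k2 <- expected_coefficient(spec, "K00001", "D00001")
  expect_equal(ec$distance, -log(k1) - log(k2))
  expect_gt(ec$se, 0)
  se1 <- expected_distance_se(spec, "H00001", "K00001")
  se2 <- expected_distance_se(spec, "K00001", "D00001")
  expect_equal(ec$se, sqrt(se1^2 + se2^2))
})
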