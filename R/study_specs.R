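#' Canned study corpus: planted disease-protein-drug chain
#'
#' The reference validation corpus for end-to-end chain recovery: a
#' disease (H00001) linked to a protein (K00001) and onward to a drug
#' (D00001) with strictly zero direct disease-drug co-occurrence, so the
#' planted drug is discoverable only through the indirect path — the
#' method's core use case in miniature.  A control drug (D00002) with a
#' weak direct link and a metabolite route (C00001) gives the tree
#' competing branches.  Synonym weights, marginals and joint
#' probabilities are fixed; they are chosen so the planted drug's
#' indirect rank key beats every competitor by a wide margin relative to
#' binomial sampling noise at the default corpus size.
#'
#' @param n_abstracts Corpus size (default 5000).
#' @param seed Generation seed.
#' @return A `corpus_spec` whose `chain` is
#'   `c("H00001", "K00001", "D00001")`.
#' @export
spec_planted_chain <- function(n_abstracts = 5000L, seed = 20210722L) {
  codes <- data.frame(
    code = c("H00001", "K00001", "D00001", "D00002", "C00001"),
    kind = c("H", "K", "D", "D", "C"),
    stringsAsFactors = FALSE)
  synonyms <- list(
    H00001 = c("covira syndrome" = 0.75, "COVIRA" = 0.25),
    K00001 = c("vexokinase" = 0.8, "VXK1" = 0.2),
    D00001 = c("niravir" = 0.7, "Zorvex" = 0.3),
    D00002 = c("baflomib" = 0.8, "Baflex" = 0.2),
    C00001 = c("flavosine" = 1.0))
  marginal <- c(H00001 = 0.12, K00001 = 0.08, D00001 = 0.05,
                D00002 = 0.06, C00001 = 0.07)
  pairs <- data.frame(
    x = c("H00001", "K00001", "H00001", "C00001", "H00001"),
    y = c("K00001", "D00001", "C00001", "D00002", "D00002"),
    p = c(0.035, 0.025, 0.010, 0.005, 0.002),
    stringsAsFactors = FALSE)
  corpus_spec(n_abstracts = n_abstracts, codes = codes,
              synonyms = synonyms, marginal_probs = marginal,
              pair_probs = pairs,
              chain = c("H00001", "K00001", "D00001"),
              noise_vocab_size = 400L, seed = seed)
}

#' Canned study corpus: heterogeneous marginals for method comparison
#'
#' A corpus built for comparing the three coefficient methods on the
#' direct-vs-indirect agreement statistic.  Nine drugs reach the root
#' disease through three proteins of very different literature
#' frequency (marginals 0.04, 0.10, 0.28), and every joint probability
#' is chosen to make the world exactly multiplicative for the
#' code-level cosine coefficient (`j_RD = j_RP * j_PD / m_P`, i.e.
#' conditional independence through the protein), so indirect and
#' direct distances agree in expectation.  Each code also carries a
#' rarely used synonym (weight 0.06-0.10): with max-pooling over term
#' pairs, the conditional-probability coefficient is destabilised by
#' rare terms' tiny denominators, while the cosine coefficient damps
#' them by `sqrt` of both term frequencies — the mechanism by which
#' frequency-heterogeneous vocabularies degrade conditional-probability
#' distance additivity.
#'
#' @inheritParams spec_planted_chain
#' @return A `corpus_spec` (root `"H00010"`).
#' @export
spec_heterogeneous <- function(n_abstracts = 5000L, seed = 20210722L) {
  prot <- c(K00011 = 0.04, K00012 = 0.10, K00013 = 0.28)
  drug_m <- c(D00011 = 0.02, D00012 = 0.05, D00017 = 0.04,
              D00013 = 0.03, D00014 = 0.06, D00018 = 0.045,
              D00015 = 0.04, D00016 = 0.07, D00019 = 0.055)
  drug_prot <- c(D00011 = "K00011", D00012 = "K00011", D00017 = "K00011",
                 D00013 = "K00012", D00014 = "K00012", D00018 = "K00012",
                 D00015 = "K00013", D00016 = "K00013", D00019 = "K00013")
  j_rp <- c(K00011 = 0.016, K00012 = 0.030, K00013 = 0.050)
  # strong and weak drug-protein links mixed, so true direct distances
  # span a wide range (the agreement statistic normalises by their SD)
  j_pd <- c(D00011 = 0.007, D00012 = 0.004, D00017 = 0.010,
            D00013 = 0.014, D00014 = 0.006, D00018 = 0.016,
            D00015 = 0.020, D00016 = 0.008, D00019 = 0.028)
  root <- "H00010"
  m_root <- 0.15

  codes <- data.frame(
    code = c(root, names(prot), names(drug_m)),
    kind = c("H", rep("K", length(prot)), rep("D", length(drug_m))),
    stringsAsFactors = FALSE)
  drug_names <- c(D00011 = "zorafen", D00012 = "milradin",
                  D00017 = "cabotrel", D00013 = "velpramod",
                  D00014 = "tegravin", D00018 = "orlafin",
                  D00015 = "dalporex", D00016 = "simbactam",
                  D00019 = "fexolun")
  synonyms <- c(
    stats::setNames(list(c(relarix = 0.95, relarodine = 0.05)), root),
    list(K00011 = c(perolase = 0.95, PRX1 = 0.05),
         K00012 = c(tremalase = 0.95, TRM5 = 0.05),
         K00013 = c(globulase = 0.96, GLB9 = 0.04)),
    stats::setNames(lapply(names(drug_m), function(d) {
      stats::setNames(c(0.94, 0.06),
                      c(drug_names[[d]], paste0(toupper(substr(
                        drug_names[[d]], 1, 3)), "X")))
    }), names(drug_m)))
  marginal <- c(stats::setNames(m_root, root), prot, drug_m)

  rows <- list()
  for (p in names(prot)) {
    rows[[length(rows) + 1L]] <- data.frame(x = root, y = p,
                                            p = j_rp[[p]])
  }
  for (d in names(drug_m)) {
    p <- drug_prot[[d]]
    rows[[length(rows) + 1L]] <- data.frame(x = p, y = d, p = j_pd[[d]])
    # cosine-multiplicative (conditionally independent) direct link
    rows[[length(rows) + 1L]] <- data.frame(
      x = root, y = d, p = j_rp[[p]] * j_pd[[d]] / prot[[p]])
  }
  pairs <- do.call(rbind, rows)
  corpus_spec(n_abstracts = n_abstracts, codes = codes,
              synonyms = synonyms, marginal_probs = marginal,
              pair_probs = pairs, chain = NULL,
              noise_vocab_size = 400L, seed = seed)
}
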