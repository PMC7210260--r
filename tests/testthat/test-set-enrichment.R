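# Signature thresholds, GMT parsing, hypergeometric enrichment and the
# hybrid MetSEA contract.

test_that("signature thresholds: strict q, inclusive fold-change bounds", {
  de <- data.frame(gene = sprintf("g%d", 1:6),
                   fold_change = c(1.25, 1.0, 0.8, 2.0, 1.3, 0.5),
                   q = c(0.05, 0.05, 0.05, 0.1, 0.001, 0.2))
  sig <- suppressMessages(build_signature(de))
  expect_true(all(c("g1", "g5") %in% sig$up))   # FC = 1.25 is inclusive
  expect_equal(sig$down, "g3")
  expect_false("g2" %in% sig$all)               # FC = 1.0 passes neither bound
  expect_false("g4" %in% sig$all)               # q = 0.1 fails the strict q < 0.1
  expect_equal(sig$all, sort(union(sig$up, sig$down)))

  # log2FC dialect and manual row-by-row filter oracle
  set.seed(3)
  de2 <- data.frame(gene = sprintf("g%d", 1:10),
                    log2FC = rnorm(10), q = runif(10, 0, 0.3))
  sig2 <- suppressMessages(build_signature(de2))
  manual_up <- de2$gene[de2$q < 0.1 & 2^de2$log2FC >= 1.25]
  expect_equal(sig2$up, sort(manual_up))
  expect_error(suppressMessages(build_signature(data.frame(gene = "g", q = 1))),
               "fold_change or log2FC")
})

test_that("GMT parsing handles hybrid namespaces and malformed lines", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tg1\tg2\tg2",
               "P2\thybrid\tGENE:Ahcy\tMET:betaine\tMET:glycine"), p)
  pw <- load_gene_sets(p)
  expect_equal(pw$P1$members, c("g1", "g2"))
  expect_equal(sort(pw$P2$members), c("GENE:Ahcy", "MET:betaine", "MET:glycine"))

  writeLines(c("P1\tdesc\tg1", "oops\tonly-two-fields"), p)
  expect_error(load_gene_sets(p), "line 2")
})

test_that("hypergeometric tail is exact against exhaustive enumeration", {
  # all C(10,3) = 120 signature draws from a 10-feature universe with a
  # 4-member pathway
  draws <- utils::combn(10, 3)
  k_obs <- apply(draws, 2, function(d) sum(d <= 4))
  for (k in 0:3) {
    expect_equal(hypergeometric_tail(k, 3, 4, 10), mean(k_obs >= k),
                 tolerance = 1e-12)
  }
  expect_equal(hypergeometric_tail(2, 3, 4, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(0, 5, 3, 20), 1)
  expect_equal(hypergeometric_tail(4, 10, 4, 10), 1)  # n = M forces full overlap
  expect_error(hypergeometric_tail(5, 3, 4, 10), "impossible")
  # p is monotone non-increasing in k
  ps <- vapply(0:4, hypergeometric_tail, numeric(1), n = 10, K = 4, M = 30)
  expect_true(all(diff(ps) <= 0))
})

test_that("hypergeometric tail matches a resampling null", {
  set.seed(9)
  M <- 40; K <- 8; n <- 10
  universe <- seq_len(M)
  k_null <- replicate(5000, length(intersect(sample(universe, n), seq_len(K))))
  for (k in c(2, 3, 4)) {
    est <- mean(k_null >= k)
    p <- hypergeometric_tail(k, n, K, M)
    expect_lt(abs(est - p), 4 * sqrt(p * (1 - p) / 5000) + 1e-3)
  }
})

toy_pathways <- function() {
  list(A = list(pathway_id = "A", name = "a", members = sprintf("g%d", 1:10)),
       B = list(pathway_id = "B", name = "b", members = sprintf("g%d", 11:25)),
       C = list(pathway_id = "C", name = "c", members = sprintf("g%d", 30:34)))
}

test_that("ORA restricts to the universe, sorts deterministically", {
  universe <- sprintf("g%d", 1:100)
  sig <- sprintf("g%d", 1:10)   # exactly pathway A
  res <- run_ora(sig, toy_pathways(), universe)
  expect_equal(res$pathway_id[1], "A")
  expect_equal(res$k[1], 10)
  expect_true(res$q_value[1] < res$q_value[2])
  # permuted pathway order yields identical output
  res_p <- run_ora(sig, rev(toy_pathways()), universe)
  expect_identical(res, res_p)
  # BH over the tested pathways
  expect_equal(res$q_value, sort(bh_oracle(res$p_value)))
  # out-of-universe signature members are dropped before testing
  res2 <- run_ora(c(sig, "not_measured"), toy_pathways(), universe)
  expect_equal(res2$n[1], 10)
  expect_warning(run_ora(character(), toy_pathways(), universe), "empty")
})

test_that("MetSEA on gene-only input reduces exactly to ORA", {
  universe <- sprintf("g%d", 1:100)
  sig <- sprintf("g%d", c(1:6, 12, 13))
  a <- run_ora(sig, toy_pathways(), universe)
  b <- run_metsea(sig, character(), toy_pathways(), universe)
  expect_identical(a, b)
})

test_that("MetSEA separates gene and metabolite overlap and p falls with universe growth", {
  universe <- c(sprintf("GENE:g%d", 1:50), sprintf("MET:m%d", 1:20))
  pw <- list(H = list(pathway_id = "H", name = "hybrid",
                      members = c(sprintf("GENE:g%d", 1:4), sprintf("MET:m%d", 1:3))))
  res <- run_metsea(sprintf("GENE:g%d", 1:4), sprintf("MET:m%d", 1:2),
                    pw, universe)
  expect_equal(res$k, 6)
  expect_equal(res$gene_overlap, 4)
  expect_equal(res$met_overlap, 2)
  # metabolite-only signature on a gene-only pathway: no metabolite overlap
  gene_pw <- list(G = list(pathway_id = "G", name = "g",
                           members = sprintf("GENE:g%d", 1:4)))
  res0 <- run_metsea(character(), sprintf("MET:m%d", 1:3), gene_pw, universe)
  expect_equal(res0$k, 0)
  expect_equal(res0$p_value, 1)
  # doubling the universe with unannotated ids (overlaps fixed) decreases p
  bigger <- c(universe, sprintf("GENE:x%d", 1:70))
  res_big <- run_metsea(sprintf("GENE:g%d", 1:4), sprintf("MET:m%d", 1:2),
                        pw, bigger)
  expect_lt(res_big$p_value, res$p_value)
})

test_that("target-set overlap reports counts per direction", {
  sig <- structure(list(up = sprintf("u%d", 1:150), down = sprintf("d%d", 1:56),
                        all = c(sprintf("u%d", 1:150), sprintf("d%d", 1:56))),
                   class = "signature")
  targets <- c(sprintf("u%d", 1:120), sprintf("d%d", 1:38), "other")
  ov <- target_overlap(sig, targets)
  expect_equal(ov$n_overlap[ov$set == "all"], 158)
  expect_equal(ov$pct[ov$set == "all"], 77)   # 158/206
  expect_equal(ov$n_overlap[ov$set == "up"], 120)
  empty <- target_overlap(character(), targets)
  expect_equal(empty$n_overlap, 0)
  expect_true(is.na(empty$pct))
})
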