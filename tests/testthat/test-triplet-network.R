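mk_mat <- function(rows, n = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(length(rows) * n), nrow = length(rows),
         dimnames = list(rows, paste0("s", seq_len(n))))
}

test_that("TF-CpG gate passes identical vectors and rejects noise", {
  expr <- mk_mat(c("TF1", "TF2"))
  meth <- mk_mat(c("cg1", "cg2"), seed = 2)
  meth["cg1", ] <- expr["TF1", ] # identical -> r = 1
  cand <- data.frame(tf = c("TF1", "TF2"), probe = c("cg1", "cg2"))
  rec <- tf_cpg_correlations(expr, meth, cand)
  expect_equal(rec$tf, "TF1")
  expect_equal(rec$r, 1)
  expect_true(all(rec$fdr < 0.05))
})

test_that("empty candidate list yields an empty result", {
  expr <- mk_mat("TF1")
  meth <- mk_mat("cg1")
  rec <- tf_cpg_correlations(expr, meth,
                             data.frame(tf = character(),
                                        probe = character()))
  expect_equal(nrow(rec), 0L)
})

test_that("missing TFs are skipped with a warning", {
  expr <- mk_mat("TF1")
  meth <- mk_mat("cg1")
  cand <- data.frame(tf = c("TF1", "ghost"), probe = "cg1")
  expect_warning(rec <- tf_cpg_correlations(expr, meth, cand), "skipped")
  expect_true(all(rec$tf != "ghost"))
})

test_that("correlation gates share the emQTL module's r/p contract", {
  set.seed(8)
  x <- matrix(rnorm(20), nrow = 1, dimnames = list("TF1", paste0("s", 1:20)))
  y <- matrix(rnorm(20), nrow = 1, dimnames = list("cg1", paste0("s", 1:20)))
  rec <- tf_cpg_correlations(x, y, data.frame(tf = "TF1", probe = "cg1"),
                             fdr_cutoff = 1.0000001)
  pairs <- data.frame(probe = "cg1", gene = "TF1", distance_to_tss = 0L)
  em <- compute_emqtl(y, x, pairs, fdr_cutoff = 1)
  expect_equal(rec$r, em$r, tolerance = 1e-12)
  expect_equal(rec$p, em$p, tolerance = 1e-12)
  ora <- oracle_pearson(x[1, ], y[1, ])
  expect_equal(rec$r, ora$r, tolerance = 1e-12)
  expect_equal(rec$p, ora$p, tolerance = 1e-12)
})

test_that("TF-gene gate excludes self-pairs and keeps anticorrelation", {
  expr <- mk_mat(c("TF1", "G1"))
  expr["G1", ] <- -expr["TF1", ]
  cand <- data.frame(tf = c("TF1", "TF1"), gene = c("TF1", "G1"))
  rec <- tf_gene_correlations(expr, expr, cand)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$gene, "G1")
  expect_equal(rec$r, -1)
  expect_equal(rec$sign, "negative")
})

test_that("BH family for the gate is the candidate family only", {
  set.seed(13)
  expr <- mk_mat(paste0("TF", 1:6), n = 15)
  meth <- mk_mat(paste0("cg", 1:6), n = 15, seed = 14)
  cand <- data.frame(tf = paste0("TF", 1:6), probe = paste0("cg", 1:6))
  rec <- tf_cpg_correlations(expr, meth, cand, fdr_cutoff = 1.0000001)
  expect_equal(rec$fdr, oracle_bh(rec$p), tolerance = 1e-12)
})

test_that("triplet assembly equals a brute-force triple join", {
  set.seed(77)
  emqtls <- data.frame(
    probe = sample(paste0("cg", 1:8), 20, TRUE),
    gene = sample(paste0("G", 1:6), 20, TRUE),
    r = runif(20, -1, 1), fdr = runif(20, 0, 0.1))
  emqtls <- emqtls[!duplicated(emqtls[, 1:2]), ]
  emqtls$is_emqtl <- emqtls$fdr < 0.05
  tf_cpg <- data.frame(tf = sample(paste0("TF", 1:4), 10, TRUE),
                       probe = sample(paste0("cg", 1:8), 10, TRUE),
                       r = runif(10, -1, 1), fdr = runif(10, 0, 0.05))
  tf_cpg <- tf_cpg[!duplicated(tf_cpg[, 1:2]), ]
  tf_gene <- data.frame(tf = sample(paste0("TF", 1:4), 10, TRUE),
                        gene = sample(paste0("G", 1:6), 10, TRUE),
                        r = runif(10, -1, 1), fdr = runif(10, 0, 0.05))
  tf_gene <- tf_gene[!duplicated(tf_gene[, 1:2]), ]
  got <- assemble_triplets(emqtls, tf_cpg, tf_gene)
  want <- character(0)
  for (i in seq_len(nrow(tf_cpg))) for (j in which(emqtls$is_emqtl)) {
    for (k in seq_len(nrow(tf_gene))) {
      if (tf_cpg$probe[i] == emqtls$probe[j] &&
          tf_cpg$tf[i] == tf_gene$tf[k] &&
          emqtls$gene[j] == tf_gene$gene[k]) {
        want <- c(want, paste(tf_cpg$tf[i], emqtls$probe[j],
                              emqtls$gene[j]))
      }
    }
  }
  expect_setequal(paste(got$tf, got$probe, got$gene), unique(want))
  # deterministic lexicographic ordering
  expect_equal(order(got$tf, got$probe, got$gene), seq_len(nrow(got)))
})

test_that("missing tf-gene edge suppresses the triplet", {
  emqtls <- data.frame(probe = "cg1", gene = "G1", r = -0.9,
                       fdr = 0.001, is_emqtl = TRUE)
  tf_cpg <- data.frame(tf = "TF1", probe = "cg1", r = 0.8, fdr = 0.01)
  tf_gene_empty <- data.frame(tf = character(), gene = character(),
                              r = numeric(), fdr = numeric())
  expect_equal(nrow(assemble_triplets(emqtls, tf_cpg, tf_gene_empty)), 0L)
  tf_gene <- data.frame(tf = "TF1", gene = "G1", r = 0.7, fdr = 0.01)
  expect_equal(nrow(assemble_triplets(emqtls, tf_cpg, tf_gene)), 1L)
})

test_that("network export produces 3 edges/nodes per triplet and shared CpGs raise degree", {
  trip <- data.frame(
    tf = c("TF1", "TF2"), probe = c("cg1", "cg1"), gene = c("G1", "G1"),
    r_tfcpg = c(0.5, -0.4), r_tfgene = c(0.6, 0.7), r_cpggene = -0.8,
    fdr_tfcpg = 0.01, fdr_tfgene = 0.01, fdr_cpggene = 0.01)
  net <- export_network(trip)
  expect_equal(nrow(net$edges), 5L) # cg1-G1 shared edge deduplicated
  # cg1 carries both TF edges plus the gene edge
  expect_equal(net$nodes$degree[net$nodes$node == "cg1"], 3L)
  expect_equal(sort(unique(net$nodes$type)), c("cpg", "gene", "tf"))
})

test_that("dimer TF names expand to one candidate per constituent", {
  m <- random_pwm(5, id = "M1", seed = 4)
  m$tf <- "TFA::TFB"
  enriched <- data.frame(motif = "M1", ci_low = 2)
  flags <- matrix(TRUE, 1, 1, dimnames = list("cg1", "M1"))
  cand <- motif_tf_candidates(enriched, flags, list(M1 = m))
  expect_setequal(cand$tf, c("TFA", "TFB"))
})
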