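toy_genes <- function() {
  data.frame(
    gene = c("plus", "minus"), chrom = "chr1",
    start = c(10000L, 5000L), end = c(12000L, 9000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
}

toy_probes <- function(pos, snp = FALSE) {
  data.frame(probe = sprintf("cg%02d", seq_along(pos)), chrom = "chr1",
             pos = pos, snp_flag = rep(snp, length.out = length(pos)),
             stringsAsFactors = FALSE)
}

test_that("promoter windows are inclusive and strand-aware", {
  genes <- toy_genes()
  # + strand TSS = 10000: probe exactly at the -3000 boundary is kept
  pairs <- map_probes_to_promoters(toy_probes(7000L), genes, 3000)
  expect_equal(pairs$distance_to_tss[pairs$gene == "plus"], -3000L)
  # one base past the +3000 boundary is dropped
  pairs <- map_probes_to_promoters(toy_probes(13001L), genes, 3000)
  expect_equal(nrow(pairs[pairs$gene == "plus", ]), 0L)
  # - strand TSS = end = 9000; probe at 11999 is 2999 bases upstream
  pairs <- map_probes_to_promoters(toy_probes(11999L), genes, 3000)
  expect_true("minus" %in% pairs$gene)
  expect_equal(pairs$distance_to_tss[pairs$gene == "minus"], -2999L)
})

test_that("SNP-flagged probes are excluded before mapping", {
  pairs <- map_probes_to_promoters(toy_probes(10000L, snp = TRUE),
                                   toy_genes(), 3000)
  expect_equal(nrow(pairs), 0L)
})

test_that("unknown strand symbols raise an annotation error", {
  genes <- toy_genes()
  genes$strand[1] <- "*"
  expect_error(map_probes_to_promoters(toy_probes(10000L), genes, 3000),
               "strand")
})

test_that("interval mapping agrees with a quadratic all-pairs check", {
  set.seed(11)
  n_genes <- 60
  genes <- data.frame(
    gene = sprintf("g%03d", 1:n_genes), chrom = "chr1",
    start = sort(sample(5000:500000, n_genes)),
    strand = sample(c("+", "-"), n_genes, TRUE),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + 1500L
  probes <- data.frame(probe = sprintf("cg%03d", 1:300), chrom = "chr1",
                       pos = sample(1:510000, 300),
                       snp_flag = runif(300) < 0.1,
                       stringsAsFactors = FALSE)
  flank <- 3000
  got <- map_probes_to_promoters(probes, genes, flank)
  naive <- list()
  for (i in seq_len(nrow(probes))) {
    if (probes$snp_flag[i]) next
    for (j in seq_len(n_genes)) {
      tss <- if (genes$strand[j] == "+") genes$start[j] else genes$end[j]
      if (abs(probes$pos[i] - tss) <= flank) {
        naive[[length(naive) + 1]] <- paste(probes$probe[i],
                                            genes$gene[j])
      }
    }
  }
  expect_setequal(paste(got$probe, got$gene), unlist(naive))
})

test_that("emQTL correlations match the closed-form r and t-transform", {
  meth <- rbind(cg1 = c(0.1, 0.2, 0.3, 0.4))
  expr <- rbind(g1 = c(1, 3, 2, 4))
  colnames(meth) <- colnames(expr) <- paste0("s", 1:4)
  pairs <- data.frame(probe = "cg1", gene = "g1", distance_to_tss = 0L)
  rec <- compute_emqtl(meth, expr, pairs)
  expect_equal(rec$r, 0.8, tolerance = 1e-12)
  expect_equal(rec$p, 0.2, tolerance = 1e-12)
  expect_equal(rec$sign, "positive")
  # perfect anticorrelation
  expr2 <- rbind(g1 = c(4, 3, 2, 1))
  colnames(expr2) <- colnames(meth)
  rec2 <- compute_emqtl(meth, expr2, pairs)
  expect_equal(rec2$r, -1)
  expect_equal(rec2$sign, "negative")
  expect_true(rec2$is_emqtl)
})

test_that("degenerate pairs are skipped with a warning and leave the FDR family", {
  meth <- rbind(flat = c(0.5, 0.5, 0.5, 0.5), cg1 = c(0.1, 0.2, 0.3, 0.4))
  expr <- rbind(g1 = c(1, 2, 3, 4))
  colnames(meth) <- colnames(expr) <- paste0("s", 1:4)
  pairs <- data.frame(probe = c("flat", "cg1"), gene = "g1",
                      distance_to_tss = 0L)
  expect_warning(rec <- compute_emqtl(meth, expr, pairs),
                 "zero variance")
  expect_true(is.na(rec$fdr[rec$probe == "flat"]))
  # family of one: fdr equals p
  expect_equal(rec$fdr[rec$probe == "cg1"], rec$p[rec$probe == "cg1"])
})

test_that("emQTL set is monotone in the FDR cutoff", {
  set.seed(9)
  n <- 40
  meth <- matrix(runif(n * 20), nrow = n,
                 dimnames = list(sprintf("cg%02d", 1:n), paste0("s", 1:20)))
  expr <- matrix(rnorm(n * 20), nrow = n,
                 dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:20)))
  pairs <- data.frame(probe = rownames(meth), gene = rownames(expr),
                      distance_to_tss = 0L)
  cuts <- c(0.01, 0.05, 0.2, 0.8)
  sets <- lapply(cuts, function(cut) {
    rec <- compute_emqtl(meth, expr, pairs, fdr_cutoff = cut)
    paste(rec$probe[rec$is_emqtl], rec$gene[rec$is_emqtl])
  })
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("PCA variance fractions match an eigendecomposition oracle", {
  set.seed(21)
  meth <- matrix(runif(10 * 10), nrow = 10,
                 dimnames = list(paste0("cg", 1:10), paste0("s", 1:10)))
  pc <- methylation_pca(meth, k = 3)
  ev <- eigen(cov(t(meth)), symmetric = TRUE)$values
  expect_equal(pc$var_frac, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(pc$var_frac) <= 1e-12))
  expect_equal(sum(pc$var_frac), 1, tolerance = 1e-12)
})

test_that("PCA of collinear data puts all variance on PC1", {
  s <- seq(0.1, 0.9, length.out = 6)
  meth <- rbind(cg1 = s, cg2 = 0.5 * s + 0.05, cg3 = 0.2 * s)
  colnames(meth) <- paste0("s", 1:6)
  pc <- methylation_pca(meth)
  expect_equal(pc$var_frac[1], 1, tolerance = 1e-12)
})

test_that("PCA scores are invariant (up to sign) under probe reordering", {
  set.seed(3)
  meth <- matrix(runif(8 * 7), nrow = 8,
                 dimnames = list(paste0("cg", 1:8), paste0("s", 1:7)))
  a <- methylation_pca(meth, k = 2)
  b <- methylation_pca(meth[sample(8), ], k = 2)
  for (j in 1:2) {
    expect_equal(abs(cor(a$scores[, j], b$scores[, j])), 1,
                 tolerance = 1e-9)
  }
})
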