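#' Filter genes by expression prevalence
#'
#' Expression values are log2(FPKM + 1), so a gene counts as expressed
#' in a sample when its stored value exceeds zero (raw FPKM > 0).  A
#' gene is kept when it is expressed in at least `min_fraction` of all
#' samples.  Row order is preserved; an empty matrix returns empty.
#'
#' @param mat numeric matrix, genes x samples, log2(FPKM + 1) scale.
#' @param min_fraction minimum fraction of samples with non-zero raw
#'   expression, in (0, 1]. Default 0.5.
#' @return the filtered matrix.
#' @export
filter_expressed <- function(mat, min_fraction = 0.5) {
  stopifnot(is.numeric(min_fraction), length(min_fraction) == 1L,
            min_fraction > 0, min_fraction <= 1)
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L) return(mat)
  frac <- rowMeans(mat > 0)
  mat[frac >= min_fraction, , drop = FALSE]
}

#' Tumor-vs-normal differential expression by pooled-variance t-test
#'
#' Per gene: Student's two-sample t-test with pooled variance between
#' the tumor and normal columns, log2 fold change as the difference of
#' group means of the already-log2 values (tumor minus normal), and
#' Benjamini-Hochberg adjusted FDR across all genes.  A gene is called
#' `up` (`down`) when `fdr < fdr_cutoff` and `log2fc > lfc_cutoff`
#' (`< -lfc_cutoff`), otherwise `ns`.
#'
#' Degenerate genes follow a documented convention: zero variance in
#' both groups with equal means gives p = 1; zero pooled variance with
#' unequal means gives p = 0.
#'
#' @param mat numeric matrix, genes x samples.
#' @param groups character vector over colnames(mat) with values
#'   `"tumor"` / `"normal"`, or a named vector keyed by sample id.
#' @param fdr_cutoff,lfc_cutoff significance thresholds (defaults 0.05
#'   and 1).
#' @return data.frame with columns `gene`, `log2fc`, `t`, `p`, `fdr`,
#'   `direction`.
#' @export
differential_expression <- function(mat, groups, fdr_cutoff = 0.05,
                                    lfc_cutoff = 1) {
  mat <- as.matrix(mat)
  if (!is.null(names(groups))) groups <- groups[colnames(mat)]
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat),
            all(groups %in% c("tumor", "normal")))
  n1 <- sum(groups == "tumor")
  n2 <- sum(groups == "normal")
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  tum <- mat[, groups == "tumor", drop = FALSE]
  nor <- mat[, groups == "normal", drop = FALSE]
  m1 <- rowMeans(tum)
  m2 <- rowMeans(nor)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1)
  v2 <- rowSums((nor - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  tt <- lfc / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  # zero pooled variance: p by convention on whether the means differ
  zero <- se == 0
  p[zero & lfc == 0] <- 1
  p[zero & lfc != 0] <- 0
  tt[zero & lfc == 0] <- 0
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- rep("ns", nrow(mat))
  direction[fdr < fdr_cutoff & lfc > lfc_cutoff] <- "up"
  direction[fdr < fdr_cutoff & lfc < -lfc_cutoff] <- "down"
  gene <- rownames(mat)
  if (is.null(gene)) gene <- as.character(seq_len(nrow(mat)))
  data.frame(gene = gene, log2fc = unname(lfc), t = unname(tt),
             p = unname(p), fdr = unname(fdr), direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric overlap test for a functional gene set
#'
#' Probability of observing at least the actual overlap between a
#' called gene set and a functional set drawn from a common universe.
#'
#' @param de_genes,functional_set,universe character vectors of gene
#'   ids; both sets must be subsets of `universe`.
#' @return the upper-tail hypergeometric p-value.
#' @export
set_overlap_test <- function(de_genes, functional_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  de_genes <- unique(de_genes)
  functional_set <- unique(functional_set)
  stopifnot(all(de_genes %in% universe), all(functional_set %in% universe))
  k <- length(intersect(de_genes, functional_set))
  if (k == 0L) return(1)
  # P(X >= k), X ~ Hypergeom(white = |functional|, black = rest, drawn = |de|)
  stats::phyper(k - 1, length(functional_set),
                length(universe) - length(functional_set),
                length(de_genes), lower.tail = FALSE)
}

#' Two-sided Fisher exact test for up/down balance within a gene set
#'
#' Tests the 2x2 table (in set / not in set) x (up / down) for
#' association, i.e. whether up- and downregulated genes are
#' represented differently inside a functional set.  An all-zero table
#' returns p = 1 by convention.
#'
#' @param up_in_set,down_in_set counts of up/down genes inside the set.
#' @param up_total,down_total total up/down counts.
#' @return two-sided Fisher exact p-value.
#' @export
direction_balance_test <- function(up_in_set, down_in_set, up_total,
                                   down_total) {
  stopifnot(up_in_set >= 0, down_in_set >= 0,
            up_in_set <= up_total, down_in_set <= down_total)
  tab <- matrix(c(up_in_set, down_in_set,
                  up_total - up_in_set, down_total - down_in_set),
                nrow = 2, byrow = TRUE)
  if (all(tab == 0)) return(1)
  stats::fisher.test(tab)$p.value
}
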