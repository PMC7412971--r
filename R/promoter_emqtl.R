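#' Map CpG probes to gene promoter windows
#'
#' A probe maps to a gene when its position lies within the closed
#' interval `[TSS - flank, TSS + flank]`, with the TSS taken
#' strand-aware (annotation `start` for `+` genes, `end` for `-`
#' genes).  Probes carrying a SNP flag are removed before mapping.  A
#' probe may map to several genes.  The signed distance to the TSS is
#' reported in gene orientation: negative means upstream of the TSS.
#'
#' @param probes data.frame with columns `probe`, `chrom`, `pos`
#'   (1-based) and `snp_flag` (logical).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based, closed) and `strand` (`"+"` or `"-"`).
#' @param flank promoter half-width in bases (default 3000).
#' @return data.frame with columns `probe`, `gene`, `distance_to_tss`.
#' @export
map_probes_to_promoters <- function(probes, genes, flank = 3000) {
  stopifnot(flank > 0)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in gene annotation")
  }
  probes <- probes[!probes$snp_flag, , drop = FALSE]
  empty <- data.frame(probe = character(), gene = character(),
                      distance_to_tss = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(probes) == 0L || nrow(genes) == 0L) return(empty)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1L, tss - flank), end = tss + flank),
    gene = genes$gene, tss = tss, gstrand = genes$strand)
  pq <- GenomicRanges::GRanges(
    probes$chrom, IRanges::IRanges(start = probes$pos, width = 1L),
    probe = probes$probe)
  ov <- GenomicRanges::findOverlaps(pq, win, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  genomic_delta <- probes$pos[qi] - win$tss[si]
  dist <- ifelse(win$gstrand[si] == "+", genomic_delta, -genomic_delta)
  out <- data.frame(probe = probes$probe[qi], gene = win$gene[si],
                    distance_to_tss = as.integer(dist),
                    stringsAsFactors = FALSE)
  out <- out[order(out$probe, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter CpG-gene correlation (emQTL) testing
#'
#' Computes the Pearson correlation between each mapped probe's beta
#' values and its gene's expression across the shared samples, with
#' two-sided p-values and Benjamini-Hochberg FDR over all tested
#' pairs.  Pairs with `fdr < fdr_cutoff` are flagged as emQTLs.  Pairs
#' where either vector has zero variance are skipped with a warning and
#' are not counted in the FDR family.
#'
#' @param meth beta-value matrix, probes x samples.
#' @param expr expression matrix, genes x samples.
#' @param pairs data.frame from [map_probes_to_promoters()].
#' @param fdr_cutoff emQTL significance threshold (default 0.05).
#' @param samples `"all"` (default) to correlate across every shared
#'   sample, or a character vector of sample ids (e.g. tumors only).
#' @return data.frame with columns `probe`, `gene`, `distance_to_tss`,
#'   `r`, `p`, `fdr`, `sign`, `is_emqtl`.
#' @export
compute_emqtl <- function(meth, expr, pairs, fdr_cutoff = 0.05,
                          samples = "all") {
  shared <- intersect(colnames(meth), colnames(expr))
  if (!identical(samples, "all")) shared <- intersect(shared, samples)
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  pairs <- pairs[pairs$probe %in% rownames(meth) &
                   pairs$gene %in% rownames(expr), , drop = FALSE]
  out <- data.frame(probe = pairs$probe, gene = pairs$gene,
                    distance_to_tss = pairs$distance_to_tss,
                    stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    out$r <- out$p <- out$fdr <- numeric(0)
    out$sign <- character(0)
    out$is_emqtl <- logical(0)
    return(out)
  }
  ct <- pearson_rows(meth[pairs$probe, shared, drop = FALSE],
                     expr[pairs$gene, shared, drop = FALSE])
  if (any(ct$degenerate)) {
    warning(sum(ct$degenerate),
            " pair(s) skipped: zero variance in methylation or expression")
  }
  out$r <- ct$r
  out$p <- ct$p
  out$fdr <- NA_real_
  keep <- !ct$degenerate
  out$fdr[keep] <- stats::p.adjust(ct$p[keep], method = "BH")
  out$sign <- ifelse(is.na(out$r), NA_character_,
                     ifelse(out$r < 0, "negative", "positive"))
  out$is_emqtl <- !is.na(out$fdr) & out$fdr < fdr_cutoff
  out
}

#' Principal component analysis of a methylation matrix
#'
#' Samples are observations and probes variables; the data are
#' probe-centered (no scaling).  Returns the per-component variance
#' fractions (non-increasing, summing to one over all components) and
#' the sample scores for the first `k` components.
#'
#' @param meth beta-value matrix, probes x samples.
#' @param k number of components to return scores for (default 3).
#' @return list with `var_frac` (all components) and `scores`
#'   (samples x k).
#' @export
methylation_pca <- function(meth, k = 3) {
  meth <- as.matrix(meth)
  if (ncol(meth) < 2L) stop("need >= 2 samples")
  if (nrow(meth) < 2L) stop("need >= 2 probes")
  pc <- stats::prcomp(t(meth), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$x))
  list(var_frac = vf, scores = pc$x[, seq_len(k), drop = FALSE])
}
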