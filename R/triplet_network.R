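# TF-CpG and TF-gene correlation gates and triplet assembly.

# Correlate arbitrary (row of x_mat, row of y_mat) candidate pairs with
# BH adjustment over the candidate family; pairs whose first member is
# missing from x_mat are skipped with a warning.
gate_correlations <- function(x_mat, y_mat, candidates, fdr_cutoff,
                              a_col, b_col, missing_label) {
  out <- data.frame(a = character(), b = character(), r = numeric(),
                    p = numeric(), fdr = numeric(), sign = character(),
                    stringsAsFactors = FALSE)
  names(out)[1:2] <- c(a_col, b_col)
  if (nrow(candidates) == 0L) return(out)
  known <- candidates[[1]] %in% rownames(x_mat) &
    candidates[[2]] %in% rownames(y_mat)
  if (any(!known)) {
    warning(sum(!known), " candidate pair(s) skipped: ", missing_label)
    candidates <- candidates[known, , drop = FALSE]
  }
  if (nrow(candidates) == 0L) return(out)
  shared <- intersect(colnames(x_mat), colnames(y_mat))
  stopifnot(length(shared) >= 3L)
  ct <- pearson_rows(x_mat[candidates[[1]], shared, drop = FALSE],
                     y_mat[candidates[[2]], shared, drop = FALSE])
  keep <- !ct$degenerate
  if (any(!keep)) {
    warning(sum(!keep), " candidate pair(s) skipped: zero variance")
  }
  res <- data.frame(a = candidates[[1]][keep], b = candidates[[2]][keep],
                    r = ct$r[keep], p = ct$p[keep],
                    stringsAsFactors = FALSE)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$sign <- ifelse(res$r < 0, "negative", "positive")
  names(res)[1:2] <- c(a_col, b_col)
  res[res$fdr < fdr_cutoff, , drop = FALSE]
}

#' Significant TF-CpG correlations among motif-supported candidates
#'
#' For candidate (TF, probe) pairs — TFs of enriched motifs paired
#' with the emQTL CpGs their motifs cover — computes Pearson r/p
#' between TF expression and CpG methylation over the shared samples,
#' adjusts with Benjamini-Hochberg over the candidate family only, and
#' returns pairs with `fdr < fdr_cutoff`.
#'
#' @param tf_expr expression matrix containing the TF rows.
#' @param meth beta-value matrix, probes x samples.
#' @param candidates data.frame with columns `tf`, `probe`.
#' @param fdr_cutoff significance threshold (default 0.05).
#' @return data.frame with columns `tf`, `probe`, `r`, `p`, `fdr`,
#'   `sign`.
#' @export
tf_cpg_correlations <- function(tf_expr, meth, candidates,
                                fdr_cutoff = 0.05) {
  gate_correlations(tf_expr, meth, candidates[, c("tf", "probe")],
                    fdr_cutoff, "tf", "probe",
                    "TF absent from expression matrix or probe unknown")
}

#' Significant TF-gene correlations among implied candidates
#'
#' Candidates are (TF, gene) pairs implied by surviving TF-CpG pairs
#' (the gene is the CpG's promoter gene).  Self-pairs (TF = gene) are
#' excluded.  BH adjustment runs over this candidate family only.
#'
#' @param tf_expr expression matrix containing the TF rows.
#' @param gene_expr expression matrix containing the gene rows.
#' @param candidates data.frame with columns `tf`, `gene`.
#' @param fdr_cutoff significance threshold (default 0.05).
#' @return data.frame with columns `tf`, `gene`, `r`, `p`, `fdr`,
#'   `sign`.
#' @export
tf_gene_correlations <- function(tf_expr, gene_expr, candidates,
                                 fdr_cutoff = 0.05) {
  candidates <- unique(candidates[, c("tf", "gene")])
  candidates <- candidates[candidates$tf != candidates$gene, ,
                           drop = FALSE]
  gate_correlations(tf_expr, gene_expr, candidates, fdr_cutoff,
                    "tf", "gene",
                    "TF or gene absent from expression matrix")
}

#' Assemble TF-CpG-gene triplets from the three correlation gates
#'
#' A triplet (tf, probe, gene) is emitted iff (probe, gene) is an
#' emQTL, (tf, probe) passed the TF-CpG gate and (tf, gene) passed the
#' TF-gene gate.  Output is deduplicated and ordered lexicographically
#' by (tf, probe, gene).
#'
#' @param emqtls data.frame from [compute_emqtl()] (rows with
#'   `is_emqtl = TRUE` are used).
#' @param tf_cpg data.frame from [tf_cpg_correlations()].
#' @param tf_gene data.frame from [tf_gene_correlations()].
#' @return data.frame with columns `tf`, `probe`, `gene`, the three
#'   correlations (`r_tfcpg`, `r_tfgene`, `r_cpggene`) and their FDRs.
#' @export
assemble_triplets <- function(emqtls, tf_cpg, tf_gene) {
  em <- emqtls[emqtls$is_emqtl, c("probe", "gene", "r", "fdr"),
               drop = FALSE]
  names(em)[3:4] <- c("r_cpggene", "fdr_cpggene")
  tc <- tf_cpg[, c("tf", "probe", "r", "fdr"), drop = FALSE]
  names(tc)[3:4] <- c("r_tfcpg", "fdr_tfcpg")
  tg <- tf_gene[, c("tf", "gene", "r", "fdr"), drop = FALSE]
  names(tg)[3:4] <- c("r_tfgene", "fdr_tfgene")
  out <- merge(merge(tc, em, by = "probe"), tg, by = c("tf", "gene"))
  out <- unique(out[, c("tf", "probe", "gene", "r_tfcpg", "r_tfgene",
                        "r_cpggene", "fdr_tfcpg", "fdr_tfgene",
                        "fdr_cpggene")])
  out <- out[order(out$tf, out$probe, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a triplet set as network edge and node tables
#'
#' @param triplets data.frame from [assemble_triplets()].
#' @return list with `edges` (from, to, from_type, to_type, edge_kind,
#'   r, sign) and `nodes` (node, type, degree).
#' @export
export_network <- function(triplets) {
  if (nrow(triplets) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        from_type = character(), to_type = character(),
                        edge_kind = character(), r = numeric(),
                        sign = character(), stringsAsFactors = FALSE)
    nodes <- data.frame(node = character(), type = character(),
                        degree = integer(), stringsAsFactors = FALSE)
    return(list(edges = edges, nodes = nodes))
  }
  mk <- function(from, to, ft, tt, kind, r) {
    data.frame(from = from, to = to, from_type = ft, to_type = tt,
               edge_kind = kind, r = r,
               sign = ifelse(r < 0, "negative", "positive"),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    mk(triplets$tf, triplets$probe, "tf", "cpg", "tf-cpg",
       triplets$r_tfcpg),
    mk(triplets$tf, triplets$gene, "tf", "gene", "tf-gene",
       triplets$r_tfgene),
    mk(triplets$probe, triplets$gene, "cpg", "gene", "cpg-gene",
       triplets$r_cpggene))
  edges <- unique(edges)
  rownames(edges) <- NULL
  nd <- rbind(data.frame(node = edges$from, type = edges$from_type),
              data.frame(node = edges$to, type = edges$to_type))
  deg <- table(c(edges$from, edges$to))
  nodes <- unique(nd)
  nodes$degree <- as.integer(deg[nodes$node])
  nodes <- nodes[order(nodes$type, nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}

#' Expand motif TF names into candidate TF-probe pairs
#'
#' Maps each enriched motif to its TF name(s) — dimer names joined
#' with `"::"` expand to one candidate per constituent TF — and pairs
#' every TF with every emQTL CpG the motif covers.
#'
#' @param enriched data.frame from [select_enriched()].
#' @param hit_flags logical matrix (CpGs x motifs) of covering-hit
#'   flags restricted to emQTL CpGs.
#' @param pwms named list of [pwm()] objects keyed by motif id.
#' @return data.frame with columns `tf`, `probe`, `motif`.
#' @export
motif_tf_candidates <- function(enriched, hit_flags, pwms) {
  out <- list()
  for (mid in enriched$motif) {
    tfs <- strsplit(pwms[[mid]]$tf, "::", fixed = TRUE)[[1]]
    probes <- rownames(hit_flags)[hit_flags[, mid]]
    if (length(probes) && length(tfs)) {
      out[[mid]] <- expand.grid(tf = tfs, probe = probes,
                                stringsAsFactors = FALSE)
      out[[mid]]$motif <- mid
    }
  }
  if (!length(out)) {
    return(data.frame(tf = character(), probe = character(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
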