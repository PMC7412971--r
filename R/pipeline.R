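# End-to-end orchestration: de -> emqtl -> motifs -> network -> survival.

#' Run the full triplet discovery and prognosis pipeline
#'
#' Executes, in order: expressed-gene filtering and differential
#' expression; promoter mapping and emQTL detection on the
#' dysregulated genes; motif scanning over CpG flanks with
#' odds-ratio enrichment of emQTL CpGs against the non-emQTL promoter
#' CpGs; TF-CpG and TF-gene correlation gating and triplet assembly;
#' and per-triplet survival evaluation.  Stage outputs are written to
#' `out_dir` (when given) as TSVs together with a `manifest.tsv` of
#' thresholds, seed and per-stage record counts, so any downstream
#' stage can be resumed from disk via the `stages` argument.
#'
#' @param input a `triplet_bundle` or a directory written by
#'   [write_bundle()].
#' @param out_dir optional output directory for stage TSVs and the
#'   manifest.
#' @param stages stages to execute; earlier stages not listed are
#'   loaded from `out_dir`.
#' @param min_expressed_fraction expressed-gene prevalence cutoff
#'   (default 0.5).
#' @param de_fdr,de_lfc differential expression thresholds (0.05, 1).
#' @param emqtl_fdr emQTL FDR cutoff (0.05).
#' @param flank_promoter promoter half-width around the TSS (3000).
#' @param flank_motif CpG flank half-width for motif scanning (100).
#' @param motif_p motif scan p-value threshold (1e-4).
#' @param or_lower strict lower bound on the enrichment CI (1.1).
#' @param edge_fdr FDR cutoff for the TF-CpG and TF-gene gates (0.05).
#' @param survival_alpha combined-p significance gate for the report
#'   (0.05).
#' @param seed integer seed for the train/test split.
#' @param emqtl_samples `"all"` (default) or sample ids to restrict
#'   the emQTL correlations (e.g. tumors only).
#' @return list with all stage results and `manifest` (named counts).
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         stages = c("de", "emqtl", "motifs", "network",
                                    "survival"),
                         min_expressed_fraction = 0.5,
                         de_fdr = 0.05, de_lfc = 1, emqtl_fdr = 0.05,
                         flank_promoter = 3000, flank_motif = 100,
                         motif_p = 1e-4, or_lower = 1.1,
                         edge_fdr = 0.05, survival_alpha = 0.05,
                         seed = 1L, emqtl_samples = "all") {
  stopifnot(de_fdr > 0, de_lfc > 0, emqtl_fdr > 0, flank_promoter > 0,
            flank_motif > 0, motif_p > 0, or_lower >= 0, edge_fdr > 0,
            survival_alpha > 0)
  if (is.character(input)) {
    if (!dir.exists(input)) stop("input path does not exist: ", input)
    input <- read_bundle(input)
  }
  stopifnot(inherits(input, "triplet_bundle"))
  b <- input
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_tsv(df, file.path(out_dir, name))
  }
  load_stage <- function(name) {
    if (is.null(out_dir)) {
      stop("stage output '", name, "' needed but no out_dir to resume from")
    }
    path <- file.path(out_dir, name)
    if (!file.exists(path)) stop("input path does not exist: ", path)
    read_tsv(path)
  }
  stage_order <- c("de", "emqtl", "motifs", "network", "survival")
  stopifnot(all(stages %in% stage_order))
  last <- max(match(stages, stage_order))
  wanted <- function(s) match(s, stage_order) <= last
  res <- list()
  counts <- c(n_genes_input = nrow(b$expr), n_samples = ncol(b$expr))

  expr_f <- filter_expressed(b$expr, min_expressed_fraction)
  counts["n_genes_expressed"] <- nrow(expr_f)

  # ---- differential expression ------------------------------------
  if ("de" %in% stages) {
    res$de <- differential_expression(expr_f, b$groups, de_fdr, de_lfc)
    emit(res$de, "de.tsv")
  } else {
    res$de <- load_stage("de.tsv")
  }
  de_genes <- res$de$gene[res$de$direction != "ns"]
  counts["n_de_genes"] <- length(de_genes)
  counts["n_de_up"] <- sum(res$de$direction == "up")
  counts["n_de_down"] <- sum(res$de$direction == "down")

  # ---- promoter emQTLs on the dysregulated genes -------------------
  if (wanted("emqtl")) {
  if ("emqtl" %in% stages) {
    gsub_ann <- b$genes[b$genes$gene %in% de_genes, , drop = FALSE]
    pairs <- map_probes_to_promoters(b$probes, gsub_ann, flank_promoter)
    res$emqtl <- compute_emqtl(b$meth, expr_f, pairs, emqtl_fdr,
                               samples = emqtl_samples)
    emit(res$emqtl, "emqtl.tsv")
  } else {
    res$emqtl <- load_stage("emqtl.tsv")
    res$emqtl$is_emqtl <- as.logical(res$emqtl$is_emqtl)
  }
  counts["n_pairs_tested"] <- sum(!is.na(res$emqtl$fdr))
  counts["n_emqtl"] <- sum(res$emqtl$is_emqtl, na.rm = TRUE)
  em_probes <- unique(res$emqtl$probe[res$emqtl$is_emqtl])
  bg_probes <- setdiff(unique(res$emqtl$probe), em_probes)
  counts["n_fg_cpgs"] <- length(em_probes)
  counts["n_bg_cpgs"] <- length(bg_probes)
  }

  # ---- motif enrichment over CpG flanks ----------------------------
  if (wanted("motifs")) {
  if ("motifs" %in% stages) {
    all_probes <- c(em_probes, bg_probes)
    pr <- b$probes[match(all_probes, b$probes$probe), , drop = FALSE]
    windows <- extract_flanks(b$genome, pr, flank_motif)
    flags <- motif_hit_flags(windows, b$pwms, motif_p)
    res$enrichment <- motif_odds_ratio(
      flags[em_probes, , drop = FALSE],
      flags[bg_probes, , drop = FALSE])
    res$enriched <- select_enriched(res$enrichment, or_lower)
    res$candidates <- motif_tf_candidates(
      res$enriched, flags[em_probes, , drop = FALSE], b$pwms)
    res$enrichment$selected <- res$enrichment$motif %in%
      res$enriched$motif
    emit(res$enrichment, "enrichment.tsv")
    emit(res$candidates, "candidates.tsv")
  } else {
    res$enrichment <- load_stage("enrichment.tsv")
    res$enriched <- res$enrichment[res$enrichment$selected, ,
                                   drop = FALSE]
    res$candidates <- load_stage("candidates.tsv")
  }
  counts["n_motifs"] <- nrow(res$enrichment)
  counts["n_enriched_motifs"] <- nrow(res$enriched)
  counts["n_candidate_pairs"] <- nrow(res$candidates)
  }

  # ---- correlation gates and triplet assembly ----------------------
  if (wanted("network")) {
  if ("network" %in% stages) {
    n_tf_dropped <- length(setdiff(unique(res$candidates$tf),
                                   rownames(expr_f)))
    if (n_tf_dropped > 0) {
      message(n_tf_dropped,
              " TF(s) failed the expressed-gene filter and were dropped")
    }
    res$tf_cpg <- tf_cpg_correlations(expr_f, b$meth, res$candidates,
                                      edge_fdr)
    implied <- merge(res$tf_cpg[, c("tf", "probe")],
                     res$emqtl[res$emqtl$is_emqtl,
                               c("probe", "gene"), drop = FALSE],
                     by = "probe")
    res$tf_gene <- tf_gene_correlations(expr_f, expr_f,
                                        implied[, c("tf", "gene"),
                                                drop = FALSE],
                                        edge_fdr)
    res$triplets <- assemble_triplets(res$emqtl, res$tf_cpg,
                                      res$tf_gene)
    net <- export_network(res$triplets)
    res$network <- net
    emit(res$tf_cpg, "tf_cpg.tsv")
    emit(res$tf_gene, "tf_gene.tsv")
    emit(res$triplets, "triplets.tsv")
    emit(net$edges, "network_edges.tsv")
    emit(net$nodes, "network_nodes.tsv")
  } else {
    res$tf_cpg <- load_stage("tf_cpg.tsv")
    res$tf_gene <- load_stage("tf_gene.tsv")
    res$triplets <- load_stage("triplets.tsv")
    res$network <- list(edges = load_stage("network_edges.tsv"),
                        nodes = load_stage("network_nodes.tsv"))
  }
  counts["n_tf_cpg"] <- nrow(res$tf_cpg)
  counts["n_tf_gene"] <- nrow(res$tf_gene)
  counts["n_triplets"] <- nrow(res$triplets)
  }

  # ---- per-triplet survival evaluation -----------------------------
  if (wanted("survival")) {
  if ("survival" %in% stages) {
    if (nrow(res$triplets) > 0) {
      rows <- lapply(seq_len(nrow(res$triplets)), function(i) {
        evaluate_triplet(res$triplets[i, ], b$expr, b$meth,
                         b$clinical, seed)
      })
      res$survival <- do.call(rbind, rows)
      res$survival$significant <- res$survival$converged &
        res$survival$p_combined < survival_alpha
    } else {
      res$survival <- data.frame()
    }
    emit(res$survival, "survival_report.tsv")
  } else {
    res$survival <- load_stage("survival_report.tsv")
  }
  counts["n_survival_significant"] <-
    if (nrow(res$survival)) sum(res$survival$significant) else 0L
  }

  thresholds <- c(min_expressed_fraction = min_expressed_fraction,
                  de_fdr = de_fdr, de_lfc = de_lfc,
                  emqtl_fdr = emqtl_fdr,
                  flank_promoter = flank_promoter,
                  flank_motif = flank_motif, motif_p = motif_p,
                  or_lower = or_lower, edge_fdr = edge_fdr,
                  survival_alpha = survival_alpha, seed = seed)
  res$manifest <- c(counts, thresholds)
  if (!is.null(out_dir)) {
    write_tsv(data.frame(key = names(res$manifest),
                         value = unname(res$manifest)),
              file.path(out_dir, "manifest.tsv"))
  }
  res
}

#' Compare recovered triplets with a bundle's ground truth
#'
#' @param triplets data.frame from [assemble_triplets()].
#' @param truth ground-truth ledger of a `triplet_bundle`.
#' @return list with `recall`, `precision`, `n_planted`,
#'   `n_recovered`.
#' @export
triplet_recovery <- function(triplets, truth) {
  planted <- truth[truth$kind == "triplet", , drop = FALSE]
  key <- function(tf, probe, gene) paste(tf, probe, gene, sep = "|")
  pk <- key(planted$id1, planted$id2, planted$id3)
  rk <- if (nrow(triplets)) key(triplets$tf, triplets$probe,
                                triplets$gene) else character(0)
  tp <- length(intersect(pk, rk))
  list(recall = if (length(pk)) tp / length(pk) else NA_real_,
       precision = if (length(rk)) tp / length(rk) else NA_real_,
       n_planted = length(pk), n_recovered = length(rk))
}
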