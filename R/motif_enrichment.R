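#' Odds-ratio enrichment of motif hits in foreground vs background CpGs
#'
#' For each motif, builds the 2x2 table of CpGs with/without a covering
#' hit in the foreground (emQTL CpGs) versus the background set and
#' computes the odds ratio `(a*d)/(b*c)` with its 95% Wald confidence
#' interval on the log scale.  When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied before
#' both the estimate and the interval.
#'
#' @param fg_flags,bg_flags logical matrices (CpGs x motifs) of
#'   covering-hit flags, e.g. from [motif_hit_flags()]; foreground and
#'   background CpG sets must be disjoint and non-empty.
#' @return data.frame with columns `motif`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `ci_low`, `ci_high`.
#' @export
motif_odds_ratio <- function(fg_flags, bg_flags) {
  fg_flags <- as.matrix(fg_flags)
  bg_flags <- as.matrix(bg_flags)
  if (nrow(fg_flags) == 0L || nrow(bg_flags) == 0L) {
    stop("foreground and background CpG sets must both be non-empty")
  }
  if (length(intersect(rownames(fg_flags), rownames(bg_flags)))) {
    stop("foreground and background CpG sets overlap")
  }
  stopifnot(identical(colnames(fg_flags), colnames(bg_flags)))
  a <- unname(colSums(fg_flags))
  b <- nrow(fg_flags) - a
  c_ <- unname(colSums(bg_flags))
  d <- nrow(bg_flags) - c_
  corr <- a == 0 | b == 0 | c_ == 0 | d == 0
  aa <- a + 0.5 * corr
  bb <- b + 0.5 * corr
  cc <- c_ + 0.5 * corr
  dd <- d + 0.5 * corr
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  data.frame(motif = colnames(fg_flags), a = a, b = b, c = c_, d = d,
             odds_ratio = or,
             ci_low = exp(log(or) - 1.96 * se),
             ci_high = exp(log(or) + 1.96 * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select enriched motifs by the lower confidence bound
#'
#' Keeps motifs whose 95% CI lower bound on the odds ratio is strictly
#' greater than `lower_bound` (default 1.1).
#'
#' @param results data.frame from [motif_odds_ratio()].
#' @param lower_bound strict lower threshold on `ci_low`.
#' @param use one of `"ci_low"` (default) or `"odds_ratio"` to filter
#'   on the point estimate instead.
#' @return the selected subset.
#' @export
select_enriched <- function(results, lower_bound = 1.1,
                            use = c("ci_low", "odds_ratio")) {
  use <- match.arg(use)
  stopifnot(lower_bound >= 0)
  out <- results[results[[use]] > lower_bound, , drop = FALSE]
  rownames(out) <- NULL
  out
}
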