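# PWM construction and log-odds scanning with exact / convolved p-values.

#' Construct a position weight matrix object
#'
#' @param mat numeric L x 4 probability matrix, columns A, C, G, T;
#'   each row must sum to 1 (tolerance 1e-6).
#' @param id motif identifier.
#' @param tf transcription factor name (defaults to `id`).
#' @param bg background base frequencies over A, C, G, T (default
#'   uniform); must sum to 1.
#' @return an object of class `pwm`.
#' @export
pwm <- function(mat, id, tf = id, bg = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4L, nrow(mat) >= 1L,
            all(abs(rowSums(mat) - 1) < 1e-6),
            length(bg) == 4L, abs(sum(bg) - 1) < 1e-6)
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, tf = tf, mat = mat, bg = setNames(bg, colnames(mat))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(TF:", x$tf, ") length", nrow(x$mat), "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (maximum-probability base per position)
#' @param x a [pwm()] object.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$mat)[apply(x$mat, 1, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param x a [pwm()] object.
#' @return a `pwm` scanning the opposite strand.
#' @export
pwm_reverse_complement <- function(x) {
  m <- x$mat[rev(seq_len(nrow(x$mat))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  pwm(m, id = x$id, tf = x$tf, bg = x$bg[c("T", "G", "C", "A")])
}

# Log2-odds matrix with zero probabilities floored at 1e-4
# (pseudo-probability; keeps scores finite).
pwm_log_odds <- function(x) {
  log2(pmax(x$mat, 1e-4) / rep(x$bg, each = nrow(x$mat)))
}

#' Null score distribution of a PWM under its background model
#'
#' The distribution of the log2-odds score of a random L-mer drawn from
#' the background.  For `L <= 10` (or `method = "exact"`) it is
#' computed by exhaustive enumeration of all 4^L words; otherwise by
#' dynamic-programming convolution of per-position score distributions
#' discretized to 1/100-bit bins.
#'
#' @param x a [pwm()] object.
#' @param method `"auto"`, `"exact"` or `"dp"`.
#' @param binwidth bin width in bits for the DP path (default 0.01).
#' @return an object of class `pwm_score_dist` with a `tail_p` lookup
#'   used by [scan_flank()].
#' @export
pwm_score_dist <- function(x, method = c("auto", "exact", "dp"),
                           binwidth = 0.01) {
  method <- match.arg(method)
  L <- nrow(x$mat)
  if (method == "auto") method <- if (L <= 10L) "exact" else "dp"
  lom <- pwm_log_odds(x)
  if (method == "exact") {
    scores <- 0
    probs <- 1
    for (i in seq_len(L)) {
      old <- length(probs)
      scores <- rep(scores, each = 4L) + rep(lom[i, ], times = old)
      probs <- rep(probs, each = 4L) * rep(x$bg, times = old)
    }
    o <- order(scores)
    scores <- scores[o]
    tailp <- rev(cumsum(rev(probs[o])))
    structure(list(kind = "exact", scores = scores, tailp = tailp, lom = lom),
              class = "pwm_score_dist")
  } else {
    imat <- round(lom / binwidth)
    # v[k] = P(integer score sum = off + k - 1), built position by position
    v <- 1
    off <- 0
    for (i in seq_len(L)) {
      mn <- min(imat[i, ])
      mx <- max(imat[i, ])
      nv <- numeric(length(v) + (mx - mn))
      for (b in 1:4) {
        sh <- imat[i, b] - mn
        idx <- seq_along(v) + sh
        nv[idx] <- nv[idx] + v * x$bg[b]
      }
      v <- nv
      off <- off + mn
    }
    tailp <- rev(cumsum(rev(v)))
    structure(list(kind = "dp", int_offset = off, tailp = tailp,
                   imat = imat, binwidth = binwidth, lom = lom),
              class = "pwm_score_dist")
  }
}

# Tail probability P(score >= s) for observed scores.  For the DP path
# the observed integer score (same discretization as the distribution)
# must be supplied so lookup is exact.
score_tail_p <- function(dist, scores, int_scores = NULL) {
  if (dist$kind == "exact") {
    idx <- findInterval(scores - 1e-9, dist$scores) + 1L
    idx <- pmin(idx, length(dist$tailp))
    dist$tailp[idx]
  } else {
    k <- int_scores - dist$int_offset + 1L
    k <- pmax(1L, pmin(k, length(dist$tailp)))
    dist$tailp[k]
  }
}

encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
}

# Sum per-offset of mat[i, code] over motif positions; NA where the
# window touches an unresolvable base (N).
window_sums <- function(mat, codes, L) {
  n_off <- length(codes) - L + 1L
  if (n_off < 1L) return(numeric(0))
  s <- numeric(n_off)
  for (i in seq_len(L)) {
    v <- mat[i, ][codes[i:(i + n_off - 1L)]]
    s <- s + v
  }
  s
}

#' Scan a CpG-flank window with a PWM on both strands
#'
#' Scores every offset on the forward and reverse strand with the
#' log2-odds score against the PWM's background, assigns each score the
#' exact (or DP-convolved, see [pwm_score_dist()]) p-value
#' `P(random L-mer score >= observed)`, and keeps hits with
#' `p < p_threshold`.  Offsets whose window contains an `N` are
#' skipped.  Hit coordinates are 0-based half-open within the window;
#' reverse-strand hits are reported by their forward-strand window.
#'
#' @param sequence character scalar (typically 2*flank+1 bases centered
#'   on the CpG's C).
#' @param x a [pwm()] object.
#' @param p_threshold retain hits with p strictly below this (default
#'   1e-4).
#' @param cpg_offset optional 0-based offset of the CpG within the
#'   window; when given, `covers_cpg` is filled in.
#' @param dist optional precomputed [pwm_score_dist()] (recomputed
#'   otherwise).
#' @return data.frame with columns `motif`, `start`, `end`, `strand`,
#'   `score`, `p`, `covers_cpg`.
#' @export
scan_flank <- function(sequence, x, p_threshold = 1e-4, cpg_offset = NULL,
                       dist = NULL) {
  L <- nrow(x$mat)
  codes <- encode_dna(sequence)
  if (is.null(dist)) dist <- pwm_score_dist(x)
  lom <- dist$lom
  comp <- c(4L, 3L, 2L, 1L)
  lom_rc <- lom[rev(seq_len(L)), comp, drop = FALSE]
  res <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") lom else lom_rc
    s <- window_sums(m, codes, L)
    if (!length(s)) next
    if (dist$kind == "dp") {
      im <- if (strand == "+") dist$imat else
        dist$imat[rev(seq_len(L)), comp, drop = FALSE]
      is_ <- window_sums(im, codes, L)
      p <- score_tail_p(dist, s, as.integer(round(is_)))
    } else {
      p <- score_tail_p(dist, s)
    }
    keep <- which(!is.na(s) & p < p_threshold)
    if (length(keep)) {
      res[[strand]] <- data.frame(
        motif = x$id, start = keep - 1L, end = keep - 1L + L,
        strand = strand, score = s[keep], p = p[keep],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(motif = character(), start = integer(), end = integer(),
               strand = character(), score = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$covers_cpg <- if (is.null(cpg_offset)) rep(NA, nrow(out)) else
    out$start <= cpg_offset & cpg_offset < out$end
  out
}

#' Keep only hits whose span covers the CpG position
#'
#' Coverage uses half-open spans: the CpG offset must satisfy
#' `start <= cpg_offset < end`.
#'
#' @param hits data.frame from [scan_flank()].
#' @param cpg_offset 0-based CpG offset within the window.
#' @return the covering subset with `covers_cpg = TRUE`.
#' @export
filter_covering <- function(hits, cpg_offset) {
  out <- hits[hits$start <= cpg_offset & cpg_offset < hits$end, ,
              drop = FALSE]
  if (nrow(out)) out$covers_cpg <- TRUE
  rownames(out) <- NULL
  out
}

#' Per-CpG covering-hit flags for a motif set
#'
#' Scans every window with every PWM and records, per (CpG, motif),
#' whether at least one hit passing `p_threshold` on either strand
#' covers the CpG.
#'
#' @param windows named character vector of flank windows (names are
#'   probe ids), each centered on the CpG's C.
#' @param pwms list of [pwm()] objects.
#' @param p_threshold scan p-value threshold (default 1e-4).
#' @param cpg_offset 0-based CpG offset within each window (default
#'   `(nchar - 1) / 2`, the center).
#' @return logical matrix, probes x motifs.
#' @export
motif_hit_flags <- function(windows, pwms, p_threshold = 1e-4,
                            cpg_offset = NULL) {
  ids <- vapply(pwms, function(m) m$id, "")
  flags <- matrix(FALSE, nrow = length(windows), ncol = length(pwms),
                  dimnames = list(names(windows), ids))
  for (j in seq_along(pwms)) {
    dist <- pwm_score_dist(pwms[[j]])
    for (i in seq_along(windows)) {
      off <- if (is.null(cpg_offset)) (nchar(windows[[i]]) - 1L) %/% 2L
             else cpg_offset
      h <- scan_flank(windows[[i]], pwms[[j]], p_threshold,
                      cpg_offset = off, dist = dist)
      flags[i, j] <- any(h$covers_cpg)
    }
  }
  flags
}
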