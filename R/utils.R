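# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", ...)
}

# Matrix I/O: first column "id" holds row names, remaining columns are samples.
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Pearson correlation with p-values for paired rows of two matrices
#'
#' Row `i` of `a` is correlated with row `i` of `b` across the shared
#' columns (samples).  The p-value is the usual two-sided t-transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Rows with zero variance on either side are flagged `degenerate` and
#' get `NA` statistics; callers drop them from their FDR family.
#'
#' This single routine backs every correlation gate (CpG-gene, TF-CpG,
#' TF-gene) so all pair kinds share one implementation contract.
#'
#' @param a,b numeric matrices with identical dimensions; columns are
#'   samples.
#' @return data.frame with columns `r`, `p`, `n`, `degenerate`.
#' @export
pearson_rows <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)), ncol(a) >= 3L)
  n <- ncol(a)
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  sa <- sqrt(rowSums(ac^2))
  sb <- sqrt(rowSums(bc^2))
  degenerate <- sa == 0 | sb == 0
  r <- rowSums(ac * bc) / (sa * sb)
  r <- pmin(1, pmax(-1, r))
  df <- n - 2
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(tt)] <- 0 # |r| == 1 exactly
  r[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  data.frame(r = r, p = p, n = n, degenerate = degenerate)
}

# Stop with a classed configuration error (used by generator/pipeline).
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("emtriplet_config_error", "error")))
}
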