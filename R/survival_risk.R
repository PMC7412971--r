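# Cox partial-likelihood fitting, Fisher's combined p, risk scoring,
# median stratification and Kaplan-Meier / log-rank evaluation.

cox_derivs <- function(beta, x, time, status) {
  p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (tt in sort(unique(time[status == 1]))) {
    R <- which(time >= tt)
    D <- which(time == tt & status == 1)
    d <- length(D)
    xR <- x[R, , drop = FALSE]
    xD <- x[D, , drop = FALSE]
    S0R <- sum(w[R])
    S1R <- colSums(w[R] * xR)
    S2R <- crossprod(xR, w[R] * xR)
    S0D <- sum(w[D])
    S1D <- colSums(w[D] * xD)
    S2D <- crossprod(xD, w[D] * xD)
    ll <- ll + sum(eta[D])
    grad <- grad + colSums(xD)
    for (l in seq_len(d) - 1L) {
      f <- l / d
      Z <- S0R - f * S0D
      M1 <- (S1R - f * S1D) / Z
      M2 <- (S2R - f * S2D) / Z
      ll <- ll - log(Z)
      grad <- grad - M1
      info <- info + (M2 - tcrossprod(M1))
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Fit a multivariate Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron approximation
#' for tied event times by Newton-Raphson with step halving.
#' Convergence is declared when the gradient infinity-norm drops below
#' `tol` (default 1e-6) within `max_iter` iterations.  Monotone
#' likelihood (perfect separation) is flagged as non-converged with
#' coefficients capped at +/-15.  Per-coefficient p-values are Wald.
#'
#' @param x covariate matrix, samples x p (for a triplet: TF
#'   expression, CpG beta, gene expression).
#' @param time non-negative follow-up times.
#' @param status event indicators (1 = event, 0 = censored).
#' @param tol,max_iter Newton-Raphson controls.
#' @return object of class `cox_fit`: `coef`, `se`, `p`, `loglik`,
#'   `converged`, `iter`, `grad_norm`.
#' @export
fit_cox <- function(x, time, status, tol = 1e-6, max_iter = 50L) {
  x <- as.matrix(x)
  stopifnot(length(time) == nrow(x), length(status) == nrow(x),
            all(status %in% c(0, 1)), all(time >= 0), all(is.finite(x)))
  if (sum(status) == 0) stop("no events: cannot fit a Cox model")
  if (any(apply(x, 2, function(v) length(unique(v))) == 1L)) {
    stop("all-constant covariate")
  }
  p <- ncol(x)
  beta <- numeric(p)
  dv <- cox_derivs(beta, x, time, status)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(dv$info, dv$grad), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    halvings <- 0L
    dv_new <- cox_derivs(new_beta, x, time, status)
    while ((!is.finite(dv_new$ll) || dv_new$ll < dv$ll) && halvings < 20L) {
      halvings <- halvings + 1L
      new_beta <- beta + step / 2^halvings
      dv_new <- cox_derivs(new_beta, x, time, status)
    }
    beta <- new_beta
    dv <- dv_new
    if (max(abs(dv$grad)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (any(abs(beta) > 15)) {
    beta <- pmin(15, pmax(-15, beta))
    dv <- cox_derivs(beta, x, time, status)
    converged <- FALSE
  }
  vc <- tryCatch(solve(dv$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vc))
  z <- beta / se
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  structure(list(coef = setNames(beta, nm), se = setNames(se, nm),
                 p = setNames(2 * stats::pnorm(-abs(z)), nm),
                 loglik = dv$ll, converged = converged, iter = iter,
                 grad_norm = max(abs(dv$grad))),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit (", if (x$converged) "converged" else "NOT converged",
      ", ", x$iter, " iterations)\n", sep = "")
  print(data.frame(coef = x$coef, se = x$se, p = x$p))
  invisible(x)
}

#' Fisher's combination of independent p-values
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2k` degrees of freedom.  Zero inputs are clamped to the smallest
#' positive double with a warning.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return the combined p-value.
#' @export
fisher_combined <- function(p_values) {
  stopifnot(length(p_values) >= 1L, all(p_values >= 0), all(p_values <= 1))
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  stat <- -2 * sum(log(p_values))
  stats::pchisq(stat, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Random half split into training and testing sets
#'
#' Uniformly random, deterministic given the seed; for odd n the
#' training set receives the extra sample.  The two sets are disjoint
#' and cover the input.
#'
#' @param samples character vector of sample ids.
#' @param seed integer seed.
#' @return list with `train` and `test` (input order preserved).
#' @export
split_train_test <- function(samples, seed) {
  stopifnot(length(samples) >= 2L)
  n_train <- ceiling(length(samples) / 2)
  tr <- with_seed(seed, sample(samples, n_train))
  list(train = samples[samples %in% tr],
       test = samples[!samples %in% tr])
}

#' Linear Cox risk score
#'
#' `risk = alpha * TF + beta * Meth + gamma * Gene` — the inner
#' product of the Cox coefficients with each sample's covariate values.
#'
#' @param coefs numeric coefficient vector (length p).
#' @param values numeric vector (length p) or matrix (samples x p).
#' @return numeric score(s).
#' @export
risk_score <- function(coefs, values) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  stopifnot(ncol(values) == length(coefs), all(is.finite(values)))
  drop(as.matrix(values) %*% coefs)
}

#' Stratify samples into low/high risk by a median cutoff
#'
#' A sample is `high` iff its score strictly exceeds the median of the
#' cutoff source (by default the scores themselves; pass training-set
#' scores to carry a training cutoff to a test set).  Ties at the
#' median go to `low`.
#'
#' @param scores named numeric vector of risk scores.
#' @param cutoff_source scores from which the median cutoff is taken.
#' @return character vector (`"low"`/`"high"`), named like `scores`.
#' @export
stratify_median <- function(scores, cutoff_source = scores) {
  stopifnot(length(scores) >= 2L)
  cut <- stats::median(cutoff_source)
  setNames(ifelse(scores > cut, "high", "low"), names(scores))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimate per group and the two-group log-rank
#' chi-square (1 df).  If no events occurred at all, the statistic is
#' 0 and p = 1 by convention.
#'
#' @param groups two-level label vector (e.g. from
#'   [stratify_median()]).
#' @param time,status survival outcome vectors aligned with `groups`.
#' @return list with `curves` (group, time, n_risk, survival),
#'   `chisq`, `p`.
#' @export
km_logrank <- function(groups, time, status) {
  groups <- as.character(groups)
  stopifnot(length(unique(groups)) == 2L,
            length(time) == length(groups),
            length(status) == length(groups))
  grp <- factor(groups)
  fit <- survival::survfit(survival::Surv(time, status) ~ grp)
  strata_lab <- sub("^grp=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(group = strata_lab, time = fit$time,
                       n_risk = fit$n.risk, survival = fit$surv,
                       stringsAsFactors = FALSE)
  if (sum(status) == 0) {
    return(list(curves = curves, chisq = 0, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  list(curves = curves, chisq = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Evaluate one triplet's prognostic value
#'
#' Orchestrates the full framework for a TF-CpG-gene triplet: fits the
#' multivariate Cox model on a random training half, combines the
#' three Wald p-values with Fisher's method, assigns each sample the
#' linear risk score, stratifies at the median and runs log-rank tests
#' on the training set, the held-out test set and the
#' chemotherapy-only subset.  A full-cohort Cox fit provides the
#' alternative combined p (`p_combined_full`).
#'
#' @param triplet list or one-row data.frame with `tf`, `probe`,
#'   `gene`.
#' @param expr expression matrix (must contain the TF and gene rows).
#' @param meth methylation matrix (must contain the probe row).
#' @param clinical data.frame with columns `sample`, `time`, `status`,
#'   `chemo_only`.
#' @param seed integer seed for the train/test split.
#' @param cutoff one of `"within"` (default; the median is recomputed
#'   inside each evaluated set) or `"training"` (the training median is
#'   carried to every set).
#' @return one-row data.frame with the coefficients, per-element and
#'   combined p-values, and the three log-rank p-values.
#' @export
evaluate_triplet <- function(triplet, expr, meth, clinical, seed,
                             cutoff = c("within", "training")) {
  cutoff <- match.arg(cutoff)
  tf <- triplet$tf
  probe <- triplet$probe
  gene <- triplet$gene
  stopifnot(tf %in% rownames(expr), gene %in% rownames(expr),
            probe %in% rownames(meth))
  samples <- intersect(clinical$sample,
                       intersect(colnames(expr), colnames(meth)))
  stopifnot(length(samples) >= 4L)
  cl <- clinical[match(samples, clinical$sample), , drop = FALSE]
  covar <- cbind(TF = expr[tf, samples], Meth = meth[probe, samples],
                 Gene = expr[gene, samples])
  rownames(covar) <- samples
  sp <- split_train_test(samples, seed)

  fit_tr <- fit_cox(covar[sp$train, , drop = FALSE],
                    cl$time[match(sp$train, samples)],
                    cl$status[match(sp$train, samples)])
  fit_full <- fit_cox(covar, cl$time, cl$status)

  lr <- function(ids, cutoff_ids) {
    sc <- risk_score(fit_tr$coef, covar[ids, , drop = FALSE])
    src <- if (cutoff == "training") {
      risk_score(fit_tr$coef, covar[cutoff_ids, , drop = FALSE])
    } else {
      sc
    }
    g <- stratify_median(setNames(sc, ids), src)
    if (length(unique(g)) < 2L) return(NA_real_)
    km_logrank(g, cl$time[match(ids, samples)],
               cl$status[match(ids, samples)])$p
  }
  chemo_ids <- samples[cl$chemo_only]
  data.frame(
    tf = tf, probe = probe, gene = gene,
    alpha = fit_tr$coef[["TF"]], beta = fit_tr$coef[["Meth"]],
    gamma = fit_tr$coef[["Gene"]],
    p_tf = fit_tr$p[["TF"]], p_cpg = fit_tr$p[["Meth"]],
    p_gene = fit_tr$p[["Gene"]],
    p_combined = fisher_combined(fit_tr$p),
    p_combined_full = fisher_combined(fit_full$p),
    p_logrank_train = lr(sp$train, sp$train),
    p_logrank_test = lr(sp$test, sp$train),
    p_logrank_chemo = if (length(chemo_ids) >= 4L)
      lr(chemo_ids, sp$train) else NA_real_,
    converged = fit_tr$converged, seed = seed,
    stringsAsFactors = FALSE, row.names = NULL)
}
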