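# Independent brute-force / closed-form oracles used to check the
# package's statistical routines.  These deliberately share no code
# with the implementation.

# Benjamini-Hochberg step-up, written directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(ps[k:m] * m / (k:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric by direct summation of the pmf.
oracle_hyper_tail <- function(overlap, n_de, n_fun, n_uni) {
  ks <- overlap:min(n_de, n_fun)
  sum(choose(n_fun, ks) * choose(n_uni - n_fun, n_de - ks)) /
    choose(n_uni, n_de)
}

# Two-sided Fisher exact p by exhaustive enumeration of all tables
# with the observed margins.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  prob <- function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(xs, prob, 0)
  p_obs <- prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled-variance two-sample t-test from first principles.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Pearson r and two-sided p from the covariance definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Log-odds PWM scanner: every offset, both strands, p-values by full
# enumeration of all 4^L words (probability floor matching the scanner
# contract).  The word table can be precomputed once per PWM.
oracle_scan_pre <- function(pw) {
  lom <- log2(pmax(pw$mat, 1e-4) / rep(pw$bg, each = nrow(pw$mat)))
  L <- nrow(lom)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  all_scores <- numeric(nrow(words))
  all_probs <- rep(1, nrow(words))
  for (i in seq_len(L)) {
    all_scores <- all_scores + lom[i, words[, i]]
    all_probs <- all_probs * pw$bg[words[, i]]
  }
  list(lom = lom, L = L, all_scores = all_scores, all_probs = all_probs)
}

oracle_scan <- function(sequence, pw, p_threshold, pre = NULL) {
  if (is.null(pre)) pre <- oracle_scan_pre(pw)
  lom <- pre$lom
  L <- pre$L
  all_scores <- pre$all_scores
  all_probs <- pre$all_probs
  # score cutoff: the smallest word score whose tail is below threshold
  o <- order(all_scores, decreasing = TRUE)
  tails <- cumsum(all_probs[o])
  pass <- all_scores[o][tails < p_threshold + 1e-15]
  cutoff <- if (length(pass)) min(pass) else Inf
  pval <- function(s) sum(all_probs[all_scores >= s - 1e-9])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(sequence, "")[[1]]
  hits <- NULL
  for (o in seq_len(length(ch) - L + 1)) {
    win <- ch[o:(o + L - 1)]
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rev(unname(comp[win]))
      idx <- match(w, c("A", "C", "G", "T"))
      if (anyNA(idx)) next
      s <- sum(lom[cbind(1:L, idx)])
      if (s < cutoff - 1e-9) next # cannot reach the p threshold
      p <- pval(s)
      if (p < p_threshold) {
        hits <- rbind(hits, data.frame(
          start = o - 1L, end = o - 1L + L, strand = strand,
          score = s, p = p, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(start = integer(), end = integer(),
                       strand = character(), score = numeric(),
                       p = numeric(), stringsAsFactors = FALSE)
  }
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

# Kaplan-Meier product-limit estimate by hand.
oracle_km <- function(time, status) {
  ev <- sort(unique(time[status == 1]))
  s <- 1
  out <- data.frame(time = numeric(), survival = numeric())
  for (t in ev) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# Two-group log-rank chi-square from the O-E table.
oracle_logrank <- function(groups, time, status) {
  g1 <- unique(groups)[1]
  ev <- sort(unique(time[status == 1]))
  O <- E <- V <- 0
  for (t in ev) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & groups == g1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & groups == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# One-covariate Cox partial log-likelihood (continuous times, no
# ties) maximized by golden-section search.
oracle_cox1 <- function(x, time, status) {
  ll <- function(beta) {
    eta <- beta * x
    s <- 0
    for (i in which(status == 1)) {
      s <- s + eta[i] - log(sum(exp(eta[time >= time[i]])))
    }
    s
  }
  optimize(ll, c(-8, 8), maximum = TRUE, tol = 1e-9)$maximum
}

# Random small PWM for scan-equivalence tests.
random_pwm <- function(L, id = "Mx", seed = NULL, sharp = FALSE) {
  gen <- function() {
    m <- matrix(rexp(L * 4), ncol = 4)
    if (sharp) {
      cons <- sample(1:4, L, replace = TRUE)
      m[cbind(1:L, cons)] <- m[cbind(1:L, cons)] + 15
    }
    m <- m / rowSums(m)
    colnames(m) <- c("A", "C", "G", "T")
    pwm(m, id = id)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
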