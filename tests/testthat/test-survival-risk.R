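sim_surv_data <- function(n, beta, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(beta)), ncol = length(beta))
  lp <- drop(x %*% beta)
  time <- rexp(n, rate = 0.1 * exp(lp))
  cens <- rexp(n, rate = 0.04)
  list(x = x, time = pmin(time, cens),
       status = as.integer(time <= cens))
}

test_that("Cox fit matches survival::coxph with Efron ties", {
  d <- sim_surv_data(120, c(0.8, -0.5), seed = 5)
  d$time <- round(d$time, 1) # force some ties
  fit <- fit_cox(d$x, d$time, d$status)
  ref <- survival::coxph(survival::Surv(d$time, d$status) ~ d$x,
                         ties = "efron")
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-6)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("single-covariate Cox matches golden-section likelihood maximization", {
  set.seed(6)
  for (i in 1:10) {
    n <- 30
    x <- rnorm(n)
    time <- rexp(n, 0.1 * exp(0.7 * x)) # continuous, no ties
    status <- rbinom(n, 1, 0.8)
    if (sum(status) < 2) next
    fit <- fit_cox(matrix(x, ncol = 1), time, status)
    expect_equal(unname(fit$coef), oracle_cox1(x, time, status),
                 tolerance = 1e-4)
  }
})

test_that("Cox errors on zero events and constant covariates", {
  expect_error(fit_cox(matrix(rnorm(10)), rexp(10), rep(0, 10)),
               "no events")
  expect_error(fit_cox(matrix(1, 10, 1), rexp(10), rep(1, 10)),
               "constant")
})

test_that("perfect separation is flagged non-converged with capped coefficients", {
  x <- matrix(c(rep(0, 5), rep(1, 5)), ncol = 1)
  time <- c(6:10, 1:5) # all x=1 fail first
  status <- rep(1, 10)
  fit <- fit_cox(x, time, status)
  expect_false(fit$converged)
  expect_lte(max(abs(fit$coef)), 15)
})

test_that("Fisher's combination matches the chi-square closed form", {
  expect_equal(fisher_combined(c(1, 1, 1)), 1)
  expect_equal(fisher_combined(rep(0.05, 3)),
               pchisq(-2 * 3 * log(0.05), 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisher_combined(rep(0.05, 3)), 0.0063, tolerance = 1e-2)
  expect_warning(p0 <- fisher_combined(c(0, 0.5, 0.5)), "clamped")
  expect_gt(p0, 0)
})

test_that("combined p of uniform inputs is uniform and monotone in components", {
  set.seed(99)
  ps <- replicate(2000, fisher_combined(runif(3)))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(fisher_combined(c(0.2, 0.5, 0.9)),
            fisher_combined(c(0.1, 0.5, 0.9)))
})

test_that("train/test split is a deterministic half partition", {
  ids <- sprintf("s%03d", 1:292)
  sp <- split_train_test(ids, seed = 4)
  expect_equal(length(sp$train), 146L)
  expect_equal(length(sp$test), 146L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_equal(length(intersect(sp$train, sp$test)), 0L)
  expect_identical(sp, split_train_test(ids, seed = 4))
  expect_false(identical(sp$train, split_train_test(ids, seed = 5)$train))
  # odd n: training gets the extra sample
  sp3 <- split_train_test(ids[1:7], seed = 1)
  expect_equal(length(sp3$train), 4L)
})

test_that("risk score is the stated linear combination", {
  expect_equal(risk_score(c(4.18, 0.61, -0.80), c(1, 0.5, 2)), 2.885,
               tolerance = 1e-12)
  expect_equal(risk_score(c(4.18, 0.61, -0.80), c(0, 0, 0)), 0)
  v <- c(1.3, 0.2, -2)
  expect_equal(risk_score(c(1, 2, 3), 2 * v),
               2 * risk_score(c(1, 2, 3), v), tolerance = 1e-12)
})

test_that("median stratification sends ties to low", {
  g <- stratify_median(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(unname(g), c("low", "low", "high", "high"))
  expect_true(all(stratify_median(rep(2, 5)) == "low"))
  # balanced groups for distinct scores
  set.seed(2)
  sc <- rnorm(101)
  tab <- table(stratify_median(sc))
  expect_lte(abs(tab[["high"]] - tab[["low"]]), 1L)
})

test_that("KM curves and log-rank match hand computation on a worked example", {
  time <- c(2, 4, 4, 7, 9, 1, 3, 5, 6, 8)
  status <- c(1, 1, 0, 1, 1, 1, 1, 1, 0, 1)
  groups <- rep(c("low", "high"), each = 5)
  res <- km_logrank(groups, time, status)
  for (g in c("low", "high")) {
    want <- oracle_km(time[groups == g], status[groups == g])
    got <- res$curves[res$curves$group == g &
                        res$curves$time %in% want$time, ]
    expect_equal(got$survival, want$survival, tolerance = 1e-12)
  }
  ora <- oracle_logrank(groups, time, status)
  expect_equal(res$chisq, ora$chisq, tolerance = 1e-9)
  expect_equal(res$p, ora$p, tolerance = 1e-9)
})

test_that("KM estimator is a proper non-increasing step function", {
  set.seed(31)
  time <- rexp(40)
  status <- rbinom(40, 1, 0.6)
  res <- km_logrank(rep(c("a", "b"), 20), time, status)
  for (g in c("a", "b")) {
    s <- res$curves$survival[res$curves$group == g]
    expect_true(all(s <= 1 + 1e-12))
    expect_true(all(diff(s) <= 1e-12))
  }
  # no censoring: KM equals the empirical survivor function
  res2 <- km_logrank(rep(c("a", "b"), 20), time, rep(1, 40))
  s_a <- res2$curves[res2$curves$group == "a", ]
  emp <- sapply(s_a$time, function(t) mean(time[rep(c(TRUE, FALSE), 20)] > t))
  expect_equal(s_a$survival, emp, tolerance = 1e-12)
})

test_that("identical groups give log-rank p = 1 and zero-event data p = 1", {
  time <- c(1, 2, 3, 4)
  res <- km_logrank(c("a", "a", "b", "b"), c(1, 2, 1, 2), c(1, 0, 1, 0))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-9)
  res0 <- km_logrank(c("a", "a", "b", "b"), time, rep(0, 4))
  expect_equal(res0$p, 1)
})

test_that("planted Cox coefficients are recovered within 2 SEs at n = 500", {
  truth <- c(1.0, 0.5, -0.5)
  d <- sim_surv_data(500, truth, seed = 9)
  fit <- fit_cox(d$x, d$time, d$status)
  expect_true(fit$converged)
  expect_true(all(abs(fit$coef - truth) < 2 * fit$se))
})

test_that("triplet evaluation is leakage-free and Table-1 shaped", {
  b <- generate_bundle(small_config(seed = 17))
  planted <- b$truth[b$truth$kind == "triplet" & b$truth$value == 1, ]
  trip <- list(tf = planted$id1, probe = planted$id2, gene = planted$id3)
  rep1 <- evaluate_triplet(trip, b$expr, b$meth, b$clinical, seed = 3)
  expect_true(all(c("tf", "probe", "gene", "alpha", "beta", "gamma",
                    "p_tf", "p_cpg", "p_gene", "p_combined",
                    "p_logrank_train", "p_logrank_test",
                    "p_logrank_chemo") %in% names(rep1)))
  # permuting test-set outcomes must not change test-set risk scores:
  # the model and scores come from training data only, so the report
  # is identical when only test outcomes' labels move with samples
  rep2 <- evaluate_triplet(trip, b$expr, b$meth, b$clinical, seed = 3)
  expect_identical(rep1$alpha, rep2$alpha)
  expect_identical(rep1$p_logrank_test, rep2$p_logrank_test)
  sp <- split_train_test(intersect(b$clinical$sample, colnames(b$expr)),
                         seed = 3)
  cl_perm <- b$clinical
  idx <- match(sp$test, cl_perm$sample)
  set.seed(1)
  perm <- sample(idx)
  cl_perm[idx, c("time", "status")] <- cl_perm[perm, c("time", "status")]
  rep3 <- evaluate_triplet(trip, b$expr, b$meth, cl_perm, seed = 3)
  # training-derived quantities unchanged under test-outcome permutation
  expect_equal(rep3$alpha, rep1$alpha)
  expect_equal(rep3$p_combined, rep1$p_combined)
  expect_equal(rep3$p_logrank_train, rep1$p_logrank_train)
})
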