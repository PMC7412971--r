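# Seedable synthetic dataset bundle with planted signal at every
# pipeline stage: DE genes, promoter emQTLs, embedded TF motifs,
# TF-CpG-gene triplets and a survival-informative triplet.

#' Configuration for the synthetic data generator
#'
#' Defaults mirror the study conditions the pipeline targets: 306
#' tumor and 19 normal samples, ~30% of genes differentially
#' expressed at |log2FC| around 2, ~30% of DE-gene promoter CpGs
#' carrying planted methylation-expression coupling of which 90% are
#' negative, and one planted triplet driving survival.
#'
#' @param seed integer; fully determines the bundle.
#' @param n_tumor,n_normal sample counts (defaults 306, 19).
#' @param n_genes number of (non-TF) genes.
#' @param n_probes_per_gene promoter CpG probes per gene.
#' @param frac_de fraction of genes differentially expressed.
#' @param de_lfc_mean mean |log2FC| of DE genes.
#' @param frac_emqtl fraction of DE-gene promoter CpGs with planted
#'   methylation-expression coupling.
#' @param frac_negative fraction of planted emQTLs with negative sign
#'   (default 0.90).
#' @param n_tfs number of transcription factors (extra expression rows
#'   with their own motifs).
#' @param n_planted_triplets number of planted TF-CpG-gene triplets.
#' @param motif_length PWM length in bases (>= 4).
#' @param flank_bp CpG flank half-width scanned for motifs (default
#'   100).
#' @param hazard_coefs length-3 log-hazard effects (TF, Meth, Gene) of
#'   the survival-informative triplet on standardized covariates.
#' @param baseline_hazard exponential baseline event rate.
#' @param censor_rate marginal censoring fraction in [0, 1).
#' @param frac_chemo fraction of tumor samples flagged
#'   chemotherapy-only.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_tumor = 306L, n_normal = 19L,
                       n_genes = 120L, n_probes_per_gene = 3L,
                       frac_de = 0.3, de_lfc_mean = 2,
                       frac_emqtl = 0.3, frac_negative = 0.90,
                       n_tfs = 8L, n_planted_triplets = 4L,
                       motif_length = 8L, flank_bp = 100L,
                       hazard_coefs = c(tf = 1, meth = 1, gene = -1),
                       baseline_hazard = 0.05, censor_rate = 0.3,
                       frac_chemo = 0.5) {
  cfg <- list(seed = as.integer(seed), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal),
              n_genes = as.integer(n_genes),
              n_probes_per_gene = as.integer(n_probes_per_gene),
              frac_de = frac_de, de_lfc_mean = de_lfc_mean,
              frac_emqtl = frac_emqtl, frac_negative = frac_negative,
              n_tfs = as.integer(n_tfs),
              n_planted_triplets = as.integer(n_planted_triplets),
              motif_length = as.integer(motif_length),
              flank_bp = as.integer(flank_bp),
              hazard_coefs = hazard_coefs,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate, frac_chemo = frac_chemo)
  fracs <- c(cfg$frac_de, cfg$frac_emqtl, cfg$frac_negative,
             cfg$censor_rate, cfg$frac_chemo)
  if (any(fracs < 0 | fracs > 1)) {
    config_error("all fractions must lie in [0, 1]")
  }
  if (cfg$n_tumor + cfg$n_normal < 4L) {
    config_error("need n_tumor + n_normal >= 4")
  }
  if (cfg$motif_length < 4L) config_error("motif_length must be >= 4")
  if (cfg$n_genes < 1L || cfg$n_probes_per_gene < 1L || cfg$n_tfs < 1L) {
    config_error("counts must be positive")
  }
  if (cfg$n_planted_triplets > cfg$n_tfs) {
    config_error("n_planted_triplets cannot exceed n_tfs")
  }
  if (length(cfg$hazard_coefs) != 3L) {
    config_error("hazard_coefs must have length 3 (TF, Meth, Gene)")
  }
  if (cfg$baseline_hazard <= 0) {
    config_error("baseline_hazard must be positive")
  }
  structure(cfg, class = "sim_config")
}

#' Embed a PWM's consensus into a sequence over a CpG site
#'
#' Writes the maximum-probability base string of the PWM into
#' `sequence` so that one of the consensus's CG dinucleotides lands
#' exactly on the CpG (C at `cpg_position`, G at `cpg_position + 1`).
#' Among candidate CG offsets the one closest to the motif center is
#' used.  If the consensus contains no CG, the default policy is an
#' error; with `force_cg = TRUE` a CG is substituted at the offset
#' where the PWM's C/G probabilities are jointly highest.
#'
#' @param sequence character scalar (A/C/G/T).
#' @param x a [pwm()] object.
#' @param cpg_position 1-based position of the CpG's C in `sequence`.
#' @param force_cg substitute a CG when the consensus lacks one.
#' @return the modified sequence, with attribute `motif_start` (1-based
#'   start of the embedded consensus).
#' @export
plant_motif_at_cpg <- function(sequence, x, cpg_position,
                               force_cg = FALSE) {
  pl <- motif_cg_placement(x, cpg_position, force_cg)
  if (pl$start < 1L || pl$start + length(pl$cons) - 1L > nchar(sequence)) {
    stop("motif window would overrun sequence bounds")
  }
  substr(sequence, pl$start, pl$start + length(pl$cons) - 1L) <-
    paste(pl$cons, collapse = "")
  attr(sequence, "motif_start") <- pl$start
  sequence
}

# Where must the consensus start so that one of its CG dinucleotides
# covers the CpG?  Shared by the string and base-vector planting paths.
motif_cg_placement <- function(x, cpg_position, force_cg = FALSE) {
  cons <- strsplit(pwm_consensus(x), "")[[1]]
  L <- length(cons)
  cg_at <- which(cons[-L] == "C" & cons[-1] == "G")
  if (!length(cg_at)) {
    if (!force_cg) {
      stop("PWM consensus contains no CG dinucleotide; ",
           "set force_cg = TRUE to substitute one")
    }
    jp <- x$mat[-L, "C"] * x$mat[-1, "G"]
    cg_at <- which.max(jp)
    cons[cg_at] <- "C"
    cons[cg_at + 1L] <- "G"
  }
  j <- cg_at[which.min(abs(cg_at - (L / 2)))]
  list(start = cpg_position - j + 1L, cons = cons)
}

#' Simulate right-censored survival times from a linear predictor
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(lp)` (Weibull shape 1).  Censoring is an
#' independent exponential clock calibrated so that the marginal
#' censored fraction approximates `censor_rate` (exact when all linear
#' predictors are equal); `censor_rate = 0` disables censoring.
#'
#' @param lp named numeric vector of per-sample linear predictors
#'   (names become sample ids).
#' @param baseline_hazard positive baseline event rate.
#' @param censor_rate target censored fraction in [0, 1).
#' @param seed optional integer seed; when `NULL` the current RNG
#'   stream is used.
#' @param frac_chemo fraction of samples flagged chemotherapy-only.
#' @return data.frame with columns `sample`, `time`, `status`
#'   (1 = event), `chemo_only`.
#' @export
simulate_survival <- function(lp, baseline_hazard = 0.05,
                              censor_rate = 0.3, seed = NULL,
                              frac_chemo = 0.5) {
  if (baseline_hazard <= 0) config_error("baseline_hazard must be positive")
  if (censor_rate < 0 || censor_rate >= 1) {
    config_error("censor_rate must lie in [0, 1)")
  }
  stopifnot(all(is.finite(lp)))
  run <- function() {
    n <- length(lp)
    ev <- stats::rexp(n, rate = baseline_hazard * exp(lp))
    cens <- if (censor_rate == 0) rep(Inf, n) else {
      stats::rexp(n, rate = baseline_hazard * exp(mean(lp)) *
                    censor_rate / (1 - censor_rate))
    }
    ids <- names(lp)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
    data.frame(sample = ids, time = pmin(ev, cens),
               status = as.integer(ev <= cens),
               chemo_only = stats::runif(n) < frac_chemo,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a complete synthetic dataset bundle
#'
#' Produces, deterministically from `config$seed`: a synthetic
#' chromosome with a CG dinucleotide at every probe position; gene and
#' probe annotations; a log2-scale expression matrix with planted
#' tumor/normal differences; a beta-value methylation matrix with
#' logit-normal CpG-gene coupling through a per-gene latent factor
#' (negative with probability `frac_negative`); one PWM per TF with
#' consensi embedded at planted triplet CpGs (and at most of the other
#' planted emQTL CpGs, so motif enrichment has a measurable foreground
#' rate); clinical survival driven by the first planted triplet; and a
#' ground-truth ledger of everything planted.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given the bundle is also
#'   written to standard formats via [write_bundle()].
#' @return object of class `triplet_bundle`.
#' @export
generate_bundle <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bundle <- with_seed(config$seed, build_bundle(config))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Internal worker; runs inside the seeded RNG scope.
build_bundle <- function(cfg) {
  n_samples <- cfg$n_tumor + cfg$n_normal
  tumor_ids <- sprintf("T%04d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("N%04d", seq_len(cfg$n_normal))
  samples <- c(tumor_ids, normal_ids)
  groups <- setNames(rep(c("tumor", "normal"),
                         c(cfg$n_tumor, cfg$n_normal)), samples)
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  all_ids <- c(gene_ids, tf_ids)

  # --- annotation: one synthetic chromosome, genes every 7 kb -------
  spacing <- 7000L
  tss <- 7000L + (seq_along(all_ids) - 1L) * spacing
  strand <- sample(c("+", "-"), length(all_ids), replace = TRUE)
  body <- 3000L
  genes <- data.frame(
    gene = all_ids, chrom = "chr1",
    start = ifelse(strand == "+", tss, tss - body + 1L),
    end = ifelse(strand == "+", tss + body - 1L, tss),
    strand = strand, stringsAsFactors = FALSE)
  genome_len <- 7000L + length(all_ids) * spacing + 7000L
  # kept as a base vector until the end; repeated substring assignment
  # on a megabase string is quadratic
  gseq <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

  # --- probes: spaced >= 220 bp apart inside each +/-2.4 kb promoter
  cand_off <- seq(-2400L, 2400L, by = 220L)
  probe_rows <- list()
  k <- 0L
  for (gi in seq_len(cfg$n_genes)) {
    offs <- sort(sample(cand_off, cfg$n_probes_per_gene))
    for (o in offs) {
      k <- k + 1L
      probe_rows[[k]] <- data.frame(
        probe = sprintf("cg%08d", k), chrom = "chr1",
        pos = tss[gi] + o, gene = gene_ids[gi],
        stringsAsFactors = FALSE)
    }
  }
  probes <- do.call(rbind, probe_rows)
  gseq[probes$pos] <- "C"
  gseq[probes$pos + 1L] <- "G"

  # --- differential expression --------------------------------------
  n_de <- round(cfg$frac_de * cfg$n_genes)
  de_genes <- if (n_de > 0) sort(sample(gene_ids, n_de)) else character(0)
  de_sign <- sample(rep(c(1, -1), length.out = n_de))
  de_lfc <- setNames(de_sign * abs(stats::rnorm(n_de, cfg$de_lfc_mean,
                                                0.2)), de_genes)

  mu <- stats::runif(length(all_ids), 3, 8)
  expr <- matrix(stats::rnorm(length(all_ids) * n_samples, mu, 1),
                 nrow = length(all_ids),
                 dimnames = list(all_ids, samples))
  if (n_de > 0) {
    expr[de_genes, tumor_ids] <- expr[de_genes, tumor_ids] + de_lfc
  }

  # --- emQTL planting through per-gene latent factors ---------------
  pool <- if (n_de > 0) probes$probe[probes$gene %in% de_genes] else
    probes$probe
  m_emqtl <- round(cfg$frac_emqtl * length(pool))
  planted_probes <- if (m_emqtl > 0) sort(sample(pool, m_emqtl)) else
    character(0)
  em_sign <- ifelse(stats::rbinom(m_emqtl, 1, cfg$frac_negative) == 1,
                    -1, 1)
  names(em_sign) <- planted_probes
  em_genes <- probes$gene[match(planted_probes, probes$probe)]

  latent <- list() # per gene carrying planted probes
  for (g in unique(em_genes)) {
    u <- stats::rnorm(n_samples)
    latent[[g]] <- u
    expr[g, ] <- expr[g, ] + 1.0 * u
  }

  meth <- matrix(NA_real_, nrow = nrow(probes), ncol = n_samples,
                 dimnames = list(probes$probe, samples))
  base_mu <- stats::runif(nrow(probes), 0.2, 0.8)
  for (i in seq_len(nrow(probes))) {
    pid <- probes$probe[i]
    if (pid %in% planted_probes) {
      g <- probes$gene[i]
      lg <- stats::qlogis(base_mu[i]) +
        em_sign[[pid]] * 1.5 * latent[[g]] +
        stats::rnorm(n_samples, 0, 0.5)
    } else {
      lg <- stats::qlogis(base_mu[i]) + stats::rnorm(n_samples, 0, 0.8)
    }
    meth[i, ] <- stats::plogis(lg)
  }

  # --- SNP flags on a sample of non-planted probes ------------------
  snp_pool <- setdiff(probes$probe, planted_probes)
  n_snp <- round(0.05 * length(snp_pool))
  snp_probes <- if (n_snp > 0) sample(snp_pool, n_snp) else character(0)
  probes$snp_flag <- probes$probe %in% snp_probes

  # --- planted triplets ---------------------------------------------
  trip_gene_pool <- intersect(de_genes, unique(em_genes))
  n_trip <- min(cfg$n_planted_triplets, cfg$n_tfs,
                length(trip_gene_pool))
  triplets <- data.frame(tf = character(), probe = character(),
                         gene = character(), tf_sign = numeric(),
                         stringsAsFactors = FALSE)
  if (n_trip > 0) {
    trip_genes <- sample(trip_gene_pool, n_trip)
    trip_tfs <- sample(tf_ids, n_trip)
    trip_probes <- vapply(trip_genes, function(g) {
      cand <- planted_probes[em_genes == g]
      cand[sample.int(length(cand), 1L)]
    }, "")
    tf_sign <- sample(c(-1, 1), n_trip, replace = TRUE)
    triplets <- data.frame(tf = trip_tfs, probe = unname(trip_probes),
                           gene = trip_genes, tf_sign = tf_sign,
                           stringsAsFactors = FALSE)
    for (i in seq_len(n_trip)) {
      u <- latent[[triplets$gene[i]]]
      expr[triplets$tf[i], ] <- expr[triplets$tf[i], ] +
        triplets$tf_sign[i] * 1.2 * u
    }
  }

  # --- PWMs (one per TF, each consensus containing a CG) ------------
  pwms <- list()
  for (i in seq_len(cfg$n_tfs)) {
    L <- cfg$motif_length
    cons <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    j <- sample.int(L - 1L, 1L)
    cons[j] <- "C"
    cons[j + 1L] <- "G"
    mat <- matrix(0.1 / 3, nrow = L, ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    mat[cbind(seq_len(L), match(cons, colnames(mat)))] <- 0.9
    mid <- sprintf("M%03d", i)
    pwms[[mid]] <- pwm(mat, id = mid, tf = tf_ids[i])
  }
  tf_motif <- setNames(names(pwms), tf_ids)

  # --- motif planting at emQTL CpGs ---------------------------------
  plants <- list()
  if (n_trip > 0) {
    plan <- data.frame(probe = triplets$probe,
                       motif = tf_motif[triplets$tf],
                       stringsAsFactors = FALSE)
    extra_pool <- planted_probes[!em_genes %in% triplets$gene]
    take <- extra_pool[stats::runif(length(extra_pool)) < 0.8]
    if (length(take)) {
      plan <- rbind(plan, data.frame(
        probe = take,
        motif = tf_motif[triplets$tf][sample.int(n_trip, length(take),
                                                 replace = TRUE)],
        stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(plan))) {
      pos <- probes$pos[match(plan$probe[i], probes$probe)]
      pl <- motif_cg_placement(pwms[[plan$motif[i]]], pos)
      stopifnot(pl$start >= 1L,
                pl$start + length(pl$cons) - 1L <= genome_len)
      gseq[pl$start:(pl$start + length(pl$cons) - 1L)] <- pl$cons
      plants[[i]] <- data.frame(
        probe = plan$probe[i], motif = plan$motif[i],
        tf = pwms[[plan$motif[i]]]$tf, motif_start = pl$start,
        stringsAsFactors = FALSE)
    }
  }
  plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(probe = character(), motif = character(),
               tf = character(), motif_start = integer(),
               stringsAsFactors = FALSE)

  genome <- paste(gseq, collapse = "")

  # --- survival driven by the first planted triplet -----------------
  lp <- setNames(rep(0, cfg$n_tumor), tumor_ids)
  surv_triplet <- NA_character_
  if (n_trip > 0 && any(cfg$hazard_coefs != 0)) {
    tr <- triplets[1, ]
    surv_triplet <- paste(tr$tf, tr$probe, tr$gene, sep = "_")
    zs <- function(v) (v - mean(v)) / stats::sd(v)
    lp <- cfg$hazard_coefs[[1]] * zs(expr[tr$tf, tumor_ids]) +
      cfg$hazard_coefs[[2]] * zs(meth[tr$probe, tumor_ids]) +
      cfg$hazard_coefs[[3]] * zs(expr[tr$gene, tumor_ids])
    names(lp) <- tumor_ids
  }
  clinical <- simulate_survival(lp, cfg$baseline_hazard,
                                cfg$censor_rate,
                                frac_chemo = cfg$frac_chemo)

  # --- ground-truth ledger ------------------------------------------
  truth <- rbind(
    if (n_de > 0) data.frame(kind = "de_gene", id1 = de_genes,
                             id2 = "", id3 = "",
                             value = unname(de_lfc),
                             stringsAsFactors = FALSE),
    if (m_emqtl > 0) data.frame(
      kind = "emqtl", id1 = planted_probes, id2 = em_genes,
      id3 = ifelse(em_sign < 0, "negative", "positive"),
      value = unname(em_sign), stringsAsFactors = FALSE),
    if (nrow(plants) > 0) data.frame(
      kind = "motif_plant", id1 = plants$probe, id2 = plants$motif,
      id3 = plants$tf, value = plants$motif_start,
      stringsAsFactors = FALSE),
    if (n_trip > 0) data.frame(
      kind = "triplet", id1 = triplets$tf, id2 = triplets$probe,
      id3 = triplets$gene,
      value = as.numeric(seq_len(n_trip) == 1L &
                           any(cfg$hazard_coefs != 0)),
      stringsAsFactors = FALSE))
  if (is.null(truth)) {
    truth <- data.frame(kind = character(), id1 = character(),
                        id2 = character(), id3 = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  }

  structure(list(config = cfg, genome = c(chr1 = genome), genes = genes,
                 probes = probes[, c("probe", "chrom", "pos",
                                     "snp_flag")],
                 expr = expr, groups = groups, meth = meth, pwms = pwms,
                 clinical = clinical, truth = truth,
                 surv_triplet = surv_triplet),
            class = "triplet_bundle")
}

#' @export
print.triplet_bundle <- function(x, ...) {
  cat("Synthetic triplet bundle (seed ", x$config$seed, ")\n", sep = "")
  cat("  genes:", nrow(x$genes), " probes:", nrow(x$probes),
      " samples:", ncol(x$expr), "\n")
  cat("  planted: ", sum(x$truth$kind == "de_gene"), " DE genes, ",
      sum(x$truth$kind == "emqtl"), " emQTLs, ",
      sum(x$truth$kind == "triplet"), " triplets\n", sep = "")
  invisible(x)
}

#' Extract CpG-centered flank windows from a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param probes data.frame with `probe`, `chrom`, `pos`.
#' @param flank half-width in bases (window length `2*flank + 1`,
#'   centered on the CpG's C).
#' @return named character vector of windows.
#' @export
extract_flanks <- function(genome, probes, flank = 100L) {
  out <- vapply(seq_len(nrow(probes)), function(i) {
    s <- genome[[probes$chrom[i]]]
    substr(s, probes$pos[i] - flank, probes$pos[i] + flank)
  }, "")
  setNames(out, probes$probe)
}
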