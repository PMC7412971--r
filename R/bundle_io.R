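# Reading and writing a synthetic bundle in standard text formats.

#' Write a synthetic bundle to standard formats
#'
#' Writes `genome.fa` (FASTA), `genes.bed` (BED6; score column
#' unused), `probes.tsv`, `expression.tsv`, `methylation.tsv`,
#' `groups.tsv`, `motifs.meme` (MEME minimal v4), `clinical.tsv`,
#' `truth.tsv` (ground-truth ledger) and `config.tsv`.  Output is
#' byte-identical for identical bundles.
#'
#' @param bundle a `triplet_bundle` from [generate_bundle()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(bundle$genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"))
  bed <- data.frame(chrom = bundle$genes$chrom,
                    start = bundle$genes$start - 1L, # BED is 0-based
                    end = bundle$genes$end,
                    name = bundle$genes$gene, score = 0L,
                    strand = bundle$genes$strand)
  utils::write.table(bed, file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(bundle$probes, file.path(dir, "probes.tsv"))
  write_matrix_tsv(bundle$expr, file.path(dir, "expression.tsv"))
  write_matrix_tsv(bundle$meth, file.path(dir, "methylation.tsv"))
  write_tsv(data.frame(sample = names(bundle$groups),
                       group = unname(bundle$groups)),
            file.path(dir, "groups.tsv"))
  write_meme(bundle$pwms, file.path(dir, "motifs.meme"))
  write_tsv(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_tsv(bundle$truth, file.path(dir, "truth.tsv"))
  cfg <- bundle$config
  cfg_df <- data.frame(
    key = names(cfg),
    value = vapply(cfg, function(v) paste(v, collapse = ","), ""))
  write_tsv(cfg_df, file.path(dir, "config.tsv"))
  invisible(dir)
}

#' Read a bundle previously written with [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a `triplet_bundle` (the `config` entry holds the parsed
#'   key/value table rather than a validated `sim_config`).
#' @export
read_bundle <- function(dir) {
  need <- c("genome.fa", "genes.bed", "probes.tsv", "expression.tsv",
            "methylation.tsv", "groups.tsv", "motifs.meme",
            "clinical.tsv", "truth.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("bundle input missing: ", file.path(dir, missing[1]))
  }
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  bed <- utils::read.table(file.path(dir, "genes.bed"), sep = "\t",
                           stringsAsFactors = FALSE)
  genes <- data.frame(gene = bed$V4, chrom = bed$V1,
                      start = bed$V2 + 1L, end = bed$V3,
                      strand = bed$V6, stringsAsFactors = FALSE)
  probes <- read_tsv(file.path(dir, "probes.tsv"))
  probes$snp_flag <- as.logical(probes$snp_flag)
  grp <- read_tsv(file.path(dir, "groups.tsv"))
  clinical <- read_tsv(file.path(dir, "clinical.tsv"))
  clinical$chemo_only <- as.logical(clinical$chemo_only)
  structure(list(
    config = read_tsv(file.path(dir, "config.tsv")),
    genome = genome, genes = genes, probes = probes,
    expr = read_matrix_tsv(file.path(dir, "expression.tsv")),
    groups = setNames(grp$group, grp$sample),
    meth = read_matrix_tsv(file.path(dir, "methylation.tsv")),
    pwms = read_meme(file.path(dir, "motifs.meme")),
    clinical = clinical,
    truth = read_tsv(file.path(dir, "truth.tsv"))),
    class = "triplet_bundle")
}
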