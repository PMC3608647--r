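#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator into a validated
#' object. Defaults describe a desk-scale stand-in for a poly-A RNA-seq
#' experiment on a diploid sample: a 2 x 100 kb annotated reference, 40 bp
#' single-end reads, a per-base substitution error rate of 0.5%, PCR
#' duplicates emitted as multi-copy fragments, and a truth set of planted
#' heterozygous / homozygous-alternate SNVs confined to exons.
#'
#' @param seed integer; master seed. Every generator operation derives its
#'   own stream from this value, so a fixed config reproduces byte-identical
#'   fixtures.
#' @param n_contigs number of reference contigs.
#' @param contig_length length of each contig in bp.
#' @param n_genes number of genes placed across the contigs.
#' @param exons_per_gene integer length-2 vector; inclusive range of exon
#'   counts per gene.
#' @param read_length read length in bp (default 40, single-end).
#' @param n_reads number of cDNA fragments sampled; PCR duplication can emit
#'   more than one aligned copy per fragment.
#' @param error_rate per-base substitution probability in `[0,1]`.
#' @param pcr_duplicate_rate probability that a fragment is emitted as
#'   k >= 2 copies sharing (contig, start, end, strand).
#' @param duplicate_error_mode one of `"exact"` (copies are photocopies,
#'   sharing errors), `"with_errors"` (each copy carries independent
#'   sequencing errors) or `"mixed"`.
#' @param het_fraction fraction of planted variants that are heterozygous.
#' @param variants_per_kb planted-variant density over transcribed bases.
#' @param expression_dispersion gamma shape parameter of per-gene expression
#'   weights (mean 1); small values give the wide dynamic range of real
#'   transcriptomes.
#' @param expression_weights optional explicit per-gene weight vector
#'   (length `n_genes`) overriding the gamma draw; used for controlled
#'   experiments.
#' @param mask_fraction fraction of transcribed bases covered by
#'   accessibility-mask intervals.
#' @param mask_error_rate optional elevated per-base error rate inside mask
#'   intervals (emulating systematic mismatches in non-unique regions);
#'   `NULL` means errors are uniform at `error_rate`.
#' @param off_exon_fraction fraction of RNA fragments drawn uniformly from
#'   the non-exonic genome (intronic/intergenic background present in real
#'   poly-A libraries).
#' @param evidence_depth target per-base depth of the orthogonal DNA
#'   evidence alignments.
#' @param base_quality constant Phred base quality assigned to simulated
#'   bases.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 4, n_reads = 500)
#' ref <- build_reference(cfg)
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       contig_length = 100000L,
                       n_genes = 50L,
                       exons_per_gene = c(1L, 8L),
                       read_length = 40L,
                       n_reads = 50000L,
                       error_rate = 0.005,
                       pcr_duplicate_rate = 0.15,
                       duplicate_error_mode = c("mixed", "exact", "with_errors"),
                       het_fraction = 0.67,
                       variants_per_kb = 2,
                       expression_dispersion = 1,
                       expression_weights = NULL,
                       mask_fraction = 0.15,
                       mask_error_rate = NULL,
                       off_exon_fraction = 0.05,
                       evidence_depth = 20,
                       base_quality = 30L) {
  duplicate_error_mode <- match.arg(duplicate_error_mode)
  cfg <- list(
    seed = as.integer(seed),
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    read_length = as.integer(read_length),
    n_reads = as.integer(n_reads),
    error_rate = error_rate,
    pcr_duplicate_rate = pcr_duplicate_rate,
    duplicate_error_mode = duplicate_error_mode,
    het_fraction = het_fraction,
    variants_per_kb = variants_per_kb,
    expression_dispersion = expression_dispersion,
    expression_weights = expression_weights,
    mask_fraction = mask_fraction,
    mask_error_rate = mask_error_rate,
    off_exon_fraction = off_exon_fraction,
    evidence_depth = evidence_depth,
    base_quality = as.integer(base_quality)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed), abs(cfg$seed) < 2^31 - 16,
    cfg$n_contigs >= 1L, cfg$contig_length >= 1L, cfg$n_genes >= 0L,
    length(cfg$exons_per_gene) == 2L,
    cfg$exons_per_gene[1] >= 1L,
    cfg$exons_per_gene[2] >= cfg$exons_per_gene[1],
    cfg$read_length >= 1L, cfg$n_reads >= 0L
  )
  probs <- c(error_rate = cfg$error_rate,
             pcr_duplicate_rate = cfg$pcr_duplicate_rate,
             het_fraction = cfg$het_fraction,
             mask_fraction = cfg$mask_fraction,
             off_exon_fraction = cfg$off_exon_fraction)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    stop("sim_config probabilities must lie in [0,1]: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$mask_error_rate) &&
      (cfg$mask_error_rate < 0 || cfg$mask_error_rate > 1)) {
    stop("mask_error_rate must lie in [0,1]")
  }
  if (cfg$variants_per_kb < 0 || cfg$variants_per_kb > 1000) {
    stop("variants_per_kb of ", cfg$variants_per_kb,
         " is impossible: at most one SNV can be placed per base ",
         "(1000 per kb)")
  }
  if (!is.null(cfg$expression_weights)) {
    if (length(cfg$expression_weights) != cfg$n_genes ||
        any(cfg$expression_weights < 0) || sum(cfg$expression_weights) <= 0) {
      stop("expression_weights must be ", cfg$n_genes,
           " non-negative values with positive sum")
    }
  }
  if (cfg$expression_dispersion <= 0) stop("expression_dispersion must be > 0")
  if (cfg$evidence_depth < 0) stop("evidence_depth must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(flat[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# fixed per-operation seed offsets; keeps streams independent while the
# whole dataset remains a pure function of cfg$seed
seed_for <- function(cfg, op) {
  offs <- c(reference = 0L, truth = 1L, mask = 2L, rna = 3L, evidence = 4L)
  cfg$seed + offs[[op]]
}
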