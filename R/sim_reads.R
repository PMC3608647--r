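# Read simulation: expression-weighted RNA fragments confined to single
# exons (plus an intronic/intergenic background fraction), with planted
# diploid alleles, per-base substitution errors and PCR duplicates; and
# uniform-depth DNA "evidence" alignments over the whole reference.

empty_reads <- function() {
  data.table(read_id = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             bases = character(), quals = character(), is_dup = logical())
}

# L x n matrix of reference bases for n ungapped reads of length L
seq_matrix <- function(ref, contig, start, L) {
  n <- length(start)
  if (n == 0L) return(matrix(character(0), nrow = L, ncol = 0L))
  seqs <- character(n)
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    seqs[sel] <- substring(ref$contigs[[ctg]], start[sel], start[sel] + L - 1L)
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE), nrow = L)
}

cols_to_strings <- function(mat) {
  if (ncol(mat) == 0L) return(character(0))
  if (nrow(mat) == 1L) return(as.character(mat[1L, ]))
  do.call(paste0, lapply(seq_len(nrow(mat)), function(r) mat[r, ]))
}

# overlay truth alleles on fragment columns; at het sites each
# (fragment, variant) pair draws one of the two haplotypes with prob 1/2,
# at hom_alt sites the alternate allele is always used
apply_truth_alleles <- function(mat, contig, start, L, truth) {
  if (ncol(mat) == 0L || nrow(truth) == 0L) return(mat)
  frags <- data.table(idx = seq_along(start), contig = contig,
                      fstart = start, fend = start + L - 1L)
  tr <- data.table(contig = truth$contig, tstart = truth$pos,
                   tend = truth$pos, alt = truth$alt,
                   zygosity = truth$zygosity)
  data.table::setkey(frags, contig, fstart, fend)
  ov <- data.table::foverlaps(tr, frags,
                              by.x = c("contig", "tstart", "tend"),
                              type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) return(mat)
  row_in_read <- ov$tstart - ov$fstart + 1L
  use_alt <- ov$zygosity == "hom_alt" | runif(nrow(ov)) < 0.5
  if (any(use_alt)) {
    mat[cbind(row_in_read[use_alt], ov$idx[use_alt])] <- ov$alt[use_alt]
  }
  mat
}
utils::globalVariables(c("fstart", "fend", "tstart", "tend", "idx"))

# independent per-base substitution errors; inside mask intervals the rate
# may be elevated (systematic-mismatch emulation)
apply_errors <- function(mat, contig, start, rate, mask = NULL,
                         mask_rate = NULL) {
  Lm <- nrow(mat); m <- ncol(mat)
  if (m == 0L || (rate == 0 && is.null(mask_rate))) return(mat)
  ncell <- Lm * m
  if (!is.null(mask_rate) && !is.null(mask) && nrow(mask) > 0L) {
    cc <- rep(seq_len(m), each = Lm)
    pos <- start[cc] + rep(seq_len(Lm) - 1L, m)
    rates <- rep(rate, ncell)
    rates[positions_in_mask(contig[cc], pos, mask)] <- mask_rate
    err <- runif(ncell) < rates
  } else {
    err <- runif(ncell) < rate
  }
  if (any(err)) mat[err] <- other_base(mat[err])
  mat
}

#' Simulate expression-weighted RNA-seq alignments
#'
#' Samples `cfg$n_reads` cDNA fragments. A fragment lands in a gene with
#' probability proportional to its expression weight, in an exon with
#' probability proportional to the exon's share of valid start positions,
#' and uniformly over those start positions (reads always fit inside one
#' exon, so alignments are ungapped and reported in genome coordinates).
#' A configurable fraction of fragments is instead drawn uniformly from
#' the whole genome (pre-mRNA / intergenic background). Planted alleles
#' are overlaid per fragment, then PCR duplication emits some fragments as
#' k >= 2 coordinate-identical copies, and sequencing errors are applied
#' according to `cfg$duplicate_error_mode`:
#' * `"exact"` - copies are photocopies (shared errors);
#' * `"with_errors"` - every copy carries independent errors;
#' * `"mixed"` - extra copies are a fair coin flip between the two.
#'
#' @param ref a `ref_model`.
#' @param truth truth-variant table from [plant_truth_variants()].
#' @param cfg a [sim_config()].
#' @param mask optional mask interval table; when `cfg$mask_error_rate` is
#'   set, bases inside mask intervals mismatch at that elevated rate.
#' @return alignment `data.table` with columns `read_id`, `contig`,
#'   `start`, `end` (1-based closed), `strand`, `bases`, `quals`,
#'   `is_dup` (all `FALSE`; flagging is the dedup stage's job).
#' @export
simulate_rna_alignments <- function(ref, truth, cfg, mask = NULL) {
  validate_sim_config(cfg)
  n <- cfg$n_reads
  L <- cfg$read_length
  if (n == 0L) return(empty_reads())
  with_seed(seed_for(cfg, "rna"), {
    ex <- ref$genes
    have_genes <- nrow(ex) > 0L
    if (have_genes) {
      if (any(ex$end - ex$start + 1L < L)) {
        stop("every exon must be at least read_length (", L, ") bp")
      }
      gene_ids <- unique(ex$gene_id)
      wg <- if (!is.null(cfg$expression_weights)) cfg$expression_weights else
        rgamma(length(gene_ids), shape = cfg$expression_dispersion,
               rate = cfg$expression_dispersion)
      names(wg) <- gene_ids
      n_pos <- ex$end - ex$start + 1L - L + 1L
      gene_tot <- tapply(n_pos, ex$gene_id, sum)[ex$gene_id]
      exon_w <- wg[ex$gene_id] * n_pos / gene_tot
    }
    off <- runif(n) < cfg$off_exon_fraction
    if (!have_genes) off <- rep(TRUE, n)
    contig <- character(n)
    start <- integer(n)
    n_on <- sum(!off)
    if (n_on > 0L) {
      ei <- sample.int(nrow(ex), n_on, replace = TRUE, prob = exon_w)
      contig[!off] <- ex$contig[ei]
      start[!off] <- ex$start[ei] +
        as.integer(floor(runif(n_on) * n_pos[ei]))
    }
    n_off <- sum(off)
    if (n_off > 0L) {
      clen <- nchar(ref$contigs)
      ci <- sample.int(length(clen), n_off, replace = TRUE, prob = clen)
      contig[off] <- names(ref$contigs)[ci]
      start[off] <- as.integer(floor(runif(n_off) * (clen[ci] - L + 1L))) + 1L
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)

    hap <- seq_matrix(ref, contig, start, L)
    hap <- apply_truth_alleles(hap, contig, start, L, truth)

    dup <- runif(n) < cfg$pcr_duplicate_rate
    extra <- rgeom(n, 0.5)                       # extra copies beyond 2
    k <- ifelse(dup, 2L + extra, 1L)
    idx <- rep(seq_len(n), k)
    copy_num <- sequence(k)

    mode <- cfg$duplicate_error_mode
    if (mode == "exact") {
      errored <- apply_errors(hap, contig, start, cfg$error_rate,
                              mask, cfg$mask_error_rate)
      cmat <- errored[, idx, drop = FALSE]
    } else if (mode == "with_errors") {
      cmat <- apply_errors(hap[, idx, drop = FALSE], contig[idx], start[idx],
                           cfg$error_rate, mask, cfg$mask_error_rate)
    } else {                                     # mixed
      errored <- apply_errors(hap, contig, start, cfg$error_rate,
                              mask, cfg$mask_error_rate)
      cmat <- errored[, idx, drop = FALSE]
      redo <- copy_num > 1L & runif(length(idx)) < 0.5
      if (any(redo)) {
        cmat[, redo] <- apply_errors(hap[, idx[redo], drop = FALSE],
                                     contig[idx[redo]], start[idx[redo]],
                                     cfg$error_rate, mask,
                                     cfg$mask_error_rate)
      }
    }

    data.table(
      read_id = sprintf("f%07d_c%d", idx, copy_num),
      contig = contig[idx],
      start = start[idx],
      end = start[idx] + L - 1L,
      strand = strand[idx],
      bases = cols_to_strings(cmat),
      quals = strrep(int_to_qual_char(cfg$base_quality), L),
      is_dup = FALSE
    )
  })
}

#' Simulate orthogonal DNA evidence alignments
#'
#' Uniform-coverage DNA-style reads over every contig at target depth
#' `cfg$evidence_depth`, standing in for an orthogonal whole-genome
#' alignment of the same individual. Alleles at truth sites are sampled as
#' in [simulate_rna_alignments()] (per-read haplotype draw at het sites);
#' sequencing errors are uniform at `cfg$error_rate`; there is no PCR
#' duplication.
#'
#' @inheritParams simulate_rna_alignments
#' @return alignment `data.table` in the same shape as
#'   [simulate_rna_alignments()].
#' @export
simulate_evidence_alignments <- function(ref, truth, cfg) {
  validate_sim_config(cfg)
  L <- cfg$read_length
  with_seed(seed_for(cfg, "evidence"), {
    clen <- nchar(ref$contigs)
    n_per <- as.integer(round(cfg$evidence_depth * clen / L))
    n <- sum(n_per)
    if (n == 0L) return(empty_reads())
    contig <- rep(names(ref$contigs), n_per)
    nstarts <- clen[contig] - L + 1L
    start <- as.integer(floor(runif(n) * nstarts)) + 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    mat <- seq_matrix(ref, contig, start, L)
    mat <- apply_truth_alleles(mat, contig, start, L, truth)
    mat <- apply_errors(mat, contig, start, cfg$error_rate)
    data.table(
      read_id = sprintf("e%07d", seq_len(n)),
      contig = contig,
      start = start,
      end = start + L - 1L,
      strand = strand,
      bases = cols_to_strings(mat),
      quals = strrep(int_to_qual_char(cfg$base_quality), L),
      is_dup = FALSE
    )
  })
}

#' Simulate a complete evaluation dataset
#'
#' Convenience wrapper running the whole generator: reference, truth
#' variants, accessibility mask, RNA alignments (with mask-elevated errors
#' if configured) and DNA evidence alignments.
#'
#' @param cfg a [sim_config()].
#' @return named list with elements `ref`, `truth`, `mask`, `rna`,
#'   `evidence`, and `config`.
#' @export
simulate_dataset <- function(cfg) {
  ref <- build_reference(cfg)
  mask <- simulate_mask(ref, cfg)
  truth <- plant_truth_variants(ref, cfg, mask = mask)
  rna <- simulate_rna_alignments(ref, truth, cfg, mask = mask)
  evidence <- simulate_evidence_alignments(ref, truth, cfg)
  list(ref = ref, truth = truth, mask = mask, rna = rna,
       evidence = evidence, config = cfg)
}
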