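#' Build a synthetic annotated reference
#'
#' Generates random contig sequences and places non-overlapping gene models
#' on them. Each gene has an exon count drawn uniformly from
#' `cfg$exons_per_gene`, exon lengths of at least one read length (so a
#' read always fits inside a single exon and alignments stay ungapped),
#' and intron/intergenic spacers.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `ref_model`: a list with
#'   * `contigs`: named character vector of contig sequences;
#'   * `genes`: data.table of exon records with columns `gene_id`, `contig`,
#'     `strand`, `exon_rank`, `start`, `end` (1-based closed intervals,
#'     non-overlapping and sorted within each gene).
#' @export
build_reference <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(seed_for(cfg, "reference"), {
    contig_names <- sprintf("chr%d", seq_len(cfg$n_contigs))
    contigs <- setNames(
      vapply(contig_names, function(x) random_dna(cfg$contig_length),
             character(1)),
      contig_names
    )
    exon_rows <- vector("list", cfg$n_genes)
    cursors <- setNames(rep(1L, cfg$n_contigs), contig_names)
    L <- cfg$read_length
    exlen_lo <- max(L, 120L)
    exlen_hi <- max(300L, L + 40L)
    if (cfg$n_genes > 0L) {
      for (g in seq_len(cfg$n_genes)) {
        n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
        ex_len <- sample(exlen_lo:exlen_hi, n_ex, replace = TRUE)
        introns <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE)
                   else integer(0)
        span <- sum(ex_len) + sum(introns)
        gap <- sample(200:2000, 1L)
        # round-robin placement with spillover to any contig with room
        pref <- contig_names[((g - 1L) %% cfg$n_contigs) + 1L]
        order_try <- c(pref, setdiff(contig_names, pref))
        placed <- FALSE
        for (ctg in order_try) {
          at <- cursors[[ctg]] + gap
          if (at + span - 1L <= cfg$contig_length) {
            starts <- at + cumsum(c(0L, head(ex_len, -1L) + introns))
            ends <- starts + ex_len - 1L
            exon_rows[[g]] <- data.table(
              gene_id = sprintf("gene%03d", g),
              contig = ctg,
              strand = sample(c("+", "-"), 1L),
              exon_rank = seq_len(n_ex),
              start = as.integer(starts),
              end = as.integer(ends)
            )
            cursors[[ctg]] <- ends[n_ex] + 1L
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("contig too short to host the requested gene models: ",
               "gene ", g, " of ", cfg$n_genes, " needs ", span,
               " bp but contig_length is ", cfg$contig_length,
               "; increase contig_length or reduce n_genes/exons_per_gene")
        }
      }
    }
    genes <- if (cfg$n_genes > 0L) data.table::rbindlist(exon_rows) else
      data.table(gene_id = character(), contig = character(),
                 strand = character(), exon_rank = integer(),
                 start = integer(), end = integer())
    structure(list(contigs = contigs, genes = genes), class = "ref_model")
  })
}

#' @export
print.ref_model <- function(x, ...) {
  cat(sprintf("<ref_model> %d contig(s), %s bp total; %d gene(s), %d exon(s), %s exonic bp\n",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              length(unique(x$genes$gene_id)), nrow(x$genes),
              format(exonic_bp(x), big.mark = ",")))
  invisible(x)
}

# total transcribed (exonic) bases; genes never overlap by construction
exonic_bp <- function(ref) {
  if (nrow(ref$genes) == 0L) return(0L)
  sum(ref$genes$end - ref$genes$start + 1L)
}

# reference base(s) at 1-based positions
ref_base_at <- function(ref, contig, pos) {
  out <- character(length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    seqc <- ref$contigs[[ctg]]
    if (is.null(seqc)) stop("unknown contig in reference: ", ctg)
    out[sel] <- substring(seqc, pos[sel], pos[sel])
  }
  out
}

#' Plant diploid truth variants in exons
#'
#' Places biallelic SNVs independently at each transcribed base with
#' probability `variants_per_kb / 1000`; each variant is heterozygous with
#' probability `het_fraction`, otherwise homozygous-alternate. The
#' alternate allele is drawn uniformly from the three non-reference bases.
#'
#' @param ref a `ref_model`.
#' @param cfg a [sim_config()].
#' @param mask optional accessibility-mask intervals; no variant is planted
#'   inside them. The truth set stands in for calls made by a reference
#'   project that attempted no calls in masked regions, so the two are
#'   disjoint by construction.
#' @return a `data.table` truth set with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`, `zygosity` (`"het"` or `"hom_alt"`), sorted by position;
#'   no two variants share a site.
#' @export
plant_truth_variants <- function(ref, cfg, mask = NULL) {
  validate_sim_config(cfg)
  p <- cfg$variants_per_kb / 1000
  empty <- data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      zygosity = character())
  if (nrow(ref$genes) == 0L || p == 0) return(empty)
  with_seed(seed_for(cfg, "truth"), {
    ex <- ref$genes
    sites <- ex[, .(pos = seq.int(start, end)), by = .(contig, rn = seq_len(nrow(ex)))]
    sites[, rn := NULL]
    sites <- unique(sites)
    keep <- runif(nrow(sites)) < p
    sites <- sites[keep]
    if (!is.null(mask) && nrow(sites) > 0L) {
      sites <- sites[!positions_in_mask(sites$contig, sites$pos,
                                        as.data.table(mask))]
    }
    if (nrow(sites) == 0L) return(empty)
    sites[, ref := ref_base_at(ref, contig, pos)]
    sites[, alt := other_base(ref)]
    sites[, zygosity := ifelse(runif(.N) < cfg$het_fraction, "het", "hom_alt")]
    setorder(sites, contig, pos)
    sites[]
  })
}
utils::globalVariables("rn")

#' Simulate an accessibility mask
#'
#' Draws random sub-intervals of exons until roughly `mask_fraction` of the
#' transcribed bases are covered, emulating the inaccessible-genome regions
#' (repeats, segmental duplications) where reliable variant calling is not
#' attempted.
#'
#' @param ref a `ref_model`.
#' @param cfg a [sim_config()].
#' @return a `data.table` of merged mask intervals with columns `contig`,
#'   `start` (0-based inclusive), `end` (0-based exclusive).
#' @export
simulate_mask <- function(ref, cfg) {
  validate_sim_config(cfg)
  empty <- data.table(contig = character(), start = integer(), end = integer())
  target <- round(cfg$mask_fraction * exonic_bp(ref))
  if (target <= 0 || nrow(ref$genes) == 0L) return(empty)
  with_seed(seed_for(cfg, "mask"), {
    ex <- ref$genes
    ex_len <- ex$end - ex$start + 1L
    acc <- empty
    covered <- 0
    iter <- 0L
    while (covered < target && iter < 10000L) {
      iter <- iter + 1L
      i <- sample.int(nrow(ex), 1L, prob = ex_len)
      len <- sample(50:200, 1L)
      s1 <- ex$start[i] + sample.int(max(ex_len[i], 1L), 1L) - 1L  # 1-based
      e1 <- min(s1 + len - 1L, ex$end[i])
      acc <- rbind(acc, data.table(contig = ex$contig[i],
                                   start = s1 - 1L, end = e1))
      acc <- merge_intervals(acc)
      covered <- interval_bp(acc)
    }
    setorder(acc, contig, start)
    acc[]
  })
}
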