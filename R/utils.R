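#' @importFrom data.table data.table as.data.table setorder setnames := .N .SD .I
#' @importFrom stats rbinom rgamma rgeom runif setNames
#' @importFrom utils head tail
NULL

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "A", "C", "G", "T", "alt", "alt_count", "alt_fraction", "base",
  "bases", "contig", "depth", "end", "exon_rank", "gene_id", "genotype",
  "is_dup", "key_", "label", "pos", "q", "quals", "read_id", "ref",
  "rescue", "start", "strand", "zygosity", "filter", "depth_bin", "fn",
  "fp", "tp", "tp_truth", "i.alt", "i.ref", "i.zygosity", "i.genotype",
  "n_pos", "w", "off", "evidence_depth", "evidence_alt_fraction",
  "sensitivity", "specificity", "bin_lo", "bin_hi", "i.depth", "x.start",
  "i.pos", "alleles", "at_truth", "strategy", "gstart", "gend"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a fixed, restored random seed
#'
#' Sets the RNG to a fixed generator/seed, runs `code`, and restores the
#' caller's RNG state, so simulation functions are deterministic without
#' clobbering the session RNG.
#'
#' @param seed integer seed (kept below 2^31).
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Phred+33 helpers
qual_to_int <- function(qual_string) utf8ToInt(qual_string) - 33L

int_to_qual_char <- function(q) intToUtf8(q + 33L)

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute each base by one of the three other bases, uniformly
other_base <- function(base, shift = NULL) {
  idx <- match(base, DNA_BASES)
  if (is.null(shift)) shift <- sample.int(3L, length(base), replace = TRUE)
  DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
}

# merge 0-based half-open intervals; expects a data.frame(contig,start,end)
merge_intervals <- function(x) {
  x <- as.data.table(x)
  if (nrow(x) == 0L) return(data.table(contig = character(),
                                       start = integer(), end = integer()))
  x <- data.table::copy(x)
  setorder(x, contig, start, end)
  x[, grp := {
    n <- .N
    if (n == 1L) 1L else {
      hi <- cummax(end)
      cumsum(c(1L, as.integer(start[-1L] > hi[-n])))
    }
  }, by = "contig"]
  out <- x[, .(start = min(start), end = max(end)), by = .(contig, grp)]
  out[, grp := NULL]
  out[]
}
utils::globalVariables(c("grp", "hi"))

# total bases covered by a (possibly overlapping) 0-based interval set
interval_bp <- function(x) {
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start))
}

# is each 1-based position inside some 0-based half-open interval?
# mask must be merged (non-overlapping, sorted) per contig
positions_in_mask <- function(contig, pos, mask) {
  if (nrow(mask) == 0L) return(rep(FALSE, length(pos)))
  mask <- merge_intervals(mask)
  out <- rep(FALSE, length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    m <- mask[mask$contig == ctg]
    if (nrow(m) == 0L) next
    p0 <- pos[sel] - 1L                     # 0-based position
    i <- findInterval(p0, m$start)
    out[sel] <- i >= 1L & p0 < m$end[pmax(i, 1L)]
  }
  out
}
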