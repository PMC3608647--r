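# Minimal threshold pileup genotype caller. Intentionally simple: depth
# gate, minimum alt-read support and an alt-allele-fraction band decide the
# genotype. It stands in for production callers so the surrounding pipeline
# (dedup -> call -> filter -> evaluate) is exactly testable; externally
# produced VCF call sets can be substituted at the pipeline boundary.

#' Caller parameters
#'
#' @param min_depth minimum post-dedup, post-quality depth at which a call
#'   is attempted (default 3, the expected-call coverage floor).
#' @param min_base_quality Phred threshold; bases below it are excluded
#'   from pileup counts.
#' @param het_band numeric length-2: inclusive alt-fraction interval called
#'   heterozygous.
#' @param hom_threshold alt fraction strictly above which a
#'   homozygous-alternate genotype is called; must be >= `het_band[2]`.
#' @param min_alt_reads minimum number of reads carrying the alternate
#'   allele.
#' @return a `caller_params` object.
#' @export
caller_params <- function(min_depth = 3L, min_base_quality = 0L,
                          het_band = c(0.2, 0.8), hom_threshold = 0.8,
                          min_alt_reads = 2L) {
  stopifnot(length(het_band) == 2L,
            het_band[1] > 0, het_band[1] < het_band[2], het_band[2] < 1,
            hom_threshold >= het_band[2],
            min_depth >= 1, min_alt_reads >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_base_quality = as.integer(min_base_quality),
                 het_band = as.numeric(het_band),
                 hom_threshold = as.numeric(hom_threshold),
                 min_alt_reads = as.integer(min_alt_reads)),
            class = "caller_params")
}

empty_pileup <- function() {
  data.table(contig = character(), pos = integer(), ref = character(),
             A = integer(), C = integer(), G = integer(), T = integer(),
             depth = integer())
}

#' Build a pileup from ungapped alignments
#'
#' Expands unflagged alignments to per-base counts. Bases with quality
#' below `min_base_quality` are excluded; columns with zero resulting depth
#' are omitted.
#'
#' @param alignments alignment table; rows with `is_dup == TRUE` are
#'   ignored.
#' @param ref a `ref_model`; all alignment contigs must exist in it.
#' @param min_base_quality Phred threshold for inclusion of a base.
#' @return `data.table` with one row per covered position: `contig`, `pos`,
#'   `ref`, counts `A`,`C`,`G`,`T`, and `depth` (= sum of the four counts).
#' @export
build_pileup <- function(alignments, ref, min_base_quality = 0L) {
  al <- drop_duplicates(alignments)
  if (nrow(al) == 0L) return(empty_pileup())
  unknown <- setdiff(unique(al$contig), names(ref$contigs))
  if (length(unknown)) {
    stop("alignments reference contig(s) absent from the reference: ",
         paste(unknown, collapse = ", "))
  }
  w <- al$end - al$start + 1L
  stopifnot(all(w == nchar(al$bases)))
  ridx <- rep(seq_len(nrow(al)), w)
  cells <- data.table(
    contig = al$contig[ridx],
    pos = al$start[ridx] + (sequence(w) - 1L),
    base = unlist(strsplit(al$bases, "", fixed = TRUE), use.names = FALSE),
    q = unlist(lapply(al$quals, qual_to_int), use.names = FALSE)
  )
  cells <- cells[q >= min_base_quality & base %in% DNA_BASES]
  if (nrow(cells) == 0L) return(empty_pileup())
  counts <- cells[, .N, by = .(contig, pos, base)]
  pile <- data.table::dcast(counts, contig + pos ~ base, value.var = "N",
                            fill = 0L)
  for (b in DNA_BASES) if (!b %in% names(pile)) pile[, (b) := 0L]
  pile[, depth := A + C + G + T]
  pile[, ref := ref_base_at(ref, contig, pos)]
  setorder(pile, contig, pos)
  pile[, .(contig, pos, ref, A, C, G, T, depth)]
}

# vectorized genotype decision over pileup rows
decide_calls <- function(pile, params) {
  empty <- data.table(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), depth = integer(),
                      alt_fraction = numeric(), filter = character())
  if (nrow(pile) == 0L) return(empty)
  m <- as.matrix(pile[, .(A, C, G, T)])
  ref_idx <- match(pile$ref, DNA_BASES)
  m2 <- m
  m2[cbind(seq_len(nrow(m2)), ref_idx)] <- -1L          # never pick ref
  alt_idx <- max.col(m2, ties.method = "first")          # alphabetical ties
  alt_count <- m[cbind(seq_len(nrow(m)), alt_idx)]
  frac <- alt_count / pile$depth
  genotype <- rep(NA_character_, nrow(pile))
  genotype[frac >= params$het_band[1] & frac <= params$het_band[2]] <- "het"
  genotype[frac > params$hom_threshold] <- "hom_alt"
  ok <- pile$depth >= params$min_depth &
    alt_count >= params$min_alt_reads &
    !is.na(genotype) &
    !is.na(ref_idx)                                      # skip non-ACGT ref
  out <- data.table(
    contig = pile$contig[ok], pos = pile$pos[ok], ref = pile$ref[ok],
    alt = DNA_BASES[alt_idx[ok]], genotype = genotype[ok],
    depth = pile$depth[ok], alt_fraction = frac[ok], filter = "PASS"
  )
  setorder(out, contig, pos)
  out
}

#' Genotype a single pileup column
#'
#' Scalar form of the caller's decision rule: no-call below `min_depth`,
#' alternate allele is the most frequent non-reference base (ties broken
#' alphabetically), no-call below `min_alt_reads` support, heterozygous
#' inside the alt-fraction band, homozygous-alternate strictly above
#' `hom_threshold`; a reference-only column is never emitted.
#'
#' @param column one-row pileup `data.table` (see [build_pileup()]).
#' @param params a [caller_params()].
#' @return one-row call `data.table`, or `NULL` for a no-call.
#' @export
call_site <- function(column, params = caller_params()) {
  column <- as.data.table(column)
  stopifnot(nrow(column) == 1L)
  stopifnot(column$depth == column$A + column$C + column$G + column$T)
  out <- decide_calls(column, params)
  if (nrow(out) == 0L) NULL else out
}

#' Call variants from alignments
#'
#' Composition of [build_pileup()] and the per-site decision rule, applied
#' to every covered position. Deterministic: identical inputs give
#' identical call sets.
#'
#' @inheritParams build_pileup
#' @param params a [caller_params()]; its `min_base_quality` is used for
#'   the pileup.
#' @return call set `data.table` with columns `contig`, `pos`, `ref`,
#'   `alt`, `genotype` (`"het"`/`"hom_alt"`), `depth`, `alt_fraction`,
#'   `filter` (`"PASS"` until a filter stage tags or drops rows).
#' @export
call_variants <- function(alignments, ref, params = caller_params()) {
  pile <- build_pileup(alignments, ref,
                       min_base_quality = params$min_base_quality)
  decide_calls(pile, params)
}
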