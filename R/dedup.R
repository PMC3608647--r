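# Duplicate-read handling. Two semantics are implemented:
#  * pre-alignment  - collapse reads whose base strings are exactly
#    identical (what a sequence-level deduplicator sees before mapping);
#  * post-alignment - group reads by mapped (contig, start, end, strand)
#    and keep one representative per group, flagging the rest.
# Sequencing errors defeat the exact-sequence key but not the coordinate
# key, which is why post-alignment marking removes more true PCR
# duplicates.

#' Collapse exactly identical reads (pre-alignment deduplication)
#'
#' Keeps exactly one read per distinct base string, preserving the input
#' order of first occurrences. Works on unaligned reads
#' (`read_id`/`bases`/`quals`) and on alignment tables alike: only the
#' `bases` column is consulted.
#'
#' @param reads a data.frame with at least a `bases` column.
#' @return the subset of `reads` with one row per distinct base string.
#' @export
collapse_identical <- function(reads) {
  reads <- as.data.table(reads)
  if (nrow(reads) == 0L) return(reads)
  reads[!duplicated(reads$bases)]
}

#' Mark coordinate duplicates (post-alignment deduplication)
#'
#' Groups alignments by (contig, start, end, strand). Within each group one
#' read is retained unflagged - the read with the highest summed base
#' quality, ties broken by first occurrence - and every other member is
#' flagged as a duplicate (`is_dup = TRUE`). Downstream stages ignore
#' flagged reads; nothing is deleted, so the decision is auditable in SAM
#' output (flag 0x400).
#'
#' @param alignments alignment `data.table` (see
#'   [simulate_rna_alignments()] for the column contract).
#' @return the same table, same row order, with `is_dup` set.
#' @export
mark_positional_duplicates <- function(alignments) {
  al <- data.table::copy(as.data.table(alignments))
  if (nrow(al) == 0L) {
    if (!"is_dup" %in% names(al)) al[, is_dup := logical(0)]
    return(al)
  }
  al[, `:=`(.row = .I,
            .qsum = vapply(quals, function(x) sum(qual_to_int(x)), numeric(1)))]
  keep_rows <- al[order(-.qsum, .row),
                  .(keep = .row[1L]),
                  by = .(contig, start, end, strand)]$keep
  al[, is_dup := !(.row %in% keep_rows)]
  al[, c(".row", ".qsum") := NULL]
  al[]
}
utils::globalVariables(c(".row", ".qsum", "keep"))

#' Drop duplicate-flagged reads
#'
#' @param alignments alignment table with an `is_dup` column.
#' @return unflagged subset.
#' @export
drop_duplicates <- function(alignments) {
  al <- as.data.table(alignments)
  if (!"is_dup" %in% names(al) || nrow(al) == 0L) return(al)
  al[is_dup == FALSE]
}
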