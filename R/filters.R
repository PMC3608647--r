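# Post-call site filters applied before evaluation: SNP-cluster removal
# and accessibility-mask removal. Both are idempotent and commute.

#' Remove SNP clusters
#'
#' A cluster is two or more calls on the same contig within a `window`-bp
#' window (default 3, i.e. positions differing by less than 3). Every
#' member of a cluster is removed (or tagged), since clustered mismatches
#' are characteristic of alignment artefacts rather than independent SNVs.
#' Positions on different contigs never cluster.
#'
#' @param calls call set `data.table` (sorted internally by contig, pos).
#' @param window cluster window in bp; two calls cluster iff
#'   `|pos1 - pos2| < window`.
#' @param mode `"drop"` removes cluster members; `"tag"` keeps them with
#'   `"snp_cluster"` appended to their `filter` field.
#' @return filtered call set.
#' @export
filter_clusters <- function(calls, window = 3L, mode = c("drop", "tag")) {
  mode <- match.arg(mode)
  calls <- data.table::copy(as.data.table(calls))
  if (nrow(calls) == 0L) return(calls)
  setorder(calls, contig, pos)
  calls[, clustered := {
    n <- .N
    if (n == 1L) FALSE else {
      d <- diff(pos)
      near_prev <- c(FALSE, d < window)
      near_next <- c(d < window, FALSE)
      near_prev | near_next
    }
  }, by = "contig"]
  out <- if (mode == "drop") {
    calls[clustered == FALSE][, clustered := NULL][]
  } else {
    calls[clustered == TRUE,
          filter := ifelse(filter %in% c("", "PASS"), "snp_cluster",
                           paste(filter, "snp_cluster", sep = ";"))]
    calls[, clustered := NULL][]
  }
  out
}
utils::globalVariables("clustered")

#' Remove calls in accessibility-mask regions
#'
#' A call at 1-based position `pos` is removed iff some mask interval
#' (0-based half-open) satisfies `start <= pos - 1 < end`, i.e. the site
#' lies in a region where reliable variant calling was not attempted.
#'
#' @param calls call set `data.table`.
#' @param mask mask `data.table` with `contig`, `start` (0-based),
#'   `end` (exclusive) columns.
#' @param mode `"drop"` or `"tag"` (tag value `"masked"`).
#' @return filtered call set.
#' @export
filter_masked <- function(calls, mask, mode = c("drop", "tag")) {
  mode <- match.arg(mode)
  calls <- data.table::copy(as.data.table(calls))
  if (nrow(calls) == 0L || is.null(mask) || nrow(mask) == 0L) return(calls)
  validate_mask(mask)
  hit <- positions_in_mask(calls$contig, calls$pos, as.data.table(mask))
  if (mode == "drop") {
    calls[!hit]
  } else {
    calls[hit, filter := ifelse(filter %in% c("", "PASS"), "masked",
                                paste(filter, "masked", sep = ";"))]
    calls[]
  }
}

validate_mask <- function(mask) {
  mask <- as.data.table(mask)
  need <- c("contig", "start", "end")
  if (!all(need %in% names(mask))) {
    stop("mask must have columns contig, start, end")
  }
  bad <- which(!(mask$start < mask$end))
  if (length(bad)) {
    stop("malformed mask interval(s) at line(s) ",
         paste(head(bad, 5L), collapse = ", "),
         ": require start < end (BED half-open)")
  }
  invisible(mask)
}
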