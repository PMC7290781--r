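## Transcript abundance: TPM computation, abundance filtering and ranking.

#' Compute transcripts per million (TPM)
#'
#' \code{tpm_i = 1e6 * (c_i / l_i) / sum_j(c_j / l_j)}, so that the
#' output always sums to one million.
#'
#' @param counts non-negative read counts.
#' @param lengths effective transcript lengths (> 0), same length as
#'   \code{counts}.
#' @return numeric TPM vector.
#' @examples
#' computeTPM(c(10, 10), c(100, 200))
#' @export
computeTPM <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("'counts' and 'lengths' must have equal length")
  if (any(lengths <= 0)) stop("all lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("cannot compute TPM: all counts are zero")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Effective length with optional mean-fragment-length correction
#'
#' \code{l_eff = l - fragMean + 1}, floored at 1. With
#' \code{fragMean = NULL} the contig length is returned unchanged.
#'
#' @param lengths contig lengths.
#' @param fragMean mean sequenced fragment length, or NULL.
#' @return effective lengths.
#' @export
effectiveLength <- function(lengths, fragMean = NULL) {
  if (is.null(fragMean)) return(lengths)
  pmax(lengths - fragMean + 1, 1)
}

#' Filter expression records on a minimum TPM
#'
#' Keeps records with \code{tpm >= threshold} (the boundary is
#' inclusive); input order is preserved.
#'
#' @param records data.frame with a \code{tpm} column.
#' @param threshold minimum TPM (default 1).
#' @return subset of \code{records}.
#' @export
filterMinTPM <- function(records, threshold = 1) {
  if (threshold < 0) stop("'threshold' must be non-negative")
  stopifnot("tpm" %in% names(records))
  out <- records[records$tpm >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top expressed records by TPM
#'
#' Descending TPM; ties broken by \code{contig_id} lexicographically.
#'
#' @param records data.frame with \code{tpm} and \code{contig_id}.
#' @param n maximum number of records (default 20).
#' @return at most \code{n} ranked records.
#' @export
topExpressed <- function(records, n = 20L) {
  if (n < 1L) stop("'n' must be >= 1")
  stopifnot(all(c("tpm", "contig_id") %in% names(records)))
  ord <- order(-records$tpm, records$contig_id)
  out <- records[head(ord, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an expression table from a contig table
#'
#' @param contigs data.frame with \code{contig_id}, \code{read_count},
#'   \code{length}.
#' @param fragMean optional mean fragment length for the effective-length
#'   correction.
#' @return data.frame with \code{contig_id}, \code{read_count},
#'   \code{effective_length}, \code{tpm}.
#' @export
expressionTable <- function(contigs, fragMean = NULL) {
  el <- effectiveLength(contigs$length, fragMean)
  data.frame(contig_id = contigs$contig_id,
             read_count = contigs$read_count,
             effective_length = el,
             tpm = computeTPM(contigs$read_count, el),
             stringsAsFactors = FALSE)
}

#' Write an expression table as TSV (TPM at 2 decimal places)
#'
#' @param expr expression table from [expressionTable()].
#' @param path output path.
#' @export
writeExpressionTsv <- function(expr, path) {
  out <- expr
  out$tpm <- sprintf("%.2f", out$tpm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
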