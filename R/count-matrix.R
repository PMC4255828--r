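#' Construct a transcript count matrix
#'
#' A light container for integer read counts per transcript per sample,
#' together with transcript lengths and per-sample library sizes (total
#' mapped reads). Library sizes may exceed the column sums, e.g. when
#' the matrix is a subset of all transcripts.
#'
#' @param counts Integer matrix, transcripts x samples, with rownames
#'   (transcript ids) and colnames (sample ids).
#' @param lengths Numeric vector of transcript lengths in bp, one per
#'   row (recycled names checked against rownames when named).
#' @param lib_sizes Per-sample library sizes; `NULL` infers column sums.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    stop("counts must have sample ids as colnames")
  }
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (any(counts < 0)) {
    i <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at transcript '", rownames(counts)[i[1]],
         "', sample '", colnames(counts)[i[2]], "'")
  }
  if (any(counts != round(counts))) {
    i <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop("non-integer count at transcript '", rownames(counts)[i[1]],
         "', sample '", colnames(counts)[i[2]], "'")
  }
  if (length(lengths) != nrow(counts)) {
    stop("lengths must have one entry per transcript")
  }
  if (nrow(counts) > 0 && any(lengths < 1)) {
    stop("transcript length < 1 bp for '",
         rownames(counts)[which(lengths < 1)[1]], "'")
  }
  lengths <- as.numeric(lengths)
  names(lengths) <- rownames(counts)
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  }
  if (length(lib_sizes) != ncol(counts)) {
    stop("lib_sizes must have one entry per sample")
  }
  lib_sizes <- as.numeric(lib_sizes)
  names(lib_sizes) <- colnames(counts)
  structure(
    list(counts = counts, lengths = lengths, lib_sizes = lib_sizes),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples\n")
  cat("library sizes:", paste0(names(x$lib_sizes), "=",
                               format(x$lib_sizes, big.mark = ",")), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by samples and/or transcripts
#'
#' @param cm A [count_matrix()].
#' @param samples Sample ids to keep (order preserved as given).
#' @param transcripts Transcript ids to keep.
#' @return A `count_matrix` over the subset; library sizes are carried
#'   over unchanged (they remain totals of the full library).
#' @export
subset_counts <- function(cm, samples = NULL, transcripts = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  s <- if (is.null(samples)) colnames(cm$counts) else samples
  missing_s <- setdiff(s, colnames(cm$counts))
  if (length(missing_s)) {
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  }
  tr <- if (is.null(transcripts)) rownames(cm$counts) else transcripts
  missing_t <- setdiff(tr, rownames(cm$counts))
  if (length(missing_t)) {
    stop("unknown transcript(s): ", paste(missing_t, collapse = ", "))
  }
  count_matrix(cm$counts[tr, s, drop = FALSE], cm$lengths[tr],
               cm$lib_sizes[s])
}

#' Construct an expression (RPKM) matrix
#'
#' @param values Numeric matrix of non-negative expression values with
#'   transcript rownames and sample colnames.
#' @param normalised Logical flag: have the columns been quantile
#'   normalised?
#' @param scope Character vector of sample ids over which normalisation
#'   was performed (empty when `normalised = FALSE`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, normalised = FALSE,
                              scope = character()) {
  values <- as.matrix(values)
  if (nrow(values) > 0 && ncol(values) > 0 && any(values < 0)) {
    stop("expression values must be non-negative")
  }
  structure(
    list(values = values, normalised = normalised, scope = scope),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "samples;",
      if (x$normalised) {
        paste0("quantile-normalised over {",
               paste(x$scope, collapse = ", "), "}")
      } else "raw RPKM", "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
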