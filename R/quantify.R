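#' Convert counts to RPKM
#'
#' RPKM = 1e9 * C / (N * L): reads per kilobase of transcript per
#' million mapped reads, with C the count, N the sample's library size
#' and L the transcript length in bp. De novo contigs have no exon
#' structure, so the "exon model" length is the full contig length.
#'
#' @param cm A [count_matrix()].
#' @return An [expression_matrix()] with `normalised = FALSE`.
#' @examples
#' cm <- count_matrix(matrix(10, 1, 1, dimnames = list("t1", "s1")),
#'                    lengths = 2000, lib_sizes = 1e6)
#' rpkm(cm)$values  # 5
#' @export
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$lib_sizes <= 0)) {
    stop("zero library size for sample '",
         names(cm$lib_sizes)[which(cm$lib_sizes <= 0)[1]], "'")
  }
  v <- 1e9 * sweep(cm$counts, 2, cm$lib_sizes, "/")
  v <- v / cm$lengths
  expression_matrix(v, normalised = FALSE)
}

#' Quantile-normalise expression values across a sample subset
#'
#' Within the chosen subset each column's values are replaced by the
#' across-column mean of the order statistics at the same rank, so all
#' normalised columns share an identical multiset of values. Tied
#' values within a column receive the mean of the row-means over the
#' tied rank range. Columns outside the subset are left untouched.
#'
#' @param expr An [expression_matrix()].
#' @param samples Sample ids to normalise together; `NULL` means all.
#' @return An [expression_matrix()] with `normalised = TRUE` and the
#'   subset recorded in `scope`.
#' @export
quantile_normalize <- function(expr, samples = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(samples)) samples <- colnames(expr$values)
  missing_s <- setdiff(samples, colnames(expr$values))
  if (length(missing_s)) {
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  }
  if (length(samples) < 2) {
    stop("quantile normalisation needs at least 2 samples")
  }
  v <- expr$values
  v[, samples] <- limma::normalizeQuantiles(v[, samples, drop = FALSE],
                                            ties = TRUE)
  expression_matrix(v, normalised = TRUE, scope = samples)
}

#' Per-transcript mean expression over a sample subset
#'
#' Arithmetic mean with zeros included; the aggregator behind the
#' screen's "mean normalised RPKM of <group> < bound" filters.
#'
#' @param expr An [expression_matrix()].
#' @param samples Non-empty character vector of sample ids.
#' @return Named numeric vector, one mean per transcript.
#' @export
group_mean <- function(expr, samples) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(samples) == 0) stop("empty sample subset")
  missing_s <- setdiff(samples, colnames(expr$values))
  if (length(missing_s)) {
    stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  }
  rowMeans(expr$values[, samples, drop = FALSE])
}

#' Principal coordinates analysis of samples
#'
#' Classical metric scaling (double-centred squared-distance matrix,
#' eigendecomposed) of inter-sample distances, for QC of library
#' clustering by stage/sex and detection of developmentally lagging
#' libraries. Axes with non-positive eigenvalues are dropped from the
#' coordinates; all eigenvalues are reported.
#'
#' @param expr An [expression_matrix()] with at least 3 samples.
#' @param metric One of `"log2euclidean"` (Euclidean distance on
#'   log2(value + 1), the default), `"euclidean"`, `"manhattan"` or
#'   `"bray"` (Bray-Curtis dissimilarity).
#' @return List with `points` (samples x axes coordinate matrix,
#'   ordered by decreasing eigenvalue), `eigenvalues` (all, including
#'   negative ones) and `metric`.
#' @export
pcoa_samples <- function(expr, metric = "log2euclidean") {
  stopifnot(inherits(expr, "expression_matrix"))
  n <- ncol(expr$values)
  if (n < 3) stop("PCoA needs at least 3 samples")
  supported <- c("log2euclidean", "euclidean", "manhattan", "bray")
  if (!metric %in% supported) {
    stop("unknown metric '", metric, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  x <- t(expr$values)
  d <- switch(metric,
    log2euclidean = stats::dist(log2(x + 1)),
    euclidean = stats::dist(x),
    manhattan = stats::dist(x, method = "manhattan"),
    bray = {
      # Bray-Curtis: sum|xi - yi| / sum(xi + yi)
      m <- as.matrix(stats::dist(x, method = "manhattan"))
      tot <- outer(rowSums(x), rowSums(x), "+")
      stats::as.dist(ifelse(tot > 0, m / tot, 0))
    }
  )
  pcoa_from_dist(d, metric = metric)
}

#' Principal coordinates from a distance matrix
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param metric Optional label recorded in the result.
#' @return As [pcoa_samples()].
#' @export
pcoa_from_dist <- function(d, metric = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  res <- withCallingHandlers(
    stats::cmdscale(d, k = n - 1, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  eig <- res$eig
  pts <- res$points
  if (is.null(dim(pts)) || ncol(pts) == 0) {
    pts <- matrix(0, n, 1)
    rownames(pts) <- attr(d, "Labels")
  }
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  if (is.null(metric)) metric <- attr(d, "method")
  list(points = pts, eigenvalues = eig, metric = metric)
}
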