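# Independent brute-force oracles and small fixture builders.

# Best-scoring contiguous segment by exhaustive O(L^2) search over
# (limit - 10^(-Q/10)); ties resolved leftmost start, then longest.
brute_mott <- function(qualities, limit = 0.05) {
  n <- length(qualities)
  if (n == 0) return(c(0L, 0L))
  s <- limit - 10^(-qualities / 10)
  tol <- 1e-12
  best <- 0; bs <- 0L; be <- 0L
  for (i in seq_len(n)) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + s[j]
      better <- acc > best + tol
      tie <- abs(acc - best) <= tol && best > tol
      if (better ||
          (tie && (i - 1L < bs || (i - 1L == bs && j > be)))) {
        best <- acc; bs <- i - 1L; be <- j
      }
    }
  }
  if (best <= tol) return(c(0L, 0L))
  c(bs, be)
}

# Step-up FDR by the definition: q_(i) = min_{j >= i} p_(j) * m / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(p[o][js] * m / js))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Classical-scaling oracle: double-centred squared distances,
# eigendecomposed by eigen(), independent of cmdscale.
brute_pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  keep <- e$values > 1e-10
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(points = pts, eigenvalues = e$values)
}

random_read <- function(len, qmin = 2, qmax = 40) {
  phred_read(paste0("r", len, "_", sample.int(1e6, 1)),
             paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""),
             sample(qmin:qmax, len, replace = TRUE))
}

small_counts <- function(counts, lengths = NULL, lib_sizes = NULL) {
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  count_matrix(counts, lengths, lib_sizes)
}

# the three cellularisation transcript profiles as a count matrix on a
# large pseudo library, for the early-vs-late worked example
cellularisation_pseudo_counts <- function(lib_size = 1e7) {
  em <- fixture_expression("cellularisation")
  lens <- stats::setNames(load_fixture("cellularisation")$length_bp,
                          rownames(em$values))
  ns <- stats::setNames(rep(lib_size, ncol(em$values)),
                        colnames(em$values))
  pseudo_counts(em, lens, ns)
}
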