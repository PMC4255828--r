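#' Reconstruct pseudo-counts from normalised expression
#'
#' The weighted proportions test operates on counts and library totals,
#' but normalisation happens on the RPKM scale. This inverts the RPKM
#' formula per cell — `x = round(value * L * N / 1e9)` — so the test
#' sees counts consistent with the normalised expression values, with
#' each sample's true library size as its total.
#'
#' @param expr An [expression_matrix()].
#' @param lengths Transcript lengths in bp (named by transcript).
#' @param lib_sizes Per-sample library sizes (named by sample).
#' @return A [count_matrix()].
#' @export
pseudo_counts <- function(expr, lengths, lib_sizes) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  lengths <- lengths[rownames(v)]
  lib_sizes <- lib_sizes[colnames(v)]
  x <- round(v * lengths *
               matrix(lib_sizes, nrow(v), ncol(v), byrow = TRUE) / 1e9)
  count_matrix(x, lengths, lib_sizes)
}

#' Weighted group proportion with between-library overdispersion
#'
#' Estimates a transcript's pooled proportion of library counts across
#' the libraries of one group, in the style of Baggerly et al. (2003)
#' for SAGE libraries: per-library proportions `p_i = x_i / n_i` are
#' combined with inverse-variance weights where each library's variance
#' `v_i = p(1-p)/n_i + sigma2` carries a binomial sampling component
#' plus a shared between-library variance `sigma2`. `sigma2` is the
#' moment-matching solution of `sum((p_i - p)^2 / v_i) = k - 1`,
#' clipped at zero, found by bisection; weights and the pooled estimate
#' are iterated to convergence. With a single library `sigma2 = 0` and
#' the estimate falls back to the plain binomial.
#'
#' @param x Integer counts per library.
#' @param n Library sizes (> 0), same length as `x`.
#' @return List with `p_hat` (pooled proportion), `sigma2`
#'   (between-library variance), `V` (variance of the estimator,
#'   `1/sum(1/v_i)`), `weights` and `k` (number of libraries).
#' @export
baggerley_group_estimate <- function(x, n) {
  k <- length(x)
  if (k < 1 || length(n) != k) stop("x and n must have equal length >= 1")
  if (any(n <= 0)) stop("library sizes must be > 0")
  p <- x / n
  if (k == 1) {
    return(list(p_hat = p, sigma2 = 0, V = p * (1 - p) / n,
                weights = 1, k = 1L))
  }
  w <- n / sum(n)
  p_hat <- sum(w * p)
  sigma2 <- 0
  v <- NULL
  for (iter in seq_len(100)) {
    b <- p_hat * (1 - p_hat) / n
    dev2 <- (p - p_hat)^2
    f <- function(s2) sum(dev2 / (b + s2)) - (k - 1)
    sigma2 <- if (all(dev2 == 0)) {
      0
    } else if (all(b == 0)) {
      # degenerate binomial floor (p_hat 0 or 1): direct solution
      sum(dev2) / (k - 1)
    } else if (f(0) <= 0) {
      0
    } else {
      hi <- sum(dev2)
      while (f(hi) > 0) hi <- hi * 2
      # tolerance relative to the bracket: the root can be ~1e-11 when
      # proportions are ~1e-5, far below any fixed absolute tolerance
      stats::uniroot(f, c(0, hi),
                     tol = hi * .Machine$double.eps^0.5)$root
    }
    v <- b + sigma2
    if (all(v == 0)) {
      # all counts zero (or all n identical at p 0/1) with no spread
      return(list(p_hat = p_hat, sigma2 = 0, V = 0,
                  weights = rep(1 / k, k), k = as.integer(k)))
    }
    if (any(v == 0)) v[v == 0] <- min(v[v > 0]) * 1e-6
    w_new <- (1 / v) / sum(1 / v)
    p_new <- sum(w_new * p)
    delta <- abs(p_new - p_hat)
    p_hat <- p_new
    w <- w_new
    if (delta < 1e-12) break
  }
  list(p_hat = p_hat, sigma2 = sigma2, V = 1 / sum(1 / v),
       weights = w, k = as.integer(k))
}

#' Weighted proportions test between two groups
#'
#' A t-type statistic on the difference of pooled proportions:
#' `t = (p_A - p_B) / sqrt(V_A + V_B)`, two-sided. Two reference
#' distributions are available: `"t"` (the default) refers the
#' statistic to a t distribution with `k_A + k_B - 2` degrees of
#' freedom (floored at 1), which accounts for the small number of
#' libraries; `"normal"` uses the standard-normal large-sample
#' approximation, the behaviour of the commercial RNA-seq workbench the
#' screening study ran (only the normal reference can declare
#' discoveries from unreplicated or two-library comparisons at
#' stringent FDR levels, at the cost of anticonservative p-values —
#' see the methods vignette). When both groups carry zero variance the
#' p-value is 1 for equal proportions (e.g. all counts zero in both
#' groups) and 0 otherwise.
#'
#' @param group_a,group_b Results of [baggerley_group_estimate()] for
#'   the same transcript.
#' @param ref Reference distribution, `"t"` or `"normal"`.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
baggerley_test <- function(group_a, group_b, ref = c("t", "normal")) {
  ref <- match.arg(ref)
  V <- group_a$V + group_b$V
  diff <- group_a$p_hat - group_b$p_hat
  df <- max(1L, group_a$k + group_b$k - 2L)
  if (V <= 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t <- diff / sqrt(V)
  }
  p <- if (is.infinite(t)) {
    0
  } else if (ref == "t") {
    2 * stats::pt(-abs(t), df)
  } else {
    2 * stats::pnorm(-abs(t))
  }
  list(t = t, df = df, p = p)
}

#' Signed fold change between two group means
#'
#' Magnitude is `max(case, baseline) / min(case, baseline)`, so always
#' >= 1; the sign is positive when the case mean exceeds the baseline
#' mean and negative otherwise. Both means zero gives `+1`, flagged
#' degenerate; exactly one zero gives an infinite magnitude, also
#' flagged (no pseudocount is added).
#'
#' @param case_mean,baseline_mean Non-negative group means (vectorised).
#' @return A data.frame with columns `fold_change` (signed, possibly
#'   `+-Inf`) and `degenerate` (logical).
#' @export
fold_change <- function(case_mean, baseline_mean) {
  if (any(case_mean < 0) || any(baseline_mean < 0)) {
    stop("group means must be non-negative")
  }
  hi <- pmax(case_mean, baseline_mean)
  lo <- pmin(case_mean, baseline_mean)
  mag <- ifelse(hi == 0, 1, hi / lo)  # Inf when lo == 0, hi > 0
  sgn <- ifelse(case_mean >= baseline_mean, 1, -1)
  fc <- ifelse(hi == 0, 1, sgn * mag)
  data.frame(fold_change = fc,
             degenerate = (hi == 0) | (lo == 0 & hi > 0))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment `q_(i) = min_(j>=i) (p_(j) * m / j)`, capped at 1,
#' returned in input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Specify one differential-expression comparison
#'
#' Mirrors one row of the study's comparison table: a case group tested
#' against a baseline group, optional excluded samples (recorded for
#' provenance; they simply do not enter either group), the FDR cutoff,
#' the up-regulation direction of interest, and an optional expression
#' filter ("mean normalised RPKM of <samples> < bound") applied to the
#' up-regulated set during screening.
#'
#' @param id Comparison label (e.g. `"A"` ... `"N"`).
#' @param case,baseline Disjoint character vectors of sample ids; the
#'   fold-change sign is positive when expression is higher in `case`.
#' @param excluded Sample ids deliberately left out (must not appear in
#'   either group).
#' @param fdr_alpha FDR significance cutoff (default 0.001).
#' @param direction `"up-in-case"`, `"up-in-baseline"` or `"both"`.
#' @param filter Optional list with `samples` and `bound`: keep only
#'   candidates whose mean normalised RPKM over `samples` is strictly
#'   below `bound`.
#' @param ref Reference distribution for the proportions test, `"t"`
#'   (replication-aware default) or `"normal"` (large-sample
#'   approximation; used by the study's screen configuration, see
#'   [baggerley_test()]).
#' @return A list of class `comparison_spec`.
#' @export
comparison_spec <- function(id, case, baseline, excluded = character(),
                            fdr_alpha = 0.001,
                            direction = c("up-in-case", "up-in-baseline",
                                          "both"),
                            filter = NULL, ref = c("t", "normal")) {
  direction <- match.arg(direction)
  ref <- match.arg(ref)
  if (length(case) == 0 || length(baseline) == 0) {
    stop("comparison '", id, "': case and baseline must be non-empty")
  }
  if (length(intersect(case, baseline))) {
    stop("comparison '", id, "': case and baseline groups overlap")
  }
  if (length(intersect(excluded, c(case, baseline)))) {
    stop("comparison '", id, "': excluded samples appear in a group")
  }
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop("comparison '", id, "': fdr_alpha must be in (0, 1)")
  }
  if (!is.null(filter) &&
      (is.null(filter$samples) || is.null(filter$bound))) {
    stop("comparison '", id, "': filter needs 'samples' and 'bound'")
  }
  structure(list(id = id, case = case, baseline = baseline,
                 excluded = excluded, fdr_alpha = fdr_alpha,
                 direction = direction, filter = filter, ref = ref),
            class = "comparison_spec")
}

#' Run one differential-expression comparison
#'
#' The full per-comparison pipeline: subset the count matrix to the
#' comparison's samples (excluded samples dropped), convert to RPKM,
#' quantile-normalise over exactly those samples, compute group means
#' and signed fold changes, reconstruct pseudo-counts, apply the
#' weighted proportions test per transcript, and BH-correct the
#' p-values. Single-library groups fall back to the binomial variance
#' and trigger an "unreplicated" warning.
#'
#' @param cm A [count_matrix()].
#' @param design A study design containing all of the spec's samples.
#' @param spec A [comparison_spec()].
#' @return A `data.frame` (the DE table): `transcript_id`, `mean_case`,
#'   `mean_baseline` (normalised RPKM), `fold_change` (signed),
#'   `degenerate_fc`, `t`, `df`, `p`, `fdr_p` and `significant`
#'   (`fdr_p < fdr_alpha`).
#' @export
run_comparison <- function(cm, design, spec) {
  stopifnot(inherits(cm, "count_matrix"), inherits(spec, "comparison_spec"))
  design <- validate_design(design)
  missing_s <- setdiff(c(spec$case, spec$baseline), design$sample_id)
  if (length(missing_s)) {
    stop("comparison '", spec$id, "': sample(s) not in design: ",
         paste(missing_s, collapse = ", "))
  }
  if (length(spec$case) == 1 || length(spec$baseline) == 1) {
    warning("comparison '", spec$id,
            "' has an unreplicated group; binomial-fallback variance used")
  }
  included <- c(spec$case, spec$baseline)
  sub <- subset_counts(cm, samples = included)
  expr <- quantile_normalize(rpkm(sub), samples = included)
  mean_case <- group_mean(expr, spec$case)
  mean_base <- group_mean(expr, spec$baseline)
  fc <- fold_change(mean_case, mean_base)
  pc <- pseudo_counts(expr, sub$lengths, sub$lib_sizes)
  n_case <- pc$lib_sizes[spec$case]
  n_base <- pc$lib_sizes[spec$baseline]
  xs_case <- pc$counts[, spec$case, drop = FALSE]
  xs_base <- pc$counts[, spec$baseline, drop = FALSE]
  m <- nrow(pc$counts)
  tt <- numeric(m); df <- integer(m); pv <- numeric(m)
  for (i in seq_len(m)) {
    ga <- baggerley_group_estimate(xs_case[i, ], n_case)
    gb <- baggerley_group_estimate(xs_base[i, ], n_base)
    r <- baggerley_test(ga, gb, ref = spec$ref)
    tt[i] <- r$t; df[i] <- r$df; pv[i] <- r$p
  }
  q <- bh_fdr(pv)
  data.frame(
    transcript_id = rownames(pc$counts),
    mean_case = unname(mean_case),
    mean_baseline = unname(mean_base),
    fold_change = fc$fold_change,
    degenerate_fc = fc$degenerate,
    t = tt, df = df, p = pv, fdr_p = q,
    significant = q < spec$fdr_alpha,
    stringsAsFactors = FALSE
  )
}
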