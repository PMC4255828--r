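#' Marker-calibrated expression threshold
#'
#' Calibrates an "already expressed at baseline" RPKM threshold from a
#' marker transcript (e.g. an early-zygotic dose-signal homologue such
#' as sisA): the raw threshold is the marker's mean over the baseline
#' samples times `1 + margin`, and the operational threshold is the raw
#' value rounded down to the nearest 10 (floored at 10), matching the
#' study's use of 50 RPKM as a conservative "no more than 20% above the
#' marker" bound.
#'
#' @param expr A normalised [expression_matrix()].
#' @param marker Transcript id of the marker.
#' @param baseline_samples Sample ids defining the baseline condition.
#' @param margin Proportional margin above the marker mean (default
#'   0.2).
#' @return List of class `marker_calibration`: `marker`,
#'   `baseline_samples`, `baseline_mean`, `margin`, `raw` and
#'   `operational`.
#' @export
calibrate_threshold <- function(expr, marker, baseline_samples,
                                margin = 0.2) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!marker %in% rownames(expr$values)) {
    stop("marker transcript '", marker, "' not present in the matrix")
  }
  bm <- mean(expr$values[marker, baseline_samples])
  raw <- bm * (1 + margin)
  op <- max(10, floor(raw / 10) * 10)
  structure(list(marker = marker, baseline_samples = baseline_samples,
                 baseline_mean = bm, margin = margin,
                 raw = raw, operational = op),
            class = "marker_calibration")
}

#' @export
print.marker_calibration <- function(x, ...) {
  cat("marker_calibration: ", x$marker, " mean ",
      signif(x$baseline_mean, 4), " over {",
      paste(x$baseline_samples, collapse = ", "), "}; raw ",
      signif(x$raw, 4), " -> operational ", x$operational, "\n", sep = "")
  invisible(x)
}

#' Select significantly up-regulated transcripts from a DE table
#'
#' @param de A DE table from [run_comparison()].
#' @param alpha FDR cutoff (default 0.001).
#' @param direction `"up-in-case"` (positive fold change),
#'   `"up-in-baseline"` (negative) or `"both"`.
#' @return Character vector of transcript ids.
#' @export
select_upregulated <- function(de, alpha = 0.001,
                               direction = c("up-in-case",
                                             "up-in-baseline", "both")) {
  direction <- match.arg(direction)
  if (nrow(de) == 0) return(character())
  sig <- de$fdr_p < alpha
  keep <- switch(direction,
    `up-in-case` = sig & de$fold_change > 0,
    `up-in-baseline` = sig & de$fold_change < 0,
    both = sig & !is.na(de$fold_change)
  )
  de$transcript_id[keep]
}

#' Apply a mean-expression upper-bound filter to a candidate set
#'
#' Keeps candidates whose mean normalised RPKM over the stated samples
#' is strictly below `bound` (the "mean normalised RPKM of <group> <
#' bound" filters of the screen), recording why each removed transcript
#' was dropped.
#'
#' @param candidates Character vector of transcript ids.
#' @param expr An [expression_matrix()] containing the candidates.
#' @param samples Sample ids over which the mean is taken.
#' @param bound Upper bound (exclusive); `Inf` keeps everything.
#' @return List with `kept` (character vector) and `removed`
#'   (data.frame `transcript_id`, `reason`).
#' @export
apply_expression_filter <- function(candidates, expr, samples, bound) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(candidates) == 0) {
    return(list(kept = character(),
                removed = data.frame(transcript_id = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  missing_t <- setdiff(candidates, rownames(expr$values))
  if (length(missing_t)) {
    stop("candidate(s) not in matrix: ", paste(missing_t, collapse = ", "))
  }
  mu <- rowMeans(expr$values[candidates, samples, drop = FALSE])
  keep <- mu < bound
  list(
    kept = candidates[keep],
    removed = data.frame(
      transcript_id = candidates[!keep],
      reason = sprintf("mean RPKM %.4g over {%s} >= %g",
                       mu[!keep], paste(samples, collapse = ","), bound),
      stringsAsFactors = FALSE
    )
  )
}

#' Intersect the time- and male-restricted candidate sets
#'
#' Computes `I \U2229 L` and the final candidate set
#' `(I \U2229 L) - (I \U2229 L \U2229 N)`: transcripts up-regulated
#' over time in the replicated comparison and in the male-only
#' comparison, minus those also up-regulated in older females.
#'
#' @param set_i,set_l,set_n Character vectors of transcript ids over
#'   the same transcript universe.
#' @return List with `i_and_l`, `i_and_l_and_n`, `final` and
#'   `provenance` (data.frame with per-transcript membership flags and
#'   outcome).
#' @export
intersect_screen <- function(set_i, set_l, set_n) {
  i_and_l <- intersect(set_i, set_l)
  i_and_l_and_n <- intersect(i_and_l, set_n)
  final <- setdiff(i_and_l, i_and_l_and_n)
  universe <- sort(unique(c(set_i, set_l, set_n)))
  prov <- data.frame(
    transcript_id = universe,
    in_i = universe %in% set_i,
    in_l = universe %in% set_l,
    in_n = universe %in% set_n,
    stringsAsFactors = FALSE
  )
  prov$outcome <- ifelse(prov$transcript_id %in% final, "final",
    ifelse(prov$transcript_id %in% i_and_l_and_n, "removed: up in females",
      ifelse(prov$in_i & !prov$in_l, "removed: not in male-only set",
        ifelse(prov$in_l & !prov$in_i, "removed: not in replicated set",
               "removed: only in female set"))))
  list(i_and_l = i_and_l, i_and_l_and_n = i_and_l_and_n,
       final = final, provenance = prov)
}

#' The study's fourteen-comparison screen configuration
#'
#' Encodes the full comparison table: male-vs-female contrasts A-G,
#' time contrasts H-N (late vs early), with their exact sample
#' memberships, exclusions, and expression filters (mean normalised
#' RPKM of female samples < 5 for B, C, D; mean normalised RPKM of
#' early samples < `early_bound` for I, J, L). The intersection screen
#' uses I (replicated both-sex time contrast), L (unreplicated
#' male-only time contrast) and N (female-only time contrast).
#'
#' All screen comparisons use the large-sample normal reference for the
#' proportions test (see [baggerley_test()]): half of the study's
#' comparisons are unreplicated or compare one library against two, and
#' only the normal approximation can call discoveries from them at the
#' 0.001 FDR level, as the original analysis did.
#'
#' @param fdr_alpha FDR cutoff used by every comparison (default
#'   0.001).
#' @param female_bound Upper bound on female mean RPKM (default 5).
#' @param early_bound Upper bound on early mean RPKM (default 50, the
#'   marker-calibrated operational threshold).
#' @param ref Reference distribution for the proportions test.
#' @return List with `comparisons` (named list of [comparison_spec()])
#'   and `intersection` (named ids for the `i`, `l`, `n` roles).
#' @export
screen_config <- function(fdr_alpha = 0.001, female_bound = 5,
                          early_bound = 50, ref = "normal") {
  bj <- function(i) paste0("BJ", i)
  f5 <- function(samples) list(samples = samples, bound = female_bound)
  f50 <- function(samples) list(samples = samples, bound = early_bound)
  cs <- function(id, case, baseline, excluded = integer(), filter = NULL) {
    comparison_spec(id, bj(case), bj(baseline), excluded = bj(excluded),
                    fdr_alpha = fdr_alpha, direction = "up-in-case",
                    filter = filter, ref = ref)
  }
  comparisons <- list(
    # male vs female
    A = cs("A", c(1, 2), c(3, 4)),
    B = cs("B", 2, c(3, 4), excluded = 1, filter = f5(bj(c(3, 4)))),
    C = cs("C", c(5, 6), c(7, 8), filter = f5(bj(c(7, 8)))),
    D = cs("D", 6, c(7, 8), excluded = 5, filter = f5(bj(c(7, 8)))),
    E = cs("E", c(1, 2, 5, 6), c(3, 4, 7, 8)),
    F = cs("F", c(2, 6), c(3, 4, 7, 8), excluded = c(1, 5)),
    G = cs("G", c(2, 5, 6), c(3, 4, 7, 8), excluded = 1),
    # late vs early
    H = cs("H", c(1, 2, 3, 4), c(5, 6, 7, 8)),
    I = cs("I", c(2, 3, 4), c(6, 7, 8), excluded = c(1, 5),
           filter = f50(bj(c(6, 7, 8)))),
    J = cs("J", c(2, 3, 4), c(5, 6, 7, 8), excluded = 1,
           filter = f50(bj(c(5, 6, 7, 8)))),
    K = cs("K", c(1, 2), c(5, 6)),
    L = cs("L", 2, 6, excluded = c(1, 5), filter = f50(bj(6))),
    M = cs("M", 1, 5, excluded = c(2, 6)),
    N = cs("N", c(3, 4), c(7, 8))
  )
  list(comparisons = comparisons,
       intersection = list(i = "I", l = "L", n = "N"))
}

#' Run the full multi-comparison intersection screen
#'
#' Executes every configured comparison via [run_comparison()], selects
#' the up-regulated transcripts per comparison, applies each
#' comparison's expression filter, and intersects the configured `i`,
#' `l` and `n` sets into the final candidate list
#' `(I \U2229 L) - (I \U2229 L \U2229 N)`. Every transcript that enters
#' any comparison's significant set and does not reach the final set
#' has a recorded removal reason.
#'
#' @param cm A [count_matrix()].
#' @param design A study design with every sex-by-stage cell non-empty.
#' @param config A screen configuration (see [screen_config()]).
#' @return List of class `screen_result`: `comparisons` (per id: the
#'   DE table `de`, `up`, `of_interest` sets and counts), `removed`
#'   (filter provenance), `intersections`, `final` and a `summary`
#'   data.frame mirroring the comparison-table columns.
#' @export
run_full_screen <- function(cm, design, config = screen_config()) {
  design <- validate_design(design, full_screen = TRUE)
  bad <- vapply(config$comparisons, function(sp) {
    any(!c(sp$case, sp$baseline) %in% design$sample_id)
  }, logical(1))
  if (any(bad)) {
    stop("screen config references unknown samples in comparison(s): ",
         paste(names(config$comparisons)[bad], collapse = ", "))
  }
  need <- unlist(config$intersection)
  missing_c <- setdiff(need, names(config$comparisons))
  if (length(missing_c)) {
    stop("intersection references unknown comparison(s): ",
         paste(missing_c, collapse = ", "))
  }
  results <- list()
  removed <- list()
  for (id in names(config$comparisons)) {
    sp <- config$comparisons[[id]]
    de <- withCallingHandlers(
      run_comparison(cm, design, sp),
      warning = function(w) {
        if (grepl("unreplicated", conditionMessage(w))) {
          message(conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      }
    )
    up <- select_upregulated(de, alpha = sp$fdr_alpha,
                             direction = sp$direction)
    if (!is.null(sp$filter)) {
      # filters act on the normalised values of this comparison's scope
      sub <- subset_counts(cm, samples = c(sp$case, sp$baseline))
      expr <- quantile_normalize(rpkm(sub))
      filt <- apply_expression_filter(up, expr, sp$filter$samples,
                                      sp$filter$bound)
      of_interest <- filt$kept
      if (nrow(filt$removed)) {
        removed[[id]] <- cbind(comparison = id, filt$removed)
      }
    } else {
      of_interest <- up
    }
    results[[id]] <- list(
      spec = sp, de = de,
      significant = de$transcript_id[de$significant],
      up = up, of_interest = of_interest,
      n_significant = sum(de$significant),
      n_up = length(up),
      n_of_interest = length(of_interest)
    )
  }
  ix <- config$intersection
  inter <- intersect_screen(results[[ix$i]]$of_interest,
                            results[[ix$l]]$of_interest,
                            results[[ix$n]]$up)
  # provenance: every significant transcript that never reached the final
  # set carries at least one recorded removal reason (filter removals are
  # already collected; intersection outcomes live in inter$provenance)
  for (id in names(results)) {
    r <- results[[id]]
    lost <- setdiff(r$significant, inter$final)
    wrong_dir <- intersect(lost, setdiff(r$significant, r$up))
    if (length(wrong_dir)) {
      removed[[paste0(id, ".direction")]] <- data.frame(
        comparison = id, transcript_id = wrong_dir,
        reason = "significant but not up-regulated in the screened direction",
        stringsAsFactors = FALSE
      )
    }
    filtered_here <- if (!is.null(removed[[id]])) {
      removed[[id]]$transcript_id
    } else character()
    unaccounted <- setdiff(lost, c(wrong_dir, filtered_here,
                                   inter$provenance$transcript_id))
    if (length(unaccounted)) {
      removed[[paste0(id, ".path")]] <- data.frame(
        comparison = id, transcript_id = unaccounted,
        reason = "comparison is not on the intersection path",
        stringsAsFactors = FALSE
      )
    }
  }
  removed_df <- if (length(removed)) {
    do.call(rbind, c(removed, make.row.names = FALSE))
  } else {
    data.frame(comparison = character(), transcript_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  summary <- data.frame(
    comparison = names(results),
    case = vapply(results, function(r) paste(r$spec$case, collapse = ","),
                  character(1)),
    baseline = vapply(results,
                      function(r) paste(r$spec$baseline, collapse = ","),
                      character(1)),
    n_significant = vapply(results, function(r) r$n_significant,
                           numeric(1)),
    n_up = vapply(results, function(r) r$n_up, numeric(1)),
    filter = vapply(results, function(r) {
      if (is.null(r$spec$filter)) "" else {
        sprintf("mean RPKM of {%s} < %g",
                paste(r$spec$filter$samples, collapse = ","),
                r$spec$filter$bound)
      }
    }, character(1)),
    n_of_interest = vapply(results, function(r) r$n_of_interest,
                           numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(comparisons = results, removed = removed_df,
                 intersections = inter, final = inter$final,
                 summary = summary, config = config),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result over", length(x$comparisons), "comparisons\n")
  print(x$summary, row.names = FALSE)
  cat("I \U2229 L:", length(x$intersections$i_and_l),
      " final:", length(x$final), "\n")
  invisible(x)
}

#' Classify a transcript's maternal/zygotic expression profile
#'
#' Uses the early and late group means (normalised RPKM), the
#' early-vs-late FDR-corrected p-value, a maternal threshold (early
#' expression at or above it indicates maternally deposited transcript
#' mass) and a detection floor:
#'
#' * `undetected` — both means below the detection floor;
#' * `zygotic` — early mean below the maternal threshold and
#'   significantly up-regulated late (purely zygotic activation);
#' * `maternal_plus_zygotic` — early mean at or above the threshold and
#'   significantly up-regulated late;
#' * `maternal` — detected early and not significantly up-regulated
#'   (stable or degrading maternal deposit);
#' * `ambiguous` — everything else (e.g. detected only late without
#'   significance).
#'
#' @param early_mean,late_mean Group means (vectorised).
#' @param q Early-vs-late FDR-corrected p-values.
#' @param maternal_threshold RPKM threshold separating purely zygotic
#'   from maternal-plus-zygotic risers (e.g. a marker-calibrated 50).
#' @param alpha Significance cutoff on `q` (default 0.001).
#' @param floor Detection floor in normalised RPKM (default 0.25).
#' @return Character vector of profile classes.
#' @export
classify_profile <- function(early_mean, late_mean, q, maternal_threshold,
                             alpha = 0.001, floor = 0.25) {
  sig_up <- !is.na(q) & q < alpha & late_mean > early_mean
  out <- rep("ambiguous", length(early_mean))
  out[sig_up & early_mean < maternal_threshold] <- "zygotic"
  out[sig_up & early_mean >= maternal_threshold] <- "maternal_plus_zygotic"
  out[!sig_up & early_mean >= floor] <- "maternal"
  out[early_mean < floor & late_mean < floor] <- "undetected"
  out
}
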