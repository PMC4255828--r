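#' Configuration for the synthetic embryo count-matrix generator
#'
#' The generator plants five transcript classes with known ground truth
#' in the eight-library sexed-embryo design:
#'
#' * `maternal_stable` — deposited in the egg, flat across stages;
#' * `maternal_degrading` — deposited, decaying by `fold_dynamics`
#'   (a value < 1) from early to late;
#' * `zygotic_shared` — near-silent early, activated in both sexes by
#'   the stated fold (default x75, emulating a slam-like
#'   cellularisation transcript rising from ~4 to ~300 RPKM);
#' * `zygotic_male_only` — expected RPKM 0 in every female library,
#'   activated over time in males (a Y-linked M-factor-like signal);
#' * `contaminant_sporadic` — expressed at high level in exactly one
#'   randomly chosen library and zero elsewhere, emulating the fungal
#'   and bacterial hits that male-vs-female screens tend to admit.
#'
#' `baseline_rpkm` is each class's expected RPKM in its "on" condition
#' (the early stage for degrading transcripts, the late stage for
#' activating ones, both for stable ones). `fold_dynamics` is the
#' multiplicative early-to-late change, so the "off" stage sits at
#' `baseline / fold` for activating classes and `baseline * fold` for
#' degrading ones.
#'
#' One late library (by default the first male late replicate,
#' mirroring the study's lagging BJ1 library) can be pulled toward the
#' early profile: its expected value is
#' `(1 - lag_fraction) * late + lag_fraction * early`.
#'
#' @param n_per_class Named integer vector of transcript counts per
#'   class; names must be the five classes above.
#' @param baseline_rpkm Named numeric vector, expected RPKM in the "on"
#'   condition per class.
#' @param fold_dynamics Named numeric vector, multiplicative
#'   early-to-late change per class.
#' @param dispersion Negative-binomial overdispersion (variance
#'   `m + dispersion * m^2`); 0 gives Poisson counts.
#' @param library_size_mean,library_size_sd Mean and spread of the
#'   per-library total read counts.
#' @param transcript_length_range Length-2 vector of bp bounds for
#'   uniform transcript lengths (>= 100 bp).
#' @param lag_fraction Mixing weight in \[0, 1\] pulling the lagging
#'   late library toward the early profile; 0 disables the lag.
#' @param lagging_sample Sample id of the lagging library.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(maternal_stable = 200,
                                       maternal_degrading = 100,
                                       zygotic_shared = 100,
                                       zygotic_male_only = 20,
                                       contaminant_sporadic = 10),
                       baseline_rpkm = c(maternal_stable = 50,
                                         maternal_degrading = 100,
                                         zygotic_shared = 300,
                                         zygotic_male_only = 24,
                                         contaminant_sporadic = 100),
                       fold_dynamics = c(maternal_stable = 1,
                                         maternal_degrading = 0.1,
                                         zygotic_shared = 75,
                                         zygotic_male_only = 60,
                                         contaminant_sporadic = 1),
                       dispersion = 0.05,
                       library_size_mean = 2e6,
                       library_size_sd = 2e5,
                       transcript_length_range = c(200, 5000),
                       lag_fraction = 0,
                       lagging_sample = NULL,
                       seed = 1L) {
  classes <- c("maternal_stable", "maternal_degrading", "zygotic_shared",
               "zygotic_male_only", "contaminant_sporadic")
  fill <- function(x, what, default = 0) {
    if (is.null(names(x)) && length(x) == length(classes)) names(x) <- classes
    bad <- setdiff(names(x), classes)
    if (length(bad)) stop(what, ": unknown class '", bad[1], "'")
    out <- stats::setNames(rep(default, length(classes)), classes)
    out[names(x)] <- x
    out
  }
  cfg <- list(
    classes = classes,
    n_per_class = fill(n_per_class, "n_per_class"),
    baseline_rpkm = fill(baseline_rpkm, "baseline_rpkm"),
    fold_dynamics = fill(fold_dynamics, "fold_dynamics", default = 1),
    dispersion = dispersion,
    library_size_mean = library_size_mean,
    library_size_sd = library_size_sd,
    transcript_length_range = sort(as.numeric(transcript_length_range)),
    lag_fraction = lag_fraction,
    lagging_sample = lagging_sample,
    seed = as.integer(seed)
  )
  if (any(cfg$n_per_class < 0)) stop("invalid n_per_class: must be >= 0")
  if (any(cfg$baseline_rpkm < 0)) stop("invalid baseline_rpkm: must be >= 0")
  if (any(cfg$fold_dynamics <= 0)) stop("invalid fold_dynamics: must be > 0")
  if (cfg$dispersion < 0) stop("invalid dispersion: must be >= 0")
  if (cfg$library_size_mean <= 0) stop("invalid library_size_mean: must be > 0")
  if (cfg$library_size_sd < 0) stop("invalid library_size_sd: must be >= 0")
  if (cfg$transcript_length_range[1] < 100) {
    stop("invalid transcript_length_range: lengths must be >= 100 bp")
  }
  if (cfg$lag_fraction < 0 || cfg$lag_fraction > 1) {
    stop("invalid lag_fraction: must be in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Expected RPKM per transcript class and sample
#'
#' @param config A [sim_config()].
#' @param design A study design (see [study_design()]).
#' @return Numeric matrix, classes x samples, of expected RPKM before
#'   the contaminant's random placement (contaminant row gives its "on"
#'   level in every sample; the realised placement zeroes all but one).
#' @keywords internal
expected_class_rpkm <- function(config, design) {
  samples <- design$sample_id
  m <- matrix(0, length(config$classes), length(samples),
              dimnames = list(config$classes, samples))
  lagging <- config$lagging_sample
  if (is.null(lagging)) {
    late_males <- design$sample_id[design$sex == "male" &
                                   design$stage == "late"]
    lagging <- if (length(late_males)) late_males[1] else NA_character_
  }
  for (cl in config$classes) {
    base <- config$baseline_rpkm[cl]
    fold <- config$fold_dynamics[cl]
    early_v <- if (fold >= 1) base / fold else base
    late_v <- if (fold >= 1) base else base * fold
    for (j in seq_along(samples)) {
      s <- samples[j]
      stage <- design$stage[j]
      v <- if (stage == "early") early_v else late_v
      if (identical(s, lagging) && stage == "late") {
        v <- (1 - config$lag_fraction) * late_v +
          config$lag_fraction * early_v
      }
      if (cl == "zygotic_male_only" && design$sex[j] == "female") v <- 0
      if (cl == "contaminant_sporadic") v <- base
      m[cl, j] <- v
    }
  }
  m
}

#' Simulate a sexed-embryo count matrix with ground truth
#'
#' Counts are drawn per transcript and sample as negative-binomial with
#' mean `expected_RPKM * length * library_size / 1e9` and variance
#' `m + dispersion * m^2` (Poisson when `dispersion = 0`). Library
#' sizes are drawn once per sample around `library_size_mean`.
#'
#' @param config A [sim_config()].
#' @param design A study design (see [study_design()]).
#' @return A list with `counts` (a [count_matrix()] whose `lib_sizes`
#'   are the drawn totals) and `truth` (a list with `labels`, a
#'   data.frame `transcript_id`/`class`, and `expected_rpkm`, the
#'   transcripts x samples expected-value matrix).
#' @export
simulate_counts <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  design <- validate_design(design)
  if (nrow(design) == 0) stop("design must be non-empty")
  samples <- design$sample_id
  withr::with_seed(config$seed, {
    n_total <- sum(config$n_per_class)
    labels <- rep(config$classes, times = config$n_per_class)
    ids <- if (n_total > 0) {
      sprintf("contig_%05d", seq_len(n_total))
    } else character()
    lengths <- stats::setNames(
      round(stats::runif(n_total, config$transcript_length_range[1],
                         config$transcript_length_range[2])), ids)
    lib_sizes <- stats::setNames(
      pmax(1000, round(stats::rnorm(length(samples),
                                    config$library_size_mean,
                                    config$library_size_sd))), samples)
    class_rpkm <- expected_class_rpkm(config, design)
    exp_rpkm <- class_rpkm[labels, , drop = FALSE]
    rownames(exp_rpkm) <- ids
    # contaminants: high in exactly one randomly chosen library
    contam <- which(labels == "contaminant_sporadic")
    for (i in contam) {
      on <- sample(seq_along(samples), 1)
      v <- exp_rpkm[i, on]
      exp_rpkm[i, ] <- 0
      exp_rpkm[i, on] <- v
    }
    mu <- sweep(exp_rpkm * lengths, 2, lib_sizes, `*`) / 1e9
    cnt <- if (config$dispersion == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$dispersion),
             nrow(mu), ncol(mu))
    }
    dimnames(cnt) <- dimnames(exp_rpkm)
    list(
      counts = count_matrix(cnt, lengths, lib_sizes),
      truth = list(
        labels = data.frame(transcript_id = ids, class = labels,
                            stringsAsFactors = FALSE),
        expected_rpkm = exp_rpkm
      )
    )
  })
}

#' Simulate Phred-scored reads for trimmer fixtures
#'
#' @param n_reads Number of reads (>= 0).
#' @param profile Quality profile: `"clean"` (all bases at `head_q`) or
#'   `"bad_tail"` (first `1 - tail_len` fraction at `head_q`, the tail
#'   at `tail_q`, low enough that the trimmer removes it).
#' @param read_length Read length in bases.
#' @param head_q,tail_q Phred scores for the head and (bad) tail.
#' @param tail_len Number of bad-tail bases (profile `"bad_tail"`).
#' @param n_rate Per-base probability of an ambiguous `N` call.
#' @param seed Integer seed.
#' @return A list of [phred_read()] objects.
#' @export
simulate_reads <- function(n_reads, profile = c("clean", "bad_tail"),
                           read_length = 100, head_q = 40, tail_q = 2,
                           tail_len = 20, n_rate = 0, seed = 1L) {
  stopifnot(n_reads >= 0)
  profile <- match.arg(profile)
  if (n_reads == 0) return(list())
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reads), function(i) {
      bases <- sample(c("A", "C", "G", "T"), read_length, replace = TRUE)
      if (n_rate > 0) {
        amb <- stats::runif(read_length) < n_rate
        bases[amb] <- "N"
      }
      quals <- rep(head_q, read_length)
      if (profile == "bad_tail") {
        tl <- min(tail_len, read_length)
        quals[(read_length - tl + 1):read_length] <- tail_q
      }
      phred_read(sprintf("read_%05d", i), paste(bases, collapse = ""),
                 quals)
    })
  })
}
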