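test_that("marker calibration reproduces the sisA-derived threshold", {
  em <- fixture_expression("sexdet")
  early <- paste0("BJ", 5:8)
  cal <- calibrate_threshold(em, "sisA", early)
  expect_equal(cal$baseline_mean, 44.72, tolerance = 1e-6)
  expect_equal(cal$raw, 53.664, tolerance = 1e-6)
  expect_equal(cal$operational, 50)
  # a silent marker floors at 10
  low <- calibrate_threshold(em, "sc", early)
  expect_equal(low$operational, 10)
  expect_error(calibrate_threshold(em, "nope", early), "nope")
  # the female-limited marker dsx stays far below the threshold
  expect_lt(max(em$values["dsx", ]), 1)
})

test_that("up-regulated selection respects significance and direction", {
  de <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    fold_change = c(10, -10, 8, -9),
    fdr_p = c(1e-5, 1e-5, 0.5, 0.9),
    stringsAsFactors = FALSE
  )
  expect_equal(select_upregulated(de), "a")
  expect_equal(select_upregulated(de, direction = "up-in-baseline"), "b")
  expect_equal(sort(select_upregulated(de, direction = "both")),
               c("a", "b"))
  expect_equal(select_upregulated(de[0, ]), character())
})

test_that("the expression filter keeps low-baseline candidates only", {
  em <- fixture_expression("cellularisation")
  early <- paste0("BJ", 5:8)
  # slam's early mean 4.095 clears the study's 50-RPKM bound easily
  res <- apply_expression_filter(c("slam", "srya", "nullo"), em, early, 50)
  expect_equal(sort(res$kept), c("nullo", "slam", "srya"))
  expect_equal(nrow(res$removed), 0)
  # a tighter bound removes srya (early mean 11.2325) with a reason
  res10 <- apply_expression_filter(c("slam", "srya"), em, early, 10)
  expect_equal(res10$kept, "slam")
  expect_equal(res10$removed$transcript_id, "srya")
  expect_match(res10$removed$reason, ">= 10")
  expect_error(apply_expression_filter("ghost", em, early, 50), "ghost")
  empty <- apply_expression_filter(character(), em, early, 50)
  expect_equal(empty$kept, character())
})

test_that("the intersection screen computes (I ∩ L) - (I ∩ L ∩ N)", {
  res <- intersect_screen(set_i = c("a", "b", "c", "d"),
                          set_l = c("b", "c", "e"),
                          set_n = c("c", "f"))
  expect_equal(sort(res$i_and_l), c("b", "c"))
  expect_equal(res$i_and_l_and_n, "c")
  expect_equal(res$final, "b")
  prov <- res$provenance
  expect_equal(prov$outcome[prov$transcript_id == "b"], "final")
  expect_equal(prov$outcome[prov$transcript_id == "c"],
               "removed: up in females")
  expect_equal(prov$outcome[prov$transcript_id == "a"],
               "removed: not in male-only set")
  expect_equal(prov$outcome[prov$transcript_id == "e"],
               "removed: not in replicated set")
  expect_equal(prov$outcome[prov$transcript_id == "f"],
               "removed: only in female set")
  # all-empty inputs
  none <- intersect_screen(character(), character(), character())
  expect_equal(none$final, character())
})

test_that("expression filters commute", {
  em <- fixture_expression("sexdet")
  cands <- rownames(em$values)
  f1 <- function(x) apply_expression_filter(x, em, paste0("BJ", 5:8), 20)$kept
  f2 <- function(x) apply_expression_filter(x, em, paste0("BJ", 3:4), 40)$kept
  expect_equal(sort(f1(f2(cands))), sort(f2(f1(cands))))
})

test_that("profile classification follows the threshold and floor rules", {
  cls <- classify_profile(
    early_mean = c(4.095, 11.23, 0.1, 60, 0.1, 100),
    late_mean = c(305.3, 4.1, 0.1, 200, 10, 101),
    q = c(1e-10, 0.5, 1, 1e-10, 0.5, 0.5),
    maternal_threshold = 50
  )
  expect_equal(cls, c("zygotic",      # silent early, strong late rise
                      "maternal",     # deposited, degrading, not sig up
                      "undetected",   # below floor in both stages
                      "maternal_plus_zygotic",
                      "ambiguous",    # late-only but not significant
                      "maternal"))    # high both stages, flat
  # floor boundary: early exactly at the floor counts as detected
  expect_equal(classify_profile(0.25, 0.1, 0.5, 50), "maternal")
})

test_that("the default screen configuration encodes the comparison table", {
  cfg <- screen_config()
  expect_equal(names(cfg$comparisons), LETTERS[1:14])
  expect_equal(cfg$comparisons$I$case, paste0("BJ", 2:4))
  expect_equal(cfg$comparisons$I$baseline, paste0("BJ", 6:8))
  expect_equal(cfg$comparisons$L$case, "BJ2")
  expect_equal(cfg$comparisons$L$baseline, "BJ6")
  expect_equal(cfg$comparisons$N$case, c("BJ3", "BJ4"))
  expect_equal(cfg$comparisons$N$baseline, c("BJ7", "BJ8"))
  expect_equal(cfg$comparisons$B$filter$bound, 5)
  expect_equal(cfg$comparisons$I$filter$bound, 50)
  expect_null(cfg$comparisons$A$filter)
  expect_equal(unlist(cfg$intersection), c(i = "I", l = "L", n = "N"))
  expect_equal(cfg$comparisons$L$ref, "normal")
})

test_that("the full screen recovers planted zygotic transcripts", {
  design <- study_design()
  sim <- simulate_counts(sim_config(seed = 7), design)
  truth <- sim$truth$labels
  res <- suppressMessages(run_full_screen(sim$counts, design))
  by_class <- split(truth$transcript_id, truth$class)

  # the replicated time contrast I recovers almost all shared zygotic
  # transcripts after the early-expression filter
  hit_i <- intersect(res$comparisons$I$of_interest,
                     by_class$zygotic_shared)
  expect_gte(length(hit_i) / length(by_class$zygotic_shared), 0.95)

  # the final intersection set contains only truly zygotic transcripts
  expect_gt(length(res$final), 0)
  expect_true(all(res$final %in% c(by_class$zygotic_shared,
                                   by_class$zygotic_male_only)))
  expect_length(intersect(res$final, by_class$maternal_stable), 0)
  expect_length(intersect(res$final, by_class$maternal_degrading), 0)
  expect_length(intersect(res$final, by_class$contaminant_sporadic), 0)

  # the single-male-library contrasts admit sporadic contaminants, as
  # the original male-vs-female screens did
  bd <- union(res$comparisons$B$of_interest, res$comparisons$D$of_interest)
  expect_gt(length(intersect(bd, by_class$contaminant_sporadic)), 0)
  # B (late male vs late females) recovers most male-limited transcripts
  expect_gte(length(intersect(res$comparisons$B$of_interest,
                              by_class$zygotic_male_only)) /
               length(by_class$zygotic_male_only), 0.8)

  # whole-group sex contrasts find nothing: the sexes share the
  # transcriptome at these stages apart from the male-limited handful
  expect_equal(res$comparisons$E$n_of_interest, 0)

  # summary mirrors the comparison table
  expect_equal(nrow(res$summary), 14)
  expect_equal(res$summary$n_of_interest[res$summary$comparison == "I"],
               res$comparisons$I$n_of_interest)

  # provenance is complete: every transcript significant anywhere that
  # misses the final set carries a recorded reason somewhere
  sig_any <- unique(unlist(lapply(res$comparisons, `[[`, "significant")))
  lost <- setdiff(sig_any, res$final)
  accounted <- union(res$removed$transcript_id,
                     res$intersections$provenance$transcript_id)
  expect_length(setdiff(lost, accounted), 0)
})

test_that("the screen reports unreplicated comparisons and bad designs", {
  design <- study_design()
  sim <- simulate_counts(
    sim_config(n_per_class = c(maternal_stable = 30), seed = 13), design)
  suppressMessages(
    expect_message(run_full_screen(sim$counts, design), "unreplicated"))
  half <- design[design$stage == "late", ]
  expect_error(suppressMessages(run_full_screen(sim$counts, half)))
})
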