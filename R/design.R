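#' The eight-library sexed embryo study design
#'
#' Returns the fixed two-sex, two-stage, two-replicate layout used
#' throughout the pipeline: BJ1, BJ2 male late (3-5h AEL); BJ3, BJ4
#' female late; BJ5, BJ6 male early (2-3h AEL); BJ7, BJ8 female early.
#'
#' @return A `data.frame` with columns `sample_id`, `sex`
#'   (`"male"`/`"female"`), `stage` (`"early"`/`"late"`), `replicate`
#'   (integer within sex-stage cell) and `include` (logical).
#' @examples
#' study_design()
#' @export
study_design <- function() {
  d <- data.frame(
    sample_id = paste0("BJ", 1:8),
    sex = c("male", "male", "female", "female",
            "male", "male", "female", "female"),
    stage = c("late", "late", "late", "late",
              "early", "early", "early", "early"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
    include = TRUE,
    stringsAsFactors = FALSE
  )
  validate_design(d)
}

#' Validate a study design table
#'
#' @param design A data.frame with at least `sample_id`, `sex`, `stage`,
#'   `replicate` columns. A `library_size` column is optional.
#' @param full_screen If `TRUE`, additionally require every sex-by-stage
#'   cell to be non-empty (needed by [run_full_screen()]).
#' @return The validated design (invisibly usable), with `include`
#'   defaulted to `TRUE` when absent.
#' @export
validate_design <- function(design, full_screen = FALSE) {
  req <- c("sample_id", "sex", "stage", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss)) {
    stop("design is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    dup <- design$sample_id[duplicated(design$sample_id)][1]
    stop("duplicate sample_id in design: ", dup)
  }
  bad_sex <- setdiff(unique(design$sex), c("male", "female"))
  if (length(bad_sex)) {
    stop("unknown sex token(s) in design: ", paste(bad_sex, collapse = ", "),
         " (expected 'male' or 'female')")
  }
  bad_stage <- setdiff(unique(design$stage), c("early", "late"))
  if (length(bad_stage)) {
    stop("unknown stage token(s) in design: ", paste(bad_stage, collapse = ", "),
         " (expected 'early' or 'late')")
  }
  if (is.null(design$include)) design$include <- TRUE
  if (full_screen) {
    cells <- table(design$sex[design$include], design$stage[design$include])
    if (length(cells) < 4 || any(cells == 0)) {
      stop("full-screen mode requires every sex-by-stage cell to be non-empty")
    }
  }
  design
}

#' Read a study design table from TSV
#'
#' The file must be tab-delimited with a header containing `sample_id`,
#' `sex`, `stage`, `replicate` and optionally `library_size`.
#'
#' @param path Path to the TSV file (gzip accepted).
#' @return A validated design `data.frame` (see [study_design()]).
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "sex", "stage", "replicate")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("design file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) {
    i <- which(duplicated(d$sample_id))[1]
    stop("design file ", path, ": duplicate sample_id '", d$sample_id[i],
         "' at line ", i + 1L)
  }
  bad <- which(!d$sex %in% c("male", "female"))
  if (length(bad)) {
    stop("design file ", path, ": unknown sex '", d$sex[bad[1]],
         "' at line ", bad[1] + 1L)
  }
  bad <- which(!d$stage %in% c("early", "late"))
  if (length(bad)) {
    stop("design file ", path, ": unknown stage '", d$stage[bad[1]],
         "' at line ", bad[1] + 1L)
  }
  validate_design(d)
}

#' Samples of a design matching a sex and/or stage
#'
#' @param design A design data.frame.
#' @param sex,stage Optional filters (`"male"`, `"female"`, `"early"`,
#'   `"late"`).
#' @param included_only Drop samples with `include == FALSE`.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, sex = NULL, stage = NULL,
                           included_only = TRUE) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(sex)) keep <- keep & design$sex %in% sex
  if (!is.null(stage)) keep <- keep & design$stage %in% stage
  if (included_only && !is.null(design$include)) keep <- keep & design$include
  design$sample_id[keep]
}
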