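#' Atomically write lines/table helpers
#'
#' All tabular output is tab-delimited UTF-8 with '.' decimal marks and
#' is written via a temp file + rename so interrupted runs never leave
#' truncated files.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 6).
#' @export
write_table_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

#' Write a count matrix to TSV
#'
#' Columns: `transcript_id`, `length_bp`, then one integer column per
#' sample. Library sizes are stored on a leading `#lib_sizes` comment
#' line so a write/read round trip is lossless.
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  ids <- rownames(cm$counts)
  if (is.null(ids)) ids <- character(nrow(cm$counts))
  df <- data.frame(transcript_id = ids,
                   length_bp = as.integer(cm$lengths),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (s in colnames(cm$counts)) df[[s]] <- as.integer(cm$counts[, s])
  tmp <- tempfile(tmpdir = dirname(path))
  header <- paste0("#lib_sizes\t",
                   paste(names(cm$lib_sizes), cm$lib_sizes,
                         sep = "=", collapse = "\t"))
  con <- file(tmp, "w", encoding = "UTF-8")
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Expects the layout written by [write_counts()]; when no `#lib_sizes`
#' comment is present, library sizes are inferred as column sums (or
#' taken from `lib_sizes_path`, a two-column `sample_id`/`library_size`
#' TSV).
#'
#' @param path Counts TSV path (gzip accepted).
#' @param lib_sizes_path Optional TSV with explicit library sizes.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, lib_sizes_path = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  first <- readLines(path, n = 1)
  lib_sizes <- NULL
  if (startsWith(first, "#lib_sizes")) {
    kv <- strsplit(strsplit(first, "\t")[[1]][-1], "=")
    lib_sizes <- stats::setNames(
      as.numeric(vapply(kv, `[`, character(1), 2)),
      vapply(kv, `[`, character(1), 1))
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("transcript_id", "length_bp")
  if (!all(req %in% names(df))) {
    stop("counts file ", path,
         ": expected columns transcript_id, length_bp, <samples>")
  }
  samples <- setdiff(names(df), req)
  if (length(samples) == 0) stop("counts file ", path, ": no sample columns")
  m <- as.matrix(df[samples])
  rownames(m) <- df$transcript_id
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("counts file ", path, ": invalid count at transcript '",
         rownames(m)[bad[1, 1]], "', sample '", samples[bad[1, 2]], "'")
  }
  if (any(df$length_bp < 1)) {
    stop("counts file ", path, ": length < 1 for transcript '",
         df$transcript_id[which(df$length_bp < 1)[1]], "'")
  }
  if (!is.null(lib_sizes_path)) {
    ls_df <- utils::read.delim(lib_sizes_path, stringsAsFactors = FALSE)
    lib_sizes <- stats::setNames(as.numeric(ls_df$library_size),
                                 ls_df$sample_id)[samples]
  }
  count_matrix(m, df$length_bp, lib_sizes)
}

#' Write an expression matrix to TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(transcript_id = rownames(expr$values),
                   expr$values, stringsAsFactors = FALSE,
                   check.names = FALSE)
  write_table_tsv(df, path)
}

#' Read a pipeline/simulation configuration (YAML or JSON)
#'
#' Unknown top-level keys are rejected.
#'
#' @param path Config path ending in `.yaml`, `.yml` or `.json`.
#' @param allowed Character vector of permitted keys; `NULL` skips the
#'   check.
#' @return Named list.
#' @export
read_config <- function(path, allowed = NULL) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(allowed)) {
    bad <- setdiff(names(cfg), allowed)
    if (length(bad)) {
      stop("config ", path, ": unknown key(s): ", paste(bad, collapse = ", "))
    }
  }
  cfg
}

#' Load a bundled expression fixture
#'
#' Small worked-example matrices shipped with the package as plain TSV:
#' `"sexdet"` (the 20 sex-determination transcript profiles),
#' `"cellularisation"` (the three cellularisation transcript profiles,
#' including the slam-like zygotic riser) and `"male_up"` (the male
#' up-regulated candidates from the late- and early-stage male-vs-female
#' comparisons). All values are normalised RPKM.
#'
#' @param name One of `"sexdet"`, `"cellularisation"`, `"male_up"`.
#' @return A data.frame.
#' @export
load_fixture <- function(name = c("sexdet", "cellularisation", "male_up")) {
  name <- match.arg(name)
  fn <- c(sexdet = "sexdet_expression.tsv",
          cellularisation = "cellularisation_expression.tsv",
          male_up = "male_up_candidates.tsv")[[name]]
  path <- system.file("extdata", fn, package = "mztscreen",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled fixture as an expression matrix
#'
#' @param name Fixture name, see [load_fixture()].
#' @return An [expression_matrix()] (values flagged as normalised: the
#'   fixture values are already quantile-normalised over the 8-sample
#'   early-vs-late comparison scope).
#' @export
fixture_expression <- function(name = c("sexdet", "cellularisation")) {
  name <- match.arg(name)
  df <- load_fixture(name)
  samples <- grep("^BJ", names(df), value = TRUE)
  m <- as.matrix(df[samples])
  rownames(m) <- df$transcript
  expression_matrix(m, normalised = TRUE, scope = samples)
}
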