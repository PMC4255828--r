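#' A sequencing read with per-base Phred qualities
#'
#' @param id Read identifier.
#' @param bases Nucleotide string over `{A, C, G, T, N}`.
#' @param qualities Integer vector of Phred scores (>= 0), one per base;
#'   the base-call error probability is `10^(-Q/10)`.
#' @return An object of class `phred_read`.
#' @export
phred_read <- function(id, bases, qualities) {
  bases <- toupper(as.character(bases))
  if (nchar(bases) != length(qualities)) {
    stop("read '", id, "': bases and qualities differ in length")
  }
  if (length(qualities) && any(qualities < 0)) {
    stop("read '", id, "': negative Phred score")
  }
  structure(list(id = id, bases = bases,
                 qualities = as.integer(qualities)),
            class = "phred_read")
}

#' @export
print.phred_read <- function(x, ...) {
  cat("phred_read", x$id, "(", nchar(x$bases), "bp )\n")
  invisible(x)
}

#' Modified Mott quality trimming
#'
#' Scores every base as `limit - 10^(-Q/10)` and retains the contiguous
#' segment maximising the score sum (a maximum-scoring-subsequence
#' search, so both read ends can be trimmed). When no segment has a
#' positive score sum the whole read is trimmed away. Among equal-score
#' maximal segments the leftmost is kept, and among those the longest
#' (trailing zero-score bases are retained).
#'
#' @param read A [phred_read()], or a bare integer vector of Phred
#'   scores.
#' @param limit Error-probability limit in (0, 1); default 0.05.
#' @return Integer vector `c(start, end)`, a 0-based half-open interval
#'   into the read; `c(0, 0)` when everything is trimmed.
#' @examples
#' mott_trim(c(2, 2, 40, 40, 40, 2))  # c(2, 5)
#' @export
mott_trim <- function(read, limit = 0.05) {
  if (limit <= 0 || limit >= 1) stop("limit must be in (0, 1)")
  q <- if (inherits(read, "phred_read")) read$qualities else as.numeric(read)
  n <- length(q)
  if (n == 0) return(c(0L, 0L))
  s <- limit - 10^(-q / 10)
  tol <- 1e-12
  best <- 0; bs <- 0L; be <- 0L
  cur <- 0; cs <- 0L
  for (i in seq_len(n)) {
    cur <- cur + s[i]
    if (cur > best + tol) {
      best <- cur; bs <- cs; be <- i
    } else if (best > tol && abs(cur - best) <= tol &&
               cs == bs && i > be) {
      be <- i  # same start, same score, longer: extend
    }
    if (cur < -tol) {
      cur <- 0; cs <- i
    }
  }
  if (best <= tol) return(c(0L, 0L))
  c(bs, be)
}

#' Apply Mott trimming to a read
#'
#' @param read A [phred_read()].
#' @param limit Error-probability limit, see [mott_trim()].
#' @return The trimmed [phred_read()] (possibly empty).
#' @export
trim_read <- function(read, limit = 0.05) {
  iv <- mott_trim(read, limit)
  if (iv[2] <= iv[1]) {
    return(phred_read(read$id, "", integer()))
  }
  phred_read(read$id,
             substr(read$bases, iv[1] + 1L, iv[2]),
             read$qualities[(iv[1] + 1L):iv[2]])
}

#' Post-trim read filter
#'
#' Discards a (trimmed) read when it contains more than `max_ambiguous`
#' ambiguous `N` bases or is shorter than `min_len` nucleotides.
#'
#' @param read A [phred_read()], already trimmed.
#' @param max_ambiguous Maximum number of `N` bases allowed (default 2).
#' @param min_len Minimum read length in nucleotides (default 50).
#' @return List with `keep` (logical) and `reason` (`NA`, `"length"` or
#'   `"ambiguity"`; length is checked first).
#' @export
filter_read <- function(read, max_ambiguous = 2, min_len = 50) {
  len <- nchar(read$bases)
  if (len < min_len) {
    return(list(keep = FALSE, reason = "length"))
  }
  n_amb <- lengths(regmatches(read$bases, gregexpr("N", read$bases,
                                                   fixed = TRUE)))
  if (n_amb > max_ambiguous) {
    return(list(keep = FALSE, reason = "ambiguity"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Trim and filter a FASTQ file
#'
#' Reads a FASTQ stream (gzip accepted), Mott-trims every read, applies
#' the ambiguity/length filter to the trimmed read, and writes the
#' survivors. In paired mode (`in2`/`out2`) both mates must survive for
#' the pair to be emitted; a surviving mate whose partner was discarded
#' is written to `broken` when given, otherwise dropped, and counted in
#' `broken_pairs`.
#'
#' @param infile Input FASTQ path (`.gz` accepted).
#' @param outfile Output FASTQ path for kept reads; `NULL` to skip
#'   writing.
#' @param limit,max_ambiguous,min_len Trimming/filter parameters, see
#'   [mott_trim()] and [filter_read()].
#' @param in2,out2 Optional mate FASTQ input/output for paired mode.
#' @param broken Optional output path for surviving orphan mates.
#' @param encoding FASTQ quality encoding, `"phred33"` (default) or
#'   `"phred64"`.
#' @return Summary list: `reads_in`, `reads_kept`, `bases_removed`
#'   (bases removed by trimming, summed over all input reads) and, in
#'   paired mode, `broken_pairs`.
#' @export
process_fastq <- function(infile, outfile = NULL, limit = 0.05,
                          max_ambiguous = 2, min_len = 50,
                          in2 = NULL, out2 = NULL, broken = NULL,
                          encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  r1 <- read_fastq(infile, encoding)
  paired <- !is.null(in2)
  r2 <- if (paired) read_fastq(in2, encoding) else NULL
  if (paired && length(r1) != length(r2)) {
    stop("paired inputs differ in read count (", length(r1), " vs ",
         length(r2), ")")
  }
  run_one <- function(reads) {
    kept <- vector("list", length(reads))
    ok <- logical(length(reads))
    removed <- 0
    for (i in seq_along(reads)) {
      tr <- trim_read(reads[[i]], limit)
      removed <- removed + (nchar(reads[[i]]$bases) - nchar(tr$bases))
      f <- filter_read(tr, max_ambiguous, min_len)
      ok[i] <- f$keep
      kept[[i]] <- tr
    }
    list(reads = kept, ok = ok, removed = removed)
  }
  a <- run_one(r1)
  summary <- list(reads_in = length(r1) + if (paired) length(r2) else 0L,
                  reads_kept = 0L, bases_removed = a$removed)
  if (!paired) {
    summary$reads_kept <- sum(a$ok)
    if (!is.null(outfile)) write_fastq(a$reads[a$ok], outfile, encoding)
  } else {
    b <- run_one(r2)
    summary$bases_removed <- summary$bases_removed + b$removed
    both <- a$ok & b$ok
    orphan1 <- a$ok & !b$ok
    orphan2 <- b$ok & !a$ok
    summary$reads_kept <- 2L * sum(both) +
      if (!is.null(broken)) sum(orphan1) + sum(orphan2) else 0L
    summary$broken_pairs <- sum(orphan1) + sum(orphan2)
    if (!is.null(outfile)) write_fastq(a$reads[both], outfile, encoding)
    if (!is.null(out2)) write_fastq(b$reads[both], out2, encoding)
    if (!is.null(broken)) {
      write_fastq(c(a$reads[orphan1], b$reads[orphan2]), broken, encoding)
    }
  }
  summary
}

# Structural FASTQ check: 4-line records with matching sequence and
# quality lengths. Guards against silently corrupt parses of records
# whose quality string is shorter than the sequence.
validate_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ in '", path,
         "': line count is not a multiple of 4")
  }
  n <- length(lines) %/% 4
  if (n == 0) return(invisible(TRUE))
  heads <- lines[seq(1, by = 4, length.out = n)]
  seps <- lines[seq(3, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ in '", path, "': record ", bad[1],
         " (", sub("^@", "", heads[bad[1]]),
         ") has a bad marker or mismatched sequence/quality length")
  }
  invisible(TRUE)
}

#' Read a FASTQ file into a list of phred_read objects
#'
#' @param path FASTQ path (gzip accepted).
#' @param encoding `"phred33"` or `"phred64"`.
#' @return List of [phred_read()].
#' @export
read_fastq <- function(path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  scoring <- if (encoding == "phred33") "phred" else "illumina"
  validate_fastq_structure(path)
  parsed <- withCallingHandlers(
    tryCatch({
      x <- Biostrings::readQualityScaledDNAStringSet(
        path, quality.scoring = scoring)
      list(x = x,
           quals = as(Biostrings::quality(x), "IntegerList"),
           seqs = as.character(x))
    },
      error = function(e) {
        stop("malformed FASTQ in '", path, "': ", conditionMessage(e))
      }
    ),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  x <- parsed$x
  quals <- parsed$quals
  seqs <- parsed$seqs
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("read_", seq_along(x))
  lapply(seq_along(x), function(i) {
    phred_read(ids[i], seqs[i], quals[[i]])
  })
}

#' Write phred_read objects to FASTQ
#'
#' Written atomically (temp file then rename). Empty reads are written
#' as zero-length records.
#'
#' @param reads List of [phred_read()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param encoding `"phred33"` or `"phred64"`.
#' @export
write_fastq <- function(reads, path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  offset <- if (encoding == "phred33") 33L else 64L
  tmp <- tempfile(tmpdir = dirname(path))
  con <- if (grepl("\\.gz$", path)) gzfile(tmp, "w") else file(tmp, "w")
  closed <- FALSE
  on.exit({
    if (!closed) close(con)
    if (file.exists(tmp)) unlink(tmp)
  })
  for (r in reads) {
    qual <- intToUtf8(pmin(r$qualities, 93L) + offset, multiple = FALSE)
    writeLines(c(paste0("@", r$id), r$bases, "+", qual), con)
  }
  close(con)
  closed <- TRUE
  file.rename(tmp, path)
  invisible(path)
}
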