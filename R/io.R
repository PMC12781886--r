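#' Read a delimited expression table
#'
#' Reads a tab-delimited expression table with a header row. The long
#' dialect requires columns `condition`, `target`, `replicate`, `value`
#' (optional extras such as `position`, `fraction` or `time` are kept);
#' the wide dialect expects `condition` and `replicate` followed by one
#' numeric column per target and is reshaped to long form. Validation
#' errors name the offending columns or rows.
#'
#' @param path File path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return A validated long-format data frame.
#' @export
read_expression_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "wide") {
    key <- c("condition", "replicate")
    missing <- setdiff(key, names(tab))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    targets <- setdiff(names(tab), key)
    if (length(targets) == 0L) stop("no target columns found", call. = FALSE)
    tab <- do.call(rbind, lapply(targets, function(tg) {
      data.frame(condition = tab$condition, target = tg,
                 replicate = tab$replicate, value = tab[[tg]])
    }))
  }
  need <- c("condition", "target", "replicate", "value")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(tab$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$value))))
    stop("malformed numeric value(s) in rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(tab$condition, tab$target, tab$replicate,
               if ("position" %in% names(tab)) tab$position else "",
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (condition, target, replicate) rows: ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Write an expression table
#'
#' Writes a long-format expression table as UTF-8 tab-delimited text with
#' a header row; `read_expression_table()` of the result is the identity.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a tiling profile as a delimited table
#'
#' Long layout with one row per position and replicate, columns
#' `fraction`, `position`, `replicate`, `value`.
#'
#' @param profile A `tiling_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiling_table <- function(profile, path) {
  stopifnot(inherits(profile, "tiling_profile"))
  reps <- attr(profile, "replicates")
  long <- data.frame(
    fraction = attr(profile, "fraction"),
    position = rep(profile$position, ncol(reps)),
    replicate = rep(seq_len(ncol(reps)), each = nrow(reps)),
    value = as.vector(reps)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a decay course as a delimited table
#'
#' Columns `time`, `mean`, `sd`, `n`.
#'
#' @param course A [decay_course()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decay_table <- function(course, path) {
  stopifnot(inherits(course, "decay_course"))
  utils::write.table(as.data.frame(course), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a decay course table
#'
#' @param path Tab-delimited file with columns `time`, `mean`, `sd`
#'   (optional `n`).
#' @return A [decay_course()].
#' @export
read_decay_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("time", "mean", "sd")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  decay_course(tab$time, tab$mean, tab$sd,
               if ("n" %in% names(tab)) tab$n else NA_integer_)
}
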