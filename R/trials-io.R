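TRIALS_SCHEMA <- c(participant = "character", group = "character",
                   block = "integer", disparity_deg = "double",
                   disparity_norm = "double", advice = "character",
                   advice_correct = "logical", response = "character",
                   rt_s = "double", conformed = "logical",
                   excluded = "logical", exclude_reason = "character")

#' Write a trial table to the canonical CSV format
#'
#' Canonical columns: participant, group, block, disparity_deg,
#' disparity_norm, advice, advice_correct, response, rt_s, conformed,
#' excluded, exclude_reason.  Reaction times are serialized with 8
#' significant digits so threshold comparisons (e.g. the 8 s limit)
#' survive a round trip; excluded rows are written too, as an audit
#' trail.
#'
#' @param trials A trial data frame carrying at least the canonical
#'   columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(names(TRIALS_SCHEMA), names(trials))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- trials[, names(TRIALS_SCHEMA)]
  for (col in c("disparity_deg", "disparity_norm", "rt_s"))
    out[[col]] <- signif(out[[col]], 8)
  # an absent reason is serialized as an empty field either way
  out$exclude_reason[!is.na(out$exclude_reason) &
                       !nzchar(out$exclude_reason)] <- NA_character_
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a canonical trial CSV
#'
#' Validates the schema: a missing required column is an error naming it;
#' unknown extra columns produce a warning and are kept; a value that
#' cannot be parsed under the column's type is an error naming the line.
#' By default excluded rows are retained (set `drop_excluded = TRUE` for
#' the analysis view).
#'
#' @param path Input CSV path.
#' @param drop_excluded Drop rows flagged `excluded`.
#' @return A trial data frame.
#' @export
read_trials <- function(path, drop_excluded = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         fileEncoding = "UTF-8", na.strings = NULL)
  missing_cols <- setdiff(names(TRIALS_SCHEMA), names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(raw), names(TRIALS_SCHEMA))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  parse_col <- function(x, type, name) {
    blank <- !nzchar(x) | x == "NA"
    val <- switch(type,
                  character = x,
                  integer = suppressWarnings(as.integer(x)),
                  double = suppressWarnings(as.numeric(x)),
                  logical = suppressWarnings(as.logical(x)))
    bad <- which(is.na(val) & !blank &
                   !(type == "character"))
    if (length(bad))
      stop(sprintf("column '%s': cannot parse value '%s' as %s at line %d",
                   name, x[bad[1]], type, bad[1] + 1L), call. = FALSE)
    val[blank] <- NA
    val
  }
  out <- raw
  for (col in names(TRIALS_SCHEMA))
    out[[col]] <- parse_col(raw[[col]], TRIALS_SCHEMA[[col]], col)
  # blank reason/response means "none", not missing-by-accident
  out$exclude_reason[is.na(out$exclude_reason)] <- ""
  if (any(is.na(out$excluded)))
    stop("column 'excluded': missing value at line ",
         which(is.na(out$excluded))[1] + 1L, call. = FALSE)
  if (drop_excluded) out <- out[!out$excluded, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-participant psychometric fits table
#'
#' Serializes the output of [psychometric_summary()] to CSV with the
#' canonical columns participant, group, mu_left, mu_right, sigma, shift,
#' adj_r2_one, adj_r2_two, p_two_vs_one, ci_low, ci_high, converged.
#'
#' @param fits The fits table from [psychometric_summary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psych_fits <- function(fits, path) {
  cols <- c("participant", "group", "mu_left", "mu_right", "sigma",
            "shift", "adj_r2_one", "adj_r2_two", "p_two_vs_one",
            "ci_low", "ci_high", "converged")
  missing_cols <- setdiff(cols, names(fits))
  if (length(missing_cols))
    stop("fits table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(fits[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
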