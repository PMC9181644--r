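# Delimited-table I/O: comma-separated values with '#'-prefixed metadata
# header lines echoing the configuration that produced them.

#' Write a result table with metadata header
#'
#' Writes `#`-prefixed `key: value` metadata lines (configuration echo,
#' package version, seed) followed by a CSV body.
#'
#' @param df A data frame.
#' @param path Output file.
#' @param meta Named list of metadata entries; nested lists are
#'   flattened with dotted keys.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, meta = list()) {
  stopifnot(is.data.frame(df))
  flat <- flatten_meta(c(list(package = paste0(
    "ionrbe ", as.character(utils::packageVersion("ionrbe")))), meta))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(flat))
    writeLines(sprintf("# %s: %s", k,
                       paste(format(flat[[k]]), collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

flatten_meta <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    v <- x[[k]]
    if (is.list(v)) out <- c(out, flatten_meta(v, key))
    else if (!is.null(v)) out[[key]] <- v
  }
  out
}

#' Read a result table written by [write_result_table()]
#'
#' @param path File path.
#' @return A data frame; metadata lines are attached as attribute
#'   `"meta"` (character vector).
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  meta <- sub("^# ", "", grep("^#", lines, value = TRUE))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  attr(df, "meta") <- meta
  df
}

#' Read a TD50-vs-fractionation table
#'
#' Two-column delimited input for [fit_lethality()]: header row with
#' columns `n_fractions` and `td50_gy`, `#` comment lines allowed.
#'
#' @param path File path.
#' @return Data frame with columns `n_fractions`, `td50_gy`.
#' @export
read_td50_table <- function(path) {
  df <- read_result_table(path)
  need <- c("n_fractions", "td50_gy")
  if (!all(need %in% names(df)))
    stop("TD50 table must have columns: ", paste(need, collapse = ", "))
  if (any(df$td50_gy <= 0) || any(df$n_fractions < 1))
    stop("TD50 table contains non-positive doses or fraction counts")
  df[need]
}
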