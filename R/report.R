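#' Write a result table
#'
#' Deterministic writer for the package's result tables: CSV (fixed column
#' order, `NA` as empty) or JSON (column-wise, lossless round trip).
#' Writing the same table twice produces byte-identical files.
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(table, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a questionnaire rank table
#'
#' Expected CSV columns: `respondent_id`, `group`, then one integer
#' column per ranked item.
#'
#' @param path CSV path.
#' @return A data.frame; item columns are everything after the first two.
#' @export
read_ranks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "group")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop("rank table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(x) <= 2L) stop("rank table has no item columns", call. = FALSE)
  x
}

#' Serialise a subgroup model to JSON
#'
#' @param model A `subgroup_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subgroup_model <- function(model, path) {
  stopifnot(inherits(model, "subgroup_model"))
  keep <- model[c("k", "slopes", "intercepts", "weights", "residual_sd",
                  "loglik", "converged", "n_iter", "seed")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a subgroup model from JSON
#'
#' @param path Path written by [write_subgroup_model()].
#' @return A `subgroup_model`.
#' @export
read_subgroup_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$k <- as.integer(m$k)
  class(m) <- "subgroup_model"
  m
}
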