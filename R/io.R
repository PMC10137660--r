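#' Read and write joint tables, sample matrices and couplings
#'
#' Joint tables travel as TSV (one state per row: a column per variable plus
#' `prob`) or as an equivalent JSON document with `variables`, `arities`,
#' `states` and `prob` fields; doubles are written with enough digits to
#' round-trip bit-exactly. Sample matrices are headered CSV/TSV of integer
#' codes. Ising couplings are a JSON object mapping comma-joined, sorted
#' variable lists to reals.
#'
#' @param path File path; format follows the extension (`.json` vs `.tsv`/
#'   `.csv`) unless `format` is given.
#' @param x Object to write.
#' @param format `"tsv"`, `"csv"` or `"json"` where applicable.
#' @param arities Optional arities override when reading.
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @name mfi_io
NULL

guess_format <- function(path, format = NULL) {
  if (!is.null(format)) return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "tsv", "csv")) ext else "tsv"
}

#' @rdname mfi_io
#' @export
read_joint_table <- function(path, format = NULL, arities = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path),
                                class = "mfi_error_io")
  fmt <- guess_format(path, format)
  if (fmt == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    states <- matrix(as.integer(doc$states), ncol = length(doc$variables),
                     byrow = FALSE, dimnames = list(NULL, doc$variables))
    df <- tibble::as_tibble(as.data.frame(states))
    df$prob <- as.numeric(doc$prob)
    joint_table(df, arities = stats::setNames(as.integer(doc$arities), doc$variables))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(df) == 0) abort("Empty joint-table file.", class = "mfi_error_io")
    joint_table(df, arities = arities)
  }
}

#' @rdname mfi_io
#' @export
write_joint_table <- function(x, path, format = NULL) {
  assert_joint_table(x)
  fmt <- guess_format(path, format)
  if (fmt == "json") {
    doc <- list(
      variables = jt_vars(x),
      arities = unname(jt_arities(x)),
      states = as.matrix(x[jt_vars(x)]),
      prob = x$prob
    )
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE)
  } else {
    readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname mfi_io
#' @export
read_sample_matrix <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path),
                                class = "mfi_error_io")
  fmt <- guess_format(path, format)
  reader <- if (fmt == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort("Empty sample file.", class = "mfi_error_empty")
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    abort(sprintf("Non-numeric sample column `%s`.", names(df)[bad[1]]),
          class = "mfi_error_io")
  }
  df
}

#' @rdname mfi_io
#' @export
write_sample_matrix <- function(x, path, format = NULL) {
  fmt <- guess_format(path, format)
  writer <- if (fmt == "csv") readr::write_csv else readr::write_tsv
  writer(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname mfi_io
#' @export
read_couplings <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(doc) == 0) return(stats::setNames(numeric(0), character(0)))
  vals <- vapply(doc, as.numeric, numeric(1))
  names(vals) <- vapply(strsplit(names(doc), "[,:]"), function(v)
    paste(trimws(v), collapse = ":"), character(1))
  vals
}

#' @rdname mfi_io
#' @export
write_couplings <- function(x, path) {
  keys <- vapply(strsplit(names(x), ":", fixed = TRUE), function(v)
    paste(sort(v), collapse = ","), character(1))
  jsonlite::write_json(as.list(stats::setNames(unname(x), keys)), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
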