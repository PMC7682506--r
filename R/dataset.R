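#' Read a rectangular dataset with missing-value markers
#'
#' Reads a delimited text table into a data frame, mapping the declared
#' missing-value token to `NA`. `NA` is the single package-wide missing
#' marker: imputers fill `NA` cells and never touch observed ones.
#'
#' @param path Path to a CSV file.
#' @param na Character token(s) encoding missing values. Default `"NA"`
#'   (empty fields are always treated as missing).
#' @param binary Optional character vector of column names that must take
#'   values in \{0, 1\} (e.g. treatment or sex indicators); validated on
#'   load.
#' @return A `data.frame` with numeric columns.
#' @seealso [write_dataset()], [validate_dataset()]
#' @export
read_dataset <- function(path, na = "NA", binary = character()) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  data <- utils::read.csv(path, na.strings = c(na, ""),
                          stringsAsFactors = FALSE)
  validate_dataset(data, binary = binary)
}

#' Write a dataset to CSV
#'
#' @param data A data frame.
#' @param path Output path.
#' @param na Token used for missing cells.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, na = "NA") {
  utils::write.csv(data, path, row.names = FALSE, na = na)
  invisible(path)
}

#' Validate a dataset
#'
#' Checks that all columns are numeric and of equal length and that the
#' declared binary columns only take values 0 or 1 (missing allowed).
#'
#' @inheritParams read_dataset
#' @param data A data frame.
#' @return `data`, invisibly usable in a pipeline (returned visibly).
#' @export
validate_dataset <- function(data, binary = character()) {
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("data must be a non-empty data frame")
  num <- vapply(data, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric columns: ", paste(names(data)[!num], collapse = ", "))
  for (col in binary) {
    if (!col %in% names(data)) stop("binary column not found: ", col)
    v <- data[[col]]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop("column '", col, "' must only take values 0 or 1")
  }
  data
}

# Numeric matrix view of a data frame, preserving column names.
.datmat <- function(data) {
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  m
}
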