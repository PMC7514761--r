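#' Observed dataset for incomplete-data analysis with an auxiliary variable
#'
#' Bundles the observed primary variable \code{y}, an optional auxiliary
#' variable \code{a}, and optional binary latent labels \code{z}.  The labels
#' are never used for estimation by the incomplete-data fitters; they exist
#' only for oracle (complete-data) fits and for evaluating losses in
#' simulations.
#'
#' @param y Numeric vector of observed primary values.
#' @param a Optional numeric vector of auxiliary values, same length.
#' @param z Optional binary (0/1) vector of latent labels, same length.
#' @return An object of class \code{"aux_dataset"}: a list with elements
#'   \code{y}, \code{a}, \code{z} (the latter two possibly \code{NULL}) and
#'   \code{n}.
#' @examples
#' d <- aux_dataset(y = rnorm(10), a = rnorm(10))
#' d$n
#' @export
aux_dataset <- function(y, a = NULL, z = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("y must contain at least one observation")
  if (anyNA(y) || !all(is.finite(y))) stop("y must be finite and non-missing")
  if (!is.null(a)) {
    a <- as.numeric(a)
    if (length(a) != n) stop("a must have the same length as y")
    if (anyNA(a) || !all(is.finite(a))) stop("a must be finite and non-missing")
  }
  if (!is.null(z)) {
    z <- as.numeric(z)
    if (length(z) != n) stop("z must have the same length as y")
    if (!all(z %in% c(0, 1))) stop("z must contain only values 0 or 1")
  }
  structure(list(y = y, a = a, z = z, n = n), class = "aux_dataset")
}

#' @export
print.aux_dataset <- function(x, ...) {
  cat("aux_dataset: n =", x$n,
      "| auxiliary:", if (is.null(x$a)) "absent" else "present",
      "| latent labels:", if (is.null(x$z)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
as.data.frame.aux_dataset <- function(x, ...) {
  df <- data.frame(y = x$y)
  if (!is.null(x$a)) df$a <- x$a
  if (!is.null(x$z)) df$z <- x$z
  df
}

#' Read a dataset from a delimited text file
#'
#' Reads a CSV with a header and builds an \code{\link{aux_dataset}} from the
#' named columns.  A missing auxiliary column yields a primary-only dataset.
#'
#' @param path Path to a CSV file.
#' @param primary_col Name of the observed primary-variable column.
#' @param aux_col Name of the auxiliary column, or \code{NULL}.
#' @param latent_col Name of the binary latent-label column, or \code{NULL}.
#' @return An \code{"aux_dataset"}.
#' @export
read_dataset <- function(path, primary_col = "y", aux_col = "a",
                         latent_col = "z") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  if (!primary_col %in% names(df))
    stop("primary column '", primary_col, "' not found in ", path)
  grab <- function(col, what) {
    if (is.null(col) || !col %in% names(df)) return(NULL)
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop("non-numeric value in column '", col, "' at row ", bad)
    }
    num
  }
  aux_dataset(y = grab(primary_col, "primary"),
              a = grab(aux_col, "auxiliary"),
              z = grab(latent_col, "latent"))
}

#' Write a dataset to CSV
#'
#' @param data An \code{"aux_dataset"}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Standardize numeric columns of a data frame
#'
#' Centers each selected column to mean zero and scales it to unit sample
#' standard deviation (n - 1 divisor).  Latent-label columns should be
#' excluded by the caller.
#'
#' @param df A data frame.
#' @param cols Columns to standardize; defaults to all numeric columns.
#' @return The data frame with standardized columns.
#' @export
standardize_columns <- function(df, cols = NULL) {
  if (is.null(cols)) cols <- names(df)[vapply(df, is.numeric, logical(1))]
  for (cl in cols) {
    v <- df[[cl]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("column '", cl, "' is constant; cannot standardize")
    df[[cl]] <- (v - mean(v)) / s
  }
  df
}

#' Random train/test split of a data frame
#'
#' @param df A data frame.
#' @param n_train Number of training rows.
#' @param seed Optional integer seed.
#' @return A list with elements \code{train} and \code{test}.
#' @export
split_train_test <- function(df, n_train, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_train < 1L || n_train >= nrow(df)) stop("n_train out of range")
  idx <- sample.int(nrow(df), n_train)
  list(train = df[idx, , drop = FALSE], test = df[-idx, , drop = FALSE])
}

#' Write small simulated fixture datasets
#'
#' Generates Case 1 / Case 2 datasets at n in \{50, 100\} with seeds derived
#' from \code{seed} and writes them as CSV files; used by the test suite and
#' as quick-start examples.
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
make_fixtures <- function(seed, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  k <- 0L
  for (case in c("case1", "case2")) for (n in c(50L, 100L)) {
    k <- k + 1L
    d <- generate_case(case, n, seed = seed + k)
    p <- file.path(out_dir, sprintf("%s_n%d.csv", case, n))
    write_dataset(d, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
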