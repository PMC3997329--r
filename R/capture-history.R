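#' Capture-history objects
#'
#' A capture history records, for each of `n` captured individuals, a binary
#' outcome over `m` trapping occasions (1 = caught on that occasion) together
#' with per-individual covariates such as sex or body weight.  Only captured
#' individuals appear: every row must contain at least one capture.  This is
#' the central data container of the package; all estimators consume it.
#'
#' @param y binary matrix, one row per captured individual, one column per
#'   occasion.  Entries must be 0 or 1 and every row must have at least one 1.
#' @param covariates optional data frame of per-individual covariates, one row
#'   per individual.  Categorical covariates must be pre-coded as numeric
#'   (e.g. sex: male = 1, female = 0).
#' @return An object of class `"capture_history"`: a list with elements `y`
#'   (the 0/1 matrix), `covariates` (data frame, possibly with zero columns),
#'   `n` (number of captured individuals) and `m` (number of occasions).
#' @examples
#' ch <- capture_history(rbind(c(1, 0, 0), c(1, 1, 0)),
#'                       data.frame(sex = c(1, 0)))
#' summary(ch)
#' @export
capture_history <- function(y, covariates = NULL) {
  y <- as.matrix(y)
  if (!is.numeric(y)) {
    stop("capture matrix must be numeric with non-binary entries coded 0/1",
         call. = FALSE)
  }
  if (anyNA(y) || any(y != 0 & y != 1)) {
    stop("non-binary entry in capture matrix: occasions must be coded 0/1",
         call. = FALSE)
  }
  if (ncol(y) < 2L) {
    stop("at least two capture occasions are required", call. = FALSE)
  }
  if (any(rowSums(y) == 0)) {
    stop("all-zero capture history found: only captured individuals may appear",
         call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- as.data.frame(matrix(nrow = nrow(y), ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(y)) {
    stop("covariates must have one row per individual", call. = FALSE)
  }
  storage.mode(y) <- "integer"
  dimnames(y) <- list(NULL, paste0("occ_", seq_len(ncol(y))))
  structure(
    list(y = y, covariates = covariates, n = nrow(y), m = ncol(y)),
    class = "capture_history"
  )
}

#' @export
print.capture_history <- function(x, ...) {
  cat("Capture history:", x$n, "individuals,", x$m, "occasions\n")
  if (ncol(x$covariates)) {
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  cat("Total captures:", sum(x$y), "\n")
  invisible(x)
}

#' Summarize a capture history
#'
#' Reduces a capture history to its sufficient statistics: per-individual
#' capture counts `T`, first-capture occasions `t_first` (1-based),
#' capture-frequency vector `f` (`f[k]` = number of individuals caught exactly
#' `k` times), and per-occasion capture counts.  These satisfy the
#' conservation identity `sum(k * f[k]) = sum(n_per_occasion) = sum(T)`.
#'
#' @param object a [capture_history()] object.
#' @param ... unused.
#' @return An object of class `"capture_summary"`: list with `T`, `t_first`,
#'   `f`, `n_per_occasion`, `n`, `m`, `total_captures` and the covariates
#'   carried over.
#' @export
summary.capture_history <- function(object, ...) {
  y <- object$y
  T_i <- as.integer(rowSums(y))
  t_first <- apply(y, 1L, function(r) which(r == 1L)[1L])
  structure(
    list(
      T = T_i,
      t_first = as.integer(t_first),
      f = tabulate(T_i, nbins = object$m),
      n_per_occasion = as.integer(colSums(y)),
      n = object$n,
      m = object$m,
      total_captures = sum(T_i),
      covariates = object$covariates
    ),
    class = "capture_summary"
  )
}

#' @export
print.capture_summary <- function(x, ...) {
  cat("Capture summary: n =", x$n, ", m =", x$m,
      ", total captures =", x$total_captures, "\n")
  cat("Capture frequencies f_1..f_m:", paste(x$f, collapse = " "), "\n")
  cat("Captures per occasion:", paste(x$n_per_occasion, collapse = " "), "\n")
  invisible(x)
}

#' Read and write capture-history CSV files
#'
#' The CSV dialect has a header row, occasion columns named `occ_1` ... `occ_m`
#' holding 0/1, and any further columns treated as individual covariates.
#'
#' @param path file path.
#' @param covariate_names optional character vector selecting (and ordering)
#'   covariate columns; default: every non-occasion column.
#' @return [read_capture_csv()] returns a [capture_history()];
#'   [write_capture_csv()] returns `path` invisibly.
#' @export
read_capture_csv <- function(path, covariate_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE)
  occ <- grep("^occ_[0-9]+$", names(df), value = TRUE)
  if (!length(occ)) stop("no occasion columns (occ_1..occ_m) found", call. = FALSE)
  occ <- occ[order(as.integer(sub("^occ_", "", occ)))]
  y <- as.matrix(df[occ])
  if (!is.numeric(y) || anyNA(y) || any(y != 0 & y != 1)) {
    stop("non-binary entry in occasion columns", call. = FALSE)
  }
  covs <- setdiff(names(df), occ)
  if (!is.null(covariate_names)) {
    missing_cov <- setdiff(covariate_names, covs)
    if (length(missing_cov)) {
      stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    }
    covs <- covariate_names
  }
  capture_history(y, df[covs])
}

#' @param ch a [capture_history()] object.
#' @rdname read_capture_csv
#' @export
write_capture_csv <- function(ch, path) {
  stopifnot(inherits(ch, "capture_history"))
  df <- cbind(as.data.frame(ch$y), ch$covariates)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write MARK-style .INP capture files
#'
#' Each line holds a contiguous 0/1 capture-history string, optional
#' whitespace-separated numeric covariate values, and a terminating `";"`.
#' Comment blocks (`/* ... */`) are ignored on input.
#'
#' @param text character vector of lines, or a length-1 string with embedded
#'   newlines.
#' @param covariate_names names for the trailing covariate fields.
#' @return [read_mark_inp()] returns a [capture_history()];
#'   [write_mark_inp()] returns a character vector of lines.
#' @export
read_mark_inp <- function(text, covariate_names = NULL) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text <- gsub("/\\*.*?\\*/", "", text)
  text <- trimws(sub(";\\s*$", "", text[grepl(";", text)]))
  text <- text[nzchar(text)]
  if (!length(text)) stop("no capture-history records found", call. = FALSE)
  parts <- strsplit(text, "[[:space:]]+")
  hist <- vapply(parts, `[[`, character(1), 1L)
  if (any(!grepl("^[01]+$", hist))) {
    stop("malformed capture-history string (must be contiguous 0/1)", call. = FALSE)
  }
  m <- nchar(hist[1L])
  if (any(nchar(hist) != m)) {
    stop("malformed line: capture-history strings differ in length", call. = FALSE)
  }
  y <- t(vapply(strsplit(hist, ""), as.integer, integer(m)))
  ncov <- lengths(parts) - 1L
  if (any(ncov != ncov[1L])) {
    stop("malformed line: records differ in number of covariate fields",
         call. = FALSE)
  }
  covs <- NULL
  if (ncov[1L] > 0L) {
    v <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(ncov[1L]))
    covs <- as.data.frame(if (ncov[1L] == 1L) matrix(v, ncol = 1L) else t(v))
    names(covs) <- if (!is.null(covariate_names)) covariate_names else
      paste0("cov_", seq_len(ncov[1L]))
  }
  capture_history(y, covs)
}

#' @rdname read_mark_inp
#' @export
write_mark_inp <- function(ch) {
  stopifnot(inherits(ch, "capture_history"))
  hist <- apply(ch$y, 1L, paste0, collapse = "")
  if (ncol(ch$covariates)) {
    covtxt <- apply(ch$covariates, 1L, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
    paste0(hist, " ", covtxt, ";")
  } else {
    paste0(hist, ";")
  }
}
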