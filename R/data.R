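#' Assemble a two-stage IV dataset from a data frame
#'
#' Validates and extracts the outcome (the only variable allowed to contain
#' missing values), treatment, covariates and instruments named by an
#' [iv_formula()].  The outcome missingness indicator is derived from the
#' outcome's `NA` pattern, or supplied explicitly (and cross-checked) via
#' `m_ind` as in selection-model workflows.
#'
#' @param data A data frame with one column per model variable.
#' @param formula An [iv_formula()], formula or formula string.
#' @param m_ind Optional missingness indicator for the outcome: either a
#'   column name in `data` or a 0/1 vector of length `nrow(data)` (1 =
#'   outcome missing).  Must agree with the outcome's `NA` mask.
#' @param treatment_type `"auto"` (default: tagged binary iff the observed
#'   support is exactly \{0, 1\}), `"continuous"`, or `"binary"`.
#' @return An object of class `iv_data`: list with elements `y` (outcome,
#'   `NA` where missing), `m` (0/1 missingness indicator), `x` (treatment),
#'   `x_type`, `C` (n x p covariate matrix), `Z` (n x J instrument matrix),
#'   `n`, and `formula`.
#' @export
iv_data <- function(data, formula, m_ind = NULL,
                    treatment_type = c("auto", "continuous", "binary")) {
  treatment_type <- match.arg(treatment_type)
  spec <- iv_formula(formula)
  if (!is.data.frame(data))
    stop("`data` must be a data frame", call. = FALSE)

  need <- c(spec$outcome, spec$treatment, spec$covariates, spec$instruments)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  y <- .num_col(data, spec$outcome)
  x <- .num_col(data, spec$treatment)
  C <- .num_mat(data, spec$covariates)
  Z <- .num_mat(data, spec$instruments)
  n <- length(y)

  if (anyNA(x) || anyNA(C) || anyNA(Z))
    stop("only the outcome may be missing; found missing values in ",
         "treatment, covariate or instrument columns", call. = FALSE)

  m <- as.integer(is.na(y))
  if (!is.null(m_ind)) {
    mi <- if (is.character(m_ind) && length(m_ind) == 1L) {
      if (!m_ind %in% names(data))
        stop("m_ind column not found: ", m_ind, call. = FALSE)
      data[[m_ind]]
    } else m_ind
    mi <- as.integer(mi)
    if (length(mi) != n || !all(mi %in% c(0L, 1L)))
      stop("m_ind must be a binary (0/1) vector aligned with the data",
           call. = FALSE)
    if (!identical(mi, m))
      stop("supplied m_ind is inconsistent with the outcome's missing values",
           call. = FALSE)
  }

  ux <- sort(unique(x))
  if (length(ux) < 2L)
    stop("treatment `", spec$treatment, "` is constant", call. = FALSE)
  if (treatment_type == "binary" || (treatment_type == "auto" &&
                                     length(ux) == 2L && all(ux %in% c(0, 1)))) {
    if (!all(ux %in% c(0, 1)))
      stop("binary or continuous treatment only: treatment `", spec$treatment,
           "` has ", length(ux), " distinct levels", call. = FALSE)
    x_type <- "binary"
  } else {
    x_type <- "continuous"
  }

  J <- ncol(Z); p <- ncol(C)
  if (n < J + p + 2L)
    stop("too few rows: need at least J + p + 2 = ", J + p + 2L,
         " observations for the two linear stages", call. = FALSE)

  structure(
    list(y = y, m = m, x = x, x_type = x_type, C = C, Z = Z, n = n,
         formula = spec),
    class = "iv_data"
  )
}

.num_col <- function(data, name) {
  v <- data[[name]]
  if (is.factor(v) || is.character(v)) {
    lev <- sort(unique(as.character(v[!is.na(v)])))
    if (length(lev) > 2L)
      stop("binary or continuous treatment only: column `", name,
           "` is categorical with ", length(lev), " levels", call. = FALSE)
    v <- as.integer(match(as.character(v), lev) - 1L)
  }
  if (!is.numeric(v))
    stop("column `", name, "` is not numeric", call. = FALSE)
  as.double(v)
}

.num_mat <- function(data, names) {
  if (!length(names))
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  mat <- vapply(names, function(nm) .num_col(data, nm), numeric(nrow(data)))
  mat <- matrix(mat, nrow = nrow(data),
                dimnames = list(NULL, names))
  mat
}

#' Read a delimited file into an `iv_data` object
#'
#' Reads a delimited text file with a header row.  Empty fields, `NA` and
#' `NaN` all encode a missing value; only the outcome column may contain
#' them.
#'
#' @param path Path to the file.
#' @param formula Model formula (see [iv_formula()]).
#' @param delim Field delimiter, default `","`.
#' @inheritParams iv_data
#' @return An `iv_data` object.
#' @export
read_iv_data <- function(path, formula, delim = ",", m_ind = NULL,
                         treatment_type = c("auto", "continuous", "binary")) {
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           na.strings = c("", "NA", "NaN"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  iv_data(tab, formula, m_ind = m_ind, treatment_type = treatment_type)
}

#' @export
print.iv_data <- function(x, ...) {
  cat("Two-stage IV dataset\n")
  cat("  formula:    ", format(x$formula), "\n", sep = "")
  cat("  rows:       ", x$n, "\n", sep = "")
  cat("  treatment:  ", x$formula$treatment, " (", x$x_type, ")\n", sep = "")
  cat("  instruments:", ncol(x$Z), " covariates:", ncol(x$C), "\n")
  cat("  outcome missing: ", sum(x$m), " (",
      round(100 * mean(x$m), 1), "%)\n", sep = "")
  invisible(x)
}

# stage-1 design [1, Z] and stage-2 design [1, xhat, C]
.design1 <- function(data) cbind(`(Intercept)` = 1, data$Z)
.design2 <- function(data, xhat) {
  cbind(`(Intercept)` = 1, xhat = xhat, data$C)
}
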