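#' Parse a two-stage instrumental-variable model formula
#'
#' The model formula has three parts joined by a tilde and a vertical bar:
#' `outcome ~ treatment + covariates | instruments`.  The first term to the
#' right of the tilde is always the causal treatment variable; any further
#' terms left of the bar are stage-two covariates; everything right of the
#' bar is an instrument entering stage one.  Terms are additive names only —
#' interactions, transformations and factor expansion are not supported.
#'
#' @param formula A formula object or a character string such as
#'   `"readingIRT ~ relAge + gender | PredEnt"`.
#' @return An object of class `iv_formula`: a list with elements `outcome`,
#'   `treatment`, `covariates` (character, possibly empty) and `instruments`
#'   (character, length >= 1).
#' @examples
#' iv_formula(y ~ x + c1 + c2 | z)
#' iv_formula("hmRating ~ voucher + headFemale + headMarried | extraBed")
#' @export
iv_formula <- function(formula) {
  if (inherits(formula, "iv_formula")) return(formula)
  txt <- if (inherits(formula, "formula")) {
    paste(deparse(formula, width.cutoff = 500L), collapse = " ")
  } else if (is.character(formula) && length(formula) == 1L) {
    formula
  } else {
    stop("`formula` must be a formula or a single character string", call. = FALSE)
  }

  if (lengths(regmatches(txt, gregexpr("~", txt, fixed = TRUE))) != 1L)
    stop("formula must contain exactly one `~`", call. = FALSE)
  nbar <- lengths(regmatches(txt, gregexpr("|", txt, fixed = TRUE)))
  if (nbar == 0L)
    stop("instruments required: formula must contain `| instruments`", call. = FALSE)
  if (nbar > 1L)
    stop("formula must contain exactly one `|`", call. = FALSE)

  lhs_rhs <- strsplit(txt, "~", fixed = TRUE)[[1L]]
  outcome <- .parse_terms(lhs_rhs[1L], "outcome")
  if (length(outcome) != 1L)
    stop("exactly one outcome variable is required", call. = FALSE)

  parts <- strsplit(lhs_rhs[2L], "|", fixed = TRUE)[[1L]]
  pred <- .parse_terms(parts[1L], "treatment/covariate")
  inst <- .parse_terms(parts[2L], "instrument")
  if (length(pred) < 1L)
    stop("parse error: at least one term (the treatment) is required left of `|`",
         call. = FALSE)
  if (length(inst) < 1L)
    stop("parse error: at least one instrument is required right of `|`",
         call. = FALSE)

  all_names <- c(outcome, pred, inst)
  if (anyDuplicated(all_names))
    stop("variable(s) used in more than one role: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "),
         call. = FALSE)

  structure(
    list(outcome = outcome, treatment = pred[1L],
         covariates = pred[-1L], instruments = inst),
    class = "iv_formula"
  )
}

.parse_terms <- function(txt, role) {
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
  if (any(!nzchar(terms)) && any(nzchar(terms)))
    stop("parse error: empty ", role, " term (dangling `+`?)", call. = FALSE)
  terms <- terms[nzchar(terms)]
  bad <- terms[!grepl("^[A-Za-z.][A-Za-z0-9._]*$", terms)]
  if (length(bad))
    stop("parse error: invalid ", role, " term(s): ",
         paste(bad, collapse = ", "),
         " (only additive variable names are supported)", call. = FALSE)
  terms
}

#' @export
format.iv_formula <- function(x, ...) {
  paste0(x$outcome, " ~ ",
         paste(c(x$treatment, x$covariates), collapse = " + "),
         " | ", paste(x$instruments, collapse = " + "))
}

#' @export
print.iv_formula <- function(x, ...) {
  cat("Two-stage IV formula: ", format(x), "\n", sep = "")
  invisible(x)
}
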