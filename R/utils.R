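#' @keywords internal
#' @useDynLib promice, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Missing-value marker used throughout: plain NA. Item columns are integer
# category codes; composites are numeric.

#' Signal a non-convergence failure
#'
#' Imputation-model fitters signal structured conditions so that chain and
#' set orchestration can distinguish statistical failure (a legitimate,
#' countable outcome of a simulation iteration) from programming errors.
#'
#' @param reason short machine-readable reason, e.g. `"perfect_prediction"`,
#'   `"collinear"`, `"overfit"`, `"singular_information"`.
#' @param message human-readable detail.
#' @keywords internal
nonconvergence <- function(reason, message = reason) {
  cond <- structure(
    class = c("promice_nonconvergence", "error", "condition"),
    list(message = message, call = sys.call(-1), reason = reason)
  )
  stop(cond)
}

#' Catch a non-convergence condition
#'
#' Runs `expr`; returns its value, or on a `promice_nonconvergence`
#' condition a list `list(failed = TRUE, reason = ...)`.
#' @keywords internal
catch_nonconvergence <- function(expr) {
  tryCatch(expr, promice_nonconvergence = function(e) {
    list(failed = TRUE, reason = e$reason, message = conditionMessage(e))
  })
}

is_failure <- function(x) is.list(x) && isTRUE(x$failed)

#' Derive a stream of reproducible sub-seeds from a master seed
#'
#' Counter-based: sub-seed k depends only on (master, k), so retried or
#' failed iterations never perturb the seeds of later ones. Values stay
#' within the positive 32-bit integer range.
#'
#' @param master integer master seed.
#' @param counter positive integer index (vectorised).
#' @return integer vector of sub-seeds.
#' @export
derive_seed <- function(master, counter) {
  master <- as.double(master)
  counter <- as.double(counter)
  # splitmix-style scrambling in double precision, folded to 31 bits
  x <- (master * 2654435761 + counter * 40503 + 813419) %% 2147483629
  as.integer(x %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
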