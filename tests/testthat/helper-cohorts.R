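# Shared builders for small synthetic cohorts used across test files.

oks_cohort <- function(n = 600, seed = 421, tau = 0, ...) {
  generate_cohort(cohort_config(n, list(instrument_sim(oks_spec())),
                                tau = tau, ...), seed)
}

eq5d_cohort <- function(n = 600, seed = 422, ...) {
  generate_cohort(
    cohort_config(n, list(instrument_sim(eq5d_spec(), orientation = -1)),
                  ...), seed)
}

sf12_cohort <- function(n = 600, seed = 423, ...) {
  generate_cohort(cohort_config(n, list(instrument_sim(sf12_spec())), ...),
                  seed)
}

amputed_oks <- function(n = 600, p = 0.2, seed = 77,
                        mixture = load_fixture("oks_observed_mixture"),
                        mechanism = "MAR", cohort = NULL) {
  cohort <- cohort %||% oks_cohort(n)
  ampute(cohort, amputation_config("oks", p, mixture, mechanism), seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_nonconvergence <- function(expr, reason = NULL) {
  cond <- tryCatch({expr; NULL},
                   promice_nonconvergence = function(e) e)
  expect_false(is.null(cond),
               info = "expected a non-convergence condition")
  if (!is.null(reason) && !is.null(cond))
    expect_identical(cond$reason, reason)
  invisible(cond)
}
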