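#' Broom-style tidiers for astadr objects
#'
#' `tidy()` returns the per-element table of a result; `glance()` a one-row
#' summary.
#'
#' @param x The object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @name astadr_tidiers
NULL

#' @rdname astadr_tidiers
#' @export
tidy.astad_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname astadr_tidiers
#' @export
glance.astad_calls <- function(x, ...) {
  tibble(
    n_domains = nrow(x),
    n_astads = sum(x$is_astad),
    n_flagged = sum(x$flagged_uninformative),
    threshold = attr(x, "threshold") %||% 2,
    max_z = if (nrow(x)) max(x$z, na.rm = TRUE) else NA_real_
  )
}

#' @rdname astadr_tidiers
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname astadr_tidiers
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(test = x$test, z = x$z, p = x$p, n_samples = x$n_samples)
}

#' @rdname astadr_tidiers
#' @export
tidy.normalization_model <- function(x, ...) {
  x$fitted_curve
}

#' @rdname astadr_tidiers
#' @export
glance.normalization_model <- function(x, ...) {
  tibble(span = x$span, n_cells_fit = x$n_cells_fit)
}
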