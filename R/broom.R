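#' Tidy a fitted kinetic model
#'
#' @param x A `tscm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated or derived quantity:
#'   `term`, `estimate`, `type` (`"parameter"` or `"derived"`).
#' @export
tidy.tscm_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(x$estimates),
                   estimate = unname(x$estimates), type = "parameter"),
    tibble::tibble(term = names(x$derived),
                   estimate = as.numeric(x$derived[1, ]), type = "derived")
  )
}

#' Glance at a fitted kinetic model
#'
#' @param x A `tscm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: variant, k, datasets, SSR (total and per
#'   dataset), counts, and the number of optimiser starts that converged.
#' @export
glance.tscm_fit <- function(x, ...) {
  comp <- as.list(x$ssr_components)
  names(comp) <- paste0("ssr_", names(comp))
  dplyr::bind_cols(
    tibble::tibble(
      variant = x$config$variant, k = x$config$k,
      datasets = paste(x$config$datasets, collapse = "+"),
      ssr = x$ssr, n_points = x$n_points, n_par = x$n_par,
      n_starts_converged = sum(x$start_log$converged)
    ),
    tibble::as_tibble(comp)
  )
}

#' Augment label data with fitted values and residuals
#'
#' @param x A `tscm_fit` object.
#' @param ... Unused.
#' @return The label tibble with `.fitted` and `.resid` columns.
#' @export
augment.tscm_fit <- function(x, ...) {
  if (is.null(x$data$label)) abort("fit carries no label data to augment.")
  d <- x$data$label
  d$.fitted <- label_predictions(x$kinetics, x$data$water, d)
  d$.resid <- d$fraction_labelled - d$.fitted
  d
}
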