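#' Broom-style tidiers and plots
#'
#' `tidy()` turns a refinement result into a per-parameter tibble and an
#' experiment report into a long per-condition tibble; `glance()` gives
#' the one-row model summary; `autoplot()` draws the headline trends of
#' a neighbour-bias experiment.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a refinement result
#'
#' One row per refined parameter: site label (empty for the scale), the
#' parameter kind, refined value and standard uncertainty.
#'
#' @param x a `refinement_result`
#' @param ... unused
#' @return a tibble with columns `term`, `estimate`, `std.error`
#' @method tidy refinement_result
#' @export
tidy.refinement_result <- function(x, ...) {
  free_names <- names(x$su)
  est <- numeric(length(free_names))
  # reconstruct values from the refined structure
  labels <- vapply(x$structure$sites, `[[`, character(1), "label")
  for (i in seq_along(free_names)) {
    nm <- free_names[i]
    if (nm == "scale") { est[i] <- x$scale; next }
    parts <- strsplit(nm, "_")[[1]]
    site <- match(parts[2], labels); j <- as.integer(parts[3])
    if (parts[1] == "x") est[i] <- x$structure$sites[[site]]$frac[j]
    else {
      ij <- list(c(1,1), c(2,2), c(3,3), c(1,2), c(1,3), c(2,3))[[j]]
      est[i] <- x$structure$sites[[site]]$U[ij[1], ij[2]]
    }
  }
  tibble::tibble(term = free_names, estimate = est, std.error = unname(x$su))
}

#' Glance at a refinement result
#'
#' @param x a `refinement_result`
#' @param ... unused
#' @return one-row tibble: `r1`, `wr2`, `goof`, `iterations`,
#'   `macro_cycles`, `converged`, `max_shift_su`, `n_param`,
#'   `n_reflections`
#' @method glance refinement_result
#' @export
glance.refinement_result <- function(x, ...) {
  tibble::tibble(r1 = x$r1, wr2 = x$wr2, goof = x$goof,
                 iterations = x$iterations, macro_cycles = x$macro_cycles,
                 converged = x$converged, max_shift_su = x$max_shift_su,
                 n_param = x$n_param, n_reflections = x$n_reflections)
}

#' Tidy an ADP comparison
#'
#' @param x an `adp_comparison`
#' @param ... unused
#' @return the per-atom tibble with the summary means appended as
#'   attribute-free columns `metric`/`mean` in long form via `glance`;
#'   `tidy` returns the per-atom rows unchanged as a plain tibble
#' @method tidy adp_comparison
#' @export
tidy.adp_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.adp_comparison
#' @method glance adp_comparison
#' @export
glance.adp_comparison <- function(x, ...) {
  s <- attr(x, "summary")
  out <- tibble::as_tibble(as.list(s))
  out$n_isotropic_skipped <- attr(x, "n_isotropic_skipped")
  out
}

#' Plot a neighbour-bias experiment
#'
#' Bond-direction MSD excess of the refined hydrogen ADP versus the
#' partition exponent n, one line per (q_fix, d_min) condition. Positive
#' excess means the refined ellipsoid is elongated along the X-H bond
#' relative to truth.
#'
#' @param object an `exphar_experiment` tibble
#' @param metric column to plot (default `bond_msd_excess`)
#' @param ... unused
#' @return a ggplot object
#' @method autoplot exphar_experiment
#' @export
autoplot.exphar_experiment <- function(object, metric = "bond_msd_excess",
                                       ...) {
  df <- tibble::as_tibble(unclass(object))
  df$condition <- sprintf("q_fix = %g, d_min = %g", df$q_fix, df$d_min)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data[[metric]],
                                   colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "partition exponent n", y = metric,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
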