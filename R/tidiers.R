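#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Pareto front
#'
#' @param x An `icu_front`.
#' @param ... Unused.
#' @return The front's per-solution table without the schedule list column.
#' @export
tidy.icu_front <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$schedule <- NULL
  for (a in c("stage", "params", "reference")) attr(out, a) <- NULL
  out
}

#' One-row summary of a Pareto front
#'
#' @param x An `icu_front`.
#' @param ... Unused.
#' @return Tibble with the front size, objective means and the dominated
#'   hypervolume.
#' @export
glance.icu_front <- function(x, ...) {
  base <- tibble::tibble(n_solutions = nrow(x),
                         hypervolume = front_hypervolume(x))
  if (attr(x, "stage") == 1L) {
    dplyr::bind_cols(base,
                     tibble::tibble(mean_f11 = mean(x$f11),
                                    mean_f12 = mean(x$f12),
                                    mean_f13 = mean(x$f13),
                                    mean_admitted = mean(x$n_current +
                                                           x$n_emergency +
                                                           x$n_elective)))
  } else {
    dplyr::bind_cols(base,
                     tibble::tibble(mean_f21 = mean(x$f21),
                                    mean_f22 = mean(x$f22)))
  }
}

#' @rdname tidy.icu_front
#' @export
tidy.icu_repairs <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$schedule <- NULL
  out
}

#' Tidy an algorithm comparison
#'
#' @param x An `icu_comparison`.
#' @param ... Unused.
#' @return The paired-test table (one row per baseline comparison).
#' @export
tidy.icu_comparison <- function(x, ...) x$tests

#' @rdname tidy.icu_comparison
#' @export
glance.icu_comparison <- function(x, ...) {
  x$runs |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) & !"seed", mean),
                     .groups = "drop")
}
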