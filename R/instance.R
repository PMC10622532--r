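#' Poisson probability of k arrivals
#'
#' Probability mass \eqn{\lambda^k e^{-\lambda} / k!} of observing `k`
#' emergency arrivals on a day whose arrival rate is `rate`. Daily emergency
#' arrivals are modelled as Poisson counts; this is the elementary building
#' block for the admission cap and the occupancy distribution.
#'
#' @param k Non-negative integer count (vectorised).
#' @param rate Non-negative Poisson rate \eqn{\lambda}.
#' @return Probability (or vector of probabilities) in `[0, 1]`.
#' @examples
#' poisson_pmf(0, 2) # exp(-2)
#' @export
poisson_pmf <- function(k, rate) {
  if (any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    abort("`k` must be a non-negative integer.")
  }
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("`rate` must be a non-negative number.")
  }
  dpois(k, rate)
}

#' Daily emergency admission cap
#'
#' The maximum plausible number of emergency arrivals on a day, defined as the
#' smallest count whose cumulative Poisson probability reaches `quantile`.
#' Arrivals beyond this cap are treated as impossible by the allocation model
#' ("a large number of emergency patients has low possibility"); the cap is
#' the denominator of the emergency admission rate objective.
#'
#' @param rate Non-negative Poisson rate \eqn{\lambda_t} (vectorised).
#' @param quantile Truncation probability in (0, 1); default 0.999.
#' @return Non-negative integer cap(s), nondecreasing in both arguments.
#' @examples
#' max_arrivals(4.8, 0.999)
#' @export
max_arrivals <- function(rate, quantile = 0.999) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("`rate` must be a non-negative number.")
  }
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      is.na(quantile) || quantile <= 0 || quantile >= 1) {
    abort("`quantile` must lie strictly between 0 and 1.")
  }
  as.integer(qpois(quantile, rate))
}

#' Estimate daily arrival rates from historical counts
#'
#' The Poisson rate for a horizon day is estimated by the average emergency
#' count observed for that day across historical planning periods.
#'
#' @param history Data frame with columns `day` (1-based horizon day) and
#'   `count` (non-negative integer arrivals observed).
#' @return Tibble with columns `day` and `lambda`, one row per day present.
#' @export
estimate_rates <- function(history) {
  stopifnot(is.data.frame(history), all(c("day", "count") %in% names(history)))
  history |>
    dplyr::group_by(day = as.integer(.data$day)) |>
    dplyr::summarise(lambda = mean(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$day)
}

#' Discrete length-of-stay extension distribution
#'
#' @param extend Support values: whole extra days in `"additive"` mode, or
#'   fractional growth rates in `"multiplicative"` mode (the extended stay is
#'   then the smallest integer at least `los * (1 + r)`).
#' @param prob Probabilities, summing to 1.
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @return An extension distribution usable as `Instance` component or
#'   stage-2 scenario.
#' @examples
#' extension_table() # the base case-study table
#' @export
extension_table <- function(extend = 0:4,
                            prob = c(0.40, 0.25, 0.20, 0.10, 0.05),
                            mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(length(extend) == length(prob), length(extend) > 0)
  if (any(prob < 0) || any(prob > 1)) abort("Probabilities must lie in [0, 1].")
  if (mode == "additive" && any(extend < 0 | extend != floor(extend))) {
    abort("Additive extensions must be non-negative whole days.")
  }
  if (any(extend < 0)) abort("Extension support must be non-negative.")
  ord <- order(extend) # sorted support: quantile draws couple across scenarios
  structure(
    list(extend = as.numeric(extend)[ord], prob = as.numeric(prob)[ord],
         mode = mode),
    class = "icu_extension"
  )
}

#' Assemble an allocation instance
#'
#' Bundles the immutable description of one planning problem: the bed stock,
#' the horizon, the three patient populations, and the two uncertainty models
#' (Poisson emergency arrivals, discrete LOS extension distribution).
#'
#' @param beds Number of ICU beds `Q` (positive integer).
#' @param horizon Planning horizon `T` in days (positive integer).
#' @param rates Per-day Poisson arrival rates, length `horizon` (a scalar is
#'   recycled).
#' @param electives Tibble with columns `id`, `expected_day`, `los`, `loss`
#'   (loss of chance if postponed, one of 0.1, 0.5, 0.9).
#' @param currents Tibble with columns `id`, `los`, `remaining`; ids carry the
#'   10000+ prefix by convention.
#' @param emergency_los Tibble with columns `los`, `prob`: the LOS law for
#'   emergency arrivals.
#' @param extension [extension_table()] describing stage-2 LOS extensions.
#' @param truncation_quantile Poisson quantile defining the daily admission
#'   cap `Mp_t` (default 0.999).
#' @return An `icu_instance` object.
#' @seealso [validate_instance()], [generate_instance()]
#' @export
new_instance <- function(beds, horizon, rates, electives, currents,
                         emergency_los = NULL, extension = extension_table(),
                         truncation_quantile = 0.999) {
  if (!is_count(beds, 1L)) abort("`beds` must be a positive integer.")
  if (!is_count(horizon, 1L)) abort("`horizon` must be a positive integer.")
  rates <- as.numeric(rates)
  if (length(rates) == 1L) rates <- rep(rates, horizon)
  if (length(rates) != horizon) {
    abort("`rates` must have one entry per horizon day.")
  }
  if (is.null(emergency_los)) {
    emergency_los <- tibble::tibble(los = 1:5, prob = rep(0.2, 5))
  }
  inst <- structure(
    list(
      beds = as.integer(beds),
      horizon = as.integer(horizon),
      electives = tibble::as_tibble(electives) |>
        dplyr::mutate(dplyr::across(c("id", "expected_day", "los"), as.integer),
                      loss = as.numeric(.data$loss)),
      currents = tibble::as_tibble(currents) |>
        dplyr::mutate(dplyr::across(c("id", "los", "remaining"), as.integer)),
      arrivals = list(
        rates = rates,
        quantile = truncation_quantile,
        max_per_day = max_arrivals(rates, truncation_quantile)
      ),
      emergency_los = tibble::as_tibble(emergency_los) |>
        dplyr::mutate(los = as.integer(.data$los), prob = as.numeric(.data$prob)),
      extension = extension
    ),
    class = "icu_instance"
  )
  inst
}

#' @export
print.icu_instance <- function(x, ...) {
  cat("<icu_instance>\n")
  cat(sprintf("  beds Q = %d, horizon T = %d days\n", x$beds, x$horizon))
  cat(sprintf("  electives: %d, currents: %d\n",
              nrow(x$electives), nrow(x$currents)))
  cat(sprintf("  arrival rates: %s (cap Mp_t at %.4g quantile: %s)\n",
              paste(signif(x$arrivals$rates, 3), collapse = ", "),
              x$arrivals$quantile,
              paste(x$arrivals$max_per_day, collapse = ", ")))
  cat(sprintf("  LOS extension mode: %s on {%s}\n",
              x$extension$mode,
              paste(x$extension$extend, collapse = ", ")))
  invisible(x)
}

#' Check an instance against its structural invariants
#'
#' Violations are returned as data, one row per breached rule, so that
#' malformed inputs can be reported in bulk rather than failing fast.
#'
#' @param inst An `icu_instance`.
#' @return Tibble with columns `component`, `id`, `message`; zero rows when
#'   the instance is well formed.
#' @export
validate_instance <- function(inst) {
  v <- list()
  bad <- function(component, id, message) {
    tibble::tibble(component = component, id = as.integer(id), message = message)
  }
  el <- inst$electives
  if (nrow(el)) {
    i <- which(el$los < 1L)
    if (length(i)) v <- c(v, list(bad("elective", el$id[i], "los must be >= 1")))
    i <- which(!(el$loss %in% c(0.1, 0.5, 0.9)))
    if (length(i)) {
      v <- c(v, list(bad("elective", el$id[i],
                         "loss of chance must be one of 0.1, 0.5, 0.9")))
    }
    i <- which(el$expected_day < 1L | el$expected_day > inst$horizon)
    if (length(i)) {
      v <- c(v, list(bad("elective", el$id[i],
                         "expected_day must lie within the horizon")))
    }
  }
  cu <- inst$currents
  if (nrow(cu)) {
    i <- which(cu$remaining < 1L | cu$remaining > cu$los)
    if (length(i)) {
      v <- c(v, list(bad("current", cu$id[i],
                         "remaining LOS must satisfy 1 <= remaining <= los")))
    }
  }
  if (nrow(cu) > inst$beds) {
    v <- c(v, list(bad("instance", NA,
                       "more current patients than beds")))
  }
  ids <- c(el$id, cu$id)
  if (anyDuplicated(ids)) {
    v <- c(v, list(bad("instance", ids[duplicated(ids)],
                       "patient ids must be unique across categories")))
  }
  if (any(inst$arrivals$rates < 0)) {
    v <- c(v, list(bad("arrivals", which(inst$arrivals$rates < 0),
                       "arrival rates must be non-negative")))
  }
  for (dn in c("emergency_los", "extension")) {
    p <- if (dn == "extension") inst$extension$prob else inst[[dn]]$prob
    if (abs(sum(p) - 1) > 1e-9) {
      v <- c(v, list(bad(dn, NA, "probabilities must sum to 1")))
    }
    if (any(p < 0 | p > 1)) {
      v <- c(v, list(bad(dn, NA, "probabilities must lie in [0, 1]")))
    }
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(component = character(), id = integer(), message = character())
  }
}

#' Read and write instances as JSON
#'
#' The JSON layout is flat and self-contained: `beds`, `horizon`, `rates`,
#' `truncation_quantile`, the two patient tables, and the two discrete
#' distributions. A written instance reads back identical.
#'
#' @param inst An `icu_instance`.
#' @param path File path.
#' @return `write_instance()` returns `inst` invisibly; `read_instance()`
#'   returns an `icu_instance`.
#' @export
write_instance <- function(inst, path) {
  x <- list(
    beds = inst$beds,
    horizon = inst$horizon,
    rates = inst$arrivals$rates,
    truncation_quantile = inst$arrivals$quantile,
    electives = inst$electives,
    currents = inst$currents,
    emergency_los = inst$emergency_los,
    extension = list(extend = inst$extension$extend,
                     prob = inst$extension$prob,
                     mode = inst$extension$mode)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(inst)
}

#' @rdname write_instance
#' @export
read_instance <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_instance(
    beds = x$beds, horizon = x$horizon, rates = x$rates,
    electives = tibble::as_tibble(x$electives),
    currents = tibble::as_tibble(x$currents),
    emergency_los = tibble::as_tibble(x$emergency_los),
    extension = extension_table(x$extension$extend, x$extension$prob,
                                x$extension$mode),
    truncation_quantile = x$truncation_quantile
  )
}

#' Export the patient tables of an instance as CSV
#'
#' Writes `electives.csv` (code, expected_day, los, loss), `currents.csv`
#' (code, los, remaining) and `arrivals.csv` (day, lambda, max_arrivals)
#' under `dir`, mirroring the three-table layout of the case-study data.
#'
#' @param inst An `icu_instance`.
#' @param dir Output directory (created if needed).
#' @return The three file paths, invisibly.
#' @export
write_instance_tables <- function(inst, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("electives.csv", "currents.csv", "arrivals.csv"))
  write.csv(dplyr::rename(inst$electives, code = "id"), paths[1], row.names = FALSE)
  write.csv(dplyr::rename(inst$currents, code = "id"), paths[2], row.names = FALSE)
  write.csv(
    tibble::tibble(day = seq_len(inst$horizon),
                   lambda = inst$arrivals$rates,
                   max_arrivals = inst$arrivals$max_per_day),
    paths[3], row.names = FALSE
  )
  invisible(paths)
}
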