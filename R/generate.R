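#' Configuration for the synthetic instance generator
#'
#' Defaults mirror the case-study conditions: a 24-bed ICU planned over one
#' week, 100 elective requests, 3 patients already in beds, and the base
#' LOS-extension table. Arrival rates are drawn per day from `rate_range`,
#' chosen so that daily admission caps land near the case study's dozen
#' emergency patients per day.
#'
#' @param beds,horizon,n_electives,n_currents Problem sizes.
#' @param rate_range Range (min, max) of the daily Poisson arrival rate.
#' @param los_range Range of elective (and current) LOS in days.
#' @param loss_weights Sampling weights over loss-of-chance levels
#'   0.1, 0.5, 0.9; must sum to 1.
#' @param emergency_los_range Range of emergency LOS in days (uniform law).
#' @param extension [extension_table()] used as the instance's extension
#'   distribution.
#' @param truncation_quantile Poisson quantile for the daily cap.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(beds = 24, horizon = 7,
                             n_electives = 100, n_currents = 3,
                             rate_range = c(3, 6), los_range = c(1, 7),
                             loss_weights = c(1, 1, 1) / 3,
                             emergency_los_range = c(1, 5),
                             extension = extension_table(),
                             truncation_quantile = 0.999,
                             seed = 1L) {
  stopifnot(is_count(beds, 1L), is_count(horizon, 1L),
            is_count(n_electives, 0L), is_count(n_currents, 0L),
            length(rate_range) == 2L, rate_range[1] <= rate_range[2],
            rate_range[1] >= 0,
            length(los_range) == 2L, los_range[1] >= 1,
            los_range[1] <= los_range[2],
            length(loss_weights) == 3L, all(loss_weights >= 0),
            length(emergency_los_range) == 2L, emergency_los_range[1] >= 1,
            emergency_los_range[1] <= emergency_los_range[2])
  if (abs(sum(loss_weights) - 1) > 1e-9) {
    abort("`loss_weights` must sum to 1.")
  }
  if (n_currents > beds) {
    abort("`n_currents` may not exceed `beds`: current patients occupy beds on day 1.")
  }
  structure(
    list(beds = beds, horizon = horizon, n_electives = n_electives,
         n_currents = n_currents, rate_range = rate_range,
         los_range = los_range, loss_weights = loss_weights,
         emergency_los_range = emergency_los_range, extension = extension,
         truncation_quantile = truncation_quantile, seed = seed),
    class = "generator_config"
  )
}

#' Generate a synthetic allocation instance
#'
#' Draws an instance with the statistical structure of the case-study data:
#' elective expected admission days uniform over the horizon, LOS uniform over
#' `los_range`, loss-of-chance levels sampled by `loss_weights`; current
#' patients with `remaining <= los`; per-day arrival rates uniform over
#' `rate_range`. Ids follow the coding convention: bare integers for
#' electives, 10000+ for current patients (20000+ is reserved for emergency
#' arrivals realised later).
#'
#' @param cfg A [generator_config()].
#' @return A validated `icu_instance`.
#' @examples
#' inst <- generate_instance(generator_config(seed = 42))
#' @export
generate_instance <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    el <- tibble::tibble(
      id = seq_len(cfg$n_electives),
      expected_day = sample.int(cfg$horizon, cfg$n_electives, replace = TRUE),
      los = resample(seq(cfg$los_range[1], cfg$los_range[2]),
                     cfg$n_electives),
      loss = resample(c(0.1, 0.5, 0.9), cfg$n_electives,
                      prob = cfg$loss_weights)
    )
    cu_los <- resample(seq(cfg$los_range[1], cfg$los_range[2]),
                       cfg$n_currents)
    cu <- tibble::tibble(
      id = 10000L + seq_len(cfg$n_currents),
      los = cu_los,
      remaining = vapply(cu_los, function(l) sample.int(l, 1L), integer(1))
    )
    rates <- runif(cfg$horizon, cfg$rate_range[1], cfg$rate_range[2])
    span <- seq(cfg$emergency_los_range[1], cfg$emergency_los_range[2])
    new_instance(
      beds = cfg$beds, horizon = cfg$horizon, rates = rates,
      electives = el, currents = cu,
      emergency_los = tibble::tibble(los = span,
                                     prob = rep(1 / length(span), length(span))),
      extension = cfg$extension,
      truncation_quantile = cfg$truncation_quantile
    )
  })
}

# Truncated Poisson: the arrival law conditioned on not exceeding the cap.
# Exact inverse-CDF sampling over the finite support 0..cap.
rtrunc_pois <- function(n, rate, cap) {
  if (cap <= 0L || rate == 0) return(integer(n))
  p <- dpois(0:cap, rate)
  sample.int(cap + 1L, n, replace = TRUE, prob = p) - 1L
}

trunc_pois_mean <- function(rate, cap) {
  if (cap <= 0L || rate == 0) return(0)
  k <- 0:cap
  p <- dpois(k, rate)
  sum(k * p) / sum(p)
}

#' Sample a realised emergency arrival stream
#'
#' Draws the daily emergency counts from the truncated Poisson law (the
#' Poisson arrival law conditioned on the daily cap `Mp_t`) and attaches an
#' LOS to each arrival from the instance's emergency LOS distribution.
#' Arrival ids carry the 20000+ prefix, numbered in day order.
#'
#' @param inst An `icu_instance`.
#' @param seed Integer seed, or NULL to draw in the ambient RNG stream.
#' @param id_offset First id is `20000 + id_offset + 1`; lets a second stream
#'   (stage-2 new arrivals) avoid colliding with an earlier one.
#' @return Tibble with columns `id`, `day`, `los`; zero rows when all rates
#'   are zero.
#' @export
sample_emergency_stream <- function(inst, seed = NULL, id_offset = 0L) {
  with_seed(seed, {
    rates <- inst$arrivals$rates
    caps <- inst$arrivals$max_per_day
    counts <- vapply(seq_len(inst$horizon),
                     function(t) rtrunc_pois(1L, rates[t], caps[t]),
                     integer(1))
    n <- sum(counts)
    if (n == 0L) {
      return(tibble::tibble(id = integer(), day = integer(), los = integer()))
    }
    tibble::tibble(
      id = 20000L + id_offset + seq_len(n),
      day = rep(seq_len(inst$horizon), counts),
      los = resample(inst$emergency_los$los, n,
                     prob = inst$emergency_los$prob)
    )
  })
}
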