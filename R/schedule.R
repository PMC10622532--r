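#' Construct a bed-allocation schedule
#'
#' A schedule is one candidate solution: admission days for elective patients,
#' a realised emergency arrival stream, and the lengths of stay in effect
#' (the instance's nominal values in stage 1; extended values in stage 2).
#' Per-day occupancy profiles are derived at construction and cached.
#'
#' A patient admitted on day `t` with LOS `L` occupies days `t .. t+L-1`;
#' days beyond the horizon are truncated for all objective computations.
#'
#' @param inst An `icu_instance`.
#' @param admissions Named integer vector `id -> day` of elective admissions
#'   (ids absent from the vector are not admitted), or an unnamed vector
#'   aligned with `inst$electives` rows with `NA` for unadmitted patients.
#' @param emergencies Tibble with columns `id`, `day`, `los`, e.g. from
#'   [sample_emergency_stream()]. Default: no emergencies.
#' @param elective_los,current_remaining Optional overrides of the per-patient
#'   LOS / remaining days in effect (named by id or aligned vectors); default
#'   the instance values. Stage-2 schedules carry extended values here.
#' @return An `icu_schedule`.
#' @export
new_schedule <- function(inst, admissions = NULL, emergencies = NULL,
                         elective_los = NULL, current_remaining = NULL) {
  el <- inst$electives
  nel <- nrow(el)
  adm <- rep(NA_integer_, nel)
  if (!is.null(admissions)) {
    if (!is.null(names(admissions))) {
      idx <- match(as.integer(names(admissions)), el$id)
      if (anyNA(idx)) abort("`admissions` names must be elective patient ids.")
      adm[idx] <- as.integer(admissions)
    } else {
      if (length(admissions) != nel) {
        abort("Unnamed `admissions` must align with the elective table.")
      }
      adm <- as.integer(admissions)
    }
  }
  elos <- resolve_override(elective_los, el$id, el$los, "elective_los")
  crem <- resolve_override(current_remaining, inst$currents$id,
                           inst$currents$remaining, "current_remaining")
  if (is.null(emergencies)) {
    emergencies <- tibble::tibble(id = integer(), day = integer(), los = integer())
  }
  build_schedule(inst, adm, elos, crem, as.data.frame(emergencies))
}

resolve_override <- function(x, ids, default, what) {
  out <- as.integer(default)
  if (is.null(x)) return(out)
  if (!is.null(names(x))) {
    idx <- match(as.integer(names(x)), ids)
    if (anyNA(idx)) abort(sprintf("`%s` names must be known patient ids.", what))
    out[idx] <- as.integer(x)
  } else {
    if (length(x) != length(ids)) {
      abort(sprintf("Unnamed `%s` must align with the patient table.", what))
    }
    out <- as.integer(x)
  }
  out
}

# Low-level builder used by the search operators: positional vectors, no
# name resolution. Profiles are recomputed from scratch (cheap at T ~ 7).
build_schedule <- function(inst, adm, elos, crem, em) {
  horizon <- inst$horizon
  adm_idx <- which(!is.na(adm))
  occ_el <- occupancy_from_windows(adm[adm_idx], adm[adm_idx] + elos[adm_idx] - 1L,
                                   horizon)
  occ_cu <- occupancy_from_windows(rep(1L, length(crem)), crem, horizon)
  occ_em <- occupancy_from_windows(em$day, em$day + em$los - 1L, horizon)
  structure(
    list(adm = adm, elos = elos, crem = crem, em = em,
         occ_ec = occ_el + occ_cu, occ_em = occ_em,
         em_count = tabulate(em$day, nbins = horizon),
         horizon = horizon, beds = inst$beds),
    class = "icu_schedule"
  )
}

#' @export
print.icu_schedule <- function(x, ...) {
  cat("<icu_schedule>\n")
  cat(sprintf("  electives admitted: %d / %d\n",
              sum(!is.na(x$adm)), length(x$adm)))
  cat(sprintf("  current patients: %d, emergency arrivals: %d\n",
              length(x$crem), nrow(x$em)))
  cat(sprintf("  daily occupancy: %s (Q = %d)\n",
              paste(x$occ_ec + x$occ_em, collapse = ", "), x$beds))
  invisible(x)
}

#' Per-day occupancy breakdown of a schedule
#'
#' @param s An `icu_schedule`.
#' @return Tibble with one row per horizon day: new elective admissions,
#'   emergency arrivals, carried-over inpatients, and the total `Oc_t`.
#' @export
occupancy <- function(s) {
  total <- s$occ_ec + s$occ_em
  new_el <- tabulate(s$adm[!is.na(s$adm)], nbins = s$horizon)
  tibble::tibble(
    day = seq_len(s$horizon),
    elective_new = new_el,
    emergency_new = s$em_count,
    carryover = total - new_el - s$em_count,
    total = total
  )
}

#' Carried-over inpatients on a day
#'
#' `Cu_t`: patients already in beds on day `t` — electives admitted earlier
#' whose stay reaches `t`, emergencies still staying, and current patients
#' with remaining LOS at least `t`.
#'
#' @param s An `icu_schedule`.
#' @param t Day index in `1..horizon`.
#' @return Non-negative integer.
#' @export
carryover_occupancy <- function(s, t) {
  check_day(s, t)
  new_el <- sum(!is.na(s$adm) & s$adm == t)
  (s$occ_ec[t] + s$occ_em[t]) - new_el - s$em_count[t]
}

#' Total ICU occupancy on a day
#'
#' `Oc_t`: newly admitted electives plus the day's emergency arrivals plus
#' carried-over inpatients. May exceed the bed stock `Q` when emergency
#' arrivals overflow it.
#'
#' @inheritParams carryover_occupancy
#' @return Non-negative integer.
#' @export
total_occupancy <- function(s, t) {
  check_day(s, t)
  s$occ_ec[t] + s$occ_em[t]
}

check_day <- function(s, t) {
  if (!is_count(t, 1L) || t > s$horizon) {
    abort(sprintf("`t` must be a day in 1..%d.", s$horizon))
  }
}

#' Stage-1 objectives
#'
#' `f11_occupancy_rate()` is the horizon-average of `Oc_t / Q` (can exceed 1
#' under emergency overflow). `f12_delay_index()` averages
#' `loss * (admission day - expected day)` over admitted electives (0 when
#' none are admitted). `f13_emergency_rate()` averages `em_t / Mp_t` over
#' days with a positive cap.
#'
#' @param s An `icu_schedule`.
#' @param inst The `icu_instance` it belongs to.
#' @return A single numeric value.
#' @export
f11_occupancy_rate <- function(s, inst) {
  sum(s$occ_ec + s$occ_em) / (inst$beds * s$horizon)
}

#' @rdname f11_occupancy_rate
#' @export
f12_delay_index <- function(s, inst) {
  i <- which(!is.na(s$adm))
  if (length(i) == 0L) return(0)
  sum(inst$electives$loss[i] * (s$adm[i] - inst$electives$expected_day[i])) /
    length(i)
}

#' @rdname f11_occupancy_rate
#' @export
f13_emergency_rate <- function(s, inst) {
  mp <- inst$arrivals$max_per_day
  keep <- mp > 0L
  if (!any(keep)) return(0)
  mean(s$em_count[keep] / mp[keep])
}

evaluate_stage1 <- function(s, inst) {
  c(f11 = f11_occupancy_rate(s, inst),
    f12 = f12_delay_index(s, inst),
    f13 = f13_emergency_rate(s, inst))
}

#' Check schedule feasibility
#'
#' A schedule is feasible when elective-plus-current occupancy stays within
#' the bed stock every day, every admitted elective is admitted exactly once
#' on or after its expected day, and daily emergency counts respect the
#' Poisson cap.
#'
#' @param s An `icu_schedule`.
#' @param inst The `icu_instance`.
#' @return Logical; the violations (tibble with `rule`, `day`/`id`, `message`)
#'   are attached as attribute `"violations"`.
#' @export
is_feasible <- function(s, inst) {
  v <- list()
  over <- which(s$occ_ec > inst$beds)
  if (length(over)) {
    v <- c(v, list(tibble::tibble(
      rule = "capacity", where = over,
      message = sprintf("elective+current occupancy %d exceeds Q=%d on day %d",
                        s$occ_ec[over], inst$beds, over))))
  }
  early <- which(!is.na(s$adm) & s$adm < inst$electives$expected_day)
  if (length(early)) {
    v <- c(v, list(tibble::tibble(
      rule = "expected_day", where = inst$electives$id[early],
      message = sprintf("elective %d admitted before its expected day",
                        inst$electives$id[early]))))
  }
  late <- which(!is.na(s$adm) & (s$adm < 1L | s$adm > s$horizon))
  if (length(late)) {
    v <- c(v, list(tibble::tibble(
      rule = "horizon", where = inst$electives$id[late],
      message = sprintf("elective %d admitted outside the horizon",
                        inst$electives$id[late]))))
  }
  capv <- which(s$em_count > inst$arrivals$max_per_day)
  if (length(capv)) {
    v <- c(v, list(tibble::tibble(
      rule = "emergency_cap", where = capv,
      message = sprintf("emergency count %d exceeds cap %d on day %d",
                        s$em_count[capv], inst$arrivals$max_per_day[capv], capv))))
  }
  viol <- if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(rule = character(), where = integer(), message = character())
  }
  structure(nrow(viol) == 0L, violations = viol)
}

# Fast feasibility core used inside the search loops.
feasible_fast <- function(s, inst) {
  all(s$occ_ec <= inst$beds) &&
    !any(s$adm < inst$electives$expected_day, na.rm = TRUE) &&
    all(s$em_count <= inst$arrivals$max_per_day)
}

# Integer keys for occupied (patient, day) pairs; day <= horizon < 64.
patient_day_keys <- function(s) {
  i <- which(!is.na(s$adm))
  starts <- c(s$adm[i], rep(1L, length(s$crem)), s$em$day)
  ends <- c(s$adm[i] + s$elos[i] - 1L, s$crem, s$em$day + s$em$los - 1L)
  ids <- c(seq_along(s$adm)[i] + 30000L, 40000L + seq_along(s$crem), s$em$id)
  ends <- pmin(ends, s$horizon)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]; ids <- ids[keep]
  len <- ends - starts + 1L
  day <- sequence(len) - 1L + rep(starts, len)
  rep(ids, len) * 64L + day
}

#' Stage-2 objectives: plan similarity and added beds
#'
#' `f21_similarity()` is the fraction of the reference (stage-1) plan's
#' occupied (patient, day) pairs that the stage-2 plan preserves — beds are
#' interchangeable, so a match means the same patient occupies some bed on
#' the same day. `f22_added_beds()` is the largest daily increase in required
#' beds over the reference plan (0 when no day needs more).
#'
#' @param reference The frozen stage-1 `icu_schedule`.
#' @param candidate The stage-2 `icu_schedule`.
#' @param normalize `"stage1"` (default) divides matches by the reference
#'   plan's patient-days; `"max"` divides by the larger plan's patient-days
#'   (so a plan that merely grows scores below 1).
#' @param by_bed Count a match only when the patient also keeps the same
#'   bed label under the deterministic first-fit layout (requires `inst`).
#' @param inst The `icu_instance`; only needed when `by_bed = TRUE`.
#' @return `f21_similarity()`: a value in `[0, 1]` (1 for an empty reference,
#'   by convention). `f22_added_beds()`: a non-negative integer.
#' @export
f21_similarity <- function(reference, candidate,
                           normalize = c("stage1", "max"),
                           by_bed = FALSE, inst = NULL) {
  normalize <- match.arg(normalize)
  if (by_bed) {
    if (is.null(inst)) abort("`by_bed = TRUE` requires `inst`.")
    key <- function(s) {
      tab <- schedule_table(s, inst)
      paste(tab$bed, tab$patient_id, tab$day)
    }
    k1 <- key(reference)
    k2 <- key(candidate)
  } else {
    k1 <- patient_day_keys(reference)
    k2 <- patient_day_keys(candidate)
  }
  if (length(k1) == 0L) return(1)
  denom <- switch(normalize, stage1 = length(k1),
                  max = max(length(k1), length(k2)))
  sum(k1 %in% k2) / denom
}

#' @rdname f21_similarity
#' @export
f22_added_beds <- function(reference, candidate) {
  q1 <- reference$occ_ec + reference$occ_em
  q2 <- candidate$occ_ec + candidate$occ_em
  max(0L, max(q2 - q1))
}

evaluate_stage2 <- function(candidate, reference) {
  c(f21 = f21_similarity(reference, candidate),
    f22 = as.numeric(f22_added_beds(reference, candidate)))
}

#' Exact bed-occupancy distribution for a day
#'
#' Treats the day's emergency arrival count as random with its truncated
#' Poisson law while holding all other occupancy (electives, currents, and
#' emergencies carried over or realised on other days) fixed, and shifts that
#' law by the deterministic part.
#'
#' @param s An `icu_schedule`.
#' @param inst The `icu_instance`.
#' @param t Day index.
#' @return Tibble with columns `beds` and `prob`; probabilities sum to 1.
#' @export
occupancy_pmf <- function(s, inst, t) {
  check_day(s, t)
  d <- (s$occ_ec[t] + s$occ_em[t]) - s$em_count[t]
  cap <- inst$arrivals$max_per_day[t]
  rate <- inst$arrivals$rates[t]
  if (cap <= 0L || rate == 0) {
    return(tibble::tibble(beds = as.integer(d), prob = 1))
  }
  k <- 0:cap
  p <- dpois(k, rate)
  tibble::tibble(beds = as.integer(d + k), prob = p / sum(p))
}

#' Long-format bed layout of a schedule
#'
#' Assigns deterministic bed labels by first-fit: patients are processed in
#' category priority (current, then emergency, then elective), by start day
#' and ascending id, and each takes the lowest-numbered bed free over their
#' whole stay. Labels beyond `B<Q>` mark overflow demand. Bed identity never
#' affects any objective; this is a reporting layout.
#'
#' @param s An `icu_schedule`.
#' @param inst The `icu_instance`.
#' @return Tibble with columns `day`, `bed`, `patient_id`, `category`.
#' @export
schedule_table <- function(s, inst) {
  i <- which(!is.na(s$adm))
  pats <- dplyr::bind_rows(
    tibble::tibble(id = inst$currents$id, start = 1L, end = s$crem,
                   category = "current", prio = 1L),
    tibble::tibble(id = s$em$id, start = s$em$day,
                   end = s$em$day + s$em$los - 1L,
                   category = "emergency", prio = 2L),
    tibble::tibble(id = inst$electives$id[i], start = s$adm[i],
                   end = s$adm[i] + s$elos[i] - 1L,
                   category = "elective", prio = 3L)
  ) |>
    dplyr::mutate(end = pmin(.data$end, s$horizon)) |>
    dplyr::filter(.data$start <= .data$end) |>
    dplyr::arrange(.data$prio, .data$start, .data$id)
  nbeds <- max(c(inst$beds, s$occ_ec + s$occ_em))
  free <- matrix(TRUE, nrow = nbeds, ncol = s$horizon)
  rows <- vector("list", nrow(pats))
  for (p in seq_len(nrow(pats))) {
    win <- pats$start[p]:pats$end[p]
    bed <- which(matrixStats_all_rows(free, win))[1]
    if (is.na(bed)) {
      # whole-stay first-fit can fragment: grow the pool
      free <- rbind(free, matrix(TRUE, nrow = 8L, ncol = s$horizon))
      bed <- which(matrixStats_all_rows(free, win))[1]
    }
    free[bed, win] <- FALSE
    rows[[p]] <- tibble::tibble(day = win, bed = paste0("B", bed),
                                patient_id = pats$id[p],
                                category = pats$category[p])
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$day, .data$bed)
}

# Rows of `m` that are TRUE across all columns in `cols`.
matrixStats_all_rows <- function(m, cols) {
  if (length(cols) == 1L) m[, cols] else rowSums(m[, cols, drop = FALSE]) == length(cols)
}
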