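#' Sample a length-of-stay extension draw
#'
#' One stage-2 disturbance: a per-patient LOS extension for every elective
#' and current patient, drawn from an extension distribution, plus a stream
#' of new emergency arrivals from the instance's arrival model. In
#' `"additive"` mode the drawn value is the number of extra days; in
#' `"multiplicative"` mode the drawn value is a growth fraction `r` and the
#' extended stay is the smallest integer at least `los * (1 + r)`.
#'
#' @param inst An `icu_instance`.
#' @param dist An [extension_table()]; default the instance's own.
#' @param seed Integer seed (extensions and new arrivals use separate
#'   substreams, so the disturbance is reproducible independently of any
#'   search randomness).
#' @param new_arrivals Sample a new emergency stream? (TRUE by default;
#'   FALSE gives a pure LOS disturbance.)
#' @return An `icu_draw`: `elective` and `current` extension-day vectors
#'   (aligned with the instance tables, named by id) and a `new_emergencies`
#'   tibble.
#' @export
sample_extensions <- function(inst, dist = NULL, seed = NULL,
                              new_arrivals = TRUE) {
  dist <- dist %||% inst$extension
  stopifnot(inherits(dist, "icu_extension"))
  if (abs(sum(dist$prob) - 1) > 1e-9) {
    abort("Extension probabilities must sum to 1.")
  }
  # inverse-CDF sampling over the sorted support: under a shared seed the
  # same uniforms map through each scenario's quantile function, so a
  # stochastically dominating scenario draws pointwise-larger extensions
  # (common random numbers across scenario sweeps)
  draw_ext <- function(base, seed) {
    with_seed(seed, {
      u <- runif(length(base))
      r <- dist$extend[findInterval(u, cumsum(dist$prob), left.open = TRUE) + 1L]
      if (dist$mode == "additive") as.integer(r)
      else as.integer(ceiling(base * (1 + r)) - base)
    })
  }
  ext_el <- draw_ext(inst$electives$los, derive_seed(seed, 2L))
  ext_cu <- draw_ext(inst$currents$remaining, derive_seed(seed, 3L))
  new_em <- if (new_arrivals) {
    sample_emergency_stream(inst, seed = derive_seed(seed, 4L), id_offset = 5000L)
  } else {
    tibble::tibble(id = integer(), day = integer(), los = integer())
  }
  structure(
    list(elective = setNames(ext_el, inst$electives$id),
         current = setNames(ext_cu, inst$currents$id),
         new_emergencies = new_em, dist = dist),
    class = "icu_draw"
  )
}

#' A disturbance with no extensions and no new arrivals
#'
#' @param inst An `icu_instance`.
#' @return An `icu_draw` under which every stage-1 schedule is unchanged.
#' @export
zero_draw <- function(inst) {
  structure(
    list(elective = setNames(integer(nrow(inst$electives)), inst$electives$id),
         current = setNames(integer(nrow(inst$currents)), inst$currents$id),
         new_emergencies = tibble::tibble(id = integer(), day = integer(),
                                          los = integer()),
         dist = extension_table(0, 1)),
    class = "icu_draw"
  )
}

# Recompute cached occupancy profiles after field edits.
rebuild_schedule <- function(s) {
  horizon <- s$horizon
  i <- which(!is.na(s$adm))
  occ_el <- occupancy_from_windows(s$adm[i], s$adm[i] + s$elos[i] - 1L, horizon)
  occ_cu <- occupancy_from_windows(rep(1L, length(s$crem)), s$crem, horizon)
  s$occ_em <- occupancy_from_windows(s$em$day, s$em$day + s$em$los - 1L, horizon)
  s$occ_ec <- occ_el + occ_cu
  s$em_count <- tabulate(s$em$day, nbins = horizon)
  s
}

#' Apply an extension draw to a schedule
#'
#' Lengthens the in-effect LOS of elective and current patients in place;
#' admission days and the emergency stream are untouched. The result may
#' violate capacity — that is exactly what the stage-2 strategies repair.
#'
#' @param s An `icu_schedule`.
#' @param draw An `icu_draw`.
#' @return An `icu_schedule` with extended stays.
#' @export
apply_extensions <- function(s, draw) {
  stopifnot(inherits(draw, "icu_draw"),
            length(draw$elective) == length(s$elos),
            length(draw$current) == length(s$crem))
  s$elos <- s$elos + as.integer(draw$elective)
  s$crem <- s$crem + as.integer(draw$current)
  rebuild_schedule(s)
}

# Extended stays + combined emergency stream, with the draw's new arrivals
# truncated at the daily Poisson cap (the cap is part of the disturbance
# definition: arrivals beyond it are never admissible, for any strategy).
prepare_stage2 <- function(inst, s1, draw) {
  elos2 <- s1$elos + as.integer(draw$elective)
  crem2 <- s1$crem + as.integer(draw$current)
  new <- as.data.frame(draw$new_emergencies)
  dropped <- 0L
  if (nrow(new)) {
    allowed <- pmax(0L, inst$arrivals$max_per_day - s1$em_count)
    keep <- unlist(lapply(seq_len(inst$horizon), function(t) {
      idx <- which(new$day == t)
      head(idx, allowed[t])
    }))
    dropped <- nrow(new) - length(keep)
    new <- new[sort(keep), , drop = FALSE]
  }
  list(elos = elos2, crem = crem2,
       em = rbind(as.data.frame(s1$em), new),
       new_kept = nrow(new), dropped_at_cap = dropped)
}

repair_result <- function(strategy, schedule, reference, inst,
                          rejected = 0L, postponed = 0L, feasible = TRUE) {
  structure(
    list(strategy = strategy, schedule = schedule,
         f21 = f21_similarity(reference, schedule),
         f22 = as.numeric(f22_added_beds(reference, schedule)),
         rejected_emergencies = as.integer(rejected),
         postponed_electives = as.integer(postponed),
         n_current = length(schedule$crem),
         n_emergency = nrow(schedule$em),
         n_elective = sum(!is.na(schedule$adm)),
         feasible = feasible),
    class = "icu_repair"
  )
}

#' @export
print.icu_repair <- function(x, ...) {
  cat(sprintf("<icu_repair: %s>  f21 = %.3f, f22 = %g\n",
              x$strategy, x$f21, x$f22))
  cat(sprintf("  admitted: %d elective, %d emergency, %d current; rejected %d, postponed %d\n",
              x$n_elective, x$n_emergency, x$n_current,
              x$rejected_emergencies, x$postponed_electives))
  invisible(x)
}

#' Stage-2 repair strategies
#'
#' Three ways to absorb an LOS-extension disturbance:
#'
#' * `elective_first()` keeps every stage-1 elective and current assignment
#'   (with extended stays) and commits beds to the whole admissible emergency
#'   demand; the existing bed stock cannot hold all of it, so emergency
#'   arrivals on saturated days are displaced onto added beds (reported as
#'   `rejected_emergencies` — patients the original stock turns away). The
#'   bed requirement counts everyone served, so this strategy needs the most
#'   added beds but preserves the elective plan exactly (`f21 = 1`).
#' * `emergency_first()` serves every emergency and current patient first,
#'   then re-admits electives greedily in re-insertion priority order under
#'   the elective-plus-current stock constraint: each keeps its stage-1 day
#'   when the extended stays still fit, and otherwise moves to the earliest
#'   feasible day at or after its expected day (so a zero disturbance
#'   reproduces stage 1 exactly). No emergency is ever rejected; electives
#'   admitted later than their stage-1 day, or not at all, are counted as
#'   `postponed_electives`.
#' * `recall()` re-runs the evolutionary search ([run_stage2()]) and returns
#'   the front member with the fewest added beds (ties broken by higher
#'   similarity); the stage-1 objective values are hard bounds.
#'
#' @param s The stage-1 `icu_schedule` being repaired.
#' @param inst The `icu_instance`.
#' @param draw An `icu_draw` disturbance.
#' @param params,seed For `recall()`: forwarded to [run_stage2()].
#' @return An `icu_repair`: strategy label, repaired schedule, `f21`, `f22`,
#'   and rejection/postponement counts.
#' @export
elective_first <- function(s, inst, draw) {
  prep <- prepare_stage2(inst, s, draw)
  s2 <- build_schedule(inst, s$adm, prep$elos, prep$crem, prep$em)
  # arrivals landing on days whose committed occupancy already fills the
  # stock are served only by added beds
  occ <- s2$occ_ec + s2$occ_em
  over <- pmax(0L, occ - inst$beds)
  rejected <- sum(pmin(s2$em_count, over))
  repair_result("elective_first", s2, s, inst, rejected = rejected)
}

#' @rdname elective_first
#' @export
emergency_first <- function(s, inst, draw) {
  prep <- prepare_stage2(inst, s, draw)
  ctx <- make_ctx(inst, elos = prep$elos, crem = prep$crem, em_fixed = prep$em)
  s2 <- build_schedule(inst, rep(NA_integer_, length(s$adm)),
                       prep$elos, prep$crem, prep$em)
  # electives re-packed under the stock constraint (elective + current <= Q,
  # as in stage 1; emergencies always overflow onto added beds instead of
  # being turned away). Pass 1: stage-1 admissions keep their day where the
  # extended stays still fit, so a zero disturbance reproduces stage 1
  # exactly. Pass 2: displaced and previously unadmitted electives go to the
  # earliest feasible day in re-insertion priority order.
  for (i in ctx$prio) {
    d0 <- s$adm[i]
    if (is.na(d0)) next
    e <- min(d0 + s2$elos[i] - 1L, s2$horizon)
    if (all(s2$occ_ec[d0:e] < ctx$Q)) s2 <- op_insert(s2, i, d0)
  }
  s2 <- op_reinsert(s2, ctx)
  was <- which(!is.na(s$adm))
  postponed <- sum(is.na(s2$adm[was]) | s2$adm[was] > s$adm[was], na.rm = TRUE)
  repair_result("emergency_first", s2, s, inst, postponed = postponed)
}

#' @rdname elective_first
#' @export
recall <- function(s, inst, draw, params = ga_params(pop = 30, generations = 40),
                   seed = NULL) {
  front <- run_stage2(inst, s, draw, params = params, seed = seed)
  # fronts are sorted by (f22 ascending, f21 descending): row 1 is the pick
  s2 <- front$schedule[[1]]
  was <- which(!is.na(s$adm))
  postponed <- sum(is.na(s2$adm[was]) | s2$adm[was] > s$adm[was], na.rm = TRUE)
  res <- repair_result("recall", s2, s, inst, postponed = postponed,
                       feasible = front$feasible[1])
  res$front <- front
  res
}

#' Run all three repair strategies on one disturbance
#'
#' @param s The stage-1 `icu_schedule`.
#' @param inst The `icu_instance`.
#' @param draw An `icu_draw`.
#' @param params,seed Forwarded to [recall()].
#' @return An `icu_repairs` tibble: one row per strategy with `f21`, `f22`,
#'   rejection/postponement counts, and the repaired schedule as a list
#'   column.
#' @export
repair_strategies <- function(s, inst, draw,
                              params = ga_params(pop = 30, generations = 40),
                              seed = NULL) {
  res <- list(
    elective_first(s, inst, draw),
    emergency_first(s, inst, draw),
    recall(s, inst, draw, params = params, seed = seed)
  )
  out <- dplyr::bind_rows(lapply(res, function(r) {
    tibble::tibble(strategy = r$strategy, f21 = r$f21, f22 = r$f22,
                   rejected_emergencies = r$rejected_emergencies,
                   postponed_electives = r$postponed_electives,
                   n_elective = r$n_elective, n_emergency = r$n_emergency,
                   n_current = r$n_current, feasible = r$feasible)
  }))
  out$schedule <- lapply(res, `[[`, "schedule")
  structure(out, class = c("icu_repairs", class(tibble::tibble())))
}
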