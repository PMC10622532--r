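#' Evolutionary search parameters
#'
#' Defaults follow the case-study settings: population 100, 200 generations,
#' mutation rate 0.1, crossover rate 0.7. Rates are applied per offspring
#' pair (crossover) and per individual (mutation).
#'
#' @param pop Population size (even, at least 2).
#' @param generations Number of generations.
#' @param mutation_rate,crossover_rate Probabilities in `[0, 1]`.
#' @return A `ga_params` list.
#' @export
ga_params <- function(pop = 100, generations = 200,
                      mutation_rate = 0.1, crossover_rate = 0.7) {
  stopifnot(is_count(pop, 2L), pop %% 2 == 0, is_count(generations, 1L),
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(list(pop = as.integer(pop), generations = as.integer(generations),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate),
            class = "ga_params")
}

# ---- search context ---------------------------------------------------------
# Plain-vector snapshot of everything the operators touch, so the hot loop
# never indexes tibbles. `em_fixed` pins the emergency stream (stage 2);
# stage-1 individuals each sample their own stream at creation.
make_ctx <- function(inst, elos = NULL, crem = NULL, em_fixed = NULL) {
  el <- inst$electives
  elos <- if (is.null(elos)) el$los else as.integer(elos)
  crem <- if (is.null(crem)) inst$currents$remaining else as.integer(crem)
  list(
    inst = inst,
    exp = el$expected_day, elos = elos, loss = el$loss,
    crem = crem,
    Q = inst$beds, horizon = inst$horizon,
    mp = inst$arrivals$max_per_day,
    em_fixed = em_fixed,
    # re-insertion priority: larger loss first, shorter stay first, then id
    prio = order(-el$loss, elos, el$id)
  )
}

empty_em <- function() data.frame(id = integer(), day = integer(), los = integer())

sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

# Start days d >= from at which an L-day stay fits under the Q cap.
feasible_days <- function(occ_ec, Q, from, L, horizon) {
  if (from > horizon) return(integer())
  free <- occ_ec < Q
  out <- integer()
  for (d in from:horizon) {
    e <- min(d + L - 1L, horizon)
    if (all(free[d:e])) out <- c(out, d)
  }
  out
}

op_insert <- function(s, i, d) {
  e <- min(d + s$elos[i] - 1L, s$horizon)
  s$occ_ec[d:e] <- s$occ_ec[d:e] + 1L
  s$adm[i] <- d
  s
}

op_remove <- function(s, i) {
  d <- s$adm[i]
  e <- min(d + s$elos[i] - 1L, s$horizon)
  s$occ_ec[d:e] <- s$occ_ec[d:e] - 1L
  s$adm[i] <- NA_integer_
  s
}

# ---- operators --------------------------------------------------------------

#' Generate one random feasible schedule
#'
#' Builds an individual the way the encoding prescribes: current patients
#' claim their beds first, an emergency stream is sampled (and thereafter
#' travels with the individual — variation operators only touch elective
#' genes), and electives are placed in random order at random feasible days
#' on or after their expected day. The result is always feasible.
#'
#' @param inst An `icu_instance`.
#' @param seed Optional seed; NULL draws in the ambient RNG stream.
#' @return An `icu_schedule`.
#' @export
random_individual <- function(inst, seed = NULL) {
  with_seed(seed, {
    ctx <- make_ctx(inst)
    op_random_individual(ctx)
  })
}

op_random_individual <- function(ctx) {
  inst <- ctx$inst
  em <- ctx$em_fixed %||% as.data.frame(sample_emergency_stream(inst))
  s <- build_schedule(inst, rep(NA_integer_, length(ctx$exp)),
                      ctx$elos, ctx$crem, em)
  for (i in sample.int(length(ctx$exp))) {
    days <- feasible_days(s$occ_ec, ctx$Q, ctx$exp[i], s$elos[i], s$horizon)
    if (length(days)) s <- op_insert(s, i, sample1(days))
  }
  s
}

# Random processing order, earliest feasible day: a low-delay individual.
op_earliest_individual <- function(ctx) {
  inst <- ctx$inst
  em <- ctx$em_fixed %||% as.data.frame(sample_emergency_stream(inst))
  s <- build_schedule(inst, rep(NA_integer_, length(ctx$exp)),
                      ctx$elos, ctx$crem, em)
  for (i in sample.int(length(ctx$exp))) {
    days <- feasible_days(s$occ_ec, ctx$Q, ctx$exp[i], s$elos[i], s$horizon)
    if (length(days)) s <- op_insert(s, i, days[1])
  }
  s
}

#' Initial population
#'
#' @param inst An `icu_instance`.
#' @param params [ga_params()].
#' @param seed Optional seed.
#' @return List of `pop` feasible `icu_schedule`s.
#' @export
initial_population <- function(inst, params = ga_params(), seed = NULL) {
  with_seed(seed, {
    ctx <- make_ctx(inst)
    lapply(seq_len(params$pop), function(i) op_reinsert(op_random_individual(ctx), ctx))
  })
}

# Swap the admission days of electives i and j inside one schedule.
# Returns NULL when the swapped placement breaks capacity or expected-day
# constraints over either patient's full stay.
swap_pair <- function(s, i, j, ctx) {
  di <- s$adm[i]; dj <- s$adm[j]
  if (identical(di, dj)) return(s)
  if (!is.na(di)) s <- op_remove(s, i)
  if (!is.na(dj)) s <- op_remove(s, j)
  if (!is.na(dj)) {
    if (dj < ctx$exp[i]) return(NULL)
    e <- min(dj + s$elos[i] - 1L, s$horizon)
    if (any(s$occ_ec[dj:e] >= ctx$Q)) return(NULL)
    s <- op_insert(s, i, dj)
  }
  if (!is.na(di)) {
    if (di < ctx$exp[j]) return(NULL)
    e <- min(di + s$elos[j] - 1L, s$horizon)
    if (any(s$occ_ec[di:e] >= ctx$Q)) return(NULL)
    s <- op_insert(s, j, di)
  }
  s
}

#' Capacity-respecting crossover
#'
#' Two elective patients are selected at random and their admission dates
#' exchanged within each parent. The exchange is kept only if both children
#' respect capacity and expected-day constraints over each patient's full
#' stay; otherwise the parents are returned unchanged.
#'
#' @param a,b Parent `icu_schedule`s (feasible).
#' @param inst The `icu_instance`.
#' @return List of two feasible `icu_schedule`s.
#' @export
crossover <- function(a, b, inst) {
  ctx <- make_ctx(inst, elos = a$elos, crem = a$crem)
  op_crossover(a, b, ctx)
}

op_crossover <- function(a, b, ctx) {
  pool <- which(!is.na(a$adm) | !is.na(b$adm))
  if (length(pool) < 2L) return(list(a, b))
  ij <- pool[sample.int(length(pool), 2L)]
  c1 <- swap_pair(a, ij[1], ij[2], ctx)
  c2 <- swap_pair(b, ij[1], ij[2], ctx)
  if (is.null(c1) || is.null(c2)) list(a, b) else list(c1, c2)
}

#' Mutation: delete one elective, insert a shorter-staying one
#'
#' A random admitted elective loses its admission; an unadmitted elective
#' whose LOS does not exceed the removed patient's is inserted at a random
#' feasible day on or after its expected day. When no candidate fits, the
#' deletion alone stands. The result is always feasible.
#'
#' @param s A feasible `icu_schedule`.
#' @param inst The `icu_instance`.
#' @return A feasible `icu_schedule`.
#' @export
mutate_schedule <- function(s, inst) {
  op_mutate(s, make_ctx(inst, elos = s$elos, crem = s$crem))
}

op_mutate <- function(s, ctx) {
  admitted <- which(!is.na(s$adm))
  if (length(admitted) == 0L) return(s)
  r <- sample1(admitted)
  lim <- s$elos[r]
  s <- op_remove(s, r)
  cand <- which(is.na(s$adm) & s$elos <= lim)
  cand <- cand[cand != r]
  for (i in cand[sample.int(length(cand))]) {
    days <- feasible_days(s$occ_ec, ctx$Q, ctx$exp[i], s$elos[i], s$horizon)
    if (length(days)) return(op_insert(s, i, sample1(days)))
  }
  s
}

#' Re-insertion repair
#'
#' Fills bed-days left vacant by variation: unadmitted electives are
#' considered by priority (loss of chance descending, LOS ascending, id
#' ascending) and each is placed at the earliest feasible day on or after its
#' expected day. Insertions only consume capacity, so a single ordered pass
#' is maximal: afterwards no unadmitted elective fits any remaining vacancy.
#'
#' @param s A feasible `icu_schedule`.
#' @param inst The `icu_instance`.
#' @return A feasible `icu_schedule` admitting at least as many electives.
#' @export
reinsert <- function(s, inst) {
  op_reinsert(s, make_ctx(inst, elos = s$elos, crem = s$crem))
}

op_reinsert <- function(s, ctx) {
  for (i in ctx$prio) {
    if (!is.na(s$adm[i])) next
    days <- feasible_days(s$occ_ec, ctx$Q, ctx$exp[i], s$elos[i], s$horizon)
    if (length(days)) s <- op_insert(s, i, days[1])
  }
  s
}

# ---- non-dominated sorting --------------------------------------------------

# obj: n x m matrix, all objectives to MINIMIZE. viol: optional non-negative
# constraint violations; infeasible points are pushed beyond the worst
# feasible value in every objective (constrained domination), so they can
# only fill fronts after every feasible point.
nd_sort <- function(obj, viol = NULL) {
  n <- nrow(obj)
  m <- ncol(obj)
  if (!is.null(viol) && any(viol > 0)) {
    feas <- viol <= 0
    for (j in seq_len(m)) {
      w <- if (any(feas)) max(obj[feas, j]) else 0
      obj[!feas, j] <- w + viol[!feas]
    }
  }
  le <- matrix(TRUE, n, n)
  eq <- matrix(TRUE, n, n)
  for (j in seq_len(m)) {
    oj <- obj[, j]
    le <- le & outer(oj, oj, "<=")
    eq <- eq & outer(oj, oj, "==")
  }
  dom <- le & !eq # dom[i, j]: i dominates j
  front <- integer(n)
  rem <- seq_len(n)
  f <- 0L
  while (length(rem)) {
    f <- f + 1L
    nd <- rem[colSums(dom[rem, rem, drop = FALSE]) == 0L]
    front[nd] <- f
    rem <- setdiff(rem, nd)
  }
  crowd <- numeric(n)
  for (fi in seq_len(f)) {
    idx <- which(front == fi)
    if (length(idx) <= 2L) {
      crowd[idx] <- Inf
      next
    }
    cd <- numeric(length(idx))
    for (j in seq_len(m)) {
      o <- obj[idx, j]
      ord <- order(o)
      rng <- o[ord[length(ord)]] - o[ord[1]]
      cd[ord[1]] <- Inf
      cd[ord[length(ord)]] <- Inf
      if (rng > 0) {
        inner <- 2:(length(ord) - 1)
        cd[ord[inner]] <- cd[ord[inner]] +
          (o[ord[inner + 1]] - o[ord[inner - 1]]) / rng
      }
    }
    crowd[idx] <- cd
  }
  list(front = front, crowding = crowd)
}

#' Non-dominated sorting with crowding distance
#'
#' Fast non-dominated sort of a set of objective vectors, with per-front
#' crowding distances (infinite at each front's per-objective extremes).
#' Maximized objectives are negated internally.
#'
#' @param data Data frame or matrix whose columns are objective values.
#' @param senses Character vector, one of `"min"`/`"max"` per column.
#' @return The input as a tibble with `.front` (1 = Pareto-first) and
#'   `.crowding` columns appended.
#' @examples
#' pareto_rank(data.frame(a = c(1, 2, 3), b = c(3, 2, 1)),
#'             senses = c("min", "min"))
#' @export
pareto_rank <- function(data, senses) {
  m <- as.matrix(as.data.frame(data))
  stopifnot(is.numeric(m), length(senses) == ncol(m),
            all(senses %in% c("min", "max")))
  sgn <- ifelse(senses == "max", -1, 1)
  r <- nd_sort(sweep(m, 2L, sgn, `*`))
  tibble::as_tibble(as.data.frame(data)) |>
    dplyr::mutate(.front = r$front, .crowding = r$crowding)
}

tournament <- function(front, crowding) {
  ij <- sample.int(length(front), 2L)
  i <- ij[1]; j <- ij[2]
  if (front[i] < front[j]) i
  else if (front[j] < front[i]) j
  else if (crowding[i] >= crowding[j]) i else j
}

# One elitist generation: parents + offspring, truncated by rank/crowding.
evolve <- function(pop, objmin, params, ctx, eval_min, viol_fn = NULL) {
  n <- length(pop)
  viol <- if (is.null(viol_fn)) NULL else vapply(pop, viol_fn, numeric(1))
  r <- nd_sort(objmin, viol)
  children <- vector("list", n)
  k <- 0L
  while (k < n) {
    p1 <- pop[[tournament(r$front, r$crowding)]]
    p2 <- pop[[tournament(r$front, r$crowding)]]
    pair <- if (runif(1) < params$crossover_rate) {
      op_crossover(p1, p2, ctx)
    } else {
      list(p1, p2)
    }
    for (c_ in pair) {
      if (k >= n) break
      if (runif(1) < params$mutation_rate) c_ <- op_mutate(c_, ctx)
      c_ <- op_reinsert(c_, ctx)
      k <- k + 1L
      children[[k]] <- c_
    }
  }
  allpop <- c(pop, children)
  allobj <- rbind(objmin, t(vapply(children, eval_min, numeric(ncol(objmin)))))
  allviol <- if (is.null(viol_fn)) NULL else
    c(viol, vapply(children, viol_fn, numeric(1)))
  ra <- nd_sort(allobj, allviol)
  keep <- order(ra$front, -ra$crowding)[seq_len(n)]
  list(pop = allpop[keep], objmin = allobj[keep, , drop = FALSE])
}

genotype_key <- function(s) {
  paste(c(s$adm, s$em$id, s$em$day, s$em$los), collapse = ",")
}

# ---- stage drivers ----------------------------------------------------------

#' Run the stage-1 allocation search
#'
#' Optimizes (maximize bed occupancy rate `f11`, minimize delay index `f12`,
#' maximize emergency admission rate `f13`) over feasible schedules with an
#' elitist NSGA-II using the encoding-aware operators. Each individual
#' carries its own realised emergency stream, sampled at creation and
#' preserved by the operators, so the front spans arrival scenarios from
#' emergency-light to emergency-heavy.
#'
#' @param inst An `icu_instance`.
#' @param params [ga_params()].
#' @param seed Integer seed for the whole run.
#' @param trace Record per-generation first-front size and dominated
#'   hypervolume? The log is attached to the result as attribute `"trace"`
#'   (a tibble with columns `generation`, `front_size`, `hypervolume`).
#' @return An `icu_front` tibble: one row per first-front solution with
#'   admitted counts per category, the three objectives, and the schedule as
#'   a list column.
#' @export
run_stage1 <- function(inst, params = ga_params(), seed = NULL, trace = FALSE) {
  with_seed(seed, {
    ctx <- make_ctx(inst)
    eval_min <- function(s) {
      c(-f11_fast(s, ctx), f12_fast(s, ctx), -f13_fast(s, ctx))
    }
    pop <- lapply(seq_len(params$pop),
                  function(i) op_reinsert(op_random_individual(ctx), ctx))
    objmin <- t(vapply(pop, eval_min, numeric(3)))
    log <- if (trace) vector("list", params$generations)
    for (g in seq_len(params$generations)) {
      step <- evolve(pop, objmin, params, ctx, eval_min)
      pop <- step$pop
      objmin <- step$objmin
      if (trace) log[[g]] <- trace_row(g, objmin)
    }
    r <- nd_sort(objmin)
    idx <- which(r$front == 1L)
    idx <- idx[!duplicated(vapply(pop[idx], genotype_key, character(1)))]
    out <- front_tibble(pop[idx], inst, stage = 1L, params = params)
    if (trace) attr(out, "trace") <- dplyr::bind_rows(log)
    out
  })
}

# One run-log record: first-front size and dominated hypervolume of the
# current population (reference point just beyond the population's worst).
trace_row <- function(g, objmin) {
  r <- nd_sort(objmin)
  f1 <- objmin[r$front == 1L, , drop = FALSE]
  ref <- apply(objmin, 2, max) + 0.1
  tibble::tibble(generation = g, front_size = nrow(unique(f1)),
                 hypervolume = hypervolume(f1, ref))
}

f11_fast <- function(s, ctx) sum(s$occ_ec + s$occ_em) / (ctx$Q * s$horizon)

f12_fast <- function(s, ctx) {
  i <- which(!is.na(s$adm))
  if (!length(i)) return(0)
  sum(ctx$loss[i] * (s$adm[i] - ctx$exp[i])) / length(i)
}

f13_fast <- function(s, ctx) {
  keep <- ctx$mp > 0L
  if (!any(keep)) return(0)
  mean(s$em_count[keep] / ctx$mp[keep])
}

front_tibble <- function(schedules, inst, stage, params,
                         ref = NULL, feasible = NULL) {
  if (stage == 1L) {
    ctx <- make_ctx(inst)
    out <- tibble::tibble(
      solution = seq_along(schedules),
      n_current = length(inst$currents$id),
      n_emergency = vapply(schedules, function(s) nrow(s$em), integer(1)),
      n_elective = vapply(schedules, function(s) sum(!is.na(s$adm)), integer(1)),
      f11 = vapply(schedules, f11_fast, numeric(1), ctx = ctx),
      f12 = vapply(schedules, f12_fast, numeric(1), ctx = ctx),
      f13 = vapply(schedules, f13_fast, numeric(1), ctx = ctx),
      schedule = schedules
    ) |>
      dplyr::arrange(dplyr::desc(.data$f13), .data$f12) |>
      dplyr::mutate(solution = dplyr::row_number())
  } else {
    out <- tibble::tibble(
      solution = seq_along(schedules),
      n_current = length(inst$currents$id),
      n_emergency = vapply(schedules, function(s) nrow(s$em), integer(1)),
      n_elective = vapply(schedules, function(s) sum(!is.na(s$adm)), integer(1)),
      f21 = vapply(schedules, function(s) f21_similarity(ref$schedule, s), numeric(1)),
      f22 = vapply(schedules, function(s) as.numeric(f22_added_beds(ref$schedule, s)),
                   numeric(1)),
      feasible = feasible %||% TRUE,
      schedule = schedules
    ) |>
      dplyr::arrange(.data$f22, dplyr::desc(.data$f21)) |>
      dplyr::mutate(solution = dplyr::row_number())
  }
  structure(out, class = c("icu_front", class(tibble::tibble())),
            stage = stage, params = params, reference = ref)
}

#' Freeze a stage-1 solution as the stage-2 reference
#'
#' @param front A stage-1 `icu_front`.
#' @param solution Row to freeze; default picks the compromise solution
#'   closest (in min-max-normalized objective space) to the ideal point.
#' @return An `icu_reference`: the frozen schedule plus its objective values,
#'   which become hard bounds for every stage-2 candidate.
#' @export
stage1_reference <- function(front, solution = NULL) {
  stopifnot(inherits(front, "icu_front"), attr(front, "stage") == 1L)
  if (is.null(solution)) {
    m <- cbind(-front$f11, front$f12, -front$f13)
    rng <- apply(m, 2, function(x) diff(range(x)))
    norm <- sweep(m, 2, apply(m, 2, min), `-`)
    norm <- sweep(norm, 2, ifelse(rng > 0, rng, 1), `/`)
    solution <- which.min(rowSums(norm^2))
  }
  s <- front$schedule[[solution]]
  structure(
    list(schedule = s,
         objectives = c(f11 = front$f11[solution], f12 = front$f12[solution],
                        f13 = front$f13[solution])),
    class = "icu_reference"
  )
}

as_reference <- function(ref, inst) {
  if (inherits(ref, "icu_reference")) return(ref)
  if (inherits(ref, "icu_schedule")) {
    return(structure(list(schedule = ref,
                          objectives = evaluate_stage1(ref, inst)),
                     class = "icu_reference"))
  }
  abort("`ref` must be an icu_reference or icu_schedule.")
}

#' Run the stage-2 re-allocation search
#'
#' Given a frozen stage-1 reference, an extension draw, and the instance,
#' searches for repaired schedules that maximize similarity to the reference
#' plan (`f21`) and minimize added beds (`f22`). Every candidate keeps the
#' realised emergency stream fixed (the stage-1 arrivals plus the draw's new
#' arrivals, truncated at the daily cap) and must not degrade any stage-1
#' objective; candidates that would are dominated by all compliant ones
#' (constrained domination). If the reference schedule itself remains within
#' capacity under the draw it is returned unchanged.
#'
#' @param inst An `icu_instance`.
#' @param ref An `icu_reference` (or stage-1 `icu_schedule`).
#' @param draw An extension draw from [sample_extensions()].
#' @param params [ga_params()]; stage 2 repairs a local neighbourhood, so
#'   smaller populations/generation counts than stage 1 suffice.
#' @param seed Integer seed.
#' @return A stage-2 `icu_front` with columns `f21`, `f22` and `feasible`
#'   (FALSE only when no candidate satisfied the stage-1 bounds).
#' @export
run_stage2 <- function(inst, ref, draw, params = ga_params(pop = 30, generations = 40),
                       seed = NULL) {
  ref <- as_reference(ref, inst)
  prep <- prepare_stage2(inst, ref$schedule, draw)
  s1x <- build_schedule(inst, ref$schedule$adm, prep$elos, prep$crem, prep$em)
  if (all(s1x$occ_ec <= inst$beds)) {
    return(front_tibble(list(s1x), inst, stage = 2L, params = params, ref = ref))
  }
  with_seed(seed, {
    ctx <- make_ctx(inst, elos = prep$elos, crem = prep$crem, em_fixed = prep$em)
    eval_min <- function(s) {
      c(-f21_similarity(ref$schedule, s),
        as.numeric(f22_added_beds(ref$schedule, s)))
    }
    tol <- 1e-9
    viol_fn <- function(s) {
      max(0, ref$objectives[["f11"]] - f11_fast(s, ctx) - tol) +
        max(0, f12_fast(s, ctx) - ref$objectives[["f12"]] - tol) +
        max(0, ref$objectives[["f13"]] - f13_fast(s, ctx) - tol)
    }
    # fresh initialization, as in stage 1: the re-run explores the whole
    # repair space rather than a neighbourhood of the reference plan, and
    # constrained domination pulls it toward the stage-1 bounds. Half the
    # individuals place electives at their earliest feasible day (the
    # low-delay side of the delay-index bound), half at random days.
    pop <- lapply(seq_len(params$pop), function(i) {
      s <- if (i %% 2L == 0L) op_earliest_individual(ctx)
           else op_random_individual(ctx)
      op_reinsert(s, ctx)
    })
    objmin <- t(vapply(pop, eval_min, numeric(2)))
    for (g in seq_len(params$generations)) {
      step <- evolve(pop, objmin, params, ctx, eval_min, viol_fn)
      pop <- step$pop
      objmin <- step$objmin
    }
    viol <- vapply(pop, viol_fn, numeric(1))
    feas <- viol <= 0
    if (any(feas)) {
      pool <- which(feas)
      r <- nd_sort(objmin[pool, , drop = FALSE])
      idx <- pool[r$front == 1L]
      ok <- TRUE
    } else {
      warn("No stage-2 candidate met the stage-1 objective bounds; returning least-violating solutions.")
      pool <- which(viol <= min(viol) + 1e-9)
      r <- nd_sort(objmin[pool, , drop = FALSE])
      idx <- pool[r$front == 1L]
      ok <- FALSE
    }
    idx <- idx[!duplicated(vapply(pop[idx], genotype_key, character(1)))]
    front_tibble(pop[idx], inst, stage = 2L, params = params, ref = ref,
                 feasible = ok)
  })
}

# Drop admitted electives until elective+current occupancy fits the bed
# stock, then re-insert. Deterministic choice: on the worst overflow day,
# drop the occupant with the smallest loss of chance, longest stay, highest
# id; `random = TRUE` picks a random occupant instead (population diversity).
repair_by_drop <- function(s, ctx, random = FALSE) {
  while (any(s$occ_ec > ctx$Q)) {
    d <- which.max(s$occ_ec)
    occ <- which(!is.na(s$adm) &
                   s$adm <= d &
                   s$adm + s$elos - 1L >= d)
    if (!length(occ)) break # overflow from currents alone: nothing to drop
    i <- if (random) sample1(occ) else {
      occ[order(ctx$loss[occ], -s$elos[occ], -occ)][1]
    }
    s <- op_remove(s, i)
  }
  op_reinsert(s, ctx)
}
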