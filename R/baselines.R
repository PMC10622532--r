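#' Baseline search parameters
#'
#' Literature-standard settings for the two baseline metaheuristics:
#' simulated annealing cools geometrically from 1000 to 1e-3 at rate 0.95;
#' tabu search runs 200 iterations with 10 candidates per iteration, a tenure
#' of 5 and a list capped at 50 move attributes.
#'
#' @param start_temp,end_temp,cooling_rate,moves_per_temp Annealing schedule.
#' @return A parameter list.
#' @export
mosa_params <- function(start_temp = 1000, end_temp = 1e-3,
                        cooling_rate = 0.95, moves_per_temp = 1L) {
  stopifnot(start_temp > end_temp, end_temp > 0,
            cooling_rate > 0, cooling_rate < 1, is_count(moves_per_temp, 1L))
  structure(list(start_temp = start_temp, end_temp = end_temp,
                 cooling_rate = cooling_rate,
                 moves_per_temp = as.integer(moves_per_temp)),
            class = "mosa_params")
}

#' @rdname mosa_params
#' @param tabu_list_size,tabu_tenure,candidate_set_size,iterations Tabu
#'   search controls.
#' @export
mots_params <- function(tabu_list_size = 50L, tabu_tenure = 5L,
                        candidate_set_size = 10L, iterations = 200L) {
  stopifnot(is_count(tabu_list_size, 1L), is_count(tabu_tenure, 1L),
            is_count(candidate_set_size, 1L), is_count(iterations, 1L))
  structure(list(tabu_list_size = as.integer(tabu_list_size),
                 tabu_tenure = as.integer(tabu_tenure),
                 candidate_set_size = as.integer(candidate_set_size),
                 iterations = as.integer(iterations)),
            class = "mots_params")
}

# Shared neighbourhood: the NSGA-II mutation, or an in-place exchange of two
# random electives' admission days (the crossover move applied to one
# solution), followed by re-insertion repair.
neighbour <- function(s, ctx) {
  if (runif(1) < 0.5) {
    s2 <- op_mutate(s, ctx)
  } else {
    pool <- which(!is.na(s$adm))
    s2 <- if (length(pool) >= 2L) {
      ij <- pool[sample.int(length(pool), 2L)]
      swap_pair(s, ij[1], ij[2], ctx) %||% s
    } else s
  }
  op_reinsert(s2, ctx)
}

# Stage-aware evaluation setup shared by both baselines.
stage_setup <- function(inst, stage, ref, draw) {
  if (stage == 1L) {
    ctx <- make_ctx(inst)
    list(
      ctx = ctx,
      eval_min = function(s) c(-f11_fast(s, ctx), f12_fast(s, ctx), -f13_fast(s, ctx)),
      viol_fn = NULL,
      init = function() op_reinsert(op_random_individual(ctx), ctx),
      m = 3L, ref = NULL
    )
  } else {
    if (is.null(ref) || is.null(draw)) {
      abort("Stage 2 requires `ref` and `draw`.")
    }
    ref <- as_reference(ref, inst)
    prep <- prepare_stage2(inst, ref$schedule, draw)
    ctx <- make_ctx(inst, elos = prep$elos, crem = prep$crem, em_fixed = prep$em)
    s1x <- build_schedule(inst, ref$schedule$adm, prep$elos, prep$crem, prep$em)
    tol <- 1e-9
    list(
      ctx = ctx,
      eval_min = function(s) c(-f21_similarity(ref$schedule, s),
                               as.numeric(f22_added_beds(ref$schedule, s))),
      viol_fn = function(s) {
        max(0, ref$objectives[["f11"]] - f11_fast(s, ctx) - tol) +
          max(0, f12_fast(s, ctx) - ref$objectives[["f12"]] - tol) +
          max(0, ref$objectives[["f13"]] - f13_fast(s, ctx) - tol)
      },
      init = function() repair_by_drop(s1x, ctx, random = TRUE),
      m = 2L, ref = ref
    )
  }
}

archive_add <- function(arch, s, o, viol, cap = 100L) {
  if (!is.null(viol) && viol > 0) return(arch)
  if (length(arch$pop)) {
    dominated_by_new <- apply(arch$obj, 1, function(x) all(o <= x) && any(o < x))
    new_dominated <- apply(arch$obj, 1, function(x) all(x <= o) && any(x < o))
    duplicate <- apply(arch$obj, 1, function(x) all(x == o))
    if (any(new_dominated) || any(duplicate)) return(arch)
    keep <- !dominated_by_new
    arch$pop <- arch$pop[keep]
    arch$obj <- arch$obj[keep, , drop = FALSE]
  }
  arch$pop <- c(arch$pop, list(s))
  arch$obj <- rbind(arch$obj, o)
  if (length(arch$pop) > cap) {
    r <- nd_sort(arch$obj)
    drop <- which.min(r$crowding)
    arch$pop <- arch$pop[-drop]
    arch$obj <- arch$obj[-drop, , drop = FALSE]
  }
  arch
}

#' Multi-objective simulated annealing
#'
#' Shares the schedule encoding, neighbourhood moves and objectives with the
#' NSGA-II. A neighbour that does not worsen any objective is always
#' accepted; a worsening neighbour is accepted with probability
#' `exp(-delta / temperature)`, where `delta` is the equal-weight sum of
#' min-max-normalized objective worsenings. An external archive of mutually
#' non-dominated solutions is maintained and returned.
#'
#' @param inst An `icu_instance`.
#' @param params [mosa_params()] / [mots_params()].
#' @param stage 1 or 2.
#' @param ref,draw Stage-2 reference and disturbance (required for stage 2).
#' @param seed Integer seed.
#' @return An `icu_front` of the archive.
#' @export
run_mosa <- function(inst, params = mosa_params(), stage = 1L,
                     ref = NULL, draw = NULL, seed = NULL) {
  stopifnot(inherits(params, "mosa_params"), stage %in% c(1L, 2L))
  with_seed(seed, {
    st <- stage_setup(inst, stage, ref, draw)
    cur <- st$init()
    cur_o <- st$eval_min(cur)
    cur_v <- if (is.null(st$viol_fn)) 0 else st$viol_fn(cur)
    arch <- archive_add(list(pop = list(), obj = NULL), cur, cur_o, cur_v)
    span <- matrix(rep(c(Inf, -Inf), each = st$m), nrow = 2, byrow = TRUE)
    temp <- params$start_temp
    while (temp > params$end_temp) {
      for (mv in seq_len(params$moves_per_temp)) {
        cand <- neighbour(cur, st$ctx)
        o <- st$eval_min(cand)
        v <- if (is.null(st$viol_fn)) 0 else st$viol_fn(cand)
        arch <- archive_add(arch, cand, o, v)
        span[1, ] <- pmin(span[1, ], o, cur_o)
        span[2, ] <- pmax(span[2, ], o, cur_o)
        scale <- pmax(span[2, ] - span[1, ], 1e-12)
        delta <- sum(pmax(0, (o - cur_o) / scale)) + pmax(0, v - cur_v) * st$m
        if (delta <= 0 || runif(1) < exp(-delta / temp)) {
          cur <- cand; cur_o <- o; cur_v <- v
        }
      }
      temp <- temp * params$cooling_rate
    }
    baseline_front(arch, inst, stage, params, st$ref)
  })
}

#' @rdname run_mosa
#' @export
run_mots <- function(inst, params = mots_params(), stage = 1L,
                     ref = NULL, draw = NULL, seed = NULL) {
  stopifnot(inherits(params, "mots_params"), stage %in% c(1L, 2L))
  with_seed(seed, {
    st <- stage_setup(inst, stage, ref, draw)
    cur <- st$init()
    cur_o <- st$eval_min(cur)
    cur_v <- if (is.null(st$viol_fn)) 0 else st$viol_fn(cur)
    arch <- archive_add(list(pop = list(), obj = NULL), cur, cur_o, cur_v)
    tabu <- tibble::tibble(key = character(), expires = integer())
    for (it in seq_len(params$iterations)) {
      cands <- lapply(seq_len(params$candidate_set_size),
                      function(i) neighbour(cur, st$ctx))
      objs <- t(vapply(cands, st$eval_min, numeric(st$m)))
      viols <- if (is.null(st$viol_fn)) numeric(length(cands)) else
        vapply(cands, st$viol_fn, numeric(1))
      keys <- lapply(cands, function(cand) move_keys(cur, cand))
      arch_sizes_before <- length(arch$pop)
      improves <- logical(length(cands))
      for (i in seq_along(cands)) {
        a2 <- archive_add(arch, cands[[i]], objs[i, ], viols[i])
        improves[i] <- !identical(a2$obj, arch$obj)
        arch <- a2
      }
      live <- tabu$key[tabu$expires > it]
      is_tabu <- vapply(keys, function(k) any(k %in% live), logical(1))
      r <- nd_sort(objs, if (any(viols > 0)) viols else NULL)
      ord <- order(r$front, -r$crowding)
      # aspiration: a tabu candidate that entered the archive is admissible
      admissible <- ord[!is_tabu[ord] | improves[ord]]
      pick <- if (length(admissible)) admissible[1] else ord[1]
      cur <- cands[[pick]]
      cur_o <- objs[pick, ]
      cur_v <- viols[pick]
      tabu <- dplyr::bind_rows(
        tabu,
        tibble::tibble(key = keys[[pick]],
                       expires = it + params$tabu_tenure)
      )
      tabu <- tabu[tabu$expires > it, , drop = FALSE]
      if (nrow(tabu) > params$tabu_list_size) {
        tabu <- tail(tabu, params$tabu_list_size)
      }
    }
    baseline_front(arch, inst, stage, params, st$ref)
  })
}

# Move attributes: (elective, old day, new day) for every admission changed.
move_keys <- function(from, to) {
  ch <- which(!(is.na(from$adm) & is.na(to$adm)) &
                (is.na(from$adm) != is.na(to$adm) |
                   (!is.na(from$adm) & !is.na(to$adm) & from$adm != to$adm)))
  if (!length(ch)) return("noop")
  sprintf("%d:%s>%s", ch, from$adm[ch], to$adm[ch])
}

baseline_front <- function(arch, inst, stage, params, ref) {
  if (!length(arch$pop)) {
    abort("Search archive is empty; no feasible solution was found.")
  }
  front_tibble(arch$pop, inst, stage = stage, params = params, ref = ref)
}

#' One-sided paired comparison of two algorithms' metrics
#'
#' Paired t-test of the alternative "the first algorithm's metric mean is
#' smaller" (appropriate for minimized metrics such as added beds).
#'
#' @param x,y Paired metric vectors (same runs, two algorithms).
#' @return One-row tibble: `mean_difference` (mean of `x - y`), `statistic`,
#'   `df`, `p_value`.
#' @export
compare_paired <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("Need at least 2 paired observations.")
  }
  ht <- t.test(x, y, paired = TRUE, alternative = "less")
  tibble::tibble(mean_difference = unname(ht$estimate),
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Compare NSGA-II against the MOSA and MOTS baselines
#'
#' For each seed: solves stage 1 with all three algorithms, freezes each
#' algorithm's own compromise solution, applies the same extension draw to
#' all three (paired design), solves stage 2, and records the comparison
#' metric. One-sided paired t-tests then ask whether NSGA-II's metric mean is
#' smaller than each baseline's.
#'
#' @param inst An `icu_instance`.
#' @param seeds Integer vector of run seeds (at least 2).
#' @param metric `"f22"` (added beds of the best stage-2 repair, default),
#'   `"f21"` (negated similarity, so that smaller is better), or
#'   `"admitted"` (negated mean admitted patients in the stage-1 front).
#' @param ga,mosa,mots,stage2 Parameter objects for the four searches.
#' @param scenario Extension distribution for the stage-2 disturbance.
#' @return An `icu_comparison`: `runs` (per seed and algorithm) and `tests`
#'   (one row per baseline).
#' @export
compare_algorithms <- function(inst, seeds, metric = c("f22", "f21", "admitted"),
                               ga = ga_params(pop = 50, generations = 100),
                               mosa = mosa_params(), mots = mots_params(),
                               stage2 = ga_params(pop = 30, generations = 40),
                               scenario = extension_table()) {
  metric <- match.arg(metric)
  if (length(seeds) < 2L) abort("Need at least 2 seeds for a paired test.")
  rows <- list()
  for (sd in seeds) {
    draw <- sample_extensions(inst, scenario, seed = derive_seed(sd, 7L))
    fronts <- list(
      nsga2 = run_stage1(inst, ga, seed = derive_seed(sd, 8L)),
      mosa = run_mosa(inst, mosa, stage = 1L, seed = derive_seed(sd, 9L)),
      mots = run_mots(inst, mots, stage = 1L, seed = derive_seed(sd, 10L))
    )
    for (alg in names(fronts)) {
      f1 <- fronts[[alg]]
      ref <- stage1_reference(f1)
      f2 <- switch(alg,
        nsga2 = run_stage2(inst, ref, draw, params = stage2,
                           seed = derive_seed(sd, 11L)),
        mosa = run_mosa(inst, mosa, stage = 2L, ref = ref, draw = draw,
                        seed = derive_seed(sd, 12L)),
        mots = run_mots(inst, mots, stage = 2L, ref = ref, draw = draw,
                        seed = derive_seed(sd, 13L))
      )
      value <- switch(metric,
        f22 = min(f2$f22),
        f21 = -max(f2$f21),
        admitted = -mean(f1$n_current + f1$n_emergency + f1$n_elective)
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seed = sd, algorithm = alg, value = value,
        stage1_f11 = mean(f1$f11), stage1_f12 = mean(f1$f12),
        stage1_f13 = mean(f1$f13),
        stage2_f21 = max(f2$f21), stage2_f22 = min(f2$f22),
        admitted = mean(f1$n_current + f1$n_emergency + f1$n_elective)
      )
    }
  }
  runs <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(runs[, c("seed", "algorithm", "value")],
                             names_from = "algorithm", values_from = "value")
  tests <- dplyr::bind_rows(
    dplyr::mutate(compare_paired(wide$nsga2, wide$mosa),
                  comparison = "nsga2 vs mosa", .before = 1),
    dplyr::mutate(compare_paired(wide$nsga2, wide$mots),
                  comparison = "nsga2 vs mots", .before = 1)
  )
  structure(list(runs = runs, tests = tests, metric = metric),
            class = "icu_comparison")
}

#' @export
print.icu_comparison <- function(x, ...) {
  cat(sprintf("<icu_comparison> metric: %s, %d paired runs\n",
              x$metric, length(unique(x$runs$seed))))
  print(x$tests)
  invisible(x)
}
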