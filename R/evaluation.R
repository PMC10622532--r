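#' The five stage-2 extension scenarios
#'
#' Five discrete LOS-extension distributions over 0–4 extra days, shifting
#' probability mass from "mostly no extension" (S1, which equals the base
#' case-study table) to "mostly long extensions" (S5). Later scenarios
#' stochastically dominate earlier ones, so the expected extension load is
#' nondecreasing from S1 to S5.
#'
#' @return Named list of five [extension_table()]s (`S1`..`S5`).
#' @export
scenario_set <- function() {
  cols <- list(
    S1 = c(0.40, 0.25, 0.20, 0.10, 0.05),
    S2 = c(0.25, 0.40, 0.20, 0.10, 0.05),
    S3 = c(0.05, 0.25, 0.40, 0.20, 0.10),
    S4 = c(0.05, 0.10, 0.20, 0.40, 0.25),
    S5 = c(0.05, 0.10, 0.20, 0.25, 0.40)
  )
  lapply(cols, function(p) extension_table(0:4, p))
}

#' Tabular summary of a front, with an average row
#'
#' One row per front solution (admitted counts per category and the stage's
#' objectives), plus an appended `"Avg."` row of column means. When stage-2
#' repair results are supplied, their objectives are joined per solution and
#' strategy as wide columns.
#'
#' @param front An `icu_front`.
#' @param stage2_results Optional tibble with columns `solution`, `strategy`,
#'   `f21`, `f22` (e.g. rows collected from [repair_strategies()] applied to
#'   each front solution).
#' @return A tibble whose `solution` column is character, ending in `"Avg."`.
#' @export
summarize_front <- function(front, stage2_results = NULL) {
  tab <- tidy(front)
  tab$solution <- as.character(tab$solution)
  if (!is.null(stage2_results)) {
    wide <- stage2_results |>
      dplyr::select("solution", "strategy", "f21", "f22") |>
      tidyr::pivot_wider(names_from = "strategy",
                         values_from = c("f21", "f22")) |>
      dplyr::mutate(solution = as.character(.data$solution))
    tab <- dplyr::left_join(tab, wide, by = "solution")
  }
  num <- vapply(tab, is.numeric, logical(1))
  avg <- tab[1, ]
  avg[] <- NA
  avg$solution <- "Avg."
  avg[num] <- lapply(tab[num], mean, na.rm = TRUE)
  dplyr::bind_rows(tab, avg)
}

#' Sweep the stage-2 scenarios
#'
#' Solves stage 1 once per seed, freezes the compromise solution, then
#' applies every scenario's extension draw to that same reference and runs
#' the repair strategies. All scenarios within a run share one disturbance
#' substream (common random numbers through the scenarios' quantile
#' functions), so a sweep over the base table alone reproduces the S1 column
#' bit for bit and a stochastically heavier scenario never draws smaller
#' extensions.
#'
#' @param inst An `icu_instance`.
#' @param scenarios Named list of [extension_table()]s; default
#'   [scenario_set()].
#' @param seeds Integer vector of run seeds.
#' @param params Stage-1 [ga_params()].
#' @param stage2_params Recall-search [ga_params()].
#' @param strategies Subset of
#'   `c("elective_first", "emergency_first", "recall")`.
#' @return An `icu_sweep` tibble: one row per seed, scenario and strategy
#'   with `f21`, `f22` and the admission/postponement counts.
#' @export
scenario_sweep <- function(inst, scenarios = scenario_set(), seeds = 1:5,
                           params = ga_params(pop = 50, generations = 100),
                           stage2_params = ga_params(pop = 30, generations = 40),
                           strategies = c("elective_first", "emergency_first",
                                          "recall")) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  rows <- list()
  for (sd in seeds) {
    front <- run_stage1(inst, params, seed = derive_seed(sd, 20L))
    ref <- stage1_reference(front)
    for (k in seq_along(scenarios)) {
      # one disturbance substream per run seed, shared by every scenario:
      # common random numbers make scenario effects comparable draw-by-draw
      draw <- sample_extensions(inst, scenarios[[k]],
                                seed = derive_seed(sd, 100L))
      for (strat in strategies) {
        r <- switch(strat,
          elective_first = elective_first(ref$schedule, inst, draw),
          emergency_first = emergency_first(ref$schedule, inst, draw),
          recall = recall(ref$schedule, inst, draw, params = stage2_params,
                          seed = derive_seed(sd, 200L + k))
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          seed = sd, scenario = names(scenarios)[k] %||% paste0("S", k),
          strategy = strat, f21 = r$f21, f22 = r$f22,
          rejected_emergencies = r$rejected_emergencies,
          postponed_electives = r$postponed_electives,
          n_elective = r$n_elective, n_emergency = r$n_emergency
        )
      }
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("icu_sweep", class(tibble::tibble())))
}

#' Per-scenario means of a sweep
#'
#' @param sweep An `icu_sweep`.
#' @param by Grouping: `"scenario"` (averaging strategies, the headline
#'   view) or `c("scenario", "strategy")`.
#' @return Tibble of mean `f21`, `f22`, and `total_beds` (bed stock plus
#'   mean added beds, rounded).
#' @param inst The `icu_instance` (for the bed stock).
#' @export
summarize_sweep <- function(sweep, inst, by = "scenario") {
  sweep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(f21 = mean(.data$f21), f22 = mean(.data$f22),
                     .groups = "drop") |>
    dplyr::mutate(total_beds = inst$beds + round(.data$f22))
}

#' Bed-occupancy probability report for a front
#'
#' For every front solution and horizon day, the exact occupancy
#' distribution from [occupancy_pmf()] plus its expectation.
#'
#' @param front An `icu_front` (stage 1).
#' @param inst The `icu_instance`.
#' @return An `icu_occupancy` tibble: `solution`, `day`, `beds`, `prob`,
#'   `expected` (the day's expected occupancy, repeated within the day).
#' @export
occupancy_report <- function(front, inst) {
  rows <- list()
  for (i in seq_len(nrow(front))) {
    s <- front$schedule[[i]]
    for (t in seq_len(inst$horizon)) {
      pmf <- occupancy_pmf(s, inst, t)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        solution = front$solution[i], day = t,
        beds = pmf$beds, prob = pmf$prob,
        expected = sum(pmf$beds * pmf$prob)
      )
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("icu_occupancy", class(tibble::tibble())))
}

#' Serialize fronts to JSON
#'
#' Stores objectives and the full genotype (admissions, in-effect LOS,
#' emergency stream) of every solution; [read_front()] rebuilds the
#' schedules against the instance.
#'
#' @param front An `icu_front`.
#' @param path File path.
#' @param inst The `icu_instance` the front was computed on.
#' @return `write_front()`: `front`, invisibly. `read_front()`: an
#'   `icu_front`.
#' @export
write_front <- function(front, path) {
  sols <- lapply(seq_len(nrow(front)), function(i) {
    s <- front$schedule[[i]]
    obj <- if (attr(front, "stage") == 1L) {
      list(f11 = front$f11[i], f12 = front$f12[i], f13 = front$f13[i])
    } else {
      list(f21 = front$f21[i], f22 = front$f22[i])
    }
    c(obj, list(admission_day = as.list(setNames(s$adm[!is.na(s$adm)],
                                                 which(!is.na(s$adm)))),
                elective_los = s$elos, current_remaining = s$crem,
                emergencies = s$em))
  })
  jsonlite::write_json(list(stage = attr(front, "stage"), solutions = sols),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(front)
}

#' @rdname write_front
#' @param ref For stage-2 fronts: the `icu_reference` the objectives are
#'   measured against.
#' @export
read_front <- function(path, inst, ref = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  schedules <- lapply(x$solutions, function(sol) {
    adm <- rep(NA_integer_, nrow(inst$electives))
    if (length(sol$admission_day)) {
      adm[as.integer(names(sol$admission_day))] <-
        as.integer(unlist(sol$admission_day))
    }
    em <- if (length(sol$emergencies)) {
      as.data.frame(lapply(sol$emergencies, as.integer))
    } else {
      empty_em()
    }
    build_schedule(inst, adm, as.integer(sol$elective_los),
                   as.integer(sol$current_remaining), em)
  })
  stage <- as.integer(x$stage)
  if (stage == 2L && is.null(ref)) {
    abort("Reading a stage-2 front requires `ref`.")
  }
  front_tibble(schedules, inst, stage = stage, params = NULL, ref = ref)
}
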