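test_that("random individuals are feasible by construction", {
  inst <- generate_instance(generator_config(seed = 2))
  for (sd in 1:60) {
    s <- random_individual(inst, seed = sd)
    expect_true(is_feasible(s, inst))
  }
  # capacity exhaustion: a lone bed held by a current patient all week
  blocked <- new_instance(
    beds = 1, horizon = 3, rates = 0,
    electives = tibble::tibble(id = 1:2, expected_day = 1L, los = 1L,
                               loss = 0.5),
    currents = tibble::tibble(id = 10001L, los = 3L, remaining = 3L)
  )
  for (sd in 1:5) {
    s <- random_individual(blocked, seed = sd)
    expect_identical(sum(!is.na(s$adm)), 0L)
  }
  # degenerate: no electives, no arrivals -> currents only
  empty <- tiny_instance(n_electives = 0,
                         currents = tibble::tibble(id = 10001L, los = 2L,
                                                   remaining = 2L))
  s <- random_individual(empty, seed = 1)
  expect_identical(nrow(s$em), 0L)
  expect_identical(total_occupancy(s, 1), 1L)
})

test_that("initial populations are reproducible and diverse", {
  inst <- generate_instance(generator_config(seed = 6))
  p1 <- initial_population(inst, ga_params(pop = 20, generations = 1), seed = 9)
  p2 <- initial_population(inst, ga_params(pop = 20, generations = 1), seed = 9)
  expect_identical(length(p1), 20L)
  expect_identical(p1, p2)
  keys <- vapply(p1, function(s) paste(s$adm, collapse = ","), character(1))
  expect_gte(length(unique(keys)), 2L)
})

test_that("crossover swaps admission days only when both children stay legal", {
  # two electives with one-day stays on a two-bed ward: swap mirrors the plan
  inst <- tiny_instance(n_electives = 2, beds = 2, horizon = 2,
                        los = c(1L, 1L), expected = c(1L, 1L))
  a <- new_schedule(inst, admissions = c("1" = 1L, "2" = 2L))
  set.seed(1)
  kids <- crossover(a, a, inst)
  expect_identical(kids[[1]]$adm, c(2L, 1L))
  expect_true(is_feasible(kids[[1]], inst))

  # identical admission days: the exchange is the identity
  b <- new_schedule(inst, admissions = c("1" = 1L, "2" = 1L))
  set.seed(2)
  kids2 <- crossover(b, b, inst)
  expect_identical(kids2[[1]]$adm, b$adm)

  # a swap that would admit a patient before its expected day is rejected
  inst3 <- tiny_instance(n_electives = 2, beds = 2, horizon = 2,
                         los = c(1L, 1L), expected = c(1L, 2L))
  c3 <- new_schedule(inst3, admissions = c("1" = 1L, "2" = 2L))
  for (sd in 1:10) {
    set.seed(sd)
    kids3 <- crossover(c3, c3, inst3)
    expect_identical(kids3[[1]]$adm, c3$adm)
    expect_identical(kids3[[2]]$adm, c3$adm)
  }
})

test_that("mutation replaces with a not-longer stay and keeps feasibility", {
  inst <- tiny_instance(n_electives = 3, beds = 1, horizon = 4,
                        los = c(3L, 2L, 4L), expected = c(1L, 1L, 1L))
  s <- new_schedule(inst, admissions = c("1" = 1L))
  hits <- character()
  for (sd in 1:30) {
    set.seed(sd)
    m <- mutate_schedule(s, inst)
    expect_true(is_feasible(m, inst))
    inserted <- which(!is.na(m$adm))
    # candidate pool for the removed LOS-3 patient is only the LOS-2 one
    expect_true(all(inserted %in% c(2L)))
    hits <- c(hits, paste(m$adm, collapse = ","))
  }
  expect_true(any(vapply(strsplit(hits, ","), function(x) x[2] != "NA",
                         logical(1))))

  # no unadmitted candidate: the removal alone stands
  lone <- tiny_instance(n_electives = 1, beds = 1, horizon = 2,
                        los = 1L, expected = 1L)
  sl <- new_schedule(lone, admissions = c("1" = 1L))
  set.seed(1)
  expect_identical(sum(!is.na(mutate_schedule(sl, lone)$adm)), 0L)

  # property sweep on a full-size instance
  big <- generate_instance(generator_config(seed = 13))
  sb <- random_individual(big, seed = 1)
  for (sd in 1:200) {
    set.seed(sd)
    sb2 <- mutate_schedule(sb, big)
    expect_true(all(sb2$occ_ec <= big$beds))
  }
})

test_that("re-insertion is priority-ordered and maximal", {
  # one vacancy; the severe (loss 0.9) patient outranks the mild one
  inst <- tiny_instance(n_electives = 2, beds = 1, horizon = 2,
                        los = c(2L, 2L), expected = c(1L, 1L),
                        loss = c(0.1, 0.9))
  s <- reinsert(new_schedule(inst), inst)
  expect_identical(which(!is.na(s$adm)), 2L)

  # nothing vacant: unchanged
  full <- reinsert(s, inst)
  expect_identical(full$adm, s$adm)

  # maximality: after re-insertion no unadmitted elective fits anywhere
  for (sd in 1:15) {
    big <- generate_instance(generator_config(seed = sd))
    sb <- reinsert(random_individual(big, seed = sd), big)
    free <- big$beds - sb$occ_ec
    for (i in which(is.na(sb$adm))) {
      for (d in big$electives$expected_day[i]:big$horizon) {
        e <- min(d + sb$elos[i] - 1L, big$horizon)
        expect_false(all(free[d:e] >= 1L))
      }
    }
    expect_gte(sum(!is.na(sb$adm)),
               sum(!is.na(random_individual(big, seed = sd)$adm)))
  }
})

test_that("pareto_rank agrees with the brute-force dominance checker", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    m <- sample(2:3, 1)
    obj <- matrix(sample(0:5, n * m, replace = TRUE), n, m)
    r <- pareto_rank(as.data.frame(obj), senses = rep("min", m))
    expect_identical(r$.front, brute_fronts(obj))
  }
  # senses: maximized columns are negated
  d <- data.frame(a = c(1, 2), b = c(1, 2))
  expect_identical(pareto_rank(d, c("max", "max"))$.front, c(2L, 1L))
  # crowding: extremes infinite, middle finite on one front
  r3 <- pareto_rank(data.frame(a = c(1, 2, 3), b = c(3, 2, 1)),
                    c("min", "min"))
  expect_identical(r3$.front, rep(1L, 3))
  expect_identical(is.infinite(r3$.crowding), c(TRUE, FALSE, TRUE))
  expect_identical(pareto_rank(data.frame(a = 1, b = 2),
                               c("min", "min"))$.front, 1L)
})

test_that("stage-1 search recovers the exact front on enumerable instances", {
  inst <- tiny_instance(n_electives = 4, beds = 2, horizon = 3,
                        los = c(1L, 2L, 1L, 2L), expected = c(1L, 1L, 2L, 1L),
                        loss = c(0.1, 0.5, 0.9, 0.5))
  truth <- enumerate_front(inst)
  hits <- 0L
  for (sd in 1:6) {
    fr <- run_stage1(inst, ga_params(pop = 100, generations = 200), seed = sd)
    got <- unique(cbind(fr$f11, fr$f12))
    hits <- hits + identical(front_key(got), front_key(truth))
    # every front member is feasible and the front is pairwise non-dominated
    expect_true(all(vapply(fr$schedule, function(s) is_feasible(s, inst),
                           logical(1))))
    rk <- pareto_rank(tidy(fr)[, c("f11", "f12", "f13")],
                      c("max", "min", "max"))
    expect_true(all(rk$.front == 1L))
  }
  expect_gte(hits, 5L)
})

test_that("elitism never loses the best single-objective values", {
  inst <- generate_instance(generator_config(seed = 30))
  set.seed(99)
  init <- initial_population(inst, ga_params(pop = 30, generations = 1))
  best_f11_init <- max(vapply(init, f11_occupancy_rate, numeric(1),
                              inst = inst))
  best_f12_init <- min(vapply(init, f12_delay_index, numeric(1), inst = inst))
  fr <- run_stage1(inst, ga_params(pop = 30, generations = 25), seed = 99)
  expect_gte(max(fr$f11), best_f11_init)
  expect_lte(min(fr$f12), best_f12_init)
})

test_that("degenerate instances yield the single trivial solution", {
  inst <- tiny_instance(n_electives = 0,
                        currents = tibble::tibble(id = 10001L, los = 3L,
                                                  remaining = 2L))
  fr <- run_stage1(inst, ga_params(pop = 4, generations = 3), seed = 1)
  expect_identical(nrow(fr), 1L)
  expect_equal(fr$f12, 0)
  expect_identical(fr$n_emergency, 0L)
})

test_that("stage-2 search returns the unchanged plan under a zero draw", {
  inst <- generate_instance(generator_config(seed = 40))
  fr <- run_stage1(inst, ga_params(pop = 20, generations = 15), seed = 40)
  ref <- stage1_reference(fr)
  f2 <- run_stage2(inst, ref, zero_draw(inst), seed = 41)
  expect_identical(nrow(f2), 1L)
  expect_equal(f2$f21, 1)
  expect_equal(f2$f22, 0)
  expect_identical(f2$schedule[[1]]$adm, ref$schedule$adm)
})

test_that("stage-2 candidates never degrade the stage-1 objectives", {
  for (sd in c(50, 51)) {
    inst <- generate_instance(generator_config(seed = sd))
    fr <- run_stage1(inst, ga_params(pop = 30, generations = 25), seed = sd)
    ref <- stage1_reference(fr)
    draw <- sample_extensions(inst, seed = sd + 1)
    f2 <- run_stage2(inst, ref, draw, params = ga_params(pop = 20,
                                                         generations = 20),
                     seed = sd + 2)
    if (!all(f2$feasible)) next
    for (s2 in f2$schedule) {
      expect_gte(f11_occupancy_rate(s2, inst) + 1e-9,
                 ref$objectives[["f11"]])
      expect_lte(f12_delay_index(s2, inst) - 1e-9, ref$objectives[["f12"]])
      expect_gte(f13_emergency_rate(s2, inst) + 1e-9,
                 ref$objectives[["f13"]])
      expect_true(all(s2$occ_ec <= inst$beds))
    }
  }
})

test_that("stage-2 search matches exhaustive enumeration on a toy repair", {
  # one current patient whose +1 extension displaces a one-bed elective plan
  inst <- new_instance(
    beds = 2, horizon = 3, rates = 0,
    electives = tibble::tibble(id = 1:3, expected_day = c(1L, 1L, 2L),
                               los = c(1L, 1L, 1L), loss = c(0.5, 0.9, 0.1)),
    currents = tibble::tibble(id = 10001L, los = 2L, remaining = 1L)
  )
  s1 <- new_schedule(inst, admissions = c("1" = 1L, "2" = 2L, "3" = 2L))
  expect_true(is_feasible(s1, inst))
  ref <- structure(list(schedule = s1,
                        objectives = evaluate_stage1_oracle(s1, inst)),
                   class = "icu_reference")
  draw <- zero_draw(inst)
  draw$current[] <- 1L # the current patient now occupies days 1-2
  # exhaustive oracle over all feasible admission maps under the extension
  best <- enumerate_stage2(inst, s1, crem2 = 2L)
  expect_gt(nrow(best), 0L)
  for (sd in 6:8) {
    f2 <- run_stage2(inst, ref, draw,
                     params = ga_params(pop = 20, generations = 60),
                     seed = sd)
    expect_true(all(f2$feasible))
    got <- unique(cbind(f2$f21, f2$f22))
    expect_identical(front_key(got), front_key(best))
  }
})
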