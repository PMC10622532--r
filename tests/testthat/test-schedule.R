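# One-day worked example: 3 current patients, 8 electives admitted that day,
# 2 emergency arrivals, no carryover from earlier days.
worked_example_schedule <- function() {
  inst <- new_instance(
    beds = 24, horizon = 1, rates = 4.5,
    electives = tibble::tibble(id = 1:8, expected_day = 1L, los = 1L,
                               loss = 0.5),
    currents = tibble::tibble(id = 10001:10003, los = 2L, remaining = 1L)
  )
  s <- new_schedule(inst,
                    admissions = setNames(rep(1L, 8), 1:8),
                    emergencies = tibble::tibble(id = 20001:20002, day = 1L,
                                                 los = 1L))
  list(inst = inst, s = s)
}

test_that("total occupancy reproduces the case study's 13-bed day", {
  w <- worked_example_schedule()
  expect_identical(total_occupancy(w$s, 1), 13L)
  expect_identical(carryover_occupancy(w$s, 1), 3L) # the current patients
  # with a single emergency arrival the day holds 12 patients
  s12 <- new_schedule(w$inst, admissions = setNames(rep(1L, 8), 1:8),
                      emergencies = tibble::tibble(id = 20001L, day = 1L,
                                                   los = 1L))
  expect_identical(total_occupancy(s12, 1), 12L)
  expect_error(total_occupancy(w$s, 2), "day")
})

test_that("occupancy windows and carryover follow the stay arithmetic", {
  inst <- tiny_instance(n_electives = 1, beds = 5, horizon = 5,
                        los = 3L, expected = 1L, loss = 0.5)
  s <- new_schedule(inst, admissions = c("1" = 2L))
  # admitted day 2 with LOS 3: carried over on days 3 and 4, gone on day 5
  expect_identical(vapply(1:5, carryover_occupancy, integer(1), s = s),
                   c(0L, 0L, 1L, 1L, 0L))
  expect_identical(vapply(1:5, total_occupancy, integer(1), s = s),
                   c(0L, 1L, 1L, 1L, 0L))

  # a current patient with remaining LOS 1 occupies day 1 only
  inst2 <- tiny_instance(n_electives = 0, beds = 2, horizon = 3,
                         currents = tibble::tibble(id = 10001L, los = 2L,
                                                   remaining = 1L))
  s2 <- new_schedule(inst2)
  expect_identical(vapply(1:3, carryover_occupancy, integer(1), s = s2),
                   c(1L, 0L, 0L))

  # empty schedule occupies nothing
  s0 <- new_schedule(tiny_instance())
  expect_identical(total_occupancy(s0, 1), 0L)
})

test_that("stage-1 objectives reproduce the in-text examples", {
  # delay index: expected day 1, admitted day 3, loss 0.5 -> (3-1)*0.5 = 1
  inst <- tiny_instance(n_electives = 1, beds = 2, horizon = 3,
                        los = 1L, expected = 1L, loss = 0.5)
  s <- new_schedule(inst, admissions = c("1" = 3L))
  expect_equal(f12_delay_index(s, inst), 1.0)

  # two delayed patients: (0.1*1 + 0.9*3) / 2 = 1.4
  inst2 <- tiny_instance(n_electives = 2, beds = 2, horizon = 4,
                         los = c(1L, 1L), expected = c(1L, 1L),
                         loss = c(0.1, 0.9))
  s2 <- new_schedule(inst2, admissions = c("1" = 2L, "2" = 4L))
  expect_equal(f12_delay_index(s2, inst2), 1.4)

  # everyone on time, or nobody admitted: zero delay
  s3 <- new_schedule(inst2, admissions = c("1" = 1L, "2" = 1L))
  expect_equal(f12_delay_index(s3, inst2), 0)
  expect_equal(f12_delay_index(new_schedule(inst2), inst2), 0)

  # emergency admission rate: em = 3 against a cap of 12 is 25%
  inst3 <- new_instance(beds = 24, horizon = 1, rates = 4.5,
                        electives = tibble::tibble(id = integer(),
                                                   expected_day = integer(),
                                                   los = integer(),
                                                   loss = numeric()),
                        currents = tibble::tibble(id = integer(),
                                                  los = integer(),
                                                  remaining = integer()))
  expect_identical(inst3$arrivals$max_per_day, 12L)
  s4 <- new_schedule(inst3, emergencies = tibble::tibble(id = 20001:20003,
                                                         day = 1L, los = 1L))
  expect_equal(f13_emergency_rate(s4, inst3), 0.25)

  # two days at ratios 0.25 and 0.75 average to 0.5
  inst5 <- new_instance(beds = 24, horizon = 2, rates = c(2, 2),
                        electives = inst3$electives, currents = inst3$currents)
  cap <- inst5$arrivals$max_per_day
  n1 <- as.integer(round(cap[1] * 0.25))
  n2 <- as.integer(round(cap[2] * 0.75))
  s5 <- new_schedule(inst5, emergencies = tibble::tibble(
    id = 20000L + seq_len(n1 + n2),
    day = rep(1:2, c(n1, n2)), los = 1L))
  expect_equal(f13_emergency_rate(s5, inst5),
               mean(c(n1 / cap[1], n2 / cap[2])))

  # full house every day: occupancy rate exactly 1
  w <- worked_example_schedule()
  full <- new_schedule(w$inst,
                       admissions = setNames(rep(1L, 8), 1:8),
                       emergencies = tibble::tibble(id = 20000L + 1:13,
                                                    day = 1L, los = 1L))
  expect_equal(f11_occupancy_rate(full, w$inst), 1.0)
  expect_equal(f11_occupancy_rate(new_schedule(w$inst), w$inst), 3 / 24)
})

test_that("occupancy decomposition is conserved on random schedules", {
  for (sd in 1:20) {
    inst <- generate_instance(generator_config(seed = sd))
    s <- random_individual(inst, seed = sd + 100)
    occ <- occupancy(s)
    expect_identical(occ$total,
                     occ$elective_new + occ$emergency_new + occ$carryover)
    expect_identical(occ$total[1] >= nrow(inst$currents), TRUE)
    # admitting one more elective never decreases occupancy or f11
    open <- which(is.na(s$adm))
    f11_before <- f11_occupancy_rate(s, inst)
    added <- FALSE
    for (i in open) {
      d <- inst$electives$expected_day[i]
      s2 <- new_schedule(inst, admissions = replace(s$adm, i, d),
                         emergencies = s$em)
      expect_gte(f11_occupancy_rate(s2, inst), f11_before)
      added <- TRUE
      break
    }
  }
})

test_that("feasibility verdicts name the violated rule", {
  inst <- tiny_instance(n_electives = 3, beds = 2, horizon = 3,
                        los = c(1L, 1L, 1L), expected = c(1L, 1L, 1L))
  ok <- new_schedule(inst, admissions = c("1" = 1L, "2" = 1L))
  expect_true(is_feasible(ok, inst)) # boundary: exactly Q beds used

  over <- new_schedule(inst, admissions = c("1" = 1L, "2" = 1L, "3" = 1L))
  verdict <- is_feasible(over, inst)
  expect_false(verdict)
  v <- attr(verdict, "violations")
  expect_identical(v$rule, "capacity")
  expect_identical(v$where, 1L)

  inst2 <- tiny_instance(n_electives = 1, expected = 2L, los = 1L)
  early <- new_schedule(inst2, admissions = c("1" = 1L))
  expect_false(is_feasible(early, inst2))
  expect_identical(attr(is_feasible(early, inst2), "violations")$rule,
                   "expected_day")
})

test_that("similarity and added beds behave at the extremes and by hand", {
  inst <- tiny_instance(n_electives = 3, beds = 3, horizon = 3,
                        los = c(2L, 1L, 1L), expected = c(1L, 1L, 1L))
  s1 <- new_schedule(inst, admissions = c("1" = 1L, "2" = 2L))
  expect_equal(f21_similarity(s1, s1), 1)
  expect_identical(f22_added_beds(s1, s1), 0L)

  disjoint <- new_schedule(inst, admissions = c("3" = 3L))
  expect_equal(f21_similarity(s1, disjoint), 0)

  # patient 1 keeps days 1-2 (2 patient-days of 3 preserved)
  moved <- new_schedule(inst, admissions = c("1" = 1L, "2" = 3L))
  expect_equal(f21_similarity(s1, moved), 2 / 3)
  # max-normalized variant divides by the larger plan instead
  expect_equal(f21_similarity(s1, moved, normalize = "max"), 2 / 3)
  grown <- new_schedule(inst, admissions = c("1" = 1L, "2" = 2L, "3" = 1L))
  expect_equal(f21_similarity(s1, grown), 1)
  expect_equal(f21_similarity(s1, grown, normalize = "max"), 3 / 4)

  # empty reference scores 1 by convention
  expect_equal(f21_similarity(new_schedule(inst), disjoint), 1)

  # bed-identity variant: identical plans still score 1; it is never more
  # permissive than the bed-agnostic match
  expect_equal(f21_similarity(s1, s1, by_bed = TRUE, inst = inst), 1)
  expect_lte(f21_similarity(s1, moved, by_bed = TRUE, inst = inst),
             f21_similarity(s1, moved))

  # added beds: daily requirements (24, 24) -> (30, 28) need 6 more
  q1 <- new_schedule(inst, admissions = c("1" = 1L))
  q2 <- new_schedule(inst, admissions = c("1" = 1L),
                     emergencies = tibble::tibble(
                       id = 20000L + 1:8,
                       day = c(rep(1L, 6), 2L, 2L), los = 1L))
  expect_identical(f22_added_beds(q1, q2), 6L)
})

test_that("occupancy_pmf is the shifted truncated-Poisson law", {
  inst <- new_instance(beds = 24, horizon = 1, rates = 4.5,
                       electives = tibble::tibble(id = 1:8, expected_day = 1L,
                                                  los = 1L, loss = 0.5),
                       currents = tibble::tibble(id = 10001:10003, los = 2L,
                                                 remaining = 1L))
  s <- new_schedule(inst, admissions = setNames(rep(1L, 8), 1:8))
  pmf <- occupancy_pmf(s, inst, 1)
  expect_equal(sum(pmf$prob), 1)
  expect_identical(min(pmf$beds), 11L) # 3 current + 8 elective
  expect_identical(max(pmf$beds), 11L + inst$arrivals$max_per_day)
  # P(occupancy = 13) equals the (truncated) chance of 2 arrivals
  p2 <- dpois(2, 4.5) / ppois(inst$arrivals$max_per_day, 4.5)
  expect_equal(pmf$prob[pmf$beds == 13L], p2)
  # mean equals deterministic occupancy + truncated-Poisson mean (brute force)
  k <- 0:inst$arrivals$max_per_day
  w <- dpois(k, 4.5)
  expect_equal(sum(pmf$beds * pmf$prob), 11 + sum(k * w) / sum(w))

  # no arrivals: point mass at the deterministic occupancy
  inst0 <- tiny_instance(n_electives = 1, los = 1L, expected = 1L)
  s0 <- new_schedule(inst0, admissions = c("1" = 1L))
  pmf0 <- occupancy_pmf(s0, inst0, 1)
  expect_identical(pmf0$beds, 1L)
  expect_equal(pmf0$prob, 1)
})

test_that("schedule export yields a consistent first-fit layout", {
  inst <- generate_instance(generator_config(seed = 4))
  s <- random_individual(inst, seed = 5)
  tab <- schedule_table(s, inst)
  # one bed per patient per day, and per-day row counts match occupancy
  expect_false(any(duplicated(tab[, c("day", "bed")])))
  daily <- dplyr::count(tab, day)
  expect_identical(daily$n, as.integer(s$occ_ec + s$occ_em))
  # a patient keeps one bed for the whole stay
  per_pat <- dplyr::summarise(dplyr::group_by(tab, patient_id),
                              nbeds = dplyr::n_distinct(bed))
  expect_true(all(per_pat$nbeds == 1L))
})
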