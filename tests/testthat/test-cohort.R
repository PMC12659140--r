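# Sampling weights, weighted matching, follow-up, drug sub-cohort.

test_that("KM-type weights reproduce hand computations", {
  pop <- data.frame(birth_year = 1980, sex = "F", count = 100)
  # single year, 10 of 100 sampled -> weight 10 each
  comp <- data.frame(id = 1:10, birth_year = 1980, sex = "F",
                     entry_year = 2000, sampling_year = 2000)
  w <- compute_sampling_weights(comp, pop)
  expect_equal(w$weights$weight, rep(10, 10))
  expect_equal(w$probabilities$prob, 0.1)

  # two years, eligible both: probabilities 0.1 then 0.2; an individual
  # sampled in year 2 has weight 1 / (0.9 * 0.2)
  comp2 <- data.frame(id = 1:30, birth_year = 1980, sex = "F",
                      entry_year = 2000,
                      sampling_year = rep(c(2000, 2001), c(10, 20)))
  w2 <- compute_sampling_weights(comp2, pop)
  expect_equal(w2$weights$weight[comp2$sampling_year == 2001],
               rep(1 / (0.9 * 0.2), 20))
  expect_equal(w2$weights$weight[comp2$sampling_year == 2000],
               rep(10, 10))

  # everyone sampled at probability 1 -> all weights 1
  comp3 <- data.frame(id = 1:5, birth_year = 1990, sex = "M",
                      entry_year = 2000, sampling_year = 2000)
  pop3 <- data.frame(birth_year = 1990, sex = "M", count = 5)
  expect_equal(compute_sampling_weights(comp3, pop3)$weights$weight,
               rep(1, 5))

  expect_error(compute_sampling_weights(
    comp3, data.frame(birth_year = 1990, sex = "F", count = 5)),
    "stratum missing")
})

test_that("weighting restores population margins", {
  # two strata sampled at very different intensities: weighted totals must
  # recover each stratum's population count exactly in the one-year design
  pop <- data.frame(birth_year = c(1980, 1985), sex = "F",
                    count = c(10000, 10000))
  comp <- data.frame(id = 1:600,
                     birth_year = rep(c(1980, 1985), c(500, 100)),
                     sex = "F", entry_year = 2000, sampling_year = 2000)
  w <- compute_sampling_weights(comp, pop)
  wt <- tapply(w$weights$weight, comp$birth_year, sum)
  expect_equal(as.numeric(wt), c(10000, 10000), tolerance = 1e-12)
})

test_that("matching yields exact 1:ratio sets inside the caliper", {
  set.seed(5)
  exposed <- data.frame(child_id = 1:40,
                        maternal_age_years = sample(25:35, 40, TRUE))
  pool <- data.frame(child_id = 100 + 1:2000,
                     maternal_age_years = sample(20:40, 2000, TRUE),
                     sampling_weight = runif(2000, 1, 5))
  m <- match_children(exposed, pool, ratio = 5, seed = 9)
  expect_equal(sum(m$role == "comparator"), 5 * 40)
  # per-set ratio and caliper
  for (s in unique(m$set_id)) {
    set <- m[m$set_id == s, ]
    expect_equal(sum(set$role == "comparator"), 5)
    age_e <- set$maternal_age_years[set$role == "exposed"]
    expect_true(all(abs(set$maternal_age_years - age_e) <= 1))
  }
  # no comparator reused
  expect_false(anyDuplicated(m$child_id[m$role == "comparator"]) > 0)
  # deterministic under the seed
  m2 <- match_children(exposed, pool, ratio = 5, seed = 9)
  expect_identical(m$child_id, m2$child_id)
})

test_that("matching uses the single eligible comparator and errors when short", {
  exposed <- data.frame(child_id = 1, maternal_age_years = 30)
  pool <- data.frame(child_id = 2, maternal_age_years = 30,
                     sampling_weight = 1)
  m <- match_children(exposed, pool, ratio = 1, seed = 1)
  expect_equal(m$child_id[m$role == "comparator"], 2)
  pool_far <- data.frame(child_id = 2, maternal_age_years = 40,
                         sampling_weight = 1)
  expect_error(match_children(exposed, pool_far, ratio = 1, seed = 1),
               "insufficient eligible comparators")
})

test_that("comparator maternal ages track the exposed distribution", {
  set.seed(17)
  exposed <- data.frame(child_id = 1:300,
                        maternal_age_years = pmin(pmax(round(
                          rnorm(300, 31, 4)), 18), 45))
  pool <- data.frame(child_id = 1000 + 1:30000,
                     maternal_age_years = pmin(pmax(round(
                       rnorm(30000, 29, 6)), 18), 45),
                     sampling_weight = 1)
  m <- match_children(exposed, pool, ratio = 5, seed = 2)
  age_e <- m$maternal_age_years[m$role == "exposed"]
  age_c <- m$maternal_age_years[m$role == "comparator"]
  expect_lt(abs(mean(age_e) - mean(age_c)), 0.2)
})

test_that("follow-up is min(death, emigration, age 5)", {
  b <- as.Date("2010-06-01")
  ch <- data.frame(
    birth_date = rep(b, 3),
    death_date = as.Date(c(NA, NA, NA)),
    emigration_date = as.Date(c(NA, NA, NA)))
  ch$death_date[2] <- b + round(2 * 365.25)
  ch$emigration_date[3] <- b + round(6 * 365.25)  # beyond the cap
  out <- define_followup(ch)
  expect_equal(out$person_years, c(5, 2, 5), tolerance = 2e-3)
  expect_true(all(out$person_years > 0 & out$person_years <= 5))

  bad <- data.frame(birth_date = b, death_date = b - 1,
                    emigration_date = as.Date(NA))
  expect_error(define_followup(bad), "death date before birth")
})

test_that("drug sub-cohort keeps sets with exposed born after register start", {
  cohort <- structure(data.frame(
    set_id = rep(1:3, each = 2),
    role = rep(c("exposed", "comparator"), 3),
    child_id = 1:6,
    birth_date = as.Date(c("2004-05-01", "2004-06-01",
                           "2010-01-01", "2004-01-01",
                           "2005-07-01", "2012-01-01"))),
    class = c("matched_cohort", "data.frame"), ratio = 1L)
  sub <- build_drug_subcohort(cohort)
  expect_setequal(unique(sub$set_id), c(2, 3))
  # comparators follow their set regardless of their own birth date
  expect_true(4 %in% sub$child_id)
  early <- cohort[cohort$set_id == 1, ]
  class(early) <- class(cohort)
  expect_warning(sub0 <- build_drug_subcohort(early), "empty")
  expect_equal(nrow(sub0), 0)
})
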