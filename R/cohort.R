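#' Cohort construction: sampling weights, weighted matching, follow-up
#'
#' The analysis cohort is built in two steps. Comparator families originate
#' from a register platform in which comparators were sampled matched to
#' patients, so their demographic distribution is not population
#' representative; Kaplan-Meier-type inverse-probability-of-sampling weights
#' undo that design. The weighted pool then supplies, for every exposed
#' child, `ratio` comparator children matched on maternal age at childbirth.
#'
#' @name cohort
#' @keywords internal
NULL

# follow-up cap: 5 years of day-resolved time. 5 * 365.25 days; events carry
# integer-day ages so the fractional day never contains an event.
.FIVE_YEARS_DAYS <- 1826.25
.DAYS_PER_YEAR <- 365.25

#' Kaplan-Meier-type inverse-probability-of-sampling weights
#'
#' Comparators were drawn from the population year by year within strata of
#' birth year and sex. For stratum \eqn{s} and calendar year \eqn{t} the
#' sampling probability is \eqn{q_{st} = m_{st} / N_s} (number sampled over
#' the stratum's population count). An individual eligible from
#' `entry_year` and sampled in `sampling_year` receives the product-limit
#' weight \deqn{w = 1 / \left(q_{sT} \prod_{t < T} (1 - q_{st})\right),}
#' the inverse probability of being sampled exactly when they were.
#'
#' @param comparators data.frame with columns `id`, `birth_year`, `sex`,
#'   `entry_year` (first year eligible for sampling), `sampling_year`.
#' @param population_counts data.frame with columns `birth_year`, `sex`,
#'   `count` -- annual population counts per stratum.
#' @return list with `weights` (data.frame `id`, `weight`) and
#'   `probabilities` (data.frame `birth_year`, `sex`, `year`, `prob`) for
#'   audit. Weights are always >= 1.
#' @export
compute_sampling_weights <- function(comparators, population_counts) {
  key <- function(by, sx) paste(by, sx, sep = "|")
  pop <- stats::setNames(population_counts$count,
                         key(population_counts$birth_year,
                             population_counts$sex))
  cs <- key(comparators$birth_year, comparators$sex)
  missing <- setdiff(unique(cs), names(pop))
  if (length(missing))
    stop("stratum missing from population counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(pop[unique(cs)] <= 0))
    stop("stratum with zero population count", call. = FALSE)

  # per-stratum, per-year sampling probability
  tab <- stats::aggregate(list(m = rep(1L, nrow(comparators))),
                          by = list(stratum = cs,
                                    year = comparators$sampling_year),
                          FUN = sum)
  tab$prob <- tab$m / pop[tab$stratum]
  if (any(tab$prob > 1))
    stop("more sampled than population in a stratum-year", call. = FALSE)
  pkey <- paste(tab$stratum, tab$year, sep = "|")
  prob_of <- stats::setNames(tab$prob, pkey)

  w <- vapply(seq_len(nrow(comparators)), function(i) {
    yrs <- seq(comparators$entry_year[i], comparators$sampling_year[i])
    q <- prob_of[paste(cs[i], yrs, sep = "|")]
    q[is.na(q)] <- 0                       # eligible year, nobody sampled
    qT <- q[length(q)]
    if (qT <= 0)
      stop("individual sampled in a year with zero sampling probability",
           call. = FALSE)
    1 / (qT * prod(1 - q[-length(q)]))
  }, numeric(1))

  strata <- do.call(rbind, strsplit(tab$stratum, "|", fixed = TRUE))
  list(
    weights = data.frame(id = comparators$id, weight = w),
    probabilities = data.frame(birth_year = as.integer(strata[, 1]),
                               sex = strata[, 2], year = tab$year,
                               prob = tab$prob))
}

#' Weighted 1:k matching of children on maternal age
#'
#' Greedy matching without replacement in a seed-controlled random order of
#' exposed children. Comparators are drawn with selection probability
#' proportional to their sampling weight among pool children of the same
#' integer maternal age; if fewer than `ratio` are available the caliper
#' widens to +/- `caliper_max` years (counted and reported).
#'
#' @param exposed,pool data.frames of children with `child_id` and
#'   `maternal_age_years`; `pool` should carry `sampling_weight` (defaults
#'   to 1 where absent).
#' @param ratio comparators per exposed child (default 5).
#' @param caliper_max fallback caliper in years when exact-age matching is
#'   exhausted (default 1).
#' @param seed optional integer seed.
#' @return a `matched_cohort`: the stacked exposed + matched comparator
#'   rows with columns `set_id` and `role` added, attribute `n_widened`
#'   counting sets that needed the wider caliper.
#' @export
match_children <- function(exposed, pool, ratio = 5L, caliper_max = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(exposed) >= 1, ratio >= 1)
  if (is.null(pool$sampling_weight)) pool$sampling_weight <- 1
  used <- rep(FALSE, nrow(pool))
  order_ex <- sample.int(nrow(exposed))
  picks <- vector("list", nrow(exposed))
  n_widened <- 0L
  for (i in order_ex) {
    age <- exposed$maternal_age_years[i]
    cand <- which(!used & pool$maternal_age_years == age)
    if (length(cand) < ratio) {
      cand <- which(!used &
                      abs(pool$maternal_age_years - age) <= caliper_max)
      n_widened <- n_widened + 1L
    }
    if (length(cand) < ratio)
      stop("insufficient eligible comparators for exposed child ",
           exposed$child_id[i], " (maternal age ", age, ")", call. = FALSE)
    sel <- if (length(cand) == ratio) cand else
      cand[sample.int(length(cand), ratio,
                      prob = pool$sampling_weight[cand])]
    used[sel] <- TRUE
    picks[[i]] <- sel
  }
  ex <- exposed
  ex$set_id <- seq_len(nrow(exposed))
  ex$role <- "exposed"
  comp <- pool[unlist(picks), , drop = FALSE]   # picks[[i]] belongs to set i
  comp$set_id <- rep(seq_len(nrow(exposed)), each = ratio)
  comp$role <- "comparator"
  cols <- intersect(names(ex), names(comp))
  out <- rbind(ex[, cols, drop = FALSE], comp[, cols, drop = FALSE])
  structure(out, class = c("matched_cohort", "data.frame"),
            ratio = as.integer(ratio), n_widened = n_widened)
}

#' Follow-up window and person-time
#'
#' Follow-up runs from birth to the earliest of death, emigration, and the
#' fifth birthday. Adds `age_end_days` and `person_years` columns.
#'
#' @param children data.frame with `birth_date` and optional `death_date`,
#'   `emigration_date` (Date or NA).
#' @return `children` with follow-up columns added.
#' @export
define_followup <- function(children) {
  death_days <- as.numeric(children$death_date - children$birth_date)
  emig_days <- as.numeric(children$emigration_date - children$birth_date)
  if (is.null(death_days)) death_days <- rep(NA_real_, nrow(children))
  if (is.null(emig_days)) emig_days <- rep(NA_real_, nrow(children))
  if (any(death_days < 0, na.rm = TRUE))
    stop("death date before birth date", call. = FALSE)
  if (any(emig_days < 0, na.rm = TRUE))
    stop("emigration date before birth date", call. = FALSE)
  end <- pmin(death_days, emig_days, .FIVE_YEARS_DAYS, na.rm = TRUE)
  children$age_end_days <- end
  children$person_years <- end / .DAYS_PER_YEAR
  children
}

#' Restrict a matched cohort to the drug-register era
#'
#' Dispensation data exist only from the start of the prescribed drug
#' register; drug analyses keep the matched sets whose exposed child was
#' born on or after that date (comparators follow their set).
#'
#' @param cohort a `matched_cohort`.
#' @param register_start Date, default 2005-07-01.
#' @return the restricted `matched_cohort`; warns if empty.
#' @export
build_drug_subcohort <- function(cohort,
                                 register_start = as.Date("2005-07-01")) {
  keep_sets <- cohort$set_id[cohort$role == "exposed" &
                               cohort$birth_date >= register_start]
  out <- cohort[cohort$set_id %in% keep_sets, , drop = FALSE]
  if (!nrow(out)) warning("drug sub-cohort is empty", call. = FALSE)
  structure(out, class = c("matched_cohort", "data.frame"),
            ratio = attr(cohort, "ratio"),
            n_sets = length(keep_sets))
}
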