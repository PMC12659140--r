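# Independent oracles and fixture builders used across the suite.

# Daily-grid brute-force mean cumulative count: walks integer-day ages,
# maintaining the death Kaplan-Meier and risk set step by step. Independent
# of the event-time implementation in the package.
mcc_daily_oracle <- function(event_ages_days, death_days, censor_days,
                             horizon = 1830L) {
  n <- length(event_ages_days)
  death_days <- ifelse(!is.na(death_days) & death_days > censor_days,
                       NA, death_days)
  end <- pmin(death_days, censor_days, na.rm = TRUE)
  ev <- unlist(event_ages_days, use.names = FALSE)
  S <- 1
  m <- 0
  for (d in 0:horizon) {
    n_d <- sum(end >= d)
    if (n_d == 0) break
    d_ev <- sum(ev == d)
    if (d_ev > 0) m <- m + S * d_ev / n_d
    d_death <- sum(!is.na(death_days) & death_days == d)
    if (d_death > 0) S <- S * (1 - d_death / n_d)
  }
  m
}

# Random small cohort with integer-day event/death/censor ages.
random_small_cohort <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:20, 1)
  censor <- sample(c(rep(1826L, 3), sample.int(1826L, 2, replace = TRUE)),
                   n, replace = TRUE)
  death <- ifelse(runif(n) < 0.2,
                  sapply(censor, function(cn) sample.int(cn, 1)), NA)
  end <- pmin(death, censor, na.rm = TRUE)
  events <- lapply(seq_len(n), function(i) {
    k <- rpois(1, 2)
    if (k == 0) numeric(0) else sort(sample.int(end[i] + 1L, k,
                                                replace = TRUE) - 1L)
  })
  list(events = events, death = death, censor = censor)
}

# Brute-force exact rate-ratio CI: invert the conditional binomial over an
# RR grid, entirely independent of the closed-form qbeta construction.
rr_ci_grid_oracle <- function(c1, pt1, c0, pt0, conf = 0.95,
                              grid = NULL) {
  if (is.null(grid)) grid <- exp(seq(log(0.01), log(100), by = 1e-4))
  alpha <- 1 - conf
  n <- c1 + c0
  pi_of <- function(rr) rr * pt1 / (rr * pt1 + pt0)
  # lower bound: largest rr with P(X >= c1 | rr) <= alpha/2 ... inverted CP
  p_upper_tail <- vapply(grid, function(rr)
    sum(dbinom(c1:n, n, pi_of(rr))), numeric(1))
  p_lower_tail <- vapply(grid, function(rr)
    sum(dbinom(0:c1, n, pi_of(rr))), numeric(1))
  lo <- if (c1 == 0) 0 else max(grid[p_upper_tail <= alpha / 2])
  hi <- if (c0 == 0) Inf else min(grid[p_lower_tail <= alpha / 2])
  c(lo, hi)
}

# Generic binomial likelihood-ratio statistic via dbinom: an independent
# algebraic route to the Bernoulli scan LLR (MLE vs null likelihood).
llr_dbinom_oracle <- function(c, n, p) {
  if (n == 0 || c / n <= p) return(0)
  dbinom(c, n, c / n, log = TRUE) - dbinom(c, n, p, log = TRUE)
}

# Random toy classification tree (2-4 levels, random branching).
random_toy_tree <- function() {
  codes <- "R0"; parents <- NA_character_
  frontier <- "R0"
  for (lv in 1:sample(2:3, 1)) {
    nxt <- character(0)
    for (p in frontier) {
      k <- sample(1:3, 1)
      kids <- paste0(p, LETTERS[seq_len(k)])
      codes <- c(codes, kids)
      parents <- c(parents, rep(p, k))
      nxt <- c(nxt, kids)
    }
    frontier <- nxt
  }
  build_tree(data.frame(code = codes, parent = parents, label = codes,
                        level = NA, stringsAsFactors = FALSE), "ICD10")
}

# Minimal followed-up cohort data.frame for rate/scan tests.
tiny_cohort <- function(exposure, person_years = NULL) {
  n <- length(exposure)
  if (is.null(person_years)) person_years <- rep(5, n)
  data.frame(child_id = seq_len(n), exposure = exposure,
             age_end_days = person_years * 365.25,
             person_years = person_years)
}

# Table 3 ICD-10 rows: cut, exposed events, comparator events (printed
# counts; denominators 1424 and 7120).
table3_icd <- data.frame(
  cut = c("H66", "H65-H75", "H60-H95", "A00-B99", "B25-B34", "G00-G09",
          "D55-D59", "R620", "B34", "M40-M54"),
  c1 = c(186, 237, 261, 424, 270, 8, 5, 7, 266, 17),
  c0 = c(675, 911, 1025, 1788, 1100, 9, 3, 7, 1091, 35),
  risk1 = c(13.06, 16.64, 18.33, 29.78, 18.96, 0.56, 0.35, 0.49, 18.68,
            1.19),
  risk0 = c(9.48, 12.79, 14.40, 25.11, 15.45, 0.13, 0.04, 0.10, 15.32,
            0.49),
  rr = c(1.38, 1.30, 1.27, 1.19, 1.23, 4.44, 8.33, 5.00, 1.22, 2.43),
  rd = c(3.58, 3.85, 3.93, 4.66, 3.51, 0.44, 0.31, 0.39, 3.36, 0.70),
  stringsAsFactors = FALSE)
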