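#' Synthetic registry data
#'
#' The real study data are confidential national registers. This module
#' generates parents, children, and coded healthcare-event streams with the
#' statistical structure the downstream analyses assume: a 1:5
#' exposed/comparator design, recurrent coded events from per-leaf Poisson
#' processes with a shared child-level gamma frailty (one
#' sickness-propensity factor per child, inducing within-child correlation
#' across codes), a uniform exposure rate multiplier, optional injected
#' code-cluster effects, and independent exponential death and emigration
#' censoring.
#'
#' @name synthetic_registry
#' @keywords internal
NULL

#' Hazard configuration for the synthetic registry
#'
#' @param baseline_rate per-leaf annual event rate (scalar, or named vector
#'   by leaf code). Default 0.04/year: with ~50 toy-dictionary leaves this
#'   yields roughly 2 events per child-year of the order seen in early
#'   childhood utilisation data.
#' @param frailty_var variance of the child-level gamma frailty (mean 1).
#'   Default 0.5; 0 switches frailty off.
#' @param exposure_mult global rate multiplier for exposed children,
#'   modelling a uniform health-seeking excess with no disease cluster.
#'   Default 1.08, the overall utilisation rate ratio the design emulates.
#' @param clusters list of `list(code =, rr =)` injected cluster effects:
#'   exposed children's rates on leaves under `code` are additionally
#'   multiplied by `rr`.
#' @param death_rate,emigration_rate annual exponential rates. Defaults
#'   5e-4 and 5e-3 (of the order of Swedish early-childhood mortality and
#'   family out-migration).
#' @param setting_probs probabilities of inpatient vs outpatient for visit
#'   events (ICD trees); ATC events are always dispensations.
#' @return a `hazard_config` list.
#' @export
hazard_config <- function(baseline_rate = 0.04, frailty_var = 0.5,
                          exposure_mult = 1.08, clusters = list(),
                          death_rate = 5e-4, emigration_rate = 5e-3,
                          setting_probs = c(inpatient = 0.15,
                                            outpatient = 0.85)) {
  setting_probs <- unlist(setting_probs)    # YAML configs give a list
  baseline_rate <- unlist(baseline_rate)
  stopifnot(all(baseline_rate >= 0), frailty_var >= 0, exposure_mult > 0,
            death_rate >= 0, emigration_rate >= 0)
  for (cl in clusters) stopifnot(!is.null(cl$code), cl$rr > 0)
  structure(list(baseline_rate = baseline_rate, frailty_var = frailty_var,
                 exposure_mult = exposure_mult, clusters = clusters,
                 death_rate = death_rate, emigration_rate = emigration_rate,
                 setting_probs = setting_probs),
            class = "hazard_config")
}

#' Simulate exposed children and a comparator pool
#'
#' Exposed children have at least one parent diagnosed with lymphoma before
#' their birth; the comparator pool is `pool_factor * ratio` times larger so
#' weighted matching has slack. Maternal age distributions overlap by
#' construction. Comparator children carry sampling weights produced by a
#' simulated year-by-year sampling design run through
#' [compute_sampling_weights()], so the weighting machinery is exercised,
#' not stubbed.
#'
#' @param n_exposed number of exposed children.
#' @param ratio matching ratio (comparators per exposed).
#' @param config a [hazard_config()].
#' @param seed integer seed.
#' @param pool_factor comparator pool size relative to `ratio * n_exposed`.
#' @return list with `exposed` and `pool` children data.frames (columns
#'   `child_id`, `exposure`, `birth_date`, `maternal_age_years`,
#'   `exposed_parent_sex`, `lymphoma_subtype`, `death_date`,
#'   `emigration_date`, `sampling_weight`) and `weight_audit`, the per-year
#'   sampling probabilities behind the weights.
#' @export
simulate_cohort <- function(n_exposed, ratio = 5L, config = hazard_config(),
                            seed = NULL, pool_factor = 3) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_exposed >= 1, ratio >= 1, pool_factor >= 1)
  n_pool <- ceiling(pool_factor * ratio * n_exposed)

  draw_children <- function(n, exposure, id0) {
    birth <- as.Date("2000-01-01") +
      sample.int(as.integer(as.Date("2018-12-31") - as.Date("2000-01-01")),
                 n, replace = TRUE)
    age <- pmin(pmax(round(stats::rnorm(n, 31, 4.5)), 18L), 45L)
    death <- stats::rexp(n, rate = max(config$death_rate, 1e-12)) *
      .DAYS_PER_YEAR
    emig <- stats::rexp(n, rate = max(config$emigration_rate, 1e-12)) *
      .DAYS_PER_YEAR
    data.frame(
      child_id = id0 + seq_len(n),
      exposure = exposure,
      birth_date = birth,
      maternal_age_years = as.integer(age),
      exposed_parent_sex = if (exposure)
        sample(c("female", "male"), n, replace = TRUE, prob = c(.457, .543))
      else NA_character_,
      lymphoma_subtype = if (exposure)
        sample(c("HL", "NHL"), n, replace = TRUE, prob = c(.563, .437))
      else NA_character_,
      death_date = birth + ifelse(death <= .FIVE_YEARS_DAYS,
                                  round(death), NA),
      emigration_date = birth + ifelse(emig <= .FIVE_YEARS_DAYS,
                                       round(emig), NA),
      stringsAsFactors = FALSE)
  }
  exposed <- draw_children(n_exposed, TRUE, 0L)
  exposed$sampling_weight <- 1
  pool <- draw_children(n_pool, FALSE, n_exposed)

  # comparator parents: year-by-year sampling within birth_year x sex strata
  par_by <- sample(1955:1990, n_pool, replace = TRUE)
  par_sex <- sample(c("F", "M"), n_pool, replace = TRUE)
  entry <- rep(2000L, n_pool)
  samp_year <- sample(2000:2018, n_pool, replace = TRUE)
  popc <- expand.grid(birth_year = 1955:1990, sex = c("F", "M"),
                      stringsAsFactors = FALSE)
  # stratum populations large relative to sampled counts
  popc$count <- 20000L
  wres <- compute_sampling_weights(
    data.frame(id = pool$child_id, birth_year = par_by, sex = par_sex,
               entry_year = entry, sampling_year = samp_year),
    popc)
  pool$sampling_weight <- wres$weights$weight[
    match(pool$child_id, wres$weights$id)]

  list(exposed = exposed, pool = pool, weight_audit = wres$probabilities)
}

# leaves under an injected cluster code
.cluster_leaves <- function(tree, code) {
  node <- resolve_code(tree, code)
  if (is.na(node)) stop("cluster code not on tree: ", code, call. = FALSE)
  tree$leaves[[node]]
}

#' Simulate recurrent coded healthcare events
#'
#' Per child and tree leaf, events arise from a Poisson process with rate
#' `baseline_rate * frailty * exposure multipliers` over the child's
#' follow-up, where the gamma frailty (mean 1, variance
#' `config$frailty_var`) is shared across all leaves within a child.
#' Exposed children's rates carry the global `exposure_mult` everywhere and
#' the cluster risk ratio on leaves under injected cuts. Event ages are
#' uniform over follow-up; follow-up is truncated at
#' min(death, emigration, age 5).
#'
#' @param children data.frame of children (exposed and/or comparators),
#'   passed through [define_followup()] if needed.
#' @param tree a `classification_tree`; its leaves receive the events.
#' @param config a [hazard_config()].
#' @param seed integer seed.
#' @return data.frame of events: `child_id`, `age_days`, `event_date`,
#'   `code`, `setting`, `diagnosis_position`.
#' @export
simulate_events <- function(children, tree, config = hazard_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(children$age_end_days)) children <- define_followup(children)
  n <- nrow(children)
  leaves <- tree$leaves[[tree$root]]
  base <- config$baseline_rate
  rates <- if (length(base) == 1L)
    stats::setNames(rep(base, length(leaves)), leaves)
  else base[leaves]
  if (anyNA(rates)) stop("baseline_rate missing for some leaves",
                         call. = FALSE)

  frailty <- if (config$frailty_var > 0)
    stats::rgamma(n, shape = 1 / config$frailty_var,
                  scale = config$frailty_var)
  else rep(1, n)

  clmult <- stats::setNames(rep(1, length(leaves)), leaves)
  for (cl in config$clusters) {
    lv <- .cluster_leaves(tree, cl$code)
    clmult[lv] <- clmult[lv] * cl$rr
  }
  exp_mult <- ifelse(children$exposure, config$exposure_mult, 1)
  pt_years <- children$age_end_days / .DAYS_PER_YEAR

  out <- vector("list", length(leaves))
  for (k in seq_along(leaves)) {
    lam <- rates[k] * frailty * exp_mult *
      ifelse(children$exposure, clmult[k], 1) * pt_years
    nev <- stats::rpois(n, lam)
    tot <- sum(nev)
    if (!tot) next
    idx <- rep.int(seq_len(n), nev)
    age <- floor(stats::runif(tot) * children$age_end_days[idx])
    out[[k]] <- data.frame(child_id = children$child_id[idx],
                           age_days = age, code = leaves[k],
                           stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(child_id = integer(0), age_days = numeric(0),
                     code = character(0), stringsAsFactors = FALSE)
  ev <- ev[order(ev$child_id, ev$age_days, ev$code), , drop = FALSE]
  rownames(ev) <- NULL
  ev$event_date <- children$birth_date[match(ev$child_id,
                                             children$child_id)] +
    ev$age_days
  if (tree$system == "ATC") {
    ev$setting <- rep("dispensation", nrow(ev))
    ev$diagnosis_position <- NA_character_
  } else {
    sp <- config$setting_probs
    ev$setting <- sample(names(sp), nrow(ev), replace = TRUE, prob = sp)
    ev$diagnosis_position <- sample(c("main", "secondary"), nrow(ev),
                                    replace = TRUE, prob = c(.8, .2))
  }
  ev
}

#' Write cohort and event tables as TSV with a seed header
#'
#' @param x data.frame.
#' @param path output file.
#' @param seed seed to record in the header comment.
#' @export
write_registry_table <- function(x, path, seed = NA) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# utilscan synthetic registry table; seed=%s; %s",
                     as.character(seed), format(Sys.time(), "%Y-%m-%d")),
             con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
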