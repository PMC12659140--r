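#' End-to-end pipeline over the synthetic registry
#'
#' Orchestrates simulate -> weight & match -> follow-up -> mask/exclude ->
#' rates -> mean cumulative counts -> tree scans (ICD on the full cohort,
#' ATC on the drug-register sub-cohort) -> optional power run, writing
#' TSV tables whose headers record the package version, master seed, and a
#' config hash. One master seed spawns fixed per-stage substreams so any
#' stage can be re-run in isolation reproducibly.
#'
#' @name pipeline
#' @keywords internal
NULL

# stage offsets for the single-seed policy
.STAGE_SEED <- c(cohort = 11L, match = 12L, events_icd = 13L,
                 events_atc = 14L, scan_icd = 15L, scan_atc = 16L,
                 power = 17L)

# small stable config fingerprint (polynomial rolling hash, hex)
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Default run configuration
#'
#' @param n_exposed,ratio cohort design (defaults 1424, 5).
#' @param R Monte-Carlo replicates for the scans.
#' @param k report size.
#' @param seed master seed.
#' @param hazard a [hazard_config()].
#' @param run_power whether to add the (slow) power stage.
#' @return config list accepted by [run_pipeline()]; can also be written
#'   to / read from YAML.
#' @export
default_config <- function(n_exposed = 1424L, ratio = 5L, R = 999L,
                           k = 10L, seed = 1L, hazard = hazard_config(),
                           run_power = FALSE) {
  hazard <- unclass(hazard)
  # lists survive YAML round trips with names intact; vectors do not
  hazard$setting_probs <- as.list(hazard$setting_probs)
  list(n_exposed = n_exposed, ratio = ratio, R = R, k = k, seed = seed,
       hazard = hazard, run_power = run_power,
       dictionaries = "toy")
}

.write_stage_table <- function(tab, path, seed, hash) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# utilscan %s; seed=%d; config=%s",
                     as.character(utils::packageVersion("utilscan")),
                     seed, hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full pipeline
#'
#' @param config a [default_config()]-style list, or the path of a YAML
#'   file holding one.
#' @param out_dir output directory for the TSV tables and log.
#' @return (invisibly) list with the in-memory stage results: `cohort`,
#'   `events_icd`, `events_atc`, `table2`, `utilisation`, `mcc`,
#'   `scan_icd`, `scan_atc`, and optionally `power`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  for (f in c("n_exposed", "ratio", "R", "k", "seed"))
    if (is.null(config[[f]]))
      stop("config field missing: ", f, call. = FALSE)
  hz <- do.call(hazard_config, config$hazard %||% list())
  if (identical(config$dictionaries %||% "toy", "toy")) {
    tree_icd <- toy_tree("ICD10")
    tree_atc <- toy_tree("ATC")
  } else {
    for (p in config$dictionaries)
      if (!file.exists(p)) stop("dictionary not found: ", p, call. = FALSE)
    tree_icd <- build_tree(read_dictionary(config$dictionaries[[1]]),
                           "ICD10")
    tree_atc <- build_tree(read_dictionary(config$dictionaries[[2]]), "ATC")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  hash <- .config_hash(config)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  sim <- simulate_cohort(config$n_exposed, config$ratio, hz,
                         seed = seed + .STAGE_SEED[["cohort"]])
  cohort <- match_children(sim$exposed, sim$pool, ratio = config$ratio,
                           seed = seed + .STAGE_SEED[["match"]])
  cohort <- define_followup(cohort)
  say("cohort: %d exposed, %d comparators (%d sets widened caliper)",
      sum(cohort$role == "exposed"), sum(cohort$role == "comparator"),
      attr(cohort, "n_widened"))

  ev_icd <- simulate_events(cohort, tree_icd, hz,
                            seed = seed + .STAGE_SEED[["events_icd"]])
  n0 <- nrow(ev_icd)
  ev_icd <- exclude_chapters(ev_icd)
  say("chapter exclusion: %d of %d visit events removed",
      attr(ev_icd, "n_removed"), n0)
  masked <- apply_mask(ev_icd$code, "ICD10", tree = tree_icd)
  say("masking: %d visit codes unresolved and dropped",
      attr(masked, "n_unresolved"))
  ev_icd$code <- as.character(masked)
  ev_icd <- ev_icd[!is.na(ev_icd$code), , drop = FALSE]

  ev_atc <- simulate_events(cohort, tree_atc, hz,
                            seed = seed + .STAGE_SEED[["events_atc"]])
  ev_atc$code <- as.character(apply_mask(ev_atc$code, "ATC",
                                         tree = tree_atc))
  ev_atc <- ev_atc[!is.na(ev_atc$code), , drop = FALSE]

  # Table-2-style rates: four event definitions x incident/all
  rows <- list(
    list(name = "Hospital visits combined", ev = ev_icd,
         setting = c("inpatient", "outpatient")),
    list(name = "Outpatient visits", ev = ev_icd, setting = "outpatient"),
    list(name = "Inpatient admissions", ev = ev_icd, setting = "inpatient"),
    list(name = "Drug dispensations", ev = ev_atc,
         setting = "dispensation"))
  table2 <- do.call(rbind, lapply(c("incident", "all"), function(kind) {
    do.call(rbind, lapply(rows, function(r) {
      ct <- count_events(r$ev, cohort, kind = kind, setting = r$setting)
      rr <- rate_ratio_exact(ct$count[1], ct$person_years[1],
                             ct$count[2], ct$person_years[2])
      data.frame(kind = kind, event = r$name,
                 n_exposed = ct$count[1], rate_exposed = rr$rate1,
                 n_comparator = ct$count[2], rate_comparator = rr$rate0,
                 rate_ratio = rr$rr, ci_lower = rr$lower,
                 ci_upper = rr$upper, p_value = rr$p.value)
    }))
  }))
  .write_stage_table(table2, file.path(out_dir, "table2.tsv"), seed, hash)

  totals <- tapply(rep(1L, nrow(ev_icd)),
                   factor(ev_icd$child_id, levels = cohort$child_id), sum,
                   default = 0L)
  util <- list(
    exposed = summarize_utilisation(totals[cohort$exposure]),
    comparator = summarize_utilisation(totals[!cohort$exposure]))

  mcc <- lapply(split(seq_len(nrow(cohort)), cohort$role), function(ix) {
    ch <- cohort[ix, ]
    ages <- split(ev_icd$age_days[ev_icd$child_id %in% ch$child_id] /
                    .DAYS_PER_YEAR,
                  factor(ev_icd$child_id[ev_icd$child_id %in% ch$child_id],
                         levels = ch$child_id))
    death <- as.numeric(ch$death_date - ch$birth_date) / .DAYS_PER_YEAR
    mean_cumulative_count(ages, death, ch$age_end_days / .DAYS_PER_YEAR)
  })
  write_mcc_curves(mcc, file.path(out_dir, "mcc_hospital.tsv"))

  scan_icd <- tbss_scan(ev_icd, cohort, tree_icd, R = config$R,
                        k = config$k,
                        seed = seed + .STAGE_SEED[["scan_icd"]])
  .write_stage_table(scan_icd$table, file.path(out_dir, "table3_icd.tsv"),
                     seed, hash)

  drug_cohort <- build_drug_subcohort(cohort)
  say("drug sub-cohort: %d of %d children retained",
      nrow(drug_cohort), nrow(cohort))
  ev_atc_sub <- ev_atc[ev_atc$child_id %in% drug_cohort$child_id, ,
                       drop = FALSE]
  scan_atc <- tbss_scan(ev_atc_sub, drug_cohort, tree_atc, R = config$R,
                        k = config$k,
                        seed = seed + .STAGE_SEED[["scan_atc"]])
  .write_stage_table(scan_atc$table, file.path(out_dir, "table3_atc.tsv"),
                     seed, hash)

  out <- list(cohort = cohort, events_icd = ev_icd, events_atc = ev_atc,
              table2 = table2, utilisation = util, mcc = mcc,
              scan_icd = scan_icd, scan_atc = scan_atc)
  if (isTRUE(config$run_power)) {
    pw <- minimum_detectable_rr(
      n_exposed = sum(cohort$exposure),
      n_comparators = sum(!cohort$exposure), prevalence = 0.10,
      R = config$R, seed = seed + .STAGE_SEED[["power"]])
    .write_stage_table(pw$curve, file.path(out_dir, "power_curve.tsv"),
                       seed, hash)
    out$power <- pw
  }
  writeLines(log, file.path(out_dir, "log.txt"))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-run the rate analysis within strata of the exposed parent
#'
#' Strata are defined on the exposed child (`exposed_parent_sex` or
#' `lymphoma_subtype`); each matched set follows its exposed child into the
#' stratum. Besides within-stratum exposed-vs-comparator rate ratios, the
#' direct between-stratum rate ratio among exposed children is reported
#' (first vs second stratum level).
#'
#' @param events event table (masked/excluded as for the main analysis).
#' @param cohort a followed-up `matched_cohort`.
#' @param key `"exposed_parent_sex"` or `"lymphoma_subtype"`.
#' @param kind,setting passed to [count_events()].
#' @return list: `per_stratum` (named list of `rate_result`) and `between`
#'   (a `rate_result` comparing exposed children across the two strata, or
#'   `NULL` with fewer than two non-empty strata).
#' @export
stratified_rerun <- function(events, cohort, key, kind = "all",
                             setting = NULL) {
  if (!key %in% c("exposed_parent_sex", "lymphoma_subtype"))
    stop("unknown stratification key: ", key, call. = FALSE)
  ex <- cohort[cohort$role == "exposed", ]
  stratum_of_set <- stats::setNames(ex[[key]], ex$set_id)
  cohort$stratum <- stratum_of_set[as.character(cohort$set_id)]
  levels <- sort(unique(stats::na.omit(cohort$stratum)))

  per_stratum <- list()
  for (lv in levels) {
    sub <- cohort[!is.na(cohort$stratum) & cohort$stratum == lv, ]
    if (!nrow(sub) || !any(sub$exposure) || !any(!sub$exposure)) {
      warning("stratum ", lv, " empty or one-armed, skipped",
              call. = FALSE)
      next
    }
    ct <- count_events(events, sub, kind = kind, setting = setting)
    per_stratum[[lv]] <- rate_ratio_exact(ct$count[1], ct$person_years[1],
                                          ct$count[2], ct$person_years[2])
  }
  between <- NULL
  if (length(levels) >= 2) {
    a <- cohort[cohort$exposure & cohort$stratum == levels[1], ]
    b <- cohort[cohort$exposure & cohort$stratum == levels[2], ]
    if (nrow(a) && nrow(b)) {
      ab <- rbind(a, b)
      ab$exposure <- ab$stratum == levels[1]
      ct <- count_events(events, ab, kind = kind, setting = setting)
      between <- rate_ratio_exact(ct$count[1], ct$person_years[1],
                                  ct$count[2], ct$person_years[2])
    }
  }
  list(per_stratum = per_stratum, between = between,
       levels = levels, key = key)
}
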