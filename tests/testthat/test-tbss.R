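# Bernoulli tree scan: LLR, aggregation, Monte-Carlo null, ranking.

test_that("the scan LLR matches its closed form and boundary algebra", {
  expect_equal(bernoulli_llr(186, 861, 1 / 6), 7.034891, tolerance = 1e-6)
  # null configuration: c/n = p exactly
  expect_equal(bernoulli_llr(1, 6, 1 / 6), 0)
  expect_equal(bernoulli_llr(10, 60, 1 / 6), 0)
  # all cases exposed
  expect_equal(bernoulli_llr(9, 9, 0.2), 9 * log(1 / 0.2))
  # not enriched -> 0
  expect_equal(bernoulli_llr(1, 60, 1 / 6), 0)
})

test_that("the LLR equals an independent dbinom-based likelihood ratio", {
  set.seed(81)
  for (i in 1:1000) {
    n <- sample(1:500, 1)
    c <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.99)
    expect_equal(bernoulli_llr(c, n, p), llr_dbinom_oracle(c, n, p),
                 tolerance = 1e-10)
  }
})

test_that("cut counts follow the distinct-children rule", {
  tr <- toy_tree("ICD10")
  cohort <- tiny_cohort(c(TRUE, FALSE, FALSE))
  # child 1 has events in two sibling categories of the same block
  ev <- data.frame(child_id = c(1, 1, 1, 2),
                   code = c("H65", "H66", "H66", "H66"))
  cc <- aggregate_cut_counts(ev, cohort, tr)
  cnt <- function(cut) cc$counts[cc$counts$cut == cut, c("c", "n")]
  expect_equal(unname(unlist(cnt("H65"))), c(1L, 1L))
  expect_equal(cnt("H66")$n, 2L)
  # once in the parent block and chapter despite two sibling hits
  expect_equal(unname(unlist(cnt("H65-H75"))), c(1L, 2L))
  expect_equal(cnt("H60-H95")$n, 2L)
  # untouched cut has n = 0 and is excluded from the report
  expect_equal(cnt("G00-G09")$n, 0L)
  rep10 <- rank_and_report(cc, null_max = rep(10, 99))
  expect_false("G00-G09" %in% rep10$cut)
  # design p comes from the whole cohort
  expect_equal(cc$p, 1 / 3)
})

test_that("one event per child on a single leaf gives n = cohort size", {
  tr <- build_tree(data.frame(code = c("R", "A"), parent = c(NA, "R"),
                              label = c("r", "a")), "ICD10")
  cohort <- tiny_cohort(rep(c(TRUE, FALSE), c(10, 50)))
  ev <- data.frame(child_id = cohort$child_id, code = "A")
  cc <- aggregate_cut_counts(ev, cohort, tr)
  expect_equal(cc$counts$n, 60L)
  expect_equal(cc$counts$c, 10L)
})

test_that("unknown codes are dropped with a warning and counted", {
  tr <- toy_tree("ICD10")
  cohort <- tiny_cohort(c(TRUE, FALSE))
  ev <- data.frame(child_id = c(1, 2), code = c("H66", "X99"))
  expect_warning(cc <- aggregate_cut_counts(ev, cohort, tr),
                 "not on the tree")
  expect_equal(cc$n_unknown, 1L)
  expect_equal(sum(cc$counts$n[cc$counts$cut == "H66"]), 1L)
})

test_that("the Monte-Carlo null matches direct binomial simulation on one cut", {
  # structure: 200 affected children, all in a single cut
  tr <- build_tree(data.frame(code = c("R", "A"), parent = c(NA, "R"),
                              label = c("r", "a")), "ICD10")
  cohort <- tiny_cohort(rep(c(TRUE, FALSE), c(40, 160)))
  ev <- data.frame(child_id = cohort$child_id, code = "A")
  cc <- aggregate_cut_counts(ev, cohort, tr)
  nm <- monte_carlo_null(cc, R = 4999, seed = 83)
  # single cut: max LLR exceeds llr(c*) exactly when the binomial count
  # exceeds c*, so tail frequencies have closed binomial form
  for (cstar in c(45, 48, 52)) {
    thr <- bernoulli_llr(cstar, 200, 0.2)
    p_exact <- pbinom(cstar - 1, 200, 0.2, lower.tail = FALSE)
    mcse <- sqrt(p_exact * (1 - p_exact) / 4999)
    expect_lt(abs(mean(nm >= thr) - p_exact), 4 * mcse)
  }
  # reproducible under a fixed seed
  expect_identical(nm, monte_carlo_null(cc, R = 4999, seed = 83))
})

test_that("adjusted p-values are the max-LLR rank over R + 1", {
  null_max <- seq(0.001, 9.999, length.out = 9999)
  expect_equal(adjusted_pvalue(10, null_max), 1 / 10000)
  expect_equal(adjusted_pvalue(0, null_max), 1)
  q95 <- unname(quantile(null_max, 0.95))
  expect_equal(adjusted_pvalue(q95, null_max), 0.05, tolerance = 0.002)
  expect_true(all(adjusted_pvalue(c(-1, 5, 100), null_max) >= 1 / 10000))
})

test_that("ranking is by descending LLR with stable code tie-breaks", {
  p <- 1424 / 8544
  cc <- structure(list(
    counts = data.frame(
      cut = c("ZZ", "AA", "BB", "CC"),
      c = c(50, 186, 186, 0),
      n = c(300, 861, 861, 0)),
    p = p, n_exposed = 1424, n_total = 8544), class = "cut_counts")
  tab <- rank_and_report(cc, null_max = seq(0, 20, length.out = 999),
                         k = 10)
  # AA and BB tie; code order breaks the tie; CC (n = 0) is dropped
  expect_equal(tab$cut[1:2], c("AA", "BB"))
  expect_equal(nrow(tab), 3)
  tab2 <- rank_and_report(cc, null_max = seq(0, 20, length.out = 999),
                          k = 2)
  expect_equal(nrow(tab2), 2)
  # risks use cohort denominators
  expect_equal(tab$risk_exposed[1], 100 * 186 / 1424)
  expect_equal(tab$risk_comparator[1], 100 * 675 / 7120)
})

test_that("membership-level relabelling is available as a variant", {
  tr <- toy_tree("ICD10")
  set.seed(86)
  cohort <- tiny_cohort(runif(400) < 1 / 6)
  ev <- data.frame(child_id = sample(cohort$child_id, 900, TRUE),
                   code = sample(c("H65", "H66", "A09", "B34", "G00"),
                                 900, TRUE))
  cc <- aggregate_cut_counts(ev, cohort, tr)
  nm_child <- monte_carlo_null(cc, R = 199, seed = 1)
  nm_memb <- monte_carlo_null(cc, R = 199, seed = 1, unit = "membership")
  expect_length(nm_memb, 199)
  expect_false(identical(nm_child, nm_memb))
})

test_that("tbss_scan is reproducible end to end under a seed", {
  tr <- toy_tree("ICD10")
  set.seed(87)
  cohort <- tiny_cohort(rep(c(TRUE, FALSE), c(50, 250)))
  ev <- data.frame(child_id = sample(cohort$child_id, 600, TRUE),
                   code = sample(c("H66", "A09", "B34", "G00", "M43"),
                                 600, TRUE))
  s1 <- tbss_scan(ev, cohort, tr, R = 199, seed = 42)
  s2 <- tbss_scan(ev, cohort, tr, R = 199, seed = 42)
  expect_identical(s1$table, s2$table)
  expect_true(all(s1$table$p_adj >= 1 / 200 & s1$table$p_adj <= 1))
  expect_true(all(diff(s1$table$llr) <= 0))
})
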