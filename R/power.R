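#' Simulation-based power for the tree-based scan design
#'
#' Estimates the probability that a scan detects an injected code cluster:
#' cohorts are simulated on a synthetic background tree with uniform
#' first-event risks, one cluster is injected at a given comparator
#' prevalence and risk ratio, and the scan (with its own Monte-Carlo null)
#' is run on each. A simulation counts as a detection when the cluster cut
#' or one of its ancestors/descendants reaches an adjusted p-value at or
#' below alpha. The generator works directly at the level of the scan's
#' sufficient statistic -- which children have a first event under which
#' leaf -- which is what the Bernoulli scan sees.
#'
#' @name power
#' @keywords internal
NULL

# all cuts strictly or weakly below a node (self included)
.descendants <- function(tree, code) {
  out <- character(0)
  stack <- code
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, x)
    kids <- tree$children[[x]]
    if (length(kids)) stack <- c(stack, kids)
  }
  out
}

# shared precomputation for a power run
.power_setup <- function(tree, cluster_code) {
  prep <- .scan_prep(tree)
  leaves <- tree$leaves[[tree$root]]
  leaf_closure <- prep$closure[leaves]
  cl_node <- resolve_code(tree, cluster_code)
  if (is.na(cl_node)) stop("cluster code not on tree", call. = FALSE)
  cl_leaves <- match(tree$leaves[[cl_node]], leaves)
  relevant <- unname(prep$idx[unique(c(.ancestor_closure(tree, cl_node),
                                       .descendants(tree, cl_node)))])
  list(prep = prep, n_leaves = length(leaves), leaf_closure = leaf_closure,
       cluster_leaves = cl_leaves, relevant = relevant)
}

# one simulated cohort's membership CSR + per-cut counts
.simulate_scan_counts <- function(n_exposed, n_comp, setup, background_risk,
                                  prevalence, rr) {
  n_tot <- n_exposed + n_comp
  n_cuts <- length(setup$prep$cuts)
  bg <- rep(background_risk, setup$n_leaves)
  bg[setup$cluster_leaves] <- 0     # cluster risk handled exactly below

  child <- integer(0); leaf <- integer(0)
  for (l in seq_len(setup$n_leaves)) {
    if (bg[l] <= 0) next
    k <- stats::rbinom(1L, n_tot, bg[l])
    if (k) {
      child <- c(child, sample.int(n_tot, k))
      leaf <- c(leaf, rep.int(l, k))
    }
  }
  aff_e <- which(stats::runif(n_exposed) < min(prevalence * rr, 1))
  aff_c <- n_exposed + which(stats::runif(n_comp) < prevalence)
  aff <- c(aff_e, aff_c)
  if (length(aff)) {
    child <- c(child, aff)
    leaf <- c(leaf, setup$cluster_leaves[
      sample.int(length(setup$cluster_leaves), length(aff),
                 replace = TRUE)])
  }
  if (!length(child))
    return(list(c_cut = integer(n_cuts), n_cut = integer(n_cuts),
                row_ptr = 0L, cut_idx = integer(0),
                unit_exposed = logical(0)))

  lens <- lengths(setup$leaf_closure)[leaf]
  cut <- unlist(setup$leaf_closure[leaf], use.names = FALSE)
  ch <- rep.int(child, lens)
  key <- (as.numeric(ch) - 1) * n_cuts + cut
  keep <- !duplicated(key)
  ch <- ch[keep]; cut <- cut[keep]
  o <- order(ch)
  ch <- ch[o]; cut <- cut[o]
  uc <- unique(ch)
  row_ptr <- c(0L, cumsum(tabulate(match(ch, uc), nbins = length(uc))))
  exp_unit <- uc <= n_exposed
  n_cut <- tabulate(cut, nbins = n_cuts)
  c_cut <- tabulate(cut[rep.int(exp_unit, diff(row_ptr))], nbins = n_cuts)
  list(c_cut = c_cut, n_cut = n_cut, row_ptr = as.integer(row_ptr),
       cut_idx = as.integer(cut - 1L), unit_exposed = exp_unit)
}

#' Power of the scan for one cluster scenario
#'
#' @param n_exposed,n_comparators cohort sizes (defaults 1424 and 7120).
#' @param prevalence comparator 5-year first-event risk of the cluster cut.
#' @param rr cluster risk ratio for exposed children; `prevalence * rr`
#'   must not exceed 1.
#' @param tree background hierarchy; default [synthetic_tree()] with 1000
#'   leaves in 3 levels.
#' @param cluster_code node carrying the cluster; default the first
#'   second-level node (10 leaves under defaults).
#' @param background_risk uniform per-leaf first-event risk outside the
#'   cluster (default 0.003, about 3 affected leaf codes per child).
#' @param alpha family-wise significance level (default 0.05).
#' @param R Monte-Carlo replicates per scan (default 999).
#' @param sims simulated cohorts (default 200).
#' @param seed integer seed.
#' @param setup internal: reuse a `.power_setup()` across grid points.
#' @return data.frame: `prevalence`, `rr`, `power`, `se`
#'   (binomial Monte-Carlo standard error), `sims`, `alpha`.
#' @export
power_at <- function(n_exposed = 1424L, n_comparators = 7120L,
                     prevalence, rr, tree = NULL, cluster_code = "T0101",
                     background_risk = 0.003, alpha = 0.05, R = 999L,
                     sims = 200L, seed = NULL, setup = NULL) {
  stopifnot(prevalence > 0, prevalence * rr <= 1, sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(setup)) {
    if (is.null(tree)) tree <- synthetic_tree(1000L, 3L)
    setup <- .power_setup(tree, cluster_code)
  }
  p <- n_exposed / (n_exposed + n_comparators)
  hits <- 0L
  for (s in seq_len(sims)) {
    sim <- .simulate_scan_counts(n_exposed, n_comparators, setup,
                                 background_risk, prevalence, rr)
    llr_rel <- max(bernoulli_llr(sim$c_cut[setup$relevant],
                                 sim$n_cut[setup$relevant], p))
    null_max <- cpp_scan_null(sim$row_ptr, sim$cut_idx,
                              as.numeric(sim$n_cut), p, as.integer(R))
    p_adj <- (1 + sum(null_max >= llr_rel)) / (R + 1)
    if (p_adj <= alpha) hits <- hits + 1L
  }
  pw <- hits / sims
  data.frame(prevalence = prevalence, rr = rr, power = pw,
             se = sqrt(pw * (1 - pw) / sims), sims = sims, alpha = alpha)
}

#' Minimum detectable risk ratio on a grid
#'
#' Walks an ascending risk-ratio grid and returns the smallest grid value
#' whose estimated power reaches the target; grid points above the first
#' hit are not simulated (power is monotone in the risk ratio up to
#' Monte-Carlo error).
#'
#' @inheritParams power_at
#' @param target_power required power (default 0.80).
#' @param grid ascending risk-ratio grid.
#' @return list: `mdrr` (smallest grid RR reaching the target, `NA` with a
#'   warning if none does) and `curve` (the per-point [power_at()] rows
#'   actually computed).
#' @export
minimum_detectable_rr <- function(n_exposed = 1424L, n_comparators = 7120L,
                                  prevalence, target_power = 0.8,
                                  grid = seq(1.15, 1.9, by = 0.05),
                                  tree = NULL, cluster_code = "T0101",
                                  background_risk = 0.003, alpha = 0.05,
                                  R = 999L, sims = 200L, seed = NULL) {
  stopifnot(!is.unsorted(grid))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- synthetic_tree(1000L, 3L)
  setup <- .power_setup(tree, cluster_code)
  rows <- list()
  mdrr <- NA_real_
  for (r in grid) {
    pt <- power_at(n_exposed, n_comparators, prevalence, r,
                   background_risk = background_risk, alpha = alpha,
                   R = R, sims = sims, setup = setup)
    rows[[length(rows) + 1L]] <- pt
    if (pt$power >= target_power) { mdrr <- r; break }
  }
  if (is.na(mdrr))
    warning("no grid point reached the target power", call. = FALSE)
  list(mdrr = mdrr, curve = do.call(rbind, rows))
}
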