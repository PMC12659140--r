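#' Unconditional Bernoulli tree-based scan statistic
#'
#' Scans every cut of a classification tree for clusters of first events in
#' which exposed children are overrepresented. Under the unconditional
#' Bernoulli model each affected child is exposed with the design
#' probability p (1/6 under 1:5 matching); a cut with c exposed of n
#' affected children is scored with the log-likelihood ratio
#' \deqn{LLR = c \ln\frac{c}{pn} + (n-c) \ln\frac{n-c}{(1-p)n}}
#' when c/n > p and 0 otherwise. Multiplicity over all cuts is adjusted by
#' Monte Carlo: the null distribution of the maximum LLR is obtained by
#' relabelling children, and a cut's adjusted p-value is its rank in that
#' distribution.
#'
#' @name tbss
#' @keywords internal
NULL

#' Bernoulli scan log-likelihood ratio
#'
#' @param c number of exposed children with a first event in the cut
#'   (vectorised).
#' @param n total children with a first event in the cut.
#' @param p design probability of exposure.
#' @return non-negative LLR; 0 when the cut is not enriched (c/n <= p).
#' @export
#' @examples
#' bernoulli_llr(186, 861, 1/6)
bernoulli_llr <- function(c, n, p) {
  stopifnot(all(c >= 0), all(c <= n), p > 0, p < 1)
  term <- function(k, mu) ifelse(k > 0, k * log(k / mu), 0)
  out <- term(c, p * n) + term(n - c, (1 - p) * n)
  ifelse(n > 0 & c / n > p, out, 0)
}

# integer cut index closure per tree node (self + ancestors, root excluded),
# in the fixed enumerate_cuts order; reused by aggregation and simulation
.scan_prep <- function(tree) {
  cuts <- names(enumerate_cuts(tree))
  idx <- stats::setNames(seq_along(cuts), cuts)
  closure <- lapply(cuts, function(cd)
    unname(idx[.ancestor_closure(tree, cd)]))
  names(closure) <- cuts
  list(cuts = cuts, idx = idx, closure = closure)
}

#' Aggregate first-event counts for every cut
#'
#' For each cut, `n` counts the distinct children with at least one event
#' whose (masked) code falls in the cut's leaf set, and `c` counts the
#' exposed children among them -- a child appears at most once per cut
#' however many qualifying events it has.
#'
#' @param events data.frame with `child_id`, `code` (already masked and
#'   chapter-excluded).
#' @param cohort data.frame with `child_id`, `exposure` for the full
#'   analysis cohort.
#' @param tree a `classification_tree`.
#' @param prep optional precomputed `.scan_prep(tree)` (internal reuse).
#' @return object of class `cut_counts`: list with `counts` (data.frame
#'   `cut`, `c`, `n` over all tree cuts in enumeration order), CSR
#'   membership of affected children (`row_ptr`, `cut_idx`, 0-based),
#'   `unit_exposed`, `p` (design exposure probability
#'   n_exposed / n_total of the cohort), and `n_unknown` (events whose code
#'   could not be placed on the tree; they are dropped and counted).
#' @export
aggregate_cut_counts <- function(events, cohort, tree, prep = NULL) {
  if (is.null(prep)) prep <- .scan_prep(tree)
  exposure <- stats::setNames(cohort$exposure, cohort$child_id)

  ucodes <- unique(events$code)
  node_of <- vapply(ucodes, function(cd) resolve_code(tree, cd),
                    character(1))
  node <- node_of[match(events$code, ucodes)]
  known <- !is.na(node) & as.character(events$child_id) %in% names(exposure)
  n_unknown <- sum(is.na(node))
  if (n_unknown > 0)
    warning(n_unknown, " event(s) with codes not on the tree dropped",
            call. = FALSE)
  child <- events$child_id[known]
  node <- node[known]

  # distinct (child, node) first events, then ancestor closure per child
  dup <- duplicated(paste(child, node, sep = "\r"))
  child <- child[!dup]
  node <- node[!dup]
  per_child <- split(node, child)
  memb <- lapply(per_child, function(nd)
    sort(unique(unlist(prep$closure[nd], use.names = FALSE))))
  units <- names(per_child)

  lens <- lengths(memb)
  cut_idx <- unlist(memb, use.names = FALSE)
  row_ptr <- c(0L, cumsum(lens))
  unit_exposed <- as.logical(exposure[units])

  n_cut <- tabulate(cut_idx, nbins = length(prep$cuts))
  c_cut <- tabulate(cut_idx[rep.int(unit_exposed, lens)],
                    nbins = length(prep$cuts))
  structure(list(
    counts = data.frame(cut = prep$cuts, c = c_cut, n = n_cut,
                        stringsAsFactors = FALSE),
    row_ptr = as.integer(row_ptr),
    cut_idx = as.integer(cut_idx - 1L),
    unit_exposed = unit_exposed,
    p = mean(cohort$exposure),
    n_total = nrow(cohort),
    n_exposed = sum(cohort$exposure),
    n_unknown = n_unknown),
    class = "cut_counts")
}

#' Monte-Carlo null distribution of the maximum LLR
#'
#' Each replicate independently relabels every affected child as exposed
#' with probability p -- all the child's cut memberships move together,
#' preserving within-child correlation across codes -- recomputes all cut
#' LLRs, and records the maximum. With `unit = "membership"` each
#' child-code first event is relabelled independently instead (an
#' event-level variant offered for comparison; the child-level null is the
#' default and the one matching the distinct-children counting rule).
#'
#' @param counts a `cut_counts` object.
#' @param R number of replicates (default 9999).
#' @param p exposure probability; defaults to the design value stored in
#'   `counts`.
#' @param seed optional integer seed.
#' @param unit `"child"` or `"membership"`.
#' @return sorted numeric vector of R max-LLR values.
#' @export
monte_carlo_null <- function(counts, R = 9999L, p = counts$p, seed = NULL,
                             unit = c("child", "membership")) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(R >= 1, p > 0, p < 1)
  if (unit == "child") {
    row_ptr <- counts$row_ptr
    cut_idx <- counts$cut_idx
    n_cut <- counts$counts$n
  } else {
    # one unit per (child, cut) membership; totals count memberships
    cut_idx <- counts$cut_idx
    row_ptr <- 0:length(cut_idx)
    n_cut <- tabulate(cut_idx + 1L, nbins = nrow(counts$counts))
  }
  sort(cpp_scan_null(as.integer(row_ptr), as.integer(cut_idx),
                     as.numeric(n_cut), p, as.integer(R)))
}

#' Multiplicity-adjusted p-value from the max-LLR null
#'
#' @param llr observed LLR(s), vectorised.
#' @param null_max the Monte-Carlo max-LLR vector (length R).
#' @return p = (1 + #\{replicates with max >= llr\}) / (R + 1), in
#'   \[1/(R+1), 1\].
#' @export
adjusted_pvalue <- function(llr, null_max) {
  R <- length(null_max)
  vapply(llr, function(x) (1 + sum(null_max >= x)) / (R + 1), numeric(1))
}

#' Rank cuts and assemble the top-k report
#'
#' Cuts are ranked by descending LLR with ties broken code-lexicographically
#' (byte-stable output). Risks, risk ratios, and risk differences use the
#' full cohort denominators via [risk_and_ratio()]. Cuts with n = 0 are
#' skipped; cuts with c = n are valid.
#'
#' @param counts a `cut_counts` object.
#' @param null_max Monte-Carlo max-LLR vector.
#' @param k report size (default 10); larger than the number of scored cuts
#'   returns all.
#' @param p exposure probability (default design value).
#' @param labels optional named character vector of cut labels.
#' @return data.frame: `rank`, `cut`, `label`, `c`, `risk_exposed`,
#'   `c0`, `risk_comparator`, `rr`, `rd`, `llr`, `p_adj`.
#' @export
rank_and_report <- function(counts, null_max, k = 10L, p = counts$p,
                            labels = NULL) {
  tab <- counts$counts[counts$counts$n > 0, , drop = FALSE]
  tab$llr <- bernoulli_llr(tab$c, tab$n, p)
  ord <- order(-tab$llr, tab$cut)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[seq_len(min(k, nrow(tab))), , drop = FALSE]
  rk <- lapply(seq_len(nrow(tab)), function(i)
    risk_and_ratio(tab$c[i], counts$n_exposed,
                   tab$n[i] - tab$c[i], counts$n_total - counts$n_exposed))
  data.frame(
    rank = seq_len(nrow(tab)),
    cut = tab$cut,
    label = if (is.null(labels)) tab$cut else
      ifelse(is.na(labels[tab$cut]), tab$cut, labels[tab$cut]),
    c = tab$c,
    risk_exposed = vapply(rk, `[[`, numeric(1), "risk1"),
    c0 = tab$n - tab$c,
    risk_comparator = vapply(rk, `[[`, numeric(1), "risk0"),
    rr = vapply(rk, `[[`, numeric(1), "rr"),
    rd = vapply(rk, `[[`, numeric(1), "rd"),
    llr = tab$llr,
    p_adj = adjusted_pvalue(tab$llr, null_max),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Run a full tree-based scan
#'
#' Convenience wrapper: aggregate cut counts, draw the Monte-Carlo null,
#' and assemble the ranked report.
#'
#' @inheritParams aggregate_cut_counts
#' @inheritParams monte_carlo_null
#' @param k report size.
#' @return list of class `tbss_scan`: `table` (the top-k report),
#'   `null_max`, `counts`, `R`, `p`, `seed`.
#' @export
tbss_scan <- function(events, cohort, tree, R = 9999L, k = 10L,
                      seed = NULL, unit = c("child", "membership")) {
  unit <- match.arg(unit)
  counts <- aggregate_cut_counts(events, cohort, tree)
  null_max <- monte_carlo_null(counts, R = R, seed = seed, unit = unit)
  labels <- stats::setNames(tree$nodes$label, tree$nodes$code)
  structure(list(table = rank_and_report(counts, null_max, k = k,
                                         labels = labels),
                 null_max = null_max, counts = counts, R = R,
                 p = counts$p, seed = seed),
            class = "tbss_scan")
}

#' @export
print.tbss_scan <- function(x, ...) {
  cat(sprintf("<tbss_scan> p = %.4f, R = %d, %d affected children\n",
              x$p, x$R, length(x$counts$unit_exposed)))
  tab <- x$table
  tab$risk_exposed <- round(tab$risk_exposed, 2)
  tab$risk_comparator <- round(tab$risk_comparator, 2)
  tab$rr <- round(tab$rr, 2)
  tab$rd <- round(tab$rd, 2)
  tab$llr <- round(tab$llr, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
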