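# Classification trees: construction, cut enumeration, masking, exclusion.

test_that("build_tree validates structure and finds leaves", {
  chain <- data.frame(code = c("R", "A", "A0"),
                      parent = c(NA, "R", "A"),
                      label = c("root", "a", "a0"))
  tr <- build_tree(chain, "ICD10")
  expect_equal(nrow(tr$nodes), 3)
  expect_equal(tr$leaves[["R"]], "A0")
  expect_length(enumerate_cuts(tr), 2)

  orphan <- data.frame(code = c("R", "A"), parent = c(NA, "B"),
                       label = c("r", "a"))
  expect_error(build_tree(orphan, "ICD10"), "orphan|exactly one root")

  dupe <- data.frame(code = c("R", "A", "A"), parent = c(NA, "R", "R"),
                     label = c("r", "a", "a"))
  expect_error(build_tree(dupe, "ICD10"), "duplicate")

  cyc <- data.frame(code = c("R", "A", "B"), parent = c(NA, "B", "A"),
                    label = c("r", "a", "b"))
  expect_error(build_tree(cyc, "ICD10"), "cycle")
})

test_that("a 2-chapter/4-block/8-category toy tree yields 14 cuts", {
  codes <- c("ROOT",
             "C1", "C2",
             "C1B1", "C1B2", "C2B1", "C2B2",
             paste0(rep(c("C1B1", "C1B2", "C2B1", "C2B2"), each = 2),
                    c("x", "y")))
  parents <- c(NA, "ROOT", "ROOT",
               "C1", "C1", "C2", "C2",
               rep(c("C1B1", "C1B2", "C2B1", "C2B2"), each = 2))
  tr <- build_tree(data.frame(code = codes, parent = parents,
                              label = codes), "ICD10")
  cuts <- enumerate_cuts(tr)
  expect_length(cuts, 14)
  # bijection onto non-root nodes
  expect_setequal(names(cuts), setdiff(toupper(codes), "ROOT"))
  # leaves(parent) is the disjoint union over children
  expect_setequal(cuts[["C1"]], c(cuts[["C1B1"]], cuts[["C1B2"]]))
  expect_equal(length(cuts[["C1"]]),
               length(cuts[["C1B1"]]) + length(cuts[["C1B2"]]))
})

test_that("cut-count conservation holds on random toy trees", {
  set.seed(41)
  for (i in 1:10) {
    tr <- random_toy_tree()
    cuts <- enumerate_cuts(tr)
    expect_setequal(names(cuts), setdiff(tr$nodes$code, tr$root))
    for (cd in names(cuts)) {
      kids <- tr$children[[cd]]
      if (length(kids)) {
        expect_setequal(cuts[[cd]],
                        unlist(cuts[kids], use.names = FALSE))
        expect_equal(length(cuts[[cd]]),
                     sum(lengths(cuts[kids])))
      }
    }
  }
})

test_that("cut order is depth-first and code-lexicographic", {
  tr <- toy_tree("ICD10")
  cuts <- names(enumerate_cuts(tr))
  # first chapter's subtree comes fully before the second chapter
  expect_equal(cuts[1], "A00-B99")
  expect_true(which(cuts == "B25-B34") < which(cuts == "D50-D89"))
  expect_identical(cuts, names(enumerate_cuts(tr)))  # byte-stable
})

test_that("granularity masking follows the shipped rules", {
  tr <- toy_tree("ICD10")
  ta <- toy_tree("ATC")
  # eye chapter collapses to the chapter range code
  expect_equal(as.character(apply_mask("H00.1", "ICD10", tree = tr)),
               "H00-H59")
  # ear chapter keeps 3-character categories
  expect_equal(as.character(apply_mask("H661", "ICD10", tree = tr)), "H66")
  # congenital malformations collapse to blocks
  expect_equal(as.character(apply_mask("Q213", "ICD10", tree = tr)),
               "Q20-Q28")
  # no rule: pass through normalised
  expect_equal(as.character(apply_mask("B34.2", "ICD10", tree = tr)),
               "B342")
  # ATC: class J full detail, class N truncated to 5 characters
  expect_equal(as.character(apply_mask("J01DD14", "ATC", tree = ta)),
               "J01DD14")
  expect_equal(as.character(apply_mask("N02BE01", "ATC", tree = ta)),
               "N02BE")
})

test_that("masking is idempotent", {
  tr <- toy_tree("ICD10")
  ta <- toy_tree("ATC")
  icd_codes <- c("H001", "H661", "H701", "Q213", "B342", "P079", "M435",
                 "A090", "G001")
  once <- as.character(apply_mask(icd_codes, "ICD10", tree = tr))
  twice <- as.character(apply_mask(once, "ICD10", tree = tr))
  expect_identical(twice, once)
  atc_codes <- c("J01DD14", "N02BE01", "B03BB01", "A01AB03", "R05CB10")
  once <- as.character(apply_mask(atc_codes, "ATC", tree = ta))
  expect_identical(as.character(apply_mask(once, "ATC", tree = ta)), once)
})

test_that("unresolvable codes are dropped with a counter", {
  tr <- toy_tree("ICD10")
  m <- apply_mask(c("H001", "X999"), "ICD10", tree = tr)
  # X999 matches no rule and passes through; resolution happens on the tree
  expect_equal(attr(m, "n_unresolved"), 0)
  expect_true(is.na(resolve_code(tr, "X999")))
  # an eye-chapter-like code outside any tree range is unresolvable
  m2 <- apply_mask("H991", "ICD10",
                   rules = data.frame(match = "H99-H99",
                                      target = "chapter"), tree = tr)
  expect_equal(attr(m2, "n_unresolved"), 1)
})

test_that("chapter exclusion removes injury/external/contact chapters", {
  ev <- data.frame(child_id = 1:4,
                   code = c("Z001", "H66", "S062", "V481"))
  out <- exclude_chapters(ev)
  expect_equal(out$code, "H66")
  expect_equal(attr(out, "n_removed"), 3)
  empty <- exclude_chapters(ev[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_removed"), 0)
})

test_that("resolve_code walks prefixes and range nodes", {
  tr <- toy_tree("ICD10")
  expect_equal(resolve_code(tr, "B34.2"), "B342")
  expect_equal(resolve_code(tr, "B343"), "B34")     # unknown subcategory
  expect_equal(resolve_code(tr, "H67"), "H65-H75")  # via block range
  expect_equal(resolve_code(tr, "J10"), "J00-J99")  # via chapter range
  expect_true(is.na(resolve_code(tr, "X99")))
  ta <- toy_tree("ATC")
  expect_equal(resolve_code(ta, "J01DD08"), "J01DD")
})
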