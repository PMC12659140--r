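#' Classification trees for ICD-10 and ATC codes
#'
#' A `classification_tree` is a rooted hierarchy of diagnosis (ICD-10) or
#' drug (ATC) codes. Every non-root node -- chapter, block, category,
#' subcategory for ICD-10; levels 1 through 5/7 for ATC -- is a candidate
#' "cut" for the tree-based scan statistic: the set of leaf codes beneath it.
#'
#' @name classification_tree
#' @keywords internal
NULL

.SYSTEMS <- c("ICD10", "ATC")

#' Normalise a raw ICD-10 or ATC code
#'
#' Strips dots (the Swedish ICD-10 dialect writes \code{R620}, not
#' \code{R62.0}), converts en-dashes in range codes to plain hyphens, removes
#' whitespace, and upper-cases.
#'
#' @param code character vector of raw codes.
#' @return character vector of normalised codes.
#' @export
#' @examples
#' normalise_code(c("H00.1", "h661", "H65–H75"))
normalise_code <- function(code) {
  code <- gsub("–", "-", code, fixed = TRUE)
  code <- gsub("[. ]", "", code)
  toupper(code)
}

#' Build a validated classification tree from a dictionary table
#'
#' @param dictionary data.frame with columns `code`, `parent`, `label`,
#'   `level`. Exactly one row must have an empty/NA parent (the root).
#'   Codes are normalised with [normalise_code()] on ingestion.
#' @param system `"ICD10"` or `"ATC"`.
#' @return an object of class `classification_tree` with elements
#'   `system`, `nodes` (the normalised dictionary), `root`, `children`
#'   (named list code -> child codes), `parent` (named character), and
#'   `leaves` (named list code -> leaf codes beneath, a terminal node being
#'   its own single leaf).
#' @export
build_tree <- function(dictionary, system = c("ICD10", "ATC")) {
  system <- match.arg(system)
  req <- c("code", "parent", "label")
  if (!all(req %in% names(dictionary)))
    stop("dictionary must have columns code, parent, label", call. = FALSE)
  nodes <- as.data.frame(dictionary, stringsAsFactors = FALSE)
  nodes$code <- normalise_code(as.character(nodes$code))
  nodes$parent <- as.character(nodes$parent)
  nodes$parent[!is.na(nodes$parent) & nodes$parent == ""] <- NA_character_
  nodes$parent[!is.na(nodes$parent)] <-
    normalise_code(nodes$parent[!is.na(nodes$parent)])
  if (is.null(nodes$level)) nodes$level <- NA_character_

  if (anyDuplicated(nodes$code))
    stop("duplicate code(s) in dictionary: ",
         paste(unique(nodes$code[duplicated(nodes$code)]), collapse = ", "),
         call. = FALSE)
  is_root <- is.na(nodes$parent)
  if (sum(is_root) != 1L)
    stop("dictionary must contain exactly one root (empty parent), found ",
         sum(is_root), call. = FALSE)
  root <- nodes$code[is_root]
  orphan <- setdiff(nodes$parent[!is_root], nodes$code)
  if (length(orphan))
    stop("orphan parent reference(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)

  parent <- stats::setNames(nodes$parent, nodes$code)
  children <- split(nodes$code[!is_root], nodes$parent[!is_root])

  # reachability doubles as the cycle check: a cycle is unreachable from root
  seen <- character(0)
  stack <- root
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, x)
    kids <- children[[x]]
    if (length(kids)) stack <- c(stack, sort(kids, decreasing = TRUE))
  }
  if (length(seen) != nrow(nodes))
    stop("cycle or disconnected node(s): ",
         paste(setdiff(nodes$code, seen), collapse = ", "), call. = FALSE)

  leaves <- .collect_leaves(root, children)
  structure(
    list(system = system, nodes = nodes, root = root, parent = parent,
         children = children, leaves = leaves),
    class = "classification_tree")
}

# post-order leaf collection; iterative to spare the call stack on deep trees
.collect_leaves <- function(root, children) {
  out <- list()
  order <- character(0)
  stack <- root
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, x)
    kids <- children[[x]]
    if (length(kids)) stack <- c(stack, kids)
  }
  for (x in rev(order)) {
    kids <- children[[x]]
    out[[x]] <- if (length(kids)) unlist(out[kids], use.names = FALSE) else x
  }
  out
}

#' @export
print.classification_tree <- function(x, ...) {
  cat(sprintf("<classification_tree> %s: %d nodes, %d leaves, root '%s'\n",
              x$system, nrow(x$nodes), length(x$leaves[[x$root]]), x$root))
  invisible(x)
}

#' Ancestor chain of a node, root excluded, self included
#' @noRd
.ancestor_closure <- function(tree, code) {
  out <- character(0)
  x <- code
  while (!is.na(x) && x != tree$root) {
    out <- c(out, x)
    x <- tree$parent[[x]]
  }
  out
}

#' Enumerate every candidate cut of a tree
#'
#' One cut per non-root node, in depth-first order with siblings visited
#' code-lexicographically, so output order is byte-stable across runs.
#'
#' @param tree a [build_tree()] object.
#' @return named list, cut code -> character vector of the leaf codes
#'   beneath it (a terminal node is its own single leaf).
#' @export
enumerate_cuts <- function(tree) {
  stopifnot(inherits(tree, "classification_tree"))
  order <- character(0)
  stack <- sort(tree$children[[tree$root]], decreasing = TRUE)
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, x)
    kids <- tree$children[[x]]
    if (length(kids)) stack <- c(stack, sort(kids, decreasing = TRUE))
  }
  tree$leaves[order]
}

# ---- code resolution -------------------------------------------------------

# 3-char ICD head within a range code like "H65-H75" or "A00-B99":
# fixed-width letter+2-digit format makes plain string comparison correct.
.in_range <- function(head, range) {
  parts <- strsplit(range, "-", fixed = TRUE)[[1]]
  length(parts) == 2L && head >= parts[1] && head <= substr(parts[2], 1, 3)
}

#' Resolve a raw code to the deepest tree node containing it
#'
#' Exact match first; then progressively shorter prefixes; then containment
#' in range-coded nodes (ICD blocks/chapters such as `"H65-H75"`).
#'
#' @param tree classification tree.
#' @param code a single raw code (normalised internally).
#' @return the matching node code, or `NA_character_` if the code cannot be
#'   placed anywhere on the tree.
#' @export
resolve_code <- function(tree, code) {
  code <- normalise_code(code)
  all_codes <- names(tree$parent)
  for (len in seq(nchar(code), 1L)) {
    head <- substr(code, 1, len)
    if (head %in% all_codes) return(head)
  }
  head3 <- substr(code, 1, 3)
  ranges <- all_codes[grepl("-", all_codes, fixed = TRUE)]
  hit <- ranges[vapply(ranges, .in_range, logical(1), head = head3)]
  if (!length(hit)) return(NA_character_)
  # deepest containing range (blocks nest inside chapters)
  depth <- vapply(hit, function(h) length(.ancestor_closure(tree, h)),
                  integer(1))
  hit[which.max(depth)]
}

# ---- granularity masking ---------------------------------------------------

#' Shipped granularity rules
#'
#' Register extracts are often coarsened by the data holder. The defaults
#' mirror a typical Swedish extract: eye (H00-H59) and perinatal (P00-P96)
#' chapters only at chapter level; ear (H60-H95) at 3-character categories;
#' congenital malformations (Q00-Q99) at block level. For ATC: class J in
#' full detail, classes A, B, C, G, H, L, M, N truncated to 5 characters,
#' and D, P, R, S, V to 4 characters.
#'
#' @param system `"ICD10"` or `"ATC"`.
#' @return data.frame with columns `match` (chapter range or ATC class
#'   letter) and `target` (one of `chapter`, `block`, `category`, `atc5`,
#'   `atc4`, `full`). Rules are non-overlapping by construction.
#' @export
default_mask_rules <- function(system = c("ICD10", "ATC")) {
  system <- match.arg(system)
  if (system == "ICD10") {
    data.frame(
      match  = c("H00-H59", "P00-P96", "H60-H95", "Q00-Q99"),
      target = c("chapter", "chapter", "category", "block"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      match  = c("J", "A", "B", "C", "G", "H", "L", "M", "N",
                 "D", "P", "R", "S", "V"),
      target = c("full", rep("atc5", 8), rep("atc4", 5)),
      stringsAsFactors = FALSE)
  }
}

#' Coarsen a code to the granularity its rule prescribes
#'
#' @param code character vector of raw codes.
#' @param system `"ICD10"` or `"ATC"`.
#' @param rules data.frame as [default_mask_rules()]; a code matching no
#'   rule passes through unchanged (after normalisation).
#' @param tree the classification tree, needed to look up chapter/block
#'   range codes.
#' @return character vector of masked codes, same length as `code`. Codes
#'   unresolvable even at chapter level come back as `NA_character_`; the
#'   number of such codes is attached as attribute `n_unresolved`.
#' @export
apply_mask <- function(code, system = c("ICD10", "ATC"),
                       rules = default_mask_rules(system), tree) {
  system <- match.arg(system)
  code <- normalise_code(code)
  out <- vapply(code, function(cd) .mask_one(cd, system, rules, tree),
                character(1), USE.NAMES = FALSE)
  structure(out, n_unresolved = sum(is.na(out)))
}

.mask_one <- function(cd, system, rules, tree) {
  if (system == "ATC") {
    hit <- match(substr(cd, 1, 1), rules$match)
    if (is.na(hit)) return(cd)
    return(switch(rules$target[hit],
                  full = cd,
                  atc5 = substr(cd, 1, 5),
                  atc4 = substr(cd, 1, 4),
                  atc3 = substr(cd, 1, 3),
                  cd))
  }
  head3 <- substr(cd, 1, 3)
  hit <- which(vapply(rules$match, .in_range, logical(1), head = head3))
  if (!length(hit)) return(cd)
  target <- rules$target[hit[1]]
  if (target == "full") return(cd)
  if (target == "category") {
    if (is.na(resolve_code(tree, head3))) return(NA_character_)
    return(head3)
  }
  # chapter / block: need the range node on the tree
  node <- resolve_code(tree, head3)
  if (is.na(node)) return(NA_character_)
  chain <- .ancestor_closure(tree, node)  # self .. chapter
  lev <- stats::setNames(tree$nodes$level, tree$nodes$code)[chain]
  pick <- chain[match(target, lev)]
  if (is.na(pick)) chain[length(chain)] else pick
}

#' Drop events from excluded ICD-10 chapters
#'
#' External-cause, injury, and health-services-contact chapters (S00-T98,
#' V01-Y98, Z00-Z99 by default) are removed before any utilisation analysis.
#'
#' @param events data.frame with a `code` column of ICD-10 codes.
#' @param excluded character vector of chapter ranges.
#' @return the retained events, with attribute `n_removed`.
#' @export
exclude_chapters <- function(events,
                             excluded = c("S00-T98", "V01-Y98", "Z00-Z99")) {
  if (!nrow(events)) return(structure(events, n_removed = 0L))
  heads <- substr(normalise_code(events$code), 1, 3)
  drop <- rep(FALSE, length(heads))
  for (rg in normalise_code(excluded)) {
    parts <- strsplit(rg, "-", fixed = TRUE)[[1]]
    drop <- drop | (heads >= parts[1] & heads <= substr(parts[2], 1, 3))
  }
  structure(events[!drop, , drop = FALSE], n_removed = sum(drop))
}

#' Read a code dictionary file
#'
#' TSV with header `code`, `parent`, `label`, `level`; UTF-8; en-dash
#' ranges permitted in block codes.
#'
#' @param path file path.
#' @return data.frame ready for [build_tree()].
#' @export
read_dictionary <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    fileEncoding = "UTF-8")
}

#' Bundled toy dictionaries
#'
#' Small ICD-10 and ATC dictionaries covering a handful of chapters/classes,
#' enough to exercise masking, exclusion, and scanning end to end. Real
#' analyses load the licensed national dictionaries with [read_dictionary()].
#'
#' @param system `"ICD10"` or `"ATC"`.
#' @return a `classification_tree`.
#' @export
toy_tree <- function(system = c("ICD10", "ATC")) {
  system <- match.arg(system)
  fn <- if (system == "ICD10") "toy_icd10.tsv" else "toy_atc.tsv"
  path <- system.file("extdata", fn, package = "utilscan", mustWork = TRUE)
  build_tree(read_dictionary(path), system)
}

#' Regular synthetic tree for scan power studies
#'
#' A balanced tree with `n_levels` internal levels below the root and
#' `n_leaves` terminal codes, used as the background hierarchy in power
#' simulations where the real dictionary is irrelevant.
#'
#' @param n_leaves total number of leaves (default 1000).
#' @param n_levels depth below root (default 3); branching is the
#'   `n_levels`-th root of `n_leaves`, so defaults give 10 x 10 x 10.
#' @return a `classification_tree` (system "ICD10" nominally).
#' @export
synthetic_tree <- function(n_leaves = 1000L, n_levels = 3L) {
  b <- round(n_leaves^(1 / n_levels))
  stopifnot(b >= 2, b <= 99)
  codes <- "T"; parents <- NA_character_; levels <- "root"
  prev <- "T"
  for (lv in seq_len(n_levels)) {
    cur <- paste0(rep(prev, each = b), sprintf("%02d", seq_len(b)))
    codes <- c(codes, cur)
    parents <- c(parents, rep(prev, each = b))
    levels <- c(levels, rep(paste0("level", lv), length(cur)))
    prev <- cur
  }
  build_tree(data.frame(code = codes, parent = parents,
                        label = codes, level = levels,
                        stringsAsFactors = FALSE), "ICD10")
}
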