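# Drug classification hierarchy and parent-category rollup.
#
# The evaluation convention of the whole package rests on this module: two
# different herbs (leaves) under the same first-category node are treated as
# clinically interchangeable, so prescriptions are compared after mapping
# every drug to its first-category ancestor.

ONTOLOGY_LEVELS <- c("leaf", "category2", "category1")

#' Construct and validate a drug ontology
#'
#' A drug ontology is a fixed three-level hierarchy: leaf drugs (individual
#' herbs or preparations), optional intermediate category-II prescriptions,
#' and first-category (category-I) medicines at the top. Every node has at
#' most one parent; first-category nodes have none. Drugs without any
#' classification (e.g. Western medicines lacking a TCM parent) are allowed
#' as parentless leaves and act as their own singleton category under
#' rollup.
#'
#' @param nodes A data.frame with columns `id`, `name`, `level`
#'   (one of `"leaf"`, `"category2"`, `"category1"`) and `parent_id`
#'   (`NA` or `""` for roots).
#' @return An object of class `drug_ontology` with elements `nodes`
#'   (the validated table), `n_category1` (number of first-category nodes,
#'   the label-space size) and internal ancestor lookup tables.
#' @export
#' @examples
#' nodes <- data.frame(
#'   id = c("c1", "c2", "herbA", "herbB"),
#'   name = c("clearing heat", "antiphlogistic", "herb A", "herb B"),
#'   level = c("category1", "category2", "leaf", "leaf"),
#'   parent_id = c(NA, "c1", "c2", "c2")
#' )
#' onto <- drug_ontology(nodes)
#' first_category(onto, c("herbA", "herbB"))
drug_ontology <- function(nodes) {
  required <- c("id", "name", "level", "parent_id")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes)))
    stopf("`nodes` must be a data.frame with columns %s",
          paste(required, collapse = ", "))
  nodes <- nodes[required]
  nodes$id <- as.character(nodes$id)
  nodes$name <- as.character(nodes$name)
  nodes$level <- as.character(nodes$level)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == ""] <- NA_character_

  if (anyDuplicated(nodes$id))
    stopf("duplicate node id(s): %s",
          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_level <- setdiff(unique(nodes$level), ONTOLOGY_LEVELS)
  if (length(bad_level))
    stopf("unknown level(s): %s", paste(bad_level, collapse = ", "))

  parent <- stats::setNames(nodes$parent_id, nodes$id)
  level <- stats::setNames(nodes$level, nodes$id)

  dangling <- setdiff(parent[!is.na(parent)], nodes$id)
  if (length(dangling))
    stopf("parent_id refers to missing node(s): %s",
          paste(dangling, collapse = ", "))
  if (any(level == "category1" & !is.na(parent)))
    stopf("category1 nodes must not have a parent")

  # Resolve every node to its root ancestor; a chain longer than the node
  # count means a cycle.
  root <- stats::setNames(nodes$id, nodes$id)
  for (step in seq_len(nrow(nodes) + 1L)) {
    up <- parent[root]
    live <- !is.na(up)
    if (!any(live)) break
    if (step > nrow(nodes)) stopf("cycle detected in parent_id chain")
    root[live] <- up[live]
  }

  # Category-II ancestor (for rollup at level "category2"): nearest ancestor
  # (or self) at level category2; nodes above/outside map to themselves.
  cat2 <- stats::setNames(nodes$id, nodes$id)
  is_leaf <- level == "leaf"
  p <- parent[nodes$id[is_leaf]]
  has_cat2 <- !is.na(p) & level[p] == "category2"
  cat2[nodes$id[is_leaf][has_cat2]] <- p[has_cat2]
  # leaves directly under a category1 node keep themselves at category2 level

  structure(
    list(nodes = nodes, parent = parent, level = level,
         cat1 = root, cat2 = cat2,
         n_category1 = sum(level == "category1")),
    class = "drug_ontology"
  )
}

#' @export
print.drug_ontology <- function(x, ...) {
  tab <- table(factor(x$level, levels = ONTOLOGY_LEVELS))
  cat("<drug_ontology> ", nrow(x$nodes), " nodes: ",
      tab[["leaf"]], " leaves, ", tab[["category2"]], " category-II, ",
      x$n_category1, " first-category\n", sep = "")
  invisible(x)
}

#' Read a drug ontology from CSV
#'
#' Expects a UTF-8 CSV with header `id,name,level,parent_id`; an empty
#' `parent_id` marks a root node.
#'
#' @param path Path to the CSV file.
#' @return A validated [drug_ontology] object.
#' @export
read_drug_ontology <- function(path) {
  nodes <- utils::read.csv(path, colClasses = "character",
                           na.strings = character(), encoding = "UTF-8")
  drug_ontology(nodes)
}

#' Write a drug ontology to CSV
#'
#' @param onto A [drug_ontology].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_drug_ontology <- function(onto, path) {
  stopifnot(inherits(onto, "drug_ontology"))
  nodes <- onto$nodes
  nodes$parent_id[is.na(nodes$parent_id)] <- ""
  utils::write.csv(nodes, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

check_known_ids <- function(onto, drug_ids) {
  unknown <- setdiff(drug_ids, names(onto$cat1))
  if (length(unknown))
    stopf("unknown drug id(s): %s", paste(unknown, collapse = ", "))
}

#' First-category ancestor of a drug
#'
#' Walks the parent chain to the top of the hierarchy. A first-category node
#' maps to itself, as does any parentless node (e.g. an unclassified Western
#' medicine, which forms its own singleton category).
#'
#' @param onto A [drug_ontology].
#' @param drug_ids Character vector of node ids.
#' @param level Rollup level: `"category1"` (default) maps to the top of the
#'   hierarchy; `"category2"` maps leaves to their category-II prescription
#'   (higher-level nodes map to themselves).
#' @return Character vector of ancestor ids, parallel to `drug_ids`.
#' @export
first_category <- function(onto, drug_ids, level = c("category1", "category2")) {
  stopifnot(inherits(onto, "drug_ontology"))
  level <- match.arg(level)
  drug_ids <- as.character(drug_ids)
  check_known_ids(onto, drug_ids)
  if (level == "category1") unname(onto$cat1[drug_ids]) else unname(onto$cat2[drug_ids])
}

#' Roll a prescription up to parent categories
#'
#' Maps every drug id in a prescription to its first-category ancestor and
#' collapses duplicates, yielding the category set on which true/false
#' positives are counted. Idempotent: re-rolling the result is a no-op.
#'
#' @inheritParams first_category
#' @param drug_ids Character vector (a prescription's drug-id set).
#' @return Sorted character vector of unique ancestor ids;
#'   `length(result) <= length(drug_ids)`.
#' @export
rollup <- function(onto, drug_ids, level = c("category1", "category2")) {
  if (length(drug_ids) == 0L) return(character())
  sort(unique(first_category(onto, drug_ids, level)))
}

#' First-category label space of an ontology
#'
#' The sorted ids onto which [rollup()] maps, i.e. the multilabel output
#' space of the classifier: all first-category nodes plus any parentless
#' lower-level nodes (singleton categories).
#'
#' @param onto A [drug_ontology].
#' @return Sorted character vector of category ids.
#' @export
category_ids <- function(onto) {
  stopifnot(inherits(onto, "drug_ontology"))
  sort(unique(unname(onto$cat1)))
}

#' Leaves belonging to each first category
#' @param onto A [drug_ontology].
#' @return Named list mapping category id to the character vector of leaf ids
#'   that roll up to it.
#' @export
category_leaves <- function(onto) {
  leaves <- onto$nodes$id[onto$level[onto$nodes$id] == "leaf"]
  split(leaves, unname(onto$cat1[leaves]))
}
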