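# Declarative, versioned category ruleset: loading, validation, and simple
# accessors. The ruleset is data (YAML), not code, so partner lists can be
# extended without touching the classifier.

#' Load a category ruleset
#'
#' @param path YAML ruleset; defaults to the packaged `categories_v1.yaml`.
#' @return a validated `paml_ruleset` object.
#' @export
read_ruleset <- function(path = system.file("extdata", "categories_v1.yaml",
                                            package = "pamlcat")) {
  rs <- yaml::read_yaml(path)
  validate_ruleset(rs)
  # resolve symbolic gene-set references
  for (i in seq_along(rs$categories)) {
    f <- rs$categories[[i]]$fusion
    if (!is.null(f) && identical(f$gene_set, "hox_cluster")) {
      rs$categories[[i]]$fusion$gene_set <- rs$hox_cluster_genes
    }
  }
  names(rs$categories) <- vapply(rs$categories, `[[`, "", "name")
  class(rs) <- "paml_ruleset"
  rs
}

# cached default; the packaged ruleset does not change within a session
.ruleset_cache <- new.env(parent = emptyenv())

#' Packaged default ruleset (23 molecular categories)
#' @return a `paml_ruleset`.
#' @export
default_ruleset <- function() {
  if (is.null(.ruleset_cache$default)) .ruleset_cache$default <- read_ruleset()
  .ruleset_cache$default
}

SUPERFAMILY_LEVELS <- c("HOXA", "HOXB", "CBF", "AMKL_AEL", "immature",
                        "CEBPA", "APL", "other")
RISK_LEVELS <- c("Low", "Intermediate", "High")

validate_ruleset <- function(rs) {
  stopifnot(is.list(rs$categories), length(rs$categories) > 0)
  nms <- vapply(rs$categories, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate category names in ruleset")
  tiers <- vapply(rs$categories, `[[`, 0, "tier")
  if (!all(tiers %in% 1:3)) stop("category tiers must be 1, 2 or 3")
  for (cat in rs$categories) {
    if (is.null(cat$fusion) && is.null(cat$fusion_pairs) &&
        is.null(cat$mutation) && is.null(cat$sv_gene)) {
      stop("category '", cat$name, "' has no trigger")
    }
    if (!cat$superfamily %in% SUPERFAMILY_LEVELS) {
      stop("category '", cat$name, "' has unknown superfamily")
    }
    if (!cat$risk_group %in% RISK_LEVELS) {
      stop("category '", cat$name, "' has unknown risk group")
    }
    if (cat$tier == 3 && is.null(cat$expression_consistency)) {
      stop("tier-3 category '", cat$name,
           "' must declare an expression_consistency gate")
    }
  }
  invisible(rs)
}

#' Category names defined by a ruleset
#' @param ruleset a `paml_ruleset`.
#' @return character vector in precedence (tier, then file) order.
#' @export
ruleset_categories <- function(ruleset = default_ruleset()) {
  tiers <- vapply(ruleset$categories, `[[`, 0, "tier")
  names(ruleset$categories)[order(tiers, seq_along(tiers))]
}

# every gene symbol a ruleset references (for symbol normalization)
ruleset_genes <- function(ruleset) {
  out <- ruleset$hox_cluster_genes
  for (cat in ruleset$categories) {
    out <- c(out, cat$fusion$gene, unlist(cat$fusion$gene_set),
             unlist(cat$fusion_pairs), cat$mutation$gene, cat$sv_gene)
  }
  out <- c(out, unlist(ruleset$rare_drivers$fusions),
           ruleset$rare_drivers$mutations)
  unique(out)
}

#' Fixed category-to-superfamily mapping
#'
#' @param category character vector of category names (or "Unclassified").
#' @param ruleset a `paml_ruleset`.
#' @return character vector of superfamilies; "Unclassified" maps to
#'   "other"; an unknown category is an error.
#' @export
assign_superfamily <- function(category, ruleset = default_ruleset()) {
  map <- vapply(ruleset$categories, `[[`, "", "superfamily")
  out <- ifelse(category == "Unclassified", "other", map[category])
  if (any(is.na(out))) {
    stop("unknown category: ",
         paste(unique(category[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Packaged category-to-risk-group mapping
#'
#' The shipped mapping reproduces the recursive-partitioning grouping of
#' categories into Low / Intermediate / High risk. Unclassified defaults to
#' Intermediate. Entries not fixed by the primary description are marked
#' provisional in the ruleset.
#'
#' @param category character vector of category names (or "Unclassified").
#' @param ruleset a `paml_ruleset`.
#' @return character vector of risk groups.
#' @export
map_risk_group <- function(category, ruleset = default_ruleset()) {
  map <- vapply(ruleset$categories, `[[`, "", "risk_group")
  out <- ifelse(category == "Unclassified", "Intermediate", map[category])
  if (any(is.na(out))) {
    stop("unknown category: ",
         paste(unique(category[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}
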