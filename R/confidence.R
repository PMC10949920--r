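# Additive-evidence confidence calculus: weak / strong / confirmed.
#
# Confidence for an RI is driven by its binding evidence; the function
# (expression) evidence acts only as a gate on the upgrade rules. Distinctness
# in rule antecedents is always counted over independence groups, never over
# raw codes: two group-4 codes (ChIP-seq + ChIP-exo) count once.

#' Confidence rule sets
#'
#' A `ruleset` is a data frame of upgrade rules evaluated against the
#' effective binding evidence of an RI. Columns:
#'
#' * `min_weak` — required count of distinct weak independence groups
#'   (counted over groups 4-7);
#' * `min_strong` — required count of distinct strong groups (groups 1-2);
#' * `requires_function` — whether the rule fires only when function
#'   (expression) evidence is present;
#' * `consequent` — `"strong"` or `"confirmed"`.
#'
#' Evaluation returns the maximum consequent among satisfied rules, floored
#' at the base level. Rules only upgrade, never demote.
#'
#' @name ruleset
NULL

#' Default upgrade rules
#'
#' The four canonical additive-evidence rules, all gated on the presence of
#' function evidence:
#'
#' 1. two distinct weak groups (4-7) upgrade to strong;
#' 2. two distinct strong groups (1 and 2) upgrade to confirmed;
#' 3. two distinct weak groups plus a strong group upgrade to confirmed;
#' 4. four distinct weak groups upgrade to confirmed.
#'
#' Group 3 (binding of cellular extracts) and group-less codes contribute to
#' the base level only and never to rule antecedents.
#'
#' @return A `ruleset` data frame.
#' @export
default_ruleset <- function() {
  rs <- data.frame(
    min_weak          = c(2L, 0L, 2L, 4L),
    min_strong        = c(0L, 2L, 1L, 0L),
    requires_function = TRUE,
    consequent        = c("strong", "confirmed", "confirmed", "confirmed"),
    stringsAsFactors  = FALSE
  )
  validate_ruleset(rs)
}

#' @rdname default_ruleset
#' @param rs a data frame with the ruleset columns.
#' @export
validate_ruleset <- function(rs) {
  need <- c("min_weak", "min_strong", "requires_function", "consequent")
  missing <- setdiff(need, names(rs))
  if (length(missing))
    stop("ruleset missing columns: ", paste(missing, collapse = ", "))
  if (!all(rs$consequent %in% c("strong", "confirmed")))
    stop("rule consequents must be 'strong' or 'confirmed' (rules only upgrade)")
  if (any(rs$min_weak < 0 | rs$min_strong < 0))
    stop("rule antecedent counts must be >= 0")
  if (any(rs$min_weak + rs$min_strong < 1))
    stop("a rule must require at least one evidence group")
  class(rs) <- c("ruleset", "data.frame")
  rs
}

#' Read a rule set from a JSON file
#'
#' Accepts either an array of rule objects or an object with a `rules`
#' array; each rule has fields `min_weak`, `min_strong`,
#' `requires_function`, `consequent`.
#'
#' @param path JSON file path.
#' @return A `ruleset`.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop("ruleset file not found: ", path)
  x <- jsonlite::fromJSON(path)
  if (!is.null(x$rules)) x <- x$rules
  validate_ruleset(as.data.frame(x))
}

level_rank <- function(level) match(level, CONF_LEVELS)

#' Base confidence level of a binding-evidence set
#'
#' Strong if any code belongs to group 1 or 2 (binding of purified protein,
#' site mutation); weak otherwise, including the empty set. Unknown codes are
#' ignored with a warning.
#'
#' @param binding_evidence character vector of evidence codes.
#' @param catalog an `evidence_catalog`.
#' @return `"weak"` or `"strong"`.
#' @export
#' @examples
#' base_level("EXP-SITE-MUTATION", default_catalog())
base_level <- function(binding_evidence, catalog) {
  codes <- resolve_codes(catalog, binding_evidence, "binding evidence")
  g <- catalog_lookup(catalog, codes, "group")
  if (any(!is.na(g) & g %in% 1:2)) "strong" else "weak"
}

# Distinct weak (4-7) and strong (1-2) groups among a resolved code set.
count_groups <- function(catalog, codes) {
  g <- catalog_lookup(catalog, codes, "group")
  g <- g[!is.na(g)]
  list(weak = length(unique(g[g %in% 4:7])),
       strong = length(unique(g[g %in% 1:2])))
}

has_function_evidence <- function(catalog, function_codes) {
  codes <- resolve_codes(catalog, function_codes, "function evidence")
  any(catalog_lookup(catalog, codes, "aspect") == "function")
}

#' Assign a confidence level to one evidence configuration
#'
#' Computes the effective evidence (given codes minus `excluded`), the base
#' level, and the maximum consequent among satisfied upgrade rules. Upgrades
#' fire only when function evidence survives the exclusion: the expression
#' gate applies to every rule in the default set.
#'
#' @param binding_evidence character vector of binding-evidence codes.
#' @param function_evidence character vector of function-evidence codes.
#' @param catalog an `evidence_catalog`.
#' @param ruleset a `ruleset`; default [default_ruleset()].
#' @param excluded codes to remove from both evidence sets before evaluation.
#' @return `"weak"`, `"strong"` or `"confirmed"`.
#' @export
#' @examples
#' cat <- default_catalog()
#' assign_confidence(c("HT-IDA-CHIP-SEQ", "HT-IDA-GSELEX"),
#'                   "EXP-GENE-EXPRESSION-ANALYSIS", cat)
assign_confidence <- function(binding_evidence, function_evidence, catalog,
                              ruleset = default_ruleset(),
                              excluded = character()) {
  b <- setdiff(resolve_codes(catalog, binding_evidence, "binding evidence"),
               excluded)
  f <- setdiff(function_evidence, excluded)
  gate <- has_function_evidence(catalog, f)
  counts <- count_groups(catalog, b)
  lvl <- base_level(b, catalog)
  ok <- ruleset$min_weak <= counts$weak &
        ruleset$min_strong <= counts$strong &
        (!ruleset$requires_function | gate)
  if (any(ok)) {
    best <- ruleset$consequent[ok][which.max(level_rank(ruleset$consequent[ok]))]
    if (level_rank(best) > level_rank(lvl)) lvl <- best
  }
  lvl
}

# Vectorized over an riset data frame (list-columns binding_evidence /
# function_evidence); returns a character vector of levels.
assign_confidence_all <- function(ris, catalog, ruleset = default_ruleset(),
                                  excluded = character()) {
  vapply(seq_len(nrow(ris)), function(i) {
    suppressWarnings(assign_confidence(ris$binding_evidence[[i]],
                                       ris$function_evidence[[i]],
                                       catalog, ruleset, excluded))
  }, character(1))
}

#' Resolve exclusion selectors to a concrete code set
#'
#' Selectors may name codes, whole categories (`classical`, `ht`,
#' `nonexperimental`) or independence groups (1..7). A selector matching
#' nothing produces a warning, not an error.
#'
#' @param catalog an `evidence_catalog`.
#' @param codes character vector of evidence codes.
#' @param categories character vector of categories.
#' @param groups integer vector of groups.
#' @return Character vector of catalog codes.
#' @export
resolve_exclusions <- function(catalog, codes = character(),
                               categories = character(), groups = integer()) {
  sel <- character()
  if (length(codes)) {
    miss <- setdiff(codes, catalog$code)
    if (length(miss))
      warning("exclusion selector matched no code: ",
              paste(miss, collapse = ", "), call. = FALSE)
    sel <- c(sel, intersect(codes, catalog$code))
  }
  if (length(categories)) {
    bad <- setdiff(categories, CATEGORIES)
    if (length(bad))
      warning("unknown category selector: ", paste(bad, collapse = ", "),
              call. = FALSE)
    sel <- c(sel, catalog$code[catalog$category %in% categories])
  }
  if (length(groups)) {
    groups <- as.integer(groups)
    hit <- catalog$code[!is.na(catalog$group) & catalog$group %in% groups]
    if (!length(hit))
      warning("group selector matched no code", call. = FALSE)
    sel <- c(sel, hit)
  }
  unique(sel)
}

#' Recompute confidence for an RI set under evidence exclusion
#'
#' The Confidence Level Calculator: removes the selected evidence codes from
#' every RI and recomputes confidence and category from scratch. A pure
#' function of its inputs; the per-level histogram before and after is
#' attached as attribute `"histogram"`.
#'
#' @param ris an `riset` (see [read_riset()]).
#' @param catalog an `evidence_catalog`.
#' @param ruleset a `ruleset`.
#' @param excluded_codes,excluded_categories,excluded_groups exclusion
#'   selectors, resolved via [resolve_exclusions()].
#' @return The `riset` with refreshed `confidence` and `category` columns.
#' @export
recompute_with_exclusions <- function(ris, catalog,
                                      ruleset = default_ruleset(),
                                      excluded_codes = character(),
                                      excluded_categories = character(),
                                      excluded_groups = integer()) {
  excluded <- resolve_exclusions(catalog, excluded_codes,
                                 excluded_categories, excluded_groups)
  before <- table(factor(ris$confidence, levels = CONF_LEVELS))
  ris$confidence <- assign_confidence_all(ris, catalog, ruleset, excluded)
  ris$category <- vapply(seq_len(nrow(ris)), function(i) {
    suppressWarnings(assign_category(ris$binding_evidence[[i]],
                                     ris$function_evidence[[i]],
                                     catalog, excluded))
  }, character(1))
  after <- table(factor(ris$confidence, levels = CONF_LEVELS))
  attr(ris, "histogram") <- list(before = before, after = after,
                                 excluded = excluded)
  ris
}
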