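# Architecture-of-knowledge summaries: evidence categories, cross-tabs by
# RI type x confidence x category, and evidence-combination (upset) counts.

RI_CATEGORIES <- c("classical", "ht", "classical_and_ht", "nonexperimental")

#' Evidence category of one RI
#'
#' Classifies the union of binding and function evidence: classical codes
#' only give `classical`, HT only `ht`, both `classical_and_ht`, and no
#' experimental code at all `nonexperimental`. Computational and other
#' nonexperimental codes never demote an experimental category — an RI with
#' both computational and classical evidence counts as classical.
#'
#' @param binding_evidence,function_evidence character vectors of codes.
#' @param catalog an `evidence_catalog`.
#' @param excluded codes removed before classification.
#' @return One of `classical`, `ht`, `classical_and_ht`, `nonexperimental`.
#' @export
#' @examples
#' assign_category(c("EXP-IDA-BINDING-OF-PURIFIED-PROTEINS", "COMP-ANALYSIS"),
#'                 character(), default_catalog())
assign_category <- function(binding_evidence, function_evidence = character(),
                            catalog = default_catalog(),
                            excluded = character()) {
  codes <- setdiff(union(binding_evidence, function_evidence), excluded)
  codes <- resolve_codes(catalog, codes, "evidence")
  cats <- unique(catalog_lookup(catalog, codes, "category"))
  has_classical <- "classical" %in% cats
  has_ht <- "ht" %in% cats
  if (has_classical && has_ht) "classical_and_ht"
  else if (has_classical) "classical"
  else if (has_ht) "ht"
  else "nonexperimental"
}

#' Summarize the architecture of an RI set
#'
#' Tabulates RIs by type, confidence level and evidence category, with
#' percentages relative to the total of the corresponding RI type (the
#' table convention of curated-database release notes), plus overall
#' level and category margins.
#'
#' @param ris an `riset`.
#' @return An `architecture_summary` list: `counts` (long data frame:
#'   ri_type, confidence, category, n, pct_of_type), `by_level`,
#'   `by_category`, `n_total`.
#' @export
summarize_architecture <- function(ris) {
  tab <- as.data.frame(table(
    ri_type = factor(ris$ri_type, levels = RI_TYPES),
    confidence = factor(ris$confidence, levels = CONF_LEVELS),
    category = factor(ris$category, levels = RI_CATEGORIES)),
    stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  type_totals <- table(factor(ris$ri_type, levels = RI_TYPES))
  denom <- as.numeric(type_totals[tab$ri_type])
  tab$pct_of_type <- ifelse(denom > 0, round(100 * tab$n / denom, 1), NA)
  by_level <- as.data.frame(table(
    confidence = factor(ris$confidence, levels = CONF_LEVELS)),
    stringsAsFactors = FALSE)
  names(by_level)[2] <- "n"
  by_level$pct <- if (nrow(ris)) round(100 * by_level$n / nrow(ris), 1) else 0
  by_category <- as.data.frame(table(
    category = factor(ris$category, levels = RI_CATEGORIES)),
    stringsAsFactors = FALSE)
  names(by_category)[2] <- "n"
  by_category$pct <- if (nrow(ris)) round(100 * by_category$n / nrow(ris), 1)
    else 0
  structure(list(counts = tab, by_level = by_level,
                 by_category = by_category, n_total = nrow(ris)),
            class = "architecture_summary")
}

#' Evidence-combination counts for upset plots
#'
#' Counts RIs at one confidence level by their exact binding-evidence code
#' set (frozen, sorted). Codes may first be collapsed to display groups via
#' `display_map` (code -> label), matching method-level plot legends.
#'
#' @param ris an `riset`.
#' @param level confidence level to restrict to, or `NULL` for all.
#' @param display_map optional named character vector mapping codes to
#'   display labels; unmapped codes keep their own code.
#' @return Data frame `combination` (labels joined with `"&"`), `n`,
#'   sorted by decreasing count; long plot-ready form in attribute
#'   `"long"` (combination id, member label).
#' @export
combination_counts <- function(ris, level = NULL, display_map = NULL) {
  if (!is.null(level)) {
    stopifnot(level %in% CONF_LEVELS)
    ris <- ris[ris$confidence == level, , drop = FALSE]
  }
  keys <- vapply(ris$binding_evidence, function(b) {
    if (!is.null(display_map)) {
      hit <- !is.na(display_map[b])
      b[hit] <- display_map[b[hit]]
    }
    paste(sort(unique(b)), collapse = "&")
  }, character(1))
  tab <- table(keys)
  out <- data.frame(combination = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  long <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    members <- strsplit(out$combination[i], "&", fixed = TRUE)[[1]]
    if (!length(members)) members <- ""
    data.frame(combination = out$combination[i], member = members,
               n = out$n[i], stringsAsFactors = FALSE)
  }))
  attr(out, "long") <- long
  out
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat("Architecture summary:", x$n_total, "RIs\n")
  bl <- x$by_level
  cat("  confidence:",
      paste(sprintf("%s %d (%.1f%%)", bl$confidence, bl$n, bl$pct),
            collapse = ", "), "\n")
  bc <- x$by_category
  cat("  category:  ",
      paste(sprintf("%s %d (%.1f%%)", bc$category, bc$n, bc$pct),
            collapse = ", "), "\n")
  invisible(x)
}
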