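# Evidence-type catalog: codes, categories, independence groups, base levels.

#' Evidence-type catalog
#'
#' An evidence catalog is a data frame with one row per evidence type and
#' class `evidence_catalog`. Columns:
#'
#' * `code` — short unique identifier (e.g. `"EXP-IDA-BINDING-OF-PURIFIED-PROTEINS"`).
#' * `name` — free-text description.
#' * `category` — `"classical"`, `"ht"` or `"nonexperimental"`.
#' * `group` — independence group, an integer in 1..7, or `NA` for codes
#'   excluded from the confidence algebra (author statements, curator
#'   inference, function-aspect codes).
#' * `base_level` — `"weak"` or `"strong"`.
#' * `aspect` — `"binding"` or `"function"`: whether the code documents TF
#'   binding at the site or the regulatory effect on expression.
#' * `assay_context` — `"in_vivo"`, `"in_vitro"` or `"na"`.
#'
#' Methods within one group share methodological bias and are never combined;
#' methods from different groups are independent and their combinations
#' upgrade confidence. Only groups 1 and 2 carry strong base confidence;
#' groups 4 to 7 are weak. Groups 1-3 are classical, 4-6 high-throughput,
#' 7 computational (nonexperimental).
#'
#' @name evidence_catalog
NULL

CATALOG_COLUMNS <- c("code", "name", "category", "group", "base_level",
                     "aspect", "assay_context")
CATEGORIES   <- c("classical", "ht", "nonexperimental")
BASE_LEVELS  <- c("weak", "strong")
ASPECTS      <- c("binding", "function")
CONF_LEVELS  <- c("weak", "strong", "confirmed")

#' Default evidence catalog
#'
#' Builds the built-in catalog of 12 evidence types covering all seven
#' independence groups, two function-aspect codes and one no-group code:
#'
#' * group 1 — binding of purified protein (EMSA, footprinting), strong;
#' * group 2 — site mutation, strong;
#' * group 3 — binding of cellular extracts, weak (indirect effects possible);
#' * group 4 — ChIP-chip, ChIP-seq, ChIP-exo (in vivo crosslinking), weak;
#' * group 5 — genomic SELEX, weak;
#' * group 6 — DAP-seq, weak;
#' * group 7 — computational analysis, weak;
#' * no group — gene expression analysis and RNA-seq (function aspect),
#'   author statement (never contributes to confidence).
#'
#' @return An `evidence_catalog` data frame.
#' @export
#' @examples
#' cat <- default_catalog()
#' subset(cat, group %in% 1:2)$code
default_catalog <- function() {
  rows <- list(
    list("EXP-IDA-BINDING-OF-PURIFIED-PROTEINS",
         "Binding of purified protein (EMSA, footprinting)",
         "classical", 1L, "strong", "binding", "in_vitro"),
    list("EXP-SITE-MUTATION",
         "Site mutation abolishing the regulatory effect",
         "classical", 2L, "strong", "binding", "in_vivo"),
    list("EXP-IDA-BINDING-OF-CELLULAR-EXTRACTS",
         "Binding of cellular extracts",
         "classical", 3L, "weak", "binding", "in_vitro"),
    list("HT-IDA-CHIP-CHIP", "ChIP-chip genome-wide binding",
         "ht", 4L, "weak", "binding", "in_vivo"),
    list("HT-IDA-CHIP-SEQ", "ChIP-seq genome-wide binding",
         "ht", 4L, "weak", "binding", "in_vivo"),
    list("HT-IDA-CHIP-EXO", "ChIP-exo genome-wide binding",
         "ht", 4L, "weak", "binding", "in_vivo"),
    list("HT-IDA-GSELEX", "Genomic SELEX screening",
         "ht", 5L, "weak", "binding", "in_vitro"),
    list("HT-IDA-DAP-SEQ", "DNA affinity purification sequencing",
         "ht", 6L, "weak", "binding", "in_vitro"),
    list("COMP-ANALYSIS", "Computational analysis (motif prediction)",
         "nonexperimental", 7L, "weak", "binding", "na"),
    list("EXP-GENE-EXPRESSION-ANALYSIS",
         "Gene expression analysis (reporter fusion, qPCR)",
         "classical", NA_integer_, "weak", "function", "in_vivo"),
    list("HT-RNA-SEQ", "RNA-seq differential expression",
         "ht", NA_integer_, "weak", "function", "in_vivo"),
    list("NONEXP-AUTHOR-STATEMENT", "Author statement without direct evidence",
         "nonexperimental", NA_integer_, "weak", "binding", "na")
  )
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    names(r) <- CATALOG_COLUMNS
    r
  })))
  for (col in CATALOG_COLUMNS) df[[col]] <- unlist(df[[col]])
  validate_catalog(df)
}

#' Validate an evidence catalog
#'
#' Checks column presence, code uniqueness, vocabulary, and the structural
#' invariants linking group to base level (groups 1-2 strong, 3-7 weak) and
#' group to category (1-3 classical, 4-6 ht, 7 nonexperimental).
#'
#' @param df data frame with the catalog columns.
#' @return The validated catalog, classed `evidence_catalog`.
#' @export
validate_catalog <- function(df) {
  missing <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing))
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  df <- df[, CATALOG_COLUMNS]
  df$group <- suppressWarnings(as.integer(df$group))
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup))
    stop("duplicate evidence code(s) in catalog: ", paste(dup, collapse = ", "))
  bad <- function(cond, what) {
    if (any(cond))
      stop("catalog invariant violated (", what, ") for code(s): ",
           paste(df$code[cond], collapse = ", "))
  }
  bad(!df$category %in% CATEGORIES, "category vocabulary")
  bad(!df$base_level %in% BASE_LEVELS, "base_level vocabulary")
  bad(!df$aspect %in% ASPECTS, "aspect vocabulary")
  bad(!is.na(df$group) & !(df$group %in% 1:7), "group must be 1..7 or empty")
  g <- df$group
  bad(!is.na(g) & g %in% 1:2 & df$base_level != "strong",
      "groups 1-2 must be strong")
  bad(!is.na(g) & g %in% 3:7 & df$base_level != "weak",
      "groups 3-7 must be weak")
  bad(!is.na(g) & g %in% 1:3 & df$category != "classical",
      "groups 1-3 must be classical")
  bad(!is.na(g) & g %in% 4:6 & df$category != "ht",
      "groups 4-6 must be ht")
  bad(!is.na(g) & g == 7 & df$category != "nonexperimental",
      "group 7 must be nonexperimental")
  rownames(df) <- NULL
  class(df) <- c("evidence_catalog", "data.frame")
  df
}

#' Read an evidence catalog from a TSV file
#'
#' The file must have a header row with the canonical columns (any order);
#' an empty `group` cell means the code has no independence group.
#'
#' @param path path to a tab-separated catalog file.
#' @return An `evidence_catalog`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("", "NA"), quote = "")
  validate_catalog(df)
}

#' Write an evidence catalog to a TSV file
#'
#' @param catalog an `evidence_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$group <- ifelse(is.na(df$group), "", as.character(df$group))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# --- catalog lookups used across modules ------------------------------------

catalog_lookup <- function(catalog, codes, column) {
  catalog[[column]][match(codes, catalog$code)]
}

#' Independence of two evidence codes
#'
#' Two codes are independent iff both carry an independence group and the
#' groups differ. The relation is symmetric and irreflexive; codes without a
#' group (author statements, function-aspect codes) are independent of
#' nothing.
#'
#' @param catalog an `evidence_catalog`.
#' @param code_a,code_b evidence codes present in the catalog.
#' @return Logical scalar.
#' @export
codes_independent <- function(catalog, code_a, code_b) {
  ga <- catalog_lookup(catalog, code_a, "group")
  gb <- catalog_lookup(catalog, code_b, "group")
  !is.na(ga) & !is.na(gb) & ga != gb
}

# Resolve a code set against a catalog, warning once about strangers.
resolve_codes <- function(catalog, codes, context = "evidence") {
  codes <- unique(codes[!is.na(codes) & nzchar(codes)])
  unknown <- setdiff(codes, catalog$code)
  if (length(unknown))
    warning("unknown ", context, " code(s) ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  intersect(codes, catalog$code)
}
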