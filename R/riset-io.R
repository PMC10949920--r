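# Reading and writing RI-set tables and HT peak tables.
#
# The RI-set dialect mirrors the downloadable curated TSVs: one row per
# regulatory interaction, evidence cells holding delimiter-separated code
# lists in fixed columns (binding and function evidence in columns 21 and 22
# by default). Coordinates are 1-based inclusive at every interface.

RI_TYPES <- c("tf_promoter", "tf_tu", "tf_gene")
EFFECTS  <- c("activation", "repression", "dual", "unknown")
METHODS  <- c("chip_seq", "chip_exo", "chip_chip", "gselex", "dap_seq")

#' RI-set table dialect
#'
#' Maps the semantic fields of a regulatory-interaction row to column
#' positions. The default is a 22-column layout with the binding and
#' function evidence-code lists in columns 21 and 22; columns not named in
#' the map pass through opaquely and round-trip unchanged.
#'
#' @param columns named integer vector: field name to 1-based column index.
#' @param n_columns total number of columns in the file.
#' @param evidence_sep delimiter inside evidence-code cells.
#' @return A `riset_dialect` list.
#' @export
riset_dialect <- function(columns = c(ri_id = 1L, ri_type = 2L, tf_name = 3L,
                                      target_id = 4L, effect = 5L,
                                      site_left = 6L, site_right = 7L,
                                      strand = 8L, genome_version = 9L,
                                      confidence = 10L, category = 11L,
                                      binding_evidence = 21L,
                                      function_evidence = 22L),
                          n_columns = 22L, evidence_sep = ",") {
  need <- c("ri_id", "ri_type", "tf_name", "target_id", "effect",
            "site_left", "site_right", "binding_evidence",
            "function_evidence")
  missing <- setdiff(need, names(columns))
  if (length(missing))
    stop("dialect must map fields: ", paste(missing, collapse = ", "))
  if (any(columns > n_columns))
    stop("dialect maps a column beyond n_columns")
  structure(list(columns = columns, n_columns = as.integer(n_columns),
                 evidence_sep = evidence_sep),
            class = "riset_dialect")
}

split_codes <- function(cells, sep) {
  lapply(cells, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    x <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
    x[nzchar(x)]
  })
}

join_codes <- function(sets, sep) {
  vapply(sets, function(x) paste(x, collapse = sep), character(1))
}

#' Construct an RI set in code
#'
#' Builds an `riset` data frame from vectors, deriving `confidence` and
#' `category` from the catalog. Evidence arguments are lists of character
#' vectors (or single code strings, recycled into one-element sets).
#'
#' @param ri_id,tf_name,target_id character vectors.
#' @param ri_type one of `tf_promoter`, `tf_tu`, `tf_gene`.
#' @param effect one of `activation`, `repression`, `dual`, `unknown`.
#' @param site_left,site_right 1-based inclusive coordinates, `NA` for RIs
#'   without a characterized site.
#' @param binding_evidence,function_evidence lists of code vectors.
#' @param strand `"forward"`, `"reverse"` or `"unknown"`.
#' @param genome_version genome tag, e.g. `"U00096.3"`.
#' @param catalog an `evidence_catalog`.
#' @param ruleset a `ruleset`.
#' @return An `riset` data frame.
#' @export
make_riset <- function(ri_id, tf_name, ri_type, target_id, effect,
                       site_left = NA_integer_, site_right = NA_integer_,
                       binding_evidence = list(character()),
                       function_evidence = list(character()),
                       strand = "unknown", genome_version = "U00096.3",
                       catalog = default_catalog(),
                       ruleset = default_ruleset()) {
  n <- length(ri_id)
  if (!is.list(binding_evidence)) binding_evidence <- as.list(binding_evidence)
  if (!is.list(function_evidence)) function_evidence <- as.list(function_evidence)
  ris <- data.frame(ri_id = ri_id, ri_type = rep_len(ri_type, n),
                    tf_name = tf_name, target_id = target_id,
                    effect = rep_len(effect, n),
                    site_left = as.integer(rep_len(site_left, n)),
                    site_right = as.integer(rep_len(site_right, n)),
                    strand = rep_len(strand, n),
                    genome_version = rep_len(genome_version, n),
                    stringsAsFactors = FALSE)
  ris$binding_evidence <- rep_len(binding_evidence, n)
  ris$function_evidence <- rep_len(function_evidence, n)
  validate_riset(ris)
  ris$confidence <- assign_confidence_all(ris, catalog, ruleset)
  ris$category <- vapply(seq_len(n), function(i) {
    suppressWarnings(assign_category(ris$binding_evidence[[i]],
                                     ris$function_evidence[[i]], catalog))
  }, character(1))
  class(ris) <- c("riset", "data.frame")
  ris
}

validate_riset <- function(ris) {
  bad_type <- setdiff(unique(ris$ri_type), RI_TYPES)
  if (length(bad_type))
    stop("unknown ri_type label(s): ", paste(bad_type, collapse = ", "),
         "; accepted: ", paste(RI_TYPES, collapse = ", "))
  bad_eff <- setdiff(unique(ris$effect), EFFECTS)
  if (length(bad_eff))
    stop("unknown effect label(s): ", paste(bad_eff, collapse = ", "),
         "; accepted: ", paste(EFFECTS, collapse = ", "))
  has_site <- !is.na(ris$site_left) | !is.na(ris$site_right)
  half <- has_site & (is.na(ris$site_left) | is.na(ris$site_right))
  if (any(half))
    stop("RI(s) with only one site coordinate: ",
         paste(ris$ri_id[half], collapse = ", "))
  bad_iv <- has_site & !half &
    (ris$site_left < 1L | ris$site_left > ris$site_right)
  if (any(bad_iv))
    stop("invalid site interval (need 1 <= left <= right) for RI(s): ",
         paste(ris$ri_id[bad_iv], collapse = ", "))
  key <- paste(ris$tf_name, ris$target_id, ris$ri_type, ris$effect, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (tf, target, ri_type, effect) tuple(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  invisible(ris)
}

#' Read an RI set from a TSV file
#'
#' Each data row yields one regulatory interaction. Empty site cells yield
#' an RI without a site; evidence cells are split on the dialect delimiter.
#' Evidence codes missing from the catalog are retained but flagged with a
#' warning (`strict = TRUE` turns parse warnings into errors). Malformed
#' rows are reported with their line number and collected in the
#' `"problems"` attribute; the parser never silently drops a row, so
#' `rows in = nrow(riset) + nrow(problems)`.
#'
#' @param path TSV file with a header row.
#' @param catalog an `evidence_catalog`, used to derive confidence/category.
#' @param dialect a [riset_dialect()].
#' @param ruleset a `ruleset`.
#' @param strict logical; promote row-level problems to errors.
#' @return An `riset` data frame with attributes `passthrough` (opaque
#'   columns), `header` (original column names) and `problems`.
#' @export
read_riset <- function(path, catalog = default_catalog(),
                       dialect = riset_dialect(),
                       ruleset = default_ruleset(), strict = FALSE) {
  if (!file.exists(path)) stop("RI-set file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           check.names = FALSE, na.strings = NULL)
  cols <- dialect$columns
  if (ncol(raw) < max(cols))
    stop("file has ", ncol(raw), " columns; dialect needs at least ",
         max(cols))
  get <- function(field) raw[[cols[[field]]]]
  n <- nrow(raw)
  problems <- list()
  note <- function(line, msg) problems[[length(problems) + 1L]] <<-
    data.frame(line = line, message = msg, stringsAsFactors = FALSE)

  int_or_na <- function(x) {
    x <- trimws(x)
    out <- suppressWarnings(as.integer(x))
    out[!nzchar(x)] <- NA_integer_
    attr(out, "bad") <- nzchar(x) & is.na(out)
    out
  }
  left <- int_or_na(get("site_left"))
  right <- int_or_na(get("site_right"))
  # data line i is file line i + 1 (header)
  bad <- attr(left, "bad") | attr(right, "bad") |
    (is.na(left) != is.na(right)) |
    (!is.na(left) & (left < 1L | left > right))
  for (i in which(bad)) note(i + 1L, "malformed site coordinate pair")
  bad_type <- !(get("ri_type") %in% RI_TYPES)
  for (i in which(bad_type & !bad))
    note(i + 1L, paste0("unknown ri_type '", get("ri_type")[i],
                        "'; accepted: ", paste(RI_TYPES, collapse = ", ")))
  drop <- bad | bad_type
  keep <- which(!drop)

  strand_col <- if ("strand" %in% names(cols)) get("strand") else
    rep("unknown", n)
  gv_col <- if ("genome_version" %in% names(cols)) get("genome_version") else
    rep("", n)
  eff <- get("effect")
  eff[!eff %in% EFFECTS] <- "unknown"

  ris <- data.frame(ri_id = get("ri_id")[keep],
                    ri_type = get("ri_type")[keep],
                    tf_name = get("tf_name")[keep],
                    target_id = get("target_id")[keep],
                    effect = eff[keep],
                    site_left = left[keep], site_right = right[keep],
                    strand = strand_col[keep],
                    genome_version = gv_col[keep],
                    stringsAsFactors = FALSE)
  ris$binding_evidence <- split_codes(get("binding_evidence")[keep],
                                      dialect$evidence_sep)
  ris$function_evidence <- split_codes(get("function_evidence")[keep],
                                       dialect$evidence_sep)

  all_codes <- unique(c(unlist(ris$binding_evidence),
                        unlist(ris$function_evidence)))
  unknown <- setdiff(all_codes, catalog$code)
  report <- function(msg) if (strict) stop(msg, call. = FALSE) else
    warning(msg, call. = FALSE)
  if (length(unknown))
    report(paste0("evidence code(s) not in catalog (retained, flagged): ",
                  paste(unknown, collapse = ", ")))
  probs <- if (length(problems)) do.call(rbind, problems) else
    data.frame(line = integer(), message = character())
  if (nrow(probs))
    report(paste0(nrow(probs), " row(s) dropped with errors; first: line ",
                  probs$line[1], ": ", probs$message[1]))

  # stored confidence/category cells (e.g. a calculator's output under
  # exclusions) are authoritative; empty or invalid cells are derived.
  derived_conf <- assign_confidence_all(ris, catalog, ruleset)
  derived_cat <- vapply(seq_len(nrow(ris)), function(i) {
    suppressWarnings(assign_category(ris$binding_evidence[[i]],
                                     ris$function_evidence[[i]], catalog))
  }, character(1))
  n_mismatch <- 0L
  if ("confidence" %in% names(cols)) {
    stored <- get("confidence")[keep]
    valid <- stored %in% CONF_LEVELS
    n_mismatch <- sum(valid & stored != derived_conf)
    ris$confidence <- ifelse(valid, stored, derived_conf)
  } else ris$confidence <- derived_conf
  if ("category" %in% names(cols)) {
    stored <- get("category")[keep]
    valid <- stored %in% RI_CATEGORIES
    ris$category <- ifelse(valid, stored, derived_cat)
  } else ris$category <- derived_cat
  class(ris) <- c("riset", "data.frame")
  attr(ris, "n_confidence_mismatch") <- n_mismatch
  attr(ris, "passthrough") <- raw[keep, setdiff(seq_len(ncol(raw)), cols),
                                  drop = FALSE]
  attr(ris, "header") <- names(raw)
  attr(ris, "dialect") <- dialect
  attr(ris, "problems") <- probs
  attr(ris, "unknown_codes") <- unknown
  ris
}

#' Write an RI set to a TSV file
#'
#' Reconstructs the dialect layout (evidence lists joined on the dialect
#' delimiter, passthrough columns restored in place) so that
#' `write_riset(read_riset(f))` reproduces `f` byte for byte on the
#' canonical dialect.
#'
#' @param ris an `riset`.
#' @param path output path.
#' @param dialect a [riset_dialect()]; defaults to the one the set was read
#'   with, if any.
#' @return `path`, invisibly.
#' @export
write_riset <- function(ris, path, dialect = NULL) {
  if (is.null(dialect)) dialect <- attr(ris, "dialect")
  if (is.null(dialect)) dialect <- riset_dialect()
  cols <- dialect$columns
  nc <- max(dialect$n_columns, max(cols))
  out <- matrix("", nrow = nrow(ris), ncol = nc)
  fmt_int <- function(x) ifelse(is.na(x), "", as.character(x))
  for (field in names(cols)) {
    out[, cols[[field]]] <- switch(field,
      site_left = fmt_int(ris$site_left),
      site_right = fmt_int(ris$site_right),
      binding_evidence = join_codes(ris$binding_evidence,
                                    dialect$evidence_sep),
      function_evidence = join_codes(ris$function_evidence,
                                     dialect$evidence_sep),
      as.character(ris[[field]]))
  }
  pass <- attr(ris, "passthrough")
  pass_idx <- setdiff(seq_len(nc), cols)
  if (!is.null(pass) && ncol(pass) == length(pass_idx) && nrow(ris))
    out[, pass_idx] <- as.matrix(pass)
  header <- attr(ris, "header")
  if (is.null(header) || length(header) != nc) {
    header <- rep("", nc)
    header[cols] <- names(cols)
    header[pass_idx] <- paste0("col", pass_idx)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(out))
    writeLines(apply(out, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# --- peak datasets ----------------------------------------------------------

#' Read an HT peak dataset from a BED-like TSV
#'
#' Columns (header required): `dataset_id`, `tf_name`, `method`, `left`,
#' `right`, `center`, `genome_version`, and optionally `no_cutoff`
#' (`TRUE` marks gSELEX-style datasets without an author-defined cutoff,
#' excluded from mapping). A peak needs either both ends or a center; rows
#' with neither, or with `left > right`, are row-level errors.
#'
#' @param path TSV path.
#' @param strict promote row problems to errors (default `TRUE`).
#' @return A `peakset` data frame; problems in attribute `"problems"`.
#' @export
read_peaks <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = c("", "NA"))
  need <- c("dataset_id", "tf_name", "method", "left", "right", "center",
            "genome_version")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("peak file missing column(s): ", paste(missing, collapse = ", "))
  pk <- data.frame(dataset_id = raw$dataset_id, tf_name = raw$tf_name,
                   method = raw$method,
                   left = suppressWarnings(as.integer(raw$left)),
                   right = suppressWarnings(as.integer(raw$right)),
                   center = suppressWarnings(as.integer(raw$center)),
                   genome_version = raw$genome_version,
                   no_cutoff = if ("no_cutoff" %in% names(raw))
                     toupper(raw$no_cutoff) %in% c("TRUE", "1", "YES") else
                     FALSE,
                   stringsAsFactors = FALSE)
  bad_method <- !pk$method %in% METHODS
  no_coord <- (is.na(pk$left) | is.na(pk$right)) & is.na(pk$center)
  inverted <- !is.na(pk$left) & !is.na(pk$right) & pk$left > pk$right
  drop <- bad_method | no_coord | inverted
  if (any(drop)) {
    msg <- paste0(sum(drop), " invalid peak row(s) at line(s) ",
                  paste(which(drop) + 1L, collapse = ", "),
                  " (need method in {", paste(METHODS, collapse = ", "),
                  "} and either left<=right or a center)")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out <- pk[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peakset", "data.frame")
  attr(out, "problems") <- data.frame(line = which(drop) + 1L)
  out
}

#' Write an HT peak dataset
#'
#' @param peaks a `peakset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- as.data.frame(peaks)
  df$no_cutoff <- ifelse(df$no_cutoff, "TRUE", "FALSE")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Extract and write a gold-standard RI subset
#'
#' Applies the Confidence Level Calculator with the given exclusions,
#' filters on minimum confidence (and optionally on having classical
#' binding evidence), writes the subset, and records the full filter
#' expression and the concrete excluded codes in a YAML provenance sidecar
#' (`<path>.provenance.yaml`) as an anti-circularity audit trail.
#'
#' @param ris an `riset`.
#' @param path output TSV path.
#' @param catalog an `evidence_catalog`.
#' @param ruleset a `ruleset`.
#' @param min_confidence keep RIs at or above this level (`"weak"` keeps
#'   all).
#' @param require_classical keep only RIs with at least one classical
#'   binding-evidence code.
#' @param excluded_codes,excluded_categories,excluded_groups exclusion
#'   selectors applied before filtering.
#' @return The written subset, invisibly.
#' @export
write_gold_standard <- function(ris, path, catalog = default_catalog(),
                                ruleset = default_ruleset(),
                                min_confidence = "strong",
                                require_classical = FALSE,
                                excluded_codes = character(),
                                excluded_categories = character(),
                                excluded_groups = integer()) {
  stopifnot(min_confidence %in% CONF_LEVELS)
  out <- recompute_with_exclusions(ris, catalog, ruleset, excluded_codes,
                                   excluded_categories, excluded_groups)
  excluded <- attr(out, "histogram")$excluded
  keep <- level_rank(out$confidence) >= level_rank(min_confidence)
  if (require_classical) {
    classical <- catalog$code[catalog$category == "classical" &
                                catalog$aspect == "binding"]
    keep <- keep & vapply(out$binding_evidence, function(b)
      length(intersect(setdiff(b, excluded), classical)) > 0, logical(1))
  }
  subset_ris <- out[keep, , drop = FALSE]
  pass <- attr(ris, "passthrough")
  if (!is.null(pass)) attr(subset_ris, "passthrough") <- pass[keep, ,
                                                              drop = FALSE]
  attr(subset_ris, "header") <- attr(ris, "header")
  attr(subset_ris, "dialect") <- attr(ris, "dialect")
  class(subset_ris) <- c("riset", "data.frame")
  write_riset(subset_ris, path)
  sidecar <- paste0(path, ".provenance.yaml")
  lines <- c(
    "gold_standard:",
    paste0("  written: ", nrow(subset_ris)),
    paste0("  source_rows: ", nrow(ris)),
    paste0("  min_confidence: ", min_confidence),
    paste0("  require_classical: ", tolower(require_classical)),
    if (length(excluded)) c("  excluded_codes:", paste0("    - ", excluded))
    else "  excluded_codes: []"
  )
  writeLines(lines, sidecar)
  invisible(subset_ris)
}
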