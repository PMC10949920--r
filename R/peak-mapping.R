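# Peak normalization, genome-version liftover, and site-in-peak mapping.
#
# Matching is by containment: an RI site matches a peak of the same TF when
# both site coordinates lie within the peak region. Strand is ignored —
# peaks are unstranded regions. Matched RIs gain the binding-evidence code
# of the peak's method (set semantics, once per method), after which
# confidence is recomputed.

METHOD_CODE <- c(chip_seq = "HT-IDA-CHIP-SEQ", chip_exo = "HT-IDA-CHIP-EXO",
                 chip_chip = "HT-IDA-CHIP-CHIP", gselex = "HT-IDA-GSELEX",
                 dap_seq = "HT-IDA-DAP-SEQ")

#' Peak normalization policy
#'
#' Controls how reported peaks become intervals for mapping:
#'
#' * `as_reported` — keep author-reported start/end when both are present;
#'   center-only peaks get a fixed-width window around the center.
#' * `uniform_200` — every peak becomes a uniform window around its center
#'   (the midpoint `floor((left+right)/2)` when ends are present).
#'
#' A center `c` expands to `[c - half, c + half - 1]`, so the default
#' `uniform_width = 200` yields exactly 200 nt ("100 bp on each side" read
#' as a 200-nt window; set `uniform_width = 201` for the inclusive-both-
#' sides alternative).
#'
#' @param mode `"as_reported"` or `"uniform_200"`.
#' @param uniform_width window width in nt for center-derived peaks.
#' @return A `peak_policy` list.
#' @export
peak_policy <- function(mode = c("as_reported", "uniform_200"),
                        uniform_width = 200L) {
  mode <- match.arg(mode)
  uniform_width <- as.integer(uniform_width)
  if (uniform_width <= 0) stop("uniform_width must be positive")
  structure(list(mode = mode, uniform_width = uniform_width,
                 center_halfwidth = uniform_width %/% 2L),
            class = "peak_policy")
}

#' Normalize peaks to mapping intervals
#'
#' Vectorized over a `peakset`; returns the peak table with `norm_left` and
#' `norm_right` columns. Windows running off the left end of the genome are
#' clamped to 1 with a warning.
#'
#' @param peaks a `peakset` (or data frame with `left`, `right`, `center`).
#' @param policy a [peak_policy()].
#' @return The input with `norm_left` / `norm_right` added.
#' @export
#' @examples
#' pk <- data.frame(left = NA, right = NA, center = 1000)
#' normalize_peaks(pk, peak_policy("as_reported"))[, c("norm_left", "norm_right")]
normalize_peaks <- function(peaks, policy = peak_policy()) {
  half <- policy$center_halfwidth
  up <- policy$uniform_width - half - 1L  # [c-half, c+up] has uniform_width nt
  has_ends <- !is.na(peaks$left) & !is.na(peaks$right)
  center <- ifelse(has_ends, (peaks$left + peaks$right) %/% 2L, peaks$center)
  if (policy$mode == "as_reported") {
    nl <- ifelse(has_ends, peaks$left, peaks$center - half)
    nr <- ifelse(has_ends, peaks$right, peaks$center + up)
  } else {
    nl <- center - half
    nr <- center + up
  }
  if (any(nl < 1L, na.rm = TRUE)) {
    warning("normalized peak(s) clamped to coordinate 1", call. = FALSE)
    nl <- pmax(nl, 1L)
  }
  peaks$norm_left <- as.integer(nl)
  peaks$norm_right <- as.integer(nr)
  peaks
}

#' Lift coordinates between genome versions with an offset table
#'
#' The offset table is a sorted data frame of `(threshold, shift)` pairs:
#' every coordinate `c` becomes `c + shift` of the last threshold `<= c`
#' (shift 0 below the first threshold). Intervals whose two ends fall in
#' different offset segments are flagged for manual review in the
#' `needs_review` column instead of being silently shifted apart.
#'
#' @param intervals data frame with `left` and `right` columns (1-based
#'   inclusive); `NA` coordinates pass through.
#' @param offsets data frame with `threshold` and `shift` columns; zero rows
#'   mean identity.
#' @param to_version new genome-version tag to stamp, or `NULL` to keep.
#' @return The input with shifted coordinates, a `needs_review` logical
#'   column, and `genome_version` updated when requested.
#' @export
lift_intervals <- function(intervals, offsets, to_version = NULL) {
  if (nrow(offsets) == 0) {
    intervals$needs_review <- FALSE
    if (!is.null(to_version) && "genome_version" %in% names(intervals))
      intervals$genome_version <- to_version
    return(intervals)
  }
  if (is.unsorted(offsets$threshold, strictly = TRUE))
    stop("offset table thresholds must be strictly increasing")
  seg <- function(c) findInterval(c, offsets$threshold)
  shift_of <- function(c) {
    i <- seg(c)
    out <- ifelse(i == 0, 0L, offsets$shift[pmax(i, 1L)])
    ifelse(is.na(c), NA_integer_, as.integer(out))
  }
  spans <- !is.na(intervals$left) & !is.na(intervals$right) &
    seg(intervals$left) != seg(intervals$right)
  if (any(spans))
    warning(sum(spans), " interval(s) span an offset breakpoint; ",
            "flagged for manual review", call. = FALSE)
  intervals$left <- intervals$left + shift_of(intervals$left)
  intervals$right <- intervals$right + shift_of(intervals$right)
  intervals$needs_review <- spans
  if (!is.null(to_version) && "genome_version" %in% names(intervals))
    intervals$genome_version <- to_version
  intervals
}

# Containment query: for each site, which normalized peaks of the same TF
# fully contain it. Returns a data.frame (site_idx, peak_idx). TF names are
# compared case-insensitively.
contained_hits <- function(site_left, site_right, site_tf,
                           peak_left, peak_right, peak_tf) {
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = site_left, end = site_right),
    IRanges::IRanges(start = peak_left, end = peak_right),
    type = "within")
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  same_tf <- tolower(site_tf[q]) == tolower(peak_tf[s])
  data.frame(site_idx = q[same_tf], peak_idx = s[same_tf])
}

#' Map an RI set onto HT peak datasets and enrich the evidence
#'
#' For every RI with a site, finds all same-TF peaks (after normalization
#' under `policy`) that fully contain the site, adds the matched methods'
#' HT binding-evidence codes to the RI (once per method, regardless of how
#' many peaks match), and recomputes confidence and category. gSELEX-style
#' datasets flagged `no_cutoff` are excluded from mapping. RIs without a
#' site are skipped and counted.
#'
#' @param ris an `riset`.
#' @param peaks a `peakset` (multiple datasets may share the table).
#' @param policy a [peak_policy()].
#' @param catalog an `evidence_catalog`.
#' @param ruleset a `ruleset`.
#' @return The enriched `riset`; match records (one row per RI-peak match:
#'   `ri_id`, `dataset_id`, `method`, interval used, policy) in attribute
#'   `"matches"`, skip count in `"n_skipped_no_site"`.
#' @export
map_riset <- function(ris, peaks, policy = peak_policy(),
                      catalog = default_catalog(),
                      ruleset = default_ruleset()) {
  usable <- peaks[!peaks$no_cutoff, , drop = FALSE]
  rv <- unique(ris$genome_version)
  pv <- unique(usable$genome_version)
  if (length(rv) && length(pv) && !all(pv %in% rv))
    stop("genome-version mismatch between RI set (",
         paste(rv, collapse = ","), ") and peaks (",
         paste(pv, collapse = ","), "); lift coordinates first")
  usable <- normalize_peaks(usable, policy)
  has_site <- !is.na(ris$site_left) & !is.na(ris$site_right)
  site_idx <- which(has_site)
  matches <- data.frame(ri_id = character(), dataset_id = character(),
                        method = character(), peak_left = integer(),
                        peak_right = integer(), policy = character())
  if (length(site_idx) && nrow(usable)) {
    hits <- contained_hits(ris$site_left[site_idx], ris$site_right[site_idx],
                           ris$tf_name[site_idx],
                           usable$norm_left, usable$norm_right,
                           usable$tf_name)
    if (nrow(hits)) {
      ri_row <- site_idx[hits$site_idx]
      matches <- data.frame(
        ri_id = ris$ri_id[ri_row],
        dataset_id = usable$dataset_id[hits$peak_idx],
        method = usable$method[hits$peak_idx],
        peak_left = usable$norm_left[hits$peak_idx],
        peak_right = usable$norm_right[hits$peak_idx],
        policy = policy$mode, stringsAsFactors = FALSE)
      add <- split(METHOD_CODE[matches$method], ri_row)
      for (row_chr in names(add)) {
        i <- as.integer(row_chr)
        ris$binding_evidence[[i]] <-
          union(ris$binding_evidence[[i]], unname(unique(add[[row_chr]])))
      }
    }
  }
  ris$confidence <- assign_confidence_all(ris, catalog, ruleset)
  ris$category <- vapply(seq_len(nrow(ris)), function(i) {
    suppressWarnings(assign_category(ris$binding_evidence[[i]],
                                     ris$function_evidence[[i]], catalog))
  }, character(1))
  attr(ris, "matches") <- matches
  attr(ris, "n_skipped_no_site") <- sum(!has_site)
  ris
}

#' Average peak size of a dataset
#'
#' Width is `right - left + 1`; center-only peaks carry no author-reported
#' width and are excluded. All-center-only datasets yield `NA` with
#' `n = 0`.
#'
#' @param peaks a `peakset`.
#' @return A list with `mean`, `sd` (sample sd) and `n` (peaks with ends).
#' @export
average_peak_size <- function(peaks) {
  w <- peaks$right - peaks$left + 1L
  w <- w[!is.na(w)]
  list(mean = if (length(w)) mean(w) else NA_real_,
       sd = if (length(w) > 1) stats::sd(w) else NA_real_,
       n = length(w))
}
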