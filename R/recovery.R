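# Recovery benchmarking: how well each HT method recovers classically
# supported regulatory sites, with nonparametric method comparison.

#' Filter an RI set to classically supported sites
#'
#' Keeps RIs carrying at least one classical binding-evidence code and a
#' characterized site. This is the "classical RI set" used as the
#' benchmark denominator.
#'
#' @param ris an `riset`.
#' @param catalog an `evidence_catalog`.
#' @return The filtered `riset`.
#' @export
filter_classical <- function(ris, catalog = default_catalog()) {
  classical <- catalog$code[catalog$category == "classical" &
                              catalog$aspect == "binding"]
  keep <- vapply(ris$binding_evidence, function(b)
    length(intersect(b, classical)) > 0, logical(1)) &
    !is.na(ris$site_left) & !is.na(ris$site_right)
  out <- ris[keep, , drop = FALSE]
  class(out) <- c("riset", "data.frame")
  out
}

#' Filter to classical RIs confirmed without HT evidence
#'
#' Recomputes confidence with the whole HT category excluded, then keeps
#' RIs that are still confirmed, have classical binding evidence and a
#' site. This is the stricter anti-circularity benchmark set.
#'
#' @param ris an `riset`.
#' @param catalog an `evidence_catalog`.
#' @param ruleset a `ruleset`.
#' @return The filtered `riset` (confidence reflects the HT exclusion).
#' @export
filter_classical_confirmed <- function(ris, catalog = default_catalog(),
                                       ruleset = default_ruleset()) {
  re <- recompute_with_exclusions(ris, catalog, ruleset,
                                  excluded_categories = "ht")
  out <- filter_classical(re[re$confidence == "confirmed", , drop = FALSE],
                          catalog)
  class(out) <- c("riset", "data.frame")
  out
}

# Distinct classical sites per TF: RIs sharing one coordinate pair count
# once ("site" granularity, not RI granularity).
distinct_sites <- function(ris) {
  key <- paste(tolower(ris$tf_name), ris$site_left, ris$site_right,
               sep = "\r")
  idx <- !duplicated(key)
  data.frame(tf_name = ris$tf_name[idx], site_left = ris$site_left[idx],
             site_right = ris$site_right[idx], stringsAsFactors = FALSE)
}

#' Benchmark HT methods on recovery of a site set
#'
#' For each method and each eligible TF (a TF with at least one site in
#' `ris_subset` and at least one usable peak dataset of the method), the
#' per-TF recovery is the percentage of the TF's distinct sites fully
#' contained in at least one same-TF normalized peak of the method. The
#' per-method summary reports the unweighted mean and sample sd over TFs
#' and the count-weighted pooled percentage. Methods with zero eligible TFs
#' are absent from the report, not zero.
#'
#' @param ris_subset an `riset`, typically from [filter_classical()].
#' @param peaks a `peakset` covering one or more methods.
#' @param policy a [peak_policy()].
#' @return A `recovery_report` list with elements `per_tf` (method,
#'   tf_name, n_sites, n_recovered, fraction), `per_method` (method, n_tfs,
#'   mean, sd, pooled, n_sites, n_recovered) and `policy`.
#' @export
recovery <- function(ris_subset, peaks, policy = peak_policy()) {
  usable <- normalize_peaks(peaks[!peaks$no_cutoff, , drop = FALSE], policy)
  sites <- distinct_sites(ris_subset)
  per_tf <- list()
  for (m in intersect(METHODS, unique(usable$method))) {
    pk <- usable[usable$method == m, , drop = FALSE]
    eligible <- intersect(unique(tolower(sites$tf_name)),
                          unique(tolower(pk$tf_name)))
    if (!length(eligible)) next
    s <- sites[tolower(sites$tf_name) %in% eligible, , drop = FALSE]
    hits <- contained_hits(s$site_left, s$site_right, s$tf_name,
                           pk$norm_left, pk$norm_right, pk$tf_name)
    recovered <- seq_len(nrow(s)) %in% hits$site_idx
    agg <- tapply(recovered, tolower(s$tf_name), function(x)
      c(n = length(x), rec = sum(x)))
    per_tf[[m]] <- data.frame(
      method = m, tf_name = names(agg),
      n_sites = vapply(agg, `[[`, numeric(1), "n"),
      n_recovered = vapply(agg, `[[`, numeric(1), "rec"),
      stringsAsFactors = FALSE)
  }
  per_tf <- if (length(per_tf)) do.call(rbind, per_tf) else
    data.frame(method = character(), tf_name = character(),
               n_sites = numeric(), n_recovered = numeric())
  rownames(per_tf) <- NULL
  per_tf$fraction <- 100 * per_tf$n_recovered / per_tf$n_sites
  if (!nrow(per_tf)) {
    per_method <- data.frame(method = character(), n_tfs = integer(),
                             mean = numeric(), sd = numeric(),
                             pooled = numeric(), n_sites = numeric(),
                             n_recovered = numeric())
    return(structure(list(per_tf = per_tf, per_method = per_method,
                          policy = policy$mode), class = "recovery_report"))
  }
  per_method <- do.call(rbind, lapply(split(per_tf, per_tf$method),
                                      function(d) data.frame(
    method = d$method[1], n_tfs = nrow(d), mean = mean(d$fraction),
    sd = if (nrow(d) > 1) stats::sd(d$fraction) else NA_real_,
    pooled = 100 * sum(d$n_recovered) / sum(d$n_sites),
    n_sites = sum(d$n_sites), n_recovered = sum(d$n_recovered),
    stringsAsFactors = FALSE)))
  rownames(per_method) <- NULL
  structure(list(per_tf = per_tf, per_method = per_method,
                 policy = policy$mode),
            class = "recovery_report")
}

#' Compare HT methods' recovery distributions
#'
#' Kruskal-Wallis test (mid-rank ties, tie-corrected statistic) on the
#' per-TF recovery fractions grouped by method, followed by pairwise
#' two-sided Mann-Whitney U tests with Bonferroni correction over the
#' number of pairs. Stars mark adjusted p < 0.05.
#'
#' @param report a `recovery_report`.
#' @return A list with `kruskal` (`statistic`, `df`, `p_value`) and
#'   `pairwise` (data frame: method_a, method_b, statistic, p_raw,
#'   p_adjusted, significant).
#' @export
compare_methods <- function(report) {
  d <- report$per_tf
  methods <- unique(d$method)
  if (length(methods) < 2)
    stop("need at least two methods to compare")
  kw <- stats::kruskal.test(d$fraction, factor(d$method))
  pairs <- utils::combn(methods, 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    a <- d$fraction[d$method == pairs[1, i]]
    b <- d$fraction[d$method == pairs[2, i]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    data.frame(method_a = pairs[1, i], method_b = pairs[2, i],
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- pmin(1, pw$p_raw * n_pairs)
  pw$significant <- pw$p_adjusted < 0.05
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = pw)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report (policy:", x$policy, ")\n")
  pm <- x$per_method
  for (i in seq_len(nrow(pm)))
    cat(sprintf("  %-9s %2d TFs  mean %5.1f%% +/- %4.1f  pooled %5.1f%% (%d/%d sites)\n",
                pm$method[i], pm$n_tfs[i], pm$mean[i],
                ifelse(is.na(pm$sd[i]), 0, pm$sd[i]), pm$pooled[i],
                pm$n_recovered[i], pm$n_sites[i]))
  invisible(x)
}
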