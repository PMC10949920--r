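# Synthetic corpus generator with planted ground truth.
#
# Emulates a curated RI set, an evidence catalog and HT peak collections:
# each regulatory site is covered by a peak of each method with a planted
# per-method probability, so recovery benchmarks have a known answer. It
# does not simulate reads, peak-caller noise or motif content.

#' Synthetic corpus configuration
#'
#' Defaults describe a desk-scale believable world: a 4.64-Mb bacterial
#' genome, 50 TFs with 20 sites each, site widths 16-30 nt (typical TF-box
#' sizes), per-method peak widths near the published collection averages
#' (ChIP-seq ~582 nt, DAP-seq ~55 nt, ChIP-exo ~34 nt, gSELEX center-only)
#' and planted per-method recovery probabilities 0.8 / 0.65 / 0.5 / 0.3
#' for ChIP-seq / gSELEX / DAP-seq / ChIP-exo.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical corpora.
#' @param genome_length genome size in bp.
#' @param n_tfs number of TFs.
#' @param sites_per_tf fixed count, or `list(kind = "power_law", max = n,
#'   exponent = g)` for heavy-tailed regulon sizes.
#' @param site_width integer range `c(min, max)` of site widths.
#' @param evidence_mix named list of combinations; each element is
#'   `list(binding = codes, func = codes, prob = p)`, probabilities
#'   summing to 1.
#' @param recovery_prob named numeric: planted probability that a site is
#'   covered by a peak of each method.
#' @param peak_width named list of `c(mean, sd)` per method (ignored for
#'   center-only methods).
#' @param center_only_fraction named numeric in `[0, 1]` per method.
#' @param decoys_per_tf number of extra non-planted peaks per TF and
#'   method.
#' @return A `corpus_config` list.
#' @export
corpus_config <- function(seed = 20260911L,
                          genome_length = 4641652L,
                          n_tfs = 50L,
                          sites_per_tf = 20L,
                          site_width = c(16L, 30L),
                          evidence_mix = default_evidence_mix(),
                          recovery_prob = c(chip_seq = 0.8, gselex = 0.65,
                                            dap_seq = 0.5, chip_exo = 0.3),
                          peak_width = list(chip_seq = c(582, 608),
                                            chip_exo = c(34, 14),
                                            dap_seq = c(55, 4.6),
                                            gselex = c(200, 0)),
                          center_only_fraction = c(chip_seq = 0, chip_exo = 0,
                                                   dap_seq = 0, gselex = 1),
                          decoys_per_tf = 2L) {
  probs <- vapply(evidence_mix, `[[`, numeric(1), "prob")
  if (abs(sum(probs) - 1) > 1e-8)
    stop("evidence_mix probabilities must sum to 1 (got ", sum(probs), ")")
  if (any(recovery_prob < 0 | recovery_prob > 1))
    stop("recovery_prob must be in [0, 1]")
  if (genome_length < 10L * max(site_width))
    stop("genome too short for site placement")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_tfs = n_tfs, sites_per_tf = sites_per_tf,
                 site_width = site_width, evidence_mix = evidence_mix,
                 recovery_prob = recovery_prob, peak_width = peak_width,
                 center_only_fraction = center_only_fraction,
                 decoys_per_tf = decoys_per_tf),
            class = "corpus_config")
}

#' Default evidence mixture
#'
#' A mixture over binding/function code sets shaped like a mature curated
#' collection: classical-confirmed, classical-strong, classical-weak,
#' HT-only, HT-plus-computational, computational-only and mixed
#' classical-and-HT strata.
#'
#' @return Named list usable as `evidence_mix` in [corpus_config()].
#' @export
default_evidence_mix <- function() {
  mix <- list(
    classical_confirmed = list(
      binding = c("EXP-IDA-BINDING-OF-PURIFIED-PROTEINS",
                  "EXP-SITE-MUTATION", "COMP-ANALYSIS"),
      func = "EXP-GENE-EXPRESSION-ANALYSIS", prob = 0.18),
    classical_strong = list(
      binding = c("EXP-IDA-BINDING-OF-PURIFIED-PROTEINS", "COMP-ANALYSIS"),
      func = "EXP-GENE-EXPRESSION-ANALYSIS", prob = 0.22),
    classical_weak = list(
      binding = "EXP-IDA-BINDING-OF-CELLULAR-EXTRACTS",
      func = character(), prob = 0.08),
    classical_and_ht = list(
      binding = c("EXP-IDA-BINDING-OF-PURIFIED-PROTEINS", "HT-IDA-GSELEX",
                  "COMP-ANALYSIS"),
      func = "EXP-GENE-EXPRESSION-ANALYSIS", prob = 0.12),
    ht_strong = list(
      binding = c("HT-IDA-CHIP-SEQ", "COMP-ANALYSIS"),
      func = c("EXP-GENE-EXPRESSION-ANALYSIS", "HT-RNA-SEQ"), prob = 0.15),
    ht_weak = list(
      binding = "HT-IDA-CHIP-SEQ", func = "HT-RNA-SEQ", prob = 0.12),
    nonexperimental = list(
      binding = "COMP-ANALYSIS", func = "EXP-GENE-EXPRESSION-ANALYSIS",
      prob = 0.13)
  )
  mix
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

sample_sites_per_tf <- function(cfg) {
  s <- cfg$sites_per_tf
  if (is.list(s)) {
    stopifnot(identical(s$kind, "power_law"))
    k <- seq_len(s$max)
    sample(k, cfg$n_tfs, replace = TRUE, prob = k^(-s$exponent))
  } else rep(as.integer(s), cfg$n_tfs)
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Produces an RI set, the default catalog, a peak table and a truth table
#' recording, for every (site, method), whether a covering peak was
#' planted. Planted peaks fully contain their site (center-only methods
#' place the center so the default 200-nt window contains it); decoy peaks
#' land uniformly elsewhere.
#'
#' @param config a [corpus_config()].
#' @return A list: `riset`, `catalog`, `peaks` (a `peakset`), `truth`
#'   (tf_name, site_left, site_right, method, covered) and `config`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  cfg <- config
  catalog <- default_catalog()
  methods <- names(cfg$recovery_prob)
  with_seed(cfg$seed, {
    n_sites <- sample_sites_per_tf(cfg)
    tf_names <- sprintf("TF%03d", seq_len(cfg$n_tfs))
    total <- sum(n_sites)
    tf <- rep(tf_names, n_sites)
    width <- sample(cfg$site_width[1]:cfg$site_width[2], total,
                    replace = TRUE)
    left <- sample.int(cfg$genome_length - max(width) - 1L, total)
    right <- left + width - 1L
    combo <- sample(names(cfg$evidence_mix), total, replace = TRUE,
                    prob = vapply(cfg$evidence_mix, `[[`, numeric(1),
                                  "prob"))
    ri_type <- sample(RI_TYPES, total, replace = TRUE,
                      prob = c(0.72, 0.05, 0.23))
    effect <- sample(c("activation", "repression"), total, replace = TRUE)
    ris <- make_riset(
      ri_id = sprintf("RI%05d", seq_len(total)),
      tf_name = tf, ri_type = ri_type,
      target_id = sprintf("tgt%05d", seq_len(total)),
      effect = effect, site_left = left, site_right = right,
      binding_evidence = lapply(combo, function(k)
        cfg$evidence_mix[[k]]$binding),
      function_evidence = lapply(combo, function(k)
        cfg$evidence_mix[[k]]$func),
      catalog = catalog)

    peak_rows <- list()
    truth_rows <- list()
    half <- 100L
    for (m in methods) {
      p <- cfg$recovery_prob[[m]]
      wpar <- cfg$peak_width[[m]]
      cfrac <- cfg$center_only_fraction[[m]]
      covered <- stats::runif(total) < p
      for (i in which(covered)) {
        center_only <- stats::runif(1) < cfrac
        if (center_only) {
          # feasible centers whose [c-100, c+99] window contains the site
          lo <- right[i] - (half - 1L)
          hi <- left[i] + half
          c0 <- if (hi >= lo) sample(lo:hi, 1L) else (left[i] + right[i]) %/% 2L
          peak_rows[[length(peak_rows) + 1L]] <-
            list(m, tf[i], NA_integer_, NA_integer_, as.integer(c0))
        } else {
          w <- max(width[i], round(stats::rnorm(1, wpar[1], wpar[2])))
          pad <- as.integer(w) - width[i]
          pl <- sample(0:pad, 1L)
          peak_rows[[length(peak_rows) + 1L]] <-
            list(m, tf[i], max(1L, left[i] - pl),
                 right[i] + (pad - pl), NA_integer_)
        }
      }
      truth_rows[[m]] <- data.frame(tf_name = tf, site_left = left,
                                    site_right = right, method = m,
                                    covered = covered,
                                    stringsAsFactors = FALSE)
      # decoys: uniform placement away from nothing in particular
      n_decoy <- cfg$decoys_per_tf * cfg$n_tfs
      if (n_decoy > 0) {
        dw <- pmax(10, round(stats::rnorm(n_decoy, wpar[1], wpar[2])))
        dl <- sample.int(cfg$genome_length - max(dw) - 1L, n_decoy)
        dtf <- rep(tf_names, length.out = n_decoy)
        for (j in seq_len(n_decoy)) {
          if (stats::runif(1) < cfrac)
            peak_rows[[length(peak_rows) + 1L]] <-
              list(m, dtf[j], NA_integer_, NA_integer_,
                   as.integer(dl[j] + dw[j] %/% 2L))
          else
            peak_rows[[length(peak_rows) + 1L]] <-
              list(m, dtf[j], as.integer(dl[j]),
                   as.integer(dl[j] + dw[j] - 1L), NA_integer_)
        }
      }
    }
    method_vec <- vapply(peak_rows, function(r) r[[1]], character(1))
    peaks <- data.frame(
      dataset_id = if (length(method_vec)) paste0("DS-", method_vec)
                   else character(),
      tf_name = vapply(peak_rows, function(r) r[[2]], character(1)),
      method = method_vec,
      left = vapply(peak_rows, function(r) as.integer(r[[3]]), integer(1)),
      right = vapply(peak_rows, function(r) as.integer(r[[4]]), integer(1)),
      center = vapply(peak_rows, function(r) as.integer(r[[5]]), integer(1)),
      genome_version = rep("U00096.3", length(peak_rows)),
      no_cutoff = rep(FALSE, length(peak_rows)),
      stringsAsFactors = FALSE)
    class(peaks) <- c("peakset", "data.frame")
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    list(riset = ris, catalog = catalog, peaks = peaks, truth = truth,
         config = cfg)
  })
}

#' Closed-form confidence distribution of an evidence mixture
#'
#' Enumerates the finite support of `evidence_mix`, assigns each
#' combination its confidence level, and aggregates probabilities — an
#' exact oracle for the level frequencies of a large generated corpus.
#'
#' @param evidence_mix as in [corpus_config()].
#' @param catalog an `evidence_catalog`.
#' @param ruleset a `ruleset`.
#' @return Named numeric vector over `weak`, `strong`, `confirmed`.
#' @export
expected_confidence_distribution <- function(evidence_mix,
                                             catalog = default_catalog(),
                                             ruleset = default_ruleset()) {
  out <- c(weak = 0, strong = 0, confirmed = 0)
  for (combo in evidence_mix) {
    lvl <- assign_confidence(combo$binding, combo$func, catalog, ruleset)
    out[lvl] <- out[lvl] + combo$prob
  }
  out
}

#' Write a generated corpus to a directory
#'
#' Emits `riset.tsv`, `catalog.tsv`, `peaks.tsv` and `truth.tsv`; the RI
#' set re-parses through [read_riset()] with zero warnings.
#'
#' @param corpus result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_riset(corpus$riset, file.path(dir, "riset.tsv"))
  write_catalog(corpus$catalog, file.path(dir, "catalog.tsv"))
  write_peaks(corpus$peaks, file.path(dir, "peaks.tsv"))
  utils::write.table(corpus$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
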