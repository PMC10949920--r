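# Shared fixtures and the independent brute-force confidence oracle.

CAT <- default_catalog()
RULES <- default_ruleset()

# Short aliases for catalog codes used throughout the tests.
BPP   <- "EXP-IDA-BINDING-OF-PURIFIED-PROTEINS"  # group 1, strong
MUT   <- "EXP-SITE-MUTATION"                     # group 2, strong
EXT   <- "EXP-IDA-BINDING-OF-CELLULAR-EXTRACTS"  # group 3, weak
CHIP  <- "HT-IDA-CHIP-SEQ"                       # group 4
CHCH  <- "HT-IDA-CHIP-CHIP"                      # group 4
EXO   <- "HT-IDA-CHIP-EXO"                       # group 4
GSEL  <- "HT-IDA-GSELEX"                         # group 5
DAP   <- "HT-IDA-DAP-SEQ"                        # group 6
COMP  <- "COMP-ANALYSIS"                         # group 7
GEA   <- "EXP-GENE-EXPRESSION-ANALYSIS"          # function aspect
RNA   <- "HT-RNA-SEQ"                            # function aspect
AUTH  <- "NONEXP-AUTHOR-STATEMENT"               # no group

# Independent oracle: literally enumerates rule antecedents over code
# tuples instead of counting distinct groups. Kept deliberately naive.
oracle_confidence <- function(binding, func, catalog = CAT) {
  binding <- intersect(unique(binding), catalog$code)
  grp <- function(code) catalog$group[match(code, catalog$code)]
  gate <- any(catalog$aspect[match(intersect(unique(func), catalog$code),
                                   catalog$code)] == "function")
  is_strong <- function(code) !is.na(grp(code)) && grp(code) %in% 1:2
  is_weakg  <- function(code) !is.na(grp(code)) && grp(code) %in% 4:7
  base <- if (any(vapply(binding, is_strong, logical(1)))) "strong" else
    "weak"
  lvl <- base
  bump <- function(to) {
    if (match(to, c("weak", "strong", "confirmed")) >
        match(lvl, c("weak", "strong", "confirmed"))) lvl <<- to
  }
  if (gate && length(binding) >= 2) {
    prs <- utils::combn(binding, 2)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1, i]; b <- prs[2, i]
      if (is_weakg(a) && is_weakg(b) && grp(a) != grp(b)) {
        bump("strong")
        if (any(vapply(binding, is_strong, logical(1)))) bump("confirmed")
      }
      if (is_strong(a) && is_strong(b) && grp(a) != grp(b))
        bump("confirmed")
    }
    if (length(binding) >= 4) {
      quads <- utils::combn(binding, 4)
      for (i in seq_len(ncol(quads))) {
        g <- vapply(quads[, i], grp, integer(1))
        if (all(!is.na(g)) && all(g %in% 4:7) && !anyDuplicated(g))
          bump("confirmed")
      }
    }
  }
  lvl
}

# A small in-code RI set with known labels.
toy_riset <- function() {
  make_riset(
    ri_id = sprintf("RI%02d", 1:5),
    tf_name = c("Cra", "Cra", "FNR", "FNR", "ArcA"),
    ri_type = c("tf_promoter", "tf_promoter", "tf_gene", "tf_tu",
                "tf_promoter"),
    target_id = paste0("t", 1:5),
    effect = c("repression", "activation", "activation", "repression",
               "dual"),
    site_left = c(2263516L, 100L, 5000L, NA, 9000L),
    site_right = c(2263533L, 120L, 5020L, NA, 9021L),
    binding_evidence = list(c(BPP, MUT), c(CHIP, GSEL), CHIP, COMP,
                            c(BPP, COMP)),
    function_evidence = list(GEA, GEA, RNA, GEA, GEA))
}

# Peak table builder for hand fixtures.
toy_peaks <- function(tf, method, left = NA, right = NA, center = NA,
                      dataset_id = "DS1", genome_version = "U00096.3",
                      no_cutoff = FALSE) {
  n <- max(length(tf), length(left), length(center))
  out <- data.frame(dataset_id = rep_len(dataset_id, n),
                    tf_name = rep_len(tf, n),
                    method = rep_len(method, n),
                    left = as.integer(rep_len(left, n)),
                    right = as.integer(rep_len(right, n)),
                    center = as.integer(rep_len(center, n)),
                    genome_version = rep_len(genome_version, n),
                    no_cutoff = rep_len(no_cutoff, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("peakset", "data.frame")
  out
}

expect_level <- function(binding, func, expected, excluded = character()) {
  expect_identical(
    suppressWarnings(assign_confidence(binding, func, CAT, RULES,
                                       excluded)),
    expected)
}
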