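test_that("peak normalization implements both policies", {
  # center-only peak becomes exactly 200 nt
  pk <- toy_peaks("Cra", "gselex", center = 1000)
  n1 <- normalize_peaks(pk, peak_policy("as_reported"))
  expect_identical(c(n1$norm_left, n1$norm_right), c(900L, 1099L))
  expect_identical(n1$norm_right - n1$norm_left + 1L, 200L)
  # reported ends are kept verbatim under as_reported
  pk2 <- toy_peaks("Cra", "chip_seq", left = 100, right = 400)
  n2 <- normalize_peaks(pk2, peak_policy("as_reported"))
  expect_identical(c(n2$norm_left, n2$norm_right), c(100L, 400L))
  # uniform_200 recenters on the midpoint: c = floor((100+400)/2) = 250
  n3 <- normalize_peaks(pk2, peak_policy("uniform_200"))
  expect_identical(c(n3$norm_left, n3$norm_right), c(150L, 349L))
  # windows never run off the left end
  expect_warning(
    n4 <- normalize_peaks(toy_peaks("Cra", "gselex", center = 10),
                          peak_policy("as_reported")),
    "clamped")
  expect_identical(n4$norm_left, 1L)
  # configurable 201-nt alternative
  n5 <- normalize_peaks(pk, peak_policy("as_reported",
                                        uniform_width = 201L))
  expect_identical(n5$norm_right - n5$norm_left + 1L, 201L)
})

test_that("offset-table liftover shifts by the last threshold at or below", {
  iv <- data.frame(left = 600L, right = 650L)
  # empty table is the identity
  no_off <- data.frame(threshold = integer(), shift = integer())
  expect_identical(lift_intervals(iv, no_off)$left, 600L)
  off <- data.frame(threshold = c(1L, 500L), shift = c(0L, 10L))
  up <- lift_intervals(iv, off, to_version = "U00096.3")
  expect_identical(c(up$left, up$right), c(610L, 660L))
  expect_false(up$needs_review)
  # round trip with the negated table restores the original
  inv <- data.frame(threshold = c(1L, 510L), shift = c(0L, -10L))
  back <- lift_intervals(up[, c("left", "right")], inv)
  expect_identical(c(back$left, back$right), c(600L, 650L))
  # an interval spanning a breakpoint is flagged, not silently split
  span <- data.frame(left = 480L, right = 520L)
  expect_warning(flagged <- lift_intervals(span, off), "manual review")
  expect_true(flagged$needs_review)
  expect_error(lift_intervals(iv, data.frame(threshold = c(5L, 2L),
                                             shift = c(0L, 1L))),
               "strictly increasing")
})

test_that("map_riset matches by same-TF containment and enriches once per method", {
  ris <- toy_riset()
  peaks <- rbind(
    toy_peaks("Cra", "chip_exo", left = 2263400, right = 2263700),
    toy_peaks("Cra", "chip_exo", left = 2263520, right = 2263700,
              dataset_id = "DS2"),              # left edge inside site: no
    toy_peaks("FNR", "chip_exo", left = 2263400, right = 2263700,
              dataset_id = "DS3"),              # wrong TF: no
    toy_peaks("Cra", "gselex", center = 2263520),
    toy_peaks("Cra", "gselex", center = 2263530, dataset_id = "DS4"),
    toy_peaks("Cra", "gselex", center = 2263540, dataset_id = "DS5"))
  out <- map_riset(ris, peaks, peak_policy("as_reported"), CAT, RULES)
  m <- attr(out, "matches")
  cra <- out[out$ri_id == "RI01", ]
  # containment match adds the method code; three gSELEX peaks add it once
  expect_true(EXO %in% cra$binding_evidence[[1]])
  expect_identical(sum(cra$binding_evidence[[1]] == GSEL), 1L)
  expect_identical(sum(m$ri_id == "RI01" & m$method == "gselex"), 3L)
  expect_false(any(m$dataset_id %in% c("DS2", "DS3")))
  # RIs without a site are skipped and counted
  expect_identical(attr(out, "n_skipped_no_site"), 1L)
  # confidence was refreshed through the engine (monotone enrichment)
  rank <- function(l) match(l, c("weak", "strong", "confirmed"))
  expect_true(all(rank(out$confidence) >= rank(ris$confidence)))
})

test_that("mapping is idempotent and monotone in peak width", {
  corp <- generate_corpus(corpus_config(n_tfs = 8, sites_per_tf = 6,
                                        seed = 303))
  once <- map_riset(corp$riset, corp$peaks, peak_policy("uniform_200"),
                    CAT, RULES)
  twice <- map_riset(once, corp$peaks, peak_policy("uniform_200"),
                     CAT, RULES)
  expect_identical(twice$binding_evidence, once$binding_evidence)
  expect_identical(twice$confidence, once$confidence)
  # widening the uniform window never loses a match
  wide <- map_riset(corp$riset, corp$peaks,
                    peak_policy("uniform_200", uniform_width = 400L),
                    CAT, RULES)
  n200 <- nrow(attr(once, "matches"))
  n400 <- nrow(attr(wide, "matches"))
  expect_gte(n400, n200)
})

test_that("mapping refuses mixed genome versions and skips no-cutoff data", {
  ris <- toy_riset()
  old <- toy_peaks("Cra", "chip_exo", left = 2263400, right = 2263700,
                   genome_version = "U00096.2")
  expect_error(map_riset(ris, old), "lift")
  nc <- toy_peaks("Cra", "gselex", center = 2263520, no_cutoff = TRUE)
  out <- map_riset(ris, nc, peak_policy("as_reported"), CAT, RULES)
  expect_identical(nrow(attr(out, "matches")), 0L)
})

test_that("average peak size uses author-reported ends only", {
  pk <- toy_peaks("Cra", "chip_seq", left = c(1, 1), right = c(100, 200))
  s <- average_peak_size(pk)  # inclusive widths 100 and 200
  expect_equal(s$mean, 150)
  expect_identical(s$n, 2L)
  all_center <- toy_peaks("Cra", "gselex", center = c(500, 900))
  expect_true(is.na(average_peak_size(all_center)$mean))
  expect_identical(average_peak_size(all_center)$n, 0L)
  # fixture of 10 widths against hand computation
  set.seed(5)
  w <- sample(20:600, 10)
  pk10 <- toy_peaks("X", "chip_seq", left = 1000 + seq_along(w),
                    right = 1000 + seq_along(w) + w - 1)
  s10 <- average_peak_size(pk10)
  expect_equal(s10$mean, mean(w))
  expect_equal(s10$sd, sd(w))
})
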