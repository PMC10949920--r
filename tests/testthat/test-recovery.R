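test_that("classical filters keep the right RIs", {
  ris <- toy_riset()
  cl <- filter_classical(ris, CAT)
  # RI01 {BPP, MUT} and RI05 {BPP, COMP} have classical binding + a site;
  # RI02/RI03 are HT-only, RI04 has no site
  expect_setequal(cl$ri_id, c("RI01", "RI05"))
  # mixed classical+HT binding is kept
  mixed <- make_riset("R1", "TF1", "tf_gene", "g1", "activation", 10L, 30L,
                      list(c(BPP, CHIP)), list(GEA))
  expect_identical(nrow(filter_classical(mixed, CAT)), 1L)
  # classical code without a site is dropped
  nosite <- make_riset("R2", "TF1", "tf_gene", "g2", "activation",
                       NA_integer_, NA_integer_, list(BPP), list(GEA))
  expect_identical(nrow(filter_classical(nosite, CAT)), 0L)
  # hand tally on a 10-RI mixed fixture
  set.seed(99)
  b <- replicate(10, sample(CAT$code[CAT$aspect == "binding"],
                            sample(1:3, 1)), simplify = FALSE)
  ten <- make_riset(sprintf("R%02d", 1:10), "TFX", "tf_gene",
                    sprintf("g%02d", 1:10), "activation",
                    site_left = 100L * (1:10), site_right = 100L * (1:10) + 20L,
                    binding_evidence = b, function_evidence = list(GEA))
  classical_codes <- CAT$code[CAT$category == "classical" &
                                CAT$aspect == "binding"]
  hand <- sum(vapply(b, function(x)
    any(x %in% classical_codes), logical(1)))
  expect_identical(nrow(filter_classical(ten, CAT)), as.integer(hand))
})

test_that("classical-confirmed filter excludes HT before judging", {
  ris <- make_riset(
    sprintf("R%d", 1:3), "TFX", "tf_promoter", sprintf("g%d", 1:3),
    "activation", site_left = c(100L, 300L, 500L),
    site_right = c(120L, 320L, 520L),
    binding_evidence = list(c(BPP, MUT),          # confirmed without HT
                            c(BPP, CHIP, GSEL),   # confirmed only via HT
                            c(CHIP, GSEL, DAP, COMP)),  # no classical
    function_evidence = list(GEA))
  cc <- filter_classical_confirmed(ris, CAT, RULES)
  expect_identical(cc$ri_id, "R1")
  # equals the brute-force route: exclude-ht recompute, then filter
  re <- recompute_with_exclusions(ris, CAT, RULES,
                                  excluded_categories = "ht")
  brute <- filter_classical(re[re$confidence == "confirmed", ], CAT)
  expect_identical(cc$ri_id, brute$ri_id)
})

test_that("recovery aggregates per TF and per method as documented", {
  # TFA: 4 distinct sites, 3 covered -> 75%; TFB: 2 sites, 1 covered -> 50%
  ris <- make_riset(
    sprintf("R%d", 1:6), c(rep("TFA", 4), rep("TFB", 2)), "tf_promoter",
    sprintf("g%d", 1:6), "activation",
    site_left = c(100L, 300L, 500L, 700L, 900L, 1100L),
    site_right = c(120L, 320L, 520L, 720L, 920L, 1120L),
    binding_evidence = list(BPP), function_evidence = list(GEA))
  peaks <- rbind(
    toy_peaks("TFA", "chip_seq", left = c(90, 290, 490),
              right = c(130, 330, 530)),
    toy_peaks("TFB", "chip_seq", left = 890, right = 930))
  rep <- recovery(filter_classical(ris, CAT), peaks,
                  peak_policy("as_reported"))
  tfa <- rep$per_tf[rep$per_tf$tf_name == "tfa", ]
  expect_equal(tfa$fraction, 75)
  expect_equal(rep$per_method$mean, mean(c(75, 50)))
  expect_equal(rep$per_method$sd, sd(c(75, 50)), tolerance = 1e-12)
  expect_equal(rep$per_method$sd, 17.67767, tolerance = 1e-4)
  # pooled is count-weighted: 4/6
  expect_equal(rep$per_method$pooled, 100 * 4 / 6)
  # a method with zero eligible TFs is absent, not zero
  expect_false("dap_seq" %in% rep$per_method$method)
  # RIs sharing one site coordinate pair count once
  dup <- make_riset(
    c("D1", "D2"), "TFA", c("tf_promoter", "tf_gene"), c("gx", "gy"),
    "activation", site_left = 100L, site_right = 120L,
    binding_evidence = list(BPP), function_evidence = list(GEA))
  rep2 <- recovery(dup, toy_peaks("TFA", "chip_seq", left = 90,
                                  right = 130))
  expect_identical(rep2$per_tf$n_sites, 1)
})

test_that("per-TF fractions {100, 50} give mean 75, sample sd 35.36", {
  ris <- make_riset(
    c("R1", "R2", "R3"), c("TFA", "TFB", "TFB"), "tf_promoter",
    c("g1", "g2", "g3"), "activation",
    site_left = c(100L, 300L, 500L), site_right = c(120L, 320L, 520L),
    binding_evidence = list(BPP), function_evidence = list(GEA))
  peaks <- toy_peaks(c("TFA", "TFB"), "chip_seq", left = c(90, 290),
                     right = c(130, 330))
  rep <- recovery(ris, peaks)
  expect_setequal(rep$per_tf$fraction, c(100, 50))
  expect_equal(rep$per_method$mean, 75)
  expect_equal(rep$per_method$sd, 35.35534, tolerance = 1e-5)
})

test_that("compare_methods runs tie-corrected KW plus Bonferroni pairwise", {
  fake_report <- function(values) {
    per_tf <- do.call(rbind, lapply(names(values), function(m)
      data.frame(method = m, tf_name = paste0("tf", seq_along(values[[m]])),
                 n_sites = 10, n_recovered = values[[m]] / 10,
                 fraction = values[[m]], stringsAsFactors = FALSE)))
    structure(list(per_tf = per_tf, per_method = NULL,
                   policy = "as_reported"), class = "recovery_report")
  }
  # four groups with identical value sets: H = 0, p = 1
  same <- fake_report(list(a = c(10, 20, 30), b = c(10, 20, 30),
                           c = c(10, 20, 30), d = c(10, 20, 30)))
  cmp <- compare_methods(same)
  expect_equal(cmp$kruskal$statistic, 0)
  expect_equal(cmp$kruskal$p_value, 1)
  expect_false(any(cmp$pairwise$significant))
  # two separated groups: U = 0, exact two-sided p = 0.1
  sep <- fake_report(list(a = c(1, 2, 3), b = c(10, 11, 12)))
  cmp2 <- compare_methods(sep)
  expect_equal(unname(cmp2$pairwise$statistic), 0)
  expect_equal(cmp2$pairwise$p_raw, 0.1)
  expect_equal(cmp2$pairwise$p_adjusted, 0.1)  # one pair: factor 1
  # KW statistic matches the textbook formula on an untied 3-group fixture
  g <- list(a = c(1, 5, 8), b = c(2, 6, 9), c = c(3, 7, 30))
  cmp3 <- compare_methods(fake_report(g))
  x <- unlist(g)
  r <- rank(x)
  n <- length(x)
  groups <- rep(names(g), lengths(g))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri)
      length(ri) * (mean(ri) - mean(r))^2))
  expect_equal(cmp3$kruskal$statistic, h, tolerance = 1e-12)
  # Bonferroni multiplies by the number of pairs, capped at 1
  expect_equal(cmp3$pairwise$p_adjusted,
               pmin(1, cmp3$pairwise$p_raw * 3))
})
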