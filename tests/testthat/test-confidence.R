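test_that("base_level follows group membership", {
  expect_identical(base_level(MUT, CAT), "strong")
  expect_identical(base_level(CHIP, CAT), "weak")
  expect_identical(base_level(character(), CAT), "weak")
  expect_identical(base_level(c(EXT, COMP, AUTH), CAT), "weak")
  expect_identical(suppressWarnings(base_level("NO-SUCH-CODE", CAT)),
                   "weak")
})

test_that("assign_confidence reproduces the canonical upgrade patterns", {
  # two independent strong groups + function -> confirmed (rule 2)
  expect_level(c(BPP, MUT), GEA, "confirmed")
  # group 4 + group 5 + expression -> strong (the (4/5/expression)-S rule)
  expect_level(c(CHIP, GSEL), GEA, "strong")
  # ChIP-seq alone stays weak
  expect_level(CHIP, RNA, "weak")
  expect_level(CHIP, character(), "weak")
  # computational-only is weak; adding three independent HT groups makes
  # four distinct weak groups -> confirmed (the Cra-frubp pattern)
  expect_level(COMP, GEA, "weak")
  expect_level(c(COMP, EXO, GSEL, DAP), GEA, "confirmed")
  # two codes of the same group count once
  expect_level(c(CHIP, EXO), GEA, "weak")
  # function gate blocks all upgrades, base still applies
  expect_level(c(BPP, MUT), character(), "strong")
  expect_level(c(CHIP, GSEL), character(), "weak")
  # rule 3: two weak groups + one strong group -> confirmed
  expect_level(c(BPP, CHIP, GSEL), GEA, "confirmed")
  # group 3 supports base only, never antecedents
  expect_level(c(EXT, CHIP), GEA, "weak")
  # no-group codes are inert
  expect_level(c(AUTH, CHIP), GEA, "weak")
})

test_that("function gate accepts any function-aspect code", {
  expect_level(c(CHIP, GSEL), RNA, "strong")
  # a binding-aspect code in the function column does not open the gate
  expect_level(c(CHIP, GSEL), COMP, "weak")
})

test_that("exclusion removes evidence before evaluation", {
  expect_level(c(CHIP, GSEL), GEA, "weak", excluded = GSEL)
  expect_level(c(CHIP, GSEL), GEA, "strong",
               excluded = "SOMETHING-ELSE")
  # excluding the function evidence closes the gate
  expect_level(c(CHIP, GSEL), GEA, "weak", excluded = GEA)
})

test_that("engine matches the brute-force oracle on random evidence sets", {
  binding_codes <- CAT$code[CAT$aspect == "binding"]
  set.seed(42)
  for (i in 1:300) {
    b <- sample(binding_codes, sample(0:6, 1))
    f <- if (runif(1) < 0.7) GEA else character()
    expect_identical(
      suppressWarnings(assign_confidence(b, f, CAT, RULES)),
      oracle_confidence(b, f),
      info = paste(c(b, "|", f), collapse = " "))
  }
})

test_that("monotonicity: more evidence never lowers, exclusion never raises", {
  rank <- function(l) match(l, c("weak", "strong", "confirmed"))
  binding_codes <- CAT$code[CAT$aspect == "binding"]
  set.seed(7)
  for (i in 1:200) {
    b <- sample(binding_codes, sample(0:5, 1))
    f <- if (runif(1) < 0.5) GEA else character()
    before <- suppressWarnings(assign_confidence(b, f, CAT, RULES))
    extra <- sample(setdiff(binding_codes, b), 1)
    after <- suppressWarnings(assign_confidence(c(b, extra), f, CAT, RULES))
    expect_gte(rank(after), rank(before))
    excl <- sample(c(b, f), min(length(c(b, f)), sample(1:3, 1)))
    reduced <- suppressWarnings(
      assign_confidence(b, f, CAT, RULES, excluded = excl))
    expect_lte(rank(reduced), rank(before))
    # order independence
    expect_identical(
      suppressWarnings(assign_confidence(rev(b), rev(f), CAT, RULES)),
      before)
  }
})

test_that("confirmed requires at least two distinct effective groups", {
  binding_codes <- CAT$code[CAT$aspect == "binding"]
  set.seed(11)
  for (i in 1:200) {
    b <- sample(binding_codes, sample(0:5, 1))
    lvl <- suppressWarnings(assign_confidence(b, GEA, CAT, RULES))
    g <- CAT$group[match(b, CAT$code)]
    if (lvl == "confirmed")
      expect_gte(length(unique(g[!is.na(g)])), 2)
  }
})

test_that("resolve_exclusions handles codes, categories and groups", {
  expect_setequal(resolve_exclusions(CAT, categories = "ht"),
                  CAT$code[CAT$category == "ht"])
  expect_setequal(resolve_exclusions(CAT, groups = 4L),
                  c(CHIP, CHCH, EXO))
  expect_warning(resolve_exclusions(CAT, codes = "NOPE"),
                 "matched no code")
  expect_warning(resolve_exclusions(CAT, categories = "bogus"),
                 "unknown category")
})

test_that("recompute_with_exclusions equals recomputation from scratch", {
  ris <- toy_riset()
  # excluding nothing is the identity on confidence
  same <- recompute_with_exclusions(ris, CAT, RULES)
  expect_identical(same$confidence, ris$confidence)
  # exclusion equals a per-RI oracle recomputation on reduced evidence
  excl <- resolve_exclusions(CAT, categories = "ht")
  re <- recompute_with_exclusions(ris, CAT, RULES,
                                  excluded_categories = "ht")
  for (i in seq_len(nrow(ris))) {
    expect_identical(
      re$confidence[i],
      oracle_confidence(setdiff(ris$binding_evidence[[i]], excl),
                        setdiff(ris$function_evidence[[i]], excl)))
  }
  h <- attr(re, "histogram")
  expect_identical(sum(h$before), sum(h$after))
  # chip_seq-only RI drops to weak and nonexperimental-free category logic
  only_chip <- recompute_with_exclusions(
    make_riset("R1", "TF1", "tf_gene", "g1", "activation", 10L, 30L,
               list(CHIP), list(RNA)),
    CAT, RULES, excluded_categories = "ht")
  expect_identical(only_chip$confidence, "weak")
  expect_identical(only_chip$category, "nonexperimental")
})
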