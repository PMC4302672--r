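test_that("cohorts round-trip through write and load byte-identically", {
  coh <- simulate_cohort(n = 3, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f1)
  reloaded <- load_cohort(f1)
  expect_equal(nrow(reloaded), 3L)
  write_cohort(reloaded, f2)
  expect_identical(readLines(f1), readLines(f2))

  # marginal counts survive a 104-row round trip
  coh104 <- simulate_cohort(n = 104, seed = 7)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh104, f3)
  expect_equal(summarize_cohort(load_cohort(f3)), summarize_cohort(coh104))
})

test_that("validation rejects out-of-range codes, missing columns and NAs", {
  coh <- simulate_cohort(n = 5, seed = 1)
  bad <- coh
  bad$grade[3] <- 5
  expect_error(validate_cohort(bad), "row 3.*grade")
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(bad, f)
  expect_error(load_cohort(f), "grade")

  expect_error(validate_cohort(coh[, setdiff(names(coh), "loh9")]),
               "schema error.*loh9")

  bad2 <- coh
  bad2$urovysion_pos[2] <- NA
  expect_error(validate_cohort(bad2), "missing values in row")
  expect_warning(ok <- validate_cohort(bad2, on_missing = "drop"), "dropping")
  expect_equal(nrow(ok), 4L)

  bad3 <- coh
  bad3$t_progression[1] <- 0
  expect_error(validate_cohort(bad3), "strictly positive")
})

test_that("schema mapping renames file columns to canonical fields", {
  coh <- simulate_cohort(n = 4, seed = 2)
  renamed <- coh
  names(renamed)[names(renamed) == "fgfr3_mut"] <- "FGFR3"
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(renamed, f, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(load_cohort(f), "fgfr3_mut")
  got <- load_cohort(f, schema = c(fgfr3_mut = "FGFR3"))
  expect_equal(got$fgfr3_mut, coh$fgfr3_mut)
  expect_error(load_cohort(f, schema = c(not_a_field = "FGFR3")),
               "unknown canonical field")
})

test_that("feature encoding is a bijection with ordinal levels equally spaced", {
  coh <- simulate_cohort(n = 30, seed = 3)
  X <- encode_features(coh)
  expect_equal(ncol(X), 10L)
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(unname(X[, "fgfr3_mut"]), coh$fgfr3_mut)

  X3 <- encode_features(coh, c("cyp1b1", "tp53_codon72", "urovysion_pos"))
  expect_setequal(unique(as.vector(X3[, "cyp1b1"])),
                  unique(coh$cyp1b1 / 2))
  expect_equal(max(encode_features(coh[coh$cyp1b1 == 2, , drop = FALSE],
                                   "cyp1b1")), 1.0)
  # decoding inverts encoding exactly
  expect_equal(unname(decode_features(X3)[, "cyp1b1"]), coh$cyp1b1)
  expect_equal(unname(decode_features(X3)[, "tp53_codon72"]),
               coh$tp53_codon72)
  expect_error(encode_features(coh, "not_a_feature"), "unknown feature")

  zero <- coh[1, ]
  zero[, cohort_fields()$markers] <- 0L
  zero$cdkn2a_a148t <- 0L
  expect_true(all(encode_features(zero) == 0))
})

test_that("composite flags follow inclusion-exclusion on the printed counts", {
  # 104 patients: 39 FGFR3, 15 TP53, 7 CHEK2; 6 FGFR3+TP53 and
  # 5 FGFR3+CHEK2 double mutants, no triples
  coh <- simulate_cohort(n = 104, seed = 1)
  coh[, c("chek2_mut", "fgfr3_mut", "tp53_mut")] <- 0L
  coh$fgfr3_mut[1:39] <- 1L
  coh$tp53_mut[c(1:6, 40:48)] <- 1L     # 6 overlap FGFR3, 9 alone
  coh$chek2_mut[c(7:11, 49:50)] <- 1L   # 5 overlap FGFR3, 2 alone
  fl <- derive_composite_flags(coh)
  expect_equal(sum(fl$any_mutation), 50L)
  expect_equal(sum(fl$n_mutations > 1), 11L)

  # brute-force per-row check on arbitrary cohorts
  coh2 <- simulate_cohort(n = 200, seed = 9)
  fl2 <- derive_composite_flags(coh2)
  expect_equal(fl2$n_mutations,
               coh2$chek2_mut + coh2$fgfr3_mut + coh2$tp53_mut)
  expect_equal(fl2$any_mutation, as.integer(fl2$n_mutations > 0))
  expect_equal(fl2$n_loh, coh2$loh9 + coh2$loh13 + coh2$loh17)
  expect_equal(fl2$any_loh, as.integer(fl2$n_loh > 0))

  coh2[, c("chek2_mut", "fgfr3_mut", "tp53_mut",
           "loh9", "loh13", "loh17")] <- 0L
  expect_true(all(derive_composite_flags(coh2)[, -1] == 0))
})

test_that("cohort summary reports recomputed one-decimal percentages", {
  coh <- simulate_cohort(n = 104, seed = 1)
  coh$urovysion_pos <- rep(c(1L, 0L), c(74, 30))
  s <- summarize_cohort(coh)
  expect_equal(s$percent[s$variable == "urovysion_pos" & s$level == "1"],
               71.2)

  coh$progression_event <- rep(c(1L, 0L), c(15, 89))
  s <- summarize_cohort(coh)
  prog <- s$percent[s$variable == "progression_event"]
  expect_equal(round(prog), 14)

  one <- simulate_cohort(n = 1, seed = 5)
  s1 <- summarize_cohort(one)
  lev <- s1[!s1$variable %in% c("recurrence_event", "progression_event"), ]
  expect_true(all(lev$percent == 100))
  expect_error(summarize_cohort(one[0, ]), "empty")
})
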