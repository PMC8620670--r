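test_that("a well-formed checklist CSV round-trips with canonical tokens", {
  path <- write_checklist_csv(toy_checklist_df())
  cl <- read_checklist(path)
  expect_s3_class(cl, "checklist")
  expect_equal(nrow(cl), 6L)
  expect_equal(cl$family[1], "asteraceae")        # canonicalized to lower case
  expect_equal(cl$origins[[2]], c("america", "europe"))
  expect_equal(cl$lifeform[3], "biennial")        # not yet normalized on read

  out <- tempfile(fileext = ".csv")
  write_checklist(cl, out)
  expect_equal(as.data.frame(read_checklist(out)), as.data.frame(cl))
})

test_that("validation rejects duplicates, bad tokens and missing columns", {
  df <- toy_checklist_df()

  dup <- df; dup$species[4] <- "Eichhornia crassipes"; dup$species[6] <- "Eichhornia crassipes"
  expect_error(as_checklist(dup), "Eichhornia crassipes.*4.*6")

  bad_status <- df; bad_status$status[2] <- "weed"
  expect_error(as_checklist(bad_status), "status.*'weed'.*casual, naturalized, invasive")

  bad_life <- df; bad_life$lifeform[1] <- "succulent"
  expect_error(as_checklist(bad_life), "lifeform")

  bad_origin <- df; bad_origin$origin[5] <- "Atlantis"
  expect_error(as_checklist(bad_origin), "origin region")

  no_origin <- df; no_origin$origin[3] <- ""
  expect_error(as_checklist(no_origin), "empty origin.*3")

  expect_error(as_checklist(df[, setdiff(names(df), "pathway")]),
               "missing required column.*pathway")
})

test_that("extra growth-form tokens map through the overridable lifeform map", {
  df <- toy_checklist_df()
  df$lifeform <- c("Shrub", "tree", "vine", "aquatic", "annual", "perennial")
  cl <- as_checklist(df)
  expect_equal(cl$lifeform, c("woody", "woody", "other", "other", "annual", "perennial"))
  cl2 <- as_checklist(df, lifeform_map = c(vine = "woody"))
  expect_equal(cl2$lifeform[3], "woody")
  expect_error(as_checklist(df, lifeform_map = c(vine = "liana")),
               "canonical lifeforms")
})

test_that("lifeform normalization maps biennial to perennial and is idempotent", {
  cl <- as_checklist(toy_checklist_df())
  norm <- normalize_lifeform(cl)
  expect_equal(norm$lifeform[3], "perennial")
  expect_equal(norm$lifeform[-3], cl$lifeform[-3])
  expect_identical(normalize_lifeform(norm), norm)
  expect_equal(normalize_lifeform(c("annual", "biennial", "woody")),
               c("annual", "perennial", "woody"))
})

test_that("status algebra yields nested assemblages with exact partition identities", {
  cl <- as_checklist(toy_checklist_df())
  a <- derive_assemblages(cl)
  expect_setequal(a$invasive, c("Aster one", "Faba two"))
  expect_setequal(a$casual, c("Aster three", "Faba one"))
  expect_setequal(a$nni, c("Aster two", "Poa one"))

  # degenerate nesting: everything invasive
  all_inv <- toy_checklist_df(); all_inv$status <- "invasive"
  a2 <- derive_assemblages(as_checklist(all_inv))
  expect_length(a2$casual, 0L)
  expect_length(a2$nni, 0L)
  expect_equal(length(a2$invasive), nrow(all_inv))

  set.seed(11)
  for (i in 1:25) {
    ar <- derive_assemblages(random_checklist(sample(3:40, 1)))
    expect_true(all(ar$invasive %in% ar$naturalized))
    expect_true(all(ar$naturalized %in% ar$alien))
    expect_setequal(ar$casual, setdiff(ar$alien, ar$naturalized))
    expect_setequal(ar$nni, setdiff(ar$naturalized, ar$invasive))
    expect_equal(length(ar$casual) + length(ar$naturalized), length(ar$alien))
    expect_equal(length(ar$nni) + length(ar$invasive), length(ar$naturalized))
  }
})

test_that("tabulations count once per category, once per origin region", {
  df <- toy_checklist_df()[1:4, ]   # 3 Asteraceae, 1 Poaceae
  cl <- as_checklist(df)
  fam <- tabulate_by(cl, "family")
  expect_equal(fam$proportion[fam$category == "asteraceae"], 0.75)
  expect_equal(fam$proportion[fam$category == "poaceae"], 0.25)

  # a species contributes one count to EACH of its origin regions
  one <- as_checklist(data.frame(species = "Solo species", family = "Asteraceae",
                                 genus = "Solo", lifeform = "annual",
                                 origin = "America;Europe", pathway = "ornamental",
                                 status = "casual"))
  org <- tabulate_by(one, "origin")
  expect_equal(org$proportion[org$category == "america"], 1.0)
  expect_equal(org$proportion[org$category == "europe"], 1.0)

  set.seed(5)
  for (i in 1:10) {
    clr <- random_checklist(sample(4:30, 1))
    for (f in c("family", "lifeform", "pathway"))
      expect_equal(sum(tabulate_by(clr, f)$proportion), 1, tolerance = 1e-12)
    expect_gte(sum(tabulate_by(clr, "origin")$count), nrow(clr))
  }

  expect_error(tabulate_by(cl, "family", character(0)), "empty assemblage")
  expect_error(tabulate_by(cl, "family", "Nonexistent species"), "absent")
})

test_that("transition rates match a brute-force row filter and compose exactly", {
  # 10 alien, 10 naturalized, 4 invasive in one family
  df <- data.frame(species = sprintf("Ten sp%02d", 1:10), family = "Tenfam",
                   genus = "Ten", lifeform = "annual", origin = "America",
                   pathway = "forage",
                   status = c(rep("invasive", 4), rep("naturalized", 6)),
                   stringsAsFactors = FALSE)
  tr <- transition_rates(as_checklist(df))
  expect_equal(tr$rate_nat, 1.0)
  expect_equal(tr$rate_inv, 0.4)

  # family with zero naturalized species: invasion rate undefined, not 0
  df0 <- df; df0$status <- "casual"
  tr0 <- transition_rates(as_checklist(df0))
  expect_equal(tr0$rate_nat, 0)
  expect_true(is.na(tr0$rate_inv))

  expect_error(transition_rates(as_checklist(df), "Rosaceae"), "not present")

  set.seed(23)
  for (i in 1:10) {
    cl <- random_checklist(sample(6:50, 1))
    tr <- transition_rates(cl)
    for (r in seq_len(nrow(tr))) {
      rows <- as.data.frame(cl)[cl$family == tr$family[r], ]
      n_nat <- sum(rows$status %in% c("naturalized", "invasive"))
      n_inv <- sum(rows$status == "invasive")
      expect_equal(tr$rate_nat[r], n_nat / nrow(rows))
      expect_equal(tr$rate_inv[r],
                   if (n_nat > 0) n_inv / n_nat else NA_real_)
      # composed identity, exact in integer arithmetic
      if (n_nat > 0)
        expect_equal(tr$rate_nat[r] * tr$rate_inv[r] * tr$n_alien[r],
                     tr$n_invasive[r])
    }
  }
})
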