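# Rule engine: classification, attribution, criterion frequencies.

test_that("severity map partitions the criteria as the instrument defines", {
  sm <- criterion_severity_map()
  expect_setequal(sm$criterion_id[sm$severity == "DEFINITE_TRIGGER"],
                  c("1a", "2", "3", "4", "5", "10", "12", "13", "14",
                    "15", "17", "18"))
  expect_setequal(sm$criterion_id[sm$severity == "PROBABLE_TRIGGER"],
                  c("6", "7", "8", "9a", "11", "16"))
  expect_setequal(sm$criterion_id[sm$severity == "GATE"], c("1", "9"))
  expect_equal(sm$gate[sm$criterion_id == "1a"], "1")
  expect_equal(sm$gate[sm$criterion_id == "9a"], "9")
})

test_that("single-trigger forms classify by their trigger severity", {
  expect_equal(as.character(classify_forms(make_form())), "NOT_PREVENTABLE")
  # toxic drug level: forced definitely preventable
  expect_equal(as.character(classify_forms(make_form(`4` = "YES"))),
               "DEFINITELY")
  # drug interaction: probably preventable
  expect_equal(as.character(classify_forms(make_form(`7` = "YES"))),
               "PROBABLY")
  # definite trigger dominates a probable one
  expect_equal(as.character(classify_forms(make_form(`7` = "YES",
                                                     `2` = "YES"))),
               "DEFINITELY")
})

test_that("nested follow-ups only fire when their gate is YES", {
  # full (Q1, Q1a) truth table against the brute-force oracle
  combos <- expand.grid(g = c("YES", "NO", "UNCERTAIN"),
                        f = c("YES", "NO", "UNCERTAIN"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    f1 <- make_form(`1` = combos$g[i], `1a` = combos$f[i])
    expect_equal(as.character(classify_forms(f1)), oracle_classify(f1))
    f9 <- make_form(`9` = combos$g[i], `9a` = combos$f[i])
    expect_equal(as.character(classify_forms(f9)), oracle_classify(f9))
  }
  # the gate/follow-up corner cases spelled out
  expect_equal(as.character(classify_forms(make_form(`1` = "YES", `1a` = "NO"))),
               "NOT_PREVENTABLE")
  expect_equal(as.character(classify_forms(make_form(`1` = "NO", `1a` = "YES"))),
               "NOT_PREVENTABLE")
  expect_equal(as.character(classify_forms(make_form(`9` = "YES", `9a` = "YES"))),
               "PROBABLY")
})

test_that("classification matches the oracle on an exhaustive reduced form", {
  # all 3^7 combinations over {1, 1a, 2, 6, 7, 9, 9a}, everything else NO
  vals <- c("YES", "NO", "UNCERTAIN")
  grid <- expand.grid(`1` = vals, `1a` = vals, `2` = vals, `6` = vals,
                      `7` = vals, `9` = vals, `9a` = vals,
                      stringsAsFactors = FALSE)
  forms <- random_forms(nrow(grid))  # template, fully overwritten below
  forms[ALL_IDS] <- "NO"
  forms[names(grid)] <- grid
  expect_equal(as.character(classify_forms(forms)), oracle_classify(forms))
})

test_that("precedence: any definite trigger dominates any probable trigger", {
  sm <- criterion_severity_map()
  def <- sm$criterion_id[sm$severity == "DEFINITE_TRIGGER"]
  prob <- sm$criterion_id[sm$severity == "PROBABLE_TRIGGER"]
  for (d in def) {
    for (p in prob) {
      over <- setNames(list("YES", "YES"), c(d, p))
      # satisfy gates for nested ids
      if (d == "1a") over[["1"]] <- "YES"
      if (p == "9a") over[["9"]] <- "YES"
      f <- do.call(make_form, over)
      expect_equal(as.character(classify_forms(f)), "DEFINITELY",
                   info = paste(d, "+", p))
    }
  }
})

test_that("flipping any NO to YES never lowers the rating (monotonicity)", {
  set.seed(42)
  forms <- random_forms(400)
  base <- classify_forms(forms)
  flip_col <- sample(ALL_IDS, nrow(forms), replace = TRUE)
  flipped <- forms
  for (i in seq_len(nrow(forms))) flipped[i, flip_col[i]] <- "YES"
  expect_true(all(classify_forms(flipped) >= base))
})

test_that("UNCERTAIN is equivalent to NO for classification", {
  set.seed(7)
  forms <- random_forms(300)
  as_no <- forms
  for (id in ALL_IDS) as_no[[id]][as_no[[id]] == "UNCERTAIN"] <- "NO"
  expect_equal(classify_forms(forms), classify_forms(as_no))
})

test_that("attribution lists exactly the fired triggers with severities", {
  expect_equal(nrow(attribute_forms(make_form())), 0L)
  a <- attribute_form(setNames(
    as.character(make_form(`1` = "YES", `1a` = "YES", `4` = "YES")[1, ALL_IDS]),
    ALL_IDS))
  expect_setequal(a$criterion_id, c("1a", "4"))
  expect_true(all(a$severity == "DEFINITE_TRIGGER"))
  b <- attribute_forms(make_form(`9` = "YES", `9a` = "YES"))
  expect_equal(b$criterion_id, "9a")
  expect_equal(b$severity, "PROBABLE_TRIGGER")
})

test_that("attribution max severity reproduces the classification", {
  set.seed(99)
  forms <- random_forms(500)
  ratings <- as.character(classify_forms(forms))
  attr <- attribute_forms(forms)
  by_ev <- split(attr$severity, attr$event_id)
  derived <- vapply(forms$event_id, function(e) {
    sev <- by_ev[[e]]
    if (is.null(sev)) "NOT_PREVENTABLE"
    else if (any(sev == "DEFINITE_TRIGGER")) "DEFINITELY"
    else "PROBABLY"
  }, character(1), USE.NAMES = FALSE)
  expect_equal(ratings, derived)
})

test_that("criterion frequencies count events and respect the denominator", {
  forms <- make_forms(list(
    list(`2` = "YES"), list(`2` = "YES"),
    list(`1` = "YES", `1a` = "YES"), list()))
  attr <- attribute_forms(forms)
  all_ev <- criterion_frequency(attr, n_events = 4,
                                denominator_policy = "all_events")
  expect_equal(all_ev$count[all_ev$criterion_id == "2"], 2L)
  expect_equal(all_ev$pct[all_ev$criterion_id == "2"], 50.0)
  expect_equal(all_ev$count[all_ev$criterion_id == "1a"], 1L)
  expect_equal(all_ev$pct[all_ev$criterion_id == "1a"], 25.0)
  expect_true(all(all_ev$denominator == 4))
  def_ev <- criterion_frequency(attr,
                                denominator_policy = "definite_trigger_events")
  expect_true(all(def_ev$denominator == 3))
  # empty input: all-zero table, not an error
  empty <- criterion_frequency(attr[0, ], n_events = 10,
                               denominator_policy = "all_events")
  expect_true(all(empty$count == 0))
})

test_that("malformed forms are rejected with the offending id named", {
  f <- make_form()
  f$`4` <- NULL
  expect_error(classify_forms(f), "4")
  g <- make_form()
  g$extra_q <- "YES"
  expect_error(classify_forms(g), "extra_q")
  h <- make_form()
  h$`7` <- "MAYBE"
  expect_error(classify_forms(h), "MAYBE")
})
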