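# Agreement statistics: kappa, proportions, binary collapse, wrappers.

test_that("kappa limits: perfect agreement is 1, independence is 0", {
  k1 <- cohens_kappa(diag(c(10, 10)))
  expect_equal(k1$kappa, 1)
  k0 <- cohens_kappa(matrix(25, 2, 2))
  expect_equal(k0$kappa, 0)
  expect_true(k0$ci_low <= 0 && k0$ci_high >= 0)
})

test_that("kappa, SE and CI match the independent oracle", {
  got <- cohens_kappa(matrix(c(10, 3, 5, 12), 2, 2))
  want <- oracle_kappa(matrix(c(10, 3, 5, 12), 2, 2))
  expect_equal(got$kappa, want$kappa, tolerance = 1e-14)
  expect_equal(got$se, want$se, tolerance = 1e-14)
  expect_equal(got$ci_low, want$ci_low, tolerance = 1e-14)
  expect_equal(got$ci_high, want$ci_high, tolerance = 1e-14)
  # and the point value against an independently maintained implementation
  skip_if_not_installed("e1071")
  m <- matrix(c(31, 7, 12, 50), 2, 2)
  expect_equal(cohens_kappa(m)$kappa,
               e1071::classAgreement(m)$kappa, tolerance = 1e-12)
})

test_that("kappa is invariant under simultaneous category relabeling", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    m <- matrix(rpois(k * k, 8), k, k)
    perm <- sample(k)
    expect_equal(cohens_kappa(m)$kappa,
                 cohens_kappa(m[perm, perm])$kappa, tolerance = 1e-12)
  }
})

test_that("degenerate tables are handled as defined", {
  one <- cohens_kappa(matrix(c(12, 0, 0, 0), 2, 2))
  expect_equal(one$kappa, 1)
  expect_equal(c(one$ci_low, one$ci_high), c(1, 1))
  expect_error(cohens_kappa(matrix(0, 2, 2)), "empty")
  expect_error(cohens_kappa(matrix(1:6, 2, 3)), "square")
})

test_that("binary collapse groups definitely and probably as preventable", {
  expect_equal(as.character(collapse_binary(
    c("DEFINITELY", "PROBABLY", "NOT_PREVENTABLE"))),
    c("PREVENTABLE", "PREVENTABLE", "NOT_PREVENTABLE"))
  expect_error(collapse_binary("MAYBE"), "invalid")
})

test_that("Wald interval reproduces hand-checked percent cells", {
  p <- wald_proportion_ci(869, 1356)
  expect_equal(round_half_up(p$pct, 1), 64.1)
  expect_equal(round_half_up(p$ci_low, 1), 61.5)
  expect_equal(round_half_up(p$ci_high, 1), 66.6)
  expect_equal(format(p), "869 (64.1, 61.5-66.6)")
  z <- wald_proportion_ci(0, 100)
  expect_equal(c(z$pct, z$ci_low, z$ci_high), c(0, 0, 0))
  expect_equal(round_half_up(wald_proportion_ci(148, 508)$pct, 1), 29.1)
})

test_that("Wilson option matches the score interval from prop.test", {
  w <- wald_proportion_ci(40, 120, method = "wilson")
  ref <- prop.test(40, 120, correct = FALSE)$conf.int
  expect_equal(c(w$ci_low, w$ci_high) / 100, as.numeric(ref),
               tolerance = 1e-12)
})

test_that("CI width shrinks monotonically with n at fixed proportion", {
  widths <- vapply(c(50, 200, 800, 3200), function(n) {
    p <- wald_proportion_ci(round(0.3 * n), n)
    p$ci_high - p$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("invalid proportion inputs error", {
  expect_error(wald_proportion_ci(5, 0), "n must be")
  expect_error(wald_proportion_ci(7, 5), "count")
})

test_that("inter-rater wrapper equals kappa on the hand-built cross-tab", {
  pharm <- c("DEFINITELY", "DEFINITELY", "PROBABLY", "NOT_PREVENTABLE",
             "PROBABLY", "NOT_PREVENTABLE", "DEFINITELY", "PROBABLY",
             "NOT_PREVENTABLE", "PROBABLY")
  phys <- c("DEFINITELY", "PROBABLY", "PROBABLY", "NOT_PREVENTABLE",
            "NOT_PREVENTABLE", "NOT_PREVENTABLE", "DEFINITELY",
            "PROBABLY", "PROBABLY", "PROBABLY")
  a <- make_assessments(pharm, phys)
  got <- interrater_agreement(a, "ALGORITHM", "binary")
  tab <- table(factor(ifelse(pharm == "NOT_PREVENTABLE", "N", "P"),
                      c("N", "P")),
               factor(ifelse(phys == "NOT_PREVENTABLE", "N", "P"),
                      c("N", "P")))
  want <- oracle_kappa(tab)
  expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
  expect_equal(got$ci_low, want$ci_low, tolerance = 1e-12)
  # identical columns: kappa 1
  same <- interrater_agreement(make_assessments(pharm, pharm),
                               "ALGORITHM", "binary")
  expect_equal(same$kappa, 1)
})

test_that("definitely-vs-probably kappa uses the preventable subset", {
  pharm <- c("DEFINITELY", "DEFINITELY", "PROBABLY", "PROBABLY",
             "NOT_PREVENTABLE", "DEFINITELY")
  phys <- c("DEFINITELY", "PROBABLY", "PROBABLY", "DEFINITELY",
            "NOT_PREVENTABLE", "DEFINITELY")
  a <- make_assessments(pharm, phys)
  got <- interrater_agreement(a, "ALGORITHM", "definitely_vs_probably",
                              subset_policy = "rater_preventable")
  keep <- pharm != "NOT_PREVENTABLE" & phys != "NOT_PREVENTABLE"
  tab <- table(factor(pharm[keep], c("PROBABLY", "DEFINITELY")),
               factor(phys[keep], c("PROBABLY", "DEFINITELY")))
  expect_equal(got$kappa, oracle_kappa(tab)$kappa, tolerance = 1e-12)
  expect_equal(got$n, sum(keep))
  # all-not-preventable cohort: the subset is empty and that is an error
  b <- make_assessments(rep("NOT_PREVENTABLE", 4), rep("NOT_PREVENTABLE", 4))
  expect_error(
    interrater_agreement(b, "ALGORITHM", "definitely_vs_probably",
                         subset_policy = "rater_preventable"),
    "empty")
})

test_that("between-method kappa composes collapse and the 2x2 kappa", {
  cons <- rbind(
    data.frame(event_id = paste0("E", 1:8), method = "BEST_PRACTICE",
               final_rating = c("DEFINITELY", "PROBABLY", "PROBABLY",
                                "NOT_PREVENTABLE", "NOT_PREVENTABLE",
                                "PROBABLY", "DEFINITELY", "NOT_PREVENTABLE"),
               path = "CONCORDANT", stringsAsFactors = FALSE),
    data.frame(event_id = paste0("E", 1:8), method = "ALGORITHM",
               final_rating = c("DEFINITELY", "DEFINITELY", "PROBABLY",
                                "PROBABLY", "NOT_PREVENTABLE",
                                "NOT_PREVENTABLE", "DEFINITELY",
                                "NOT_PREVENTABLE"),
               path = "CONCORDANT", stringsAsFactors = FALSE))
  got <- intermethod_agreement(cons, "BEST_PRACTICE", "ALGORITHM")
  bp <- ifelse(cons$final_rating[1:8] == "NOT_PREVENTABLE", "N", "P")
  al <- ifelse(cons$final_rating[9:16] == "NOT_PREVENTABLE", "N", "P")
  tab <- table(factor(bp, c("N", "P")), factor(al, c("N", "P")))
  expect_equal(got$kappa, oracle_kappa(tab)$kappa, tolerance = 1e-12)
  # identical consensus columns give kappa 1
  same <- cons
  same$final_rating[9:16] <- same$final_rating[1:8]
  expect_equal(intermethod_agreement(same, "BEST_PRACTICE", "ALGORITHM")$kappa, 1)
  # disjoint event sets are an error, partial overlap a logged exclusion
  dis <- cons
  dis$event_id[9:16] <- paste0("X", 1:8)
  expect_error(intermethod_agreement(dis, "BEST_PRACTICE", "ALGORITHM"),
               "no events")
  part <- cons
  part$event_id[9] <- "X1"
  expect_message(intermethod_agreement(part, "BEST_PRACTICE", "ALGORITHM"),
                 "excluded")
})
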