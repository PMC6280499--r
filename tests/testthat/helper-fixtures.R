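# Shared fixtures and independent oracles. The oracles are coded
# separately from the package internals on purpose: they re-derive the
# same quantities from first principles so tests compare two routes.

ALL_IDS <- criterion_severity_map()$criterion_id

# one form data.frame with every criterion NO, then the named overrides
make_form <- function(..., event_id = "E1", rater_id = "R1") {
  over <- list(...)
  resp <- setNames(rep("NO", length(ALL_IDS)), ALL_IDS)
  resp[names(over)] <- unlist(over)
  df <- as.data.frame(as.list(resp), check.names = FALSE,
                      stringsAsFactors = FALSE)
  cbind(data.frame(event_id = event_id, rater_id = rater_id,
                   stringsAsFactors = FALSE), df)
}

# stack several make_form() results with distinct event ids
make_forms <- function(overrides) {
  do.call(rbind, lapply(seq_along(overrides), function(i) {
    do.call(make_form, c(overrides[[i]], list(event_id = paste0("E", i))))
  }))
}

# n random forms (uniform over YES/NO/UNCERTAIN on every criterion)
random_forms <- function(n) {
  m <- matrix(sample(c("YES", "NO", "UNCERTAIN"), n * length(ALL_IDS),
                     replace = TRUE),
              nrow = n, dimnames = list(NULL, ALL_IDS))
  cbind(data.frame(event_id = paste0("E", seq_len(n)),
                   rater_id = "R1", stringsAsFactors = FALSE),
        as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE))
}

# Independent brute-force classifier: a literal transcription of the
# instrument's footnote rules, one explicit condition per trigger.
oracle_classify_one <- function(resp) {
  fires <- function(id) resp[[id]] == "YES"
  definite <- fires("2") || fires("3") || fires("4") || fires("5") ||
    fires("10") || fires("12") || fires("13") || fires("14") ||
    fires("15") || fires("17") || fires("18") ||
    (fires("1") && fires("1a"))
  probable <- fires("6") || fires("7") || fires("8") || fires("11") ||
    fires("16") || (fires("9") && fires("9a"))
  if (definite) "DEFINITELY" else if (probable) "PROBABLY" else "NOT_PREVENTABLE"
}

oracle_classify <- function(forms) {
  vapply(seq_len(nrow(forms)),
         function(i) oracle_classify_one(as.list(forms[i, ALL_IDS])),
         character(1))
}

# Independent kappa oracle: explicit element-wise loops, no matrix
# algebra shared with the implementation.
oracle_kappa <- function(m, conf.level = 0.95) {
  n <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) n <- n + m[i, j]
  po <- 0
  for (i in seq_len(nrow(m))) po <- po + m[i, i] / n
  pe <- 0
  for (i in seq_len(nrow(m))) {
    ri <- 0; ci <- 0
    for (j in seq_len(ncol(m))) {
      ri <- ri + m[i, j]
      ci <- ci + m[j, i]
    }
    pe <- pe + (ri / n) * (ci / n)
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - conf.level) / 2)
  list(kappa = kappa, po = po, pe = pe, se = se,
       ci_low = max(-1, kappa - z * se), ci_high = min(1, kappa + z * se))
}

# small assessment fixture: k events, one method, two raters with given
# rating vectors
make_assessments <- function(pharm, phys, method = "ALGORITHM") {
  k <- length(pharm)
  rbind(
    data.frame(event_id = paste0("E", 1:k), rater_id = "P1",
               rater_role = "PHARMACIST", method = method, rating = pharm,
               stringsAsFactors = FALSE),
    data.frame(event_id = paste0("E", 1:k), rater_id = "D1",
               rater_role = "PHYSICIAN", method = method, rating = phys,
               stringsAsFactors = FALSE)
  )
}
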