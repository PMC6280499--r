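# Synthetic rater cohort generator.
#
# The model: each event carries one latent preventability category drawn
# from `prevalence`. A method-level confusion matrix maps that latent
# category to the event's "method truth" (so the three instruments agree
# strongly but not perfectly, and the algorithm instrument can be biased
# toward DEFINITELY, as explicit instruments are). Each rater then
# observes the method truth through their own row-stochastic confusion
# matrix, independently given the method truth. Criterion-response forms
# are built to be exactly consistent with each rater's algorithm rating:
# one trigger criterion of matching severity is answered YES (with its
# gate), everything else NO or UNCERTAIN.
#
# Category order everywhere: NOT_PREVENTABLE, PROBABLY, DEFINITELY.

stochastic_matrix <- function(rows, name) {
  m <- if (is.matrix(rows)) rows else matrix(unlist(rows), nrow = 3, byrow = TRUE)
  if (!identical(dim(m), c(3L, 3L))) abort(name, " must be 3x3")
  dimnames(m) <- list(rating_levels(), rating_levels())
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    abort(name, " must have non-negative rows summing to 1")
  }
  m
}

default_rater_confusion <- function() {
  # binary sensitivity 0.90, specificity 0.85 for both roles: puts the
  # expected binary inter-rater kappa in the mid-0.5 range seen in
  # dual-clinician chart review
  m <- stochastic_matrix(list(
    c(0.85, 0.12, 0.03),   # truth NOT_PREVENTABLE
    c(0.10, 0.80, 0.10),   # truth PROBABLY
    c(0.10, 0.30, 0.60)),  # truth DEFINITELY
    "rater confusion")
  list(PHARMACIST = m, PHYSICIAN = m)
}

default_method_confusion <- function() {
  ident <- diag(3)
  dimnames(ident) <- list(rating_levels(), rating_levels())
  list(
    BEST_PRACTICE = ident,
    # near-identical to best practice (binary agreement ~0.99)
    ERROR_BASED = stochastic_matrix(list(
      c(0.990, 0.008, 0.002),
      c(0.005, 0.990, 0.005),
      c(0.005, 0.015, 0.980)), "method confusion"),
    # explicit algorithm over-calls "definitely" (single hard triggers)
    # and nets a few extra preventables (binary agreement ~0.88)
    ALGORITHM = stochastic_matrix(list(
      c(0.88, 0.07, 0.05),
      c(0.02, 0.34, 0.64),
      c(0.00, 0.00, 1.00)), "method confusion")
  )
}

default_definite_mix <- function() {
  # relative frequencies of the definite triggers, echoing the pattern
  # seen in practice: re-exposure and toxic-level criteria dominate
  w <- c("1a" = 148, "4" = 144, "2" = 78, "3" = 66, "5" = 38,
         "17" = 17, "12" = 11, "15" = 5, "10" = 1,
         "13" = 0, "14" = 0, "18" = 0)
  w <- w[DEFINITE_TRIGGERS]
  names(w) <- DEFINITE_TRIGGERS
  w[is.na(w)] <- 0
  w / sum(w)
}

default_probable_mix <- function() {
  w <- rep(1 / length(PROBABLE_TRIGGERS), length(PROBABLE_TRIGGERS))
  names(w) <- PROBABLE_TRIGGERS
  w
}

#' Configuration for the synthetic rater cohort
#'
#' Bundles and validates every parameter of the generator. Defaults
#' emulate a dual-clinician emergency-department chart-review cohort:
#' 1356 events, about two thirds preventable, an algorithm instrument
#' biased toward "definitely preventable", rater misclassification
#' giving a binary inter-rater kappa in the mid-0.5 range, and
#' near-perfect between-method consensus agreement.
#'
#' @param n_events number of adverse drug events (default 1356).
#' @param prevalence latent category probabilities, named or ordered
#'   `NOT_PREVENTABLE, PROBABLY, DEFINITELY`; must sum to 1.
#' @param method_confusion named list of 3x3 row-stochastic matrices
#'   (one per method) mapping latent category to the method-level truth.
#' @param rater_confusion named list (`PHARMACIST`, `PHYSICIAN`) of 3x3
#'   row-stochastic matrices mapping method truth to observed rating.
#' @param definite_trigger_mix probability vector over the definite
#'   trigger criteria (which criterion fires for a DEFINITELY form).
#' @param probable_trigger_mix probability vector over the probable
#'   trigger criteria.
#' @param uncertain_rate probability that a non-fired criterion cell is
#'   recorded UNCERTAIN instead of NO (UNCERTAIN never fires).
#' @param adjudication_prob probability that a discordant pair is
#'   settled by the third reviewer instead of by discussion.
#' @param seed integer RNG seed.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_events = 1356,
                              prevalence = c(NOT_PREVENTABLE = 0.359,
                                             PROBABLY = 0.577,
                                             DEFINITELY = 0.064),
                              method_confusion = default_method_confusion(),
                              rater_confusion = default_rater_confusion(),
                              definite_trigger_mix = default_definite_mix(),
                              probable_trigger_mix = default_probable_mix(),
                              uncertain_rate = 0.05,
                              adjudication_prob = 0.1,
                              seed = 1L) {
  if (length(n_events) != 1 || n_events < 1) abort("n_events must be >= 1")
  if (length(prevalence) != 3) abort("prevalence must have 3 entries")
  if (is.null(names(prevalence))) {
    names(prevalence) <- rating_levels()
  } else {
    prevalence <- prevalence[rating_levels()]
    if (anyNA(prevalence)) abort("prevalence must be named over rating_levels()")
  }
  if (abs(sum(prevalence) - 1) > 1e-9 || any(prevalence < 0)) {
    abort("prevalence must be a probability vector summing to 1")
  }
  stopifnot(setequal(names(method_confusion), assessment_methods()),
            setequal(names(rater_confusion), c("PHARMACIST", "PHYSICIAN")))
  method_confusion <- lapply(method_confusion, stochastic_matrix,
                             name = "method confusion")
  rater_confusion <- lapply(rater_confusion, stochastic_matrix,
                            name = "rater confusion")
  check_mix <- function(mix, ids, name) {
    if (!setequal(names(mix), ids)) {
      abort(name, " must be named over criteria ", paste(ids, collapse = ", "))
    }
    mix <- mix[ids]
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
      abort(name, " must be a probability vector summing to 1")
    }
    mix
  }
  definite_trigger_mix <- check_mix(definite_trigger_mix, DEFINITE_TRIGGERS,
                                    "definite_trigger_mix")
  probable_trigger_mix <- check_mix(probable_trigger_mix, PROBABLE_TRIGGERS,
                                    "probable_trigger_mix")
  if (uncertain_rate < 0 || uncertain_rate > 1 ||
      adjudication_prob < 0 || adjudication_prob > 1) {
    abort("uncertain_rate and adjudication_prob must be in [0, 1]")
  }
  cfg <- list(n_events = as.integer(n_events), prevalence = prevalence,
              method_confusion = method_confusion,
              rater_confusion = rater_confusion,
              definite_trigger_mix = definite_trigger_mix,
              probable_trigger_mix = probable_trigger_mix,
              uncertain_rate = uncertain_rate,
              adjudication_prob = adjudication_prob,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# one categorical draw per row: P is 3x3 row-stochastic, idx selects the
# row per observation; returns rating strings
draw_categorical <- function(P, idx) {
  cp <- t(apply(P, 1, cumsum))
  u <- stats::runif(length(idx))
  k <- 1L + (u > cp[idx, 1]) + (u > cp[idx, 2])
  rating_levels()[k]
}

# Build one criterion-response form row per rating, consistent with the
# rule engine: returns a character matrix n x 20 (canonical columns).
build_forms_matrix <- function(ratings, def_mix, prob_mix, uncertain_rate) {
  n <- length(ratings)
  m <- matrix("NO", nrow = n, ncol = length(CRITERION_IDS),
              dimnames = list(NULL, CRITERION_IDS))
  # sprinkle UNCERTAIN first; fired cells and gates are overwritten below
  # (UNCERTAIN never fires, so leftover UNCERTAINs cannot change ratings)
  if (uncertain_rate > 0) {
    mask <- stats::runif(n * length(CRITERION_IDS)) < uncertain_rate
    m[mask] <- "UNCERTAIN"
  }
  is_def <- ratings == "DEFINITELY"
  is_prob <- ratings == "PROBABLY"
  if (any(is_def)) {
    pick <- sample(DEFINITE_TRIGGERS, sum(is_def), replace = TRUE,
                   prob = def_mix)
    m[cbind(which(is_def), match(pick, CRITERION_IDS))] <- "YES"
    gated <- which(is_def)[pick == "1a"]
    m[gated, "1"] <- "YES"
  }
  if (any(is_prob)) {
    pick <- sample(PROBABLE_TRIGGERS, sum(is_prob), replace = TRUE,
                   prob = prob_mix)
    m[cbind(which(is_prob), match(pick, CRITERION_IDS))] <- "YES"
    gated <- which(is_prob)[pick == "9a"]
    m[gated, "9"] <- "YES"
    # a PROBABLY form must not fire any definite trigger: enforce NO on
    # cells the sprinkle may have touched is unnecessary (UNCERTAIN does
    # not fire), but the 1a gate must not be YES
  }
  m
}

#' Simulate a dual-rater preventability cohort
#'
#' Draws a complete synthetic dataset under [simulation_config()]:
#' latent categories, method-level truths, pharmacist and physician
#' ratings for all three methods, algorithm criterion-response forms
#' consistent with each rater's algorithm rating, and a resolutions
#' table (discussion or adjudication outcome = the event's method-level
#' truth) for every discordant pair. The same seed reproduces the same
#' dataset bit for bit. Draw order is fixed: latent categories; then per
#' method (BEST_PRACTICE, ERROR_BASED, ALGORITHM) the method truth, the
#' pharmacist ratings, the physician ratings; then pharmacist forms,
#' physician forms; then resolution coin flips per method.
#'
#' @param config a `simulation_config`.
#' @return Object of class `ade_cohort`: list with data.frames
#'   `assessments` (event x rater x method ratings), `forms` (criterion
#'   responses per event x rater), `resolutions`, `truth` (latent and
#'   method-level categories per event x method), and the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_events = 20, seed = 7))
#' head(cohort$assessments)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_events
  ev <- sprintf("E%05d", seq_len(n))
  lv <- rating_levels()
  latent <- lv[sample.int(3, n, replace = TRUE, prob = config$prevalence)]
  latent_idx <- match(latent, lv)

  roles <- c(PHARMACIST = "R_PHARM", PHYSICIAN = "R_PHYS")
  truth <- list()
  assess <- list()
  for (m in assessment_methods()) {
    mt <- draw_categorical(config$method_confusion[[m]], latent_idx)
    truth[[m]] <- data.frame(event_id = ev, method = m, latent = latent,
                             method_truth = mt, stringsAsFactors = FALSE)
    mt_idx <- match(mt, lv)
    for (role in names(roles)) {
      r <- draw_categorical(config$rater_confusion[[role]], mt_idx)
      assess[[paste(m, role)]] <- data.frame(
        event_id = ev, rater_id = roles[[role]], rater_role = role,
        method = m, rating = r, stringsAsFactors = FALSE)
    }
  }
  assessments <- do.call(rbind, c(assess, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))

  forms <- list()
  for (role in names(roles)) {
    alg <- assessments[assessments$method == "ALGORITHM" &
                         assessments$rater_role == role, ]
    fm <- build_forms_matrix(alg$rating, config$definite_trigger_mix,
                             config$probable_trigger_mix,
                             config$uncertain_rate)
    df <- as.data.frame(fm, stringsAsFactors = FALSE, check.names = FALSE)
    forms[[role]] <- cbind(data.frame(event_id = alg$event_id,
                                      rater_id = alg$rater_id,
                                      stringsAsFactors = FALSE), df)
  }
  forms <- do.call(rbind, c(forms, list(make.row.names = FALSE)))

  res <- list()
  for (m in assessment_methods()) {
    a <- assessments[assessments$method == m, ]
    ph <- a$rating[a$rater_role == "PHARMACIST"]
    md <- a$rating[a$rater_role == "PHYSICIAN"]
    disc <- which(ph != md)
    if (length(disc)) {
      adj <- stats::runif(length(disc)) < config$adjudication_prob
      outcome <- truth$method_truth[truth$method == m][disc]
      res[[m]] <- data.frame(
        event_id = ev[disc], method = m,
        discussion_rating = ifelse(adj, NA_character_, outcome),
        adjudication_rating = ifelse(adj, outcome, NA_character_),
        stringsAsFactors = FALSE)
    }
  }
  resolutions <- if (length(res)) {
    do.call(rbind, c(res, list(make.row.names = FALSE)))
  } else {
    data.frame(event_id = character(), method = character(),
               discussion_rating = character(),
               adjudication_rating = character(), stringsAsFactors = FALSE)
  }

  out <- list(assessments = assessments, forms = forms,
              resolutions = resolutions, truth = truth, config = config)
  class(out) <- "ade_cohort"
  out
}

#' @export
print.ade_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ADE cohort: %d events, %d assessments, seed %d\n",
              x$config$n_events, nrow(x$assessments), x$config$seed))
  invisible(x)
}

#' Closed-form expected binary inter-rater kappa
#'
#' The exact expected Cohen's kappa between the pharmacist and the
#' physician after binary collapse, for one method, under a
#' `simulation_config`. Computed by enumerating the latent-category x
#' method-truth x observed-pair probability table (no sampling): the
#' analytic oracle used in parameter-recovery tests against
#' [simulate_cohort()].
#'
#' @param config a `simulation_config`.
#' @param method one of [assessment_methods()].
#' @return The expected kappa (length-1 numeric).
#' @export
expected_binary_kappa <- function(config, method = "BEST_PRACTICE") {
  stopifnot(inherits(config, "simulation_config"),
            method %in% assessment_methods())
  # P(method truth = t) = sum_k prevalence_k * MC[k, t]
  pt <- as.numeric(config$prevalence %*% config$method_confusion[[method]])
  # binary collapse: column 1 = NOT_PREVENTABLE, columns 2:3 preventable
  bin <- function(P) cbind(P[, 1], P[, 2] + P[, 3])
  A <- bin(config$rater_confusion$PHARMACIST)
  B <- bin(config$rater_confusion$PHYSICIAN)
  joint <- matrix(0, 2, 2)
  for (t in 1:3) joint <- joint + pt[t] * (A[t, ] %o% B[t, ])
  po <- sum(diag(joint))
  pe <- sum(rowSums(joint) * colSums(joint))
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12) return(1)
    abort("expected kappa undefined: degenerate chance agreement")
  }
  (po - pe) / (1 - pe)
}
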