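# Rule engine for the modified Schumock-Thornton preventability algorithm.
#
# The instrument asks 18 top-level Yes/No/Uncertain questions about one
# adverse drug event, two of which (Q1 and Q9) gate a nested follow-up
# (Q1a, Q9a). Each *trigger* criterion carries a fixed severity: an
# affirmative answer forces either a "definitely preventable" or a
# "probably preventable" rating. Definite triggers dominate probable
# triggers; if nothing fires the event is not preventable. UNCERTAIN
# responses never fire a trigger.

# canonical criterion order (gates immediately before their follow-up)
CRITERION_IDS <- c("1", "1a", "2", "3", "4", "5", "6", "7", "8",
                   "9", "9a", "10", "11", "12", "13", "14", "15",
                   "16", "17", "18")
TOP_LEVEL_IDS <- as.character(1:18)
DEFINITE_TRIGGERS <- c("1a", "2", "3", "4", "5", "10", "12", "13",
                       "14", "15", "17", "18")
PROBABLE_TRIGGERS <- c("6", "7", "8", "9a", "11", "16")
GATE_OF <- c("1a" = "1", "9a" = "9")
RESPONSE_LEVELS <- c("YES", "NO", "UNCERTAIN")

CRITERION_TEXT <- c(
  "1"  = "History of allergy or previous reactions to the drug or drug class?",
  "1a" = "If yes, was the re-exposure inappropriate?",
  "2"  = "Drug involved inappropriate for the patient's clinical condition?",
  "3"  = "Dose, route or frequency inappropriate for age, weight or disease state?",
  "4"  = "Toxic serum drug concentration (or laboratory monitoring test) documented?",
  "5"  = "Known treatment for the ADE (e.g. to prevent predictable side effects)?",
  "6"  = "Required therapeutic drug monitoring or other necessary tests not performed?",
  "7"  = "Drug interaction involved in the ADE?",
  "8"  = "Poor compliance involved in the ADE?",
  "9"  = "Preventative measures not prescribed or administered (e.g. untreated indication)?",
  "9a" = "If yes, were preventative measures not contraindicated?",
  "10" = "Error in ADE diagnosis contributing to the event persisting/getting worse?",
  "11" = "Delay in ADE diagnosis contributing to the event persisting/getting worse?",
  "12" = "Failure to act on the result of monitoring or testing?",
  "13" = "Errors in the transcription of the culprit drug order?",
  "14" = "Errors in dispensing of the culprit drug order?",
  "15" = "Errors in the administration of the culprit drug(s)?",
  "16" = "Superior alternative treatment available (without contraindication)?",
  "17" = "Failure in communication that contributed to the ADE?",
  "18" = "Equipment failure that contributed to the ADE?"
)

#' Criterion severity map of the modified preventability algorithm
#'
#' Machine-readable description of the instrument: one row per criterion
#' with its role (`DEFINITE_TRIGGER`, `PROBABLE_TRIGGER` or `GATE`), the
#' gate it depends on (for the nested follow-ups 1a and 9a), and the
#' question text. Downstream modules read the trigger sets from here so
#' the mapping is defined exactly once.
#'
#' @return A data.frame with columns `criterion_id`, `severity`, `gate`,
#'   `question`.
#' @export
#' @examples
#' subset(criterion_severity_map(), severity == "DEFINITE_TRIGGER")
criterion_severity_map <- function() {
  sev <- ifelse(CRITERION_IDS %in% DEFINITE_TRIGGERS, "DEFINITE_TRIGGER",
         ifelse(CRITERION_IDS %in% PROBABLE_TRIGGERS, "PROBABLE_TRIGGER",
                "GATE"))
  data.frame(
    criterion_id = CRITERION_IDS,
    severity = sev,
    gate = unname(GATE_OF[CRITERION_IDS]),
    question = unname(CRITERION_TEXT[CRITERION_IDS]),
    stringsAsFactors = FALSE
  )
}

# Validate and canonicalise a forms data.frame: requires event_id,
# rater_id and all 20 criterion columns; returns the data.frame with
# uppercase responses. Criterion columns may be prefixed "q"/"Q".
validate_forms <- function(forms) {
  stopifnot(is.data.frame(forms))
  names(forms) <- sub("^[qQ]", "", names(forms))
  for (key in c("event_id", "rater_id")) {
    if (!key %in% names(forms)) abort("forms are missing column '", key, "'")
  }
  missing <- setdiff(CRITERION_IDS, names(forms))
  if (length(missing)) {
    abort("forms are missing criterion column(s): ",
          paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(forms), c("event_id", "rater_id", CRITERION_IDS))
  if (length(extra)) {
    abort("unknown criterion column(s) in forms: ",
          paste(extra, collapse = ", "))
  }
  for (id in CRITERION_IDS) {
    v <- toupper(trimws(as.character(forms[[id]])))
    bad <- !(v %in% RESPONSE_LEVELS)
    if (any(bad)) {
      abort("invalid response(s) for criterion ", id, ": ",
            paste(unique(v[bad]), collapse = ", "),
            " (expected YES/NO/UNCERTAIN)")
    }
    forms[[id]] <- v
  }
  forms
}

# n x k logical matrix of fired triggers (columns = trigger ids, in
# canonical order). A trigger fires when its response is YES and, for a
# nested follow-up, its gate is YES. UNCERTAIN never fires.
fired_matrix <- function(forms) {
  trig <- c(DEFINITE_TRIGGERS, PROBABLE_TRIGGERS)
  trig <- CRITERION_IDS[CRITERION_IDS %in% trig]
  m <- vapply(trig, function(id) {
    f <- forms[[id]] == "YES"
    gate <- GATE_OF[id]
    if (!is.na(gate)) f <- f & forms[[gate]] == "YES"
    f
  }, logical(nrow(forms)))
  if (nrow(forms) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, trig))
  m
}

#' Classify criterion-response forms
#'
#' Applies the modified preventability algorithm to one form per row:
#' the event is `DEFINITELY` preventable if any definite trigger fires,
#' else `PROBABLY` preventable if any probable trigger fires, else
#' `NOT_PREVENTABLE`. A nested follow-up (1a, 9a) only fires when its
#' gate question (1, 9) is answered YES; its recorded response is
#' ignored otherwise. UNCERTAIN is treated as non-affirmative and never
#' fires a trigger.
#'
#' @param forms data.frame with columns `event_id`, `rater_id` and one
#'   column per criterion id (`1`, `1a`, `2`, ..., `18`; a leading `q` is
#'   tolerated), values YES/NO/UNCERTAIN (case-insensitive).
#' @return Ordered factor of ratings, one per row of `forms`.
#' @seealso [classify_form()] for a single named-vector form,
#'   [attribute_forms()] for which criteria fired.
#' @export
classify_forms <- function(forms) {
  forms <- validate_forms(forms)
  m <- fired_matrix(forms)
  def <- rowSums(m[, DEFINITE_TRIGGERS, drop = FALSE]) > 0
  prob <- rowSums(m[, PROBABLE_TRIGGERS, drop = FALSE]) > 0
  preventability_factor(ifelse(def, "DEFINITELY",
                        ifelse(prob, "PROBABLY", "NOT_PREVENTABLE")))
}

#' Classify a single response form
#'
#' @param responses named character vector of YES/NO/UNCERTAIN responses,
#'   names being criterion ids (all of `1`...`18`, `1a`, `9a` required).
#' @return Single ordered-factor rating.
#' @export
#' @examples
#' resp <- setNames(rep("NO", 20),
#'                  criterion_severity_map()$criterion_id)
#' resp["4"] <- "YES"
#' classify_form(resp)  # DEFINITELY
classify_form <- function(responses) {
  df <- as.data.frame(as.list(responses), check.names = FALSE,
                      stringsAsFactors = FALSE)
  df$event_id <- "e"
  df$rater_id <- "r"
  classify_forms(df)[1L]
}

#' Criterion attribution: which triggers fired
#'
#' Long-format attribution of every fired trigger (criterion answered
#' YES with its gate satisfied) with its severity. The classification is
#' recoverable as the maximum severity among fired criteria; an event
#' with no row is `NOT_PREVENTABLE`.
#'
#' @inheritParams classify_forms
#' @return data.frame with columns `event_id`, `rater_id`,
#'   `criterion_id`, `severity`; zero rows when nothing fired.
#' @export
attribute_forms <- function(forms) {
  forms <- validate_forms(forms)
  m <- fired_matrix(forms)
  idx <- which(m, arr.ind = TRUE)
  ids <- colnames(m)[idx[, "col"]]
  out <- data.frame(
    event_id = forms$event_id[idx[, "row"]],
    rater_id = forms$rater_id[idx[, "row"]],
    criterion_id = ids,
    severity = ifelse(ids %in% DEFINITE_TRIGGERS,
                      "DEFINITE_TRIGGER", "PROBABLE_TRIGGER"),
    stringsAsFactors = FALSE
  )
  out[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

#' @rdname attribute_forms
#' @inheritParams classify_form
#' @export
attribute_form <- function(responses) {
  df <- as.data.frame(as.list(responses), check.names = FALSE,
                      stringsAsFactors = FALSE)
  df$event_id <- "e"
  df$rater_id <- "r"
  attribute_forms(df)[, c("criterion_id", "severity")]
}

#' Criterion attribution frequencies
#'
#' Counts, for each trigger criterion, the number of events in which it
#' fired, with percentages over a configurable denominator: all events
#' in the cohort, or only events with at least one definite trigger
#' (the subset for which the instrument's rating is forced to
#' "definitely preventable" with no option to soften it).
#'
#' @param attributions data.frame as returned by [attribute_forms()]
#'   (typically restricted to one rater).
#' @param n_events total number of events assessed; required for the
#'   `all_events` denominator.
#' @param denominator_policy `"all_events"` or `"definite_trigger_events"`.
#' @param digits decimal digits for the rounded percent (round half up).
#' @return data.frame with one row per trigger criterion: `criterion_id`,
#'   `severity`, `count`, `denominator`, `pct` (rounded), `pct_raw`.
#' @export
criterion_frequency <- function(attributions, n_events = NULL,
                                denominator_policy = c("all_events",
                                                       "definite_trigger_events"),
                                digits = 1) {
  denominator_policy <- match.arg(denominator_policy)
  trig <- CRITERION_IDS[CRITERION_IDS %in%
                          c(DEFINITE_TRIGGERS, PROBABLE_TRIGGERS)]
  if (nrow(attributions) == 0) {
    counts <- setNames(integer(length(trig)), trig)
  } else {
    stopifnot(all(c("event_id", "criterion_id", "severity") %in%
                    names(attributions)))
    u <- unique(attributions[, c("event_id", "criterion_id")])
    tab <- table(factor(u$criterion_id, levels = trig))
    counts <- setNames(as.integer(tab), trig)
  }
  denom <- switch(denominator_policy,
    all_events = {
      if (is.null(n_events)) {
        abort("n_events is required for denominator_policy = 'all_events'")
      }
      n_events
    },
    definite_trigger_events = length(unique(
      attributions$event_id[attributions$severity == "DEFINITE_TRIGGER"]))
  )
  pct_raw <- if (denom > 0) 100 * counts / denom else rep(NA_real_, length(counts))
  data.frame(
    criterion_id = trig,
    severity = ifelse(trig %in% DEFINITE_TRIGGERS,
                      "DEFINITE_TRIGGER", "PROBABLE_TRIGGER"),
    count = unname(counts),
    denominator = denom,
    pct = unname(round_half_up(pct_raw, digits)),
    pct_raw = unname(pct_raw),
    stringsAsFactors = FALSE
  )
}
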