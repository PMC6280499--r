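# Delimited-text readers and writers for the three tabular inputs
# (ratings, criterion-response forms, resolutions). All files are
# comma-separated UTF-8 with a header row. Readers canonicalise case
# and known input-form dialects; writers emit the canonical layout so a
# write-then-read round trip is the identity.

read_delim_chr <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
}

write_delim_chr <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read and write rater assessment files
#'
#' One row per (event, rater, method) with columns `event_id`,
#' `rater_id`, `rater_role`, `method`, `rating`. Roles, methods and
#' ratings are validated against the package vocabularies
#' (case-insensitive on read).
#'
#' @param path file path.
#' @return `read_ratings()`: data.frame of assessments.
#' @export
read_ratings <- function(path) {
  df <- read_delim_chr(path)
  need <- c("event_id", "rater_id", "rater_role", "method", "rating")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort("ratings file ", path, " is missing column(s): ",
          paste(missing, collapse = ", "))
  }
  df$rater_role <- toupper(trimws(df$rater_role))
  df$method <- toupper(trimws(df$method))
  bad_role <- !df$rater_role %in% rater_roles()
  if (any(bad_role)) {
    abort("invalid rater_role in ", path, ": ",
          paste(unique(df$rater_role[bad_role]), collapse = ", "))
  }
  bad_m <- !df$method %in% assessment_methods()
  if (any(bad_m)) {
    abort("invalid method in ", path, ": ",
          paste(unique(df$method[bad_m]), collapse = ", "))
  }
  df$rating <- as.character(preventability_factor(df$rating))
  key <- paste(df$event_id, df$rater_id, df$method)
  if (anyDuplicated(key)) {
    abort("duplicate (event, rater, method) row(s) in ", path, ": ",
          paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  df[need]
}

#' @rdname read_ratings
#' @param assessments data.frame of assessments.
#' @export
write_ratings <- function(assessments, path) {
  write_delim_chr(
    assessments[, c("event_id", "rater_id", "rater_role", "method", "rating")],
    path)
}

#' Read and write criterion-response form files
#'
#' One row per (event, rater) with a column per criterion id. The
#' canonical header is `event_id, rater_id, 1, 1a, 2, ..., 18`; readers
#' also accept two documented input-form dialects and normalise them
#' with a message:
#'
#' * a `q`/`Q` prefix on criterion columns (`q1`, `q1a`, ...);
#' * reversed polarity on the re-exposure follow-up, a column
#'   `1a_appropriate` ("was the re-exposure appropriate?") whose YES/NO
#'   are inverted into the canonical "was the re-exposure
#'   inappropriate?" question;
#' * the three-part known-treatment chain `5` / `5a` ("known treatment
#'   not prescribed or administered?") / `5b` ("known treatment
#'   contraindicated?"), collapsed into the canonical flat `5`: YES only
#'   when the chain answers YES / YES / NO, UNCERTAIN when a consulted
#'   link is UNCERTAIN, otherwise NO.
#'
#' @param path file path.
#' @return `read_forms()`: validated forms data.frame in canonical
#'   layout.
#' @export
read_forms <- function(path) {
  df <- read_delim_chr(path)
  names(df) <- sub("^[qQ]", "", names(df))
  if ("1a_appropriate" %in% names(df)) {
    v <- toupper(trimws(df[["1a_appropriate"]]))
    df[["1a"]] <- ifelse(v == "YES", "NO", ifelse(v == "NO", "YES", v))
    df[["1a_appropriate"]] <- NULL
    message("normalised '1a_appropriate' (appropriateness polarity) to ",
            "canonical criterion 1a")
  }
  if (all(c("5a", "5b") %in% names(df))) {
    g <- toupper(trimws(df[["5"]]))
    s1 <- toupper(trimws(df[["5a"]]))
    s2 <- toupper(trimws(df[["5b"]]))
    flat <- ifelse(g == "YES" & s1 == "YES" & s2 == "NO", "YES",
            ifelse(g == "UNCERTAIN" |
                     (g == "YES" & (s1 == "UNCERTAIN" |
                                      (s1 == "YES" & s2 == "UNCERTAIN"))),
                   "UNCERTAIN", "NO"))
    df[["5"]] <- flat
    df[["5a"]] <- NULL
    df[["5b"]] <- NULL
    message("collapsed known-treatment chain (5/5a/5b) to canonical ",
            "flat criterion 5")
  }
  validate_forms(df)[, c("event_id", "rater_id", CRITERION_IDS)]
}

#' @rdname read_forms
#' @param forms forms data.frame.
#' @export
write_forms <- function(forms, path) {
  forms <- validate_forms(forms)
  write_delim_chr(forms[, c("event_id", "rater_id", CRITERION_IDS)], path)
}

#' Read and write consensus resolution files
#'
#' One row per discordant (event, method) with `discussion_rating`
#' and/or `adjudication_rating`; blanks mean "not used".
#'
#' @param path file path.
#' @return `read_resolutions()`: data.frame of resolutions.
#' @export
read_resolutions <- function(path) {
  df <- read_delim_chr(path)
  need <- c("event_id", "method", "discussion_rating", "adjudication_rating")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort("resolutions file ", path, " is missing column(s): ",
          paste(missing, collapse = ", "))
  }
  df$method <- toupper(trimws(df$method))
  for (col in c("discussion_rating", "adjudication_rating")) {
    v <- toupper(trimws(df[[col]]))
    v[v == ""] <- NA_character_
    bad <- !is.na(v) & !v %in% rating_levels()
    if (any(bad)) {
      abort("invalid ", col, " in ", path, ": ",
            paste(unique(v[bad]), collapse = ", "))
    }
    df[[col]] <- v
  }
  df[need]
}

#' @rdname read_resolutions
#' @param resolutions resolutions data.frame.
#' @export
write_resolutions <- function(resolutions, path) {
  write_delim_chr(
    resolutions[, c("event_id", "method", "discussion_rating",
                    "adjudication_rating")],
    path)
}

#' Write or read a full cohort directory
#'
#' Persists a cohort (simulated or assembled) as `ratings.csv`,
#' `forms.csv`, `resolutions.csv`, plus -- for simulated cohorts --
#' `truth.csv` and `config.json` for parameter-recovery work.
#'
#' @param cohort an `ade_cohort` or a list with `assessments`, `forms`,
#'   `resolutions` (and optionally `truth`).
#' @param dir directory (created if needed).
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`:
#'   list with `assessments`, `forms`, `resolutions` (and `truth` if
#'   present on disk).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ratings(cohort$assessments, file.path(dir, "ratings.csv"))
  write_forms(cohort$forms, file.path(dir, "forms.csv"))
  write_resolutions(cohort$resolutions, file.path(dir, "resolutions.csv"))
  if (!is.null(cohort$truth)) {
    write_delim_chr(cohort$truth, file.path(dir, "truth.csv"))
  }
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    jsonlite::write_json(
      list(n_events = cfg$n_events, prevalence = as.list(cfg$prevalence),
           uncertain_rate = cfg$uncertain_rate,
           adjudication_prob = cfg$adjudication_prob, seed = cfg$seed),
      file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  out <- list(
    assessments = read_ratings(file.path(dir, "ratings.csv")),
    forms = read_forms(file.path(dir, "forms.csv")),
    resolutions = read_resolutions(file.path(dir, "resolutions.csv"))
  )
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) out$truth <- read_delim_chr(tp)
  out
}
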