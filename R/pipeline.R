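# End-to-end orchestration: read (or simulate) a cohort, classify the
# algorithm forms, build the consensus dataset, compute the agreement
# statistics, and emit the study report tables.

#' Run the full preventability analysis
#'
#' Produces the five report tables of a dual-rater preventability study:
#'
#' * `consensus_proportions` -- consensus rating proportions per method
#'   with confidence intervals (preventable combined, definitely,
#'   probably, not preventable);
#' * `interrater_binary` -- binary inter-rater kappa per method;
#' * `interrater_def_vs_prob` -- definitely-vs-probably inter-rater
#'   kappa per method on the preventable subset;
#' * `intermethod` -- pairwise between-method kappas on binary
#'   consensus ratings;
#' * `criterion_frequencies` -- how often each algorithm criterion
#'   fired, from the pharmacist's forms.
#'
#' When `forms` are supplied, each rater's recorded ALGORITHM rating is
#' checked against the rule engine's classification of their form; any
#' mismatch count is reported in the run log (a data-entry signal, not
#' an error).
#'
#' @param cohort an `ade_cohort` from [simulate_cohort()], or a list
#'   with `assessments`, `forms` (optional), `resolutions`.
#' @param conf.level confidence level for all intervals.
#' @param denominator_policy denominator for criterion frequencies
#'   (see [criterion_frequency()]); default counts over events with at
#'   least one definite trigger.
#' @param subset_policy subset rule for the definitely-vs-probably
#'   kappa (see [interrater_agreement()]).
#' @param proportion_method `"wald"` or `"wilson"` intervals for the
#'   proportion table.
#' @return Object of class `study_report`: list of the five tables
#'   (data.frames with full-precision values plus formatted strings),
#'   the `consensus` dataset, and a `log` list (event counts, path
#'   counts, seed when simulated, form-consistency check).
#' @export
#' @examples
#' rep <- run_study(simulate_cohort(simulation_config(n_events = 60, seed = 3)))
#' rep$consensus_proportions
run_study <- function(cohort, conf.level = 0.95,
                      denominator_policy = "definite_trigger_events",
                      subset_policy = "consensus_preventable",
                      proportion_method = "wald") {
  assessments <- cohort$assessments
  forms <- cohort$forms
  consensus <- consensus_dataset(assessments, cohort$resolutions)
  methods <- assessment_methods()

  form_mismatch <- NA_integer_
  attributions <- NULL
  if (!is.null(forms) && nrow(forms)) {
    forms <- validate_forms(forms)
    pred <- as.character(classify_forms(forms))
    alg <- assessments[assessments$method == "ALGORITHM" &
                         assessments$rater_role != "ADJUDICATOR", ]
    m <- match(paste(forms$event_id, forms$rater_id),
               paste(alg$event_id, alg$rater_id))
    form_mismatch <- sum(pred != alg$rating[m], na.rm = TRUE)
    pharm_ids <- unique(alg$rater_id[alg$rater_role == "PHARMACIST"])
    attributions <- attribute_forms(
      forms[forms$rater_id %in% pharm_ids, , drop = FALSE])
  }

  # consensus proportion table
  rows <- list()
  for (m in methods) {
    fr <- consensus$final_rating[consensus$method == m]
    n <- length(fr)
    cat_counts <- c(
      PREVENTABLE = sum(fr != "NOT_PREVENTABLE"),
      DEFINITELY = sum(fr == "DEFINITELY"),
      PROBABLY = sum(fr == "PROBABLY"),
      NOT_PREVENTABLE = sum(fr == "NOT_PREVENTABLE"))
    for (cat in names(cat_counts)) {
      pr <- wald_proportion_ci(cat_counts[[cat]], n, conf.level,
                               proportion_method)
      rows[[paste(m, cat)]] <- data.frame(
        method = m, category = cat, count = pr$count, n = pr$n,
        pct = pr$pct, ci_low = pr$ci_low, ci_high = pr$ci_high,
        formatted = format(pr), stringsAsFactors = FALSE)
    }
  }
  table2 <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  kappa_row <- function(m, k) data.frame(
    method = m, kappa = k$kappa, se = k$se, ci_low = k$ci_low,
    ci_high = k$ci_high, po = k$po, pe = k$pe, n = k$n,
    formatted = format(k), stringsAsFactors = FALSE)

  table3 <- do.call(rbind, lapply(methods, function(m) {
    kappa_row(m, interrater_agreement(assessments, m, "binary",
                                      conf.level = conf.level))
  }))
  table4 <- do.call(rbind, lapply(methods, function(m) {
    kappa_row(m, interrater_agreement(assessments, m,
                                      "definitely_vs_probably",
                                      consensus = consensus,
                                      subset_policy = subset_policy,
                                      conf.level = conf.level))
  }))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  table5 <- do.call(rbind, lapply(pairs, function(p) {
    k <- intermethod_agreement(consensus, p[1], p[2], conf.level)
    df <- kappa_row(paste(p[1], "vs", p[2]), k)
    names(df)[1] <- "comparison"
    df
  }))

  table6 <- NULL
  if (!is.null(attributions)) {
    n_alg <- length(unique(
      assessments$event_id[assessments$method == "ALGORITHM"]))
    table6 <- criterion_frequency(attributions, n_events = n_alg,
                                  denominator_policy = denominator_policy)
  }

  report <- list(
    consensus_proportions = table2,
    interrater_binary = table3,
    interrater_def_vs_prob = table4,
    intermethod = table5,
    criterion_frequencies = table6,
    consensus = consensus,
    log = list(
      n_events = length(unique(assessments$event_id)),
      n_assessments = nrow(assessments),
      path_counts = as.list(attr(consensus, "path_counts")),
      seed = if (!is.null(cohort$config)) cohort$config$seed else NA_integer_,
      conf.level = conf.level,
      denominator_policy = denominator_policy,
      subset_policy = subset_policy,
      algorithm_form_mismatches = form_mismatch
    )
  )
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Preventability study report: %d events\n", x$log$n_events))
  cat("\nConsensus proportions by method:\n")
  print(x$consensus_proportions[, c("method", "category", "formatted")],
        row.names = FALSE)
  cat("\nInter-rater agreement (binary):\n")
  print(x$interrater_binary[, c("method", "n", "formatted")],
        row.names = FALSE)
  cat("\nInter-rater agreement (definitely vs probably):\n")
  print(x$interrater_def_vs_prob[, c("method", "n", "formatted")],
        row.names = FALSE)
  cat("\nBetween-method agreement (binary consensus):\n")
  print(x$intermethod[, c("comparison", "n", "formatted")],
        row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits one CSV per table (formatted values alongside full-precision
#' numbers), a machine-readable `summary.json` with full-precision
#' statistics and the run log, and a plain-text `run_log.txt`. Output is
#' deterministic for a fixed input (no timestamps), so identical runs
#' produce byte-identical files.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("consensus_proportions", "interrater_binary",
            "interrater_def_vs_prob", "intermethod",
            "criterion_frequencies")
  for (t in tabs) {
    if (!is.null(report[[t]])) {
      utils::write.csv(report[[t]], file.path(dir, paste0(t, ".csv")),
                       row.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  utils::write.csv(report$consensus, file.path(dir, "consensus.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    c(lapply(report[tabs], function(x) x %||% list()),
      list(log = report$log)),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", na = "null")
  log_lines <- c(
    sprintf("events: %d", report$log$n_events),
    sprintf("assessments: %d", report$log$n_assessments),
    sprintf("seed: %s", report$log$seed),
    sprintf("conf.level: %s", report$log$conf.level),
    sprintf("consensus paths: %s",
            paste(names(report$log$path_counts),
                  unlist(report$log$path_counts),
                  sep = "=", collapse = " ")),
    sprintf("algorithm form mismatches: %s",
            report$log$algorithm_form_mismatches))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Regenerate formatted tables from a machine-readable summary
#'
#' Rebuilds the formatted report strings from the full-precision values
#' stored in `summary.json`, so a written report can be checked or
#' re-rendered without the original inputs.
#'
#' @param path path to a `summary.json` written by [write_report()].
#' @return Named list of data.frames with regenerated `formatted`
#'   columns.
#' @export
report_tables_from_summary <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (length(s$consensus_proportions)) {
    t2 <- as.data.frame(s$consensus_proportions)
    t2$formatted <- sprintf("%d (%s, %s-%s)", t2$count, fmt1(t2$pct),
                            fmt1(t2$ci_low), fmt1(t2$ci_high))
    out$consensus_proportions <- t2
  }
  for (t in c("interrater_binary", "interrater_def_vs_prob", "intermethod")) {
    if (length(s[[t]])) {
      df <- as.data.frame(s[[t]])
      df$formatted <- sprintf("%s (%s-%s)", fmt2(df$kappa),
                              fmt2(df$ci_low), fmt2(df$ci_high))
      out[[t]] <- df
    }
  }
  if (length(s$criterion_frequencies)) {
    out$criterion_frequencies <- as.data.frame(s$criterion_frequencies)
  }
  out
}

#' Validate input files without running the analysis
#'
#' Checks a ratings file (and optionally forms and resolutions files)
#' for structural problems: duplicate keys, out-of-scale ratings,
#' invalid roles or methods, events missing one of the two primary
#' raters, unknown criterion columns and invalid responses. Inputs are
#' never modified.
#'
#' @param ratings path to a ratings CSV.
#' @param forms optional path to a forms CSV.
#' @param resolutions optional path to a resolutions CSV.
#' @return data.frame of findings (`file`, `row`, `issue`); zero rows
#'   when everything is clean.
#' @export
validate_inputs <- function(ratings, forms = NULL, resolutions = NULL) {
  findings <- list()
  note <- function(file, row, issue) {
    findings[[length(findings) + 1]] <<- data.frame(
      file = file, row = row, issue = issue, stringsAsFactors = FALSE)
  }

  df <- read_delim_chr(ratings)
  need <- c("event_id", "rater_id", "rater_role", "method", "rating")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    note(ratings, NA_integer_,
         paste("missing column(s):", paste(missing, collapse = ", ")))
  } else {
    role <- toupper(trimws(df$rater_role))
    meth <- toupper(trimws(df$method))
    rat <- toupper(trimws(df$rating))
    for (i in which(!role %in% rater_roles())) {
      note(ratings, i, paste("invalid rater_role:", df$rater_role[i]))
    }
    for (i in which(!meth %in% assessment_methods())) {
      note(ratings, i, paste("invalid method:", df$method[i]))
    }
    for (i in which(!rat %in% rating_levels())) {
      note(ratings, i, paste("out-of-scale rating:", df$rating[i]))
    }
    key <- paste(df$event_id, df$rater_id, meth)
    for (i in which(duplicated(key))) {
      note(ratings, i, paste("duplicate (event, rater, method):",
                             df$event_id[i], df$rater_id[i], meth[i]))
    }
    prim <- role %in% c("PHARMACIST", "PHYSICIAN")
    pair <- table(paste(df$event_id[prim], meth[prim], sep = "/"))
    for (k in names(pair)[pair != 2]) {
      note(ratings, NA_integer_,
           paste0("event/method ", k, " has ", pair[[k]],
                  " primary rating(s), expected 2"))
    }
  }

  if (!is.null(forms)) {
    fdf <- read_delim_chr(forms)
    names(fdf) <- sub("^[qQ]", "", names(fdf))
    cols <- setdiff(names(fdf), c("event_id", "rater_id"))
    for (cn in setdiff(cols, CRITERION_IDS)) {
      note(forms, NA_integer_, paste("unknown criterion column:", cn))
    }
    for (cn in setdiff(CRITERION_IDS, cols)) {
      note(forms, NA_integer_, paste("missing criterion column:", cn))
    }
    for (cn in intersect(cols, CRITERION_IDS)) {
      v <- toupper(trimws(fdf[[cn]]))
      for (i in which(!v %in% RESPONSE_LEVELS)) {
        note(forms, i, paste0("invalid response for criterion ", cn, ": ",
                              fdf[[cn]][i]))
      }
    }
  }

  if (!is.null(resolutions)) {
    rdf <- read_delim_chr(resolutions)
    need_r <- c("event_id", "method", "discussion_rating",
                "adjudication_rating")
    missing_r <- setdiff(need_r, names(rdf))
    if (length(missing_r)) {
      note(resolutions, NA_integer_,
           paste("missing column(s):", paste(missing_r, collapse = ", ")))
    } else {
      for (col in c("discussion_rating", "adjudication_rating")) {
        v <- toupper(trimws(rdf[[col]]))
        for (i in which(v != "" & !is.na(v) & !v %in% rating_levels())) {
          note(resolutions, i, paste0("out-of-scale ", col, ": ", rdf[[col]][i]))
        }
      }
      rkey <- paste(rdf$event_id, toupper(trimws(rdf$method)))
      for (i in which(duplicated(rkey))) {
        note(resolutions, i, "duplicate (event, method) resolution row")
      }
    }
  }

  if (!length(findings)) {
    return(data.frame(file = character(), row = integer(),
                      issue = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(findings, list(make.row.names = FALSE)))
}
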