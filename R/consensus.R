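# Dual-reviewer consensus workflow: two clinicians rate every event
# under every method independently; discordant pairs are discussed to
# consensus, and a third reviewer adjudicates cases that discussion does
# not resolve. Discussion and adjudication outcomes are *inputs* (a
# resolutions table) -- the workflow records human decisions, it never
# fabricates them.

#' Resolve one event's pair of ratings into a consensus record
#'
#' Concordant pairs keep the shared rating (path `CONCORDANT`; any
#' supplied discussion or adjudication value is ignored). Discordant
#' pairs take the discussion outcome when present (path `DISCUSSED`),
#' otherwise the adjudicator's rating (path `ADJUDICATED`). A discordant
#' pair with neither is an error: the study design requires every case
#' to end in a consensus.
#'
#' @param r1,r2 one-row data.frames (or lists) with `event_id`,
#'   `rater_id`, `method`, `rating` for the same event and method from
#'   two different raters. Order is irrelevant.
#' @param discussion_rating,adjudication_rating optional three-level
#'   ratings (NA when absent).
#' @return List with `event_id`, `method`, `final_rating` (ordered
#'   factor) and `path`.
#' @export
#' @examples
#' r1 <- list(event_id = "E1", rater_id = "A", method = "ALGORITHM",
#'            rating = "PROBABLY")
#' r2 <- list(event_id = "E1", rater_id = "B", method = "ALGORITHM",
#'            rating = "NOT_PREVENTABLE")
#' resolve_consensus(r1, r2, discussion_rating = "PROBABLY")
resolve_consensus <- function(r1, r2, discussion_rating = NA,
                              adjudication_rating = NA) {
  if (!identical(as.character(r1$event_id), as.character(r2$event_id)) ||
      !identical(as.character(r1$method), as.character(r2$method))) {
    abort("ratings to resolve must share event_id and method (got ",
          r1$event_id, "/", r1$method, " vs ", r2$event_id, "/", r2$method, ")")
  }
  if (identical(as.character(r1$rater_id), as.character(r2$rater_id))) {
    abort("ratings to resolve must come from two different raters")
  }
  a <- preventability_factor(r1$rating)
  b <- preventability_factor(r2$rating)
  if (a == b) {
    final <- a
    path <- "CONCORDANT"
  } else if (!is.na(discussion_rating)) {
    final <- preventability_factor(discussion_rating)
    path <- "DISCUSSED"
  } else if (!is.na(adjudication_rating)) {
    final <- preventability_factor(adjudication_rating)
    path <- "ADJUDICATED"
  } else {
    abort("unresolved discordant ratings for event ", r1$event_id,
          " (method ", r1$method, "): no discussion or adjudication outcome")
  }
  list(event_id = as.character(r1$event_id),
       method = as.character(r1$method),
       final_rating = final, path = path)
}

#' Build the consensus dataset for a cohort
#'
#' Applies [resolve_consensus()] across every (event, method) pair in an
#' assessment table, pulling discussion/adjudication outcomes from a
#' resolutions table keyed by event and method.
#'
#' @param assessments data.frame with columns `event_id`, `rater_id`,
#'   `rater_role`, `method`, `rating`; adjudicator rows are ignored here
#'   (their outcome belongs in `resolutions`). Every (event, method)
#'   must have exactly two primary ratings.
#' @param resolutions data.frame with columns `event_id`, `method`,
#'   `discussion_rating`, `adjudication_rating` (NA/empty when not
#'   applicable). May be NULL if all pairs are concordant.
#' @return data.frame with columns `event_id`, `method`, `final_rating`,
#'   `path`, carrying a `path_counts` attribute (table of resolution
#'   paths).
#' @export
consensus_dataset <- function(assessments, resolutions = NULL) {
  stopifnot(all(c("event_id", "rater_id", "rater_role", "method", "rating")
                %in% names(assessments)))
  prim <- assessments[assessments$rater_role != "ADJUDICATOR", , drop = FALSE]
  prim$rating <- as.character(preventability_factor(prim$rating))
  key <- paste(prim$event_id, prim$method, sep = "\r")
  counts <- table(key)
  bad <- names(counts)[counts != 2L]
  if (length(bad)) {
    abort("each (event, method) needs exactly two primary ratings; offending: ",
          paste(gsub("\r", "/", utils::head(bad, 10)), collapse = ", "),
          if (length(bad) > 10) " ..." else "")
  }
  ord <- order(key, prim$rater_id)
  prim <- prim[ord, , drop = FALSE]
  i1 <- seq(1, nrow(prim), by = 2)
  i2 <- i1 + 1L
  ev <- prim$event_id[i1]
  me <- prim$method[i1]
  ra <- prim$rating[i1]
  rb <- prim$rating[i2]

  disc <- rep(NA_character_, length(ev))
  adj <- rep(NA_character_, length(ev))
  if (!is.null(resolutions) && nrow(resolutions)) {
    stopifnot(all(c("event_id", "method") %in% names(resolutions)))
    rkey <- paste(resolutions$event_id, resolutions$method, sep = "\r")
    if (anyDuplicated(rkey)) {
      abort("duplicate (event, method) rows in resolutions table")
    }
    m <- match(paste(ev, me, sep = "\r"), rkey)
    blank_to_na <- function(x) {
      x <- as.character(x)
      x[!is.na(x) & trimws(x) == ""] <- NA_character_
      x
    }
    disc <- blank_to_na(resolutions$discussion_rating)[m]
    adj <- blank_to_na(resolutions$adjudication_rating)[m]
  }

  concord <- ra == rb
  final <- ifelse(concord, ra, ifelse(!is.na(disc), disc, adj))
  path <- ifelse(concord, "CONCORDANT",
          ifelse(!is.na(disc), "DISCUSSED",
          ifelse(!is.na(adj), "ADJUDICATED", NA_character_)))
  unresolved <- is.na(path)
  if (any(unresolved)) {
    abort("unresolved discordant events (no discussion/adjudication outcome): ",
          paste(utils::head(paste0(ev[unresolved], "/", me[unresolved]), 10),
                collapse = ", "),
          if (sum(unresolved) > 10) " ..." else "")
  }
  out <- data.frame(
    event_id = ev, method = me,
    final_rating = as.character(preventability_factor(final)),
    path = path, stringsAsFactors = FALSE
  )
  attr(out, "path_counts") <- table(factor(
    path, levels = c("CONCORDANT", "DISCUSSED", "ADJUDICATED")))
  out
}
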