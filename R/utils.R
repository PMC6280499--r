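# Shared scale definitions and small numeric helpers.

#' Preventability rating scale
#'
#' The ordered three-level preventability scale used throughout the
#' package: `NOT_PREVENTABLE < PROBABLY < DEFINITELY`. The order matters
#' for trigger precedence in the rule engine (definite triggers dominate
#' probable ones) and for monotonicity properties.
#'
#' @return Character vector of the three levels, lowest first.
#' @export
#' @examples
#' rating_levels()
rating_levels <- function() {
  c("NOT_PREVENTABLE", "PROBABLY", "DEFINITELY")
}

#' Assessment methods
#'
#' The three preventability assessment instruments a chart-review cohort
#' is rated under: a best-practice definition, an error-based definition,
#' and the explicit algorithm. The two definition-based instruments are
#' human judgments whose ratings enter the pipeline as data; only the
#' algorithm method is backed by criterion-response forms.
#'
#' @return Character vector of method codes.
#' @export
assessment_methods <- function() {
  c("BEST_PRACTICE", "ERROR_BASED", "ALGORITHM")
}

#' Rater roles
#'
#' @return Character vector of recognised rater roles.
#' @export
rater_roles <- function() {
  c("PHARMACIST", "PHYSICIAN", "ADJUDICATOR")
}

#' Coerce to an ordered preventability factor
#'
#' @param x character vector of ratings (case-insensitive).
#' @return Ordered factor with levels `rating_levels()`.
#' @export
preventability_factor <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad <- !is.na(x) & !(x %in% rating_levels())
  if (any(bad)) {
    stop("invalid preventability rating(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  factor(x, levels = rating_levels(), ordered = TRUE)
}

#' Collapse the three-level scale to preventable / not preventable
#'
#' Groups definitely and probably preventable events into a single
#' `PREVENTABLE` category, the binary scale used for the headline
#' proportions and the binary inter-rater kappas.
#'
#' @param rating character or factor of three-level ratings.
#' @return Factor with levels `NOT_PREVENTABLE`, `PREVENTABLE`.
#' @export
#' @examples
#' collapse_binary(c("DEFINITELY", "PROBABLY", "NOT_PREVENTABLE"))
collapse_binary <- function(rating) {
  r <- preventability_factor(rating)
  out <- ifelse(is.na(r), NA_character_,
                ifelse(r == "NOT_PREVENTABLE", "NOT_PREVENTABLE", "PREVENTABLE"))
  factor(out, levels = c("NOT_PREVENTABLE", "PREVENTABLE"))
}

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (`0.25 -> 0.3` at one
#' digit), the convention used for all reported percentages and kappas.
#' Base `round()` rounds half to even, which disagrees on exactly the tie
#' cases that occur in percent tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(28.35, 1)  # 28.4, where round() gives 28.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon absorbs representation error in x * p (values here are
  # percents/kappas of magnitude <= 100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

# one-decimal percent string
fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)

# two-decimal string (kappa reporting)
fmt2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with no call, consistent error style
abort <- function(...) stop(..., call. = FALSE)
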