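# Agreement statistics: Cohen's kappa with an asymptotic 95% CI,
# binomial proportions with Wald (default) or Wilson intervals, and the
# cohort-level wrappers that cross-tabulate rater or method ratings.

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement for a square contingency table of two
#' raters (or two methods) over the same categories:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed agreement
#' (diagonal proportion) and `pe` the chance agreement from the margins.
#' The confidence interval is `kappa +/- z * se` with the asymptotic
#' standard error `se = sqrt(po (1 - po) / (n (1 - pe)^2))`, truncated
#' to `[-1, 1]`.
#'
#' Degenerate margins: if both raters use a single identical category,
#' `pe = po = 1` and kappa is defined as 1 with a zero-width interval;
#' `pe = 1` with `po < 1` cannot arise from a contingency table but is
#' rejected defensively.
#'
#' @param x square numeric matrix or table of counts; rows are rater A,
#'   columns rater B, in the same category order.
#' @param conf.level confidence level (default 0.95).
#' @return Object of class `kappa_result`: list with `kappa`, `po`,
#'   `pe`, `se`, `ci_low`, `ci_high`, `n`, `conf.level`, `table`.
#' @export
#' @examples
#' cohens_kappa(matrix(c(10, 3, 5, 12), 2, 2))
cohens_kappa <- function(x, conf.level = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) abort("contingency table must be square")
  if (any(x < 0) || any(!is.finite(x))) abort("counts must be finite and non-negative")
  if (!is.null(rownames(x)) && !is.null(colnames(x)) &&
      !identical(rownames(x), colnames(x))) {
    abort("row and column categories must match (same order)")
  }
  n <- sum(x)
  if (n < 1) abort("contingency table is empty")
  po <- sum(diag(x)) / n
  pe <- sum(rowSums(x) * colSums(x)) / n^2
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12) {
      res <- list(kappa = 1, po = 1, pe = 1, se = 0,
                  ci_low = 1, ci_high = 1, n = n,
                  conf.level = conf.level, table = x)
      class(res) <- "kappa_result"
      return(res)
    }
    abort("kappa undefined: chance agreement is 1 but observed agreement < 1")
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  res <- list(kappa = kappa, po = po, pe = pe, se = se,
              ci_low = max(-1, kappa - z * se),
              ci_high = min(1, kappa + z * se),
              n = n, conf.level = conf.level, table = x)
  class(res) <- "kappa_result"
  res
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %s (%d%% CI %s-%s), n = %d\n",
              fmt2(x$kappa), round(100 * x$conf.level),
              fmt2(x$ci_low), fmt2(x$ci_high), as.integer(x$n)))
  cat(sprintf("  observed agreement %.4f, chance agreement %.4f, SE %.4f\n",
              x$po, x$pe, x$se))
  invisible(x)
}

#' @export
format.kappa_result <- function(x, ...) {
  sprintf("%s (%s-%s)", fmt2(x$kappa), fmt2(x$ci_low), fmt2(x$ci_high))
}

#' Kappa from two parallel rating vectors
#'
#' Cross-tabulates two equal-length vectors over a shared category set
#' and delegates to [cohens_kappa()].
#'
#' @param a,b rating vectors of equal length (factors or character).
#' @param levels category levels; defaults to the union of observed
#'   values (factor levels are kept when supplied).
#' @inheritParams cohens_kappa
#' @return `kappa_result`.
#' @export
kappa_from_ratings <- function(a, b, levels = NULL, conf.level = 0.95) {
  if (length(a) != length(b)) abort("rating vectors must have equal length")
  if (is.null(levels)) {
    levels <- if (is.factor(a)) levels(a) else
      sort(unique(c(as.character(a), as.character(b))))
  }
  tab <- table(factor(as.character(a), levels = levels),
               factor(as.character(b), levels = levels))
  cohens_kappa(tab, conf.level = conf.level)
}

#' Binomial proportion with confidence interval
#'
#' Percent and interval for `count` successes out of `n`, on the percent
#' scale. The default Wald (normal-approximation) interval is
#' `p +/- z sqrt(p (1 - p) / n)`, clipped to `[0, 1]`; the Wilson score
#' interval is available as an alternative.
#'
#' @param count,n non-negative integers with `count <= n`, `n >= 1`.
#' @param conf.level confidence level.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Object of class `proportion_result`: `count`, `n`, `pct`,
#'   `ci_low`, `ci_high` (all percents, full precision), `conf.level`,
#'   `method`.
#' @export
#' @examples
#' wald_proportion_ci(869, 1356)  # 64.1 (61.5-66.6)
wald_proportion_ci <- function(count, n, conf.level = 0.95,
                               method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (length(count) != 1 || length(n) != 1) abort("count and n must be scalars")
  if (is.na(count) || is.na(n) || n < 1) abort("n must be >= 1")
  if (count < 0 || count > n) abort("count must be in [0, n]")
  p <- count / n
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  } else {
    ci <- stats::prop.test(count, n, conf.level = conf.level,
                           correct = FALSE)$conf.int
    lo <- ci[1]
    hi <- ci[2]
  }
  res <- list(count = as.integer(count), n = as.integer(n),
              pct = 100 * p, ci_low = 100 * lo, ci_high = 100 * hi,
              conf.level = conf.level, method = method)
  class(res) <- "proportion_result"
  res
}

#' @export
print.proportion_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.proportion_result <- function(x, ...) {
  sprintf("%d (%s, %s-%s)", x$count, fmt1(x$pct),
          fmt1(x$ci_low), fmt1(x$ci_high))
}

# pivot primary assessments of one method to one row per event with a
# pharmacist and a physician rating
pivot_rater_pair <- function(assessments, method) {
  a <- assessments[assessments$method == method &
                     assessments$rater_role %in% c("PHARMACIST", "PHYSICIAN"), ,
                   drop = FALSE]
  if (!nrow(a)) abort("no pharmacist/physician ratings for method ", method)
  ph <- a[a$rater_role == "PHARMACIST", ]
  md <- a[a$rater_role == "PHYSICIAN", ]
  if (anyDuplicated(ph$event_id) || anyDuplicated(md$event_id)) {
    abort("duplicate ratings per event/rater for method ", method)
  }
  common <- intersect(ph$event_id, md$event_id)
  missing <- setdiff(union(ph$event_id, md$event_id), common)
  if (length(missing)) {
    abort("events missing one of the two rater ratings for method ", method,
          ": ", paste(utils::head(missing, 10), collapse = ", "))
  }
  data.frame(event_id = common,
             pharmacist = ph$rating[match(common, ph$event_id)],
             physician = md$rating[match(common, md$event_id)],
             stringsAsFactors = FALSE)
}

#' Inter-rater agreement for one assessment method
#'
#' Cross-tabulates the pharmacist's and physician's original
#' (pre-consensus) ratings of each event under one method and returns
#' Cohen's kappa.
#'
#' * `scale = "binary"`: ratings collapsed to preventable vs not
#'   preventable, over all events.
#' * `scale = "definitely_vs_probably"`: a 2x2 table of DEFINITELY vs
#'   PROBABLY over the preventable subset only. With
#'   `subset_policy = "consensus_preventable"` the subset is events
#'   whose consensus rating under the method is preventable (requires
#'   `consensus`); with `"rater_preventable"` it is events both raters
#'   rated preventable. Events in the subset where a rater nevertheless
#'   rated NOT_PREVENTABLE cannot be placed on the 2-level scale and
#'   are dropped with a message.
#'
#' @param assessments assessment data.frame (see [consensus_dataset()]).
#' @param method one of [assessment_methods()].
#' @param scale `"binary"` or `"definitely_vs_probably"`.
#' @param consensus consensus data.frame from [consensus_dataset()];
#'   needed for `subset_policy = "consensus_preventable"`.
#' @param subset_policy subset rule for the definitely-vs-probably scale.
#' @inheritParams cohens_kappa
#' @return `kappa_result`.
#' @export
interrater_agreement <- function(assessments, method,
                                 scale = c("binary", "definitely_vs_probably"),
                                 consensus = NULL,
                                 subset_policy = c("consensus_preventable",
                                                   "rater_preventable"),
                                 conf.level = 0.95) {
  scale <- match.arg(scale)
  subset_policy <- match.arg(subset_policy)
  wide <- pivot_rater_pair(assessments, method)
  if (scale == "binary") {
    return(kappa_from_ratings(collapse_binary(wide$pharmacist),
                              collapse_binary(wide$physician),
                              levels = c("NOT_PREVENTABLE", "PREVENTABLE"),
                              conf.level = conf.level))
  }
  keep <- switch(subset_policy,
    consensus_preventable = {
      if (is.null(consensus)) {
        abort("consensus records are required for subset_policy = ",
              "'consensus_preventable'")
      }
      cm <- consensus[consensus$method == method, , drop = FALSE]
      prev <- cm$event_id[collapse_binary(cm$final_rating) == "PREVENTABLE"]
      wide$event_id %in% prev
    },
    rater_preventable =
      collapse_binary(wide$pharmacist) == "PREVENTABLE" &
      collapse_binary(wide$physician) == "PREVENTABLE"
  )
  sub <- wide[keep, , drop = FALSE]
  if (!nrow(sub)) {
    abort("empty preventable subset for method ", method,
          "; the definitely-vs-probably scale is undefined")
  }
  on_scale <- sub$pharmacist != "NOT_PREVENTABLE" &
    sub$physician != "NOT_PREVENTABLE"
  if (any(!on_scale)) {
    message(sum(!on_scale), " event(s) dropped from the definitely-vs-",
            "probably table for ", method,
            " (a rater rated them not preventable)")
    sub <- sub[on_scale, , drop = FALSE]
  }
  if (!nrow(sub)) {
    abort("no events ratable on the definitely-vs-probably scale for method ",
          method)
  }
  kappa_from_ratings(sub$pharmacist, sub$physician,
                     levels = c("PROBABLY", "DEFINITELY"),
                     conf.level = conf.level)
}

#' Between-method agreement on consensus ratings
#'
#' Cohen's kappa between two assessment methods' consensus ratings,
#' collapsed to preventable vs not preventable, over the events rated
#' under both methods. Events present under only one method are
#' excluded with a message; fully disjoint event sets are an error.
#'
#' @param consensus consensus data.frame from [consensus_dataset()].
#' @param method_a,method_b the two methods to compare.
#' @inheritParams cohens_kappa
#' @return `kappa_result`.
#' @export
intermethod_agreement <- function(consensus, method_a, method_b,
                                  conf.level = 0.95) {
  ca <- consensus[consensus$method == method_a, , drop = FALSE]
  cb <- consensus[consensus$method == method_b, , drop = FALSE]
  common <- intersect(ca$event_id, cb$event_id)
  if (!length(common)) {
    abort("methods ", method_a, " and ", method_b,
          " share no events; agreement is undefined")
  }
  excluded <- length(union(ca$event_id, cb$event_id)) - length(common)
  if (excluded > 0) {
    message(excluded, " event(s) excluded from ", method_a, " vs ",
            method_b, " (consensus present under only one method)")
  }
  kappa_from_ratings(
    collapse_binary(ca$final_rating[match(common, ca$event_id)]),
    collapse_binary(cb$final_rating[match(common, cb$event_id)]),
    levels = c("NOT_PREVENTABLE", "PREVENTABLE"),
    conf.level = conf.level)
}
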