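#' Maturity rule for one developmental milestone test
#'
#' Each test is scored daily during the first three postnatal weeks, either
#' as absence/presence of the mature response (binary 0/1) or on a graded
#' 0-3 scale (0-2 for eye opening). A response is mature when the criterion
#' score is held for the required number of consecutive days; the
#' registered maturity day is, by default, the final day of that first
#' qualifying run (the day the criterion is first satisfied in full), with
#' the first day of the run available as an alternative convention.
#'
#' @param test_name Test label.
#' @param score_type `"binary"` or `"graded"`.
#' @param criterion Score that must be met or exceeded.
#' @param consecutive_days_required Length of the qualifying run, days.
#' @param score_max Maximum admissible daily score.
#' @param day_range Observation window, postnatal days.
#' @param registered `"final"` or `"first"` day of the qualifying run.
#' @return An object of class `maturity_rule`.
#' @export
maturity_rule <- function(test_name,
                          score_type = c("binary", "graded"),
                          criterion = 1,
                          consecutive_days_required = 3,
                          score_max = if (score_type == "binary") 1 else 3,
                          day_range = c(1, 21),
                          registered = c("final", "first")) {
  score_type <- match.arg(score_type)
  registered <- match.arg(registered)
  force(score_max)
  if (consecutive_days_required < 1) {
    stop("`consecutive_days_required` must be >= 1", call. = FALSE)
  }
  if (criterion < 0 || criterion > score_max) {
    stop("`criterion` must lie within the score range", call. = FALSE)
  }
  structure(
    list(test_name = test_name, score_type = score_type,
         criterion = criterion,
         consecutive_days_required = as.integer(consecutive_days_required),
         score_max = score_max, day_range = day_range,
         registered = registered),
    class = "maturity_rule"
  )
}

#' Default milestone rule set
#'
#' Rules for the thirteen standard tests: reflex tests scored 0/1 mostly
#' require three consecutive successful days; graded 0-3 tests (walking,
#' surface righting, grasping, negative geotaxis, cliff aversion) require
#' the top score, with the three-consecutive-day rule where the protocol
#' states one; eye opening is scored 0/1/2 (one eye / both) and matures on
#' the first day both eyes are open. Every rule can be overridden.
#'
#' @return Named list of [maturity_rule()]s.
#' @export
default_milestone_rules <- function() {
  r <- list(
    rooting = maturity_rule("rooting", "binary", 1, 3, day_range = c(7, 12)),
    ear_twitch = maturity_rule("ear_twitch", "binary", 1, 3, day_range = c(7, 15)),
    auditory_startle = maturity_rule("auditory_startle", "binary", 1, 3,
                                     day_range = c(7, 18)),
    open_field = maturity_rule("open_field", "binary", 1, 3, day_range = c(7, 18)),
    walking = maturity_rule("walking", "graded", 3, 1, day_range = c(5, 21)),
    surface_righting = maturity_rule("surface_righting", "graded", 3, 3,
                                     day_range = c(1, 13)),
    negative_geotaxis = maturity_rule("negative_geotaxis", "graded", 3, 3,
                                      day_range = c(1, 14)),
    cliff_aversion = maturity_rule("cliff_aversion", "graded", 3, 3,
                                   day_range = c(1, 14)),
    postural_reflex = maturity_rule("postural_reflex", "binary", 1, 1,
                                    day_range = c(5, 21)),
    air_righting = maturity_rule("air_righting", "binary", 1, 3,
                                 day_range = c(8, 21)),
    wire_suspension = maturity_rule("wire_suspension", "binary", 1, 1,
                                    day_range = c(5, 21)),
    grasping = maturity_rule("grasping", "graded", 3, 1, day_range = c(5, 21)),
    eye_opening = maturity_rule("eye_opening", "graded", 2, 1, score_max = 2,
                                day_range = c(1, 21))
  )
  r
}

#' Milestone score table
#'
#' Long-format daily scores: one row per animal, test and postnatal day,
#' with the per-test maturity rules attached. Scores must lie within each
#' test's declared range and days within P1-P21.
#'
#' @param records Data frame with columns `animal_id`, `group`,
#'   `test_name`, `day`, `score`.
#' @param rules Named list of [maturity_rule()]s covering every test in
#'   `records`.
#' @return An object of class `milestone_table`.
#' @export
milestone_table <- function(records, rules = default_milestone_rules()) {
  records <- as.data.frame(records)
  need <- c("animal_id", "group", "test_name", "day", "score")
  if (!all(need %in% names(records))) {
    stop("`records` must have columns animal_id, group, test_name, day, score",
         call. = FALSE)
  }
  records <- records[, need]
  if (any(records$day < 1 | records$day > 21)) {
    stop("days must lie within P1-P21", call. = FALSE)
  }
  for (tn in unique(records$test_name)) {
    rule <- rules[[tn]]
    if (is.null(rule)) stop(sprintf("no maturity rule for test '%s'", tn),
                            call. = FALSE)
    sc <- records$score[records$test_name == tn]
    if (any(sc < 0 | sc > rule$score_max)) {
      stop(sprintf("scores for '%s' outside [0, %g]", tn, rule$score_max),
           call. = FALSE)
    }
  }
  structure(list(records = records, rules = rules), class = "milestone_table")
}

#' @export
print.milestone_table <- function(x, ...) {
  r <- x$records
  cat(sprintf("<milestone_table> %d records, %d animals, %d tests\n",
              nrow(r), length(unique(r$animal_id)),
              length(unique(r$test_name))))
  invisible(x)
}

#' Read milestone scores from delimited text
#'
#' @param path File with header `animal_id,group,test_name,day,score`
#'   (comma- or tab-delimited).
#' @param rules Named list of [maturity_rule()]s.
#' @return A [milestone_table()].
#' @export
read_milestones <- function(path, rules = default_milestone_rules()) {
  sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  milestone_table(d, rules)
}

#' Maturity day of one animal on one test
#'
#' Scans the contiguous daily scores for the first run of
#' `consecutive_days_required` days meeting the criterion and registers
#' the run's final (default) or first day. Gaps in the day sequence are an
#' error; an animal that never qualifies by the end of the window returns
#' `NA` ("not reached").
#'
#' @param days Integer vector of postnatal days (will be sorted).
#' @param scores Daily scores aligned with `days`.
#' @param rule A [maturity_rule()].
#' @return The maturity day, or `NA_integer_` if not reached.
#' @examples
#' mature_day(5:9, c(0, 0, 1, 1, 1), maturity_rule("righting", "binary", 1, 3))
#' @export
mature_day <- function(days, scores, rule) {
  stopifnot(inherits(rule, "maturity_rule"))
  o <- order(days)
  days <- as.integer(days[o])
  scores <- scores[o]
  if (anyDuplicated(days)) stop("duplicate days for one animal/test", call. = FALSE)
  gaps <- which(diff(days) != 1L)
  if (length(gaps)) {
    stop(sprintf("missing day between P%d and P%d", days[gaps[1]],
                 days[gaps[1] + 1L]), call. = FALSE)
  }
  if (any(scores < 0 | scores > rule$score_max)) {
    stop("scores outside the test's declared range", call. = FALSE)
  }
  ok <- scores >= rule$criterion
  L <- rule$consecutive_days_required
  n <- length(ok)
  if (n >= L) {
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (ok[i]) run + 1L else 0L
      if (run == L) {
        return(if (rule$registered == "final") days[i] else days[i - L + 1L])
      }
    }
  }
  NA_integer_
}

#' Group summaries of maturity days
#'
#' For every test and group: the median maturity day over animals that
#' reached maturity (even group sizes use the mean of the middle pair),
#' the number of animals, and how many never reached the criterion (these
#' are excluded from the median).
#'
#' @param table A [milestone_table()].
#' @return Data frame with `test_name`, `group`, `median_day`, `n`,
#'   `n_not_reached`.
#' @export
group_summary <- function(table) {
  stopifnot(inherits(table, "milestone_table"))
  r <- table$records
  combos <- unique(r[, c("test_name", "group")])
  if (!nrow(combos)) stop("empty milestone table", call. = FALSE)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    tn <- combos$test_name[i]
    g <- combos$group[i]
    sub <- r[r$test_name == tn & r$group == g, ]
    if (!nrow(sub)) stop("empty group", call. = FALSE)
    rule <- table$rules[[tn]]
    md <- vapply(split(sub, sub$animal_id),
                 function(a) mature_day(a$day, a$score, rule), integer(1))
    data.frame(test_name = tn, group = g,
               median_day = stats::median(md[!is.na(md)]),
               n = length(md), n_not_reached = sum(is.na(md)))
  })
  do.call(rbind, out)
}

#' Mann-Whitney U statistic
#'
#' Rank-based computation of the U statistic, counting tied pairs as one
#' half. `convention = "min"` (the conventional reported statistic) returns
#' `min(U, n1 * n2 - U)`; `"less"` returns the number of (a, b) pairs with
#' `a < b` plus half the ties; `"greater"` its complement. The p-value is
#' deliberately out of scope (use [stats::wilcox.test()] for inference).
#'
#' @param a,b Numeric samples.
#' @param convention `"min"`, `"less"`, or `"greater"`.
#' @return The U statistic.
#' @examples
#' rank_sum_u(c(1, 2), c(3, 4)) # complete separation: 0
#' @export
rank_sum_u <- function(a, b, convention = c("min", "less", "greater")) {
  convention <- match.arg(convention)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  rk <- rank(c(a, b))
  u_greater <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2 # pairs with a > b (+ ties/2)
  u_less <- n1 * n2 - u_greater
  switch(convention,
         min = min(u_less, u_greater),
         less = u_less,
         greater = u_greater)
}
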