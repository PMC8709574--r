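test_that("maturity day registers the final day of the qualifying run", {
  rule <- maturity_rule("surface_righting", "graded", 3, 3)
  expect_equal(mature_day(5:9, c(0, 0, 3, 3, 3), rule), 9L)
  expect_equal(mature_day(5:9, c(0, 0, 0, 0, 0), rule), NA_integer_)

  first <- maturity_rule("surface_righting", "graded", 3, 3,
                         registered = "first")
  expect_equal(mature_day(5:9, c(0, 0, 3, 3, 3), first), 7L)

  # binary example: 0,0,1,1,1 on P5-P9 with the 3-day rule
  bin <- maturity_rule("rooting", "binary", 1, 3)
  expect_equal(mature_day(5:9, c(0, 0, 1, 1, 1), bin), 9L)

  expect_error(mature_day(c(5, 6, 8, 9), c(0, 1, 1, 1), bin),
               "missing day between P6 and P8")
  expect_error(mature_day(5:7, c(0, 1, 2), bin), "declared range")
})

test_that("maturity day matches the exhaustive window scanner", {
  set.seed(31)
  for (i in 1:200) {
    L <- sample(1:3, 1)
    rule <- maturity_rule("t", "binary", 1, L)
    n <- sample(L:12, 1)
    d0 <- sample(1:(21 - n + 1), 1)
    days <- d0:(d0 + n - 1)
    scores <- sample(0:1, n, replace = TRUE)
    expect_identical(mature_day(days, scores, rule),
                     oracle_mature_day(days, scores, 1, L))
  }
})

test_that("maturity day is monotone in daily scores", {
  rule <- maturity_rule("t", "graded", 3, 3)
  set.seed(8)
  for (i in 1:50) {
    days <- 1:15
    scores <- sample(0:3, 15, replace = TRUE)
    d1 <- mature_day(days, scores, rule)
    j <- sample(15, 1)
    improved <- scores
    improved[j] <- 3
    d2 <- mature_day(days, improved, rule)
    expect_lte(ifelse(is.na(d2), Inf, d2), ifelse(is.na(d1), Inf, d1))
  }
})

test_that("group summaries use medians over animals that reached maturity", {
  rule <- maturity_rule("t", "binary", 1, 1)
  mk <- function(animal, group, mday) {
    score <- as.integer(1:21 >= mday)
    data.frame(animal_id = animal, group = group, test_name = "t",
               day = 1:21, score = score)
  }
  recs <- rbind(mk("a1", "WT", 7), mk("a2", "WT", 7), mk("a3", "WT", 8),
                mk("b1", "KO", 6), mk("b2", "KO", 8))
  tb <- milestone_table(recs, list(t = rule))
  gs <- group_summary(tb)
  expect_equal(gs$median_day[gs$group == "WT"], 7)
  expect_equal(gs$median_day[gs$group == "KO"], 7) # even n: mean of middle pair

  # a never-maturing animal is counted separately, not in the median
  recs2 <- rbind(recs, data.frame(animal_id = "b3", group = "KO",
                                  test_name = "t", day = 1:21, score = 0L))
  gs2 <- group_summary(milestone_table(recs2, list(t = rule)))
  expect_equal(gs2$median_day[gs2$group == "KO"], 7)
  expect_equal(gs2$n_not_reached[gs2$group == "KO"], 1)
  expect_equal(gs2$n[gs2$group == "KO"], 3)
})

test_that("milestone tables validate scores, days and rules", {
  rule <- maturity_rule("t", "binary", 1, 1)
  bad_day <- data.frame(animal_id = "a", group = "WT", test_name = "t",
                        day = 22, score = 0)
  expect_error(milestone_table(bad_day, list(t = rule)), "P1-P21")
  bad_score <- data.frame(animal_id = "a", group = "WT", test_name = "t",
                          day = 5, score = 3)
  expect_error(milestone_table(bad_score, list(t = rule)), "outside")
  expect_error(
    milestone_table(data.frame(animal_id = "a", group = "WT",
                               test_name = "nope", day = 5, score = 0),
                    list(t = rule)),
    "no maturity rule"
  )

  # read/write round trip through delimited text
  g <- gen_milestone_table(n_per_group = 3, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(g$table$records, f, row.names = FALSE, quote = FALSE)
  back <- read_milestones(f, g$table$rules)
  expect_equal(back$records$score, g$table$records$score)
})

test_that("the default rule set covers the standard tests", {
  rules <- default_milestone_rules()
  expect_true(all(c("rooting", "surface_righting", "negative_geotaxis",
                    "cliff_aversion", "air_righting", "eye_opening",
                    "grasping", "walking", "wire_suspension") %in% names(rules)))
  expect_equal(rules$surface_righting$consecutive_days_required, 3L)
  expect_equal(rules$eye_opening$criterion, 2)
  expect_equal(rules$eye_opening$consecutive_days_required, 1L)
})

test_that("the U statistic equals brute-force pair counting", {
  expect_equal(rank_sum_u(c(1, 2), c(3, 4)), 0)
  expect_equal(rank_sum_u(c(1, 2), c(1, 2)), 2) # ties: n1 n2 / 2

  set.seed(12)
  for (i in 1:100) {
    a <- sample(1:10, sample(2:15, 1), replace = TRUE)
    b <- sample(1:10, sample(2:15, 1), replace = TRUE)
    expect_equal(rank_sum_u(a, b), oracle_u(a, b))
    # conservation before the min-convention
    expect_equal(rank_sum_u(a, b, "less") + rank_sum_u(b, a, "less"),
                 length(a) * length(b))
  }

  # tie-free samples agree with the base-R Wilcoxon statistic
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1))
    expect_equal(rank_sum_u(a, b, "greater"),
                 unname(stats::wilcox.test(a, b)$statistic))
  }

  expect_error(rank_sum_u(numeric(0), 1:3), "non-empty")
})
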