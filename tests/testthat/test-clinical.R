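ctrl_counts <- c(bleeding = 2, subcutaneous_emphysema = 0, pain = 1,
                 nausea_vomiting = 1, infection = 1, high_fever = 2,
                 abdominal_distension = 1, back_soreness = 0)
expt_counts <- c(bleeding = 1, subcutaneous_emphysema = 0, pain = 1,
                 nausea_vomiting = 0, infection = 0, high_fever = 1,
                 abdominal_distension = 0, back_soreness = 1)

test_that("complication rates reproduce the published group percentages", {
  expt <- outcome_group("experimental", 50, complications = expt_counts)
  ctrl <- outcome_group("control", 50, complications = ctrl_counts)
  expect_equal(complication_rate(expt), 8)
  expect_equal(complication_rate(ctrl), 16)
  none <- outcome_group("none", 50, complications = expt_counts * 0)
  expect_equal(complication_rate(none), 0)
})

test_that("total satisfaction reproduces the published group percentages", {
  expt <- outcome_group("experimental", 50,
                        satisfaction = c(very_satisfied = 76, satisfied = 22,
                                         dissatisfied = 2), percent = TRUE)
  ctrl <- outcome_group("control", 50,
                        satisfaction = c(very_satisfied = 69, satisfied = 24,
                                         dissatisfied = 7), percent = TRUE)
  expect_equal(total_satisfaction(expt), 98)
  expect_equal(total_satisfaction(ctrl), 93)
  zero <- outcome_group("z", 50,
                        satisfaction = c(very_satisfied = 0, satisfied = 0,
                                         dissatisfied = 50))
  expect_equal(total_satisfaction(zero), 0)
})

test_that("rates are scale-free in counts and n", {
  g1 <- outcome_group("g", 50, complications = expt_counts,
                      satisfaction = c(very_satisfied = 30, satisfied = 10,
                                       dissatisfied = 10))
  g2 <- outcome_group("g2", 100, complications = expt_counts * 2,
                      satisfaction = c(very_satisfied = 60, satisfied = 20,
                                       dissatisfied = 20))
  expect_equal(complication_rate(g1), complication_rate(g2))
  expect_equal(total_satisfaction(g1), total_satisfaction(g2))
})

test_that("group validation enforces the one-complication-per-patient bound", {
  expect_error(outcome_group("g", 3, complications = c(a = 4)),
               "\\[0, n\\]")
  g <- outcome_group("g", 5, complications = c(a = 3, b = 3))
  expect_error(complication_rate(g), "exceed")
  expect_error(outcome_group("g", 50,
                             satisfaction = c(very_satisfied = 10,
                                              satisfied = 10,
                                              dissatisfied = 10)),
               "sum to n")
  expect_error(outcome_group("g", 50, percent = TRUE,
                             satisfaction = c(very_satisfied = 80,
                                              satisfied = 30,
                                              dissatisfied = 7)),
               "100")
})

test_that("the two-sample t statistic matches its closed form", {
  tt <- two_sample_t(c(0, 1, 50), c(1, 1, 50), "pooled")
  expect_equal(tt$t_statistic, -5, tolerance = 1e-9)
  expect_equal(tt$df, 98)
  expect_lt(tt$p_value, 0.05)
  expect_equal(tt$p_value, 2 * pt(-5, 98))

  same <- two_sample_t(c(3.2, 1.1, 40), c(3.2, 1.1, 40))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("the t test is antisymmetric and Welch matches pooled when balanced", {
  a <- c(55.45, 16.13, 50)
  b <- c(60.83, 17.62, 50)
  tp <- two_sample_t(a, b, "pooled")
  tr <- two_sample_t(b, a, "pooled")
  expect_equal(tp$t_statistic, -tr$t_statistic)
  expect_equal(tp$p_value, tr$p_value)

  w <- two_sample_t(c(1, 2, 30), c(4, 2, 30), "welch")
  p <- two_sample_t(c(1, 2, 30), c(4, 2, 30), "pooled")
  expect_equal(w$t_statistic, p$t_statistic)
  expect_equal(w$df, p$df)
  expect_error(two_sample_t(c(1, 0, 30), c(1, 1, 30)), "positive")
})

test_that("the packaged fixture loads and yields the published summary", {
  groups <- load_clinical_tables()
  expect_named(groups, c("control", "experimental"))
  expect_equal(groups$control$n, 50)
  rep <- clinical_report(groups)
  rates <- rep$rates
  expect_equal(rates$complication_rate_pct[rates$group == "experimental"], 8)
  expect_equal(rates$complication_rate_pct[rates$group == "control"], 16)
  expect_equal(rates$total_satisfaction_pct[rates$group == "experimental"], 98)
  expect_equal(rates$total_satisfaction_pct[rates$group == "control"], 93)
  expect_true(all(rep$tests$p >= 0 & rep$tests$p <= 1))
  # hospital stay difference is significant under both variants
  hs <- rep$tests[rep$tests$outcome == "hospital_stay_days", ]
  expect_true(all(hs$p < 0.05))
})
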