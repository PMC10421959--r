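test_that("prevalence counts administrations with any positive attribute", {
  lib <- tiny_library()
  # all levels zero -> 0
  ds <- severity_dataset(lib, "ache", "severity", integer(), n_zero = 10)
  p <- prevalence(pool_timepoints(ds), "ache")
  expect_equal(p$value, 0)
  expect_equal(p$denominator, 10)
  # presence-only term, 2 yes of 10
  ds <- severity_dataset(lib, "rash", "presence", c(1, 1), n_zero = 8)
  expect_equal(prevalence(pool_timepoints(ds), "rash")$value, 0.2)
  # "any attribute" disjunction: severity 0 but interference 2 still counts
  df <- resp_rows(list("p1", "baseline", "ache", "severity", 0),
                  list("p1", "baseline", "ache", "interference", 2),
                  list("p2", "baseline", "ache", "severity", 0),
                  list("p2", "baseline", "ache", "interference", 0))
  p <- prevalence(pool_timepoints(response_dataset(df, lib)), "ache")
  expect_equal(p$numerator, 1)
  expect_equal(p$denominator, 2)
  # never-presented term: undefined score, flagged, not an error
  p <- prevalence(pool_timepoints(ds), "ache")
  expect_true(is.na(p$value))
  expect_equal(p$denominator, 0)
})

test_that("attribute proportion score uses the symptomatic denominator and level-2 cut", {
  lib <- tiny_library()
  # severity responses {1:6, 2:3, 3:1} -> 4/10
  ds <- severity_dataset(lib, "ache", "severity", c(rep(1, 6), rep(2, 3), 3))
  s <- attribute_proportion_score(pool_timepoints(ds), "ache", "severity")
  expect_equal(s$value, 0.4)
  expect_equal(s$denominator, 10)
  # all level 0 -> undefined
  ds0 <- severity_dataset(lib, "ache", "severity", integer(), n_zero = 5)
  expect_true(is.na(attribute_proportion_score(pool_timepoints(ds0), "ache", "severity")$value))
  # not asked -> marker, never 0
  s <- attribute_proportion_score(pool_timepoints(ds), "ache", "amount")
  expect_true(s$not_asked)
  # presence is rejected outright
  expect_error(attribute_proportion_score(pool_timepoints(ds), "rash", "presence"),
               class = "proctailor_validation_error")
})

test_that("high-end proportion shares the denominator and nests the cut", {
  lib <- tiny_library()
  ds <- severity_dataset(lib, "ache", "severity", c(rep(2, 9), 3))
  pooled <- pool_timepoints(ds)
  expect_equal(high_end_proportion(pooled, "ache", "severity", 3)$value, 0.1)
  expect_equal(high_end_proportion(pooled, "ache", "severity", proportion_cut_level()),
               attribute_proportion_score(pooled, "ache", "severity"))
  expect_equal(high_end_proportion(pooled, "ache", "severity", 4)$value, 0)
})

test_that("impact proportion scores with a 9-member panel print as 0/11.1/22.2", {
  for (n_high in 0:9) {
    s <- impact_proportion_score(impact_panel("ache", n_high), "ache")
    expect_equal(s$value, n_high / 9)
    # every defined score is a multiple of 1/9
    expect_equal(s$value * 9, round(s$value * 9))
  }
  expect_equal(percent(impact_proportion_score(impact_panel("ache", 1), "ache")$value), 11.1)
  expect_equal(percent(impact_proportion_score(impact_panel("ache", 0), "ache")$value), 0)
  expect_equal(percent(impact_proportion_score(impact_panel("ache", 2), "ache")$value), 22.2)
  # unrated term -> undefined
  expect_true(is.na(impact_proportion_score(impact_panel("ache", 1), "cramp")$value))
  expect_error(impact_proportion_score(impact_panel("ache", 1)[0, ], "ache"),
               class = "proctailor_validation_error")
})

test_that("score table has one row per term and metric with explicit markers", {
  lib <- tiny_library()
  df <- resp_rows(list("p1", "baseline", "ache", "severity", 3),
                  list("p1", "baseline", "ache", "interference", 1))
  tab <- score_table(pool_timepoints(response_dataset(df, lib)))
  expect_equal(nrow(tab), nrow(lib) * 5)
  expect_equal(unique(table(tab$term_id)), 5L)
  # single symptomatic survey: prevalence 1/1 for that term, others undefined
  expect_equal(tab$value[tab$term_id == "ache" & tab$metric == "prevalence"], 1)
  expect_true(is.na(tab$value[tab$term_id == "rash" & tab$metric == "prevalence"]))
  # absent attribute carries the not-asked marker, never 0
  row <- tab[tab$term_id == "rash" & tab$metric == "severity", ]
  expect_true(row$not_asked)
  expect_true(is.na(row$value))
  # defined scores lie in [0, 1]
  expect_true(all(tab$value[!is.na(tab$value)] >= 0 & tab$value[!is.na(tab$value)] <= 1))
})

test_that("attribute denominators never exceed the term's prevalence numerator", {
  fx <- study_like_fixture(seed = 42, n_patients = 80)
  tab <- score_table(pool_timepoints(fx$dataset))
  prev_num <- tab$numerator[tab$metric == "prevalence"]
  names(prev_num) <- tab$term_id[tab$metric == "prevalence"]
  attr_rows <- tab[tab$metric != "prevalence" & !tab$not_asked, ]
  expect_true(all(attr_rows$denominator <= prev_num[attr_rows$term_id]))
  # and no denominator exceeds the administration count
  expect_true(all(tab$denominator <= pool_timepoints(fx$dataset)$n_administrations))
})

test_that("display rounding is half-up to one decimal", {
  expect_equal(round_half_up(11.15, 1), 11.2)
  expect_equal(round_half_up(11.24, 1), 11.2)
  expect_equal(percent(0.394), 39.4)
  expect_equal(percent(1 - 0.394), 60.6)
  expect_equal(percent(0.0955, 1), 9.6)
})
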