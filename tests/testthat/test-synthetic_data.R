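test_that("generator validates its configuration", {
  lib <- tiny_library()
  expect_error(generator_config(lib, prevalence = 1.2), class = "proctailor_config_error")
  expect_error(generator_config(lib, loading = 1), class = "proctailor_config_error")
  expect_error(generator_config(lib, attribute_levels = c(0.5, 0.5)), class = "proctailor_config_error")
  expect_error(generator_config(lib, prevalence = c(ache = 0.5)), class = "proctailor_config_error")
  expect_error(generator_config(lib, attribute_levels = list(rash = list(severity = c(1, 0, 0, 0)))),
               class = "proctailor_config_error")
})

test_that("identical seeds give identical datasets, different seeds differ", {
  lib <- tiny_library()
  cfg <- generator_config(lib, n_patients = 40, seed = 9)
  d1 <- simulate_survey_data(cfg)
  d2 <- simulate_survey_data(cfg)
  expect_identical(d1$responses, d2$responses)
  d3 <- simulate_survey_data(generator_config(lib, n_patients = 40, seed = 10))
  expect_false(identical(d1$responses, d3$responses))
  # simulation must not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- stats::runif(1)
  })
  withr::with_seed(1, {
    invisible(simulate_survey_data(cfg))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("zero prevalence yields all-zero responses and zero scores", {
  lib <- tiny_library()
  cfg <- generator_config(lib, n_patients = 30, prevalence = 0, seed = 3)
  ds <- simulate_survey_data(cfg)
  expect_true(all(ds$responses$level == 0L))
  tab <- score_table(pool_timepoints(ds))
  expect_true(all(tab$value[tab$metric == "prevalence"] == 0))
})

test_that("analytic marginals are the configured masses", {
  lib <- tiny_library()
  cfg <- generator_config(lib, prevalence = c(ache = 0.2, rash = 0.04, tremor = 0.5,
                                              shedding = 0.3, cramp = 0.1),
                          attribute_levels = list(ache = list(severity = c(0.6, 0.3, 0.1, 0))))
  am <- analytic_marginals(cfg)
  expect_equal(am$value[am$term_id == "ache" & am$metric == "severity"], 0.4)
  expect_equal(am$value[am$term_id == "rash" & am$metric == "prevalence"], 0.04)
  expect_true(is.na(am$value[am$term_id == "rash" & am$metric == "severity"]))
  # a 4% term sits below the 5% prevalence threshold by construction
  expect_lt(am$value[am$term_id == "rash" & am$metric == "prevalence"], 0.05)
})

test_that("empirical scores recover the analytic marginals within 3 MC standard errors", {
  lib <- tiny_library()
  # ~ 2400 pooled administrations
  cfg <- generator_config(lib, n_patients = 1000, prevalence = 0.5, seed = 17,
                          attribute_levels = c(0.3, 0.4, 0.2, 0.1))
  ds <- simulate_survey_data(cfg)
  pooled <- pool_timepoints(ds)
  tab <- score_table(pooled)
  am <- analytic_marginals(cfg)
  key <- function(d) paste(d$term_id, d$metric)
  truth <- stats::setNames(am$value, key(am))
  defined <- !is.na(tab$value) & !tab$not_asked
  for (i in which(defined)) {
    p <- truth[[paste(tab$term_id[i], tab$metric[i])]]
    se <- sqrt(p * (1 - p) / tab$denominator[i])
    expect_lt(abs(tab$value[i] - p), 3 * se + 1e-12)
  }
})

test_that("domain correlation drives Cronbach's alpha monotonically", {
  lib <- tiny_library()
  alphas <- vapply(c(0, 0.5, 0.85), function(lam) {
    cfg <- generator_config(lib, n_patients = 700, prevalence = 0.5,
                            loading = lam, seed = 29)
    pooled <- pool_timepoints(simulate_survey_data(cfg))
    m <- composite_item_scores(pooled, domain = "d1")
    as.numeric(cronbach_alpha(m))
  }, numeric(1))
  expect_lt(abs(alphas[1]), 0.1)              # independent terms: alpha ~ 0
  expect_true(all(diff(alphas) > 0))          # increasing loading raises alpha
})

test_that("analytic alpha matches simulation", {
  lib <- tiny_library()
  cfg <- generator_config(lib, n_patients = 1500, prevalence = 0.4,
                          loading = 0.7, seed = 31)
  terms_d1 <- domain_terms(lib, "d1")
  a_theory <- analytic_alpha(cfg, terms_d1)
  pooled <- pool_timepoints(simulate_survey_data(cfg))
  a_sim <- as.numeric(cronbach_alpha(composite_item_scores(pooled, domain = "d1")))
  expect_equal(a_sim, a_theory, tolerance = 0.05)
  # bivariate normal CDF against closed-form orthant identities
  expect_equal(bvn_cdf(0, 0, 0), 0.25, tolerance = 1e-9)
  expect_equal(bvn_cdf(0, 0, 0.6), 0.25 + asin(0.6) / (2 * pi), tolerance = 1e-8)
  expect_equal(bvn_cdf(Inf, 1, 0.5), stats::pnorm(1), tolerance = 1e-8)
})

test_that("physician panel simulation is seeded and hits its analytic mean", {
  pc <- panel_config(c("ache", "rash"), impact_levels = c(1, 0, 0, 0, 0), seed = 2)
  panel <- simulate_physician_panel(pc)
  expect_equal(nrow(panel), 18)
  expect_true(all(impact_proportion_score(panel, "ache")$value == 0))
  expect_identical(panel, simulate_physician_panel(pc))
  # every defined score is a multiple of 1/9
  pc2 <- panel_config("ache", impact_levels = c(0.2, 0.2, 0.2, 0.2, 0.2), seed = 4)
  s <- impact_proportion_score(simulate_physician_panel(pc2), "ache")
  expect_equal(s$value * 9, round(s$value * 9))
  # long-run mean of the score equals P(impact >= moderate) = 1/9
  p_high <- 1 / 9
  vals <- vapply(1:300, function(s) {
    pc3 <- panel_config("ache", impact_levels = c(1 - p_high, 0, p_high, 0, 0), seed = s)
    impact_proportion_score(simulate_physician_panel(pc3), "ache")$value
  }, numeric(1))
  se <- sqrt(p_high * (1 - p_high) / 9 / 300)
  expect_lt(abs(mean(vals) - p_high), 3 * se)
})

test_that("study-like config places margins on the right side of every threshold", {
  cfg <- study_like_config(n_patients = 50)   # margins are n-free
  am <- analytic_marginals(cfg)
  e <- study_eliminations()
  lib <- proctcae_library()
  prev <- am[am$metric == "prevalence", ]
  low_prev <- prev$term_id[prev$value < 0.05]
  expect_setequal(low_prev, e$term_id[e$step == "prevalence"])
  sev <- am[am$metric == "severity" & !is.na(am$value), ]
  expect_setequal(sev$term_id[sev$value < 0.25], e$term_id[e$step == "severity"])
  amt <- am[am$metric == "amount" & !is.na(am$value), ]
  expect_setequal(amt$term_id[amt$value < 0.25], "hair_loss")
  # calibrated loadings make each published reliability removal its domain's
  # population argmin of |percent change|
  working_vi <- setdiff(lib$term_id,
                        e$term_id[e$step %in% c("prevalence", "severity", "interference", "amount")])
  for (tid in e$term_id[e$step == "reliability"]) {
    dom <- lib$domain[lib$term_id == tid]
    dterms <- intersect(domain_terms(lib, dom), working_vi)
    pc <- analytic_loo_percent_change(cfg, dterms)
    expect_equal(pc$term_id[which.min(abs(pc$percent_change))], tid)
  }
})
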