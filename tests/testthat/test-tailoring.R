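test_that("threshold filter eliminates strictly below threshold and carries missing attributes", {
  lib <- tiny_library()
  vals <- data.frame(metric = c("prevalence", "prevalence", "severity", "severity"),
                     term_id = c("ache", "rash", "ache", "tremor"),
                     value_percent = c(4.9, 5.0, 25.0, 24.9),
                     stringsAsFactors = FALSE)
  scores <- score_table_from_values(vals, lib)
  f <- apply_threshold_filter(scores, lib$term_id, "prevalence", 0.05, carry_forward = FALSE)
  expect_equal(f$eliminated$term_id, "ache")        # 4.9% < 5%
  expect_true("rash" %in% f$retained)               # exactly at threshold retained
  f <- apply_threshold_filter(scores, lib$term_id, "severity", 0.25)
  expect_equal(f$eliminated$term_id, "tremor")      # 24.9% < 25%
  expect_true("ache" %in% f$retained)               # 25.0% retained
  # terms lacking the severity question are carried forward, flagged
  expect_setequal(f$carried_forward, c("rash", "shedding"))
  # nothing eliminated when every score passes
  f <- apply_threshold_filter(scores, lib$term_id, "interference", 0.25)
  expect_equal(nrow(f$eliminated), 0)
  expect_error(apply_threshold_filter(scores, c(lib$term_id, "ghost"), "severity", 0.25),
               class = "proctailor_validation_error")
})

test_that("raising a threshold never shrinks the eliminated set", {
  lib <- proctcae_library()
  scores <- study_score_table()
  prev_elim <- function(th) apply_threshold_filter(scores, lib$term_id, "prevalence", th,
                                                   carry_forward = FALSE)$eliminated$term_id
  thresholds <- c(0.01, 0.03, 0.05, 0.2, 0.5)
  sets <- lapply(thresholds, prev_elim)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("undefined scores follow the stated policy", {
  lib <- tiny_library()
  # a never-presented term has undefined prevalence -> eliminated as not administered
  df <- resp_rows(list("p1", "baseline", "ache", "severity", 3))
  scores <- score_table(pool_timepoints(response_dataset(df, lib)))
  f <- apply_threshold_filter(scores, lib$term_id, "prevalence", 0.05, carry_forward = FALSE)
  expect_setequal(f$eliminated$term_id[f$eliminated$reason == "not_administered"],
                  setdiff(lib$term_id, "ache"))
  # an asked attribute with a 0/0 score is carried forward, not eliminated
  df2 <- resp_rows(list("p1", "baseline", "cramp", "severity", 0),
                   list("p1", "baseline", "cramp", "interference", 2),
                   list("p1", "baseline", "cramp", "frequency", 2))
  scores2 <- score_table(pool_timepoints(response_dataset(df2, lib)))
  f2 <- apply_threshold_filter(scores2, "cramp", "severity", 0.25)
  expect_equal(f2$carried_forward, "cramp")
  expect_equal(nrow(f2$eliminated), 0)
})

test_that("physician step eliminates by impact and validates reintroduction", {
  lib <- tiny_library()
  vals <- data.frame(metric = "prevalence", term_id = "ache", value_percent = 1.0)
  scores <- score_table_from_values(vals, lib)
  config <- tailoring_config(reintroduction_terms = "ache")
  ledger <- tailor_from_scores(scores, lib, config)   # ache eliminated at prevalence
  panel <- rbind(impact_panel("rash", 5), impact_panel("tremor", 1),
                 impact_panel("shedding", 3), impact_panel("cramp", 2))
  phys <- run_physician_step(ledger, panel, lib, config)
  # tremor 1/9 and cramp 2/9 fall below 25%; shedding 3/9 retained; ache reintroduced
  expect_setequal(phys$final_set, c("rash", "shedding", "ache"))
  # reintroducing a never-eliminated term is an error
  bad <- tailoring_config(reintroduction_terms = "rash")
  ledger2 <- tailor_from_scores(scores, lib, bad)
  expect_error(run_physician_step(ledger2, panel, lib, bad),
               "never eliminated", class = "proctailor_validation_error")
  ghost <- tailoring_config(reintroduction_terms = "ghost")
  expect_error(run_physician_step(ledger2, panel, lib, ghost),
               class = "proctailor_lookup_error")
  # all impact scores passing + empty reintroduction -> final = working set
  allpass <- do.call(rbind, lapply(c("rash", "tremor", "shedding", "cramp"),
                                   impact_panel, n_high = 9))
  keep <- run_physician_step(tailor_from_scores(scores, lib, tailoring_config()),
                             allpass, lib, tailoring_config())
  expect_setequal(keep$final_set, c("rash", "tremor", "shedding", "cramp"))
})

test_that("ledger conservation holds on randomized runs and the report enforces it", {
  lib <- proctcae_library()
  withr::with_seed(23, {
    for (i in 1:8) {
      vals <- data.frame(metric = "prevalence", term_id = lib$term_id,
                         value_percent = round(stats::runif(nrow(lib), 0, 60), 1),
                         stringsAsFactors = FALSE)
      scores <- score_table_from_values(vals, lib)
      config <- tailoring_config(prevalence_threshold = stats::runif(1, 0.02, 0.4))
      ledger <- tailor_from_scores(scores, lib, config)
      expect_true(ledger_conservation(ledger))
      expect_equal(length(lib$term_id) - length(ledger_eliminated(ledger)),
                   length(ledger$working))
    }
  })
  # a tampered ledger refuses to render
  r <- replay_study_tailoring()
  broken <- r$ledger
  broken$working <- c(broken$working, "smuggled_term")
  expect_error(build_report(broken, lib), class = "proctailor_integrity_error")
})

test_that("the pipeline is deterministic given dataset and config", {
  fx <- study_like_fixture(seed = 5, n_patients = 60)
  config <- tailoring_config()   # reintroduction needs the large-n fixture
  r1 <- tailor_survey(fx$dataset, fx$panel, config = config)
  r2 <- tailor_survey(fx$dataset, fx$panel, config = config)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$survey$term_ids, r2$survey$term_ids)
})

test_that("report annotates attributes and counts items and domains", {
  r <- replay_study_tailoring()
  lib <- proctcae_library()
  s <- r$survey
  expect_equal(s$item_count, item_count(s$term_ids, lib))
  expect_equal(s$n_domains, length(unique(lib$domain[lib$term_id %in% s$term_ids])))
  expect_true(all(grepl("\\[[APSIF,]+\\]$", s$terms$annotation)))
  expect_true(any(grepl("Fatigue \\[S,I\\]", s$terms$annotation)))
  # empty eliminations: final = library
  vals <- data.frame(metric = "prevalence", term_id = lib$term_id[1], value_percent = 50)
  ledger <- tailor_from_scores(score_table_from_values(vals, lib), lib, tailoring_config())
  survey <- build_report(ledger, lib)
  expect_equal(length(survey$term_ids), nrow(lib))
  expect_equal(survey$item_count, 124)
})

test_that("configuration validates and round-trips through YAML", {
  expect_error(tailoring_config(prevalence_threshold = 0), class = "proctailor_config_error")
  expect_error(tailoring_config(impact_threshold = 1), class = "proctailor_config_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("prevalence_threshold: 0.1", "reintroduction_terms:", "  - headache"), path)
  cfg <- read_tailoring_config(path)
  expect_equal(cfg$prevalence_threshold, 0.1)
  expect_equal(cfg$reintroduction_terms, "headache")
  expect_equal(cfg$proportion_score_threshold, 0.25)
  writeLines("not_a_key: 1", path)
  expect_error(read_tailoring_config(path), class = "proctailor_config_error")
})
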