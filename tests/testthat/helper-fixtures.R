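# Small in-code fixtures shared across the suite.

# five terms over two domains covering every attribute composition the
# pipeline distinguishes: multi-attribute ordinal, presence-only,
# single-ordinal, amount-only
tiny_library <- function() {
  term_library(data.frame(
    term_id      = c("ache", "rash", "tremor", "shedding", "cramp"),
    display_name = c("Ache", "Rash", "Tremor", "Shedding", "Cramp"),
    domain       = c("d1", "d1", "d1", "d2", "d2"),
    presence     = c(0L, 1L, 0L, 0L, 0L),
    severity     = c(1L, 0L, 1L, 0L, 1L),
    interference = c(1L, 0L, 0L, 0L, 1L),
    frequency    = c(0L, 0L, 0L, 0L, 1L),
    amount       = c(0L, 0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  ))
}

# long-format response rows from a compact spec: list(patient, timepoint,
# term, attribute, level)
resp_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], timepoint = r[[2]], term_id = r[[3]],
               attribute = r[[4]], level = as.integer(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

# one-term-per-patient dataset with a given number of administrations where
# `n_pos` of them report the ordinal levels in `levels` (rest level 0)
severity_dataset <- function(library, term, attribute, levels, n_zero = 0) {
  n <- length(levels) + n_zero
  df <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                   timepoint = "baseline", term_id = term,
                   attribute = attribute,
                   level = as.integer(c(levels, rep(0L, n_zero))),
                   stringsAsFactors = FALSE)
  response_dataset(df, library)
}

# independent route to Cronbach's alpha: via the sample covariance matrix
# rather than item variances and the variance of row sums
alpha_cov_oracle <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  S <- stats::cov(m)
  k <- ncol(S)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# a panel data frame where `n_high` of `n` respondents rate the term at or
# above moderate
impact_panel <- function(term, n_high, n = 9) {
  data.frame(respondent_id = sprintf("MD%02d", seq_len(n)), term_id = term,
             impact = rep(c(3L, 1L), c(n_high, n - n_high)),
             stringsAsFactors = FALSE)
}
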