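#' @title Closed-form moments of the generator
#'
#' @description
#' Because the generator is a Gaussian latent-threshold model with levels
#' drawn independently of the thresholding noise, the composite item score of
#' term `t` is `X_t = s_t * M_t`, where `s_t` is the symptomatic indicator
#' (marginal probability `pi_t`) and `M_t` the composite level given
#' symptomatic. Its moments, the pairwise covariances within a domain (via
#' bivariate-normal orthant probabilities with correlation
#' `lambda_t lambda_u`) and hence the population Cronbach's alpha of any term
#' set are available in closed form. These are used to design and verify
#' reliability behaviour of synthetic fixtures without simulation.
#'
#' @name analytic
NULL

#' Bivariate standard normal CDF
#'
#' `P(Z1 <= a, Z2 <= b)` for standard normals with correlation `rho`, by
#' one-dimensional quadrature of the conditional normal CDF.
#'
#' @param a,b upper limits.
#' @param rho correlation in (-1, 1).
#' @return probability.
#' @export
bvn_cdf <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((b - rho * z) / sqrt(1 - rho^2))
  }, -Inf, a, rel.tol = 1e-10)$value
}

# distribution of the composite (max across attributes) given symptomatic
composite_conditional_dist <- function(config, tid) {
  attrs <- term_attributes(config$library, tid)
  if (identical(attrs, "presence")) return(c(`1` = 1))
  dists <- config$attribute_levels[[tid]]
  if (config$attribute_coupling == "comonotone") {
    # all attributes share one uniform; the max is piecewise constant in it
    breaks <- sort(unique(c(0, 1, unlist(lapply(dists, cumsum)))))
    breaks <- breaks[breaks >= 0 & breaks <= 1]
    mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
    lens <- diff(breaks)
    lv <- apply(vapply(dists, function(p) sample_levels(p, mids), numeric(length(mids))), 1, max)
    p <- tapply(lens, factor(lv, levels = 1:4), sum, default = 0)
    stats::setNames(as.numeric(p), 1:4)
  } else {
    # independent attributes: P(max <= l) is the product of the CDFs
    cdf <- function(l) prod(vapply(dists, function(p) sum(p[seq_len(l)]), numeric(1)))
    p <- diff(c(0, vapply(1:4, cdf, numeric(1))))
    stats::setNames(p, 1:4)
  }
}

composite_moments <- function(config, tid) {
  p <- composite_conditional_dist(config, tid)
  lv <- as.numeric(names(p))
  list(m1 = sum(lv * p), m2 = sum(lv^2 * p))
}

#' Population covariance matrix of composite scores within a domain
#'
#' @param config a [generator_config()].
#' @param terms term ids (must share one domain).
#' @return covariance matrix of the composite item scores.
#' @export
analytic_domain_covariance <- function(config, terms) {
  library <- config$library
  doms <- unique(library$domain[match(terms, library$term_id)])
  if (length(doms) != 1) abort_config("terms must belong to a single domain")
  k <- length(terms)
  pi_t <- config$prevalence[terms]
  tau <- stats::qnorm(pi_t)
  mom <- lapply(terms, function(t) composite_moments(config, t))
  m1 <- vapply(mom, `[[`, numeric(1), "m1")
  m2 <- vapply(mom, `[[`, numeric(1), "m2")
  lam <- config$loading[terms]
  S <- diag(pi_t * m2 - (pi_t * m1)^2, k)
  dimnames(S) <- list(terms, terms)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      p11 <- bvn_cdf(tau[i], tau[j], lam[i] * lam[j])
      S[i, j] <- S[j, i] <- m1[i] * m1[j] * (p11 - pi_t[i] * pi_t[j])
    }
  }
  S
}

alpha_from_cov <- function(S) {
  k <- ncol(S)
  if (k < 2) return(NA_real_)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

#' Population Cronbach's alpha of a term set under the generator
#'
#' @param config a [generator_config()].
#' @param terms term ids of one domain.
#' @return scalar alpha.
#' @export
analytic_alpha <- function(config, terms) {
  alpha_from_cov(analytic_domain_covariance(config, terms))
}

#' Population leave-one-out percent change in alpha
#'
#' @param config a [generator_config()].
#' @param terms term ids of one domain (>= 3 for eligibility).
#' @return data frame `term_id`, `percent_change`.
#' @export
analytic_loo_percent_change <- function(config, terms) {
  S <- analytic_domain_covariance(config, terms)
  a1 <- alpha_from_cov(S)
  pc <- vapply(seq_along(terms), function(j) {
    100 * (alpha_from_cov(S[-j, -j, drop = FALSE]) - a1) / a1
  }, numeric(1))
  data.frame(term_id = terms, percent_change = pc, stringsAsFactors = FALSE)
}

#' Calibrate a weak loading so a designated term is the pruning candidate
#'
#' Solves for the designated term's loading at which its population
#' leave-one-out percent change in domain alpha crosses zero. At that loading
#' the term is the argmin of |percent change| within the domain (the other,
#' strong-loading terms sit at clearly negative percent changes), so the
#' reliability step removes it deterministically up to Monte-Carlo noise.
#'
#' @param config a [generator_config()].
#' @param terms the domain's working term set.
#' @param designated the term whose loading is tuned.
#' @param lower,upper search bracket for the loading.
#' @return the calibrated loading.
#' @export
calibrate_weak_loading <- function(config, terms, designated, lower = 0.02, upper = NULL) {
  if (!designated %in% terms) abort_config("designated term must be among terms")
  if (is.null(upper)) upper <- max(config$loading[setdiff(terms, designated)]) - 0.01
  pc_at <- function(lam) {
    config$loading[designated] <- lam
    res <- analytic_loo_percent_change(config, terms)
    res$percent_change[res$term_id == designated]
  }
  stats::uniroot(pc_at, lower = lower, upper = upper, tol = 1e-4)$root
}
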