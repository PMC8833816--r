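#' Specification of a paired non-inferiority power calculation
#'
#' Describes the design: `n` women assessed by both methods, a reference
#' method with accuracy `accuracy_reference`, a new method whose true
#' accuracy differs by `true_difference` (new minus reference), a
#' non-inferiority margin, and a correlation between the two methods'
#' per-record correctness indicators.  The joint distribution of the paired
#' correctness indicators is
#' `p11 = pa * pb + correlation * sqrt(pa (1-pa) pb (1-pb))`, which must
#' yield a valid four-cell probability vector.
#'
#' @param n paired sample size.
#' @param accuracy_reference reference-method accuracy, in (0, 1).
#' @param true_difference true accuracy difference, new minus reference.
#' @param margin non-inferiority margin (> 0), default 0.05.
#' @param correlation correlation of the correctness indicators.
#' @param alpha one-sided significance level.
#' @param n_sims Monte-Carlo replicates.
#' @param seed RNG seed (optional; `NULL` leaves the RNG state alone).
#' @return a `power_spec` list (includes the implied cell probabilities
#'   `cells = c(p11, p10, p01, p00)`).
#' @export
power_spec <- function(n = 160, accuracy_reference = 0.85,
                       true_difference = 0.05, margin = 0.05,
                       correlation = 0.15, alpha = 0.05, n_sims = 10000,
                       seed = NULL) {
  if (margin <= 0) stopf("margin must be > 0")
  pa <- accuracy_reference + true_difference   # new method
  pb <- accuracy_reference
  if (pa < 0 || pa > 1 || pb <= 0 || pb >= 1)
    stopf("accuracy_reference +/- true_difference must stay within [0, 1]")
  cells <- paired_correctness_probs(pa, pb, correlation)
  structure(list(n = as.integer(n), accuracy_reference = accuracy_reference,
                 true_difference = true_difference, margin = margin,
                 correlation = correlation, alpha = alpha,
                 n_sims = as.integer(n_sims), seed = seed, cells = cells),
            class = "power_spec")
}

#' Joint cell probabilities of two correlated correctness indicators
#'
#' @param p_new,p_ref marginal probabilities of a correct call.
#' @param correlation correlation of the two Bernoulli indicators.
#' @return named probability vector `c(p11, p10, p01, p00)` (new x ref).
#' @export
paired_correctness_probs <- function(p_new, p_ref, correlation) {
  p11 <- p_new * p_ref +
    correlation * sqrt(p_new * (1 - p_new) * p_ref * (1 - p_ref))
  cells <- c(p11 = p11, p10 = p_new - p11, p01 = p_ref - p11,
             p00 = 1 - p_new - p_ref + p11)
  if (any(cells < -1e-12) || any(cells > 1 + 1e-12)) {
    lo <- max((p_new + p_ref - 1 - p_new * p_ref) /
                sqrt(p_new * (1 - p_new) * p_ref * (1 - p_ref)),
              -sqrt(p_new * p_ref / ((1 - p_new) * (1 - p_ref))))
    hi <- min(sqrt(p_new * (1 - p_ref) / ((1 - p_new) * p_ref)),
              sqrt(p_ref * (1 - p_new) / ((1 - p_ref) * p_new)))
    stopf(paste0("correlation %.3f incompatible with marginals ",
                 "(%.3f, %.3f); feasible range is roughly [%.3f, %.3f]"),
          correlation, p_new, p_ref, lo, hi)
  }
  pmin(pmax(cells, 0), 1)
}

#' Restricted-MLE score test for paired non-inferiority (Tango)
#'
#' One-sided score test of `H0: p_new - p_ref <= -margin` against
#' non-inferiority, for paired binary outcomes.  `b` is the number of pairs
#' correct by the new method only, `c` correct by the reference only, out of
#' `n` pairs.  The nuisance discordant probability is replaced by its
#' maximum-likelihood estimate restricted to the null boundary (the positive
#' root of the score quadratic), giving the usual well-calibrated statistic
#' `z = ((b - c)/n + margin) / se`.  Vectorised over `b` and `c`.
#'
#' @param b,c discordant-pair counts.
#' @param n number of pairs.
#' @param margin non-inferiority margin.
#' @return list with `z` (statistic) and `p` (one-sided normal p-value).
#' @export
tango_score_test <- function(b, c, n, margin) {
  d0 <- -margin                       # null difference p10 - p01
  w <- 1 - d0
  m <- n - b - c
  # stationary point of the restricted log-likelihood: 2n p^2 - Bq p - c d0 w = 0
  Bq <- w * (b + c) - 2 * d0 * (c + m)
  disc <- Bq^2 + 8 * n * c * d0 * w
  p01 <- (Bq + sqrt(pmax(disc, 0))) / (4 * n)
  p01 <- pmin(pmax(p01, pmax(0, -d0)), (1 - d0) / 2)
  v <- (2 * p01 + d0 - d0^2) / n      # p10 + p01 - d0^2, with p10 = p01 + d0
  z <- ifelse(v > 0, ((b - c) / n - d0) / sqrt(v),
              ifelse((b - c) / n - d0 > 0, Inf, -Inf))
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Monte-Carlo power of the paired non-inferiority test
#'
#' Simulates paired correct/incorrect indicators under the design in a
#' [power_spec()], applies [tango_score_test()] at the given margin and
#' alpha, and returns the rejection rate with a binomial Monte-Carlo CI.
#' At the boundary null (`true_difference = -margin`) the rejection rate
#' estimates the test's actual size.
#'
#' @param spec a [power_spec()].
#' @return object of class `power_estimate`: list with `power`, `mc_se`,
#'   `ci` (95% Monte-Carlo interval), `n_sims`, and the `spec`.
#' @export
noninferiority_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  draws <- stats::rmultinom(spec$n_sims, spec$n, spec$cells)
  test <- tango_score_test(draws[2, ], draws[3, ], spec$n, spec$margin)
  reject <- test$z > stats::qnorm(1 - spec$alpha)
  power <- mean(reject)
  mc_se <- sqrt(power * (1 - power) / spec$n_sims)
  structure(list(power = power, mc_se = mc_se,
                 ci = c(max(0, power - 1.96 * mc_se),
                        min(1, power + 1.96 * mc_se)),
                 n_sims = spec$n_sims, spec = spec),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Paired non-inferiority power (n = %d, margin = %.3f, alpha = %.3f)\n",
    s$n, s$margin, s$alpha))
  cat(sprintf("  reference accuracy %.3f, true difference %+.3f, r = %.2f\n",
              s$accuracy_reference, s$true_difference, s$correlation))
  cat(sprintf("  power = %.3f (MC 95%% CI %.3f-%.3f, %d simulations)\n",
              x$power, x$ci[1], x$ci[2], x$n_sims))
  invisible(x)
}
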