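#' Boyd-Richerson conformist learning rule
#'
#' Constructs the classical three-demonstrator conformist-bias rule
#' \eqn{p(q) = q + D\,q(1-q)(2q-1)}, where \eqn{D \in [0, 1]} measures the
#' strength of the positive frequency-dependent bias. At \eqn{D = 1} the rule
#' coincides with majority-of-three copying, i.e. the probability that at
#' least two of three independently sampled demonstrators show the focal
#' trait.
#'
#' @param D Bias strength, a single number in \eqn{[0, 1]}.
#' @return An object of class `boyd_richerson_rule`.
#' @seealso [boyd_richerson_prob()], [logistic_rule()]
#' @examples
#' rule <- boyd_richerson_rule(D = 1)
#' boyd_richerson_prob(0.6, rule) # 0.648, the majority-of-three probability
#' @export
boyd_richerson_rule <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0 || D > 1) {
    stop("`D` must be a single number in [0, 1]; got ", format(D), call. = FALSE)
  }
  structure(list(D = as.numeric(D)), class = "boyd_richerson_rule")
}

#' Logistic (discrete-choice) learning rule
#'
#' Constructs the logistic frequency-dependent learning rule
#' \eqn{p(q) = q^\beta / (q^\beta + (1-q)^\beta)}, optionally mixed with a
#' uniform behavioural error: with probability `alpha` the learner picks a
#' trait at random, and with probability `1 - alpha` it applies the
#' conformist rule. The conformity strength `beta` may take any finite real
#' value: `beta > 1` is conformist transmission (hyper-conformity),
#' `beta = 1` unbiased copying, `0 < beta < 1` weak conformity, and
#' `beta < 0` anti-conformity.
#'
#' The rule has a random-utility micro-foundation: it is the choice rule of a
#' learner maximising \eqn{\ln q_j + \epsilon_j / \beta} over traits
#' \eqn{j}, with i.i.d. standard Gumbel (Extreme Value Type-I) noise
#' \eqn{\epsilon_j}; see [sample_choice()].
#'
#' @param beta Conformity strength, any finite real number.
#' @param alpha Error rate in \eqn{[0, 1]}; default 0 (no behavioural error).
#' @return An object of class `logistic_rule`.
#' @seealso [logistic_prob()], [multi_logistic_probs()], [classify_regime()]
#' @examples
#' logistic_prob(0.6, logistic_rule(beta = 2.8))        # about 0.757
#' logistic_prob(1.0, logistic_rule(beta = 3, alpha = 0.1)) # plateau 0.95
#' @export
logistic_rule <- function(beta, alpha = 0) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop("`beta` must be a single finite number; got ", format(beta), call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single number in [0, 1]; got ", format(alpha),
         call. = FALSE)
  }
  structure(list(beta = as.numeric(beta), alpha = as.numeric(alpha)),
            class = "logistic_rule")
}

#' @export
print.logistic_rule <- function(x, ...) {
  reg <- classify_regime(x$beta)
  cat(sprintf("Logistic learning rule: beta = %g (%s), alpha = %g\n",
              x$beta, reg$label, x$alpha))
  invisible(x)
}

#' @export
print.boyd_richerson_rule <- function(x, ...) {
  cat(sprintf("Boyd-Richerson learning rule: D = %g\n", x$D))
  invisible(x)
}

check_freq <- function(q, what = "q") {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    bad <- q[!is.finite(q) | q < 0 | q > 1][1L]
    stop("`", what, "` must lie in [0, 1]; got ", format(bad), call. = FALSE)
  }
  as.numeric(q)
}

#' Adoption probability under the Boyd-Richerson rule
#'
#' Evaluates \eqn{p(q) = q + D\,q(1-q)(2q-1)}, the probability of adopting
#' the focal trait when a fraction `q` of demonstrators exhibits it.
#' Vectorised over `q`.
#'
#' @param q Demonstrator frequency (or frequencies) in \eqn{[0, 1]}.
#' @param rule A [boyd_richerson_rule()].
#' @return Adoption probabilities, guaranteed in \eqn{[0, 1]}.
#' @export
boyd_richerson_prob <- function(q, rule) {
  stopifnot(inherits(rule, "boyd_richerson_rule"))
  q <- check_freq(q)
  q + rule$D * q * (1 - q) * (2 * q - 1)
}

## Stable two-trait logistic response: computed in logit form
## 1/(1 + exp(-beta * (log q - log(1-q)))) so that large |beta| cannot
## overflow q^beta.
logistic_core <- function(q, beta) {
  p <- stats::plogis(beta * (log(q) - log1p(-q)))
  # continuity at the endpoints, valid for beta > 0 only (callers enforce)
  p[q == 0] <- if (beta > 0) 0 else NaN
  p[q == 1] <- if (beta > 0) 1 else NaN
  p
}

#' Adoption probability under the logistic rule
#'
#' Evaluates the two-trait logistic learning rule
#' \eqn{p(q) = q^\beta/(q^\beta + (1-q)^\beta)}, mixed with uniform error if
#' the rule carries `alpha > 0`:
#' \eqn{p'(q) = \alpha/2 + (1-\alpha)\,p(q)}. Computation uses the logit
#' form \eqn{1/(1 + e^{-\beta(\ln q - \ln(1-q))})} for numerical stability
#' at large \eqn{|\beta|}. For \eqn{\beta > 0} the endpoints are resolved by
#' continuity, \eqn{p(0) = 0} and \eqn{p(1) = 1}; for \eqn{\beta \le 0} the
#' limit at unanimity diverges, so `q` of 0 or 1 is an error. Vectorised
#' over `q`.
#'
#' @inheritParams boyd_richerson_prob
#' @param rule A [logistic_rule()].
#' @return Adoption probabilities in \eqn{[0, 1]}.
#' @export
logistic_prob <- function(q, rule) {
  stopifnot(inherits(rule, "logistic_rule"))
  q <- check_freq(q)
  if (rule$beta <= 0 && any(q == 0 | q == 1)) {
    stop("degenerate input: q = 0 or 1 with beta <= 0 has no well-defined ",
         "adoption probability (the log-odds limit diverges)", call. = FALSE)
  }
  p <- logistic_core(q, rule$beta)
  rule$alpha / 2 + (1 - rule$alpha) * p
}

check_freq_vector <- function(freqs, tol = 1e-9) {
  freqs <- check_freq(freqs, "freqs")
  if (length(freqs) < 2L) {
    stop("a frequency vector needs at least 2 traits", call. = FALSE)
  }
  if (abs(sum(freqs) - 1) > tol) {
    stop("trait frequencies must sum to 1 (got ", format(sum(freqs), digits = 12),
         ")", call. = FALSE)
  }
  freqs
}

#' Multi-trait logistic choice probabilities
#'
#' Extends the logistic rule to \eqn{K \ge 2} traits:
#' \eqn{p_i = q_i^\beta / \sum_j q_j^\beta}, mixed with a uniform error
#' component \eqn{\alpha/K + (1-\alpha) p_i} when the rule carries
#' `alpha > 0`. Computed via a log-space softmax
#' (\eqn{p_i \propto e^{\beta \ln q_i}}) with max subtraction, so large
#' \eqn{|\beta|} cannot overflow. With any zero frequency present,
#' \eqn{\beta > 0} is required (a zero-share trait then has probability 0 by
#' continuity); for \eqn{\beta \le 0} zero shares are a degenerate input.
#'
#' @param freqs Vector of trait frequencies summing to 1 (length \eqn{\ge 2}).
#' @param rule A [logistic_rule()].
#' @return A probability vector of the same length as `freqs`, summing to 1.
#' @export
multi_logistic_probs <- function(freqs, rule) {
  stopifnot(inherits(rule, "logistic_rule"))
  freqs <- check_freq_vector(freqs)
  if (rule$beta <= 0 && any(freqs == 0)) {
    stop("degenerate input: zero trait frequency with beta <= 0", call. = FALSE)
  }
  lw <- rule$beta * log(freqs) # -Inf for zero shares when beta > 0
  lw <- lw - max(lw)
  w <- exp(lw)
  p <- w / sum(w)
  rule$alpha / length(freqs) + (1 - rule$alpha) * p
}

#' Sample a trait by the random-utility (Gumbel-max) mechanism
#'
#' Draws trait choices from the logistic rule's micro-foundation: each draw
#' picks the trait \eqn{j} maximising \eqn{\ln q_j + \epsilon_j/\beta} with
#' i.i.d. standard Gumbel noise \eqn{\epsilon_j}, so that choice
#' probabilities equal [multi_logistic_probs()]. With `alpha > 0` the learner
#' instead picks uniformly at random with probability `alpha`. Because the
#' sampler never evaluates the closed-form probabilities, it serves as an
#' independent Monte-Carlo oracle for the logistic family.
#'
#' Draws consume the R random number stream; use [set.seed()] for
#' reproducibility.
#'
#' @param freqs Vector of trait frequencies summing to 1.
#' @param rule A [logistic_rule()] with `beta > 0`.
#' @param n Number of independent draws (default 1).
#' @return An integer vector of `n` trait indices in `1:length(freqs)`.
#' @export
sample_choice <- function(freqs, rule, n = 1) {
  stopifnot(inherits(rule, "logistic_rule"))
  freqs <- check_freq_vector(freqs)
  if (rule$beta <= 0) {
    stop("sample_choice requires beta > 0 (the Gumbel-max utility scale is 1/beta)",
         call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)
  k <- length(freqs)
  lq <- log(freqs) # -Inf for zero shares: those traits are never chosen
  eps <- matrix(-log(-log(stats::runif(n * k))), nrow = n, ncol = k)
  idx <- max.col(matrix(lq, n, k, byrow = TRUE) + eps / rule$beta,
                 ties.method = "first")
  if (rule$alpha > 0) {
    err <- stats::runif(n) < rule$alpha
    if (any(err)) idx[err] <- sample.int(k, sum(err), replace = TRUE)
  }
  idx
}

#' Classify the conformity regime of a logistic rule
#'
#' Maps the conformity strength `beta` to its qualitative regime:
#' `beta > 1` hyper-conformity (conformist transmission in the classical,
#' disproportionate-majority sense), `beta = 1` unbiased copying,
#' `0 < beta < 1` weak conformity, `beta <= 0` anti-conformity. `beta = 0`
#' is flagged in the `note` field as the uniform-random boundary case
#' (every trait chosen with probability \eqn{1/K} regardless of frequency).
#'
#' @param beta A single finite number.
#' @return A list of class `conformity_regime` with elements `beta`, `label`
#'   (one of `"hyper-conformity"`, `"unbiased"`, `"weak-conformity"`,
#'   `"anti-conformity"`) and `note` (possibly `NA`).
#' @export
classify_regime <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop("`beta` must be a single finite number", call. = FALSE)
  }
  label <- if (beta > 1) "hyper-conformity"
  else if (beta == 1) "unbiased"
  else if (beta > 0) "weak-conformity"
  else "anti-conformity"
  note <- if (beta == 0) {
    "boundary case: choice is uniform over traits, independent of frequency"
  } else {
    NA_character_
  }
  structure(list(beta = beta, label = label, note = note),
            class = "conformity_regime")
}

#' @export
print.conformity_regime <- function(x, ...) {
  cat(sprintf("beta = %g: %s\n", x$beta, x$label))
  if (!is.na(x$note)) cat("note: ", x$note, "\n", sep = "")
  invisible(x)
}
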