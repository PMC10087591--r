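#' @name conformity_estimators
#' @title Estimating conformity strength from choice-frequency data
#'
#' @description
#' The logistic learning rule implies a linear relationship between log odds:
#' \deqn{\ln\frac{p(q)}{1-p(q)} = \beta \ln\frac{q}{1-q},}
#' so the conformity strength \eqn{\beta} is the slope of a through-origin
#' regression of response log odds on demonstrator log odds, and
#' \eqn{\beta > 1} ("significantly above 1") is evidence of conformist
#' transmission. [fit_beta_binary()] implements this two-trait regression;
#' [fit_beta_multitrait()] generalises it to \eqn{K \ge 2} traits via the
#' pairwise identity \eqn{\ln(p_A/p_B) = \beta \ln(q_A/q_B)};
#' [fit_error_mixture()] fits the error-mixture model
#' \eqn{p'(q) = \alpha/2 + (1-\alpha)\,q^\beta/(q^\beta + (1-q)^\beta)}
#' by maximum likelihood, which is robust to departures from unanimous
#' majorities.
#'
#' Observed proportions of 0 or 1 have infinite log odds. The default
#' `unanimity = "correct"` applies the Haldane-Anscombe continuity
#' correction (add 0.5 to counts, 1 to the total) to the affected rows only,
#' leaving exact interior data untouched; `unanimity = "drop"` removes such
#' rows instead (with a warning).
NULL

new_beta_estimate <- function(beta_hat, se, df, n_points, method,
                              correction_applied = FALSE, alpha_hat = NA_real_,
                              alpha_se = NA_real_, boundary = FALSE,
                              intercept = NA_real_, options = list()) {
  p_value <- if (is.na(se) || se == 0) {
    # exact (zero-residual) data: the test degenerates to a comparison
    as.numeric(beta_hat <= 1 + sqrt(.Machine$double.eps))
  } else if (is.finite(df)) {
    stats::pt((beta_hat - 1) / se, df = df, lower.tail = FALSE)
  } else {
    stats::pnorm((beta_hat - 1) / se, lower.tail = FALSE)
  }
  structure(list(beta_hat = beta_hat, se = se, p_value = p_value, df = df,
                 n_points = n_points, method = method,
                 correction_applied = correction_applied,
                 alpha_hat = alpha_hat, alpha_se = alpha_se,
                 boundary = boundary, intercept = intercept,
                 options = options),
            class = "beta_estimate")
}

#' @export
print.beta_estimate <- function(x, ...) {
  cat("Conformity strength estimate (", x$method, ")\n", sep = "")
  cat(sprintf("  beta_hat = %.6g  (se = %.4g, n = %d)\n",
              x$beta_hat, x$se, x$n_points))
  if (!is.na(x$alpha_hat)) {
    cat(sprintf("  alpha_hat = %.6g  (se = %.4g)\n", x$alpha_hat, x$alpha_se))
  }
  cat(sprintf("  one-sided test of beta > 1: p = %.4g\n", x$p_value))
  cat("  regime: ", classify_regime(x$beta_hat)$label, "\n", sep = "")
  if (x$correction_applied) {
    cat("  note: continuity correction applied to unanimous rows\n")
  }
  if (isTRUE(x$boundary)) cat("  note: estimate on a parameter boundary\n")
  invisible(x)
}

## Through-origin weighted least squares with analytic slope and t test.
slope_fit <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  if (length(x) < 2L || sum(w * x^2) <= 0) {
    stop("insufficient data: need at least 2 usable points with non-zero ",
         "demonstrator log odds", call. = FALSE)
  }
  b <- sum(w * x * y) / sum(w * x^2)
  df <- length(x) - 1L
  rss <- sum(w * (y - b * x)^2)
  # residuals at floating-point noise level mean the data lie exactly on the
  # line; report an exact fit rather than an astronomically small se
  if (rss <= 1e-24 * max(sum(w * y^2), .Machine$double.xmin)) rss <- 0
  se <- sqrt(max(rss, 0) / df / sum(w * x^2))
  list(b = b, se = se, df = df)
}

## Extract one (q, phat, n) row per group from a two-trait table, focal trait
## first in alphabetical order, applying the unanimity policy.
binary_points <- function(tab, unanimity) {
  traits <- sort(unique(tab$trait))
  if (length(traits) != 2L) {
    stop("expected exactly 2 traits, found ", length(traits), call. = FALSE)
  }
  focal <- traits[1L]
  rows <- tab[tab$trait == focal, , drop = FALSE]
  q <- rows$freq
  n <- rows$observers
  phat <- rows$adoptions / n
  corrected <- FALSE
  deg_p <- phat <= 0 | phat >= 1
  deg_q <- q <= 0 | q >= 1
  if (unanimity == "correct") {
    if (any(deg_p)) {
      phat[deg_p] <- (rows$adoptions[deg_p] + 0.5) / (n[deg_p] + 1)
      corrected <- TRUE
    }
    if (any(deg_q)) {
      q[deg_q] <- (q[deg_q] * n[deg_q] + 0.5) / (n[deg_q] + 1)
      corrected <- TRUE
    }
    keep <- rep(TRUE, length(q))
  } else {
    keep <- !(deg_p | deg_q)
    if (!all(keep)) {
      warning(sum(!keep), " unanimous row(s) dropped from the regression",
              call. = FALSE)
    }
  }
  list(q = q[keep], phat = phat[keep], n = n[keep], corrected = corrected)
}

#' Fit conformity strength by the binary log-odds regression
#'
#' Regresses observed adoption log odds on demonstrator log odds through the
#' origin; the slope is the conformity strength \eqn{\hat\beta}, tested
#' one-sided against \eqn{H_0: \beta \le 1} with a t reference on
#' (points - 1) degrees of freedom. See [conformity_estimators] for the
#' model.
#'
#' @param tab A two-trait [choice_table()].
#' @param weighting `"binomial"` (default) weights each point by
#'   \eqn{n \hat p (1-\hat p)}, the inverse of the approximate sampling
#'   variance of the empirical logit, which keeps the t test close to its
#'   nominal level; `"ols"` is plain unweighted least squares. The two
#'   coincide on exact (noiseless) data.
#' @param unanimity `"correct"` (default, Haldane-Anscombe continuity
#'   correction on unanimous rows) or `"drop"`.
#' @param intercept If `TRUE`, also fits a free intercept as a diagnostic
#'   for miscalibrated data; the reported slope then comes from the
#'   two-parameter fit.
#' @return A `beta_estimate` object.
#' @examples
#' tab <- simulate_choices(logistic_rule(2), freq_levels = seq(0.1, 0.9, 0.1),
#'                         observers = 200, seed = 1)
#' fit_beta_binary(tab)
#' @export
fit_beta_binary <- function(tab, weighting = c("binomial", "ols"),
                            unanimity = c("correct", "drop"),
                            intercept = FALSE) {
  tab <- validate_choice_table(tab)
  weighting <- match.arg(weighting)
  unanimity <- match.arg(unanimity)
  pts <- binary_points(tab, unanimity)
  if (length(pts$q) < 2L) {
    stop("insufficient data: fewer than 2 usable groups", call. = FALSE)
  }
  if (all(pts$phat <= 0) || all(pts$phat >= 1)) {
    stop("estimation impossible: all adoption proportions degenerate",
         call. = FALSE)
  }
  x <- log(pts$q) - log1p(-pts$q)
  y <- log(pts$phat) - log1p(-pts$phat)
  w <- if (weighting == "binomial") pts$n * pts$phat * (1 - pts$phat) else NULL
  icpt <- NA_real_
  if (intercept) {
    fit <- stats::lm(y ~ x, weights = w)
    sm <- summary(fit)$coefficients
    est <- new_beta_estimate(sm["x", 1], sm["x", 2], fit$df.residual,
                             length(x), "log-odds regression (binary)",
                             pts$corrected, intercept = sm["(Intercept)", 1],
                             options = list(weighting = weighting,
                                            unanimity = unanimity,
                                            intercept = TRUE))
    return(est)
  }
  sf <- slope_fit(x, y, w)
  new_beta_estimate(sf$b, sf$se, sf$df, length(x),
                    "log-odds regression (binary)", pts$corrected,
                    options = list(weighting = weighting,
                                   unanimity = unanimity, intercept = FALSE))
}

#' Fit conformity strength from multi-trait choice data
#'
#' For every group and every unordered pair of traits (taken once, in a
#' fixed alphabetical ordering to avoid pseudo-replication), computes the
#' log adoption ratio \eqn{\ln(\hat p_A/\hat p_B)} and the log demonstrator
#' ratio \eqn{\ln(q_A/q_B)}, then fits a single through-origin slope pooled
#' over all pairs. With two traits this reduces exactly to
#' [fit_beta_binary()].
#'
#' @param tab A [choice_table()] with \eqn{K \ge 2} traits.
#' @inheritParams fit_beta_binary
#' @return A `beta_estimate` object.
#' @export
fit_beta_multitrait <- function(tab, unanimity = c("correct", "drop")) {
  tab <- validate_choice_table(tab)
  unanimity <- match.arg(unanimity)
  xs <- numeric(0)
  ys <- numeric(0)
  corrected <- FALSE
  dropped <- 0L
  for (g in split(tab, tab$group)) {
    g <- g[order(g$trait), , drop = FALSE]
    n <- g$observers[1L]
    cnt <- g$adoptions
    if (unanimity == "correct" && any(cnt <= 0 | cnt >= n)) {
      cnt <- cnt + 0.5 # correct all cells of the group so ratios stay coherent
      corrected <- TRUE
    }
    k <- nrow(g)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (g$freq[i] <= 0 || g$freq[j] <= 0 || cnt[i] <= 0 || cnt[j] <= 0) {
          dropped <- dropped + 1L
          next
        }
        xs <- c(xs, log(g$freq[i]) - log(g$freq[j]))
        ys <- c(ys, log(cnt[i]) - log(cnt[j]))
      }
    }
  }
  if (dropped > 0L) {
    warning(dropped, " trait pair(s) dropped (zero frequency or count)",
            call. = FALSE)
  }
  if (length(xs) == 0L) {
    stop("estimation impossible: no usable trait pairs remain", call. = FALSE)
  }
  sf <- slope_fit(xs, ys)
  new_beta_estimate(sf$b, sf$se, sf$df, length(xs),
                    "pairwise log-ratio regression (multi-trait)", corrected,
                    options = list(unanimity = unanimity))
}

#' Maximum-likelihood fit of the error-mixture conformity model
#'
#' Fits \eqn{p'(q) = \alpha/2 + (1-\alpha)\,q^\beta/(q^\beta+(1-q)^\beta)}
#' to two-trait choice data by maximising the binomial likelihood of the
#' adoption counts over \eqn{\alpha \in [0,1]} and
#' \eqn{\beta \in [-\code{bound}, \code{bound}]}. Standard errors come from
#' the observed information (inverse Hessian at the optimum); estimates on a
#' parameter boundary are flagged (`boundary = TRUE`) rather than silently
#' accepted, and their standard errors should be treated with caution. The
#' one-sided \eqn{\beta > 1} test uses a normal reference.
#'
#' Unlike the log-odds regression, the mixture likelihood handles unanimous
#' demonstrator frequencies (`q` of 0 or 1) directly: there the model
#' predicts the error plateau \eqn{\alpha/2} and \eqn{1 - \alpha/2}.
#'
#' @param tab A two-trait [choice_table()] with at least 3 distinct
#'   frequency levels, at least one of which is informative about
#'   \eqn{\beta} (not in \{0, 1/2, 1\}).
#' @param bound Box half-width for \eqn{\beta} (default 50).
#' @param fix_alpha Optionally fix \eqn{\alpha} at a value in \eqn{[0,1]}
#'   (e.g. 0 for the pure logistic model) and profile only \eqn{\beta}.
#' @return A `beta_estimate` with `alpha_hat` and `alpha_se` filled in.
#' @export
fit_error_mixture <- function(tab, bound = 50, fix_alpha = NULL) {
  tab <- validate_choice_table(tab)
  traits <- sort(unique(tab$trait))
  if (length(traits) != 2L) {
    stop("expected exactly 2 traits, found ", length(traits), call. = FALSE)
  }
  rows <- tab[tab$trait == traits[1L], , drop = FALSE]
  q <- rows$freq
  n <- rows$observers
  y <- rows$adoptions
  if (length(unique(q)) < 3L) {
    stop("insufficient data: need at least 3 distinct frequency levels ",
         "for the two-parameter mixture", call. = FALSE)
  }
  if (all(q %in% c(0, 0.5, 1))) {
    stop("estimation impossible: beta is unidentifiable when all ",
         "demonstrator frequencies lie in {0, 0.5, 1}", call. = FALSE)
  }
  eps <- 1e-12
  has_endpoint <- any(q == 0 | q == 1)
  nll <- function(par) {
    alpha <- if (is.null(fix_alpha)) par[1L] else fix_alpha
    beta <- par[length(par)]
    if (beta <= 0 && has_endpoint) return(1e10) # degenerate region
    p <- alpha / 2 + (1 - alpha) * logistic_core(q, beta)
    p <- pmin(pmax(p, eps), 1 - eps)
    -sum(y * log(p) + (n - y) * log1p(-p))
  }
  starts <- if (is.null(fix_alpha)) {
    list(c(0.01, 1), c(0.1, 2.5), c(0.3, 5), c(0.05, 0.5), c(0.2, -1))
  } else {
    list(1, 2.5, 5, 0.5, -1)
  }
  lower <- if (is.null(fix_alpha)) c(0, -bound) else -bound
  upper <- if (is.null(fix_alpha)) c(1, bound) else bound
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(unlist(st), nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("optimizer failed to converge from any starting point", call. = FALSE)
  }
  if (best$convergence != 0) {
    stop("optimizer did not converge: ", best$message, call. = FALSE)
  }
  alpha_hat <- if (is.null(fix_alpha)) best$par[1L] else fix_alpha
  beta_hat <- best$par[length(best$par)]
  btol <- 1e-6
  boundary <- (is.null(fix_alpha) &&
                 (alpha_hat <= btol || alpha_hat >= 1 - btol)) ||
    abs(abs(beta_hat) - bound) <= btol
  hess <- stats::optimHess(best$par, nll)
  ses <- rep(NA_real_, length(best$par))
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (!is.null(vc)) {
    d <- diag(as.matrix(vc))
    ses <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  beta_se <- ses[length(ses)]
  alpha_se <- if (is.null(fix_alpha)) ses[1L] else NA_real_
  if (!is.finite(beta_se)) beta_se <- NA_real_
  new_beta_estimate(beta_hat, beta_se, Inf, length(q),
                    "error-mixture maximum likelihood",
                    alpha_hat = alpha_hat, alpha_se = alpha_se,
                    boundary = boundary,
                    options = list(bound = bound, fix_alpha = fix_alpha))
}

#' Power and calibration study for the conformity test
#'
#' Monte-Carlo harness for the one-sided \eqn{\beta > 1} test of
#' [fit_beta_binary()]: for each value in `betas`, simulates `replicates`
#' choice tables with [simulate_choices()] and records the fraction rejected
#' at the given level. The `beta = 1` row estimates the type-I error.
#'
#' @param betas Grid of generating conformity strengths.
#' @param freq_levels,observers,groups Design passed to [simulate_choices()].
#' @param replicates Number of Monte-Carlo replicates per beta (>= 1).
#' @param seed Base seed; per-replicate seeds are derived deterministically.
#' @param level Test level (default 0.05).
#' @param alpha Error rate of the generating rule (default 0).
#' @return A `data.frame` with columns `beta`, `replicates`, `rejections`,
#'   `rejection_rate`.
#' @export
power_study <- function(betas, freq_levels, observers, replicates, seed,
                        groups = 1, level = 0.05, alpha = 0) {
  replicates <- check_count(replicates, "replicates")
  stopifnot(length(betas) >= 1)
  res <- lapply(seq_along(betas), function(i) {
    rule <- logistic_rule(betas[i], alpha)
    rej <- 0L
    for (r in seq_len(replicates)) {
      tab <- simulate_choices(rule, freq_levels, observers, groups,
                              seed = derive_seed(seed, i, r))
      est <- fit_beta_binary(tab)
      if (est$p_value < level) rej <- rej + 1L
    }
    data.frame(beta = betas[i], replicates = replicates, rejections = rej,
               rejection_rate = rej / replicates)
  })
  do.call(rbind, res)
}
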