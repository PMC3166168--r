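#' Lagged association rate model family
#'
#' Candidate descriptions of temporal social structure, fitted to the
#' per-lag numerator/denominator contributions of the LAR estimator:
#'
#' * `rd_cc` (k = 1): g(tau) = a. Rapid disassociation + constant
#'   companions: a fraction 1 - a of associations dissolves within one
#'   sampling period, the rest are stable.
#' * `rd_ca` (k = 2): g(tau) = a exp(-b tau). Rapid disassociation +
#'   casual acquaintances decaying to zero.
#' * `rd_cc_ca` (k = 3): g(tau) = a + c exp(-b tau). Decay to a non-zero
#'   plateau of constant companions.
#' * `rd_2ca` (k = 4): g(tau) = a exp(-b tau) + c exp(-d tau). Two levels
#'   of casual acquaintances: fission on a short time scale 1/b and a
#'   longer scale 1/d. Reported with b >= d.
#' * `linear` (k = 2): g(tau) = f + e tau. Gradual change in association
#'   over time (used on the day scale).
#'
#' Amplitudes a, c lie in \[0, 1\] with a + c <= 1; the rate b is
#' non-negative; the slow rate d and the linear slope e may be negative (a
#' negative rate means association *increases* with lag). Inside the
#' likelihood g is clamped to \[1e-9, 1 - 1e-9\].
#'
#' @param name one of `"rd_cc"`, `"rd_ca"`, `"rd_cc_ca"`, `"rd_2ca"`,
#'   `"linear"`
#' @return a `lar_model` list: `name`, `k`, `par_names`, `g(theta, tau)`,
#'   plus internal raw-parameter transforms used by the optimiser
#' @export
lar_model <- function(name = c("rd_cc", "rd_ca", "rd_cc_ca", "rd_2ca",
                               "linear")) {
  name <- match.arg(name)
  mk <- function(k, par_names, g, to_theta, start) {
    structure(list(name = name, k = k, par_names = par_names, g = g,
                   to_theta = to_theta, start = start),
              class = "lar_model")
  }
  switch(name,
    rd_cc = mk(1, "a",
      g = function(th, tau) rep(th[["a"]], length(tau)),
      to_theta = function(r) c(a = stats::plogis(r[1])),
      start = function() stats::rnorm(1, 0, 1.5)),
    rd_ca = mk(2, c("a", "b"),
      g = function(th, tau) th[["a"]] * exp(-th[["b"]] * tau),
      to_theta = function(r) c(a = stats::plogis(r[1]), b = exp(r[2])),
      start = function() c(stats::rnorm(1, 0, 1.5),
                           stats::runif(1, log(0.005), log(5)))),
    rd_cc_ca = mk(3, c("a", "c", "b"),
      g = function(th, tau) th[["a"]] + th[["c"]] * exp(-th[["b"]] * tau),
      to_theta = function(r) {
        s <- stats::plogis(r[1]); w <- stats::plogis(r[2])
        c(a = s * w, c = s * (1 - w), b = exp(r[3]))
      },
      start = function() c(stats::rnorm(2, 0, 1.5),
                           stats::runif(1, log(0.005), log(5)))),
    rd_2ca = mk(4, c("a", "b", "c", "d"),
      g = function(th, tau) th[["a"]] * exp(-th[["b"]] * tau) +
        th[["c"]] * exp(-th[["d"]] * tau),
      to_theta = function(r) {
        s <- stats::plogis(r[1]); w <- stats::plogis(r[2])
        c(a = s * w, b = exp(r[3]), c = s * (1 - w), d = r[4])
      },
      start = function() c(stats::rnorm(2, 0, 1.5),
                           stats::runif(1, log(0.05), log(5)),
                           exp(stats::runif(1, log(0.001), log(0.5))) *
                             sample(c(1, -1), 1, prob = c(0.85, 0.15)))),
    linear = mk(2, c("f", "e"),
      g = function(th, tau) th[["f"]] + th[["e"]] * tau,
      to_theta = function(r) c(f = stats::plogis(r[1]), e = r[2]),
      start = function() c(stats::rnorm(1, 0, 1.5),
                           stats::rnorm(1, 0, 0.05)))
  )
}

#' Evaluate a LAR model
#'
#' @param model a [lar_model()] (or its name)
#' @param theta named parameter vector on the natural scale
#' @param tau lag(s)
#' @param clamp if TRUE, clamp to \[1e-9, 1 - 1e-9\] as in the likelihood
#' @return g(tau | theta)
#' @export
evaluate_lar_model <- function(model, theta, tau, clamp = FALSE) {
  if (is.character(model)) model <- lar_model(model)
  g <- model$g(theta, tau)
  if (clamp) g <- pmin(pmax(g, 1e-9), 1 - 1e-9)
  g
}

.curve_counts <- function(curve) {
  if (inherits(curve, "lar_curve")) {
    ok <- curve$den > 0
    list(tau = curve$lags[ok], num = curve$num[ok], den = curve$den[ok])
  } else {
    stopifnot(all(c("tau", "num", "den") %in% names(curve)))
    ok <- curve$den > 0
    list(tau = curve$tau[ok], num = curve$num[ok], den = curve$den[ok])
  }
}

.lnql <- function(g, num, den) {
  g <- pmin(pmax(g, 1e-9), 1 - 1e-9)
  sum(num * log(g) + (den - num) * log(1 - g))
}

#' Fit a LAR model by binomial quasi-likelihood
#'
#' Maximises sum over lags of N(tau) log g + (D(tau) - N(tau)) log(1 - g)
#' where N, D are the LAR estimator's per-lag numerator and denominator.
#' Multi-start optimisation in an unconstrained parameterisation (seeded by
#' the caller's RNG state). For `rd_2ca` the two exponential components are
#' reported with b >= d (fast component first).
#'
#' @param curve a [lar_curve()] or a list/data.frame with `tau`, `num`,
#'   `den`
#' @param model a [lar_model()] or model name
#' @param n_starts random restarts (default 20)
#' @return object of class `lar_fit`: `model`, `theta`, `lnQL`,
#'   `converged`, `k`, `n_lags`, `timescales` (1/rate for each rate
#'   parameter; negative when the rate is negative)
#' @export
fit_lar_model <- function(curve, model, n_starts = 20) {
  if (is.character(model)) model <- lar_model(model)
  cc <- .curve_counts(curve)
  if (length(unique(cc$tau)) < model$k) {
    stop(sprintf("model %s has %d parameters but only %d distinct lags supplied",
                 model$name, model$k, length(unique(cc$tau))))
  }
  obj <- function(r) {
    th <- model$to_theta(r)
    -.lnql(model$g(th, cc$tau), cc$num, cc$den)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    r0 <- model$start()
    fit <- tryCatch(
      if (length(r0) == 1) {
        stats::optim(r0, obj, method = "Brent", lower = -20, upper = 20)
      } else {
        stats::optim(r0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
      },
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(model = model$name, theta = NULL, lnQL = -Inf,
                          converged = FALSE, k = model$k,
                          n_lags = length(unique(cc$tau)),
                          timescales = NULL), class = "lar_fit"))
  }
  theta <- model$to_theta(best$par)
  if (model$name == "rd_2ca" && theta[["d"]] > theta[["b"]]) {
    theta <- c(a = theta[["c"]], b = theta[["d"]],
               c = theta[["a"]], d = theta[["b"]])
  }
  ts <- lar_timescales(theta)
  structure(list(model = model$name, theta = theta,
                 lnQL = -best$value, converged = best$convergence == 0,
                 k = model$k, n_lags = length(unique(cc$tau)),
                 timescales = ts), class = "lar_fit")
}

#' @export
print.lar_fit <- function(x, ...) {
  cat(sprintf("lar_fit: %s (k = %d), lnQL = %.3f, converged = %s\n",
              x$model, x$k, x$lnQL, x$converged))
  if (!is.null(x$theta)) {
    cat("  theta:", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                          collapse = ", "), "\n")
  }
  if (!is.null(x$timescales)) {
    cat("  timescales:", paste(sprintf("%s = %.4g", names(x$timescales),
                                       x$timescales), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Time scales implied by exponential decay rates
#'
#' The decay rate b (or d) of a casual-acquaintance component corresponds
#' to a dissociation time scale of 1/b lag units: a rate of 0.20 per
#' minute means associations dissolve over about 5 minutes, a rate of 0.01
#' over about 100. A negative rate yields a negative "time scale",
#' signalling association that *increases* with lag.
#'
#' @param theta named parameter vector; entries named `b` and/or `d` are
#'   interpreted as rates
#' @return named vector `1/b`, `1/d` (NULL if no rate parameter present)
#' @export
lar_timescales <- function(theta) {
  rates <- intersect(names(theta), c("b", "d"))
  if (length(rates) == 0) return(NULL)
  stats::setNames(1 / unlist(theta[rates]), paste0("1/", rates))
}

#' Overdispersion factor for QAIC
#'
#' Pearson chi-square over residual degrees of freedom of a fitted model,
#' floored at 1. Estimated once from the most general candidate and shared
#' across the set.
#'
#' @param curve counts (see [fit_lar_model()])
#' @param fit a `lar_fit`
#' @return c-hat >= 1
#' @export
estimate_chat <- function(curve, fit) {
  cc <- .curve_counts(curve)
  g <- evaluate_lar_model(fit$model, fit$theta, cc$tau, clamp = TRUE)
  pearson <- sum((cc$num - cc$den * g)^2 / (cc$den * g * (1 - g)))
  df <- length(cc$tau) - fit$k
  if (df <= 0) return(1)
  max(1, pearson / df)
}

#' QAIC of a fitted LAR model
#'
#' QAIC = -2 lnQL / c-hat + 2k; reduces to AIC at c-hat = 1. Lower values
#' indicate better support.
#'
#' @param fit a `lar_fit`
#' @param chat overdispersion factor (from [estimate_chat()])
#' @return QAIC value (+Inf for unconverged fits)
#' @export
qaic <- function(fit, chat = 1) {
  if (!is.finite(fit$lnQL)) return(Inf)
  -2 * fit$lnQL / chat + 2 * fit$k
}

#' Fit a candidate set and select by QAIC
#'
#' Fits every candidate model, estimates the overdispersion c-hat from the
#' most-parameterised candidate, and picks the minimum-QAIC fit.
#'
#' @param curve counts (see [fit_lar_model()])
#' @param models character vector of model names (default: the four
#'   exponential minute-scale candidates)
#' @param n_starts restarts per model
#' @return list: `best` (a `lar_fit`), `fits` (all fits), `chat`, `table`
#'   (data.frame model, k, lnQL, QAIC, dQAIC sorted by QAIC)
#' @export
select_lar_model <- function(curve,
                             models = c("rd_cc", "rd_ca", "rd_cc_ca", "rd_2ca"),
                             n_starts = 20) {
  fits <- lapply(models, function(m) fit_lar_model(curve, m, n_starts))
  names(fits) <- models
  conv <- vapply(fits, function(f) is.finite(f$lnQL), logical(1))
  if (!any(conv)) stop("no candidate model converged")
  ks <- vapply(fits, function(f) f$k, numeric(1))
  general <- fits[[which(conv & ks == max(ks[conv]))[1]]]
  chat <- estimate_chat(curve, general)
  q <- vapply(fits, qaic, numeric(1), chat = chat)
  tab <- data.frame(model = models, k = ks, lnQL =
                      vapply(fits, function(f) f$lnQL, numeric(1)),
                    QAIC = q, dQAIC = q - min(q), row.names = NULL)
  tab <- tab[order(tab$QAIC), ]
  list(best = fits[[which.min(q)]], fits = fits, chat = chat, table = tab)
}

#' Benjamini-Yekutieli adjusted critical values
#'
#' Critical significance values k alpha / (m sum_{i=1..m} 1/i) for ranks
#' k = 1..m: the false discovery rate control valid under arbitrary
#' dependence between the m comparisons. At m = 4 and alpha = 0.05 the
#' largest-rank critical value is 0.024.
#'
#' @param m number of comparisons
#' @param alpha family-wise FDR level
#' @return numeric vector of critical values for ranks 1..m
#' @export
by_critical_values <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  (seq_len(m) * alpha) / (m * sum(1 / seq_len(m)))
}

#' Compare fitted model parameters between population classes
#'
#' Pooled two-sample t-test per parameter (df = n1 + n2 - 2) comparing
#' per-population parameter estimates grouped into two classes, with
#' Benjamini-Yekutieli FDR control across the parameters: p-values are
#' ranked and the step-up rule flags all ranks up to the largest k with
#' p_(k) <= k alpha / (m sum 1/i).
#'
#' @param estimates data.frame of per-population parameter estimates (one
#'   column per parameter, one row per population)
#' @param class factor/character of length nrow(estimates) with exactly two
#'   levels
#' @param alpha FDR level (default 0.05)
#' @return data.frame: parameter, per-class means and SEs, t, df, p,
#'   by_critical (that parameter's rank critical value), significant
#' @export
compare_classes <- function(estimates, class, alpha = 0.05) {
  class <- as.factor(class)
  stopifnot(nlevels(class) == 2, nrow(estimates) == length(class))
  lv <- levels(class)
  if (min(table(class)) < 2) stop("need at least 2 populations per class")
  rows <- lapply(names(estimates), function(p) {
    v1 <- estimates[[p]][class == lv[1]]
    v2 <- estimates[[p]][class == lv[2]]
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0 && mean(v1) == mean(v2)) {
      return(data.frame(parameter = p,
                        mean_1 = mean(v1), se_1 = 0, mean_2 = mean(v2),
                        se_2 = 0, t = 0, df = length(v1) + length(v2) - 2,
                        p = 1))
    }
    tt <- tryCatch(stats::t.test(v1, v2, var.equal = TRUE),
                   error = function(e) NULL)
    data.frame(parameter = p,
               mean_1 = mean(v1), se_1 = stats::sd(v1) / sqrt(length(v1)),
               mean_2 = mean(v2), se_2 = stats::sd(v2) / sqrt(length(v2)),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = length(v1) + length(v2) - 2,
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  out <- do.call(rbind, rows)
  names(out)[c(2, 3, 4, 5)] <- c(paste0("mean_", lv[1]), paste0("se_", lv[1]),
                                 paste0("mean_", lv[2]), paste0("se_", lv[2]))
  m <- nrow(out)
  crit <- by_critical_values(m, alpha)
  rk <- rank(out$p, ties.method = "first")
  out$by_critical <- crit[rk]
  ok <- which(sort(out$p) <= crit)
  kmax <- if (length(ok) > 0) max(ok) else 0
  out$significant <- rk <= kmax & !is.na(out$p)
  out
}
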