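#' Simple ratio association index
#'
#' SRI = x / (x + y_AB + y_A + y_B): the proportion of sampling periods in
#' which the dyad was seen in the same group, out of the periods in which at
#' least one of the two was identified. Under complete detection (every
#' individual located in every scan, as in a laboratory arena) the simple
#' ratio is unbiased for the true co-membership probability.
#'
#' @param x periods together in one group
#' @param y_AB periods both observed, in different groups
#' @param y_A,y_B periods only the first (second) individual was observed
#' @return association index in \[0, 1\]
#' @export
simple_ratio_index <- function(x, y_AB, y_A, y_B) {
  d <- x + y_AB + y_A + y_B
  if (any(d == 0)) stop("undefined dyad: all counts zero (never observed)")
  x / d
}

#' Half-weight association index
#'
#' HWI = x / (x + y_AB + (y_A + y_B) / 2). Down-weights periods in which
#' only one member was identified; commonly used for field data where joint
#' detection is less likely than single detection. Identical to the simple
#' ratio when detection is complete (y_A = y_B = 0).
#'
#' @inheritParams simple_ratio_index
#' @return association index in \[0, 1\]
#' @export
half_weight_index <- function(x, y_AB, y_A, y_B) {
  d <- x + y_AB + (y_A + y_B) / 2
  if (any(d == 0)) stop("undefined dyad: all counts zero (never observed)")
  x / d
}

#' Dyadic association matrix
#'
#' Computes the symmetric matrix of pairwise association indices for every
#' dyad, together with the per-dyad co-occurrence counts `x` and
#' denominators `d` that the social-differentiation estimator and the
#' permutation machinery need.
#'
#' @param obs an [observation_set()]
#' @param index `"simple_ratio"` (default) or `"half_weight"`
#' @return object of class `assoc_matrix`: list with `ids`, `AI` (symmetric,
#'   zero diagonal), `x`, `denom`, `index`, `n_periods`
#' @export
association_matrix <- function(obs, index = c("simple_ratio", "half_weight")) {
  index <- match.arg(index)
  m <- membership_matrix(obs)
  am_from_membership(m, obs$individuals, index)
}

# Shared kernel: membership-code matrix (periods x individuals, NA = unseen)
# -> association matrix. Used directly by the bootstrap to avoid rebuilding
# observation_set objects per replicate.
am_from_membership <- function(m, ids, index = "simple_ratio") {
  n <- length(ids)
  seen <- !is.na(m)
  storage.mode(seen) <- "integer"
  n_i <- colSums(seen)
  both <- crossprod(seen)                 # periods both observed
  # co-membership: for each period, individuals sharing a group code
  x <- matrix(0, n, n)
  for (t in seq_len(nrow(m))) {
    g <- m[t, ]
    ok <- which(!is.na(g))
    if (length(ok) < 2) next
    same <- outer(g[ok], g[ok], "==")
    x[ok, ok] <- x[ok, ok] + same
  }
  diag(x) <- 0
  y_ab <- both - x
  diag(y_ab) <- 0
  only_i <- outer(n_i, n_i, "+") - 2 * both   # y_A + y_B
  denom <- if (index == "simple_ratio") {
    x + y_ab + only_i
  } else {
    x + y_ab + only_i / 2
  }
  ai <- matrix(0, n, n)
  pos <- denom > 0
  ai[pos] <- x[pos] / denom[pos]
  diag(ai) <- 0
  dimnames(ai) <- dimnames(x) <- dimnames(denom) <- list(ids, ids)
  structure(
    list(ids = ids, AI = ai, x = x, denom = denom, index = index,
         n_periods = nrow(m)),
    class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  ut <- upper.tri(x$AI)
  cat(sprintf(
    "assoc_matrix (%s): %d individuals, %d periods, mean AI = %.3f, CV = %.3f\n",
    x$index, length(x$ids), x$n_periods, mean(x$AI[ut]), cv_of_ais(x)))
  invisible(x)
}

#' Gregariousness (mean experienced group size, self excluded)
#'
#' For each individual, the mean over its observations of (group size - 1):
#' 0 for an animal always alone, 2 for one always in a trio. Individuals
#' never observed get NA with a warning.
#'
#' @param obs an [observation_set()]
#' @return named numeric vector, one value per individual
#' @export
gregariousness <- function(obs) {
  m <- membership_matrix(obs)
  out <- rep(NA_real_, obs$N)
  names(out) <- obs$individuals
  for (t in seq_len(nrow(m))) {
    g <- m[t, ]
    ok <- !is.na(g)
    if (!any(ok)) next
    sizes <- table(g[ok])
    sz <- as.integer(sizes[as.character(g[ok])])
    idx <- which(ok)
    out[idx] <- ifelse(is.na(out[idx]), 0, out[idx]) + (sz - 1)
  }
  n_obs <- colSums(!is.na(m))
  never <- n_obs == 0
  if (any(never)) {
    warning("individual(s) never observed: ",
            paste(obs$individuals[never], collapse = ", "))
  }
  out[!never] <- out[!never] / n_obs[!never]
  out[never] <- NA_real_
  out
}

#' Coefficient of variation of association indices
#'
#' SD / mean over the off-diagonal (upper triangle) association indices.
#' High CV relative to a permutation null indicates preferred/avoided
#' companions. Sample (n - 1) SD convention.
#'
#' @param am an [association_matrix()] result (or a plain symmetric matrix)
#' @return non-negative real
#' @export
cv_of_ais <- function(am) {
  ai <- if (inherits(am, "assoc_matrix")) am$AI else am
  v <- ai[upper.tri(ai)]
  if (length(v) < 2) stop("need at least 2 dyads for a CV")
  mu <- mean(v)
  if (mu == 0) stop("CV undefined: mean association index is 0")
  stats::sd(v) / mu
}

#' Social differentiation
#'
#' Estimates S, the coefficient of variation of the *true* dyadic
#' association probabilities, correcting the observed variance of the
#' indices for binomial sampling noise. Values below 0.3 indicate a nearly
#' homogeneous society, above 0.5 well differentiated, above 2.0 extremely
#' differentiated. Also returns `power_r`, the implied correlation between
#' true and estimated indices (a power diagnostic for whether the sampling
#' effort can reveal the true social system).
#'
#' Default is a closed-form method-of-moments estimator:
#' S^2 = max(0, var(AI) - mean(AI (1 - AI) / d)) / mean(AI)^2,
#' with var() the sample variance over dyads. `method = "mle"` instead fits
#' a beta-binomial to the per-dyad counts (x, d) by maximum likelihood and
#' reports the CV of the fitted beta.
#'
#' @param am an [association_matrix()] result (needs `x` and `denom`)
#' @param method `"moment"` (default) or `"mle"`
#' @return list with `S`, `power_r`, `mean_AI`, `method`, and
#'   `interpretation` (text band for S)
#' @export
social_differentiation <- function(am, method = c("moment", "mle")) {
  method <- match.arg(method)
  stopifnot(inherits(am, "assoc_matrix"))
  ut <- upper.tri(am$AI)
  ok <- am$denom[ut] > 0
  ai <- am$AI[ut][ok]
  d <- am$denom[ut][ok]
  if (length(ai) < 2) stop("need at least 2 defined dyads")
  mu <- mean(ai)
  if (mu == 0) stop("social differentiation undefined: mean AI is 0")
  noise <- mean(ai * (1 - ai) / d)
  if (all(d <= 1)) warning("single sampling period: S has essentially no power")
  if (method == "moment") {
    s2 <- max(0, stats::var(ai) - noise) / mu^2
    s <- sqrt(s2)
  } else {
    x <- am$x[ut][ok]
    nll <- function(par) {
      m <- stats::plogis(par[1])
      s_ <- exp(par[2])
      v <- (s_ * m)^2
      if (v >= m * (1 - m)) return(1e10)
      a <- m * (m * (1 - m) / v - 1)
      b <- (1 - m) * (m * (1 - m) / v - 1)
      -sum(lchoose(d, x) + lbeta(x + a, d - x + b) - lbeta(a, b))
    }
    fit <- stats::optim(c(stats::qlogis(min(max(mu, 1e-4), 1 - 1e-4)),
                          log(0.5)), nll, method = "Nelder-Mead")
    s <- exp(fit$par[2])
  }
  power_r <- (s * mu) / sqrt(s^2 * mu^2 + noise)
  interp <- if (s < 0.3) "little variation (homogeneous)"
  else if (s <= 0.5) "moderately differentiated"
  else if (s <= 2.0) "well differentiated"
  else "extremely differentiated"
  list(S = s, power_r = power_r, mean_AI = mu, method = method,
       interpretation = interp)
}

#' Population-level association summary
#'
#' Mean association index, its CV, mean gregariousness, and social
#' differentiation with its power diagnostic, for one population.
#'
#' @param obs an [observation_set()]
#' @param index association index variant (see [association_matrix()])
#' @return list: `mean_AI`, `cv_AI`, `gregariousness` (per individual),
#'   `mean_gregariousness`, `S`, `power_r`
#' @export
association_summary <- function(obs, index = "simple_ratio") {
  am <- association_matrix(obs, index)
  sd_ <- social_differentiation(am)
  greg <- gregariousness(obs)
  list(mean_AI = mean(am$AI[upper.tri(am$AI)]),
       cv_AI = cv_of_ais(am),
       gregariousness = greg,
       mean_gregariousness = mean(greg, na.rm = TRUE),
       S = sd_$S, power_r = sd_$power_r)
}
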