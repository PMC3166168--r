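#' Lagged association rate curve
#'
#' Estimates g(tau), the probability that two individuals associated at
#' time t are still associated tau time units later, for every realised
#' lag. Summing over ordered dyads (i, j) and period pairs (t, t + tau):
#' numerator = associated at both times; denominator = associated at t and
#' both still identified at t + tau (under complete detection, simply the
#' associated pairs at t). Under random association the curve sits at the
#' [null_association_rate()]. Two time scales are supported:
#'
#' * `"minute"`: lags are within-day minute differences; period pairs never
#'   span days (no lag bridges the multi-day gaps between sessions).
#' * `"day"`: period pairs share the same within-day minute and differ in
#'   study day; the lag unit is the difference in sampling *occasion*
#'   (day rank), with the realised mean day difference reported alongside.
#'
#' @param obs an [observation_set()]
#' @param scale `"minute"` or `"day"`
#' @return object of class `lar_curve`: data.frame-like list with `lags`,
#'   `g`, `num`, `den`, `n_pairs`, `lag_days` (day scale only), `scale`,
#'   `null_rate`, and `se` (NULL until [lar_jackknife()] fills it)
#' @export
lar_curve <- function(obs, scale = c("minute", "day")) {
  scale <- match.arg(scale)
  m <- membership_matrix(obs)
  per <- obs$periods
  np <- nrow(per)
  # per-period comembership matrices and presence outer products
  A <- vector("list", np)
  Pres <- vector("list", np)
  for (t in seq_len(np)) {
    g <- m[t, ]
    a <- outer(g, g, "==")
    a[is.na(a)] <- FALSE
    diag(a) <- FALSE
    storage.mode(a) <- "double"
    A[[t]] <- a
    p <- !is.na(g)
    Pres[[t]] <- outer(p, p) * 1
  }
  num <- c(); den <- c(); npair <- c(); lagd <- c()
  add <- function(lag, t1, t2, daydiff = NA_real_) {
    key <- as.character(lag)
    d_contrib <- sum(A[[t1]] * Pres[[t2]])  # associated at t, both seen at t+tau
    num[key] <<- (if (key %in% names(num)) num[[key]] else 0) +
      sum(A[[t1]] * A[[t2]])
    den[key] <<- (if (key %in% names(den)) den[[key]] else 0) + d_contrib
    npair[key] <<- (if (key %in% names(npair)) npair[[key]] else 0) + d_contrib
    if (!is.na(daydiff)) {
      lagd[key] <<- daydiff  # constant per occasion-lag under a regular design
    }
  }
  if (scale == "minute") {
    for (d in unique(per$day)) {
      idx <- which(per$day == d)
      idx <- idx[order(per$minute[idx])]
      nd <- length(idx)
      if (nd < 2) next
      for (i1 in 1:(nd - 1)) for (i2 in (i1 + 1):nd) {
        add(per$minute[idx[i2]] - per$minute[idx[i1]], idx[i1], idx[i2])
      }
    }
  } else {
    days <- sort(unique(per$day))
    base <- if (length(days) > 1) min(diff(days)) else 1
    for (mnt in unique(per$minute)) {
      idx <- which(per$minute == mnt)
      idx <- idx[order(per$day[idx])]
      nd <- length(idx)
      if (nd < 2) next
      for (i1 in 1:(nd - 1)) for (i2 in (i1 + 1):nd) {
        dd <- per$day[idx[i2]] - per$day[idx[i1]]
        add(dd, idx[i1], idx[i2], dd)
      }
    }
  }
  lag_vals <- as.numeric(names(num))
  o <- order(lag_vals)
  num <- as.numeric(num)[o]; den <- as.numeric(den)[o]
  npair <- as.numeric(npair)[o]
  # day-scale lags are reported in sampling units: day difference divided
  # by the design's base revisit interval (3 days -> lag 1, 6 -> 2, ...)
  lag_units <- if (scale == "day") lag_vals[o] / base else lag_vals[o]
  structure(list(
    lags = lag_units,
    g = ifelse(den > 0, num / den, NA_real_),
    num = num, den = den, n_pairs = npair,
    lag_days = if (scale == "day") as.numeric(lagd)[o] else NULL,
    scale = scale,
    null_rate = null_association_rate(obs),
    se = NULL), class = "lar_curve")
}

#' @export
print.lar_curve <- function(x, ...) {
  cat(sprintf("lar_curve (%s scale): %d lags, null rate = %.4f\n",
              x$scale, length(x$lags), x$null_rate))
  df <- as.data.frame(x)
  print(utils::head(df, 10))
  if (length(x$lags) > 10) cat(sprintf("  ... %d more lags\n", length(x$lags) - 10))
  invisible(x)
}

#' @export
as.data.frame.lar_curve <- function(x, ...) {
  df <- data.frame(lag = x$lags, g = x$g, num = x$num, den = x$den,
                   n_pairs = x$n_pairs)
  if (!is.null(x$se)) df$se <- x$se
  if (!is.null(x$lag_days)) df$lag_days <- x$lag_days
  df$null_rate <- x$null_rate
  df
}

#' Lagged association rate at one lag
#'
#' @inheritParams lar_curve
#' @param tau time lag (minutes within a day, or occasion difference for
#'   the day scale)
#' @return list `g`, `n_pairs` (g is NA with n_pairs 0 when no period pair
#'   realises the lag)
#' @export
lagged_association_rate <- function(obs, tau, scale = c("minute", "day")) {
  cur <- lar_curve(obs, scale)
  i <- match(tau, cur$lags)
  if (is.na(i)) return(list(g = NA_real_, n_pairs = 0))
  list(g = cur$g[i], n_pairs = cur$n_pairs[i])
}

#' Null association rate
#'
#' Expected lagged association rate if individuals associated at random:
#' the mean over individuals and periods of g_i(t) / (N_t - 1), where
#' g_i(t) is the number of associates of i at t and N_t the number of
#' individuals observed at t. Periods with fewer than two individuals
#' observed are excluded.
#'
#' @param obs an [observation_set()]
#' @return real in \[0, 1\]
#' @export
null_association_rate <- function(obs) {
  m <- membership_matrix(obs)
  tot <- 0; cnt <- 0
  for (t in seq_len(nrow(m))) {
    g <- m[t, ]
    ok <- which(!is.na(g))
    nt <- length(ok)
    if (nt < 2) next
    sizes <- table(g[ok])
    gi <- as.integer(sizes[as.character(g[ok])]) - 1
    tot <- tot + sum(gi / (nt - 1))
    cnt <- cnt + nt
  }
  if (cnt == 0) return(NA_real_)
  tot / cnt
}

#' Moving-average smoothing of a LAR curve
#'
#' Re-estimates g in sliding windows over adjacent lags, pooling the
#' numerator and denominator contributions (ratio of sums, not mean of
#' ratios). The window is expressed as a number of contributing
#' (dyad, period-pair) terms: at each lag the neighbourhood is grown
#' symmetrically until it holds at least `window` contributions (or the
#' whole curve). `window = 1` is the identity.
#'
#' @param curve a [lar_curve()]
#' @param window positive number of contributions to pool (default 10000)
#' @return a `lar_curve` with smoothed `g` (SEs, if present, are dropped)
#' @export
smooth_lar <- function(curve, window = 10000) {
  stopifnot(inherits(curve, "lar_curve"), window >= 1)
  nl <- length(curve$lags)
  g <- numeric(nl)
  for (l in seq_len(nl)) {
    lo <- hi <- l
    while (sum(curve$n_pairs[lo:hi]) < window && (lo > 1 || hi < nl)) {
      # expand toward the nearer lag first, keeping the window symmetric
      grow_lo <- lo > 1 && (hi == nl || (l - lo) <= (hi - l))
      if (grow_lo) lo <- lo - 1 else hi <- hi + 1
    }
    g[l] <- sum(curve$num[lo:hi]) / sum(curve$den[lo:hi])
  }
  out <- curve
  out$g <- g
  out$se <- NULL
  out
}

#' Jackknife standard errors for a LAR curve
#'
#' Delete-one-block jackknife across sampling periods: blocks are either
#' 5-minute chunks of each session (`"five_minutes"`) or whole study days
#' (`"one_day"`). For each block the curve is re-estimated without it and
#' SE^2(tau) = (k - 1)/k * sum_b (g_(-b) - mean(g_(-b)))^2 over the k
#' blocks. Lags not estimable in every leave-one-out sample get NA.
#'
#' @param obs an [observation_set()]
#' @param scale `"minute"` or `"day"`
#' @param block `"five_minutes"` or `"one_day"`
#' @return the [lar_curve()] with `se` filled in and attribute `k_blocks`
#' @export
lar_jackknife <- function(obs, scale = c("minute", "day"),
                          block = c("five_minutes", "one_day")) {
  scale <- match.arg(scale)
  block <- match.arg(block)
  full <- lar_curve(obs, scale)
  per <- obs$periods
  bid <- if (block == "five_minutes") {
    paste(per$day, per$minute %/% 5)
  } else {
    as.character(per$day)
  }
  blocks <- unique(bid)
  k <- length(blocks)
  if (k < 2) stop("jackknife needs at least 2 blocks")
  gk <- matrix(NA_real_, nrow = k, ncol = length(full$lags))
  for (b in seq_len(k)) {
    keep <- which(bid != blocks[b])
    rec <- obs$records[obs$records$period %in% keep, ]
    rec_df <- data.frame(day = per$day[rec$period],
                         minute = per$minute[rec$period],
                         group_id = rec$group_id,
                         individual_id = rec$individual_id)
    sub <- observation_set(rec_df, individuals = obs$individuals)
    cur <- lar_curve(sub, scale)
    # align day-scale curves by actual day difference (the leave-out's own
    # base interval may differ from the full design's)
    pos <- if (scale == "day") match(cur$lag_days, full$lag_days)
           else match(cur$lags, full$lags)
    gk[b, pos[!is.na(pos)]] <- cur$g[!is.na(pos)]
  }
  se <- apply(gk, 2, function(v) {
    if (anyNA(v)) return(NA_real_)
    sqrt((k - 1) / k * sum((v - mean(v))^2))
  })
  full$se <- se
  attr(full, "k_blocks") <- k
  full
}
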