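# Independent brute-force oracles and small random-data generators.
# Everything here enumerates directly over the long-format records or over
# plain loops, deliberately avoiding the package's vectorised kernels.

random_obs <- function(N = sample(3:8, 1), n_days = sample(1:3, 1),
                       ppd = sample(2:7, 1), p_absent = 0.2) {
  ids <- sprintf("a%02d", seq_len(N))
  days <- sort(sample(1:20, n_days))
  rows <- list()
  for (d in days) for (mnt in seq_len(ppd) - 1) {
    present <- which(stats::runif(N) > p_absent)
    if (length(present) == 0) next
    k <- sample(seq_len(N), 1)
    grp <- sample(seq_len(k), length(present), replace = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      day = d, minute = mnt, group_id = paste0("g", grp),
      individual_id = ids[present])
  }
  observation_set(do.call(rbind, rows), individuals = ids)
}

# long-format record lookup: group of individual i in period p (NA if unseen)
.rec_group <- function(obs, p, i) {
  r <- obs$records
  g <- r$group_id[r$period == p & r$individual_id == i]
  if (length(g) == 0) NA_character_ else g
}

oracle_dyad_counts <- function(obs, i, j) {
  x <- yab <- ya <- yb <- 0L
  for (p in obs$periods$index) {
    gi <- .rec_group(obs, p, i)
    gj <- .rec_group(obs, p, j)
    if (!is.na(gi) && !is.na(gj)) {
      if (gi == gj) x <- x + 1L else yab <- yab + 1L
    } else if (!is.na(gi)) ya <- ya + 1L
    else if (!is.na(gj)) yb <- yb + 1L
  }
  c(x = x, y_AB = yab, y_A = ya, y_B = yb)
}

oracle_ai_matrix <- function(obs, index = "simple_ratio") {
  n <- obs$N
  ai <- matrix(0, n, n, dimnames = list(obs$individuals, obs$individuals))
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    ct <- oracle_dyad_counts(obs, obs$individuals[a], obs$individuals[b])
    d <- if (index == "simple_ratio") sum(ct) else
      ct["x"] + ct["y_AB"] + (ct["y_A"] + ct["y_B"]) / 2
    v <- if (d > 0) unname(ct["x"] / d) else 0
    ai[a, b] <- ai[b, a] <- v
  }
  ai
}

# network measure oracles: plain loops over the AI matrix, all unnamed
oracle_strength <- function(ai) sapply(seq_len(nrow(ai)), function(i)
  sum(ai[i, -i]))

oracle_reach <- function(ai) {
  n <- nrow(ai)
  s <- oracle_strength(ai)
  sapply(1:n, function(i)
    sum(sapply((1:n)[-i], function(j) ai[i, j] * s[j])))
}

oracle_clustering <- function(ai) {
  n <- nrow(ai)
  max_ai <- max(ai[row(ai) != col(ai)])
  sapply(1:n, function(i) {
    num <- den <- 0
    for (j in (1:n)[-i]) for (k in (1:n)[-c(i, j)]) {
      num <- num + ai[i, j] * ai[j, k] * ai[k, i]
      den <- den + ai[i, j] * ai[i, k]
    }
    if (sum(ai[i, -i] > 0) < 2 || den == 0 || max_ai == 0) NA_real_
    else num / (max_ai * den)
  })
}

oracle_affinity <- function(ai) {
  s <- oracle_strength(ai)
  r <- oracle_reach(ai)
  unname(ifelse(s > 0, r / s, NA_real_))
}

oracle_power_eigen <- function(ai, iter = 10000) {
  # shift by the largest row sum so the dominant eigenvalue is strictly
  # largest in modulus (bipartite-like spectra otherwise make plain power
  # iteration oscillate); the principal eigenvector is unchanged
  m <- ai + diag(max(rowSums(ai)), nrow(ai))
  v <- rep(1 / sqrt(nrow(ai)), nrow(ai))
  for (k in seq_len(iter)) {
    w <- as.numeric(m %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(v)
    w <- w / nw
    if (max(abs(w - v)) < 1e-14) return(w)
    v <- w
  }
  v
}

is_connected_ai <- function(ai) {
  n <- nrow(ai)
  reach <- (ai > 0) | diag(TRUE, n)
  for (k in seq_len(n)) reach <- (reach %*% reach) > 0
  all(reach)
}

# lagged association rate by full enumeration over ordered dyads and
# period pairs
oracle_lar <- function(obs, scale = "minute") {
  per <- obs$periods
  ids <- obs$individuals
  pairs <- list()
  if (scale == "minute") {
    for (t1 in per$index) for (t2 in per$index) {
      if (per$day[t1] == per$day[t2] && per$minute[t2] > per$minute[t1]) {
        pairs[[length(pairs) + 1]] <-
          c(t1, t2, per$minute[t2] - per$minute[t1])
      }
    }
  } else {
    base <- min(diff(sort(unique(per$day))))
    for (t1 in per$index) for (t2 in per$index) {
      if (per$minute[t1] == per$minute[t2] && per$day[t2] > per$day[t1]) {
        pairs[[length(pairs) + 1]] <-
          c(t1, t2, (per$day[t2] - per$day[t1]) / base)
      }
    }
  }
  num <- c(); den <- c()
  for (pp in pairs) {
    key <- as.character(pp[3])
    if (!key %in% names(num)) { num[key] <- 0; den[key] <- 0 }
    for (i in ids) for (j in ids) {
      if (i == j) next
      g1i <- .rec_group(obs, pp[1], i); g1j <- .rec_group(obs, pp[1], j)
      if (is.na(g1i) || is.na(g1j) || g1i != g1j) next
      g2i <- .rec_group(obs, pp[2], i); g2j <- .rec_group(obs, pp[2], j)
      if (is.na(g2i) || is.na(g2j)) next
      den[key] <- den[key] + 1
      if (g2i == g2j) num[key] <- num[key] + 1
    }
  }
  lag <- as.numeric(names(num))
  o <- order(lag)
  data.frame(lag = lag[o], num = as.numeric(num)[o], den = as.numeric(den)[o])
}

oracle_null_rate <- function(obs) {
  tot <- 0; cnt <- 0
  for (p in obs$periods$index) {
    r <- obs$records[obs$records$period == p, ]
    if (nrow(r) < 2) next
    for (i in r$individual_id) {
      gi <- r$group_id[r$individual_id == i]
      mates <- sum(r$group_id == gi) - 1
      tot <- tot + mates / (nrow(r) - 1)
      cnt <- cnt + 1
    }
  }
  if (cnt == 0) NA_real_ else tot / cnt
}

# tiny fixed fixture: 3 individuals, explicit hand-checkable structure
toy_obs <- function() {
  observation_set(data.frame(
    day = rep(1, 9),
    minute = rep(0:2, each = 3),
    group_id = c("g1", "g1", "g2",   # m0: {A,B} {C}
                 "g1", "g1", "g2",   # m1: {A,B} {C}
                 "g1", "g2", "g1"),  # m2: {A,C} {B}
    individual_id = rep(c("A", "B", "C"), 3)))
}
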