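#' Simulation configuration (study design)
#'
#' Defaults reproduce the laboratory scan-sampling design the analyses are
#' built around: 12 individuals per population, group membership recorded
#' once per minute for 30 minutes, repeated every 3 days over a 12-day
#' span (4 sessions, 120 scans in total), with complete detection.
#'
#' @param N individuals (>= 2)
#' @param periods_per_day scans per session (minutes 0 .. periods_per_day-1)
#' @param days study days of the sessions
#' @param seed optional integer seed set at the start of each generator
#' @return list of class `sim_config`
#' @export
sim_config <- function(N = 12, periods_per_day = 30, days = c(1, 4, 7, 10),
                       seed = NULL) {
  stopifnot(N >= 2, periods_per_day >= 1, length(days) >= 1)
  structure(list(N = as.integer(N),
                 periods_per_day = as.integer(periods_per_day),
                 days = as.integer(sort(days)), seed = seed),
            class = "sim_config")
}

# component labels of an undirected adjacency matrix by boolean
# reachability (a handful of N x N boolean products; N is small here)
.adj_components <- function(adj) {
  n <- nrow(adj)
  M <- adj | diag(TRUE, n)
  repeat {
    M2 <- (M %*% M) > 0
    if (all(M2 == M)) break
    M <- M2
  }
  unname(apply(M, 1, which.max))  # smallest reachable index labels the component
}

.cfg_periods <- function(cfg) {
  data.frame(day = rep(cfg$days, each = cfg$periods_per_day),
             minute = rep(seq_len(cfg$periods_per_day) - 1L,
                          times = length(cfg$days)))
}

# assemble an observation_set from a periods x individuals group-code
# matrix (complete detection: every individual observed in every period)
.obs_from_codes <- function(codes, cfg) {
  per <- .cfg_periods(cfg)
  np <- nrow(per)
  ids <- sprintf("i%02d", seq_len(cfg$N))
  observation_set(data.frame(
    day = rep(per$day, each = cfg$N),
    minute = rep(per$minute, each = cfg$N),
    group_id = paste0("g", as.integer(t(codes))),
    individual_id = rep(ids, times = np)),
    individuals = ids)
}

#' Homogeneous association generator
#'
#' Null-structure fixture: every dyad associates independently with the
#' same probability p in every period, and groups are the transitive
#' closure of the dyadic links. Optionally a set of dyads can be made
#' permanent companions (linked in every period) to embed a known
#' preference in otherwise exchangeable noise.
#'
#' @param cfg a [sim_config()]
#' @param p common dyadic association probability in \[0, 1\]
#' @param permanent_dyads optional 2-column matrix (or list of length-2
#'   vectors) of individual indices forced into the same group every period
#' @return an [observation_set()]
#' @export
generate_homogeneous <- function(cfg, p, permanent_dyads = NULL) {
  stopifnot(inherits(cfg, "sim_config"), p >= 0, p <= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.list(permanent_dyads)) permanent_dyads <- do.call(rbind, permanent_dyads)
  per <- .cfg_periods(cfg)
  n <- cfg$N
  ut <- which(upper.tri(matrix(0, n, n)))
  codes <- matrix(0L, nrow = nrow(per), ncol = n)
  for (t in seq_len(nrow(per))) {
    adj <- matrix(FALSE, n, n)
    adj[ut] <- stats::runif(length(ut)) < p
    adj <- adj | t(adj)
    if (!is.null(permanent_dyads)) {
      adj[permanent_dyads] <- TRUE
      adj[permanent_dyads[, 2:1, drop = FALSE]] <- TRUE
    }
    codes[t, ] <- .adj_components(adj)
  }
  .obs_from_codes(codes, cfg)
}

#' Beta-distributed dyadic association generator
#'
#' Fixture with exactly known ground truth for social-differentiation
#' recovery. True dyadic probabilities p_ij are drawn once from a Beta
#' distribution with the requested mean and CV. Each period a uniformly
#' random disjoint pairing of the population is drawn, and a paired dyad
#' (i, j) associates with probability (N - 1) p_ij, so that unconditionally
#' each dyad's co-membership is Bernoulli(p_ij) per period while groups
#' (pairs and singletons) stay trivially transitive -- no closure step
#' distorts the target probabilities. Requires p_ij <= 1/(N - 1); draws
#' above the cap are truncated (keep mean_p well below 1/(N - 1)).
#'
#' @param cfg a [sim_config()]
#' @param mean_p mean true association probability (< 1/(N - 1))
#' @param cv_p target CV of the true probabilities (S of the society)
#' @return list: `obs` (an [observation_set()]), `true_p` (symmetric matrix
#'   of true dyadic probabilities)
#' @export
generate_beta_dyadic <- function(cfg, mean_p, cv_p) {
  stopifnot(inherits(cfg, "sim_config"), mean_p > 0, cv_p >= 0)
  n <- cfg$N
  if (mean_p >= 1 / (n - 1)) {
    stop(sprintf("mean_p must be below 1/(N-1) = %.4f for the pairing scheme",
                 1 / (n - 1)))
  }
  v <- (cv_p * mean_p)^2
  if (v >= mean_p * (1 - mean_p)) {
    stop("no Beta distribution has this mean and CV")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ids <- sprintf("i%02d", seq_len(n))
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  ut <- upper.tri(P)
  if (cv_p == 0) {
    P[ut] <- mean_p
  } else {
    shape_sum <- mean_p * (1 - mean_p) / v - 1
    P[ut] <- stats::rbeta(sum(ut), mean_p * shape_sum, (1 - mean_p) * shape_sum)
  }
  P[ut] <- pmin(P[ut], 1 / (n - 1))
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  per <- .cfg_periods(cfg)
  codes <- matrix(0L, nrow = nrow(per), ncol = n)
  n_pairs <- n %/% 2
  for (t in seq_len(nrow(per))) {
    ord <- sample.int(n)
    code <- seq_len(n) + n  # singleton codes
    for (k in seq_len(n_pairs)) {
      i <- ord[2 * k - 1]; j <- ord[2 * k]
      if (stats::runif(1) < (n - 1) * P[i, j]) code[j] <- code[i] <- k
    }
    codes[t, ] <- code
  }
  list(obs = .obs_from_codes(codes, cfg), true_p = P)
}

#' Parameters for the bonded Markov generator
#'
#' @param fraction_bonded fraction of dyads with the slow (bonded) dynamics
#' @param p_assoc_eq_fast,p_assoc_eq_slow equilibrium association
#'   probabilities of casual and bonded dyads
#' @param rate_fast,rate_slow per-minute dissociation hazards (> 0); the
#'   chain's relaxation rate is hazard / (1 - equilibrium)
#' @return list of class `bonded_markov_params`
#' @export
bonded_markov_params <- function(fraction_bonded = 0.3,
                                 p_assoc_eq_fast = 0.1,
                                 p_assoc_eq_slow = 0.35,
                                 rate_fast = 1.0, rate_slow = 0.01) {
  stopifnot(fraction_bonded >= 0, fraction_bonded <= 1,
            rate_fast > 0, rate_slow > 0,
            p_assoc_eq_fast > 0, p_assoc_eq_fast < 1,
            p_assoc_eq_slow > 0, p_assoc_eq_slow < 1)
  structure(list(fraction_bonded = fraction_bonded,
                 p_assoc_eq_fast = p_assoc_eq_fast,
                 p_assoc_eq_slow = p_assoc_eq_slow,
                 rate_fast = rate_fast, rate_slow = rate_slow),
            class = "bonded_markov_params")
}

#' Two-timescale bonded Markov association generator
#'
#' Each dyad runs an independent two-state (associated/apart)
#' continuous-time Markov chain sampled once per minute: bonded dyads
#' dissolve with the slow hazard, casual dyads with the fast hazard, and
#' each day starts at the chain's equilibrium (no overnight memory, so the
#' minute and day scales separate). Groups are the transitive closure of
#' the dyadic links. The mixture of the two relaxation rates produces a
#' lagged association rate that decays on two time scales -- the structure
#' behind a two-level casual-acquaintance model, e.g. stable groups moving
#' in and out of other groups.
#'
#' @param cfg a [sim_config()]
#' @param params a [bonded_markov_params()]
#' @return list: `obs` (an [observation_set()]), `bonded` (logical matrix),
#'   `implied` -- sparse-limit mixture parameters of the implied LAR:
#'   amplitudes and relaxation rates of the fast and slow exponential
#'   components plus the long-run floor
#' @export
generate_bonded_markov <- function(cfg, params = bonded_markov_params()) {
  stopifnot(inherits(cfg, "sim_config"),
            inherits(params, "bonded_markov_params"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$N
  nd <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  bonded_v <- rep(FALSE, nd)
  nb <- round(params$fraction_bonded * nd)
  if (nb > 0) bonded_v[sample.int(nd, nb)] <- TRUE
  pi_v <- ifelse(bonded_v, params$p_assoc_eq_slow, params$p_assoc_eq_fast)
  mu_v <- ifelse(bonded_v, params$rate_slow, params$rate_fast)
  rho_v <- mu_v / (1 - pi_v)          # relaxation rate lambda + mu
  p_stay <- pi_v + (1 - pi_v) * exp(-rho_v)   # P(on -> on) over 1 minute
  p_gain <- pi_v * (1 - exp(-rho_v))          # P(off -> on)
  per <- .cfg_periods(cfg)
  codes <- matrix(0L, nrow = nrow(per), ncol = n)
  state <- NULL
  for (t in seq_len(nrow(per))) {
    state <- if (t == 1 || per$day[t] != per$day[t - 1]) {
      stats::runif(nd) < pi_v          # re-equilibrate at day start
    } else {
      ifelse(state, stats::runif(nd) < p_stay, stats::runif(nd) < p_gain)
    }
    adj <- matrix(FALSE, n, n)
    adj[ut] <- state
    adj <- adj | t(adj)
    codes[t, ] <- .adj_components(adj)
  }
  w <- c(fast = sum(!bonded_v) * params$p_assoc_eq_fast,
         slow = sum(bonded_v) * params$p_assoc_eq_slow)
  w <- w / sum(w)
  rho_fast <- params$rate_fast / (1 - params$p_assoc_eq_fast)
  rho_slow <- params$rate_slow / (1 - params$p_assoc_eq_slow)
  bonded_m <- matrix(FALSE, n, n)
  bonded_m[ut] <- bonded_v
  bonded_m <- bonded_m | t(bonded_m)
  list(obs = .obs_from_codes(codes, cfg),
       bonded = bonded_m,
       implied = list(
         amplitude_fast = unname(w["fast"]) * (1 - params$p_assoc_eq_fast),
         rate_fast = rho_fast,
         amplitude_slow = unname(w["slow"]) * (1 - params$p_assoc_eq_slow),
         rate_slow = rho_slow,
         floor = unname(w["fast"]) * params$p_assoc_eq_fast +
           unname(w["slow"]) * params$p_assoc_eq_slow))
}

#' Parameters for the spatial arena generator
#'
#' Defaults describe a 120 cm circular observation arena holding fish of
#' 26.9 mm total length; the association radius is the standard 4 body
#' lengths of the chain rule.
#'
#' @param arena_diameter_cm arena diameter (cm)
#' @param body_length_mm mean body length (mm)
#' @param step_sd_cm per-minute random-walk SD per coordinate (cm)
#' @param cohesion fraction of the distance to the own-group centroid moved
#'   per minute (0 = ignore the group, values near 1 = tight cohesion)
#' @param fission_hazard per-group per-minute probability that a random
#'   subset is kicked away from the group
#' @param fusion_hazard per-group per-minute probability that the group
#'   drifts toward another group's centroid
#' @return list of class `arena_params` (includes the derived
#'   `association_radius_cm` = 4 body lengths)
#' @export
arena_params <- function(arena_diameter_cm = 120, body_length_mm = 26.9,
                         step_sd_cm = 4, cohesion = 0.25,
                         fission_hazard = 0.04, fusion_hazard = 0.1) {
  stopifnot(arena_diameter_cm > 0, body_length_mm > 0, step_sd_cm >= 0,
            cohesion >= 0, cohesion <= 1)
  structure(list(arena_diameter_cm = arena_diameter_cm,
                 body_length_mm = body_length_mm,
                 association_radius_cm = 4 * body_length_mm / 10,
                 step_sd_cm = step_sd_cm, cohesion = cohesion,
                 fission_hazard = fission_hazard,
                 fusion_hazard = fusion_hazard),
            class = "arena_params")
}

#' Chain-rule group assignment from positions
#'
#' Single-linkage chaining: individuals are in the same group when they are
#' connected through a chain of neighbours each within `radius` of the
#' next, so a group may span far more than `radius` end to end (three fish
#' in a line at 3.9 body-length spacing form one 7.8-length-wide shoal).
#'
#' @param xy 2-column matrix of positions
#' @param radius association radius (same units as `xy`)
#' @return integer group labels
#' @export
group_by_chain_rule <- function(xy, radius) {
  d <- as.matrix(stats::dist(xy))
  adj <- d <= radius
  diag(adj) <- FALSE
  .adj_components(adj)
}

#' Spatially explicit arena generator
#'
#' Fish move in a circular arena by a biased random walk with cohesion
#' toward their current group's centroid, stochastic fission (a subset of a
#' group is kicked away) and fusion (a group drifts toward another group).
#' Scan samples record groups by the 4-body-length chain rule, emitting a
#' standard observation set. Positions are re-randomised at the start of
#' each day. Unlike the dyadic generators, this one has no closed-form
#' ground truth but produces transitive, spatially realistic data.
#'
#' @param cfg a [sim_config()]
#' @param params an [arena_params()]
#' @return an [observation_set()]
#' @export
generate_arena <- function(cfg, params = arena_params()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(params, "arena_params"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$N
  R <- params$arena_diameter_cm / 2
  rad <- params$association_radius_cm
  per <- .cfg_periods(cfg)
  codes <- matrix(0L, nrow = nrow(per), ncol = n)
  rand_pos <- function() {
    r <- R * sqrt(stats::runif(n)); a <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  }
  xy <- rand_pos()
  for (t in seq_len(nrow(per))) {
    if (t > 1 && per$day[t] != per$day[t - 1]) xy <- rand_pos()
    grp <- group_by_chain_rule(xy, rad)
    target <- xy
    gids <- unique(grp)
    cens <- t(vapply(gids, function(g)
      colMeans(xy[grp == g, , drop = FALSE]), numeric(2)))
    # a fusing group approaches its nearest neighbour group; a group that
    # is being approached stays put, so two groups cannot endlessly swap
    approached <- rep(FALSE, length(gids))
    fuse_order <- sample(seq_along(gids))
    for (gi in fuse_order) {
      mem <- which(grp == gids[gi])
      cen <- cens[gi, ]
      if (length(gids) > 1 && !approached[gi] &&
          stats::runif(1) < params$fusion_hazard) {
        d2 <- rowSums((cens - matrix(cen, nrow(cens), 2, byrow = TRUE))^2)
        d2[gi] <- Inf
        tgt <- which.min(d2)
        approached[tgt] <- TRUE
        cen <- cens[tgt, ]
      }
      target[mem, ] <- matrix(cen, length(mem), 2, byrow = TRUE)
      if (length(mem) > 1 && stats::runif(1) < params$fission_hazard) {
        kick <- sample(mem, max(1, length(mem) %/% 2))
        ang <- stats::runif(1, 0, 2 * pi)
        target[kick, 1] <- xy[kick, 1] + 3 * rad * cos(ang)
        target[kick, 2] <- xy[kick, 2] + 3 * rad * sin(ang)
      }
    }
    xy <- xy + params$cohesion * (target - xy) +
      matrix(stats::rnorm(2 * n, 0, params$step_sd_cm), n, 2)
    rr <- sqrt(rowSums(xy^2))
    out <- rr > R
    if (any(out)) xy[out, ] <- xy[out, ] * (R / rr[out])
    codes[t, ] <- group_by_chain_rule(xy, rad)
  }
  .obs_from_codes(codes, cfg)
}

#' Simulate per-lag LAR count data from a parametric curve
#'
#' Draws binomial numerators N(tau) ~ Bin(D(tau), g(tau | theta)) for a
#' given model and lag design: the direct fixture for quasi-likelihood
#' fitting and QAIC selection tests, bypassing the observation layer.
#'
#' @param model a [lar_model()] or name
#' @param theta parameter vector on the natural scale
#' @param tau lag grid
#' @param den per-lag denominators (number of contributions)
#' @return list with `tau`, `num`, `den`
#' @export
simulate_lar_counts <- function(model, theta, tau, den) {
  g <- pmin(pmax(evaluate_lar_model(model, theta, tau), 0), 1)
  list(tau = tau, num = stats::rbinom(length(tau), round(den), g),
       den = round(den))
}

#' Within-session lag design
#'
#' Per-lag denominators proportional to the number of period pairs a
#' within-session lag realises under the scan design (periods_per_day - tau
#' pairs per session), scaled to a requested total number of contributions.
#'
#' @param total_contributions total of the denominators
#' @param periods_per_day scans per session (lags 1 .. periods_per_day - 1)
#' @return list with `tau` and `den`
#' @export
lar_lag_design <- function(total_contributions, periods_per_day = 30) {
  tau <- seq_len(periods_per_day - 1)
  w <- (periods_per_day - tau) / sum(periods_per_day - tau)
  list(tau = tau, den = round(w * total_contributions))
}
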