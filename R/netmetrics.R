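#' Strength
#'
#' Per-individual sum of association indices with all other individuals:
#' the weighted analogue of degree. Under complete detection, mean strength
#' equals (N - 1) times the mean association index exactly.
#'
#' @param am an [association_matrix()] result or a plain symmetric AI matrix
#' @return named numeric vector
#' @export
net_strength <- function(am) {
  ai <- .ai_of(am)
  rowSums(ai)
}

.ai_of <- function(am) {
  ai <- if (inherits(am, "assoc_matrix")) am$AI else am
  stopifnot(is.matrix(ai), nrow(ai) == ncol(ai))
  ai
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weighted association matrix, normalised to
#' unit Euclidean norm with non-negative sign: how well connected an
#' individual is, counting both its own ties and how connected its
#' neighbours are. In a homogeneous network every individual scores
#' 1/sqrt(N) regardless of the common tie weight.
#'
#' @inheritParams net_strength
#' @return named numeric vector with unit Euclidean norm
#' @export
eigenvector_centrality <- function(am) {
  ai <- .ai_of(am)
  if (all(ai == 0)) stop("eigenvector centrality undefined for an empty network")
  e <- eigen(ai, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8) {
    # disconnected network: Perron vector of the dominant component; fall
    # back to a power iteration from a positive start
    v <- rep(1 / sqrt(nrow(ai)), nrow(ai))
    for (k in 1:10000) {
      w <- ai %*% v
      nw <- sqrt(sum(w^2))
      if (nw == 0) break
      w <- as.numeric(w / nw)
      if (max(abs(w - v)) < 1e-12) { v <- w; break }
      v <- w
    }
  }
  v[v < 0] <- 0
  v <- v / sqrt(sum(v^2))
  names(v) <- rownames(ai)
  v
}

#' Reach
#'
#' Two-step weighted connectivity: r_i = sum over j of AI_ij * s_j, the
#' overall strength of an individual's neighbours weighted by its tie to
#' each. Measures how well an individual is indirectly connected.
#'
#' @inheritParams net_strength
#' @return named numeric vector
#' @export
net_reach <- function(am) {
  ai <- .ai_of(am)
  as.numeric(ai %*% rowSums(ai))
}

#' Weighted clustering coefficient
#'
#' How well an individual's neighbours are connected to one another:
#' C_i = sum_{j != k} AI_ij AI_jk AI_ki / (max AI * sum_{j != k} AI_ij AI_ik),
#' normalised by the largest off-diagonal index so a saturated
#' neighbourhood scores 1 and disconnected neighbours score 0. Undefined
#' (NA) for individuals with fewer than two positive-weight neighbours.
#'
#' @inheritParams net_strength
#' @param variant `"max_ai"` (default, 0-1 normalisation by the network's
#'   largest index) or `"mean_triadic"` (numerator / plain two-path weight,
#'   i.e. the mean AI over closing legs)
#' @return named numeric vector in \[0, 1\] (NA where undefined)
#' @export
clustering_coefficient <- function(am, variant = c("max_ai", "mean_triadic")) {
  variant <- match.arg(variant)
  ai <- .ai_of(am)
  num <- diag(ai %*% ai %*% ai)                 # closed weighted triples
  s <- rowSums(ai)
  two_paths <- s^2 - rowSums(ai^2)              # sum_{j != k} AI_ij AI_ik
  max_ai <- max(ai[upper.tri(ai)], ai[lower.tri(ai)])
  den <- if (variant == "max_ai") max_ai * two_paths else two_paths
  out <- ifelse(den > 0, num / den, NA_real_)
  out[rowSums(ai > 0) < 2] <- NA_real_
  names(out) <- rownames(ai)
  out
}

#' Affinity
#'
#' Weighted mean strength of an individual's neighbours, weighting each
#' neighbour's strength by the association index to it: f_i = r_i / s_i.
#' NA for isolated individuals.
#'
#' @inheritParams net_strength
#' @return named numeric vector
#' @export
net_affinity <- function(am) {
  ai <- .ai_of(am)
  s <- rowSums(ai)
  r <- as.numeric(ai %*% s)
  out <- ifelse(s > 0, r / s, NA_real_)
  names(out) <- rownames(ai)
  out
}

#' All five weighted network measures
#'
#' Per-individual strength, eigenvector centrality, reach, clustering
#' coefficient and affinity, plus their population means.
#'
#' @inheritParams net_strength
#' @return list with `individual` (data.frame, one row per individual) and
#'   `means` (named numeric vector, NA-stripped means)
#' @export
network_metrics <- function(am) {
  ai <- .ai_of(am)
  ev <- tryCatch(eigenvector_centrality(am),
                 error = function(e) rep(NA_real_, nrow(ai)))
  ind <- data.frame(
    id = if (!is.null(rownames(ai))) rownames(ai) else as.character(seq_len(nrow(ai))),
    strength = net_strength(am),
    eigenvector = ev,
    reach = net_reach(am),
    clustering = clustering_coefficient(am),
    affinity = net_affinity(am),
    stringsAsFactors = FALSE, row.names = NULL)
  means <- vapply(ind[, -1], function(v) mean(v, na.rm = TRUE), numeric(1))
  list(individual = ind, means = means)
}

#' Bootstrap standard errors of population-mean network measures
#'
#' Resamples sampling periods with replacement (periods are the
#' exchangeable sampling unit; within-period group structure is kept
#' intact), rebuilds the association matrix, recomputes the population mean
#' of each measure, and reports the SD across replicates as the SE.
#'
#' @param obs an [observation_set()]
#' @param n_boot bootstrap replicates (1000 in the standard protocol)
#' @param seed optional integer seed
#' @param index association index variant
#' @return list: `se` (named vector), `means` (observed-data means),
#'   `replicates` (matrix of replicate means), `n_boot`
#' @export
bootstrap_network_ses <- function(obs, n_boot = 1000, seed = NULL,
                                  index = "simple_ratio") {
  if (n_periods(obs) < 2) stop("bootstrap SEs need at least 2 sampling periods")
  if (!is.null(seed)) set.seed(seed)
  m <- membership_matrix(obs)
  np <- nrow(m)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = 5,
                 dimnames = list(NULL, c("strength", "eigenvector", "reach",
                                         "clustering", "affinity")))
  for (b in seq_len(n_boot)) {
    take <- sample.int(np, np, replace = TRUE)
    amb <- am_from_membership(m[take, , drop = FALSE], obs$individuals, index)
    reps[b, ] <- network_metrics(amb)$means
  }
  se <- apply(reps, 2, stats::sd)
  if (n_boot < 2) {
    se[] <- 0
    warning("n_boot < 2: SEs degenerate (reported as 0)")
  }
  obs_means <- network_metrics(association_matrix(obs, index))$means
  list(se = se, means = obs_means, replicates = reps, n_boot = n_boot)
}
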