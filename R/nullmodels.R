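#' Permutation test configuration
#'
#' Settings for the margin-preserving swap null models. The defaults (5000
#' recorded permutations, 1000 flips between consecutive recordings) are
#' the operating point at which two-sided p-values for this study design
#' stabilise to within about 0.01; scale them down for quick exploration.
#'
#' `flips_per_permutation` counts *successful* checkerboard swaps by
#' default (`count = "successful"`): the serial dependence between
#' consecutive recorded permutations -- and with it the calibration of the
#' sequential test at practical chain lengths -- is governed by swaps that
#' actually happen, not by rejected proposals. `count = "attempts"` counts
#' raw proposals instead.
#'
#' `swap_within` controls which rows a swap may pair: `"period"` (default)
#' exchanges two individuals between two groups of the same scan, so every
#' permuted period remains a valid partition of the population and, under
#' complete detection, the null ensemble is exactly the uniform
#' distribution over within-period group assignments with all group sizes
#' and per-individual group counts conserved; `"day"` allows any two
#' groups of the same 30-minute session; `"none"` drops the restriction.
#'
#' @param n_permutations recorded null samples (chain recordings)
#' @param flips_per_permutation flips (or attempts) between recordings
#' @param swap_within `"period"`, `"day"` or `"none"`
#' @param count `"successful"` (default) or `"attempts"`
#' @param seed optional integer seed applied at the start of each test
#' @return list of class `perm_config`
#' @export
permutation_config <- function(n_permutations = 5000,
                               flips_per_permutation = 1000,
                               swap_within = c("period", "day", "none"),
                               count = c("successful", "attempts"),
                               seed = NULL) {
  stopifnot(n_permutations >= 1, flips_per_permutation >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 flips_per_permutation = as.integer(flips_per_permutation),
                 swap_within = match.arg(swap_within),
                 count = match.arg(count),
                 seed = seed),
            class = "perm_config")
}

.gbi_block <- function(gbi, within) {
  switch(within,
         period = attr(gbi, "period"),
         day = attr(gbi, "day"),
         none = rep(-1L, nrow(gbi)))
}

#' One checkerboard swap attempt
#'
#' Picks a first row uniformly, a second row uniformly among the other
#' rows of the same block (period/day, or any row when unrestricted), and
#' two distinct columns uniformly; if the 2x2 submatrix is [[1,0],[0,1]]
#' or [[0,1],[1,0]] it is flipped, exchanging two individuals between two
#' groups. Row and column sums are invariant. A failed draw returns the
#' matrix unchanged.
#'
#' @param gbi a [to_gbi()] matrix (needs `period`/`day` attributes unless
#'   `within = "none"`)
#' @param within `"period"`, `"day"` or `"none"`
#' @return the (possibly flipped) GBI, with logical attribute `swapped`
#' @export
checkerboard_swap <- function(gbi, within = c("day", "period", "none")) {
  within <- match.arg(within)
  block <- .gbi_block(gbi, within)
  if (is.null(block)) stop("gbi lacks the '", within, "' attribute; use to_gbi()")
  res <- .swap_chain_cpp(gbi, block, 1L, FALSE)
  out <- res$gbi
  attributes(out) <- attributes(gbi)
  attr(out, "swapped") <- res$successes == 1
  out
}

#' Run a long swap chain
#'
#' Applies checkerboard swap attempts to a GBI matrix (the permutation
#' null's Markov chain). Mostly useful for checking margin conservation
#' and mixing; the test functions drive the chain themselves.
#'
#' @inheritParams checkerboard_swap
#' @param n_flips chain length
#' @param count `"attempts"` (default here) or `"successful"`
#' @return list: `gbi` (permuted matrix, attributes preserved),
#'   `successes`, `attempts`
#' @export
swap_chain <- function(gbi, n_flips, within = c("day", "period", "none"),
                       count = c("attempts", "successful")) {
  within <- match.arg(within)
  count <- match.arg(count)
  block <- .gbi_block(gbi, within)
  if (is.null(block)) stop("gbi lacks the '", within, "' attribute; use to_gbi()")
  res <- .swap_chain_cpp(gbi, block, as.integer(n_flips),
                         count == "successful")
  out <- res$gbi
  attributes(out) <- attributes(gbi)
  list(gbi = out, successes = res$successes, attempts = res$attempts)
}

# Sequential permutation engine. The observed GBI is the chain start; each
# recorded null follows flips_per_permutation further swaps. stat_fun maps
# a GBI to a numeric vector.
.perm_engine <- function(obs, cfg, stat_fun) {
  stopifnot(inherits(cfg, "perm_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  gbi <- to_gbi(obs)
  block <- .gbi_block(gbi, cfg$swap_within)
  observed <- stat_fun(gbi)
  nulls <- matrix(NA_real_, nrow = cfg$n_permutations, ncol = length(observed))
  successes <- 0
  for (k in seq_len(cfg$n_permutations)) {
    res <- .swap_chain_cpp(gbi, block, cfg$flips_per_permutation,
                           cfg$count == "successful")
    gbi <- res$gbi
    successes <- successes + res$successes
    nulls[k, ] <- stat_fun(gbi)
  }
  list(observed = observed, nulls = nulls, successes = successes)
}

# AI matrix implied by a (possibly permuted) GBI: x from shared group
# memberships, denominators fixed at their observed-data values.
.gbi_ai <- function(gbi, denom) {
  x <- crossprod(gbi)
  ai <- matrix(0, nrow(x), ncol(x))
  pos <- denom > 0
  ai[pos] <- x[pos] / denom[pos]
  diag(ai) <- 0
  ai
}

.new_perm_result <- function(statistic_name, eng, cfg) {
  obs_s <- eng$observed
  nulls <- as.numeric(eng$nulls)
  structure(list(
    statistic_name = statistic_name,
    observed = obs_s,
    null_values = nulls,
    null_mean = mean(nulls),
    p_high = mean(nulls >= obs_s),
    p_low = mean(nulls <= obs_s),
    attainable_min_p = 1 / cfg$n_permutations,
    n_successful_swaps = eng$successes,
    informative = eng$successes > 0,
    config = cfg), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s\n", x$statistic_name))
  cat(sprintf("  observed = %.4f, null mean = %.4f (%d permutations)\n",
              x$observed, x$null_mean, length(x$null_values)))
  cat(sprintf("  p_high = %.4f, p_low = %.4f (attainable min %.4g)\n",
              x$p_high, x$p_low, x$attainable_min_p))
  if (!x$informative) cat("  WARNING: no successful swaps; result non-informative\n")
  invisible(x)
}

#' Permutation test for non-random association (CV of indices)
#'
#' Tests whether the coefficient of variation of the association indices is
#' higher (preferred/avoided companions) or lower than expected when group
#' memberships are randomised subject to conserved group sizes and
#' per-individual group counts. p_high is the proportion of null CVs at or
#' above the observed CV, p_low the proportion at or below (ties count in
#' both, so p_high + p_low >= 1).
#'
#' @param obs an [observation_set()]
#' @param cfg a [permutation_config()]
#' @return a `perm_test` object
#' @export
permutation_test_cv <- function(obs, cfg = permutation_config()) {
  denom <- association_matrix(obs)$denom
  ut <- upper.tri(denom)
  stat <- function(gbi) {
    ai <- .gbi_ai(gbi, denom)[ut]
    stats::sd(ai) / mean(ai)
  }
  eng <- .perm_engine(obs, cfg, stat)
  .new_perm_result("cv_of_association_indices", eng, cfg)
}

#' Permutation test for gregariousness
#'
#' Null hypothesis: all individuals prefer groups of similar size. The
#' statistic is the standard deviation, across individuals, of typical
#' group size (gregariousness + 1), compared between the real data and the
#' margin-preserving null.
#'
#' @inheritParams permutation_test_cv
#' @return a `perm_test` object
#' @export
permutation_test_gregariousness <- function(obs, cfg = permutation_config()) {
  stat <- function(gbi) {
    sizes <- rowSums(gbi)
    n_grp <- colSums(gbi)
    typ <- as.numeric(crossprod(gbi, sizes)) / n_grp  # typical group size
    stats::sd(typ[n_grp > 0])
  }
  eng <- .perm_engine(obs, cfg, stat)
  .new_perm_result("sd_of_typical_group_size", eng, cfg)
}

#' Dyadic preference/avoidance significance
#'
#' For every dyad, locates the observed association index within its own
#' null distribution: `quantile` is the proportion of null indices
#' strictly below the observed one, `quantile_above` strictly above. A
#' dyad is preferred when more than 97.5% of its null indices fall below
#' the observed index, avoided when more than 97.5% fall above; ties with
#' the observed value count in neither direction. Dyads whose null
#' distribution is constant, or whose denominator is below
#' `min_denominator`, are marked untestable.
#'
#' @inheritParams permutation_test_cv
#' @param min_denominator smallest per-dyad denominator considered testable
#' @return list of class `dyadic_significance`: data.frame `dyads` (ids,
#'   observed AI, quantiles, status), `preferred`, `avoided` (subsets),
#'   `n_successful_swaps`, `config`
#' @export
dyadic_significance <- function(obs, cfg = permutation_config(),
                                min_denominator = 2) {
  am <- association_matrix(obs)
  denom <- am$denom
  ut_idx <- which(upper.tri(denom))
  stat <- function(gbi) .gbi_ai(gbi, denom)[ut_idx]
  eng <- .perm_engine(obs, cfg, stat)
  obs_ai <- eng$observed
  below <- colMeans(sweep(eng$nulls, 2, obs_ai, "<"))
  above <- colMeans(sweep(eng$nulls, 2, obs_ai, ">"))
  const_null <- apply(eng$nulls, 2, function(v) length(unique(v)) == 1)
  rc <- arrayInd(ut_idx, dim(denom))
  status <- ifelse(denom[ut_idx] < min_denominator | const_null, "untestable",
            ifelse(below > 0.975, "preferred",
            ifelse(above > 0.975, "avoided", "ns")))
  dyads <- data.frame(
    id1 = am$ids[rc[, 1]], id2 = am$ids[rc[, 2]],
    AI = obs_ai, quantile = below, quantile_above = above, status = status,
    stringsAsFactors = FALSE)
  structure(list(
    dyads = dyads,
    preferred = dyads[dyads$status == "preferred", ],
    avoided = dyads[dyads$status == "avoided", ],
    n_successful_swaps = eng$successes,
    config = cfg), class = "dyadic_significance")
}

#' @export
print.dyadic_significance <- function(x, ...) {
  cat(sprintf(
    "Dyadic significance: %d dyads; %d preferred, %d avoided, %d untestable\n",
    nrow(x$dyads), nrow(x$preferred), nrow(x$avoided),
    sum(x$dyads$status == "untestable")))
  invisible(x)
}
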