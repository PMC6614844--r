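# Jensen-Shannon ranking of (molecule, direction) entries against the
# BPC-derived distribution Q, rank aggregation across scoring variants,
# candidate selection and success evaluation.

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(p, q) = D(p||m)/2 + D(q||m)/2` with `m = (p + q)/2` and `D` the
#' Kullback-Leibler divergence in nats.  Supports may differ: the union is
#' taken with missing mass 0, so the result is finite and bounded by
#' `log(2)`.
#'
#' @param p,q named numeric vectors, each summing to 1 (tolerance 1e-9).
#' @return divergence in `[0, log(2)]`.
#' @export
jsd <- function(p, q) {
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("distributions must sum to 1")
  if (any(p < 0) || any(q < 0)) stop("distributions must be non-negative")
  support <- union(names(p), names(q))
  pp <- setNames(numeric(length(support)), support)
  qq <- pp
  pp[names(p)] <- p
  qq[names(q)] <- q
  m <- (pp + qq) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / m[nz]))
  }
  max(0, (kl(pp) + kl(qq)) / 2)
}

#' Rank molecule profiles of one variant by JSD against Q
#'
#' Competition ranking ("1224"): ties share the minimum rank and the next
#' distinct value skips ahead.  Molecules with empty profiles are
#' unrankable and excluded.
#'
#' @param profiles named list: entry names are `"<molecule>|<direction>"`
#'   (direction `activation` or `inhibition`), values are pair-keyed
#'   probability vectors (possibly empty).
#' @param q the [compute_q()] distribution.
#' @return named numeric vector of ranks (same names as rankable
#'   profiles); attribute `jsd` carries the divergences.
#' @export
rank_variant <- function(profiles, q) {
  if (!length(q)) stop("Q is empty")
  rankable <- profiles[lengths(profiles) > 0L]
  if (!length(rankable)) return(setNames(numeric(0), character(0)))
  div <- vapply(rankable, jsd, numeric(1), q = q)
  ranks <- rank(div, ties.method = "min")
  structure(setNames(as.numeric(ranks), names(rankable)), jsd = div)
}

#' Aggregate ranks across the two scoring variants
#'
#' `R = min(rank_correlation, rank_length)`; entries present in only one
#' variant keep that variant's rank.
#'
#' @param rank_correlation,rank_length named rank vectors from
#'   [rank_variant()].
#' @return named numeric vector of aggregated ranks R.
#' @export
aggregate_ranks <- function(rank_correlation, rank_length) {
  keys <- union(names(rank_correlation), names(rank_length))
  if (!length(keys)) return(setNames(numeric(0), character(0)))
  rc <- rank_correlation[keys]
  rl <- rank_length[keys]
  out <- pmin(rc, rl, na.rm = TRUE)
  setNames(as.numeric(out), keys)
}

#' Select candidate molecules under the rank cut-off
#'
#' The threshold is `cutoff_fraction` times the maximum aggregated rank;
#' candidates are entries with `R` strictly below it.
#'
#' @param ranking a ranking data.frame (from [rank_candidates()]) or a
#'   named numeric vector of aggregated ranks.
#' @param cutoff_fraction fraction of the maximum R, default 0.06.
#' @return for a data.frame input, the candidate subset (with the
#'   `candidate` column set); for a vector input, the candidate names.
#' @export
select_candidates <- function(ranking, cutoff_fraction = 0.06) {
  if (cutoff_fraction <= 0 || cutoff_fraction >= 1)
    stop("cutoff_fraction must lie in (0, 1)")
  if (is.data.frame(ranking)) {
    thr <- cutoff_fraction * max(ranking$R)
    ranking[ranking$R < thr, , drop = FALSE]
  } else {
    if (!length(ranking)) return(character())
    thr <- cutoff_fraction * max(ranking)
    names(ranking)[ranking < thr]
  }
}

#' Full candidate ranking across both variants
#'
#' @param profiles_corr,profiles_len named profile lists (one entry per
#'   molecule and direction) for the correlation and length variants.
#' @param q the [compute_q()] distribution.
#' @param cutoff_fraction candidate cut-off fraction, default 0.06.
#' @return object of class `candidate_ranking`: a data.frame with columns
#'   `molecule`, `direction`, `jsd_correlation`, `jsd_length`,
#'   `rank_correlation`, `rank_length`, `R`, `candidate`, ordered by `R`,
#'   then molecule, then direction.
#' @export
rank_candidates <- function(profiles_corr, profiles_len, q,
                            cutoff_fraction = 0.06) {
  rc <- rank_variant(profiles_corr, q)
  rl <- rank_variant(profiles_len, q)
  R <- aggregate_ranks(rc, rl)
  if (!length(R)) stop("no rankable molecules")
  keys <- names(R)
  parts <- strsplit(keys, "|", fixed = TRUE)
  df <- data.frame(
    molecule = vapply(parts, `[`, character(1), 1L),
    direction = vapply(parts, `[`, character(1), 2L),
    jsd_correlation = as.numeric(attr(rc, "jsd")[keys]),
    jsd_length = as.numeric(attr(rl, "jsd")[keys]),
    rank_correlation = as.numeric(rc[keys]),
    rank_length = as.numeric(rl[keys]),
    R = as.numeric(R),
    stringsAsFactors = FALSE
  )
  thr <- cutoff_fraction * max(df$R)
  df$candidate <- df$R < thr
  df <- df[order(df$R, df$molecule, df$direction), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "cutoff_fraction") <- cutoff_fraction
  class(df) <- c("candidate_ranking", "data.frame")
  df
}

#' Was the prediction successful?
#'
#' True iff at least one known perturbation-target molecule appears among
#' the candidates.  When `sign_aware = TRUE`, targets carry a required
#' direction and only direction-matched candidates count.
#'
#' @param candidates a `candidate_ranking` subset or data.frame with
#'   columns `molecule` (and `direction`).
#' @param targets character vector of target molecule ids, or a
#'   data.frame `molecule`, `direction` when `sign_aware`.
#' @param sign_aware match direction as well, default FALSE.
#' @return logical.
#' @export
evaluate_success <- function(candidates, targets, sign_aware = FALSE) {
  if (is.data.frame(candidates)) {
    mols <- candidates$molecule
    dirs <- candidates$direction
  } else {
    mols <- candidates; dirs <- rep(NA_character_, length(candidates))
  }
  if (sign_aware) {
    if (!is.data.frame(targets))
      stop("sign-aware evaluation needs a targets data.frame with direction")
    if (!nrow(targets)) stop("targets are empty")
    any(paste(mols, dirs) %in% paste(targets$molecule, targets$direction))
  } else {
    tm <- if (is.data.frame(targets)) targets$molecule else targets
    if (!length(tm)) stop("targets are empty")
    any(mols %in% tm)
  }
}

#' Probability that a random selection contains a target
#'
#' `P(at least one of n_targets in a uniform random subset of size
#' n_selected from n_universe) = 1 - C(N-K, n)/C(N, n)` (one-sided
#' hypergeometric tail).
#'
#' @param n_universe,n_targets,n_selected non-negative counts with
#'   `0 < n_targets <= n_universe` and `n_selected <= n_universe`.
#' @return probability in `[0, 1]`.
#' @export
random_success_probability <- function(n_universe, n_targets, n_selected) {
  if (n_targets <= 0 || n_targets > n_universe)
    stop("need 0 < n_targets <= n_universe")
  if (n_selected < 0 || n_selected > n_universe)
    stop("need 0 <= n_selected <= n_universe")
  if (n_selected == 0) return(0)
  if (n_selected > n_universe - n_targets) return(1)
  1 - exp(lchoose(n_universe - n_targets, n_selected) -
            lchoose(n_universe, n_selected))
}
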