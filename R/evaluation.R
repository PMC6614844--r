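# Validation analyses: differential-phosphorylation enrichment along MPPs
# and topological distance of candidates to known perturbation targets.

#' Sample distinct random simple paths between two nodes
#'
#' Randomized depth-first walks from `source`: at each step an unvisited
#' out-neighbour is chosen uniformly; walks that hit `target` within
#' `max_len` edges are kept, duplicates are rejected.  The sampler is
#' biased towards short paths (documented caveat) but never returns a
#' non-simple path or one exceeding `max_len` edges.
#'
#' @param graph a [scoring_graph()] or [signed_network()].
#' @param source,target node ids.
#' @param n_paths number of distinct paths wanted, default 100.
#' @param max_len maximum number of edges per path, default 10.
#' @param max_tries attempt budget, default `50 * n_paths`.
#' @return list of character-vector paths (possibly fewer than `n_paths`).
#' @export
sample_simple_paths <- function(graph, source, target, n_paths = 100L,
                                max_len = 10L, max_tries = 50L * n_paths) {
  adj <- .out_adjacency(graph)
  if (!source %in% names(adj) && !source %in% .all_nodes(graph))
    stop("source not in graph")
  paths <- list(); seen <- character()
  for (i in seq_len(max_tries)) {
    if (length(paths) >= n_paths) break
    path <- source
    node <- source
    repeat {
      if (node == target) break
      if (length(path) - 1L >= max_len) { path <- NULL; break }
      nxt <- setdiff(adj[[node]], path)
      if (!length(nxt)) { path <- NULL; break }
      node <- if (length(nxt) == 1L) nxt else sample(nxt, 1L)
      path <- c(path, node)
    }
    if (is.null(path)) next
    key <- paste(path, collapse = "\r")
    if (!key %in% seen) { seen <- c(seen, key); paths[[length(paths) + 1L]] <- path }
  }
  paths
}

.all_nodes <- function(graph) {
  if (inherits(graph, "scoring_graph")) graph$nodes else graph$nodes
}

.out_adjacency <- function(graph) {
  if (inherits(graph, "scoring_graph")) {
    e <- data.frame(source = graph$nodes[graph$edges$from],
                    target = graph$nodes[graph$edges$to])
  } else if (inherits(graph, "signed_network")) {
    e <- graph$edges[, c("source", "target")]
  } else stop("unsupported graph object")
  adj <- split(e$target, factor(e$source, levels = .all_nodes(graph)))
  lapply(adj, unique)
}

#' Differential-phosphorylation enrichment of an MPP
#'
#' Compares the fraction of differentially phosphorylated (DP) proteins on
#' the MPP against up to `n_random` randomly sampled distinct simple paths
#' between the same endpoints (at most `max_len` edges), with a one-sided
#' t-test (MPP fraction greater).
#'
#' @param graph a [scoring_graph()] or [signed_network()].
#' @param mpp_result an [mpp()] result.
#' @param dp_proteins character vector of DP protein ids.
#' @param n_random number of random paths, default 100.
#' @param max_len maximum random-path length in edges, default 10.
#' @param alpha significance level, default 0.05.
#' @param seed RNG seed for the path sampler.
#' @param test `"one_sample"` (default; MPP fraction vs the random-path
#'   sample) or `"two_sample"` (Welch, treating the MPP as a size-1
#'   sample is impossible, so the MPP fraction is compared against the
#'   sample mean as in the one-sample case unless several MPPs are given).
#' @return a `path_enrichment` list: `mpp_dp_fraction`,
#'   `random_dp_fractions`, `p_value`, `verdict` (one of `enriched`,
#'   `not_significant`, `no_dp_on_any_path`).
#' @export
phospho_enrichment <- function(graph, mpp_result, dp_proteins,
                               n_random = 100L, max_len = 10L, alpha = 0.05,
                               seed = 1L, test = c("one_sample", "two_sample")) {
  test <- match.arg(test)
  frac <- function(path) mean(path %in% dp_proteins)
  set.seed(seed)
  rnd <- sample_simple_paths(graph, mpp_result$source, mpp_result$target,
                             n_paths = n_random, max_len = max_len)
  if (!length(rnd))
    stop("endpoints are disconnected under the sampling constraints")
  mpp_frac <- frac(mpp_result$path)
  rnd_frac <- vapply(rnd, frac, numeric(1))
  if (mpp_frac == 0 && all(rnd_frac == 0)) {
    return(structure(list(source = mpp_result$source,
                          target = mpp_result$target,
                          mpp_dp_fraction = 0, random_dp_fractions = rnd_frac,
                          p_value = NA_real_, verdict = "no_dp_on_any_path"),
                     class = "path_enrichment"))
  }
  if (length(rnd_frac) < 2L || stats::sd(rnd_frac) == 0) {
    # degenerate sample: decide by direct comparison
    p <- if (mpp_frac > mean(rnd_frac)) 0 else 1
  } else {
    # one-sided: random fractions centred below the MPP fraction
    p <- t.test(rnd_frac, mu = mpp_frac, alternative = "less")$p.value
  }
  structure(
    list(source = mpp_result$source, target = mpp_result$target,
         mpp_dp_fraction = mpp_frac, random_dp_fractions = rnd_frac,
         p_value = p,
         verdict = if (p < alpha && mpp_frac > mean(rnd_frac)) "enriched"
                   else "not_significant"),
    class = "path_enrichment"
  )
}

#' Collapse a phosphosite table to DP proteins
#'
#' @param sites data.frame with columns `protein` and `lfc` (site-level
#'   log fold changes).
#' @param cutoff absolute fold-change cutoff: a protein is DP when the
#'   highest `|lfc|` over its sites reaches the cutoff.
#' @return character vector of DP proteins.
#' @export
dp_proteins_from_sites <- function(sites, cutoff) {
  mx <- tapply(abs(sites$lfc), sites$protein, max)
  names(mx)[mx >= cutoff]
}

#' Topological distance of candidates vs non-candidates to targets
#'
#' For every molecule the directed shortest-path distance to each target
#' is computed in both orientations and the shorter one kept per target;
#' distances are averaged over reachable targets.  Candidate and
#' non-candidate average distances are compared with a rank-sum statistic
#' whose null distribution is obtained by Monte-Carlo label permutation
#' (one-sided: candidates closer).
#'
#' @param signalling a [signed_network()].
#' @param candidates,non_candidates disjoint character vectors of
#'   molecule ids.
#' @param targets character vector of target ids.
#' @param n_mc number of Monte-Carlo permutations, default 100000.
#' @param seed RNG seed.
#' @return list with `statistic` (candidate rank sum), `p_value`,
#'   `effect` (mean candidate minus mean non-candidate distance) and the
#'   per-group average distances.
#' @export
distance_analysis <- function(signalling, candidates, non_candidates,
                              targets, n_mc = 100000L, seed = 1L) {
  if (length(intersect(candidates, non_candidates)))
    stop("candidate and non-candidate sets must be disjoint")
  if (!length(targets)) stop("targets are empty")
  g <- as_igraph(signalling)
  mols <- c(candidates, non_candidates)
  mols <- mols[mols %in% signalling$nodes]
  tg <- intersect(targets, signalling$nodes)
  if (!length(tg)) stop("no target is present in the network")
  d_out <- igraph::distances(g, v = mols, to = tg, mode = "out")
  d_in <- igraph::distances(g, v = mols, to = tg, mode = "in")
  d <- pmin(d_out, d_in)
  avg <- apply(d, 1L, function(row) {
    finite <- is.finite(row)
    if (!any(finite)) NA_real_ else mean(row[finite])
  })
  grp <- ifelse(names(avg) %in% candidates, "candidate", "non_candidate")
  ok <- !is.na(avg)
  avg <- avg[ok]; grp <- grp[ok]
  if (!any(grp == "candidate") || !any(grp == "non_candidate"))
    stop("no molecule reaches any target in one of the groups")
  r <- rank(avg)
  is_cand <- grp == "candidate"
  obs <- sum(r[is_cand])
  n_cand <- sum(is_cand)
  set.seed(seed)
  perm <- vapply(seq_len(n_mc), function(i)
    sum(r[sample.int(length(r), n_cand)]), numeric(1))
  p <- (1 + sum(perm <= obs)) / (n_mc + 1)
  list(statistic = obs, p_value = p,
       effect = mean(avg[is_cand]) - mean(avg[!is_cand]),
       mean_candidate = mean(avg[is_cand]),
       mean_non_candidate = mean(avg[!is_cand]),
       n_candidate = n_cand, n_non_candidate = sum(!is_cand))
}
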