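# Most probably expressed paths (MPPs) over the signalling network.
#
# The score of a simple directed path x -> ... -> y is the product of the
# expression probabilities of its intermediate nodes (source and target
# contribute factor 1).  Two variants:
#  * correlation: per-edge contributions may be boosted to max(p(v), |r|)
#    when the expression correlation r of the endpoints exceeds the
#    threshold in absolute value and matches the edge sign;
#  * length: the plain product is additionally multiplied by e^-n for a
#    path with n edges.
# Maximisation is a shortest-path problem under additive -log weights
# (+1 per edge in log space for the length variant); all per-edge costs
# are >= 0, so optimal walks are simple.  Ties are broken deterministically
# by (fewer edges, lexicographic node sequence, positive sign).
#
# Implementation: one label-correcting sweep per *target* on the reversed
# graph gives the MPP from every molecule to that target; labels are
# (cost, hops, suffix sequence) ordered lexicographically, which is
# compatible with path extension, plus the set of achievable path signs
# for the optimal label (parallel edges of opposite sign can tie exactly).

#' Build the weighted scoring graph
#'
#' Drops unspecified-sign edges and nodes with expression probability
#' exactly 0, applies the default probability to unmeasured nodes, and
#' attaches per-edge contributions for both scoring variants.
#'
#' @param net filtered signalling [signed_network()].
#' @param probs named numeric vector of expression probabilities
#'   (typically the initial state of a transition).
#' @param correlations optional data.frame `gene_a`, `gene_b`, `r` of
#'   pairwise expression correlations (symmetric; values in `[-1, 1]`).
#' @param corr_threshold absolute-correlation threshold for the boost,
#'   default 0.7.
#' @param default_prob probability assigned to unmeasured nodes,
#'   default 0.5.
#' @return object of class `scoring_graph`.
#' @export
scoring_graph <- function(net, probs, correlations = NULL,
                          corr_threshold = 0.7, default_prob = 0.5) {
  stopifnot(inherits(net, "signed_network"))
  p <- setNames(rep(default_prob, length(net$nodes)), net$nodes)
  known <- intersect(names(probs), net$nodes)
  p[known] <- probs[known]
  if (any(p < 0 | p > 1)) stop("expression probabilities must lie in [0, 1]")
  nodes <- net$nodes[p > 0]                     # p = 0 excludes the node
  p <- p[nodes]
  e <- net$edges
  e <- e[e$sign != 0L & e$source %in% nodes & e$target %in% nodes &
           e$source != e$target, c("source", "target", "sign")]
  e <- unique(e)
  contrib <- unname(p[e$target])
  boosted <- contrib
  if (!is.null(correlations) && nrow(e)) {
    if (any(abs(correlations$r) > 1))
      stop("correlations must lie in [-1, 1]")
    ckey <- c(paste(correlations$gene_a, correlations$gene_b),
              paste(correlations$gene_b, correlations$gene_a))
    cval <- rep(correlations$r, 2L)
    cval <- cval[!duplicated(ckey)]
    ckey <- ckey[!duplicated(ckey)]
    r <- cval[match(paste(e$source, e$target), ckey)]
    boost <- !is.na(r) & abs(r) > corr_threshold & sign(r) == e$sign
    boosted[boost] <- pmax(contrib[boost], abs(r[boost]))
  }
  idx <- setNames(seq_along(nodes), nodes)
  edges <- data.frame(from = unname(idx[e$source]), to = unname(idx[e$target]),
                      sign = e$sign, contrib_base = contrib,
                      contrib_corr = boosted)
  structure(
    list(nodes = nodes, p = p, edges = edges,
         in_edges = split(edges[, c("from", "sign", "contrib_base",
                                    "contrib_corr")],
                          factor(edges$to, levels = seq_along(nodes)))),
    class = "scoring_graph"
  )
}

#' @export
print.scoring_graph <- function(x, ...) {
  cat(sprintf("<scoring_graph: %d nodes, %d signed edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# lexicographic comparison of integer vectors a, b (equal length);
# returns -1, 0, 1
.cmp_seq <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) return(0L)
  if (a[d[1L]] < b[d[1L]]) -1L else 1L
}

# Labels from every node to `target_i` (node index).  Returns parallel
# vectors/lists over nodes: cost, hops, seq (suffix node-index sequence
# including the node itself and the target), spos/sneg (achievable path
# signs of the optimal label class).
.mpp_labels <- function(graph, target_i, variant = c("correlation", "length")) {
  variant <- match.arg(variant)
  n <- length(graph$nodes)
  lenpen <- variant == "length"
  contrib <- if (variant == "length") graph$edges$contrib_base else
    graph$edges$contrib_corr
  cost <- numeric(nrow(graph$edges))
  interm <- graph$edges$to != target_i        # target itself contributes 1
  cost[interm] <- -log(contrib[interm])
  if (lenpen) cost <- cost + 1

  d <- rep(Inf, n); h <- rep(NA_integer_, n)
  seqs <- vector("list", n)
  spos <- logical(n); sneg <- logical(n)
  d[target_i] <- 0; h[target_i] <- 0L
  seqs[[target_i]] <- target_i; spos[target_i] <- TRUE

  # node-name order for lexicographic sequence comparison
  name_rank <- rank(graph$nodes, ties.method = "first")

  queue <- target_i
  inq <- logical(n); inq[target_i] <- TRUE
  edge_by_to <- graph$in_edges
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; inq[v] <- FALSE
    ein <- edge_by_to[[v]]
    if (is.null(ein) || !nrow(ein)) next
    ecost <- cost[as.integer(rownames(ein))]
    for (ui in unique(ein$from)) {
      if (ui == target_i) next
      rows <- which(ein$from == ui)
      emin <- min(ecost[rows])
      esigns <- unique(ein$sign[rows][ecost[rows] == emin])
      cand_d <- d[v] + emin
      if (!is.finite(cand_d)) next
      cand_h <- h[v] + 1L
      better <- FALSE; merge <- FALSE
      if (!is.finite(d[ui])) {
        better <- TRUE
      } else {
        tol <- 1e-12 * max(1, cand_d, d[ui])
        if (cand_d < d[ui] - tol) {
          better <- TRUE
        } else if (cand_d <= d[ui] + tol) {       # cost tie
          if (cand_h < h[ui]) better <- TRUE
          else if (cand_h == h[ui]) {
            cc <- .cmp_seq(name_rank[c(ui, seqs[[v]])], name_rank[seqs[[ui]]])
            if (cc < 0L) better <- TRUE
            if (cc == 0L) merge <- TRUE
          }
        }
      }
      pos_via_v <- (1L %in% esigns && spos[v]) || (-1L %in% esigns && sneg[v])
      neg_via_v <- (1L %in% esigns && sneg[v]) || (-1L %in% esigns && spos[v])
      if (better) {
        d[ui] <- cand_d; h[ui] <- cand_h
        seqs[[ui]] <- c(ui, seqs[[v]])
        spos[ui] <- pos_via_v; sneg[ui] <- neg_via_v
        if (!inq[ui]) { queue <- c(queue, ui); inq[ui] <- TRUE }
      } else if (merge) {
        np <- spos[ui] || pos_via_v
        nn <- sneg[ui] || neg_via_v
        if (np != spos[ui] || nn != sneg[ui]) {
          spos[ui] <- np; sneg[ui] <- nn
          if (!inq[ui]) { queue <- c(queue, ui); inq[ui] <- TRUE }
        }
      }
    }
  }
  list(d = d, h = h, seqs = seqs, spos = spos, sneg = sneg)
}

#' Most probably expressed path between two molecules
#'
#' @param graph a [scoring_graph()].
#' @param source,target molecule ids (must differ).
#' @param variant `"correlation"` or `"length"`.
#' @return `NULL` when `target` is unreachable from `source`; otherwise a
#'   `mpp_result` list with `source`, `target`, `path` (node ids),
#'   `probability` (the variant-specific M), `sign` (+1/-1, ties broken
#'   towards +1), `sign_ambiguous` (TRUE when an equally probable
#'   opposite-sign path exists) and `variant`.
#' @export
mpp <- function(graph, source, target, variant = c("correlation", "length")) {
  variant <- match.arg(variant)
  stopifnot(inherits(graph, "scoring_graph"))
  if (identical(source, target)) stop("source and target must differ")
  si <- match(source, graph$nodes); ti <- match(target, graph$nodes)
  if (is.na(si) || is.na(ti)) return(NULL)
  lab <- .mpp_labels(graph, ti, variant)
  if (!is.finite(lab$d[si])) return(NULL)
  sign <- if (lab$spos[si]) 1L else -1L
  structure(
    list(source = source, target = target,
         path = graph$nodes[lab$seqs[[si]]],
         probability = exp(-lab$d[si]),
         sign = sign, sign_ambiguous = lab$spos[si] && lab$sneg[si],
         variant = variant),
    class = "mpp_result"
  )
}

#' Sign of a path
#'
#' Product of edge signs along a node sequence.  When consecutive nodes
#' are joined by parallel edges of opposite sign the positive edge is
#' preferred (deterministic tie-break).
#'
#' @param path character vector of node ids.
#' @param graph a [scoring_graph()].
#' @return +1 or -1.
#' @export
path_sign <- function(path, graph) {
  stopifnot(inherits(graph, "scoring_graph"))
  idx <- match(path, graph$nodes)
  if (anyNA(idx)) stop("path contains nodes absent from the graph")
  s <- 1L
  for (k in seq_len(length(idx) - 1L)) {
    rows <- graph$edges$from == idx[k] & graph$edges$to == idx[k + 1L]
    signs <- graph$edges$sign[rows]
    if (!length(signs)) stop("path uses a missing edge: ",
                             path[k], " -> ", path[k + 1L])
    if (any(signs == 0L)) stop("path uses an unspecified-sign edge")
    s <- s * max(signs)
  }
  s
}

#' MPP probabilities and signs from every molecule to a set of targets
#'
#' One reverse sweep per target; the workhorse behind
#' [molecule_profiles()] and the pipeline.
#'
#' @param graph a [scoring_graph()].
#' @param targets character vector of target ids (interface TFs).
#' @param variant `"correlation"` or `"length"`.
#' @return list of matrices (`molecules x targets`): `M` (probabilities,
#'   `NA` when unreachable), `sign` (+1/-1/`NA`) and `ambiguous` (logical).
#' @export
mpp_field <- function(graph, targets, variant = c("correlation", "length")) {
  variant <- match.arg(variant)
  targets <- intersect(targets, graph$nodes)
  n <- length(graph$nodes)
  M <- matrix(NA_real_, n, length(targets),
              dimnames = list(graph$nodes, targets))
  S <- matrix(NA_integer_, n, length(targets),
              dimnames = list(graph$nodes, targets))
  A <- matrix(FALSE, n, length(targets), dimnames = list(graph$nodes, targets))
  for (y in targets) {
    lab <- .mpp_labels(graph, match(y, graph$nodes), variant)
    ok <- is.finite(lab$d)
    M[ok, y] <- exp(-lab$d[ok])
    S[ok, y] <- ifelse(lab$spos[ok], 1L, -1L)
    A[ok, y] <- lab$spos[ok] & lab$sneg[ok]
  }
  for (y in intersect(targets, rownames(M)))
    M[y, y] <- NA                         # a TF does not route to itself
  list(M = M, sign = S, ambiguous = A)
}

#' Activation and inhibition profiles of one molecule
#'
#' For a molecule `x`, `P_{x,y} = M_{x,y} / sum_i M_{x,i}` over all
#' reachable interface TFs.  In the activation profile a TF with positive
#' MPP sign is assigned state 1 (and state 0 for a negative sign); the
#' inhibition profile flips the assignment.  Both profiles share the same
#' probabilities.
#'
#' @param graph a [scoring_graph()].
#' @param molecule molecule id.
#' @param interface_tfs character vector of interface TFs.
#' @param variant `"correlation"` or `"length"`.
#' @param field optional precomputed [mpp_field()] for these targets.
#' @return list with `activation` and `inhibition`: named numeric vectors
#'   over pair keys (see [pair_key()]) summing to 1, or empty vectors when
#'   the molecule reaches no interface TF.
#' @export
molecule_profiles <- function(graph, molecule, interface_tfs,
                              variant = c("correlation", "length"),
                              field = NULL) {
  variant <- match.arg(variant)
  if (is.null(field)) field <- mpp_field(graph, interface_tfs, variant)
  if (!molecule %in% rownames(field$M))
    return(list(activation = numeric(), inhibition = numeric()))
  m <- field$M[molecule, ]
  s <- field$sign[molecule, ]
  reach <- !is.na(m) & m > 0
  if (!any(reach))
    return(list(activation = numeric(), inhibition = numeric()))
  tfs <- colnames(field$M)[reach]
  p <- m[reach] / sum(m[reach])
  act_state <- ifelse(s[reach] == 1L, 1L, 0L)
  list(
    activation = setNames(as.numeric(p), pair_key(tfs, act_state)),
    inhibition = setNames(as.numeric(p), pair_key(tfs, 1L - act_state))
  )
}
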