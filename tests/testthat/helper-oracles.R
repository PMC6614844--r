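# Independent oracles and random-instance generators.  Everything here is
# deliberately written against the raw data structures (edge data frames,
# named vectors) with its own logic, not by calling the code paths under
# test.

## ---- random instances ------------------------------------------------

# random signed directed (multi)graph as a signed_network
random_signed_net <- function(n_nodes, edge_prob = 0.25, p_zero_sign = 0,
                              p_parallel_opposite = 0) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  from <- rep(nodes, each = n_nodes)
  to <- rep(nodes, n_nodes)
  keep <- from != to & runif(length(from)) < edge_prob
  from <- from[keep]; to <- to[keep]
  sgn <- sample(c(-1L, 1L), length(from), replace = TRUE)
  sgn[runif(length(sgn)) < p_zero_sign] <- 0L
  e <- data.frame(source = from, target = to, sign = sgn,
                  mechanism = "Binding", stringsAsFactors = FALSE)
  dup <- runif(nrow(e)) < p_parallel_opposite & e$sign != 0L
  if (any(dup)) {
    opp <- e[dup, , drop = FALSE]
    opp$sign <- -opp$sign
    e <- rbind(e, opp)
  }
  signed_network(e, "signalling", nodes = nodes)
}

# random Boolean GRN prior (edge df) over n TFs
random_grn_prior <- function(n_tfs, edge_prob = 0.3, p_zero_sign = 0) {
  tfs <- sprintf("g%02d", seq_len(n_tfs))
  from <- rep(tfs, each = n_tfs)
  to <- rep(tfs, n_tfs)
  keep <- from != to & runif(length(from)) < edge_prob
  sgn <- sample(c(-1L, 1L), sum(keep), replace = TRUE)
  sgn[runif(length(sgn)) < p_zero_sign] <- 0L
  list(tfs = tfs,
       edges = data.frame(source = from[keep], target = to[keep],
                          sign = sgn, stringsAsFactors = FALSE))
}

random_state <- function(tfs) setNames(sample(0:1, length(tfs), TRUE), tfs)

## ---- MPP brute-force oracle -------------------------------------------

# contribution of traversing edge row `er` into node `v` (the head), for a
# path whose final target is `target`
.oracle_contrib <- function(er, probs, target, correlations, corr_threshold) {
  if (er$target == target) return(1)
  p <- probs[[er$target]]
  if (!is.null(correlations)) {
    hit <- which((correlations$gene_a == er$source &
                    correlations$gene_b == er$target) |
                   (correlations$gene_b == er$source &
                      correlations$gene_a == er$target))
    if (length(hit)) {
      r <- correlations$r[hit[1L]]
      if (abs(r) > corr_threshold && sign(r) == er$sign)
        return(max(p, abs(r)))
    }
  }
  p
}

# exhaustive enumeration of all simple paths + per-hop parallel-edge
# choices; returns list(probability, sign, path) or NULL, applying the
# documented tie-break: max score, then fewest edges, then lexicographic
# node sequence, then positive sign.
oracle_mpp <- function(net, probs, source, target,
                       variant = c("correlation", "length"),
                       correlations = NULL, corr_threshold = 0.7) {
  variant <- match.arg(variant)
  e <- net$edges[net$edges$sign != 0L & net$edges$source != net$edges$target, ,
                 drop = FALSE]
  keep_node <- names(probs)[probs > 0]
  e <- e[e$source %in% keep_node & e$target %in% keep_node, , drop = FALSE]
  if (!source %in% keep_node || !target %in% keep_node) return(NULL)
  g <- igraph::graph_from_data_frame(unique(e[, c("source", "target")]),
                                     directed = TRUE, vertices = keep_node)
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    mode = "out")
  if (!length(paths)) return(NULL)
  best <- NULL
  for (pth in paths) {
    nodes <- names(pth)
    n <- length(nodes) - 1L
    # per hop: vector of (contribution, sign) options over parallel edges
    opts <- lapply(seq_len(n), function(k) {
      rows <- which(e$source == nodes[k] & e$target == nodes[k + 1L])
      data.frame(
        contrib = vapply(rows, function(ri)
          if (variant == "length") {
            if (nodes[k + 1L] == target) 1 else probs[[nodes[k + 1L]]]
          } else
            .oracle_contrib(e[ri, ], probs, target, correlations,
                            corr_threshold), numeric(1)),
        sign = e$sign[rows])
    })
    choice_grid <- expand.grid(lapply(opts, function(o) seq_len(nrow(o))))
    for (ci in seq_len(nrow(choice_grid))) {
      score <- 1; sgn <- 1L
      for (k in seq_len(n)) {
        o <- opts[[k]][choice_grid[ci, k], ]
        score <- score * o$contrib
        sgn <- sgn * o$sign
      }
      if (variant == "length") score <- score * exp(-n)
      if (score <= 0) next
      cand <- list(probability = score, sign = sgn, path = nodes)
      if (is.null(best)) { best <- cand; next }
      rel <- (cand$probability - best$probability) /
        max(best$probability, cand$probability)
      if (rel > 1e-9) best <- cand
      else if (abs(rel) <= 1e-9) {
        # tie: fewer edges, then lexicographic sequence, then + sign
        bn <- length(best$path); cn <- length(cand$path)
        if (cn < bn) best <- cand
        else if (cn == bn) {
          cmp <- .oracle_cmp_seq(cand$path, best$path)
          if (cmp < 0) best <- cand
          else if (cmp == 0 && cand$sign > best$sign) best <- cand
        }
      }
    }
  }
  best
}

.oracle_cmp_seq <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  0L
}

## ---- Boolean engine oracle --------------------------------------------

# one synchronous majority step computed with an explicit per-node loop
oracle_step <- function(state, edges, tfs, clamped = character()) {
  new <- state
  for (t in setdiff(tfs, clamped)) {
    ein <- edges[edges$target == t & edges$sign != 0L, , drop = FALSE]
    if (!nrow(ein)) next
    act <- state[ein$source] == 1L
    a <- sum(ein$sign[act] == 1L)
    i <- sum(ein$sign[act] == -1L)
    if (a - i > 0) new[t] <- 1L
    else if (a - i < 0) new[t] <- 0L
  }
  new
}

# trajectory from s0 under clamping until fixed point or revisit; uses the
# full enumerable state space implicitly through exact step iteration
oracle_trajectory <- function(s0, edges, tfs, clamped, max_steps = 2^14) {
  seen <- character()
  state <- s0
  for (i in seq_len(max_steps)) {
    key <- paste(state[tfs], collapse = "")
    if (key %in% seen) return(list(converged = FALSE))
    seen <- c(seen, key)
    nxt <- oracle_step(state, edges, tfs, clamped)
    if (identical(nxt[tfs], state[tfs]))
      return(list(converged = TRUE, fixed = state[tfs]))
    state <- nxt
  }
  list(converged = FALSE)
}

## ---- misc oracles -----------------------------------------------------

# P(at least one of K targets in a size-n subset of N) by full enumeration
oracle_hypergeom <- function(N, K, n) {
  if (n == 0) return(0)
  subsets <- combn(N, n)
  targets <- seq_len(K)
  mean(apply(subsets, 2L, function(s) any(s %in% targets)))
}

# brute-force in-degree source nodes
oracle_sources <- function(net) {
  indeg <- setNames(numeric(length(net$nodes)), net$nodes)
  for (t in net$edges$target) indeg[t] <- indeg[t] + 1
  names(indeg)[indeg == 0]
}

# direct-formula JSD on the union support
oracle_jsd <- function(p, q) {
  s <- union(names(p), names(q))
  pv <- ifelse(s %in% names(p), p[s], 0)
  qv <- ifelse(s %in% names(q), q[s], 0)
  m <- (pv + qv) / 2
  kl <- function(x) sum(ifelse(x > 0, x * log(x / m), 0))
  (kl(pv) + kl(qv)) / 2
}

# brute-force combination generator: all TF subsets x allowed states
oracle_combinations <- function(tfs, allowed_states, max_size) {
  out <- character()
  for (k in seq_len(min(max_size, length(tfs)))) {
    for (ss in combn(sort(tfs), k, simplify = FALSE)) {
      grid <- expand.grid(allowed_states[ss], KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid)))
        out <- c(out, paste(ss, unlist(grid[r, ]), sep = "=", collapse = ","))
    }
  }
  sort(out)
}

combo_key <- function(combo)
  paste(names(combo), combo, sep = "=", collapse = ",")

# a tiny fully hand-checkable scoring graph fixture
tiny_two_route_graph <- function() {
  # x -> a -> y (p(a)=0.8)  vs  x -> b -> c -> y (p(b)=p(c)=0.95)
  e <- data.frame(
    source = c("x", "a", "x", "b", "c"),
    target = c("a", "y", "b", "c", "y"),
    sign = c(1L, 1L, 1L, -1L, -1L),
    mechanism = "Binding")
  net <- signed_network(e, "signalling")
  probs <- c(x = 0.9, a = 0.8, b = 0.95, c = 0.95, y = 0.99)
  list(net = net, probs = probs,
       graph = scoring_graph(net, probs))
}
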