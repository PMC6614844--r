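# In-silico perturbation of interface TFs: clamped Boolean simulation,
# exhaustive combination enumeration, BPC selection and the Q distribution.
#
# A TF-state pair is encoded as "<tf>|<0 or 1>"; a combination is a named
# integer vector (names = interface TFs, values = clamped states).

#' Encode TF-state pairs
#' @param tf character vector of TF ids.
#' @param state 0/1 vector.
#' @return character keys `"<tf>|<state>"`.
#' @export
pair_key <- function(tf, state) paste(tf, as.integer(state), sep = "|")

#' Identify interface transcription factors
#'
#' Interface TFs connect the signalling layer to the GRN: they (i)
#' regulate at least one GRN-TF in the regulatory prior, (ii) are
#' expressed at the initial time point and (iii) are reachable from a
#' 0-indegree source node of the signalling network through a directed
#' path whose every node is expressed initially (nodes absent from the
#' transition are treated as expressed).
#'
#' @param signalling filtered signalling [signed_network()].
#' @param regulatory regulatory [signed_network()] over the TF universe.
#' @param grn a [transition_grn()].
#' @param transition a [build_transition()] result (initial states used).
#' @return character vector of interface-TF ids (sorted).
#' @export
identify_interface_tfs <- function(signalling, regulatory, grn, transition) {
  regulates_grn <- unique(
    regulatory$edges$source[regulatory$edges$target %in% grn$tfs])
  expressed <- function(ids) {
    known <- ids %in% transition$genes
    out <- rep(TRUE, length(ids))            # unmeasured: treated expressed
    out[known] <- transition$state_initial[ids[known]] == 1L
    out
  }
  cand <- regulates_grn[expressed(regulates_grn)]
  cand <- cand[cand %in% signalling$nodes]
  if (!length(cand)) return(character())
  # reachability from sources within the expressed induced subgraph
  keep_nodes <- signalling$nodes[expressed(signalling$nodes)]
  sub_edges <- signalling$edges[signalling$edges$source %in% keep_nodes &
                                  signalling$edges$target %in% keep_nodes, ,
                                drop = FALSE]
  sources <- intersect(source_nodes(signalling), keep_nodes)
  if (!length(sources)) return(character())
  g <- igraph::graph_from_data_frame(
    unique(sub_edges[, c("source", "target")]),
    directed = TRUE, vertices = keep_nodes)
  reach <- unique(unlist(lapply(
    igraph::ego(g, order = length(keep_nodes), nodes = sources,
                mode = "out"),
    names)))
  sort(intersect(cand, reach))
}

#' Simulate the GRN under a clamped interface-TF combination
#'
#' Clamped combination TFs are fixed at their assigned state; every other
#' external input source of the GRN is held constant at its value in
#' `external_inputs` (by default its initial Boolean expression state).
#' The network is updated synchronously from `s_init` until a fixed point
#' or a revisited state.
#'
#' @param grn a [transition_grn()] with input edges attached.
#' @param s_init named 0/1 vector over the GRN-TFs.
#' @param combination named 0/1 vector: interface TFs to clamp.
#' @param external_inputs named 0/1 vector of held states for all
#'   non-perturbed external input sources.
#' @param max_steps simulation step budget, default 1000.
#' @return a `perturbation_result` list: `combination`, `flipped`
#'   (GRN-TFs differing from `s_init` at the fixed point),
#'   `flipping_score` (`-1` when not converged) and `converged`.
#' @export
simulate_clamped <- function(grn, s_init, combination,
                             external_inputs = integer(), max_steps = 1000L) {
  stopifnot(inherits(grn, "transition_grn"))
  if (anyDuplicated(names(combination)))
    stop("combination assigns more than one state to a TF")
  state <- c(.check_state(s_init, grn$tfs), external_inputs)
  for (tf in setdiff(names(combination), names(state)))
    state[tf] <- 0L                            # value set by the clamp below
  ext <- setdiff(unique(grn$input_edges$source), names(state))
  if (length(ext))
    stop("missing external input states for: ", paste(ext, collapse = ", "))
  state[names(combination)] <- as.integer(combination)
  clamped <- union(names(combination),
                   setdiff(names(external_inputs), grn$tfs))
  # matrix form of the majority rule: W[r, t] = sum of signs of edges
  # r -> t; push = state %*% W reproduces a - i including multiplicity
  nodes <- names(state)
  edges <- rbind(grn$edges, grn$input_edges)
  edges <- edges[edges$sign != 0L, , drop = FALSE]
  W <- matrix(0L, length(nodes), length(grn$tfs),
              dimnames = list(nodes, grn$tfs))
  if (nrow(edges))
    for (k in seq_len(nrow(edges)))
      W[edges$source[k], edges$target[k]] <-
        W[edges$source[k], edges$target[k]] + edges$sign[k]
  has_reg <- colSums(W != 0L) > 0L
  free <- setdiff(grn$tfs[has_reg], clamped)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  converged <- FALSE
  for (step in seq_len(max_steps)) {
    key <- paste(state[grn$tfs], collapse = "")
    if (!is.null(seen[[key]])) break          # cycle: no fixed point
    seen[[key]] <- TRUE
    push <- as.vector(state[nodes] %*% W)
    names(push) <- grn$tfs
    new <- state
    p <- push[free]
    new[free] <- ifelse(p > 0, 1L, ifelse(p < 0, 0L, state[free]))
    if (identical(new[grn$tfs], state[grn$tfs])) { converged <- TRUE; break }
    state <- new
  }
  flipped <- if (converged)
    grn$tfs[state[grn$tfs] != s_init[grn$tfs]] else character()
  structure(
    list(combination = combination, flipped = flipped,
         flipping_score = if (converged) length(flipped) else -1L,
         converged = converged),
    class = "perturbation_result"
  )
}

#' Enumerate interface-TF-state combinations
#'
#' All sets of 1..`max_size` interface TFs, each TF contributing one
#' clamped state.  A TF whose Boolean expression differs between the
#' initial and final condition is only clamped to its final state (its
#' required direction is known); all other TFs are enumerated in both
#' states (their activity at the initial time point is unknown).
#'
#' @param interface_tfs character vector of interface-TF ids.
#' @param transition a [build_transition()] result (used to detect
#'   differential interface TFs); may be `NULL` to enumerate both states
#'   for every TF.
#' @param max_size maximum combination size, default 4.
#' @param differential_tf_states `"final_only"` (default) or `"both"`.
#' @return list of named 0/1 integer vectors, in deterministic
#'   lexicographic order.
#' @export
enumerate_combinations <- function(interface_tfs, transition = NULL,
                                   max_size = 4L,
                                   differential_tf_states = c("final_only", "both")) {
  differential_tf_states <- match.arg(differential_tf_states)
  if (max_size < 1L) stop("max_size must be >= 1")
  tfs <- sort(unique(interface_tfs))
  states <- lapply(tfs, function(t) {
    if (!is.null(transition) && differential_tf_states == "final_only" &&
        t %in% transition$genes &&
        transition$state_initial[[t]] != transition$state_final[[t]])
      transition$state_final[[t]]
    else c(0L, 1L)
  })
  names(states) <- tfs
  out <- list()
  for (k in seq_len(min(max_size, length(tfs)))) {
    subsets <- combn(tfs, k, simplify = FALSE)
    for (ss in subsets) {
      grid <- expand.grid(rev(states[ss]), KEEP.OUT.ATTRS = FALSE)
      grid <- grid[, rev(seq_along(ss)), drop = FALSE]   # lexicographic order
      for (r in seq_len(nrow(grid))) {
        combo <- as.integer(grid[r, ])
        names(combo) <- ss
        out[[length(out) + 1L]] <- combo
      }
    }
  }
  out
}

#' Remove non-synergistic combinations
#'
#' A multi-TF combination is dropped when its flipped set equals the union
#' of the flipped sets of its constituent singleton perturbations;
#' singletons are never dropped.
#'
#' @param bpcs list of `perturbation_result`s.
#' @param singleton_results named list mapping pair keys
#'   (see [pair_key()]) to flipped-set character vectors.
#' @return the filtered list.
#' @export
synergy_filter <- function(bpcs, singleton_results) {
  keep <- vapply(bpcs, function(res) {
    if (length(res$combination) <= 1L) return(TRUE)
    keys <- pair_key(names(res$combination), res$combination)
    missing <- setdiff(keys, names(singleton_results))
    if (length(missing))
      stop("missing singleton results for: ", paste(missing, collapse = ", "))
    union_flips <- sort(unique(unlist(singleton_results[keys])))
    !identical(sort(res$flipped), union_flips)
  }, logical(1))
  bpcs[keep]
}

#' Select best-performing combinations (BPCs)
#'
#' Keeps every converged combination whose flipping score is among the
#' `best` highest distinct scores (ties included), removes non-synergistic
#' combinations with [synergy_filter()], derives the TF-state frequency
#' distribution Q with [compute_q()], and raises a dataset-level flag when
#' the best flipping score covers less than `min_flip_fraction` of the
#' GRN-TFs.
#'
#' @param results list of `perturbation_result`s (all enumerated
#'   combinations; non-converged entries are ignored).
#' @param n_grn_tfs number of GRN-TFs (for the coverage flag).
#' @param best number of top distinct scores to keep, default 3.
#' @param min_flip_fraction flag threshold, default 0.4.
#' @return object of class `bpc_set`: list with `combinations`, `q`,
#'   `best_score`, `flag_low_flip` and `scores`.
#' @export
select_bpcs <- function(results, n_grn_tfs, best = 3L, min_flip_fraction = 0.4) {
  results <- Filter(function(r) isTRUE(r$converged), results)
  if (!length(results)) stop("no converged perturbation results")
  scores <- vapply(results, `[[`, integer(1), "flipping_score")
  top <- head(sort(unique(scores), decreasing = TRUE), best)
  kept <- results[scores %in% top]
  singles <- results[lengths(lapply(results, `[[`, "combination")) == 1L]
  singleton_results <- setNames(
    lapply(singles, `[[`, "flipped"),
    vapply(singles, function(r)
      pair_key(names(r$combination), r$combination), character(1)))
  kept <- synergy_filter(kept, singleton_results)
  if (!length(kept)) stop("no combinations left after synergy filtering")
  best_score <- max(scores)
  structure(
    list(combinations = kept, q = compute_q(kept), best_score = best_score,
         flag_low_flip = best_score < min_flip_fraction * n_grn_tfs,
         scores = sort(top, decreasing = TRUE)),
    class = "bpc_set"
  )
}

#' @export
print.bpc_set <- function(x, ...) {
  cat(sprintf("<bpc_set: %d BPCs, best score %d%s>\n",
              length(x$combinations), x$best_score,
              if (x$flag_low_flip) ", LOW-FLIP FLAG" else ""))
  invisible(x)
}

#' Frequency distribution Q over interface-TF-state pairs
#'
#' `F_s = k_s / k` where `k` is the number of BPCs and `k_s` the number of
#' BPCs containing pair `s`; Q is F normalized to sum to one.  Pairs absent
#' from every BPC do not appear.
#'
#' @param bpcs list of `perturbation_result`s.
#' @return named numeric vector (pair keys) summing to 1.
#' @export
compute_q <- function(bpcs) {
  if (!length(bpcs)) stop("empty BPC set")
  keys <- unlist(lapply(bpcs, function(r)
    pair_key(names(r$combination), r$combination)))
  f <- table(keys) / length(bpcs)
  q <- as.numeric(f) / sum(f)
  names(q) <- names(f)
  q[order(names(q))]
}
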