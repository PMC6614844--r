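# Transition-specific Boolean GRN: majority update, attractor check,
# consistency pruning.
#
# Update semantics (synchronous majority/threshold rule): for a TF t with
# signed regulators, let a = number of activating regulators in state 1 and
# i = number of inhibiting regulators in state 1.  t becomes 1 if a - i > 0,
# 0 if a - i < 0, and keeps its state on a tie or when it has no regulator.
# Unspecified-sign (0) edges carry no Boolean semantics: they are excluded
# from the majority sum but count as connectivity for the size filter.

#' Construct a transition GRN
#'
#' @param tfs character vector of GRN-TF ids (all differential).
#' @param edges data.frame `source`, `target`, `sign` restricted to `tfs`
#'   (for internal edges) — external inputs are attached later with
#'   [add_external_inputs()].
#' @param s_init,s_final named 0/1 vectors over `tfs`.
#' @param removed optional data.frame of pruned edges (with `reason`).
#' @return object of class `transition_grn`.
#' @export
transition_grn <- function(tfs, edges, s_init, s_final, removed = NULL) {
  tfs <- as.character(tfs)
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  edges <- as.data.frame(edges[, c("source", "target", "sign")],
                         stringsAsFactors = FALSE)
  if (!all(c(edges$source, edges$target) %in% tfs))
    stop("GRN edges must connect GRN-TFs only")
  s_init <- .check_state(s_init, tfs)
  s_final <- .check_state(s_final, tfs)
  structure(
    list(tfs = tfs, edges = edges, s_init = s_init, s_final = s_final,
         input_edges = data.frame(source = character(), target = character(),
                                  sign = integer(), stringsAsFactors = FALSE),
         removed = removed),
    class = "transition_grn"
  )
}

.check_state <- function(state, tfs) {
  missing <- setdiff(tfs, names(state))
  if (length(missing))
    stop("Boolean state missing TFs: ", paste(missing, collapse = ", "))
  out <- as.integer(state[tfs])
  if (any(!out %in% c(0L, 1L))) stop("Boolean states must be 0/1")
  names(out) <- tfs
  out
}

#' @export
print.transition_grn <- function(x, ...) {
  cat(sprintf("<transition_grn: %d TFs, %d internal edges, %d input edges>\n",
              length(x$tfs), nrow(x$edges), nrow(x$input_edges)))
  invisible(x)
}

#' Attach external (interface-TF) input edges to a GRN
#'
#' Input edges point from molecules outside the GRN (typically interface
#' TFs) into GRN-TFs; their source states are supplied at simulation time.
#'
#' @param grn a [transition_grn()].
#' @param edges data.frame `source`, `target`, `sign` with targets in the
#'   GRN and sources outside it.
#' @return the GRN with `input_edges` set.
#' @export
add_external_inputs <- function(grn, edges) {
  stopifnot(inherits(grn, "transition_grn"))
  edges <- as.data.frame(edges[, c("source", "target", "sign")],
                         stringsAsFactors = FALSE)
  if (!all(edges$target %in% grn$tfs))
    stop("input edges must target GRN-TFs")
  if (any(edges$source %in% grn$tfs))
    stop("input edges must come from outside the GRN")
  grn$input_edges <- unique(edges)
  grn
}

#' Differentially expressed transcription factors
#'
#' @param transition a [build_transition()] result.
#' @param tf_universe character vector of TF ids.
#' @return TFs of the universe whose Boolean state differs between the
#'   initial and final condition.
#' @export
differential_tfs <- function(transition, tf_universe) {
  stopifnot(inherits(transition, "boolean_transition"))
  tfs <- intersect(tf_universe, transition$genes)
  tfs[transition$state_initial[tfs] != transition$state_final[tfs]]
}

#' One synchronous majority-rule update
#'
#' @param state named 0/1 vector covering all GRN-TFs and every external
#'   input source present in the GRN.
#' @param grn a [transition_grn()].
#' @param clamped character vector of TF ids held fixed at their value in
#'   `state`.
#' @return the updated state (same names as `state`; only GRN-TFs change).
#' @export
majority_update <- function(state, grn, clamped = character()) {
  stopifnot(inherits(grn, "transition_grn"))
  edges <- rbind(grn$edges, grn$input_edges)
  need <- unique(c(grn$tfs, edges$source))
  missing <- setdiff(need, names(state))
  if (length(missing))
    stop("state is missing nodes: ", paste(missing, collapse = ", "))
  new <- state
  active <- state[edges$source] == 1L & edges$sign != 0L
  push <- tapply(edges$sign[active], edges$target[active], sum)
  upd <- setdiff(intersect(names(push), grn$tfs), clamped)
  if (length(upd)) {
    p <- push[upd]
    new[upd] <- ifelse(p > 0, 1L, ifelse(p < 0, 0L, state[upd]))
  }
  new
}

#' Is a state a point attractor?
#'
#' True iff one synchronous majority update (without clamping, internal
#' edges only) maps the state to itself.
#'
#' @param state named 0/1 vector over the GRN-TFs.
#' @param grn a [transition_grn()].
#' @return logical.
#' @export
is_point_attractor <- function(state, grn) {
  internal <- grn
  internal$input_edges <- internal$input_edges[0L, , drop = FALSE]
  state <- state[grn$tfs]
  identical(unname(majority_update(state, internal)[grn$tfs]),
            unname(state))
}

#' Prune a regulatory prior so both states are point attractors
#'
#' The point-attractor condition decomposes over nodes: the fixed-point
#' constraint of TF `v` involves only its incoming edges.  For each TF the
#' maximum-cardinality subset of incoming signed edges satisfying the
#' constraint in both states is kept (exact subset search; ties broken by
#' preferring activating edges, then lexicographic source/target id).
#' Unspecified-sign edges never enter the majority sum and are always kept.
#' The empty edge set is always feasible, so pruning always succeeds.
#'
#' @param prior a [signed_network()] (or edge data.frame) whose edges
#'   connect differential TFs.
#' @param s_init,s_final named 0/1 vectors over the differential TFs.
#' @param max_exact_indegree in-degrees above this fall back to a greedy
#'   repair (drop conflicting edges by increasing preference) instead of
#'   the exponential exact search.
#' @return a [transition_grn()] with `removed` listing pruned edges.
#' @export
prune_to_attractors <- function(prior, s_init, s_final,
                                max_exact_indegree = 20L) {
  edges <- if (inherits(prior, "signed_network")) prior$edges else prior
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  tfs <- sort(unique(names(s_init)))
  if (!setequal(tfs, names(s_final)))
    stop("s_init and s_final must cover the same TFs")
  if (nrow(edges) && !all(c(edges$source, edges$target) %in% tfs))
    stop("prior edges must connect differential TFs only")
  s_init <- s_init[tfs]; s_final <- s_final[tfs]

  kept <- list(); removed <- list()
  for (v in tfs) {
    ein <- edges[edges$target == v, , drop = FALSE]
    if (!nrow(ein)) next
    zero <- ein[ein$sign == 0L, , drop = FALSE]    # no Boolean semantics
    ein <- ein[ein$sign != 0L, , drop = FALSE]
    kept[[length(kept) + 1L]] <- zero
    if (!nrow(ein)) next
    # canonical order: activating first, then source, then mechanism cols
    ord <- order(-ein$sign, ein$source, seq_len(nrow(ein)))
    ein <- ein[ord, , drop = FALSE]
    feasible <- function(sel) {
      ok <- TRUE
      for (st in list(s_init, s_final)) {
        push <- sum(ein$sign[sel][st[ein$source[sel]] == 1L])
        want <- st[[v]]
        if ((push > 0 && want == 0L) || (push < 0 && want == 1L)) ok <- FALSE
      }
      ok
    }
    n <- nrow(ein)
    best <- logical(n)
    if (n <= max_exact_indegree) {
      # enumerate subsets largest-first in canonical order; stop at first hit
      found <- FALSE
      for (k in n:0) {
        if (found) break
        combs <- combn(n, k)
        for (j in seq_len(ncol(combs))) {
          sel <- logical(n); sel[combs[, j]] <- TRUE
          if (feasible(sel)) { best <- sel; found <- TRUE; break }
        }
      }
    } else {
      # greedy: drop least-preferred edges until feasible
      sel <- rep(TRUE, n)
      for (j in n:1) {
        if (feasible(sel)) break
        sel[j] <- FALSE
      }
      best <- sel
    }
    kept[[length(kept) + 1L]] <- ein[best, , drop = FALSE]
    if (any(!best)) {
      rem <- ein[!best, , drop = FALSE]
      rem$reason <- "attractor_conflict"
      removed[[length(removed) + 1L]] <- rem
    }
  }
  kept_df <- if (length(kept)) do.call(rbind, kept) else edges[0L, , drop = FALSE]
  removed_df <- if (length(removed)) do.call(rbind, removed) else NULL
  if (!is.null(removed_df)) rownames(removed_df) <- NULL
  rownames(kept_df) <- NULL
  grn <- transition_grn(tfs, kept_df, s_init, s_final, removed = removed_df)
  stopifnot(is_point_attractor(s_init, grn), is_point_attractor(s_final, grn))
  grn
}

#' Does the pruned GRN pass the minimum-size filter?
#'
#' @param grn a [transition_grn()].
#' @param min_tfs minimum number of connected TFs (TFs with at least one
#'   incident internal edge of any sign), default 10; the boundary is
#'   inclusive.
#' @return logical.
#' @export
grn_passes_filter <- function(grn, min_tfs = 10L) {
  stopifnot(inherits(grn, "transition_grn"))
  connected <- unique(c(grn$edges$source, grn$edges$target))
  length(connected) >= min_tfs
}
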