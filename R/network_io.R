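# Signed prior-knowledge networks: parsing, filtering, topology queries.
#
# Networks are SIF-like 4-column TSVs: source <TAB> effect <TAB> mechanism
# <TAB> target.  Effects map to signs: Activation -> +1, Inhibition -> -1,
# Unspecified/Technical -> 0 (label retained so that effect-based filters
# can still see "Technical").  Parallel edges between the same pair with
# different sign or mechanism are retained as distinct edges.

.EFFECT_SIGNS <- c(
  "Activation"  = 1L,
  "Inhibition"  = -1L,
  "Unspecified" = 0L,
  "Technical"   = 0L
)

# Default exclusions applied to a signalling-kind network.
SIGNALLING_EXCLUDED_EFFECTS <- c("Technical", "Unspecified")
SIGNALLING_EXCLUDED_MECHANISMS <- c(
  "Technical", "Transcriptional Regulation", "Influence on Expression",
  "Catalysis", "Transport"
)

# Mechanism / effect whitelists defining the transcriptional prior.
REGULATORY_MECHANISMS <- c(
  "Transcriptional regulation", "Influence on Expression", "Regulation"
)
REGULATORY_EFFECTS <- c("Activation", "Inhibition", "Unspecified")

#' Construct a signed network from an edge table
#'
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (integer in -1/0/+1), `mechanism` and optionally `effect` (original
#'   effect label; reconstructed from the sign when absent).
#' @param kind `"signalling"` or `"regulatory"`.
#' @param nodes optional character vector of node ids; edge endpoints are
#'   always added.
#' @return An object of class `signed_network`: a list with elements
#'   `nodes` (character), `edges` (data.frame) and `kind`.
#' @export
signed_network <- function(edges = NULL, kind = c("signalling", "regulatory"),
                           nodes = character()) {
  kind <- match.arg(kind)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), mechanism = character(),
                        effect = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    required <- c("source", "target", "sign", "mechanism")
    missing_cols <- setdiff(required, names(edges))
    if (length(missing_cols))
      stop("edge table lacks columns: ", paste(missing_cols, collapse = ", "))
    if (is.null(edges$effect)) {
      edges$effect <- c("Inhibition", "Unspecified", "Activation")[edges$sign + 2L]
    }
    edges$sign <- as.integer(edges$sign)
    if (any(!edges$sign %in% c(-1L, 0L, 1L)))
      stop("edge signs must be -1, 0 or +1")
    if (any(!nzchar(edges$source)) || any(!nzchar(edges$target)))
      stop("edge endpoints must be non-empty molecule ids")
    edges <- edges[, c("source", "target", "sign", "mechanism", "effect")]
    edges <- unique(edges)
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = sort(unique(c(nodes, edges$source, edges$target))),
         edges = edges, kind = kind),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network (%s): %d nodes, %d edges>\n",
              x$kind, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Parse a signed network from a 4-column TSV
#'
#' Columns are `source`, `effect`, `mechanism`, `target`; lines starting
#' with `#` are comments.  Effect labels `Activation`, `Inhibition`,
#' `Unspecified` and `Technical` are recognised (mapping to signs +1, -1,
#' 0, 0); any other label is an error.
#'
#' @param path file path.
#' @param kind network kind, `"signalling"` or `"regulatory"`.
#' @return a [signed_network()].
#' @export
parse_network <- function(path, kind = c("signalling", "regulatory")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) return(signed_network(NULL, kind))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 4L)) {
    bad <- keep[which(nfield != 4L)[1L]]
    stop(sprintf("malformed network row at line %d of %s (expected 4 tab-separated fields)",
                 bad, path))
  }
  m <- do.call(rbind, parts)
  effect <- m[, 2L]
  unknown <- !effect %in% names(.EFFECT_SIGNS)
  if (any(unknown)) {
    bad <- keep[which(unknown)[1L]]
    stop(sprintf("unknown effect label '%s' at line %d of %s",
                 effect[which(unknown)[1L]], bad, path))
  }
  signed_network(
    data.frame(source = m[, 1L], target = m[, 4L],
               sign = unname(.EFFECT_SIGNS[effect]),
               mechanism = m[, 3L], effect = effect,
               stringsAsFactors = FALSE),
    kind
  )
}

#' Write a signed network to the 4-column TSV dialect
#'
#' @param net a [signed_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  out <- data.frame(source = net$edges$source, effect = net$edges$effect,
                    mechanism = net$edges$mechanism, target = net$edges$target)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sigflip %s network: %d nodes, %d edges",
                     net$kind, length(net$nodes), nrow(net$edges)), con)
  # isolated nodes are preserved as comment metadata so round-trips keep them
  iso <- setdiff(net$nodes, c(net$edges$source, net$edges$target))
  if (length(iso))
    writeLines(paste0("#node\t", iso), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove edges by effect and mechanism label
#'
#' Drops every edge whose effect label is in `excluded_effects` or whose
#' mechanism is in `excluded_mechanisms`.  Nodes left without edges are
#' retained: 0-indegree pathway sources must survive filtering.  Defaults
#' are the standard signalling-network exclusions (Technical/Unspecified
#' effects; Technical, Transcriptional Regulation, Influence on Expression,
#' Catalysis and Transport mechanisms).
#'
#' @param net a [signed_network()].
#' @param excluded_effects,excluded_mechanisms character vectors of labels.
#' @return the filtered [signed_network()].
#' @export
filter_interactions <- function(net,
                                excluded_effects = SIGNALLING_EXCLUDED_EFFECTS,
                                excluded_mechanisms = SIGNALLING_EXCLUDED_MECHANISMS) {
  stopifnot(inherits(net, "signed_network"))
  keep <- !(net$edges$effect %in% excluded_effects |
              net$edges$mechanism %in% excluded_mechanisms)
  out <- net
  out$edges <- net$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Apply an edge blacklist
#'
#' The blacklist TSV has columns `source`, `target`, `mechanism` (used for
#' manually curated removals, e.g. around TF complexes).  All matching
#' edges are removed regardless of sign.
#'
#' @param net a [signed_network()].
#' @param blacklist data.frame with columns `source`, `target`, `mechanism`,
#'   or a path to such a TSV (with header).
#' @return the filtered network.
#' @export
apply_edge_blacklist <- function(net, blacklist) {
  stopifnot(inherits(net, "signed_network"))
  if (is.character(blacklist))
    blacklist <- read.delim(blacklist, stringsAsFactors = FALSE)
  key <- function(s, t, m) paste(s, t, m, sep = "\r")
  drop <- key(net$edges$source, net$edges$target, net$edges$mechanism) %in%
    key(blacklist$source, blacklist$target, blacklist$mechanism)
  out <- net
  out$edges <- net$edges[!drop, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Restrict a network to the transcriptional-regulation prior
#'
#' Keeps edges whose mechanism is `Transcriptional regulation`,
#' `Influence on Expression` or `Regulation`, whose effect is `Activation`,
#' `Inhibition` or `Unspecified`, and whose endpoints both lie in
#' `tf_universe`.
#'
#' @param net a regulatory-kind [signed_network()].
#' @param tf_universe character vector of transcription-factor ids.
#' @return the restricted [signed_network()] (nodes = `tf_universe`).
#' @export
regulatory_prior <- function(net, tf_universe) {
  stopifnot(inherits(net, "signed_network"))
  if (!length(tf_universe)) stop("tf_universe is empty")
  keep <- net$edges$mechanism %in% REGULATORY_MECHANISMS &
    net$edges$effect %in% REGULATORY_EFFECTS &
    net$edges$source %in% tf_universe &
    net$edges$target %in% tf_universe
  signed_network(net$edges[keep, , drop = FALSE], "regulatory",
                 nodes = intersect(net$nodes, tf_universe))
}

#' Source nodes (0-indegree) of a network
#'
#' @param net a [signed_network()].
#' @return character vector of node ids with no incoming edge (a self-loop
#'   counts as incoming).
#' @export
source_nodes <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  setdiff(net$nodes, unique(net$edges$target))
}

#' Convert a signed network to an igraph graph
#'
#' Edge attributes `sign` and `mechanism` are carried over.
#'
#' @param net a [signed_network()].
#' @return a directed [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "sign", "mechanism")],
    directed = TRUE, vertices = net$nodes
  )
}
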