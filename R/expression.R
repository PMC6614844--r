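# Booleanization of expression data.
#
# Two routes to per-gene Boolean states and expression probabilities:
#  * barcode mixture: non-expressed values ~ N(mu, sigma), expressed values
#    ~ U(mu, upper); the expression probability is the posterior of the
#    uniform component under equal priors;
#  * detection calls: probability = 1 - p, expressed iff >= threshold.

#' Barcode mixture parameters
#'
#' Per-gene location/scale of the non-expressed Gaussian plus the fixed
#' upper bound of the expressed uniform component (log2 expression units).
#'
#' @param genes character vector of gene ids.
#' @param mu,sigma numeric vectors (recycled) with `sigma > 0`.
#' @param upper upper bound of the expressed uniform, default 15; must
#'   exceed every `mu`.
#' @return object of class `barcode_params` (data.frame `gene`, `mu`,
#'   `sigma` plus attribute `upper`).
#' @export
barcode_params <- function(genes, mu, sigma, upper = 15) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  df <- data.frame(gene = as.character(genes), mu = as.numeric(mu),
                   sigma = as.numeric(sigma), stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicated gene ids in barcode parameters")
  if (any(upper <= df$mu)) stop("upper must exceed mu for every gene")
  attr(df, "upper") <- upper
  class(df) <- c("barcode_params", "data.frame")
  df
}

#' Expression probability under the barcode mixture
#'
#' `p = (f_e/2) / (f_e/2 + f_n/2)` where `f_e` is the density of
#' `Uniform(mu, upper)` and `f_n` the density of `Normal(mu, sigma)` at
#' `value`.  Values below `mu` lie outside the uniform support and get
#' probability 0; if both densities vanish the probability is 0.
#'
#' @param value normalized log2 expression value(s).
#' @param mu,sigma Gaussian location/scale of the non-expressed component.
#' @param upper upper bound of the expressed uniform component.
#' @return probability in `[0, 1]`, vectorized over `value`.
#' @export
expression_probability <- function(value, mu, sigma, upper = 15) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(upper <= mu)) stop("upper must exceed mu")
  fe <- dunif(value, min = mu, max = upper)
  fn <- dnorm(value, mean = mu, sd = sigma)
  denom <- 0.5 * fe + 0.5 * fn
  p <- ifelse(denom > 0, (0.5 * fe) / denom, 0)
  p[is.na(value)] <- 0    # missing measurements treated as non-expressed
  p
}

#' Booleanize an expression matrix with the barcode mixture
#'
#' Per gene the expression probability is the maximum of
#' [expression_probability()] across replicate columns; the Boolean state
#' is 1 iff that probability strictly exceeds `cutoff`.
#'
#' @param values numeric matrix (genes x replicates) with gene ids as
#'   rownames, or a data.frame whose first column is the gene id.
#' @param params a [barcode_params()] covering all genes in `values`.
#' @param cutoff expression-probability cutoff in (0, 1); default 0.95;
#'   the boundary is exclusive (probability exactly `cutoff` is state 0).
#' @return list with `state` (named 0/1 integer vector) and `prob`
#'   (named numeric vector).
#' @export
booleanize_barcode <- function(values, params, cutoff = 0.95) {
  stopifnot(inherits(params, "barcode_params"))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  values <- .as_expression_matrix(values)
  missing_genes <- setdiff(rownames(values), params$gene)
  if (length(missing_genes))
    stop("genes missing from barcode parameters: ",
         paste(missing_genes, collapse = ", "))
  idx <- match(rownames(values), params$gene)
  upper <- attr(params, "upper")
  probs <- vapply(seq_len(nrow(values)), function(i) {
    p <- expression_probability(values[i, ], params$mu[idx[i]],
                                params$sigma[idx[i]], upper)
    max(p, 0)
  }, numeric(1))
  names(probs) <- rownames(values)
  state <- as.integer(probs > cutoff)
  names(state) <- rownames(values)
  list(state = state, prob = probs)
}

.as_expression_matrix <- function(values) {
  if (is.data.frame(values)) {
    genes <- as.character(values[[1L]])
    values <- as.matrix(values[, -1L, drop = FALSE])
    rownames(values) <- genes
  }
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  storage.mode(values) <- "double"
  values
}

#' Booleanize detection-call p-values
#'
#' Expression probability is `1 - p`; the Boolean state is 1 iff the
#' probability is greater than or equal to `threshold` (inclusive
#' boundary, matching MAS5-style 'marginal'/'present' calls).
#'
#' @param pvalues named numeric vector of detection-call p-values in
#'   `[0, 1]` (names are gene ids).
#' @param threshold inclusive probability threshold, default 0.94.
#' @return list with `state` and `prob` as in [booleanize_barcode()].
#' @export
booleanize_detection_call <- function(pvalues, threshold = 0.94) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("detection-call p-values must lie in [0, 1]")
  if (is.null(names(pvalues))) stop("pvalues must be named by gene id")
  prob <- 1 - pvalues
  prob[is.na(prob)] <- 0
  state <- as.integer(prob >= threshold)
  names(state) <- names(pvalues)
  list(state = state, prob = prob)
}

#' Assemble a Boolean transition between two cell states
#'
#' Restricts both states to their common genes and bundles Boolean states
#' and expression probabilities into a `boolean_transition`.
#'
#' @param initial,final lists with `state` and `prob` named vectors, as
#'   returned by the Booleanization routes.
#' @param genes optional gene subset to restrict to.
#' @return object of class `boolean_transition`: list with `genes`,
#'   `state_initial`, `state_final`, `prob_initial`, `prob_final`.
#' @export
build_transition <- function(initial, final, genes = NULL) {
  common <- intersect(names(initial$state), names(final$state))
  if (!is.null(genes)) common <- intersect(common, genes)
  if (!length(common))
    stop("no genes shared between initial and final states")
  structure(
    list(genes = common,
         state_initial = initial$state[common],
         state_final = final$state[common],
         prob_initial = initial$prob[common],
         prob_final = final$prob[common]),
    class = "boolean_transition"
  )
}

#' @export
print.boolean_transition <- function(x, ...) {
  cat(sprintf("<boolean_transition: %d genes, %d differential>\n",
              length(x$genes), sum(x$state_initial != x$state_final)))
  invisible(x)
}

#' Collapse a probe-level matrix to genes by highest variance
#'
#' When several probes map to a gene, the probe with the highest variance
#' across all supplied samples is retained.
#'
#' @param values numeric matrix (probes x samples), probe ids as rownames.
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @return gene-level matrix.
#' @export
collapse_probes <- function(values, probe_map) {
  probe_map <- probe_map[probe_map$probe %in% rownames(values), , drop = FALSE]
  vars <- apply(values[probe_map$probe, , drop = FALSE], 1L, stats::var)
  ord <- order(probe_map$gene, -vars)
  pick <- probe_map[ord, ][!duplicated(probe_map$gene[ord]), , drop = FALSE]
  out <- values[pick$probe, , drop = FALSE]
  rownames(out) <- pick$gene
  out
}
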