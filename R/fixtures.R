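# Fully synthetic, ground-truthed test cases.
#
# A case plants one perturbation: a signalling molecule X whose inhibition
# switches the GRN from the initial to the final attractor.  Construction:
#
#  * GRN: n_chains independent chains of TFs.  Each chain has a backbone
#    of "up" TFs (0 -> 1) headed by u1 and a set of "down" leaf TFs
#    (1 -> 0) inhibited by the backbone.  Backbone edges are activating,
#    backbone->leaf edges inhibiting; in the initial state no internal
#    regulator is active, so the initial state is a point attractor; in
#    the final state every active regulator pushes towards the final
#    state, so it is an attractor too (pruning removes nothing except
#    deliberately planted inconsistent distractor edges).
#  * Each chain head u1 is balanced by two interface TFs: a driver T
#    (pushes the initial state) and a helper H (pushes the final state),
#    both expressed and hence held active by default, which keeps the
#    head tied at its initial state.  Clamping the driver to 0 releases
#    the head, the helper flips it, and the flip cascades down the chain.
#    The best-performing combinations are therefore exactly the driver
#    singletons (T, 0) -- multi-driver combinations act on disjoint chains
#    and are removed by the synergy filter -- so Q is uniform over them.
#  * Signalling: a layered DAG from source nodes through general
#    molecules; X sits below a source and fans out through disjoint
#    branches, one per driver, with branch signs adjusted to a product of
#    +1.  Inhibiting X therefore assigns state 0 to every driver: the
#    profile P_X matches Q and (X, inhibition) ranks at the top.
#  * Junk interface TFs and cross edges into the first branch give the
#    ranking a broad, graded background.
#
# Noise flips the Boolean expression state of a fraction of non-GRN genes
# in both conditions, degrading interface-TF identification and path
# probabilities without touching the GRN ground truth.

#' Default generator configuration
#'
#' @return named list of generator parameters (sizes, noise, planted
#'   effect structure); see the package vignette for the rationale behind
#'   each default.
#' @export
default_case_config <- function() {
  list(
    n_molecules = 60L,     # general signalling molecules incl. sources
    n_sources = 3L,        # 0-indegree pathway sources
    n_layers = 4L,         # molecule layers below the sources
    n_chains = 3L,         # GRN chains = number of planted drivers
    backbone_len = 2L,     # "up" TFs per chain
    leaves_per_chain = 2L, # "down" TFs per chain
    n_junk_tfs = 4L,       # interface TFs with no effect on the GRN
    branch_len = 3L,       # edges on each X -> ... -> driver branch
    n_cross_edges = 8L,    # extra edges from molecules into branch 1
    frac_nonexpressed = 0.15,
    noise = 0,             # expression-flip fraction of non-GRN genes
    n_replicates = 2L,
    upper = 15,
    max_combo_size = 4L,
    min_tfs = 10L
  )
}

#' Generate a synthetic ground-truthed case
#'
#' @param config list of generator parameters; see
#'   [default_case_config()].  Partial lists are merged over the defaults.
#' @param seed integer seed; the same seed reproduces the case exactly.
#' @return object of class `synthetic_case`: list with `signalling`,
#'   `regulatory` ([signed_network()]s), `expr_initial`, `expr_final`
#'   (replicate matrices), `barcode_params`, `transition`
#'   (noise-free Booleanization), `correlations`, `tf_universe`,
#'   `planted_target` (`molecule`, `direction`), `truth` (drivers,
#'   helpers, GRN states) and `provenance`.
#' @export
generate_case <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(default_case_config(), config)
  if (cfg$n_sources < 1L) stop("n_pathway_sources must be >= 1")
  if (cfg$n_molecules < cfg$n_sources + 5L)
    stop("n_molecules too small for the layered construction")
  n_grn <- cfg$n_chains * (cfg$backbone_len + cfg$leaves_per_chain)
  if (n_grn < cfg$min_tfs)
    stop("GRN would have fewer than min_tfs TFs; enlarge the chains")
  set.seed(as.integer(seed))

  ## ---- node inventory -------------------------------------------------
  mols <- sprintf("M%02d", seq_len(cfg$n_molecules))
  sources <- mols[seq_len(cfg$n_sources)]
  x <- "X"
  branch_nodes <- lapply(seq_len(cfg$n_chains), function(i)
    sprintf("B%d_%d", i, seq_len(cfg$branch_len - 1L)))
  drivers <- sprintf("T%d", seq_len(cfg$n_chains))
  helpers <- sprintf("H%d", seq_len(cfg$n_chains))
  junk <- if (cfg$n_junk_tfs) sprintf("J%d", seq_len(cfg$n_junk_tfs)) else character()
  chains <- lapply(seq_len(cfg$n_chains), function(i) list(
    up = sprintf("U%d_%d", i, seq_len(cfg$backbone_len)),
    down = sprintf("D%d_%d", i, seq_len(cfg$leaves_per_chain))))
  grn_tfs <- unlist(lapply(chains, unlist), use.names = FALSE)
  tf_universe <- c(grn_tfs, drivers, helpers, junk)

  ## ---- signalling network --------------------------------------------
  mech <- function(n) sample(c("Phosphorylation", "Binding",
                               "Covalent modification"), n, replace = TRUE)
  rsign <- function(n) sample(c(-1L, 1L), n, replace = TRUE)
  sig <- list()
  add_edges <- function(from, to, sign) {
    data.frame(source = from, target = to, sign = as.integer(sign),
               mechanism = mech(length(from)),
               effect = ifelse(sign > 0, "Activation", "Inhibition"),
               stringsAsFactors = FALSE)
  }
  # layered DAG over the general molecules
  others <- setdiff(mols, sources)
  layer_of <- setNames(c(rep(1L, cfg$n_sources),
                         sort(rep_len(2:(cfg$n_layers + 1L), length(others)))),
                       c(sources, others))
  for (m in others) {
    parents_pool <- names(layer_of)[layer_of == layer_of[[m]] - 1L]
    k <- min(length(parents_pool), sample(1:3, 1L))
    par <- sample(parents_pool, k)
    sig[[length(sig) + 1L]] <- add_edges(par, rep(m, k), rsign(k))
  }
  # X below the first source
  x_parent <- sources[1L]
  sig[[length(sig) + 1L]] <- add_edges(x_parent, x, 1L)
  # disjoint branches X -> ... -> driver, path sign forced to +1
  for (i in seq_len(cfg$n_chains)) {
    chain_nodes <- c(x, branch_nodes[[i]], drivers[i])
    s <- rsign(length(chain_nodes) - 1L)
    s[length(s)] <- prod(s[-length(s)])   # total product -> +1
    sig[[length(sig) + 1L]] <-
      add_edges(chain_nodes[-length(chain_nodes)], chain_nodes[-1L], s)
  }
  # helpers hang off the sources; junk TFs off late-layer molecules
  for (i in seq_along(helpers))
    sig[[length(sig) + 1L]] <-
      add_edges(sources[1L + (i - 1L) %% cfg$n_sources], helpers[i], rsign(1L))
  late <- names(layer_of)[layer_of >= cfg$n_layers]
  for (j in seq_along(junk))
    sig[[length(sig) + 1L]] <- add_edges(sample(late, 1L), junk[j], rsign(1L))
  # cross edges from general molecules into branch 1 (each from a distinct
  # molecule, so nothing outside X's subtree reaches more than one driver)
  cross_from <- sample(others, min(cfg$n_cross_edges, length(others)))
  for (m in cross_from) {
    tgt <- sample(branch_nodes[[1L]], 1L)
    sig[[length(sig) + 1L]] <- add_edges(m, tgt, rsign(1L))
  }
  signalling <- signed_network(do.call(rbind, sig), "signalling",
                               nodes = c(mols, x,
                                         unlist(branch_nodes),
                                         drivers, helpers, junk))

  ## ---- regulatory network --------------------------------------------
  reg <- list()
  reg_edge <- function(from, to, sign) {
    data.frame(source = from, target = to, sign = as.integer(sign),
               mechanism = "Transcriptional regulation",
               effect = ifelse(sign > 0, "Activation", "Inhibition"),
               stringsAsFactors = FALSE)
  }
  junk_leaves <- character()
  if (length(junk)) {
    leaf_pool <- unlist(lapply(chains, `[[`, "down"))
    if (length(junk) > length(leaf_pool))
      stop("n_junk_tfs exceeds the number of GRN leaf TFs")
    junk_leaves <- leaf_pool[seq_along(junk)]   # at most one junk TF per leaf
  }
  for (i in seq_len(cfg$n_chains)) {
    up <- chains[[i]]$up; down <- chains[[i]]$down
    head <- up[1L]
    reg[[length(reg) + 1L]] <- reg_edge(drivers[i], head, -1L)
    reg[[length(reg) + 1L]] <- reg_edge(helpers[i], head, 1L)
    if (length(up) > 1L)
      reg[[length(reg) + 1L]] <- reg_edge(up[-length(up)], up[-1L], 1L)
    # each leaf inhibited by one backbone TF (round robin)
    owner <- rep_len(up, length(down))
    reg[[length(reg) + 1L]] <- reg_edge(owner, down, -1L)
    # junk-covered leaves get a second backbone inhibitor
    for (d in intersect(junk_leaves, down)) {
      extra <- setdiff(up, owner[match(d, down)])
      if (length(extra))
        reg[[length(reg) + 1L]] <- reg_edge(extra[1L], d, -1L)
    }
  }
  for (j in seq_along(junk))
    reg[[length(reg) + 1L]] <- reg_edge(junk[j], junk_leaves[j], 1L)
  # a planted inconsistent distractor edge, removed by pruning
  reg[[length(reg) + 1L]] <- reg_edge(chains[[1L]]$down[1L],
                                      chains[[1L]]$up[min(2L, cfg$backbone_len)],
                                      1L)
  regulatory <- signed_network(do.call(rbind, reg), "regulatory",
                               nodes = tf_universe)

  ## ---- Boolean ground truth ------------------------------------------
  up_tfs <- unlist(lapply(chains, `[[`, "up"))
  down_tfs <- unlist(lapply(chains, `[[`, "down"))
  s_init <- setNames(c(rep(0L, length(up_tfs)), rep(1L, length(down_tfs))),
                     c(up_tfs, down_tfs))
  s_final <- 1L - s_init

  non_grn <- setdiff(c(signalling$nodes), grn_tfs)
  protected <- c(sources, x, unlist(branch_nodes), drivers, helpers, junk,
                 x_parent)
  pool <- setdiff(non_grn, protected)
  nonexpr <- sample(pool, round(cfg$frac_nonexpressed * length(pool)))
  expressed0 <- setdiff(non_grn, nonexpr)

  # noise: flip expression of a fraction of non-GRN genes in both states
  flip <- character()
  if (cfg$noise > 0) {
    flip <- non_grn[runif(length(non_grn)) < cfg$noise]
  }
  state_of <- setNames(as.integer(non_grn %in% expressed0), non_grn)
  state_of[flip] <- 1L - state_of[flip]

  genes <- c(non_grn, grn_tfs)
  bstate_init <- c(state_of, s_init)[genes]
  bstate_final <- c(state_of, s_final)[genes]

  ## ---- expression values + barcode parameters ------------------------
  mu <- runif(length(genes), 5.5, 6.5)
  sg <- runif(length(genes), 0.8, 1.2)
  params <- barcode_params(genes, mu, sg, upper = cfg$upper)
  draw <- function(states) {
    vals <- matrix(NA_real_, length(genes), cfg$n_replicates,
                   dimnames = list(genes, paste0("rep", seq_len(cfg$n_replicates))))
    for (r in seq_len(cfg$n_replicates)) {
      z <- ifelse(states == 1L,
                  3.0 + runif(length(genes), 0, 2.5),   # p in ~(0.956, 1)
                  runif(length(genes), -1, 1.5))        # p well below cutoff
      vals[, r] <- pmin(mu + sg * z, cfg$upper - 0.2)
    }
    vals
  }
  expr_initial <- draw(bstate_init)
  expr_final <- draw(bstate_final)

  ## ---- correlations ---------------------------------------------------
  e <- signalling$edges
  pick <- sample(nrow(e), round(0.3 * nrow(e)))
  correlations <- data.frame(
    gene_a = e$source[pick], gene_b = e$target[pick],
    r = e$sign[pick] * runif(length(pick), 0.75, 0.95),
    stringsAsFactors = FALSE)
  weak <- sample(nrow(e), min(10L, nrow(e)))
  correlations <- rbind(correlations, data.frame(
    gene_a = e$source[weak], gene_b = e$target[weak],
    r = runif(length(weak), -0.4, 0.4)))
  correlations <- correlations[!duplicated(paste(correlations$gene_a,
                                                 correlations$gene_b)), ]
  rownames(correlations) <- NULL

  # Booleanize the emitted values: at any noise level the drawn values
  # realize the intended states exactly, so this is self-consistent.
  transition <- build_transition(booleanize_barcode(expr_initial, params),
                                 booleanize_barcode(expr_final, params))
  stopifnot(identical(unname(transition$state_initial[genes]),
                      unname(bstate_init)))

  structure(
    list(signalling = signalling, regulatory = regulatory,
         expr_initial = expr_initial, expr_final = expr_final,
         barcode_params = params, correlations = correlations,
         tf_universe = tf_universe, transition = transition,
         planted_target = list(molecule = x, direction = "inhibition"),
         truth = list(drivers = drivers, helpers = helpers, junk = junk,
                      grn_tfs = grn_tfs, s_init = s_init, s_final = s_final,
                      driver_states = setNames(rep(0L, length(drivers)),
                                               drivers)),
         provenance = list(seed = as.integer(seed), config = cfg)),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case: seed %d, %d signalling nodes, %d TFs, planted %s of %s>\n",
              x$provenance$seed, length(x$signalling$nodes),
              length(x$tf_universe), x$planted_target$direction,
              x$planted_target$molecule))
  invisible(x)
}

#' Write a synthetic case to plain-text input files
#'
#' Emits every pipeline input in its external format plus a ground-truth
#' JSON and a checksum manifest; [read_case_files()] parses them back.
#'
#' @param case a [generate_case()] result.
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
case_to_files <- function(case, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(directory, f)
  write_network(case$signalling, path("signalling.tsv"))
  write_network(case$regulatory, path("regulatory.tsv"))
  wm <- function(m, f) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wm(case$expr_initial, "expr_initial.tsv")
  wm(case$expr_final, "expr_final.tsv")
  bp <- as.data.frame(case$barcode_params)
  write.table(bp, path("barcode_params.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(case$correlations, path("correlations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(case$tf_universe, path("tf_universe.txt"))
  jsonlite::write_json(
    list(planted_target = case$planted_target, truth = case$truth,
         provenance = case$provenance),
    path("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c("signalling.tsv", "regulatory.tsv", "expr_initial.tsv",
             "expr_final.tsv", "barcode_params.tsv", "correlations.tsv",
             "tf_universe.txt", "ground_truth.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(directory, files))),
                         stringsAsFactors = FALSE)
  write.table(manifest, path("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}

#' Read back a case written by [case_to_files()]
#'
#' @param directory the case directory.
#' @return list with the parsed inputs (`signalling`, `regulatory`,
#'   `expr_initial`, `expr_final`, `barcode_params`, `correlations`,
#'   `tf_universe`, `ground_truth`).
#' @export
read_case_files <- function(directory) {
  path <- function(f) file.path(directory, f)
  rm <- function(f) {
    df <- read.delim(path(f), check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  bp <- read.delim(path("barcode_params.tsv"))
  gt <- jsonlite::read_json(path("ground_truth.json"), simplifyVector = TRUE)
  list(
    signalling = parse_network(path("signalling.tsv"), "signalling"),
    regulatory = parse_network(path("regulatory.tsv"), "regulatory"),
    expr_initial = rm("expr_initial.tsv"),
    expr_final = rm("expr_final.tsv"),
    barcode_params = barcode_params(bp$gene, bp$mu, bp$sigma,
                                    upper = attr(bp, "upper") %||% 15),
    correlations = read.delim(path("correlations.tsv")),
    tf_universe = readLines(path("tf_universe.txt")),
    ground_truth = gt
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
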