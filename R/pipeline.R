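# End-to-end orchestration: expression -> GRN -> perturbation search ->
# path scoring -> JSD ranking (-> evaluation), plus file-based inputs,
# output writers and a minimal CLI.

#' Default pipeline parameters
#'
#' All tunables of the method with their standard values: barcode cutoff
#' 0.95, detection threshold 0.94, minimum of 10 connected GRN-TFs,
#' combinations of up to 4 interface TFs, top 3 flipping scores (with
#' ties), 40% minimum flip coverage, correlation threshold 0.7, candidate
#' cut-off fraction 0.06, default node probability 0.5.
#'
#' @return named list of parameters.
#' @export
default_params <- function() {
  list(
    barcode_cutoff = 0.95,
    detection_threshold = 0.94,
    min_tfs = 10L,
    max_combo_size = 4L,
    best = 3L,
    min_flip_fraction = 0.4,
    corr_threshold = 0.7,
    cutoff_fraction = 0.06,
    default_prob = 0.5,
    max_steps = 1000L,
    max_targets = 30L,
    differential_tf_states = "final_only",
    success_universe = "molecules"
  )
}

#' Run the full analysis on in-memory inputs
#'
#' Sequences the method: differential TFs -> attractor-consistent GRN ->
#' interface-TF identification -> exhaustive clamped perturbations ->
#' BPC selection and Q -> MPP scoring (correlation and length variants)
#' -> JSD ranking and candidate selection -> optional evaluation against
#' known targets.  Fully deterministic for fixed inputs.
#'
#' @param signalling signalling [signed_network()] (unfiltered; default
#'   effect/mechanism exclusions are applied here).
#' @param regulatory regulatory [signed_network()].
#' @param transition a [build_transition()] result covering the measured
#'   genes.
#' @param tf_universe character vector of TF ids.
#' @param params list merged over [default_params()].
#' @param correlations optional correlation data.frame
#'   (`gene_a`, `gene_b`, `r`).
#' @param targets optional character vector (or data.frame) of known
#'   perturbation-target molecules for evaluation.
#' @return object of class `run_result`: list with `transition`, `grn`,
#'   `interface_tfs`, `perturbations`, `bpcs`, `graph`, `ranking`,
#'   `candidates`, `flags`, `evaluation`, `params`.
#' @export
run_analysis <- function(signalling, regulatory, transition, tf_universe,
                         params = list(), correlations = NULL,
                         targets = NULL) {
  p <- utils::modifyList(default_params(), params)
  flags <- list()

  sig <- filter_interactions(signalling)
  reg <- regulatory_prior(regulatory, tf_universe)

  diff <- differential_tfs(transition, tf_universe)
  if (!length(diff))
    stop("GRN stage failed: no differentially expressed TF ",
         "(check the Booleanization inputs)")
  prior <- reg$edges[reg$edges$source %in% diff & reg$edges$target %in% diff, ,
                     drop = FALSE]
  grn <- prune_to_attractors(prior, transition$state_initial[diff],
                             transition$state_final[diff])
  flags$grn_too_small <- !grn_passes_filter(grn, p$min_tfs)

  itfs <- identify_interface_tfs(sig, reg, grn, transition)
  if (!length(itfs))
    stop("perturbation stage failed: no interface TF connects the ",
         "signalling network to the GRN")
  ext_itfs <- setdiff(itfs, grn$tfs)
  input_edges <- reg$edges[reg$edges$source %in% ext_itfs &
                             reg$edges$target %in% grn$tfs, , drop = FALSE]
  grn <- add_external_inputs(grn, input_edges)
  held <- setNames(transition$state_initial[ext_itfs], ext_itfs)

  combos <- enumerate_combinations(itfs, transition, p$max_combo_size,
                                   p$differential_tf_states)
  results <- lapply(combos, function(cb)
    simulate_clamped(grn, transition$state_initial[grn$tfs], cb,
                     external_inputs = held, max_steps = p$max_steps))
  flags$non_converged <- sum(!vapply(results, `[[`, logical(1), "converged"))
  bpcs <- select_bpcs(results, n_grn_tfs = length(grn$tfs),
                      best = p$best, min_flip_fraction = p$min_flip_fraction)
  flags$low_flip <- bpcs$flag_low_flip

  graph <- scoring_graph(sig, transition$prob_initial,
                         correlations = correlations,
                         corr_threshold = p$corr_threshold,
                         default_prob = p$default_prob)
  field_corr <- mpp_field(graph, itfs, "correlation")
  field_len <- mpp_field(graph, itfs, "length")
  profiles <- function(field, variant) {
    out <- list()
    for (m in graph$nodes) {
      pr <- molecule_profiles(graph, m, itfs, variant, field = field)
      out[[paste(m, "activation", sep = "|")]] <- pr$activation
      out[[paste(m, "inhibition", sep = "|")]] <- pr$inhibition
    }
    out
  }
  profiles_corr <- profiles(field_corr, "correlation")
  profiles_len <- profiles(field_len, "length")
  ranking <- rank_candidates(profiles_corr, profiles_len, bpcs$q,
                             cutoff_fraction = p$cutoff_fraction)
  candidates <- ranking[ranking$candidate, , drop = FALSE]

  evaluation <- NULL
  if (!is.null(targets)) {
    tmol <- if (is.data.frame(targets)) targets$molecule else targets
    tmol_in <- intersect(tmol, signalling$nodes)
    flags$too_many_targets <- length(tmol_in) > p$max_targets
    n_universe <- length(unique(ranking$molecule))
    n_selected <- length(unique(candidates$molecule))
    evaluation <- list(
      success = evaluate_success(candidates, tmol),
      n_targets = length(tmol_in),
      n_candidates = n_selected,
      n_universe = n_universe,
      random_success_probability =
        if (length(intersect(tmol_in, ranking$molecule)) > 0)
          random_success_probability(n_universe,
                                     length(intersect(tmol_in,
                                                      ranking$molecule)),
                                     n_selected)
        else NA_real_
    )
  }
  structure(
    list(transition = transition, grn = grn, interface_tfs = itfs,
         perturbations = results, bpcs = bpcs, graph = graph,
         ranking = ranking, candidates = candidates, flags = flags,
         evaluation = evaluation, params = p),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(paste0("<run_result: %d GRN-TFs, %d interface TFs, %d BPCs ",
                     "(best score %d), %d ranked entries, %d candidates>\n"),
              length(x$grn$tfs), length(x$interface_tfs),
              length(x$bpcs$combinations), x$bpcs$best_score,
              nrow(x$ranking), nrow(x$candidates)))
  for (f in names(x$flags))
    if (isTRUE(x$flags[[f]]) || (is.numeric(x$flags[[f]]) && x$flags[[f]] > 0))
      cat("  flag:", f, "=", x$flags[[f]], "\n")
  invisible(x)
}

#' Run a generated synthetic case through the pipeline
#'
#' @param case a [generate_case()] result.
#' @param params parameter overrides, see [default_params()].
#' @param use_correlations apply the case's correlation table,
#'   default TRUE.
#' @return a `run_result`; the planted target is passed as the known
#'   evaluation target.
#' @export
run_case <- function(case, params = list(), use_correlations = TRUE) {
  stopifnot(inherits(case, "synthetic_case"))
  params <- utils::modifyList(
    list(max_combo_size = case$provenance$config$max_combo_size,
         min_tfs = case$provenance$config$min_tfs),
    params)
  run_analysis(case$signalling, case$regulatory, case$transition,
               case$tf_universe, params = params,
               correlations = if (use_correlations) case$correlations,
               targets = case$planted_target$molecule)
}

#' Run the pipeline from files
#'
#' @param config named list (or path to a JSON file) with entries:
#'   `signalling`, `regulatory`, `tf_universe` (file paths); either
#'   `expr_initial` + `expr_final` + `barcode_params` (barcode route) or
#'   `pvalues_initial` + `pvalues_final` (detection-call route);
#'   optional `correlations`, `targets`, `blacklist`, `out` (output
#'   directory) and any parameter of [default_params()].
#' @return a `run_result` (outputs written to `config$out` when set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  p <- utils::modifyList(default_params(),
                         config[intersect(names(config),
                                          names(default_params()))])
  signalling <- parse_network(config$signalling, "signalling")
  if (!is.null(config$blacklist))
    signalling <- apply_edge_blacklist(signalling, config$blacklist)
  regulatory <- parse_network(config$regulatory, "regulatory")
  tf_universe <- readLines(config$tf_universe)

  read_matrix <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  if (!is.null(config$expr_initial)) {
    bp <- read.delim(config$barcode_params)
    params <- barcode_params(bp$gene, bp$mu, bp$sigma)
    init <- booleanize_barcode(read_matrix(config$expr_initial), params,
                               cutoff = p$barcode_cutoff)
    fin <- booleanize_barcode(read_matrix(config$expr_final), params,
                              cutoff = p$barcode_cutoff)
  } else if (!is.null(config$pvalues_initial)) {
    rp <- function(path) {
      df <- read.delim(path)
      setNames(df[[2L]], df[[1L]])
    }
    init <- booleanize_detection_call(rp(config$pvalues_initial),
                                      threshold = p$detection_threshold)
    fin <- booleanize_detection_call(rp(config$pvalues_final),
                                     threshold = p$detection_threshold)
  } else stop("config must provide a barcode or detection-call route")
  transition <- build_transition(init, fin)

  correlations <- if (!is.null(config$correlations))
    read.delim(config$correlations)
  targets <- if (!is.null(config$targets)) readLines(config$targets)
  res <- run_analysis(signalling, regulatory, transition, tf_universe,
                      params = p, correlations = correlations,
                      targets = targets)
  if (!is.null(config$out)) write_run_outputs(res, config$out)
  res
}

#' Write run outputs to a directory
#'
#' Emits `ranking.tsv`, `bpcs.json`, `grn.tsv`, `grn.json` and
#' `flags.json` (flags + parameters + provenance).  Output is
#' byte-deterministic for identical inputs.
#'
#' @param result a `run_result`.
#' @param directory output directory.
#' @return invisibly, the vector of files written.
#' @export
write_run_outputs <- function(result, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(directory, f)
  rk <- result$ranking
  rk$jsd_correlation <- sprintf("%.12g", rk$jsd_correlation)
  rk$jsd_length <- sprintf("%.12g", rk$jsd_length)
  write.table(rk, path("ranking.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(
      q = as.list(result$bpcs$q),
      best_score = result$bpcs$best_score,
      flag_low_flip = result$bpcs$flag_low_flip,
      combinations = lapply(result$bpcs$combinations, function(r)
        list(tfs = as.list(r$combination), flipped = r$flipped,
             flipping_score = r$flipping_score))
    ),
    path("bpcs.json"), auto_unbox = TRUE, digits = NA)
  write.table(result$grn$edges, path("grn.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(tfs = result$grn$tfs,
         s_init = as.list(result$grn$s_init),
         s_final = as.list(result$grn$s_final),
         removed = result$grn$removed,
         input_edges = result$grn$input_edges),
    path("grn.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(flags = result$flags, params = result$params,
         interface_tfs = result$interface_tfs,
         evaluation = result$evaluation,
         n_candidates = nrow(result$candidates)),
    path("flags.json"), auto_unbox = TRUE, digits = NA)
  invisible(c("ranking.tsv", "bpcs.json", "grn.tsv", "grn.json",
              "flags.json"))
}

#' Predict the GRN state reached via a ranked molecule
#'
#' Selects the interface-TF-state pairs of the BPCs that the molecule
#' reaches with positive probability and matching state, keeps the BPCs
#' composed only of such pairs, and returns the GRN-TFs expected to flip
#' (the union over kept BPCs) together with the predicted state.
#'
#' @param grn a [transition_grn()].
#' @param bpcs a [select_bpcs()] result.
#' @param profile named pair-keyed probability vector for the molecule
#'   and direction of interest (one entry of the profile lists built by
#'   [molecule_profiles()]).
#' @return list with `flipped` (character), `predicted_state` (named 0/1
#'   vector over GRN-TFs) and `kept_bpcs` (indices).
#' @export
predict_treated_state <- function(grn, bpcs, profile) {
  covered <- names(profile)[profile > 0]
  kept <- which(vapply(bpcs$combinations, function(r)
    all(pair_key(names(r$combination), r$combination) %in% covered),
    logical(1)))
  if (!length(kept))
    warning("no BPC is fully covered by the molecule's profile; ",
            "empty flip set")
  flipped <- sort(unique(unlist(lapply(bpcs$combinations[kept],
                                       `[[`, "flipped"))))
  predicted <- grn$s_init
  predicted[flipped] <- 1L - predicted[flipped]
  list(flipped = flipped, predicted_state = predicted, kept_bpcs = kept)
}

#' Minimal command-line interface
#'
#' Subcommands: `run --config cfg.json` (file-based pipeline) and
#' `generate --seed N --out dir [--noise x]` (synthetic case emission).
#'
#' @param args character vector, defaults to [commandArgs()] trailing
#'   arguments.
#' @return exit status, invisibly.
#' @export
sigflip_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: sigflip run --config cfg.json | sigflip generate --seed N --out dir [--noise x]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i) || i == length(args)) default else args[i + 1L]
  }
  switch(args[[1L]],
    run = {
      cfg <- opt("--config")
      if (is.null(cfg)) stop(usage)
      res <- run_pipeline(cfg)
      print(res)
      invisible(0L)
    },
    generate = {
      seed <- as.integer(opt("--seed", "1"))
      out <- opt("--out")
      if (is.null(out)) stop(usage)
      noise <- as.numeric(opt("--noise", "0"))
      case <- generate_case(list(noise = noise), seed = seed)
      case_to_files(case, out)
      message("case written to ", out)
      invisible(0L)
    },
    stop(usage)
  )
}
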