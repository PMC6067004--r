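# End-to-end drivers: evidence bundle -> reconstructed network -> complexes.

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[mlpr %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Reconstruct a weighted interaction network from an evidence bundle
#'
#' Runs the full reconstruction: enumerate all protein pairs, build their
#' 17-component evidence vectors, collapse identical vectors into
#' fingerprints, link each fingerprint to its `T` most similar ones, run
#' the random walk with restart from the reliable-seed prior, and keep the
#' `top_n` highest-scoring pairs as the reconstructed weighted network.
#'
#' @param bundle An `evidence_bundle`.
#' @param config An [mlpr_config()].
#' @param proteins Protein universe; defaults to every protein seen in the
#'   bundle.
#' @param verbose Emit per-stage progress with timings to stderr?
#' @return An `mlpr_run` list: `network` (the reconstructed weighted edge
#'   table), `ranked` (all pairs in rank order), `posterior`,
#'   `fingerprints`, `graph`, `prior`, `rwr` (iteration diagnostics),
#'   `config`, `proteins`.
#' @export
reconstruct_network <- function(bundle, config = mlpr_config(),
                                proteins = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  tick <- function(what) {
    t1 <- proc.time()[["elapsed"]]
    stage_msg(verbose, "%s (%.1fs)", what, t1 - t0)
    t0 <<- t1
  }
  if (is.null(proteins)) proteins <- bundle_proteins(bundle)
  pairs <- enumerate_pairs(proteins)
  tick(sprintf("enumerated %d pairs over %d proteins", nrow(pairs),
               length(proteins)))
  V <- build_pair_vectors(pairs, bundle,
                          cd_as_similarity = config$cd_as_similarity)
  tick("built evidence vectors")
  fpt <- assign_fingerprints(pairs, V, config$quantize_precision)
  tick(sprintf("collapsed into %d fingerprints", length(fpt$id)))
  graph <- build_knn_graph(fpt, config$T)
  tick(sprintf("similarity graph with %d edges", nrow(graph$edges)))
  prior <- seed_priors(fpt, config$seed_indicators, config$seed_min_db)
  rw <- random_walk_with_restart(graph$transition, prior, config$alpha,
                                 config$tol, config$max_iter)
  tick(sprintf("walk converged in %d iterations", rw$iterations))
  ranked <- score_and_rank_pairs(rw$posterior, fpt)
  network <- select_top(ranked, config$top_n %||% nrow(ranked))
  tick(sprintf("selected top %d pairs", nrow(network)))
  structure(
    list(network = network, ranked = ranked, posterior = rw$posterior,
         fingerprints = fpt, graph = graph, prior = prior, rwr = rw,
         config = config, proteins = proteins),
    class = "mlpr_run"
  )
}

#' @export
print.mlpr_run <- function(x, ...) {
  cat(sprintf(
    "<mlpr_run> %d proteins, %d fingerprints, network of %d edges (walk: %d iterations)\n",
    length(x$proteins), length(x$fingerprints$id), nrow(x$network),
    x$rwr$iterations
  ))
  invisible(x)
}

#' Reconstruct and detect complexes in one call
#'
#' @inheritParams reconstruct_network
#' @return The `mlpr_run` augmented with element `complexes`, the detected
#'   complex list from [detect_complexes()].
#' @export
run_mlpr <- function(bundle, config = mlpr_config(), proteins = NULL,
                     verbose = FALSE) {
  run <- reconstruct_network(bundle, config, proteins, verbose)
  run$complexes <- detect_complexes(run$network, config)
  stage_msg(verbose, "detected %d complexes", length(run$complexes))
  run
}
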