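#' Run configuration for the reconstruction and detection pipeline
#'
#' Collects every tunable parameter of the pipeline in one validated object.
#' Defaults follow the method's reference settings: restart probability
#' `alpha = 0.8`, convergence tolerance `1e-6`, `T = 10` nearest fingerprints,
#' expansion threshold `T_in = 0.6`, and neighborhood-affinity match
#' threshold `omega = 0.25`.
#'
#' @param T Number of most-similar fingerprints each fingerprint is linked
#'   to in the similarity graph (integer, >= 1).
#' @param alpha Restart probability of the random walk, in (0, 1].
#' @param tol L1 convergence threshold for the walk.
#' @param max_iter Iteration cap for the walk.
#' @param top_n Size of the reconstructed network (number of top-ranked
#'   pairs kept). `NULL` keeps every ranked pair.
#' @param T_in Cluster-expansion admission threshold on the interaction
#'   probability, in \[0, 1\].
#' @param d Diameter bound (unweighted hops) for growing clusters
#'   (integer, >= 1).
#' @param omega Neighborhood-affinity threshold used when matching predicted
#'   complexes to benchmark complexes; 0.20 and 0.25 are the customary
#'   values.
#' @param min_complex_size Predicted/benchmark complexes smaller than this
#'   are discarded (the benchmark filter drops singletons and pairs).
#' @param quantize_precision Decimal places used when deciding that two
#'   evidence vectors are "the same" for fingerprinting.
#' @param log_expression Should expression matrices be log2(x+1)-transformed
#'   at read time?
#' @param seed_indicators Names of vector components that count as
#'   curated-database membership indicators in the seed rule.
#' @param seed_min_db Minimum number of nonzero indicator components for a
#'   fingerprint to be a seed.
#' @param allow_overlap May proteins belong to several detected complexes?
#'   (Queue removal always blocks re-seeding; this flag controls membership.)
#' @param cd_as_similarity Store the topological feature as
#'   1 - Czekanowski-Dice distance (larger = stronger evidence)? `FALSE`
#'   stores the raw distance.
#' @param rng_seed Optional integer seed recorded in the configuration.
#'
#' @return An object of class `mlpr_config` (a validated named list).
#' @examples
#' cfg <- mlpr_config(top_n = 500)
#' cfg$alpha
#' @export
mlpr_config <- function(T = 10L, alpha = 0.8, tol = 1e-6, max_iter = 10000L,
                        top_n = NULL, T_in = 0.6, d = 2L, omega = 0.25,
                        min_complex_size = 3L, quantize_precision = 4L,
                        log_expression = FALSE,
                        seed_indicators = c("EPPI1", "EPPI2", "TAP1", "TAP5"),
                        seed_min_db = 2L, allow_overlap = TRUE,
                        cd_as_similarity = TRUE, rng_seed = NULL) {
  cfg <- list(
    T = as.integer(T), alpha = alpha, tol = tol,
    max_iter = as.integer(max_iter),
    top_n = if (!is.null(top_n)) as.integer(top_n),
    T_in = T_in, d = as.integer(d), omega = omega,
    min_complex_size = as.integer(min_complex_size),
    quantize_precision = as.integer(quantize_precision),
    log_expression = isTRUE(log_expression),
    seed_indicators = as.character(seed_indicators),
    seed_min_db = as.integer(seed_min_db),
    allow_overlap = isTRUE(allow_overlap),
    cd_as_similarity = isTRUE(cd_as_similarity),
    rng_seed = if (!is.null(rng_seed)) as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "mlpr_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    "T must be >= 1" = cfg$T >= 1L,
    "alpha must be in (0, 1]" = cfg$alpha > 0 && cfg$alpha <= 1,
    "tol must be positive" = cfg$tol > 0,
    "max_iter must be >= 1" = cfg$max_iter >= 1L,
    "T_in must be in [0, 1]" = cfg$T_in >= 0 && cfg$T_in <= 1,
    "d must be >= 1" = cfg$d >= 1L,
    "omega must be in (0, 1]" = cfg$omega > 0 && cfg$omega <= 1,
    "min_complex_size must be >= 1" = cfg$min_complex_size >= 1L,
    "quantize_precision must be >= 0" = cfg$quantize_precision >= 0L,
    "seed_min_db must be >= 1" = cfg$seed_min_db >= 1L
  )
  if (!is.null(cfg$top_n)) stopifnot("top_n must be >= 0" = cfg$top_n >= 0L)
  invisible(cfg)
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [mlpr_config()]; unknown keys raise an
#' error so typos are not silently ignored. Keys that are absent keep their
#' defaults.
#'
#' @param path Path to a YAML file of scalar key/value entries.
#' @return An `mlpr_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(mlpr_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(mlpr_config, raw)
}

#' @export
print.mlpr_config <- function(x, ...) {
  cat("<mlpr_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
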