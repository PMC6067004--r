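# The evidence bundle: every source a pair vector draws on, normalized into
# lookup-friendly structures at construction time. Missing sources are
# allowed; the corresponding vector components are then 0.

GO_ASPECTS <- c("MF", "BP", "CC")

edge_score_map <- function(df) {
  if (is.null(df) || !nrow(df)) return(setNames(numeric(0), character(0)))
  w <- df$weight
  if (all(is.na(w))) w <- rep(1, nrow(df))
  if (any(is.na(w) | w < 0)) stop("score tables must be non-negative and complete")
  setNames(w, pair_key(df$protein_a, df$protein_b))
}

#' Assemble an evidence bundle
#'
#' Collects the six evidence sources that feed the 17-component pair vector:
#' per-aspect GO annotations and GO-slim annotations plus the ontology DAG,
#' an expression matrix, protein domains with domain-domain interaction
#' confidences, a STRING-like pair score table, up to five AP-MS reliability
#' score tables, up to two curated interaction databases, and a topology
#' network for the shared-neighborhood feature. Any component may be omitted.
#'
#' @param go_annotations List with elements named among `MF`, `BP`, `CC`;
#'   each a named list protein -> term IDs (as from [read_annotations()]).
#' @param go_slims Same shape, with GO-slim terms.
#' @param ontology An `mlpr_ontology` shared by all aspects (required when
#'   `go_annotations` is given).
#' @param slim_roots Trivial root terms excluded from slim sharing; defaults
#'   to the ontology roots.
#' @param expression Numeric matrix, protein row names
#'   (as from [read_expression_matrix()]).
#' @param domains Named list protein -> domain IDs.
#' @param ddi `data.frame(domain_a, domain_b, weight)` of domain-domain
#'   interaction confidences (unordered pairs).
#' @param string_scores Weighted edge `data.frame` of STRING-like scores.
#' @param tap_scores List of up to 5 weighted edge `data.frame`s
#'   (AP-MS-derived reliability scores), in component order TAP1..TAP5.
#' @param eppi_sets List of up to 2 edge `data.frame`s: membership in
#'   curated interaction databases, in component order EPPI1..EPPI2.
#' @param topology Edge `data.frame` of an observed interaction network used
#'   for the Czekanowski-Dice shared-neighborhood feature.
#' @return An object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(go_annotations = list(), go_slims = list(),
                            ontology = NULL, slim_roots = NULL,
                            expression = NULL, domains = NULL, ddi = NULL,
                            string_scores = NULL, tap_scores = list(),
                            eppi_sets = list(), topology = NULL) {
  check_aspects <- function(x, what) {
    if (length(x) && !all(names(x) %in% GO_ASPECTS)) {
      stop(what, " names must be among ", paste(GO_ASPECTS, collapse = ", "))
    }
  }
  check_aspects(go_annotations, "go_annotations")
  check_aspects(go_slims, "go_slims")
  if (length(go_annotations) && is.null(ontology)) {
    stop("an ontology is required to score GO annotations")
  }
  if (length(tap_scores) > 5L) stop("at most 5 TAP score tables")
  if (length(eppi_sets) > 2L) stop("at most 2 curated interaction databases")

  ic <- list()
  for (a in names(go_annotations)) {
    ic[[a]] <- term_information_content(ontology, go_annotations[[a]])
  }
  if (is.null(slim_roots)) {
    slim_roots <- if (!is.null(ontology)) ontology$roots else character(0)
  }

  # Domain confidences keyed by canonical unordered domain pair.
  ddi_map <- setNames(numeric(0), character(0))
  if (!is.null(ddi) && nrow(ddi)) {
    stopifnot(all(c("domain_a", "domain_b", "weight") %in% names(ddi)))
    if (any(is.na(ddi$weight) | ddi$weight < 0)) {
      stop("domain-domain confidences must be non-negative")
    }
    canon <- canonicalize_pairs(ddi$domain_a, ddi$domain_b)
    key <- pair_key(canon$protein_a, canon$protein_b)
    ddi_map <- tapply(ddi$weight, key, max)
    ddi_map <- setNames(as.numeric(ddi_map), names(ddi_map))
  }

  tap <- lapply(tap_scores, edge_score_map)
  if (length(tap)) names(tap) <- paste0("TAP", seq_along(tap))
  eppi <- lapply(eppi_sets, function(df) {
    if (is.null(df) || !nrow(df)) character(0)
    else pair_key(df$protein_a, df$protein_b)
  })
  if (length(eppi)) names(eppi) <- paste0("EPPI", seq_along(eppi))

  zs <- NULL
  if (!is.null(expression)) {
    stopifnot(is.matrix(expression), !is.null(rownames(expression)))
    if (ncol(expression) < 2L) stop("expression needs >= 2 samples")
    mu <- rowMeans(expression)
    sd <- sqrt(rowSums((expression - mu)^2) / (ncol(expression) - 1L))
    zs <- (expression - mu) / ifelse(sd > 0, sd, 1)
    zs[sd == 0, ] <- 0 # zero-variance profiles correlate with nothing
  }

  structure(
    list(
      go_annotations = go_annotations, go_slims = go_slims,
      ontology = ontology, slim_roots = slim_roots, ic = ic,
      expression = expression, zscores = zs,
      domains = domains, ddi_map = ddi_map,
      string_map = edge_score_map(string_scores),
      tap_maps = tap, eppi_keys = eppi,
      topology = topology
    ),
    class = "evidence_bundle"
  )
}

#' Proteins covered by any source of a bundle
#'
#' @param bundle An `evidence_bundle`.
#' @return Sorted character vector of protein IDs seen in any source.
#' @export
bundle_proteins <- function(bundle) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  ids <- c(
    unlist(lapply(bundle$go_annotations, names), use.names = FALSE),
    unlist(lapply(bundle$go_slims, names), use.names = FALSE),
    rownames(bundle$expression),
    names(bundle$domains),
    if (!is.null(bundle$topology)) {
      c(bundle$topology$protein_a, bundle$topology$protein_b)
    }
  )
  keys <- c(names(bundle$string_map),
            unlist(lapply(bundle$tap_maps, names), use.names = FALSE),
            unlist(bundle$eppi_keys, use.names = FALSE))
  if (length(keys)) {
    ids <- c(ids, unlist(strsplit(keys, "\t", fixed = TRUE), use.names = FALSE))
  }
  radix_sort(unique(ids))
}

#' Assemble an evidence bundle from a manifest file
#'
#' The manifest is a YAML file (as written by [write_fixture()]) whose
#' `files` section names the source tables; absent entries are permitted
#' and leave the corresponding evidence empty. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Path to a manifest YAML file.
#' @param log_expression Log2(x+1)-transform the expression matrix at read
#'   time?
#' @return An `evidence_bundle`.
#' @export
bundle_from_manifest <- function(path, log_expression = FALSE) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  res <- function(p) if (is.null(p)) NULL else file.path(base, p)
  f <- man$files %||% list()

  ont <- if (!is.null(f$ontology)) read_ontology(res(f$ontology))
  read_aspects <- function(entry) {
    if (is.null(entry)) return(list())
    out <- lapply(entry, function(p) read_annotations(res(p)))
    out[lengths(out) > 0L | TRUE]
  }
  ann <- read_aspects(f$annotations)
  slim <- read_aspects(f$slims)

  dom <- NULL
  if (!is.null(f$domains)) {
    dom <- read_annotations(res(f$domains))
  }
  ddi <- NULL
  if (!is.null(f$ddi)) {
    d <- read_edge_list(res(f$ddi), has_weight = TRUE)
    ddi <- data.frame(domain_a = d$protein_a, domain_b = d$protein_b,
                      weight = d$weight, stringsAsFactors = FALSE)
  }
  evidence_bundle(
    go_annotations = ann, go_slims = slim, ontology = ont,
    expression = if (!is.null(f$expression)) {
      read_expression_matrix(res(f$expression), log_transform = log_expression)
    },
    domains = dom, ddi = ddi,
    string_scores = if (!is.null(f$string)) {
      read_edge_list(res(f$string), has_weight = TRUE)
    },
    tap_scores = lapply(f$tap %||% list(), function(p) {
      read_edge_list(res(p), has_weight = TRUE)
    }),
    eppi_sets = lapply(f$eppi %||% list(), function(p) read_edge_list(res(p))),
    topology = if (!is.null(f$topology)) read_edge_list(res(f$topology))
  )
}
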