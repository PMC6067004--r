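# Seedable synthetic fixtures: planted complexes, a true interaction
# network, and all six evidence sources, so every pipeline stage is
# testable without external downloads.

#' Specification of a synthetic ground truth
#'
#' The default regime plants 20 complexes of 5-8 proteins among 300, wires
#' within-complex pairs with probability 0.9 against a 0.005 background,
#' corrupts each observed source with 10% false positives and negatives,
#' and gives co-complex expression profiles a pairwise correlation of 0.7
#' over 50 samples.
#'
#' @param n_proteins Number of proteins.
#' @param n_complexes Number of planted complexes (disjoint).
#' @param size_range Inclusive complex size range (sizes >= 3).
#' @param p_in Within-complex edge probability.
#' @param p_bg Background edge probability (must be < `p_in`).
#' @param fp_rate,fn_rate False-positive and false-negative rate of each
#'   simulated observed source (fp as a fraction of the true edge count).
#' @param n_samples Expression samples.
#' @param rho Target pairwise expression correlation within complexes.
#' @param annotation_share Probability that a complex member carries the
#'   complex's annotation (GO term, domain).
#' @param seed Integer RNG seed; every generated byte is a function of the
#'   spec including this seed.
#' @return A validated `truth_spec` list.
#' @export
truth_spec <- function(n_proteins = 300L, n_complexes = 20L,
                       size_range = c(5L, 8L), p_in = 0.9, p_bg = 0.005,
                       fp_rate = 0.1, fn_rate = 0.1, n_samples = 50L,
                       rho = 0.7, annotation_share = 0.9, seed = 1L) {
  spec <- list(
    n_proteins = as.integer(n_proteins), n_complexes = as.integer(n_complexes),
    size_range = as.integer(size_range), p_in = p_in, p_bg = p_bg,
    fp_rate = fp_rate, fn_rate = fn_rate, n_samples = as.integer(n_samples),
    rho = rho, annotation_share = annotation_share, seed = as.integer(seed)
  )
  probs <- c(spec$p_in, spec$p_bg, spec$fp_rate, spec$fn_rate, spec$rho,
             spec$annotation_share)
  stopifnot(
    "probabilities must be in [0, 1]" = all(probs >= 0 & probs <= 1),
    "p_in must exceed p_bg" = spec$p_in > spec$p_bg,
    "complex sizes must be >= 3" = spec$size_range[1] >= 3L,
    "size range must be ordered" = spec$size_range[1] <= spec$size_range[2],
    "n_samples must be >= 2" = spec$n_samples >= 2L
  )
  class(spec) <- "truth_spec"
  spec
}

#' Generate the ground truth: complexes and the true edge set
#'
#' Samples disjoint complexes with sizes in the spec's range, then wires
#' within-complex pairs with probability `p_in` and all remaining pairs
#' with probability `p_bg`. Deterministic given the spec (seed included).
#'
#' @param spec A [truth_spec()].
#' @return List with `proteins`, `complexes` (list of member vectors),
#'   `edges` (canonical edge `data.frame`), and `co_complex` (logical
#'   vector over the full pair enumeration).
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  with_seed(spec$seed, {
    proteins <- sprintf("P%04d", seq_len(spec$n_proteins))
    size_choices <- seq(spec$size_range[1], spec$size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), spec$n_complexes,
                                     replace = TRUE)]
    if (sum(sizes) > spec$n_proteins) {
      stop("infeasible spec: complex members exceed available proteins")
    }
    members <- sample(proteins, sum(sizes))
    complexes <- split(members, rep(seq_along(sizes), times = sizes))
    complexes <- lapply(complexes, radix_sort)
    names(complexes) <- sprintf("CPX%02d", seq_along(complexes))

    pairs <- enumerate_pairs(proteins)
    cx_of <- setNames(rep(NA_integer_, spec$n_proteins), proteins)
    for (i in seq_along(complexes)) cx_of[complexes[[i]]] <- i
    ca <- cx_of[pairs$protein_a]
    cb <- cx_of[pairs$protein_b]
    co <- !is.na(ca) & !is.na(cb) & ca == cb
    p_edge <- ifelse(co, spec$p_in, spec$p_bg)
    keep <- runif(nrow(pairs)) < p_edge
    edges <- pairs[keep, , drop = FALSE]
    rownames(edges) <- NULL
    list(proteins = proteins, complexes = complexes, edges = edges,
         co_complex = co)
  })
}

# One fp/fn-corrupted copy of the true edge set. `non_edges` supplies the
# false-positive pool.
corrupt_edges <- function(edges, non_edges, fp_rate, fn_rate) {
  keep <- runif(nrow(edges)) >= fn_rate
  n_fp <- round(fp_rate * nrow(edges))
  fp <- non_edges[sample(nrow(non_edges), min(n_fp, nrow(non_edges))), ,
                  drop = FALSE]
  out <- rbind(edges[keep, c("protein_a", "protein_b"), drop = FALSE],
               fp[, c("protein_a", "protein_b"), drop = FALSE])
  attr(out, "is_fp") <- rep(c(FALSE, TRUE), c(sum(keep), nrow(fp)))
  rownames(out) <- NULL
  out
}

# Reliability scores for a corrupted edge set: genuine edges look strong
# (Beta(5,2)), false positives weak (Beta(2,5)).
score_corrupted <- function(edges) {
  is_fp <- attr(edges, "is_fp")
  w <- numeric(nrow(edges))
  w[!is_fp] <- rbeta(sum(!is_fp), 5, 2)
  w[is_fp] <- rbeta(sum(is_fp), 2, 5)
  edges$weight <- pmax(w, 1e-6)
  edges
}

#' Generate the six evidence sources for a ground truth
#'
#' Expression rows of co-complex proteins share a per-complex latent factor
#' giving pairwise correlation about `rho`; complex members share GO leaf
#' terms, slim terms and domains with probability `annotation_share`; two
#' curated-database edge sets, five AP-MS score tables and a STRING-like
#' score table are independently fp/fn-corrupted copies of the true edges;
#' the second database doubles as the topology network.
#'
#' @param truth Output of [generate_truth()].
#' @param spec The same [truth_spec()].
#' @return A `synthetic_fixture`: the truth plus every evidence component
#'   and the assembled `evidence_bundle` (element `bundle`).
#' @export
generate_evidence <- function(truth, spec) {
  stopifnot(inherits(spec, "truth_spec"))
  with_seed((spec$seed + 982451653L) %% 2147483647L, {
    proteins <- truth$proteins
    complexes <- truth$complexes
    nc <- length(complexes)

    # expression: one latent factor per complex
    expr <- matrix(rnorm(length(proteins) * spec$n_samples),
                   nrow = length(proteins),
                   dimnames = list(proteins,
                                   sprintf("S%03d", seq_len(spec$n_samples))))
    for (i in seq_len(nc)) {
      z <- rnorm(spec$n_samples)
      for (p in complexes[[i]]) {
        expr[p, ] <- sqrt(spec$rho) * z +
          sqrt(1 - spec$rho) * rnorm(spec$n_samples)
      }
    }

    # ontology: per aspect a root, 5 mid-level terms, background leaves and
    # one leaf per complex under a random mid
    parents <- list()
    namespace <- character(0)
    leaf_of <- list()
    mids_of <- list()
    for (aspect in GO_ASPECTS) {
      root <- sprintf("GO:%s:root", aspect)
      mids <- sprintf("GO:%s:mid%02d", aspect, 1:5)
      bg <- sprintf("GO:%s:bg%02d", aspect, 1:10)
      leaves <- sprintf("GO:%s:cpx%02d", aspect, seq_len(nc))
      parents[[root]] <- character(0)
      for (m in mids) parents[[m]] <- root
      for (t in c(bg, leaves)) parents[[t]] <- sample(mids, 1L)
      namespace[c(root, mids, bg, leaves)] <- aspect
      leaf_of[[aspect]] <- leaves
      mids_of[[aspect]] <- mids
    }
    ont <- ontology(parents, namespace = namespace)

    go_annotations <- list()
    go_slims <- list()
    for (aspect in GO_ASPECTS) {
      ann <- setNames(vector("list", length(proteins)), proteins)
      for (p in proteins) {
        ann[[p]] <- sample(sprintf("GO:%s:bg%02d", aspect, 1:10), 1L)
      }
      for (i in seq_len(nc)) {
        for (p in complexes[[i]]) {
          if (runif(1) < spec$annotation_share) {
            ann[[p]] <- radix_sort(unique(c(ann[[p]], leaf_of[[aspect]][i])))
          }
        }
      }
      go_annotations[[aspect]] <- ann
      # slims: the mid-level ancestors of each protein's leaves
      mids <- mids_of[[aspect]]
      go_slims[[aspect]] <- lapply(ann, function(ts) {
        radix_sort(unique(unlist(ont$ancestors[ts], use.names = FALSE)[
          unlist(ont$ancestors[ts], use.names = FALSE) %in% mids
        ]))
      })
    }

    # domains: two interacting domains per complex plus background noise
    bg_doms <- sprintf("DOMBG%02d", 1:40)
    domains <- setNames(vector("list", length(proteins)), proteins)
    for (p in proteins) domains[[p]] <- sample(bg_doms, 1L)
    ddi_a <- character(0); ddi_b <- character(0); ddi_w <- numeric(0)
    for (i in seq_len(nc)) {
      da <- sprintf("DOMC%02dA", i)
      db <- sprintf("DOMC%02dB", i)
      for (p in complexes[[i]]) {
        if (runif(1) < spec$annotation_share) {
          domains[[p]] <- radix_sort(unique(c(domains[[p]], da, db)))
        }
      }
      ddi_a <- c(ddi_a, da); ddi_b <- c(ddi_b, db)
      ddi_w <- c(ddi_w, rbeta(1, 5, 2))
    }
    bg_pairs <- matrix(sample(bg_doms, 60, replace = TRUE), ncol = 2)
    ok <- bg_pairs[, 1] != bg_pairs[, 2]
    ddi <- data.frame(
      domain_a = c(ddi_a, bg_pairs[ok, 1]),
      domain_b = c(ddi_b, bg_pairs[ok, 2]),
      weight = c(ddi_w, rbeta(sum(ok), 2, 5)),
      stringsAsFactors = FALSE
    )

    # observed interaction sources: independent fp/fn corruptions
    all_pairs <- enumerate_pairs(proteins)
    true_key <- pair_key(truth$edges$protein_a, truth$edges$protein_b)
    non_edges <- all_pairs[!(pair_key(all_pairs$protein_a, all_pairs$protein_b)
                             %in% true_key), , drop = FALSE]
    eppi <- lapply(1:2, function(i) {
      corrupt_edges(truth$edges, non_edges, spec$fp_rate, spec$fn_rate)
    })
    tap <- lapply(1:5, function(i) {
      score_corrupted(corrupt_edges(truth$edges, non_edges,
                                    spec$fp_rate, spec$fn_rate))
    })
    string <- score_corrupted(corrupt_edges(truth$edges, non_edges,
                                            spec$fp_rate, spec$fn_rate))

    fixture <- list(
      spec = spec, proteins = proteins, complexes = complexes,
      true_edges = truth$edges, co_complex = truth$co_complex,
      ontology = ont, go_annotations = go_annotations, go_slims = go_slims,
      expression = expr, domains = domains, ddi = ddi,
      eppi = eppi, tap = tap, string = string,
      topology = eppi[[2]]
    )
    fixture$bundle <- as_evidence_bundle(fixture)
    class(fixture) <- "synthetic_fixture"
    fixture
  })
}

#' Generate a complete synthetic fixture
#'
#' @param spec A [truth_spec()].
#' @return A `synthetic_fixture` (see [generate_evidence()]).
#' @export
generate_fixture <- function(spec = truth_spec()) {
  generate_evidence(generate_truth(spec), spec)
}

#' Assemble the evidence bundle of a synthetic fixture
#'
#' @param fixture A `synthetic_fixture`.
#' @return An `evidence_bundle`.
#' @export
as_evidence_bundle <- function(fixture) {
  evidence_bundle(
    go_annotations = fixture$go_annotations,
    go_slims = fixture$go_slims,
    ontology = fixture$ontology,
    expression = fixture$expression,
    domains = fixture$domains,
    ddi = fixture$ddi,
    string_scores = fixture$string,
    tap_scores = fixture$tap,
    eppi_sets = fixture$eppi,
    topology = fixture$topology
  )
}

#' Write a synthetic fixture to disk
#'
#' Emits every source in the package's tab-separated dialects plus an OBO
#' ontology and a `manifest.yaml` recording paths, spec and seed, so that
#' [bundle_from_manifest()] (and the truth readers) reconstruct the bundle.
#'
#' @param fixture A `synthetic_fixture`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "synthetic_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_complexes(fixture$complexes, p("complexes_truth.tsv"))
  write_pairs <- function(df, f, weighted) {
    if (weighted) {
      write_weighted_edges(df, p(f))
    } else {
      writeLines(paste(df$protein_a, df$protein_b, sep = "\t"), p(f))
    }
    f
  }
  write_map <- function(map, f) {
    prot <- rep(names(map), lengths(map))
    writeLines(paste(prot, unlist(map, use.names = FALSE), sep = "\t"), p(f))
    f
  }
  files <- list(
    complexes = "complexes_truth.tsv",
    true_edges = write_pairs(fixture$true_edges, "true_edges.tsv", FALSE),
    ontology = "ontology.obo",
    annotations = lapply(setNames(nm = names(fixture$go_annotations)),
                         function(a) {
                           write_map(fixture$go_annotations[[a]],
                                     sprintf("annotations_%s.tsv", a))
                         }),
    slims = lapply(setNames(nm = names(fixture$go_slims)), function(a) {
      write_map(fixture$go_slims[[a]], sprintf("slims_%s.tsv", a))
    }),
    expression = "expression.tsv",
    domains = write_map(fixture$domains, "domains.tsv"),
    ddi = "ddi.tsv",
    string = write_pairs(fixture$string, "string.tsv", TRUE),
    tap = lapply(seq_along(fixture$tap), function(i) {
      write_pairs(fixture$tap[[i]], sprintf("tap%d.tsv", i), TRUE)
    }),
    eppi = lapply(seq_along(fixture$eppi), function(i) {
      write_pairs(fixture$eppi[[i]], sprintf("eppi%d.tsv", i), FALSE)
    }),
    topology = "eppi2.tsv"
  )
  write_ontology_obo(fixture$ontology, p("ontology.obo"))
  expr <- fixture$expression
  expr_lines <- c(
    paste(c("protein", colnames(expr)), collapse = "\t"),
    paste(rownames(expr),
          apply(expr, 1L, function(r) {
            paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
                  collapse = "\t")
          }),
          sep = "\t")
  )
  writeLines(expr_lines, p("expression.tsv"))
  ddi_df <- fixture$ddi
  writeLines(paste(ddi_df$domain_a, ddi_df$domain_b,
                   format(ddi_df$weight, digits = 15, trim = TRUE,
                          scientific = FALSE), sep = "\t"),
             p("ddi.tsv"))
  manifest <- list(seed = fixture$spec$seed, files = files,
                   spec = unclass(fixture$spec))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(p("manifest.yaml"))
}
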