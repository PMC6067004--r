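# Ontology handling: a minimal DAG container, an OBO-subset reader, term
# ancestor closures, and annotation-corpus information content.

#' Construct an ontology DAG
#'
#' @param parents Named list: term ID -> character vector of parent term IDs
#'   (empty for roots). Terms appearing only as parents are added
#'   automatically.
#' @param namespace Optional named character vector of per-term namespaces
#'   (e.g. `"MF"`, `"BP"`, `"CC"`).
#' @return An object of class `mlpr_ontology` with elements `terms`,
#'   `parents`, `namespace`, `roots`, and the self-inclusive ancestor
#'   closure `ancestors`.
#' @export
ontology <- function(parents, namespace = NULL) {
  terms <- radix_sort(unique(c(names(parents), unlist(parents, use.names = FALSE))))
  full <- setNames(vector("list", length(terms)), terms)
  for (t in names(parents)) full[[t]] <- unique(parents[[t]])
  for (t in terms) if (is.null(full[[t]])) full[[t]] <- character(0)
  anc <- ancestor_closure(full)
  roots <- terms[lengths(full) == 0L]
  ns <- setNames(rep(NA_character_, length(terms)), terms)
  if (!is.null(namespace)) ns[names(namespace)] <- namespace
  structure(
    list(terms = terms, parents = full, namespace = ns,
         roots = roots, ancestors = anc),
    class = "mlpr_ontology"
  )
}

# Self-inclusive ancestor sets by memoized traversal; errors on cycles.
ancestor_closure <- function(parents) {
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  walk <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (isTRUE(visiting[[t]])) stop("ontology is not acyclic at term ", t)
    visiting[[t]] <- TRUE
    res <- t
    for (p in parents[[t]]) res <- union(res, walk(p))
    visiting[[t]] <- FALSE
    memo[[t]] <- res
    res
  }
  setNames(lapply(names(parents), walk), names(parents))
}

#' Read an ontology DAG from OBO or a parent table
#'
#' Understands the OBO subset sufficient for a GO-style DAG: `[Term]`
#' stanzas with `id`, `name`, `namespace`, `is_a` and `is_obsolete` tags
#' (obsolete terms are skipped; trailing `! comments` on `is_a` lines are
#' stripped). Files without a `[Term]` stanza are parsed as a two-column
#' tab-separated child/parent table.
#'
#' @param path Path to the file.
#' @return An `mlpr_ontology` object.
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (any(startsWith(trimws(lines), "[Term]"))) {
    return(parse_obo(lines))
  }
  tl <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(tl, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) != 2L)) {
    stop("parent table in ", path, " must have exactly 2 tab-separated columns")
  }
  child <- vapply(parts, `[[`, character(1), 1L)
  parent <- vapply(parts, `[[`, character(1), 2L)
  ontology(lapply(split(parent, child), unique))
}

parse_obo <- function(lines) {
  lines <- trimws(lines)
  in_term <- FALSE
  id <- NA_character_
  ns <- NA_character_
  isa <- character(0)
  obsolete <- FALSE
  parents <- list()
  namespace <- character(0)
  flush <- function() {
    if (in_term && !is.na(id) && !obsolete) {
      parents[[id]] <<- unique(c(parents[[id]], isa))
      if (!is.na(ns)) namespace[[id]] <<- ns
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      id <- NA_character_; ns <- NA_character_
      isa <- character(0); obsolete <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "namespace:")) {
      ns <- trimws(sub("^namespace:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      v <- trimws(sub("^is_a:", "", ln))
      v <- trimws(sub("!.*$", "", v))
      if (nzchar(v)) isa <- c(isa, v)
    } else if (startsWith(ln, "is_obsolete:")) {
      obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  flush()
  if (!length(parents)) stop("no usable [Term] stanzas found")
  ontology(parents, namespace = unlist(namespace))
}

#' Write an ontology in OBO format
#'
#' Minimal emitter matching what [read_ontology()] parses; used by the
#' synthetic-fixture writer.
#'
#' @param ont An `mlpr_ontology`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ontology_obo <- function(ont, path) {
  stopifnot(inherits(ont, "mlpr_ontology"))
  out <- c("format-version: 1.2", "")
  for (t in ont$terms) {
    out <- c(out, "[Term]", paste0("id: ", t))
    if (!is.na(ont$namespace[[t]])) {
      out <- c(out, paste0("namespace: ", ont$namespace[[t]]))
    }
    for (p in ont$parents[[t]]) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Information content of ontology terms from an annotation corpus
#'
#' IC(t) = -log of the fraction of corpus proteins annotated to `t` or any
#' of its descendants (annotations are propagated up the DAG). The root of
#' a fully annotated corpus has IC 0; terms annotating no protein get `NA`.
#'
#' @param ont An `mlpr_ontology`.
#' @param annotations Named list protein -> direct term IDs (the corpus).
#' @return Named numeric vector of IC values over `ont$terms`.
#' @export
term_information_content <- function(ont, annotations) {
  stopifnot(inherits(ont, "mlpr_ontology"))
  used <- unique(unlist(annotations, use.names = FALSE))
  missing <- setdiff(used, ont$terms)
  if (length(missing)) {
    stop("annotation term(s) absent from the ontology: ",
         paste(head(missing, 3L), collapse = ", "))
  }
  n <- sum(lengths(annotations) > 0L)
  ic <- setNames(rep(NA_real_, length(ont$terms)), ont$terms)
  if (n == 0L) return(ic)
  closed <- lapply(annotations, function(ts) {
    unique(unlist(ont$ancestors[ts], use.names = FALSE))
  })
  counts <- table(unlist(closed, use.names = FALSE))
  ic[names(counts)] <- -log(as.numeric(counts) / n)
  ic
}

# Pairwise term similarity: IC-normalized most-informative-common-ancestor,
# 2 * IC(MICA) / (IC(t1) + IC(t2)), with 0/0 defined as 0. Bounded in [0,1]
# because propagation makes ancestor counts monotone.
term_pair_similarity <- function(ont, ic, t1, t2) {
  for (t in c(t1, t2)) {
    if (!t %in% ont$terms) stop("term absent from the ontology DAG: ", t)
  }
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  if (!length(common)) return(0)
  mica <- suppressWarnings(max(ic[common], na.rm = TRUE))
  if (!is.finite(mica)) return(0)
  denom <- ic[[t1]] + ic[[t2]]
  if (is.na(denom) || denom <= 0) return(0)
  min(1, 2 * mica / denom)
}
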