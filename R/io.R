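# Readers and writers for the tab-separated tables the pipeline touches.
# All formats are UTF-8, tab-separated; lines starting with "#" are ignored.

read_tab_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a protein interaction edge list
#'
#' Parses a 2-column (unweighted) or 3-column (weighted) tab-separated edge
#' list into a canonical edge table: the lexicographically smaller protein
#' ID is stored first, self-interactions are dropped, and duplicate pairs
#' are collapsed keeping the maximum weight (the strongest reported
#' evidence). Rows are returned in lexicographic pair order.
#'
#' @param path Path to the file. Lines starting with `#` are ignored.
#' @param has_weight `TRUE` if a third numeric, non-negative score column is
#'   present.
#' @return A `data.frame` with columns `protein_a`, `protein_b`, `weight`
#'   (`NA` for unweighted input). Empty input yields zero rows.
#' @examples
#' f <- tempfile()
#' writeLines(c("B\tA", "A\tB"), f)
#' read_edge_list(f) # one canonical row A-B
#' @export
read_edge_list <- function(path, has_weight = FALSE) {
  tl <- read_tab_lines(path)
  lines <- tl$lines
  nonblank <- nzchar(trimws(lines))
  lineno <- tl$lineno[nonblank]
  lines <- lines[nonblank]
  if (!length(lines)) return(empty_edge_df())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  want <- if (has_weight) 3L else 2L
  bad <- which(nf != want)
  if (length(bad)) {
    stop(sprintf(
      "parse error at line %d of %s: expected %d tab-separated fields, found %d",
      lineno[bad[1L]], path, want, nf[bad[1L]]
    ))
  }
  a <- trimws(vapply(parts, `[[`, character(1), 1L))
  b <- trimws(vapply(parts, `[[`, character(1), 2L))
  blank <- which(!nzchar(a) | !nzchar(b))
  if (length(blank)) {
    stop(sprintf("parse error at line %d of %s: empty protein ID",
                 lineno[blank[1L]], path))
  }
  if (has_weight) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
    if (anyNA(w)) {
      stop(sprintf("parse error at line %d of %s: non-numeric weight",
                   lineno[which(is.na(w))[1L]], path))
    }
    if (any(w < 0)) {
      stop(sprintf("parse error at line %d of %s: negative weight",
                   lineno[which(w < 0)[1L]], path))
    }
  } else {
    w <- rep(NA_real_, length(a))
  }
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropping %d self-interaction(s) in %s", sum(self), path))
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  if (!length(a)) return(empty_edge_df())
  canon <- canonicalize_pairs(a, b)
  key <- pair_key(canon$protein_a, canon$protein_b)
  wmax <- tapply(w, key, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  first <- !duplicated(key)
  out <- data.frame(
    protein_a = canon$protein_a[first],
    protein_b = canon$protein_b[first],
    weight = as.numeric(wmax[key[first]]),
    stringsAsFactors = FALSE
  )
  out <- out[radix_order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a protein-to-term annotation table
#'
#' Two tab-separated columns: protein ID, term ID. Duplicated rows collapse
#' to set semantics. Proteins absent from the file simply have no entry;
#' look them up with [annotation_terms()].
#'
#' @param path Path to the file.
#' @return A named list mapping each protein to a sorted character vector of
#'   term IDs.
#' @export
read_annotations <- function(path) {
  tl <- read_tab_lines(path)
  lines <- tl$lines
  nonblank <- nzchar(trimws(lines))
  lineno <- tl$lineno[nonblank]
  lines <- lines[nonblank]
  if (!length(lines)) return(structure(list(), names = character(0)))
  trailing <- which(grepl("\t\\s*$", lines))
  if (length(trailing)) {
    stop(sprintf("parse error at line %d of %s: empty protein or term",
                 lineno[trailing[1L]], path))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 2L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected 2 fields, found %d",
                 lineno[bad[1L]], path, nf[bad[1L]]))
  }
  prot <- trimws(vapply(parts, `[[`, character(1), 1L))
  term <- trimws(vapply(parts, `[[`, character(1), 2L))
  bad <- which(!nzchar(term) | !nzchar(prot))
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: empty protein or term",
                 lineno[bad[1L]], path))
  }
  lapply(split(term, prot), function(x) radix_sort(unique(x)))
}

#' Look up a protein's annotation set
#'
#' @param annotations A map as returned by [read_annotations()].
#' @param protein A protein ID.
#' @return Character vector of terms; empty for unannotated proteins.
#' @export
annotation_terms <- function(annotations, protein) {
  annotations[[protein]] %||% character(0)
}

#' Read a protein x sample expression matrix
#'
#' Expects a header row of sample IDs and a first column of protein IDs.
#' With `log_transform = TRUE` values are log2(x + 1) transformed at read
#' time.
#'
#' @param path Path to the file.
#' @param log_transform Apply log2(x + 1)?
#' @return A numeric matrix with protein row names, row order preserved.
#' @export
read_expression_matrix <- function(path, log_transform = FALSE) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE,
               colClasses = NA),
    error = function(e) stop(sprintf("parse error in %s: %s", path, conditionMessage(e)))
  )
  if (ncol(df) < 2L) stop(sprintf("parse error in %s: need >= 1 sample column", path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate protein row '%s' in %s",
                 ids[duplicated(ids)][1L], path))
  }
  vals <- df[, -1L, drop = FALSE]
  numeric_cols <- vapply(vals, is.numeric, logical(1))
  if (!all(numeric_cols)) {
    stop(sprintf("parse error in %s: non-numeric cell in column '%s'",
                 path, names(vals)[!numeric_cols][1L]))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (log_transform) {
    if (any(m < 0)) {
      stop(sprintf("cannot log-transform %s: negative expression values", path))
    }
    m <- log2(m + 1)
  }
  m
}

#' Read a complex catalog (one complex per line)
#'
#' Each line lists the tab-separated member protein IDs of one complex.
#' Members are deduplicated per line; complexes with fewer than `min_size`
#' members after deduplication are dropped, mirroring the usual benchmark
#' filter that removes complexes of a single protein or a single pair.
#'
#' @param path Path to the file.
#' @param min_size Minimum retained complex size (default 1 keeps all).
#' @return A list of character vectors (sorted member IDs).
#' @export
read_complexes <- function(path, min_size = 1L) {
  tl <- read_tab_lines(path)
  lines <- tl$lines
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sprintf("skipping %d blank line(s) in %s", sum(blank), path))
  }
  lines <- lines[!blank]
  cx <- lapply(strsplit(lines, "\t", fixed = TRUE), function(m) {
    m <- trimws(m)
    radix_sort(unique(m[nzchar(m)]))
  })
  cx[lengths(cx) >= min_size]
}

#' Write a weighted edge list
#'
#' Emits a 3-column tab-separated file in descending score order with
#' deterministic lexicographic tie order, so that writing and re-reading
#' ([read_edge_list()] with `has_weight = TRUE`) reproduces the network.
#'
#' @param network A `data.frame` with `protein_a`, `protein_b`, `weight`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_weighted_edges <- function(network, path) {
  stopifnot(all(c("protein_a", "protein_b", "weight") %in% names(network)))
  if (nrow(network) && !all(is.finite(network$weight))) {
    stop("cannot write edges with non-finite weights")
  }
  o <- radix_order(-network$weight, network$protein_a, network$protein_b)
  net <- network[o, c("protein_a", "protein_b", "weight"), drop = FALSE]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(net)) {
    writeLines(paste(net$protein_a, net$protein_b,
                     format(net$weight, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a complex catalog (one complex per line)
#'
#' @param complexes List of character vectors of member IDs.
#' @param path Output path.
#' @param scores Optional numeric vector (e.g. cluster weight) prepended as
#'   a first column.
#' @return Invisibly, the path.
#' @export
write_complexes <- function(complexes, path, scores = NULL) {
  lines <- vapply(complexes, paste, character(1), collapse = "\t")
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(complexes))
    lines <- paste(format(scores, digits = 15, trim = TRUE), lines, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
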