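#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a line are dropped with a warning; duplicate set
#' names or lines with fewer than three fields are errors naming the
#' offending line(s). Gene identifiers are whitespace-trimmed and matched
#' case-sensitively; `normalize = "upper"` upper-cases them for symbol-cased
#' inputs.
#'
#' @param path Path to a GMT file.
#' @param normalize `"none"` (default) or `"upper"`.
#' @return Named list of character vectors; descriptions are kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path, normalize = c("none", "upper")) {
  normalize <- match.arg(normalize)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort(paste0("empty GMT file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(paste0("malformed GMT line(s) with fewer than 3 fields: ",
                 paste(short, collapse = ", ")))
  }
  nm <- trimws(map_chr(fields, 1L))
  dup <- which(duplicated(nm) | duplicated(nm, fromLast = TRUE))
  if (length(dup)) {
    abort(paste0("duplicate set name(s) on lines ",
                 paste(dup, collapse = ", "), ": ",
                 paste(unique(nm[dup]), collapse = ", ")))
  }
  desc <- map_chr(fields, 2L)
  sets <- lapply(fields, function(f) {
    g <- trimws(f[-(1:2)])
    g <- g[nzchar(g)]
    if (normalize == "upper") g <- toupper(g)
    g
  })
  n_dup <- sum(lengths(sets) - lengths(lapply(sets, unique)))
  if (n_dup > 0L) {
    warn(paste0(n_dup, " duplicate member(s) within sets were dropped."))
    sets <- lapply(sets, unique)
  }
  if (any(lengths(sets) == 0L)) {
    abort(paste0("empty set(s): ",
                 paste(nm[lengths(sets) == 0L], collapse = ", ")))
  }
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(desc, nm)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector; defaults to the set
#'   names (GMT requires a description field).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must have unique names.")
  }
  if (any(lengths(sets) == 0L)) abort("empty sets cannot be written.")
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_tsv_quiet <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  out
}

# readr serialises doubles with the shortest round-trippable representation,
# so write -> read reproduces numeric tables exactly
write_tsv_full <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Export a network to GraphML, SIF or TSV
#'
#' GraphML carries node attributes (`layer`, `score`, `direction`,
#' `set_size`) and edge attributes (`relationship`, `overlap`,
#' `coefficient`). SIF uses the relationship type as the interaction label
#' (isolated nodes are written as single-field lines). TSV writes the edge
#' table with columns `edge_id`, `relationship`, `overlap_size`,
#' `similarity_coefficient`.
#'
#' @param net A `trilayer_network`.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, format = c("graphml", "sif", "tsv"), path) {
  stopifnot(inherits(net, "trilayer_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net$graph
    # igraph cannot serialise NA numeric attributes portably; encode as NaN
    sc <- igraph::V(g)$score
    if (!is.null(sc)) igraph::V(g)$score <- ifelse(is.na(sc), NaN, sc)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    lines <- character(0)
    if (nrow(net$edges)) {
      lines <- paste(net$edges$from, net$edges$relationship, net$edges$to,
                     sep = "\t")
    }
    linked <- unique(c(net$edges$from, net$edges$to))
    isolated <- setdiff(net$nodes$id, linked)
    writeLines(c(lines, isolated), path)
  } else {
    write_tsv_full(edge_table(net), path)
  }
  invisible(path)
}

#' Edge table in the layout of the published connection table
#'
#' @param net A `trilayer_network`.
#' @return Tibble with columns `edge_id`, `relationship`, `overlap_size`,
#'   `similarity_coefficient`.
#' @export
edge_table <- function(net) {
  stopifnot(inherits(net, "trilayer_network"))
  tibble(edge_id = paste(net$edges$from, net$edges$to, sep = "--"),
         relationship = net$edges$relationship,
         overlap_size = net$edges$overlap,
         similarity_coefficient = net$edges$coefficient)
}

#' Read a GraphML file written by [export_network()]
#'
#' @param path GraphML path.
#' @return An igraph graph with the exported attributes.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  igraph::read_graph(path, format = "graphml")
}
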