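#' Read an interaction network from a delimited edge list
#'
#' Reads a whitespace/tab-delimited file with at least two identifier
#' columns per line and returns a simplified [as_interactome()] graph.
#' Self-pairs are dropped by default and unordered duplicate pairs are
#' collapsed; the counts of dropped records are attached as a load summary
#' (`attr(net, "load_summary")`), which conserves input lines:
#' `lines = kept + dropped_self + dropped_duplicate + dropped_malformed`.
#'
#' @param path Path to the edge-list file.
#' @param keep_self_loops Retain self-interactions (see [as_interactome()]).
#' @param header Skip one header line before parsing.
#' @param malformed `"error"` (default) stops at the first line with fewer
#'   than two fields, naming the line number; `"drop"` counts and skips it.
#' @param node_path Optional sidecar file of one node id per line, used to
#'   restore isolated nodes that an edge list cannot encode.
#' @return An `interactome` with a `load_summary` attribute.
#' @export
read_edge_list <- function(path, keep_self_loops = FALSE, header = FALSE,
                           malformed = c("error", "drop"), node_path = NULL) {
  malformed <- match.arg(malformed)
  if (!file.exists(path)) stop("cannot read edge list: ", path, call. = FALSE)
  lines <- readr::read_lines(path, progress = FALSE)
  if (header && length(lines) > 0) lines <- lines[-1]
  nonempty <- which(nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[nonempty]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 2)
  if (length(bad) > 0 && malformed == "error") {
    stop(sprintf("parse error at line %d of %s: fewer than 2 fields",
                 nonempty[bad[1]] + as.integer(header), path), call. = FALSE)
  }
  ok <- which(nf >= 2)
  from <- vapply(fields[ok], `[[`, character(1), 1)
  to <- vapply(fields[ok], `[[`, character(1), 2)
  loops <- from == to
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  kept_mask <- if (keep_self_loops) !dup else !loops & !dup
  nodes <- NULL
  if (!is.null(node_path) && file.exists(node_path)) {
    nodes <- trimws(readr::read_lines(node_path, progress = FALSE))
    nodes <- nodes[nzchar(nodes)]
  }
  net <- as_interactome(
    data.frame(from = from[kept_mask], to = to[kept_mask],
               stringsAsFactors = FALSE),
    nodes = nodes, keep_self_loops = keep_self_loops
  )
  attr(net, "load_summary") <- tibble::tibble(
    lines = length(nonempty),
    kept = sum(kept_mask),
    dropped_self = if (keep_self_loops) 0L else sum(loops & !dup),
    dropped_duplicate = sum(dup),
    dropped_malformed = length(bad)
  )
  net
}

#' Write an interaction network as a two-column edge list
#'
#' Writes one tab-delimited line per edge with endpoints in lexicographic
#' order and lines sorted, so output is deterministic and
#' `read_edge_list()` of the result reproduces the network.  Isolated
#' nodes cannot be encoded in an edge list; pass `node_path` to write a
#' one-id-per-line sidecar preserving the full node set.
#'
#' @param net An `interactome`.
#' @param path Output path.
#' @param node_path Optional sidecar node-list path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, node_path = NULL) {
  edges <- net_edges(net)
  readr::write_lines(paste(edges$from, edges$to, sep = "\t"), path)
  if (!is.null(node_path)) {
    readr::write_lines(sort(net_nodes(net)), node_path)
  }
  invisible(path)
}

#' Read and write gene sets, ranked lists, annotations and DE tables
#'
#' @description
#' Plain-text readers for the non-network inputs of the pipeline:
#'
#' * `read_gene_set()`: one identifier per line (training/candidate sets,
#'   locus-window gene sets); duplicates collapsed with a warning.
#' * `read_ranked_list()`: header TSV with columns `id`, `score`,
#'   `p_value` (an externally produced relatedness ranking, e.g. text
#'   mining output); rows are re-ordered by increasing p-value with ties
#'   broken lexicographically, and p-values validated to `[0, 1]`.
#' * `read_annotations()`: GMT dialect (`class<TAB>description<TAB>gene...`),
#'   giving functional class to gene-set annotations; duplicate class
#'   names are an error.
#' * `read_de_table()`: header TSV with columns `id`, `p_adj` of
#'   multiple-testing-adjusted differential-expression p-values.
#'
#' @param path File to read.
#' @return `read_gene_set()`: a character vector. `read_ranked_list()`:
#'   a tibble `(id, score, p_value)` ordered by p-value. `read_annotations()`:
#'   a named list of character vectors. `read_de_table()`: a tibble
#'   `(id, p_adj)`.
#' @export
read_gene_set <- function(path) {
  ids <- trimws(readr::read_lines(path, progress = FALSE))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    warning("duplicate identifiers collapsed in ", path, call. = FALSE)
    ids <- unique(ids)
  }
  ids
}

#' @rdname read_gene_set
#' @export
read_ranked_list <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    score = readr::col_double(),
    p_value = readr::col_double()
  ), progress = FALSE)
  check_pvalues(x$p_value, path)
  if (anyDuplicated(x$id)) {
    warning("duplicate identifiers collapsed in ", path, call. = FALSE)
    x <- dplyr::slice_min(dplyr::group_by(x, .data$id), .data$p_value,
                          n = 1, with_ties = FALSE) |> dplyr::ungroup()
  }
  dplyr::arrange(x, .data$p_value, .data$id)
}

#' @rdname read_gene_set
#' @export
read_annotations <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT parse error at line %d of %s: fewer than 3 fields",
                 short[1], path), call. = FALSE)
  }
  classes <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(classes)) {
    stop("duplicate class name in ", path, ": ",
         classes[duplicated(classes)][1], call. = FALSE)
  }
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  setNames(members, classes)
}

#' @rdname read_gene_set
#' @export
read_de_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    p_adj = readr::col_double()
  ), progress = FALSE)
  check_pvalues(x$p_adj, path)
  if (anyDuplicated(x$id)) {
    warning("duplicate identifiers collapsed in ", path, call. = FALSE)
    x <- dplyr::slice_min(dplyr::group_by(x, .data$id), .data$p_adj,
                          n = 1, with_ties = FALSE) |> dplyr::ungroup()
  }
  dplyr::arrange(x, .data$id)
}

check_pvalues <- function(p, path) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values outside [0, 1] in ", path, call. = FALSE)
  }
  invisible(p)
}

#' @rdname read_gene_set
#' @param genes Character vector of identifiers to write.
#' @export
write_gene_set <- function(genes, path) {
  readr::write_lines(sort(unique(genes)), path)
  invisible(path)
}

#' @rdname read_gene_set
#' @param ranked A tibble `(id, score, p_value)`.
#' @export
write_ranked_list <- function(ranked, path) {
  ranked <- dplyr::arrange(ranked, .data$p_value, .data$id)
  readr::write_tsv(ranked, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_gene_set
#' @param annotations A named list of character vectors.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(names(annotations), function(cl) {
    paste(c(cl, "na", sort(annotations[[cl]])), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname read_gene_set
#' @param de A tibble `(id, p_adj)`.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(dplyr::arrange(de, .data$id), path, progress = FALSE)
  invisible(path)
}
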