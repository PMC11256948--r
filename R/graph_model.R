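#' Construct a variation graph
#'
#' A variation graph is a vertex-labelled directed acyclic graph together
#' with a nonempty set of distinguished source-to-sink paths, each
#' representing a known haplotype or strain.  Vertices carry nucleotide
#' label strings; the unique source and sink carry empty labels and serve
#' only to mark genome boundaries.  Internally vertices are renumbered to
#' dense integer ids in topological order, so that every arc goes from a
#' smaller id to a larger one.
#'
#' @param labels character vector of vertex labels, one per vertex; the
#'   source and sink must be labelled `""`.
#' @param arcs two-column integer matrix of arcs `(from, to)`, indices into
#'   `labels`.
#' @param paths named list of integer vertex sequences; every path must
#'   start at `source`, end at `sink`, follow arcs, and visit no vertex
#'   twice.
#' @param source,sink integer ids of the source and sink vertices.
#' @param seg_names character vector of external (GFA segment) names, one
#'   per vertex.  Defaults to the vertex index as a string.
#' @return An object of class `variation_graph` with components `labels`,
#'   `seg_names`, `arcs`, `paths`, `source`, `sink`.
#' @export
variation_graph <- function(labels, arcs, paths, source, sink,
                            seg_names = NULL) {
  nv <- length(labels)
  if (is.null(seg_names)) seg_names <- as.character(seq_len(nv))
  arcs <- matrix(as.integer(arcs), ncol = 2L)
  ord <- topological_order_ids(nv, arcs)
  rank <- integer(nv)
  rank[ord] <- seq_len(nv)
  g <- structure(list(
    labels    = labels[ord],
    seg_names = seg_names[ord],
    arcs      = matrix(rank[arcs], ncol = 2L),
    paths     = lapply(paths, function(p) rank[as.integer(p)]),
    source    = rank[as.integer(source)],
    sink      = rank[as.integer(sink)]
  ), class = "variation_graph")
  validate_variation_graph(g)
  g
}

#' Validate the invariants of a variation graph
#'
#' Checks acyclicity, that the path set is nonempty, that every
#' distinguished path runs from the empty-labelled source to the
#' empty-labelled sink along arcs of the graph, and that no path visits a
#' vertex twice.
#'
#' @param g a `variation_graph`.
#' @return `g`, invisibly; errors if an invariant is violated.
#' @export
validate_variation_graph <- function(g) {
  stopifnot(inherits(g, "variation_graph"))
  nv <- length(g$labels)
  if (length(g$paths) == 0L) stop("variation graph must have at least one path")
  if (is.null(names(g$paths)) || anyNA(names(g$paths)) ||
      any(names(g$paths) == "")) stop("paths must be named")
  if (g$labels[g$source] != "" || g$labels[g$sink] != "")
    stop("source and sink labels must be empty strings")
  if (nrow(g$arcs) > 0 && any(g$arcs < 1L | g$arcs > nv))
    stop("arc endpoint out of range")
  topological_order(g)  # errors on a cycle
  akey <- arc_keys(g)
  for (nm in names(g$paths)) {
    p <- g$paths[[nm]]
    if (p[1L] != g$source) stop("path '", nm, "' does not start at the source")
    if (p[length(p)] != g$sink) stop("path '", nm, "' does not end at the sink")
    if (anyDuplicated(p)) stop("path '", nm, "' visits a vertex twice")
    if (length(p) > 1L) {
      steps <- paste(p[-length(p)], p[-1L])
      if (!all(steps %in% akey))
        stop("path '", nm, "' uses a pair that is not an arc")
    }
  }
  invisible(g)
}

arc_keys <- function(g) paste(g$arcs[, 1L], g$arcs[, 2L])

#' @export
print.variation_graph <- function(x, ...) {
  cat(sprintf(
    "%s: %d vertices (%d labelled), %d arcs, %d paths\n",
    class(x)[1L], length(x$labels),
    sum(nzchar(x$labels)), nrow(x$arcs), length(x$paths)))
  cat("  paths:", paste(names(x$paths), collapse = ", "), "\n")
  invisible(x)
}

# Kahn traversal with smallest-id tie-breaking: deterministic for a given
# input, every arc goes forward in the returned order.
topological_order_ids <- function(nv, arcs) {
  indeg <- tabulate(arcs[, 2L], nbins = nv)
  adj <- split(arcs[, 2L], factor(arcs[, 1L], levels = seq_len(nv)))
  avail <- sort(which(indeg == 0L))
  ord <- integer(0L)
  while (length(avail) > 0L) {
    v <- avail[1L]
    avail <- avail[-1L]
    ord <- c(ord, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(ord) != nv) stop("not a DAG")
  ord
}

#' Topological order of a variation graph
#'
#' @param g a `variation_graph`.
#' @return integer vector of vertex ids such that every arc goes forward;
#'   ties are broken by smallest vertex id, so the order is deterministic.
#' @export
topological_order <- function(g) {
  topological_order_ids(length(g$labels), g$arcs)
}

#' Spell the label of a walk
#'
#' Concatenates the vertex labels along a walk.  The walk need not be a
#' distinguished path; the source and sink contribute empty strings.
#'
#' @param g a `variation_graph`.
#' @param walk integer vector of vertex ids.
#' @return a single string.
#' @export
spell_path <- function(g, walk) {
  walk <- as.integer(walk)
  if (length(walk) == 0L) return("")
  if (any(walk < 1L | walk > length(g$labels))) stop("unknown vertex id in walk")
  paste(g$labels[walk], collapse = "")
}

#' Read a variation graph from GFA 1.x text
#'
#' Accepts S, L and P lines.  Links must be forward-oriented (`+`/`+`) with
#' overlap `0M` or `*`; at least one P line is required.  If the graph does
#' not already have a unique empty-labelled source (resp. sink) shared by
#' all paths, a virtual one is added with arcs to (from) every path start
#' (end) vertex, and every path is extended to include it.
#'
#' @param gfa path to a GFA file, or a character vector of GFA lines.
#' @return a validated `variation_graph`.
#' @export
load_gfa <- function(gfa) {
  lines <- if (length(gfa) == 1L && file.exists(gfa)) readLines(gfa) else gfa
  lines <- lines[nzchar(lines)]
  segs <- list(); links <- list(); paths <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "S") {
      if (length(f) < 3L) stop("malformed S line: ", ln)
      segs[[f[2L]]] <- toupper(f[3L])
    } else if (f[1L] == "L") {
      if (length(f) < 5L) stop("malformed L line: ", ln)
      if (f[3L] != "+" || f[5L] != "+")
        stop("reverse-orientation links are not supported")
      if (length(f) >= 6L && !(f[6L] %in% c("0M", "*")))
        stop("nontrivial link overlap '", f[6L], "' is not supported")
      links[[length(links) + 1L]] <- c(f[2L], f[4L])
    } else if (f[1L] == "P") {
      if (length(f) < 3L) stop("malformed P line: ", ln)
      toks <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
      orient <- substring(toks, nchar(toks))
      if (any(orient != "+"))
        stop("reverse-orientation path steps are not supported")
      paths[[f[2L]]] <- substring(toks, 1L, nchar(toks) - 1L)
    }
  }
  if (length(segs) == 0L) stop("GFA document has no S lines")
  if (length(paths) == 0L) stop("GFA document has no P lines")
  seg_names <- names(segs)
  id_of <- stats::setNames(seq_along(seg_names), seg_names)
  resolve <- function(nms, what) {
    unknown <- setdiff(nms, seg_names)
    if (length(unknown) > 0L)
      stop(what, " references unknown segment: ", unknown[1L])
    unname(id_of[nms])
  }
  arcs <- if (length(links) > 0L) {
    lm <- do.call(rbind, links)
    cbind(resolve(lm[, 1L], "L line"), resolve(lm[, 2L], "L line"))
  } else matrix(integer(0L), ncol = 2L)
  path_ids <- lapply(paths, resolve, what = "P line")
  labels <- unname(unlist(segs))

  starts <- unique(vapply(path_ids, function(p) p[1L], integer(1L)))
  ends <- unique(vapply(path_ids, function(p) p[length(p)], integer(1L)))
  have_src <- length(starts) == 1L && labels[starts] == "" &&
    !(starts %in% arcs[, 2L])
  have_snk <- length(ends) == 1L && labels[ends] == "" &&
    !(ends %in% arcs[, 1L])
  if (!have_src) {
    labels <- c(labels, "")
    seg_names <- c(seg_names, "__source__")
    src <- length(labels)
    arcs <- rbind(arcs, cbind(src, starts))
    path_ids <- lapply(path_ids, function(p) c(src, p))
  } else src <- starts
  if (!have_snk) {
    labels <- c(labels, "")
    seg_names <- c(seg_names, "__sink__")
    snk <- length(labels)
    arcs <- rbind(arcs, cbind(ends, snk))
    path_ids <- lapply(path_ids, function(p) c(p, snk))
  } else snk <- ends

  variation_graph(labels, arcs, path_ids, source = src, sink = snk,
                  seg_names = seg_names)
}

#' Write a variation graph as GFA 1.x text
#'
#' Emits S, L and P lines for all labelled vertices; the empty-labelled
#' source and sink (and their arcs) are dropped, since [load_gfa()] re-adds
#' them.  Round-tripping reproduces an isomorphic graph with identical path
#' spellings.
#'
#' @param g a `variation_graph`.
#' @param file optional path; if `NULL` the lines are returned.
#' @return character vector of GFA lines, invisibly when `file` is given.
#' @export
write_gfa <- function(g, file = NULL) {
  keep <- setdiff(seq_along(g$labels), c(g$source, g$sink))
  s_lines <- sprintf("S\t%s\t%s", g$seg_names[keep], g$labels[keep])
  inner <- g$arcs[g$arcs[, 1L] != g$source & g$arcs[, 2L] != g$sink, ,
                  drop = FALSE]
  l_lines <- sprintf("L\t%s\t+\t%s\t+\t0M",
                     g$seg_names[inner[, 1L]], g$seg_names[inner[, 2L]])
  p_lines <- vapply(names(g$paths), function(nm) {
    p <- setdiff(g$paths[[nm]], c(g$source, g$sink))
    sprintf("P\t%s\t%s\t*", nm,
            paste0(g$seg_names[p], "+", collapse = ","))
  }, character(1L))
  out <- c(s_lines, l_lines, p_lines)
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' Canonicalize a variation graph
#'
#' Replaces every multi-character vertex by a chain of single-character
#' vertices, so that the dynamic programs can treat one vertex as one
#' alignment row.  Incoming arcs attach to the head of each chain and
#' outgoing arcs to its tail; paths are remapped through the chains and
#' their spelled labels are unchanged.  The mapping back to the original
#' GFA segments is retained in `origin`, a data frame with one row per
#' canonical vertex (`segment`, `offset` 0-based, `seg_len`), used for GAF
#' output.
#'
#' @param g a `variation_graph`.
#' @return an object of class `canonical_graph` (also a `variation_graph`)
#'   with the extra component `origin`.
#' @export
canonicalize <- function(g) {
  validate_variation_graph(g)
  labels <- character(0L); seg <- character(0L); off <- integer(0L)
  slen <- integer(0L)
  head_of <- integer(length(g$labels)); tail_of <- integer(length(g$labels))
  chain_arcs <- list()
  for (v in seq_along(g$labels)) {
    lab <- g$labels[v]
    k <- nchar(lab)
    if (k <= 1L) {
      labels <- c(labels, lab)
      seg <- c(seg, if (v %in% c(g$source, g$sink)) NA_character_ else
        g$seg_names[v])
      off <- c(off, 0L); slen <- c(slen, k)
      head_of[v] <- tail_of[v] <- length(labels)
    } else {
      ids <- length(labels) + seq_len(k)
      labels <- c(labels, strsplit(lab, "", fixed = TRUE)[[1L]])
      seg <- c(seg, rep(g$seg_names[v], k))
      off <- c(off, seq_len(k) - 1L); slen <- c(slen, rep(k, k))
      head_of[v] <- ids[1L]; tail_of[v] <- ids[k]
      chain_arcs[[length(chain_arcs) + 1L]] <- cbind(ids[-k], ids[-1L])
    }
  }
  arcs <- rbind(
    cbind(tail_of[g$arcs[, 1L]], head_of[g$arcs[, 2L]]),
    do.call(rbind, c(chain_arcs, list(matrix(integer(0L), ncol = 2L)))))
  expand <- function(p) unlist(lapply(p, function(v)
    seq.int(head_of[v], tail_of[v])), use.names = FALSE)
  paths <- lapply(g$paths, expand)
  nv <- length(labels)
  seg_names <- ifelse(is.na(seg), c("__source__", "__sink__")[
    match(seq_len(nv), c(head_of[g$source], head_of[g$sink]))],
    ifelse(slen > 1L, paste0(seg, ":", off), seg))
  gc <- variation_graph(labels, arcs, paths, source = head_of[g$source],
                        sink = head_of[g$sink], seg_names = seg_names)
  # variation_graph() reorders vertices topologically; recover the
  # permutation through the (unique) seg_names to carry origin along.
  perm <- match(gc$seg_names, seg_names)
  gc$origin <- data.frame(segment = seg[perm], offset = off[perm],
                          seg_len = slen[perm], stringsAsFactors = FALSE)
  class(gc) <- c("canonical_graph", "variation_graph")
  gc
}

#' Test whether a graph is canonical
#' @param g a `variation_graph`.
#' @return `TRUE` if every non-source/sink label has length 1.
#' @export
is_canonical <- function(g) {
  keep <- setdiff(seq_along(g$labels), c(g$source, g$sink))
  all(nchar(g$labels[keep]) == 1L)
}

# Labelled vertices of a path, in order (source and sink stripped).
path_labelled <- function(g, name_or_idx) {
  p <- if (is.character(name_or_idx)) g$paths[[name_or_idx]] else
    g$paths[[name_or_idx]]
  if (is.null(p)) stop("unknown path: ", name_or_idx)
  setdiff(p, c(g$source, g$sink))
}
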