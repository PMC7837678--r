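#' Read and write SWC reconstructions
#'
#' Standard 7-column SWC dialect: `id type x y z radius parent`,
#' whitespace-separated, `#` comments, 1-based ids, `parent = -1` for the
#' root. Exactly one root is required. Coordinates survive a
#' write/read round trip bit-exact (written with 17 significant digits).
#'
#' @param path file path.
#' @return `read_swc()`: a [dtree]. `write_swc()`: `path`, invisibly.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"),
                           colClasses = c("integer", "integer", "numeric",
                                          "numeric", "numeric", "numeric",
                                          "integer"))
  if (nrow(tab) == 0L) stop("SWC file is empty: ", path)
  if (anyDuplicated(tab$id)) stop("duplicate node ids in SWC file: ", path)
  roots <- tab$parent == -1L
  if (sum(roots) != 1L)
    stop("SWC format error: expected exactly one root (parent = -1), found ",
         sum(roots), " in ", path)
  idx <- match(tab$parent, tab$id)
  if (any(is.na(idx) & !roots))
    stop("SWC format error: dangling parent reference in ", path)
  idx[roots] <- 0L
  dtree(x = tab$x, y = tab$y, z = tab$z, r = tab$radius,
        parent = idx, id = tab$id, type = tab$type)
}

#' @param t a [dtree].
#' @rdname read_swc
#' @export
write_swc <- function(t, path) {
  ids <- seq_len(n_nodes(t))
  parent <- ifelse(t$parent == 0L, -1L, t$parent)
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   ids, t$type, t$x, t$y, t$z, t$r, parent)
  writeLines(c("# SWC exported by combgrow", lines), path)
  invisible(path)
}

#' Export a per-node table
#'
#' Flat data frame view of a tree (one row per node), optionally with the
#' derived per-node quantities produced by the alignment/ordering analysis.
#'
#' @param t a [dtree].
#' @return a data.frame with columns id, x, y, z, radius, parent,
#'   branch_order.
#' @export
node_table <- function(t) {
  data.frame(id = seq_len(n_nodes(t)), x = t$x, y = t$y, z = t$z,
             radius = t$r, parent = ifelse(t$parent == 0L, -1L, t$parent),
             branch_order = branch_order(t))
}
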