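#' Branch length order decomposition
#'
#' Orders the branches of a (sub)tree by recursive longest-path
#' decomposition: the metric-longest path from the subtree root to a
#' termination point is branch length order (blo) 1; the longest paths
#' branching off a blo-k path get blo k+1, until every node is labelled
#' exactly once. Equal-length competing paths are broken deterministically
#' towards the lowest terminal node index. This ordering matches the
#' traditional primary/secondary/tertiary branch reading of comb dendrites
#' and differs from both topological branch order and Strahler order.
#'
#' `blo_decompose()` works on a full `dtree` (rooted at its own root);
#' the lateral-subtree version used in the comb analysis is driven by
#' [branch_table()].
#'
#' @param t a [dtree].
#' @param entry node index at which the decomposed subtree starts (its
#'   parent is the attachment node; use the root's child for a full tree).
#' @param attach attachment node (first node of the blo-1 branch path).
#' @return list with `blo` (per-node labels, NA outside the subtree),
#'   `branch_id` (per-node), and `branches`: a data.frame with one row per
#'   branch (`branch_id`, `blo`, `attach`, `tip`, `length`, and list column
#'   `node_path` starting at the branch's attachment node).
#' @export
blo_decompose <- function(t, entry, attach = t$parent[entry]) {
  if (attach == 0L) attach <- entry
  nodes <- descendants_of(t, entry)
  seg <- segment_lengths(t)
  kids <- children_list(t)
  n <- n_nodes(t)
  down <- rep(NA_real_, n)      # longest tipward path below node
  btip <- rep(NA_integer_, n)   # terminal realising it (lowest index on tie)
  for (v in rev(nodes)) {       # children come after parents in index order
    ch <- kids[[v]]
    if (is.null(ch) || length(ch) == 0L) {
      down[v] <- 0; btip[v] <- v
    } else {
      cand <- seg[ch] + down[ch]
      best <- max(cand)
      ties <- ch[cand >= best - 1e-12]
      pick <- ties[which.min(btip[ties])]
      down[v] <- seg[pick] + down[pick]
      btip[v] <- btip[pick]
    }
  }
  blo <- rep(NA_integer_, n)
  bid <- rep(NA_integer_, n)
  branches <- list()
  # stack of (first chain node, its attachment node, order)
  stack <- list(list(head = entry, attach = attach, k = 1L))
  next_id <- 1L
  while (length(stack) > 0L) {
    s <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    chain <- integer(0)
    v <- s$head
    repeat {
      chain <- c(chain, v)
      ch <- kids[[v]]
      if (is.null(ch) || length(ch) == 0L) break
      cand <- seg[ch] + down[ch]
      best <- max(cand)
      ties <- ch[cand >= best - 1e-12]
      nxt <- ties[which.min(btip[ties])]
      for (off in setdiff(ch, nxt))
        stack[[length(stack) + 1L]] <- list(head = off, attach = v,
                                            k = s$k + 1L)
      v <- nxt
    }
    blo[chain] <- s$k
    bid[chain] <- next_id
    np <- if (s$attach == chain[1]) chain else c(s$attach, chain)
    branches[[next_id]] <- data.frame(
      branch_id = next_id, blo = s$k, attach = s$attach,
      tip = chain[length(chain)], length = sum(seg[chain]),
      node_path = I(list(np)))
    next_id <- next_id + 1L
  }
  br <- do.call(rbind, branches)
  br <- br[order(br$branch_id), ]
  list(blo = blo, branch_id = bid, branches = br)
}

#' Per-branch records of an aligned tree
#'
#' Partitions an aligned tree into its lateral subtrees (one per lateral
#' child of a main-branch node, rooted at that MB node), orders each by
#' branch length order, and assembles per-branch records: length, blo,
#' order class (blo 1 within its lateral subtree = second-order branch
#' sprouting directly from the MB; blo >= 2 = higher-order), per-segment
#' orientation angles and their plain and length-weighted means.
#'
#' @param at an `aligned_dtree` from [find_main_branch()].
#' @return data.frame with one row per lateral branch: `branch_id`,
#'   `subtree_id`, `blo`, `order_class`, `attach`, `tip`, `length`,
#'   `mean_angle`, `lw_mean_angle`, `n_segments`, plus list columns
#'   `node_path`, `segment_angles`, `segment_lengths`. Zero-length segments
#'   propagate as missing angles and are excluded from the means.
#' @export
branch_table <- function(at) {
  t <- at$tree
  mb <- at$mb_node_path
  on_mb <- logical(n_nodes(t))
  on_mb[mb] <- TRUE
  ang <- segment_orientation_angles(at)
  seg <- segment_lengths(t)
  kids <- children_list(t)
  out <- list()
  sub_id <- 0L
  for (m in mb) {
    lat <- setdiff(kids[[m]], mb)
    for (c0 in lat) {
      sub_id <- sub_id + 1L
      dec <- blo_decompose(t, c0, attach = m)
      br <- dec$branches
      br$subtree_id <- sub_id
      out[[length(out) + 1L]] <- br
    }
  }
  if (length(out) == 0L) {
    return(data.frame(branch_id = integer(0), subtree_id = integer(0),
                      blo = integer(0), order_class = character(0),
                      attach = integer(0), tip = integer(0),
                      length = numeric(0), mean_angle = numeric(0),
                      lw_mean_angle = numeric(0), n_segments = integer(0)))
  }
  br <- do.call(rbind, out)
  br$branch_id <- seq_len(nrow(br))
  br$order_class <- ifelse(br$blo == 1L, "second_order", "higher_order")
  br$segment_angles <- lapply(br$node_path, function(p) ang[p[-1]])
  br$segment_lengths <- lapply(br$node_path, function(p) seg[p[-1]])
  br$n_segments <- vapply(br$segment_angles, length, integer(1))
  br$mean_angle <- vapply(br$segment_angles, function(a)
    if (all(is.na(a))) NA_real_ else mean(a, na.rm = TRUE), numeric(1))
  br$lw_mean_angle <- mapply(function(a, l) {
    ok <- !is.na(a) & l > 0
    if (!any(ok)) return(NA_real_)
    sum(a[ok] * l[ok]) / sum(l[ok])
  }, br$segment_angles, br$segment_lengths)
  rownames(br) <- NULL
  br[, c("branch_id", "subtree_id", "blo", "order_class", "attach", "tip",
         "length", "mean_angle", "lw_mean_angle", "n_segments",
         "node_path", "segment_angles", "segment_lengths")]
}
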