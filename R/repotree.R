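#' Grow the rooted distance tree
#'
#' Connects KEGG codes to the root disease code one by one, in
#' nondecreasing order of cumulative distance (shortest-path-tree
#' semantics, the default): each node's tree path realizes the minimum
#' sum of edge distances from the root over the whole edge set, so that
#' `exp(-cumulative)` is the largest attainable product of per-edge
#' coefficients.  `method = "edge"` instead attaches, at each step, the
#' unconnected node with the smallest single edge distance to any
#' already-connected node (nearest-neighbour attachment).  Ties are
#' broken by lexicographic code order; codes unreachable from the root
#' are absent from the tree.
#'
#' For the asymmetric conditional-probability coefficient, traversing an
#' edge away from the root uses the direction "new code given the
#' already-connected code".
#'
#' @param root The root KEGG code (e.g. the disease).
#' @param edges An `association_edges` data.frame.
#' @param method `"cumulative"` (shortest-path tree, default) or
#'   `"edge"` (nearest-neighbour attachment).
#' @return A `distance_tree`: data.frame with columns `code`, `parent`,
#'   `depth`, `cumulative_distance`; the root has depth 0, distance 0
#'   and `NA` parent.  The root code is kept in `attr(, "root")`.
#' @export
build_tree <- function(root, edges, method = c("cumulative", "edge")) {
  method <- match.arg(method)
  adj <- .edge_adjacency(edges)
  codes <- sort(unique(c(root, edges$code_x, edges$code_y)))
  if (!root %in% codes) stop(sprintf("root '%s' not in the code universe", root))
  res <- if (method == "cumulative") {
    .dijkstra(root, adj, codes)
  } else {
    .greedy_attach(root, adj, codes)
  }
  reach <- names(res$dist)[is.finite(res$dist)]
  reach <- reach[order(res$dist[reach], reach)]
  out <- data.frame(code = reach,
                    parent = unname(res$parent[reach]),
                    depth = unname(res$depth[reach]),
                    cumulative_distance = unname(res$dist[reach]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "root") <- root
  class(out) <- c("distance_tree", "data.frame")
  out
}

# adjacency list: for each code, data.frame(to, w) using the
# direction-appropriate distance
.edge_adjacency <- function(edges, drop_pair = NULL) {
  if (!is.null(drop_pair)) {
    drop <- (edges$code_x == drop_pair[1L] & edges$code_y == drop_pair[2L]) |
      (edges$code_x == drop_pair[2L] & edges$code_y == drop_pair[1L])
    edges <- edges[!drop, , drop = FALSE]
  }
  from <- c(edges$code_x, edges$code_y)
  to <- c(edges$code_y, edges$code_x)
  w <- c(edges$distance, edges$distance_yx)
  keep <- is.finite(w)
  split(data.frame(to = to[keep], w = w[keep], stringsAsFactors = FALSE),
        from[keep])
}

.dijkstra <- function(root, adj, codes) {
  dist <- stats::setNames(rep(Inf, length(codes)), codes)
  parent <- stats::setNames(rep(NA_character_, length(codes)), codes)
  depth <- stats::setNames(rep(NA_integer_, length(codes)), codes)
  dist[root] <- 0
  depth[root] <- 0L
  done <- stats::setNames(rep(FALSE, length(codes)), codes)
  tol <- 1e-12
  repeat {
    cand <- names(dist)[!done & is.finite(dist)]
    if (!length(cand)) break
    # next node: smallest cumulative distance, lexicographic tie-break
    u <- cand[order(dist[cand], cand)][1L]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      if (done[v]) next
      nd <- dist[u] + nb$w[i]
      if (nd < dist[v] - tol ||
          (abs(nd - dist[v]) <= tol &&
           (is.na(parent[v]) || u < parent[v]))) {
        dist[v] <- nd
        parent[v] <- u
        depth[v] <- depth[u] + 1L
      }
    }
  }
  list(dist = dist, parent = parent, depth = depth)
}

.greedy_attach <- function(root, adj, codes) {
  dist <- stats::setNames(rep(Inf, length(codes)), codes)
  parent <- stats::setNames(rep(NA_character_, length(codes)), codes)
  depth <- stats::setNames(rep(NA_integer_, length(codes)), codes)
  dist[root] <- 0
  depth[root] <- 0L
  attached <- root
  repeat {
    best <- NULL
    for (u in attached) {
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (i in seq_len(nrow(nb))) {
        v <- nb$to[i]
        if (v %in% attached) next
        cand <- list(w = nb$w[i], u = u, v = v)
        if (is.null(best) || cand$w < best$w - 1e-12 ||
            (abs(cand$w - best$w) <= 1e-12 &&
             (cand$u < best$u || (cand$u == best$u && cand$v < best$v)))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    dist[best$v] <- dist[best$u] + best$w
    parent[best$v] <- best$u
    depth[best$v] <- depth[best$u] + 1L
    attached <- c(attached, best$v)
  }
  list(dist = dist, parent = parent, depth = depth)
}

#' @export
print.distance_tree <- function(x, ...) {
  cat(sprintf("<distance_tree> root %s, %d nodes, max depth %d\n",
              attr(x, "root"), nrow(x),
              if (nrow(x)) max(x$depth) else 0L))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' Shortest indirect distance, direct edge excluded
#'
#' Cumulative distance from `root` to `code` over the edge set with the
#' direct root-code edge removed; `+Inf` when removing it disconnects
#' the code.  This is the indirect (predicted) distance that the method
#' compares with the direct (co-occurrence) distance.
#'
#' @param root,code KEGG codes, `code != root`.
#' @param edges An `association_edges` data.frame.
#' @return A single number (possibly `Inf`).
#' @export
indirect_distance_excluding_direct <- function(root, code, edges) {
  if (identical(root, code)) stop("`code` must differ from `root`")
  r <- .indirect_profile(root, code, edges)
  r$dist
}

# distance and depth of the direct-edge-excluded shortest path
.indirect_profile <- function(root, code, edges) {
  adj <- .edge_adjacency(edges, drop_pair = c(root, code))
  codes <- sort(unique(c(root, code, edges$code_x, edges$code_y)))
  res <- .dijkstra(root, adj, codes)
  list(dist = unname(res$dist[code]), depth = unname(res$depth[code]))
}

#' Rank drug codes as repositioning candidates
#'
#' Builds the candidate list: for each code of the requested kinds in
#' the tree, the indirect distance `D_id` (tree path with the direct
#' root edge excluded) with its depth, and the direct distance `D_d`
#' (the root-code edge, `NA` when the pair never co-occurs).  Rows are
#' sorted by the shorter of the two distances (absent `D_d` counts as
#' `+Inf`), with lexicographic code order breaking ties.
#'
#' @param tree A `distance_tree` from [build_tree()].
#' @param edges The `association_edges` the tree was built from.
#' @param dictionary A `term_dictionary`, used for the Name column and
#'   the code kinds.
#' @param kinds Code kinds to keep (default `"D"`, drugs).
#' @return A `candidate_table` data.frame with columns `code`,
#'   `indirect_distance`, `indirect_depth`, `direct_distance`,
#'   `rank_key`, `name`.
#' @export
rank_candidates <- function(tree, edges, dictionary, kinds = "D") {
  root <- attr(tree, "root")
  if (is.null(root)) stop("tree lacks a root attribute")
  if (!nrow(tree)) {
    return(.empty_candidates())
  }
  kind_of <- tapply(dictionary$kind, dictionary$code, `[`, 1L)
  name_of <- vapply(split(dictionary$term, dictionary$code),
                    function(t) paste(unique(t), collapse = ", "),
                    character(1L))

  # direct distances: root-incident edges, direction root -> code
  direct <- numeric(0)
  sel_x <- edges$code_x == root
  if (any(sel_x)) direct[edges$code_y[sel_x]] <- edges$distance[sel_x]
  sel_y <- edges$code_y == root
  if (any(sel_y)) direct[edges$code_x[sel_y]] <- edges$distance_yx[sel_y]

  nodes <- tree[tree$code != root, , drop = FALSE]
  keep <- !is.na(kind_of[nodes$code]) & kind_of[nodes$code] %in% kinds
  nodes <- nodes[keep, , drop = FALSE]
  if (!nrow(nodes)) return(.empty_candidates())

  d_id <- numeric(nrow(nodes))
  depth_id <- integer(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    if (identical(nodes$parent[i], root)) {
      # tree path is the direct edge: recompute without it
      pr <- .indirect_profile(root, nodes$code[i], edges)
      d_id[i] <- pr$dist
      depth_id[i] <- if (is.finite(pr$dist)) pr$depth else NA_integer_
    } else {
      d_id[i] <- nodes$cumulative_distance[i]
      depth_id[i] <- nodes$depth[i]
    }
  }
  d_d <- unname(direct[nodes$code])
  key <- pmin(d_id, ifelse(is.na(d_d), Inf, d_d))
  out <- data.frame(code = nodes$code,
                    indirect_distance = d_id,
                    indirect_depth = depth_id,
                    direct_distance = d_d,
                    rank_key = key,
                    name = unname(name_of[nodes$code]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_key, out$code), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "root") <- root
  class(out) <- c("candidate_table", "data.frame")
  out
}

.empty_candidates <- function() {
  out <- data.frame(code = character(0), indirect_distance = numeric(0),
                    indirect_depth = integer(0),
                    direct_distance = numeric(0), rank_key = numeric(0),
                    name = character(0), stringsAsFactors = FALSE)
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("<candidate_table> %d candidates\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' Node counts by tree depth
#'
#' @param tree A `distance_tree`.
#' @return Named integer vector: number of nodes at each depth; sums to
#'   the number of reachable nodes.
#' @export
depth_histogram <- function(tree) {
  tb <- table(tree$depth)
  stats::setNames(as.integer(tb), names(tb))
}

#' Serialize a distance tree
#'
#' `write_tree_tsv()` writes the node table (code, parent, depth,
#' cumulative_distance); `write_tree_newick()` writes the rooted tree in
#' Newick with branch lengths equal to edge distances.
#'
#' @param tree A `distance_tree`.
#' @param path Output path.
#' @return `path`, invisibly (readers return the reloaded object).
#' @export
write_tree_tsv <- function(tree, path) {
  df <- as.data.frame(tree)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tree_tsv
#' @export
read_tree_tsv <- function(path) {
  df <- utils::read.delim(path, quote = "", fileEncoding = "UTF-8",
                          colClasses = c(code = "character",
                                         parent = "character"))
  root <- df$code[is.na(df$parent) | df$parent == ""][1L]
  df$parent[df$parent == ""] <- NA_character_
  attr(df, "root") <- root
  class(df) <- c("distance_tree", "data.frame")
  df
}

#' @rdname write_tree_tsv
#' @export
write_tree_newick <- function(tree, path) {
  root <- attr(tree, "root")
  kids <- split(tree$code[!is.na(tree$parent)],
                tree$parent[!is.na(tree$parent)])
  blen <- stats::setNames(
    tree$cumulative_distance -
      ifelse(is.na(tree$parent), 0,
             tree$cumulative_distance[match(tree$parent, tree$code)]),
    tree$code)
  emit <- function(code) {
    ch <- kids[[code]]
    inner <- if (is.null(ch)) "" else
      paste0("(", paste(vapply(sort(ch), emit, character(1L)),
                        collapse = ","), ")")
    paste0(inner, code,
           if (identical(code, root)) "" else
             sprintf(":%.10g", blen[[code]]))
  }
  writeLines(paste0(emit(root), ";"), path)
  invisible(path)
}
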