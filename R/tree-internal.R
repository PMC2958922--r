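# Internal light-weight unrooted tree representation used by the parsimony
# searches.  A "utree" is a list(edges, ntip, next_id): `edges` is an
# undirected 2-column integer matrix; tip ids are indices into the character
# matrix's taxa (1..ntip, not all necessarily present during stepwise
# addition); internal node ids start at ntip + 1 and may be non-contiguous.

ut_new <- function(edges, ntip, next_id) {
  list(edges = edges, ntip = as.integer(ntip), next_id = as.integer(next_id))
}

ut_star3 <- function(t1, t2, t3, ntip) {
  centre <- ntip + 1L
  ut_new(cbind(c(t1, t2, t3), rep(centre, 3L)), ntip, ntip + 2L)
}

# attach `tip` on edge row `eidx`, subdividing it with a new internal node
ut_insert <- function(ut, tip, eidx) {
  x <- ut$next_id
  u <- ut$edges[eidx, 1]; v <- ut$edges[eidx, 2]
  edges <- rbind(ut$edges[-eidx, , drop = FALSE],
                 c(u, x), c(x, v), c(tip, x))
  ut_new(edges, ut$ntip, x + 1L)
}

ut_score <- function(ut, states) {
  score_uedge_cpp(ut$edges, ut$ntip, states)
}

# adjacency list keyed by node id (as character)
ut_adj <- function(edges) {
  nodes <- unique(as.vector(edges))
  adj <- vector("list", length(nodes))
  names(adj) <- as.character(nodes)
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    adj[[a]] <- c(adj[[a]], edges[i, 2])
    adj[[b]] <- c(adj[[b]], edges[i, 1])
  }
  adj
}

# nodes reachable from `start` using the given edge rows
ut_component <- function(edges, start) {
  seen <- start
  frontier <- start
  while (length(frontier) > 0) {
    hit <- edges[, 1] %in% frontier | edges[, 2] %in% frontier
    nxt <- setdiff(as.vector(edges[hit, , drop = FALSE]), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# canonical nontrivial splits of a utree, as strings of sorted tip ids for
# the side not containing the smallest present tip
ut_splits <- function(ut) {
  edges <- ut$edges
  tips <- sort(unique(as.vector(edges)[as.vector(edges) <= ut$ntip]))
  m <- length(tips)
  if (m < 4) return(character(0))
  ref <- tips[1]
  keys <- character(0)
  internal <- which(edges[, 1] > ut$ntip & edges[, 2] > ut$ntip)
  for (i in internal) {
    side <- ut_component(edges[-i, , drop = FALSE], edges[i, 1])
    side_tips <- sort(side[side <= ut$ntip])
    if (ref %in% side_tips) side_tips <- setdiff(tips, side_tips)
    if (length(side_tips) >= 2 && length(side_tips) <= m - 2)
      keys <- c(keys, paste(side_tips, collapse = ","))
  }
  sort(unique(keys))
}

ut_key <- function(ut) paste(ut_splits(ut), collapse = ";")

# All TBR rearrangements of a binary utree: bisect each edge, suppress the
# freed degree-2 endpoints, and reconnect every pair of attachment points
# (any edge of one fragment x any edge of the other; a fragment that is a
# single tip attaches directly).  The reconnection that recreates the input
# tree is skipped.
ut_tbr_neighbors <- function(ut) {
  edges <- ut$edges
  nE <- nrow(edges)
  out <- vector("list", 4 * nE * nE)  # generous; trimmed at the end
  n_out <- 0
  for (e in seq_len(nE)) {
    u <- edges[e, 1]; v <- edges[e, 2]
    rest <- edges[-e, , drop = FALSE]
    compA <- ut_component(rest, u)
    inA <- rest[, 1] %in% compA  # edges are within one component
    edgesA <- rest[inA, , drop = FALSE]
    edgesB <- rest[!inA, , drop = FALSE]
    side <- function(ed, w) {
      # suppress w (degree 2 after bisection) unless the fragment is tip w
      if (nrow(ed) == 0) return(list(edges = ed, origin = NA_integer_,
                                     is_tip = TRUE))
      touch <- which(ed[, 1] == w | ed[, 2] == w)
      nb <- setdiff(as.vector(ed[touch, , drop = FALSE]), w)
      ed <- rbind(ed[-touch, , drop = FALSE], nb)
      list(edges = ed, origin = nrow(ed), is_tip = FALSE)
    }
    A <- side(edgesA, u)
    B <- side(edgesB, v)
    ptsA <- if (A$is_tip) 0L else seq_len(nrow(A$edges))
    ptsB <- if (B$is_tip) 0L else seq_len(nrow(B$edges))
    for (pA in ptsA) for (pB in ptsB) {
      origA <- A$is_tip || identical(pA, A$origin)
      origB <- B$is_tip || identical(pB, B$origin)
      if (origA && origB) next  # rebuilds the input tree
      if (pA > 0) {
        ea <- A$edges[pA, ]
        newA <- rbind(A$edges[-pA, , drop = FALSE],
                      c(ea[1], u), c(u, ea[2]))
        xA <- u
      } else {
        newA <- A$edges
        xA <- u
      }
      if (pB > 0) {
        eb <- B$edges[pB, ]
        newB <- rbind(B$edges[-pB, , drop = FALSE],
                      c(eb[1], v), c(v, eb[2]))
        xB <- v
      } else {
        newB <- B$edges
        xB <- v
      }
      n_out <- n_out + 1
      out[[n_out]] <- ut_new(rbind(newA, newB, c(xA, xB)), ut$ntip,
                             ut$next_id)
    }
  }
  out[seq_len(n_out)]
}

# convert a utree to an ape phylo (unrooted, basal trichotomy at an
# internal node)
ut_to_phylo <- function(ut, labels) {
  edges <- ut$edges
  tips <- sort(unique(as.vector(edges)[as.vector(edges) <= ut$ntip]))
  adj <- ut_adj(edges)
  degs <- vapply(adj, length, 1L)
  internals <- as.integer(names(adj)[as.integer(names(adj)) > ut$ntip])
  if (length(internals) == 0) {  # 2 or 3 taxa corner handled by caller
    stop("tree too small to convert")
  }
  root <- internals[which.max(degs[as.character(internals)])]
  # DFS preorder orientation (parent precedes child: ape "cladewise")
  order <- integer(0)
  prnt <- integer(0)
  stack_v <- root
  stack_p <- NA_integer_
  while (length(stack_v) > 0) {
    v <- stack_v[1]; p <- stack_p[1]
    stack_v <- stack_v[-1]; stack_p <- stack_p[-1]
    order <- c(order, v)
    prnt <- c(prnt, p)
    kids <- setdiff(adj[[as.character(v)]], p)
    if (length(kids) > 0) {
      stack_v <- c(kids, stack_v)
      stack_p <- c(rep(v, length(kids)), stack_p)
    }
  }
  new_tip_id <- setNames(seq_along(tips), tips)
  int_nodes <- order[order > ut$ntip]
  new_int_id <- setNames(length(tips) + seq_along(int_nodes), int_nodes)
  remap <- function(v) {
    ifelse(v <= ut$ntip, new_tip_id[as.character(v)],
           new_int_id[as.character(v)])
  }
  keep <- !is.na(prnt)
  em <- cbind(unname(remap(prnt[keep])), unname(remap(order[keep])))
  storage.mode(em) <- "integer"
  structure(list(edge = em,
                 tip.label = labels[tips],
                 Nnode = length(int_nodes)),
            class = "phylo", order = "cladewise")
}

# convert an ape phylo (rooted or unrooted) to a utree over taxa indices
phylo_to_ut <- function(phy, taxa) {
  phy <- ape::unroot(ape::collapse.singles(phy))
  tipmap <- match(phy$tip.label, taxa)
  if (any(is.na(tipmap)))
    stop("tree contains leaves absent from the matrix: ",
         paste(phy$tip.label[is.na(tipmap)], collapse = ", "))
  ntip_phy <- length(phy$tip.label)
  ntip <- length(taxa)
  remap <- function(v) ifelse(v <= ntip_phy, tipmap[v],
                              ntip + (v - ntip_phy))
  edges <- cbind(remap(phy$edge[, 1]), remap(phy$edge[, 2]))
  ut_new(edges, ntip, max(edges) + 1L)
}
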