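#' Morphometry parameters for skeleton-graph extraction
#'
#' @param r closing radius (sites): disk used to close irregularities of
#'   the cell-network mask before skeletonization.
#' @param t thinning radius (sites). The mask is thinned to a one-site
#'   skeleton by iterated guaranteed-safe (topology-preserving) thinning
#'   passes; since full thinning subsumes any fixed number of safe passes,
#'   `t` is recorded for provenance but does not alter the skeleton.
#' @param p pruning distance (sites): terminal branches shorter than this
#'   are removed.
#' @param m node-merge radius (sites): nodes closer than this are merged.
#' @return an object of class `morph_params`.
#' @export
morph_params <- function(r = 4, t = 4, p = 10, m = 10) {
  stopifnot(r >= 0, t >= 0, p >= 0, m >= 0)
  structure(list(r = r, t = t, p = p, m = m), class = "morph_params")
}

#' Convert a cell-network mask into a skeleton graph
#'
#' Pipeline: morphological closing with a disk of radius `r`, thinning to
#' a one-site skeleton, pruning of terminal branches shorter than `p`, and
#' merging of nodes within `m` sites. Nodes are classified as end nodes
#' (degree 1) or branch nodes (degree >= 3).
#'
#' @param mask logical or 0/1 matrix: union of all cell sites.
#' @param params a [morph_params()].
#' @return an object of class `skeleton_graph`: list with `nodes` (data
#'   frame `id`, `row`, `col`, `kind`, `degree`), `edges` (data frame
#'   `from`, `to`, `length`), `paths` (list of site-path matrices per
#'   edge), `skeleton` (binary matrix) and `params`.
#' @export
network_to_graph <- function(mask, params = morph_params()) {
  mask <- (mask > 0) * 1L
  if (!any(mask == 1L))
    return(structure(list(nodes = data.frame(id = integer(), row = integer(),
                                             col = integer(),
                                             kind = character(),
                                             degree = integer()),
                          edges = data.frame(from = integer(),
                                             to = integer(),
                                             length = numeric()),
                          paths = list(), skeleton = mask, params = params),
                     class = "skeleton_graph"))
  closed <- mask
  if (params$r > 0) {
    brush <- EBImage::makeBrush(2 * params$r + 1, shape = "disc")
    closed <- (EBImage::imageData(EBImage::closing(mask, brush)) > 0) * 1L
  }
  skel <- .thin_cpp(closed)
  g <- skeleton_to_graph(skel)
  g <- prune_graph(g, params$p)
  g <- merge_nodes(g, params$m)
  structure(c(g, list(skeleton = skel, params = params)),
            class = "skeleton_graph")
}

# 8-neighborhood offsets
.moore <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# raw pixel graph of a 1-wide skeleton: nodes at degree != 2 pixels,
# edges traced along degree-2 chains
skeleton_to_graph <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  on <- which(skel == 1L)
  deg <- integer(length(on))
  pos <- cbind(row = (on - 1L) %% H + 1L, col = (on - 1L) %/% H + 1L)
  onmat <- matrix(FALSE, H, W); onmat[on] <- TRUE
  key <- function(r, c) (c - 1L) * H + r
  idx_of <- integer(H * W); idx_of[on] <- seq_along(on)
  nbrs <- function(i) {
    r <- pos[i, 1] + .moore[, 1]; c <- pos[i, 2] + .moore[, 2]
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    r <- r[ok]; c <- c[ok]
    k <- key(r, c)
    idx_of[k[onmat[k]]]
  }
  nblist <- lapply(seq_along(on), nbrs)
  deg <- lengths(nblist)
  node_px <- which(deg != 2L)
  is_node <- rep(FALSE, length(on)); is_node[node_px] <- TRUE
  nodes <- data.frame(id = seq_along(node_px), row = pos[node_px, 1],
                      col = pos[node_px, 2], degree = deg[node_px])
  node_id_of <- integer(length(on)); node_id_of[node_px] <- nodes$id
  edges_from <- integer(); edges_to <- integer(); lens <- numeric()
  paths <- list()
  visited_step <- new.env(hash = TRUE)
  step_key <- function(a, b) paste(min(a, b), max(a, b))
  for (np in node_px) {
    for (nb in nblist[[np]]) {
      sk <- step_key(np, nb)
      if (!is.null(visited_step[[sk]])) next
      # trace from np through nb along the chain
      path <- c(np, nb)
      visited_step[[sk]] <- TRUE
      prev <- np; cur <- nb
      while (!is_node[cur]) {
        nxt <- setdiff(nblist[[cur]], prev)
        if (length(nxt) == 0) break
        nxt <- nxt[1]
        visited_step[[step_key(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      if (is_node[cur]) {
        edges_from <- c(edges_from, node_id_of[np])
        edges_to <- c(edges_to, node_id_of[cur])
        lens <- c(lens, length(path) - 1)
        paths[[length(paths) + 1]] <- pos[path, , drop = FALSE]
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = edges_from, to = edges_to, length = lens),
       paths = paths)
}

classify_nodes <- function(g) {
  deg <- integer(nrow(g$nodes))
  if (nrow(g$edges))
    for (k in seq_len(nrow(g$edges))) {
      deg[g$edges$from[k]] <- deg[g$edges$from[k]] + 1L
      deg[g$edges$to[k]] <- deg[g$edges$to[k]] + 1L
    }
  g$nodes$degree <- deg
  g$nodes$kind <- ifelse(deg == 1L, "end",
                         ifelse(deg >= 3L, "branch", "internal"))
  g
}

# drop terminal edges shorter than p, dissolving nodes that fall to
# degree 2, until stable
prune_graph <- function(g, p) {
  g <- classify_nodes(g)
  repeat {
    if (!nrow(g$edges)) break
    endn <- g$nodes$id[g$nodes$degree == 1L]
    short <- which((g$edges$from %in% endn | g$edges$to %in% endn) &
                     g$edges$length < p &
                     # never remove an isolated segment entirely
                     !(g$edges$from %in% endn & g$edges$to %in% endn))
    if (!length(short)) break
    g$edges <- g$edges[-short, , drop = FALSE]
    g$paths <- g$paths[-short]
    g <- classify_nodes(g)
    g <- dissolve_degree2(g)
  }
  keep <- g$nodes$degree > 0L | nrow(g$edges) == 0L
  g
}

# splice out degree-2 nodes by concatenating their two incident edges
dissolve_degree2 <- function(g) {
  repeat {
    d2 <- g$nodes$id[g$nodes$degree == 2L]
    if (!length(d2)) break
    v <- d2[1]
    inc <- which(g$edges$from == v | g$edges$to == v)
    if (length(inc) != 2) { g$nodes$degree[v] <- -1L; next }
    e1 <- inc[1]; e2 <- inc[2]
    # orient both paths away from v
    p1 <- g$paths[[e1]]; p2 <- g$paths[[e2]]
    a1 <- if (g$edges$from[e1] == v) g$edges$to[e1] else g$edges$from[e1]
    a2 <- if (g$edges$from[e2] == v) g$edges$to[e2] else g$edges$from[e2]
    vpos <- c(g$nodes$row[v], g$nodes$col[v])
    orient <- function(path) {
      if (all(path[1, ] == vpos)) path else path[nrow(path):1, , drop = FALSE]
    }
    p1 <- orient(p1); p2 <- orient(p2)
    newpath <- rbind(p1[nrow(p1):1, , drop = FALSE], p2[-1, , drop = FALSE])
    g$edges$from[e1] <- a1; g$edges$to[e1] <- a2
    g$edges$length[e1] <- g$edges$length[e1] + g$edges$length[e2]
    g$paths[[e1]] <- newpath
    g$edges <- g$edges[-e2, , drop = FALSE]
    g$paths <- g$paths[-e2]
    g <- classify_nodes(g)
  }
  g
}

# merge nodes within m sites (single linkage); merged node at the mean
merge_nodes <- function(g, m) {
  n <- nrow(g$nodes)
  if (n == 0) return(classify_nodes(g))
  if (m > 0 && n > 1) {
    d <- as.matrix(stats::dist(g$nodes[, c("row", "col")]))
    adj <- d <= m
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
    if (max(comp) < n) {
      newrow <- tapply(g$nodes$row, comp, mean)
      newcol <- tapply(g$nodes$col, comp, mean)
      g$edges$from <- comp[g$edges$from]
      g$edges$to <- comp[g$edges$to]
      keep <- !(g$edges$from == g$edges$to)
      g$edges <- g$edges[keep, , drop = FALSE]
      g$paths <- g$paths[keep]
      g$nodes <- data.frame(id = seq_len(max(comp)),
                            row = as.numeric(newrow),
                            col = as.numeric(newcol))
    }
  }
  g <- classify_nodes(g)
  rownames(g$edges) <- NULL
  g
}

#' Sprouts of a skeleton graph
#'
#' A sprout is a graph edge connecting a branch node `B` to an end node
#' `E`. For a graph consisting of a single segment (two end nodes, no
#' branch node), both orientations... are not sprouts; such segments are
#' skipped unless `allow_segments` is set, in which case each end is
#' treated as a sprout tip with the opposite end as its base.
#'
#' @param graph a [network_to_graph()] result.
#' @param allow_segments treat isolated branchless segments as two
#'   sprouts (used at early times when the spheroid has no branch point).
#' @return data frame with `B_row`, `B_col`, `E_row`, `E_col` per sprout.
#' @export
graph_sprouts <- function(graph, allow_segments = FALSE) {
  nodes <- graph$nodes; edges <- graph$edges
  out <- data.frame(B_row = numeric(), B_col = numeric(),
                    E_row = numeric(), E_col = numeric())
  if (!nrow(edges)) return(out)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    ka <- nodes$kind[a]; kb <- nodes$kind[b]
    if (ka == "branch" && kb == "end") {
      out <- rbind(out, data.frame(B_row = nodes$row[a], B_col = nodes$col[a],
                                   E_row = nodes$row[b], E_col = nodes$col[b]))
    } else if (kb == "branch" && ka == "end") {
      out <- rbind(out, data.frame(B_row = nodes$row[b], B_col = nodes$col[b],
                                   E_row = nodes$row[a], E_col = nodes$col[a]))
    } else if (allow_segments && ka == "end" && kb == "end") {
      out <- rbind(out,
                   data.frame(B_row = c(nodes$row[a], nodes$row[b]),
                              B_col = c(nodes$col[a], nodes$col[b]),
                              E_row = c(nodes$row[b], nodes$row[a]),
                              E_col = c(nodes$col[b], nodes$col[a])))
    }
  }
  out
}

# integer (Bresenham) rasterization of the segment p0 -> p1
bresenham <- function(p0, p1) {
  r0 <- p0[1]; c0 <- p0[2]; r1 <- p1[1]; c1 <- p1[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  pts <- matrix(NA_integer_, dr + dc + 1L, 2)
  n <- 0L; r <- r0; c <- c0
  repeat {
    n <- n + 1L
    pts[n, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  pts[seq_len(n), , drop = FALSE]
}

# rasterized ray from p0 in direction dir, clipped to the lattice
raster_ray <- function(p0, dir, H, W) {
  if (all(dir == 0)) return(matrix(round(p0), 1, 2))
  scale <- ceiling((H + W) / max(abs(dir)))
  p1 <- round(p0 + dir * scale)
  pts <- bresenham(round(p0), p1)
  ok <- pts[, 1] >= 1 & pts[, 1] <= H & pts[, 2] >= 1 & pts[, 2] <= W
  last <- if (all(ok)) nrow(pts) else which(!ok)[1] - 1L
  pts[seq_len(max(last, 0L)), , drop = FALSE]
}

# most frequent nonzero label among the Moore neighbors of a site
dominant_neighbor_cell <- function(labels, site) {
  H <- nrow(labels); W <- ncol(labels)
  r <- site[1] + .moore[, 1]; c <- site[2] + .moore[, 2]
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  vals <- labels[cbind(r[ok], c[ok])]
  vals <- vals[vals > 0]
  if (!length(vals)) return(NA_integer_)
  tab <- sort(table(vals), decreasing = TRUE)
  as.integer(names(tab)[1])
}

# label pairs adjacent in the Moore neighborhood (for the cell-adjacency
# graph and the neighbors-of-G test)
adjacency_pairs_8 <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  pr <- list()
  for (sft in shifts) {
    dr <- sft[1]; dc <- sft[2]
    r1 <- seq_len(H - dr)
    c1 <- if (dc >= 0) seq_len(W - dc) else seq.int(1 - dc, W)
    a <- labels[r1, c1, drop = FALSE]
    b <- labels[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a != b & a > 0 & b > 0
    if (any(sel))
      pr[[length(pr) + 1]] <- cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel]))
  }
  if (!length(pr)) return(matrix(integer(), 0, 2))
  unique(do.call(rbind, pr))
}

#' Identify the leader cell of a sprout
#'
#' Implements the geometric leader-identification procedure: (1) the first
#' guess `G` is the cell containing the end node `E` (or, when `E` lies in
#' the ECM, the most frequent cell identifier among its neighboring
#' sites); (2) a ray `e` is traced from the branch node `B` through `E`
#' and the tip site `T` is the farthest cell site on the ray followed by
#' at least five consecutive ECM sites (or the ray's end); (3) cells with
#' a site on the perpendicular line `a` through `T` that are neighbors of
#' `G` become additional candidates; (4) candidates whose shortest
#' cell-adjacency path to the cell containing `B` is shorter than `G`'s
#' are dropped; (5) among the remaining candidates and `G`, the cell
#' owning the site with the largest Euclidean distance to `B` is the
#' leader (ties broken toward the smaller cell id).
#'
#' @param labels integer label matrix.
#' @param B,E `(row, col)` positions of the branch and end node.
#' @param adj optional precomputed Moore-adjacency label pairs (two-column
#'   matrix), to avoid recomputation when many sprouts of one frame are
#'   processed.
#' @return the leader's cell id, or `NA_integer_` when no cell site lies
#'   on the ray (leader undefined; the sprout is skipped).
#' @export
identify_leader <- function(labels, B, E, adj = NULL) {
  H <- nrow(labels); W <- ncol(labels)
  B <- as.numeric(B); E <- as.numeric(E)
  Ei <- pmin(pmax(round(E), 1), c(H, W))
  # step 1: first guess
  G <- labels[Ei[1], Ei[2]]
  if (G == 0L) G <- dominant_neighbor_cell(labels, Ei)
  if (is.na(G)) return(NA_integer_)
  # step 2: ray e from B through E, tip site T
  ray <- raster_ray(B, E - B, H, W)
  labs <- labels[ray]
  dim(labs) <- NULL
  cellpos <- which(labs > 0)
  if (!length(cellpos)) return(NA_integer_)
  Tidx <- NA_integer_
  for (i in rev(cellpos)) {
    after <- labs[seq.int(i + 1, length.out = min(5, length(labs) - i))]
    if (length(after) < 5) {
      if (all(after == 0)) { Tidx <- i; break }
    } else if (all(after == 0)) { Tidx <- i; break }
  }
  if (is.na(Tidx)) Tidx <- cellpos[length(cellpos)]
  Tsite <- ray[Tidx, ]
  # step 3: perpendicular line a through T; candidate neighbors of G
  dir <- E - B
  perp <- c(-dir[2], dir[1])
  aline <- rbind(raster_ray(Tsite, perp, H, W),
                 raster_ray(Tsite, -perp, H, W))
  on_a <- unique(labels[aline][labels[aline] > 0])
  if (is.null(adj)) adj <- adjacency_pairs_8(labels)
  neighbors_of <- function(id) {
    c(adj[adj[, 1] == id, 2], adj[adj[, 2] == id, 1])
  }
  cand <- intersect(on_a, neighbors_of(G))
  cand <- setdiff(cand, G)
  # step 4: Dijkstra filter on the cell-adjacency graph
  Bi <- pmin(pmax(round(B), 1), c(H, W))
  Bcell <- labels[Bi[1], Bi[2]]
  if (Bcell == 0L) Bcell <- dominant_neighbor_cell(labels, Bi)
  if (length(cand) && !is.na(Bcell)) {
    ncell <- max(labels)
    gr <- igraph::make_empty_graph(n = ncell, directed = FALSE)
    if (nrow(adj)) gr <- igraph::add_edges(gr, t(adj))
    dists <- igraph::distances(gr, v = Bcell)[1, ]
    cand <- cand[dists[cand] >= dists[G]]
  }
  # step 5: farthest site from B
  pool <- unique(c(G, cand))
  best_id <- NA_integer_; best_d <- -Inf
  for (id in sort(pool)) {
    s <- which(labels == id, arr.ind = TRUE)
    if (!nrow(s)) next
    d <- max((s[, 1] - B[1])^2 + (s[, 2] - B[2])^2)
    if (d > best_d + 1e-9) { best_d <- d; best_id <- id }
  }
  best_id
}

#' Sprout membership by breadth-first contact expansion
#'
#' Lists the leader cell and up to ten nearest neighbors: cells contacting
#' the leader, then the cells they contact, layer by layer, until ten
#' neighbors are listed. Within a layer, cells are ordered by their total
#' contact size with the previous layer (descending), ties by cell id.
#'
#' @param labels integer label matrix, or `NULL` if `contacts` given.
#' @param leader leader cell id.
#' @param contacts optional precomputed [compute_contact_map()].
#' @param max_members total member count cap (leader included).
#' @return ordered integer vector of member cell ids, leader first.
#' @export
sprout_members <- function(labels, leader, contacts = NULL,
                           max_members = 11L) {
  if (is.null(contacts)) contacts <- compute_contact_map(labels)
  pairs <- contacts$pairs
  members <- leader
  frontier <- leader
  while (length(members) < max_members) {
    touch <- pairs[(pairs$i %in% frontier & !(pairs$j %in% members)) |
                     (pairs$j %in% frontier & !(pairs$i %in% members)), ,
                   drop = FALSE]
    if (!nrow(touch)) break
    cand <- ifelse(touch$i %in% frontier & !(touch$j %in% members),
                   touch$j, touch$i)
    size <- tapply(touch$links, cand, sum)
    ids <- as.integer(names(size))
    ord <- order(-as.numeric(size), ids)
    layer <- ids[ord]
    layer <- setdiff(layer, members)
    take <- head(layer, max_members - length(members))
    members <- c(members, take)
    frontier <- take
    if (!length(take)) break
  }
  members
}
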