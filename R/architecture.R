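#' Physical tree architecture
#'
#' Wraps a rooted `ape::phylo` tree whose edge lengths are meters of
#' physical growth. The root is the base-of-stem sample (the cambium
#' reference, conventionally labelled `"0"`); the tips are the sampled
#' branch apices.
#'
#' @param phylo A rooted `ape::phylo` object with positive edge lengths.
#' @param age Tree age in years (optional; needed for per-year rates).
#' @param base_label Label used for the base sample at the root.
#' @return An object of class `physical_tree`.
#' @export
physical_tree <- function(phylo, age = NULL, base_label = "0") {
  if (!inherits(phylo, "phylo")) stop("`phylo` must be an ape phylo tree", call. = FALSE)
  if (is.null(phylo$edge.length)) stop("tree must have branch lengths (meters)", call. = FALSE)
  if (any(phylo$edge.length <= 0)) stop("branch lengths must be positive", call. = FALSE)
  roots <- unique(setdiff(phylo$edge[, 1], phylo$edge[, 2]))
  if (length(roots) != 1L) {
    stop("tree must have a single root (the base sample)", call. = FALSE)
  }
  if (!is.null(age) && age <= 0) stop("`age` must be positive", call. = FALSE)
  height <- max(node_depths(phylo)[seq_along(phylo$tip.label)])
  structure(list(phylo = phylo, age = age, base = base_label,
                 height = height),
            class = "physical_tree")
}

#' Generate a physical tree architecture
#'
#' Builds a rooted branching architecture with branch lengths in meters.
#' The default emulates the study design: a base sample at the root plus
#' seven branch-tip samples on a random bifurcating architecture whose
#' tips all sit `height` meters from the base (extension growth is shared
#' until branches split).
#'
#' @param n_tips Number of branch tips (>= 2); 7 by default.
#' @param topology `"random"` (ultrametric random bifurcation),
#'   `"star"` (all tips attached to the base) or `"caterpillar"`
#'   (ladder).
#' @param branch_lengths For `"star"`/`"caterpillar"`: edge lengths in
#'   meters, recycled over edges in construction order (default 1 m).
#'   Ignored for `"random"`, which uses `height`.
#' @param height Root-to-tip distance in meters for the random topology.
#' @param age Tree age in years, stored on the architecture.
#' @param seed Optional seed for the random topology.
#' @param tip_labels Tip sample labels; defaults to `"1"..."n"`.
#' @return A [physical_tree()].
#' @examples
#' tr <- generate_architecture(n_tips = 7, seed = 1, age = 100)
#' length(tr$phylo$tip.label)
#' @export
generate_architecture <- function(n_tips = 7L,
                                  topology = c("random", "star", "caterpillar"),
                                  branch_lengths = NULL,
                                  height = 40,
                                  age = NULL,
                                  seed = NULL,
                                  tip_labels = as.character(seq_len(n_tips))) {
  topology <- match.arg(topology)
  n_tips <- as.integer(n_tips)
  if (n_tips < 2L) stop("`n_tips` must be >= 2", call. = FALSE)
  if (!is.null(branch_lengths) && any(branch_lengths <= 0)) {
    stop("branch lengths must be positive", call. = FALSE)
  }
  if (height <= 0) stop("`height` must be positive", call. = FALSE)
  phy <- switch(topology,
    star = {
      len <- rep_len(if (is.null(branch_lengths)) 1 else branch_lengths, n_tips)
      edge <- cbind(rep(n_tips + 1L, n_tips), seq_len(n_tips))
      structure(list(edge = edge, edge.length = len,
                     tip.label = tip_labels, Nnode = 1L),
                class = "phylo", order = "cladewise")
    },
    caterpillar = {
      n_edge <- 2L * n_tips - 2L
      len <- rep_len(if (is.null(branch_lengths)) 1 else branch_lengths, n_edge)
      edge <- matrix(0L, n_edge, 2L)
      k <- 0L
      internal <- n_tips + 1L
      for (i in seq_len(n_tips - 1L)) {
        parent <- n_tips + i
        k <- k + 1L; edge[k, ] <- c(parent, i)
        child <- if (i < n_tips - 1L) n_tips + i + 1L else n_tips
        k <- k + 1L; edge[k, ] <- c(parent, child)
      }
      structure(list(edge = edge, edge.length = len,
                     tip.label = tip_labels, Nnode = n_tips - 1L),
                class = "phylo", order = "cladewise")
    },
    random = with_seed_if(seed, random_ultrametric(n_tips, height, tip_labels))
  )
  physical_tree(phy, age = age)
}

# random bifurcating architecture, all tips `height` from the root
random_ultrametric <- function(n_tips, height, tip_labels) {
  edge <- matrix(0L, 2L * n_tips - 2L, 2L)
  len <- numeric(2L * n_tips - 2L)
  k <- 0L
  next_node <- n_tips + 2L
  grow <- function(parent, depth_left, tipset) {
    cut <- if (length(tipset) == 2L) 1L else
      sample.int(length(tipset) - 1L, 1L)
    for (ts in list(tipset[seq_len(cut)], tipset[-seq_len(cut)])) {
      if (length(ts) == 1L) {
        k <<- k + 1L; edge[k, ] <<- c(parent, ts); len[k] <<- depth_left
      } else {
        s <- runif(1, 0.2, 0.8) * depth_left
        ch <- next_node; next_node <<- next_node + 1L
        k <<- k + 1L; edge[k, ] <<- c(parent, ch); len[k] <<- s
        grow(ch, depth_left - s, ts)
      }
    }
  }
  grow(n_tips + 1L, height, seq_len(n_tips))
  structure(list(edge = edge, edge.length = len,
                 tip.label = tip_labels, Nnode = n_tips - 1L),
            class = "phylo", order = "cladewise")
}

# distance of every node from the root
node_depths <- function(phy) {
  n_node <- max(phy$edge)
  depth <- numeric(n_node)
  # edges are stored parent-before-child in construction order; process
  # in an order that guarantees parents first
  remaining <- seq_len(nrow(phy$edge))
  done <- rep(FALSE, n_node)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  done[root] <- TRUE
  while (length(remaining)) {
    ready <- remaining[done[phy$edge[remaining, 1]]]
    if (!length(ready)) stop("tree is not connected", call. = FALSE)
    depth[phy$edge[ready, 2]] <- depth[phy$edge[ready, 1]] +
      phy$edge.length[ready]
    done[phy$edge[ready, 2]] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  depth
}

#' Pairwise physical distances between samples
#'
#' Path-length distances, in meters, between every pair of tip samples
#' (optionally including the base sample at the root).
#'
#' @param tree A [physical_tree()].
#' @param include_base Include the base sample as a row/column.
#' @return A symmetric labelled matrix of distances in meters.
#' @examples
#' tr <- generate_architecture(3, topology = "star", branch_lengths = 1)
#' pairwise_physical_distance(tr)
#' @export
pairwise_physical_distance <- function(tree, include_base = FALSE) {
  stopifnot(inherits(tree, "physical_tree"))
  phy <- tree$phylo
  n <- length(phy$tip.label)
  dn <- ape::dist.nodes(phy)
  root <- n + 1L
  idx <- seq_len(n)
  labels <- phy$tip.label
  if (include_base) {
    idx <- c(idx, root)
    labels <- c(labels, tree$base)
  }
  d <- dn[idx, idx, drop = FALSE]
  dimnames(d) <- list(labels, labels)
  d
}

#' @export
print.physical_tree <- function(x, ...) {
  cat(sprintf("Physical tree: %d tips + base '%s', height %.3g m%s\n",
              length(x$phylo$tip.label), x$base, x$height,
              if (is.null(x$age)) "" else sprintf(", age %.3g yr", x$age)))
  invisible(x)
}

# tip indices below the child node of each edge
edge_tip_sets <- function(phy) {
  n <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  below <- function(v) {
    if (v <= n) return(v)
    unlist(lapply(kids[[as.character(v)]], below), use.names = FALSE)
  }
  lapply(phy$edge[, 2], below)
}
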