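#' Pairwise somatic-SNV distances between samples
#'
#' Entry (i, j) is the number of mutation sites at which presence differs
#' between samples i and j — the size of the symmetric difference of
#' their mutation sets.
#'
#' @param matrix A [mutation_matrix()].
#' @param include_base Add the mutation-free base sample as an extra
#'   all-absent column before computing distances.
#' @param base_label Label for that base column.
#' @return A symmetric labelled matrix of SNV counts.
#' @export
pairwise_snv_distance <- function(matrix, include_base = FALSE,
                                  base_label = "0") {
  stopifnot(inherits(matrix, "mutation_matrix"))
  m <- matrix$mat * 1L
  if (include_base) {
    m <- cbind(m, 0L)
    colnames(m)[ncol(m)] <- base_label
  }
  d <- as.matrix(stats::dist(t(m), method = "manhattan"))
  storage.mode(d) <- "double"
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with
#' the standard limb-length and distance-update formulas. Ties in Q are
#' broken deterministically by the lexicographically smallest sorted
#' label pair. Negative limb lengths are clamped to zero with the deficit
#' transferred to the sister limb. Three remaining nodes are connected by
#' the closed-form three-point solution.
#'
#' @param D Symmetric distance matrix with row/column labels; >= 3 taxa.
#' @return An unrooted `ape::phylo` tree, with the emitted Newick string
#'   (labels quoted, branch lengths at 6 significant digits) in the
#'   `"newick"` attribute.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' tr <- neighbor_joining(d)
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  if (is.null(rownames(D))) stop("distance matrix must be labelled", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(D < 0)) stop("distances must be nonnegative", call. = FALSE)

  fmt <- function(x) sprintf("%.6g", x)    # display precision (emitted file)
  fmtp <- function(x) sprintf("%.17g", x)  # parse precision (phylo object)
  labels <- rownames(D)
  nodes <- sprintf("'%s'", labels)  # newick fragment per active node (quoted)
  nodes_p <- labels                 # unquoted twin, for parsing
  sort_key <- labels                # smallest original label in each node

  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(sort_key[ij[1]], sort_key[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    new_p <- sprintf("(%s:%s,%s:%s)", nodes_p[i], fmtp(li), nodes_p[j],
                     fmtp(lj))
    new_d <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
                c(new_d[keep], 0))
    nodes <- c(nodes[keep], new_node)
    nodes_p <- c(nodes_p[keep], new_p)
    sort_key <- c(sort_key[keep], min(sort_key[c(i, j)]))
    D <- D2
  }
  if (length(nodes) == 3L) {
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    lens <- fmt(pmax(c(a, b, c3), 0))
    lens_p <- fmtp(pmax(c(a, b, c3), 0))
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                      nodes[1], lens[1], nodes[2], lens[2],
                      nodes[3], lens[3])
    newick_p <- sprintf("(%s:%s,%s:%s,%s:%s);",
                        nodes_p[1], lens_p[1], nodes_p[2], lens_p[2],
                        nodes_p[3], lens_p[3])
  } else {
    newick <- sprintf("(%s:%s,%s:%s);", nodes[1], fmt(D[1, 2] / 2),
                      nodes[2], fmt(D[1, 2] / 2))
    newick_p <- sprintf("(%s:%s,%s:%s);", nodes_p[1], fmtp(D[1, 2] / 2),
                        nodes_p[2], fmtp(D[1, 2] / 2))
  }
  phy <- ape::read.tree(text = newick_p)
  attr(phy, "newick") <- newick
  phy
}

# non-trivial bipartitions of an unrooted topology, as canonical strings
bipartitions <- function(phy) {
  n <- length(phy$tip.label)
  labs <- phy$tip.label
  ref <- sort(labs)[1]
  sets <- edge_tip_sets(phy)
  internal <- phy$edge[, 2] > n
  out <- character(0)
  for (s in sets[internal]) {
    side <- labs[s]
    if (ref %in% side) side <- setdiff(labs, side)
    k <- length(side)
    if (k >= 2 && k <= n - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Robinson-Foulds congruence between two topologies
#'
#' The RF distance is the cardinality of the symmetric difference of the
#' two trees' non-trivial bipartition sets, normalized by its maximum
#' `2(n-3)`.
#'
#' @param t1,t2 `ape::phylo` trees or [physical_tree()] objects over the
#'   same tip label set.
#' @return List with `rf`, `max_rf`, `normalized` (in `[0, 1]`) and
#'   `congruent` (`rf == 0`).
#' @export
topology_congruence <- function(t1, t2) {
  p1 <- if (inherits(t1, "physical_tree")) t1$phylo else t1
  p2 <- if (inherits(t2, "physical_tree")) t2$phylo else t2
  if (!setequal(p1$tip.label, p2$tip.label)) {
    stop("trees must share the same tip labels", call. = FALSE)
  }
  b1 <- bipartitions(p1)
  b2 <- bipartitions(p2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(p1$tip.label)
  max_rf <- 2 * (n - 3)
  list(rf = rf, max_rf = max_rf,
       normalized = if (max_rf > 0) rf / max_rf else NA_real_,
       congruent = rf == 0)
}

#' Classify mutation sharing patterns across branch tips
#'
#' Each mutation site is categorized by the number of tip samples
#' carrying it (relative to the base-sample genotype): `Single` (one
#' tip), `Double` (two tips), `More` (three or more). The full
#' presence/absence pattern histogram is also returned.
#'
#' @param matrix A [mutation_matrix()] over the branch-tip samples.
#' @return List with `counts` (named Single/Double/More) and `histogram`
#'   (table over pattern strings, samples in column order).
#' @export
classify_patterns <- function(matrix) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  k <- rowSums(matrix$mat)
  if (any(k == 0)) {
    stop("all-zero pattern: not a somatic mutation relative to the base sample",
         call. = FALSE)
  }
  counts <- c(Single = sum(k == 1), Double = sum(k == 2), More = sum(k >= 3))
  pat <- apply(matrix$mat * 1L, 1L, paste, collapse = "")
  list(counts = counts, histogram = table(pat))
}

#' Write a tree to a Newick file
#'
#' @param phy An `ape::phylo` tree (the `"newick"` attribute from
#'   [neighbor_joining()] is reused when present).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(phy, path) {
  nwk <- attr(phy, "newick")
  if (is.null(nwk)) {
    ape::write.tree(phy, file = path)
  } else {
    writeLines(nwk, path)
  }
  invisible(path)
}
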