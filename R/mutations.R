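#' Mutation presence/absence matrix
#'
#' @param sites Data frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `genotype` (`"het"`/`"hom"`), one row per mutation event.
#' @param mat Logical matrix, sites x tip samples, `TRUE` where the
#'   sample carries the mutation.
#' @return An object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(sites, mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "logical"
  if (nrow(sites) != nrow(mat)) stop("sites and matrix row mismatch", call. = FALSE)
  if (is.null(colnames(mat))) stop("matrix must have sample column names", call. = FALSE)
  if (anyNA(mat)) stop("presence/absence matrix must be complete", call. = FALSE)
  structure(list(sites = sites, mat = mat, samples = colnames(mat)),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("Mutation matrix: %d sites x %d samples (%d homozygous)\n",
              nrow(x$mat), ncol(x$mat), sum(x$sites$genotype == "hom")))
  invisible(x)
}

#' Simulate somatic mutations along a physical tree
#'
#' Mutations arise on each branch as a Poisson process with mean
#' `2 * G * mu * length` (diploid genome of `G` callable sites, per-meter
#' rate `mu`, branch length in meters). Each mutation is placed at a
#' genome site drawn uniformly, except that cytosines/guanines in CpG
#' context receive `cpg_ct_multiplier`-fold weight with the excess being
#' C>T (G>A on the other strand) — the spontaneous-deamination signal.
#' Mutations are inherited by all descendant branches, but at every
#' branching each daughter independently loses the mutation with
#' probability `loss_prob` (stochastic loss of mutant cell lineages).
#' Colliding sites are resampled (infinite-sites approximation).
#'
#' @param genome An [generate_genome()] result.
#' @param tree A [physical_tree()].
#' @param config A [sim_config()]; exactly one of its rate
#'   parameterizations must be set.
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `matrix` (a [mutation_matrix()] over the tips;
#'   only mutations carried by at least one tip) and `truth` (list with
#'   `true_mutations` including originating branch and carrier tips,
#'   `mu_per_meter`, and the generating `tree`).
#' @export
simulate_somatic_mutations <- function(genome, tree, config, seed = NULL) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(tree, "physical_tree"),
            inherits(config, "sim_config"))
  mu <- effective_mu_per_meter(config)
  if (mu < 0) stop("mutation rate must be nonnegative", call. = FALSE)
  phy <- tree$phylo
  tips <- phy$tip.label
  n_tip <- length(tips)
  contig <- names(genome$seq)[1]
  seq1 <- genome$seq[[contig]]
  G <- nchar(seq1)

  with_seed_if(if (is.null(seed)) config$seed else seed, {
    # CpG-context positions: the C and the G of every CG dinucleotide
    cg <- gregexpr("CG", seq1, fixed = TRUE)[[1]]
    cpg_pos <- if (cg[1] == -1L) integer(0) else sort(c(cg, cg + 1L))
    m <- config$cpg_ct_multiplier
    n_cpg <- length(cpg_pos)
    w_cpg <- m * n_cpg
    w_tot <- w_cpg + (G - n_cpg)

    edge_len <- phy$edge.length
    counts <- rpois(length(edge_len), 2 * G * mu * edge_len)
    total <- sum(counts)

    sites <- integer(0)
    origin_edge <- integer(0)
    if (total > 0) {
      if (total > G) stop("more mutations than sites; lower the rate",
                          call. = FALSE)
      if (m == 1 || n_cpg == 0) {
        # uniform site weights: draw without replacement directly
        sites <- sample.int(G, total)
      } else {
        is_cpg <- logical(G)
        is_cpg[cpg_pos] <- TRUE
        taken <- logical(G)
        draw_site <- function() {
          repeat {
            p <- if (runif(1) < w_cpg / w_tot) {
              cpg_pos[sample.int(n_cpg, 1L)]
            } else {
              repeat {
                cand <- sample.int(G, 1L)
                if (!is_cpg[cand]) break
              }
              cand
            }
            if (!taken[p]) { taken[p] <<- TRUE; return(p) }
            warning("site collision resampled", call. = FALSE)
          }
        }
        sites <- vapply(seq_len(total), function(i) draw_site(), integer(1))
      }
      origin_edge <- rep(seq_along(edge_len), counts)
    }

    refs <- if (total) substring(seq1, sites, sites) else character(0)
    is_cpg_site <- sites %in% cpg_pos
    alts <- character(total)
    if (total) {
      for (i in seq_len(total)) {
        ref <- refs[i]
        others <- setdiff(BASES, ref)
        if (is_cpg_site[i] && m > 0) {
          # weight of the deamination alt within a CpG site's total m:
          # baseline 1 split evenly over 3 alts plus excess (m - 1)
          ct_alt <- if (ref == "C") "T" else "A"
          p_ct <- ((m - 1) + 1 / 3) / m
          alts[i] <- if (runif(1) < p_ct) ct_alt else
            sample(setdiff(others, ct_alt), 1L)
        } else {
          alts[i] <- sample(others, 1L)
        }
      }
    }

    # inheritance with stochastic loss at branch points
    tip_sets <- edge_tip_sets(phy)
    carriers <- matrix(FALSE, total, n_tip, dimnames = list(NULL, tips))
    if (total) {
      if (config$loss_prob == 0) {
        for (i in seq_len(total)) carriers[i, tip_sets[[origin_edge[i]]]] <- TRUE
      } else {
        kids_edges <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
        n <- n_tip
        percolate <- function(node) {
          # returns tip indices reached from `node` (inclusive if tip)
          if (node <= n) return(node)
          out <- integer(0)
          for (e in kids_edges[[as.character(node)]]) {
            if (runif(1) >= config$loss_prob) {
              out <- c(out, percolate(phy$edge[e, 2]))
            }
          }
          out
        }
        for (i in seq_len(total)) {
          carriers[i, percolate(phy$edge[origin_edge[i], 2])] <- TRUE
        }
      }
    }

    genotype <- if (total) {
      ifelse(runif(total) < config$hom_fraction, "hom", "het")
    } else character(0)

    truth_df <- data.frame(
      contig = rep(contig, total),
      pos = sites,
      ref = refs,
      alt = alts,
      genotype = genotype,
      origin_edge = origin_edge,
      carriers = if (total) apply(carriers, 1L, function(z)
        paste(tips[z], collapse = ",")) else character(0),
      stringsAsFactors = FALSE)

    keep <- if (total) rowSums(carriers) > 0 else logical(0)
    ord <- order(truth_df$pos[keep])
    mm <- mutation_matrix(
      truth_df[keep, c("contig", "pos", "ref", "alt", "genotype")][ord, ,
                                                                   drop = FALSE],
      carriers[keep, , drop = FALSE][ord, , drop = FALSE])
    rownames(mm$sites) <- NULL
    list(matrix = mm,
         truth = list(true_mutations = truth_df,
                      mu_per_meter = mu,
                      mu_per_year = config$mu_per_year,
                      tree = tree))
  })
}
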