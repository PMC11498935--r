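#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator:
#' genome composition, the somatic mutation rate (per meter of growth or
#' per year), the CpG C>T excess, stochastic loss of mutations at branch
#' points, replicate call noise, and sequencing depth.
#'
#' Exactly one of `mu_per_meter` / `mu_per_year` must be set. In per-year
#' mode the simulator converts to a per-meter rate through `growth_rate`
#' (meters of extension growth per year), so the same machinery exercises
#' both mutational clocks.
#'
#' @param seed Integer seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param genome_length Genome size in bp (single contig).
#' @param n_genes Number of protein-coding genes to place.
#' @param mean_cds_length Mean CDS length in bp; must be a multiple of 3.
#' @param gc_content GC fraction of the background sequence, in `[0, 1]`.
#' @param mu_per_meter Somatic mutation rate, substitutions per nucleotide
#'   per meter of growth. Mutually exclusive with `mu_per_year`.
#' @param mu_per_year Somatic mutation rate per nucleotide per year;
#'   requires `growth_rate`.
#' @param growth_rate Extension growth in meters per year; used only to
#'   convert `mu_per_year` into a per-meter rate.
#' @param cpg_ct_multiplier Fold-excess of C>T mutations at CpG sites
#'   relative to the baseline per-site rate (1 = no excess).
#' @param loss_prob Probability that a mutation present on a parent branch
#'   is absent from a given daughter branch (stochastic loss at branching).
#' @param hom_fraction Fraction of simulated mutations emitted as
#'   homozygous calls; the default reproduces the observed 46/1136.
#' @param fp_rate Per-site, per-replicate false-positive call probability.
#' @param fn_rate Per-true-site, per-replicate false-negative probability.
#' @param mean_depth Mean sequencing depth (reads) per site.
#' @param fail_annotation_frac Fraction of emitted call records whose
#'   quality annotations are drawn from the failing mixture, so that the
#'   hard filters have something to remove.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 50000, n_genes = 5,
#'                   mu_per_meter = 1e-5)
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_genes = 20L,
                       mean_cds_length = 900L,
                       gc_content = 0.37,
                       mu_per_meter = NULL,
                       mu_per_year = NULL,
                       growth_rate = NULL,
                       cpg_ct_multiplier = 1,
                       loss_prob = 0,
                       hom_fraction = 46 / 1136,
                       fp_rate = 0,
                       fn_rate = 0,
                       mean_depth = 30,
                       fail_annotation_frac = 0) {
  if (is.null(mu_per_meter) == is.null(mu_per_year)) {
    stop("exactly one of `mu_per_meter` and `mu_per_year` must be set",
         call. = FALSE)
  }
  if (!is.null(mu_per_year)) {
    if (is.null(growth_rate) || growth_rate <= 0) {
      stop("`mu_per_year` requires a positive `growth_rate` (m/yr)",
           call. = FALSE)
    }
  }
  mu <- if (is.null(mu_per_meter)) mu_per_year else mu_per_meter
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0) {
    stop("mutation rate must be a single nonnegative number", call. = FALSE)
  }
  if (mean_cds_length %% 3 != 0) {
    stop("`mean_cds_length` must be divisible by 3", call. = FALSE)
  }
  if (mean_cds_length < 9) stop("`mean_cds_length` must be >= 9", call. = FALSE)
  stopifnot_scalar_prob(gc_content, "gc_content")
  stopifnot_scalar_prob(loss_prob, "loss_prob")
  stopifnot_scalar_prob(hom_fraction, "hom_fraction")
  stopifnot_scalar_prob(fp_rate, "fp_rate")
  stopifnot_scalar_prob(fn_rate, "fn_rate")
  stopifnot_scalar_prob(fail_annotation_frac, "fail_annotation_frac")
  if (fp_rate >= 1 || fn_rate >= 1) {
    stop("`fp_rate` and `fn_rate` must be < 1", call. = FALSE)
  }
  if (cpg_ct_multiplier < 0) stop("`cpg_ct_multiplier` must be >= 0", call. = FALSE)
  if (genome_length < 3) stop("`genome_length` too small", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    mean_cds_length = as.integer(mean_cds_length),
    gc_content = gc_content,
    mu_per_meter = mu_per_meter,
    mu_per_year = mu_per_year,
    growth_rate = growth_rate,
    cpg_ct_multiplier = cpg_ct_multiplier,
    loss_prob = loss_prob,
    hom_fraction = hom_fraction,
    fp_rate = fp_rate,
    fn_rate = fn_rate,
    mean_depth = mean_depth,
    fail_annotation_frac = fail_annotation_frac,
    ploidy = 2L
  ), class = "sim_config")
}

# effective per-meter rate under either parameterization
effective_mu_per_meter <- function(config) {
  if (!is.null(config$mu_per_meter)) return(config$mu_per_meter)
  config$mu_per_year / config$growth_rate
}

#' @export
print.sim_config <- function(x, ...) {
  mode <- if (is.null(x$mu_per_meter)) {
    sprintf("%.3g / yr (growth %.3g m/yr)", x$mu_per_year, x$growth_rate)
  } else {
    sprintf("%.3g / m", x$mu_per_meter)
  }
  cat("Simulation configuration\n")
  cat(sprintf("  genome: %d bp, %d genes, GC %.2f\n",
              x$genome_length, x$n_genes, x$gc_content))
  cat(sprintf("  mutation rate: %s, CpG C>T x%.2g, loss %.2g\n",
              mode, x$cpg_ct_multiplier, x$loss_prob))
  cat(sprintf("  call noise: fp %.2g, fn %.2g, depth %.3g\n",
              x$fp_rate, x$fn_rate, x$mean_depth))
  invisible(x)
}
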