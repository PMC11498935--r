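#' Linear regression through the origin
#'
#' Zero-intercept least squares of SNV counts against physical distance:
#' `b = sum(x*y) / sum(x^2)`, with the classical t-based confidence
#' interval on `n - 1` degrees of freedom and
#' `SE = sqrt(RSS / (n - 1) / sum(x^2))`.
#'
#' @param x Distances (meters), not all zero.
#' @param y SNV counts, same length.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `slope`, `se`, `ci` (NA with `df = 0`, flagged via
#'   `ci_defined = FALSE`), `df`, `residuals`, `fitted`.
#' @examples
#' regress_through_origin(c(1, 2, 3), c(2, 4, 6))$slope
#' @export
regress_through_origin <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 1) stop("need at least one pair", call. = FALSE)
  if (all(x == 0)) stop("all distances are zero", call. = FALSE)
  sxx <- sum(x^2)
  b <- sum(x * y) / sxx
  n <- length(x)
  fitted <- b * x
  res <- y - fitted
  df <- n - 1L
  if (df > 0) {
    se <- sqrt(sum(res^2) / df / sxx)
    tq <- qt(1 - (1 - conf_level) / 2, df)
    ci <- c(b - tq * se, b + tq * se)
    defined <- TRUE
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
    defined <- FALSE
  }
  list(slope = b, se = se, ci = ci, df = df, ci_defined = defined,
       residuals = res, fitted = fitted, conf_level = conf_level)
}

#' Somatic mutation rate per nucleotide per meter
#'
#' `mu_g = b / (2R)`: the regression slope divided by twice the number of
#' callable sites (the factor two reflects diploidy).
#'
#' @param b Slope, SNVs per meter.
#' @param R Callable sites (bp), > 0.
#' @param ci Optional slope confidence interval, transformed identically.
#' @return List with `mu_g` and (when `ci` given) `mu_g_ci`.
#' @examples
#' rate_per_meter(2, 1)$mu_g
#' @export
rate_per_meter <- function(b, R, ci = NULL) {
  if (R <= 0) stop("callable sites `R` must be positive", call. = FALSE)
  out <- list(mu_g = b / (2 * R))
  if (!is.null(ci)) out$mu_g_ci <- ci / (2 * R)
  out
}

#' Somatic mutation rate per nucleotide per year
#'
#' Per branch tip, `mu_y = M / (2 R A)` where `M` is the number of SNVs
#' accumulated from the base to that tip, `R` the callable sites and `A`
#' the tree age in years; the tree-level summary is the mean across tips
#' with a t-based confidence interval.
#'
#' @param M Per-tip SNV counts (one per branch tip).
#' @param R Callable sites, > 0.
#' @param A Tree age in years, > 0.
#' @param conf_level Confidence level.
#' @return List with `mu_y` (per tip), `mean`, `ci`.
#' @export
rate_per_year <- function(M, R, A, conf_level = 0.95) {
  if (!length(M)) stop("`M` must contain at least one tip count", call. = FALSE)
  if (R <= 0) stop("callable sites `R` must be positive", call. = FALSE)
  if (A <= 0) stop("tree age `A` must be positive", call. = FALSE)
  mu <- M / (2 * R * A)
  n <- length(mu)
  m <- mean(mu)
  if (n > 1) {
    se <- stats::sd(mu) / sqrt(n)
    tq <- qt(1 - (1 - conf_level) / 2, n - 1)
    ci <- c(m - tq * se, m + tq * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(mu_y = mu, mean = m, ci = ci, conf_level = conf_level)
}

#' Per-species rate summary and fold-ratio
#'
#' Unweighted per-species means of per-tree rates, plus the ratio of the
#' first species mean over the second (slow over fast, in the standard
#' presentation).
#'
#' @param rates Named numeric vector of per-tree rates.
#' @param species Factor/character of the same length assigning each tree
#'   to a species; the ratio is `mean(first level) / mean(second level)`.
#' @return List with `means` (named by species) and `ratio`.
#' @examples
#' species_summary(c(S1 = 7.08e-9, S2 = 4.27e-9, F1 = 1.77e-9, F2 = 1.29e-9),
#'                 c("slow", "slow", "fast", "fast"))
#' @export
species_summary <- function(rates, species) {
  if (!length(rates)) stop("no rates supplied", call. = FALSE)
  species <- factor(species, levels = unique(species))
  if (any(tabulate(species) == 0)) stop("empty species", call. = FALSE)
  means <- tapply(rates, species, mean)
  means <- setNames(as.numeric(means), names(means))
  ratio <- if (nlevels(species) >= 2) unname(means[1] / means[2]) else NA_real_
  list(means = means, ratio = ratio)
}

#' Approximate tree age from diameter and growth increment
#'
#' `age = DBH / MAI`: diameter at breast height over mean annual
#' increment.
#'
#' @param dbh Diameter at breast height, cm.
#' @param mai Mean annual increment, cm/year, > 0.
#' @return Age in years.
#' @examples
#' estimate_age(10, 1)
#' @export
estimate_age <- function(dbh, mai) {
  if (any(mai <= 0)) stop("`mai` must be positive", call. = FALSE)
  dbh / mai
}

#' Fit somatic mutation rates on a physical tree
#'
#' The central estimator: regresses pairwise somatic-SNV counts against
#' pairwise physical distances over all unordered tip pairs, with a zero
#' intercept, and converts the slope into per-meter (and, given an age,
#' per-year) mutation rates on the diploid callable genome.
#'
#' Two confidence-interval methods are available for the slope. The
#' default, `"edge"`, uses the branching structure: the slope estimate is
#' a fixed weighted sum of the independent Poisson mutation counts on the
#' tree's edges, giving the plug-in variance
#' `Var(b) = sum_e w_e^2 * b * len_e`. The `"pairs"` method is the
#' classical t interval of [regress_through_origin()] applied to the 21
#' pairs; because pairs share edges it understates the slope variance and
#' is retained for comparability with the conventional presentation.
#'
#' @param x A [mutation_matrix()] over the tree's tips, or a pairwise
#'   SNV-count distance matrix labelled by tip.
#' @param tree The [physical_tree()] the samples were taken from.
#' @param callable_sites Number of callable sites `R` (bp).
#' @param age Tree age in years; enables the per-year rate (defaults to
#'   the age stored on the tree).
#' @param ci_method `"edge"` (default) or `"pairs"`.
#' @param conf_level Confidence level.
#' @return An object of class `somatic_rate_fit` with, among others,
#'   `slope` (SNVs/m), `slope_ci`, `mu_g` (+ CI), per-tip counts `M`,
#'   and `mu_y` (per tip, mean, CI) when an age is available.
#' @examples
#' cfg <- sim_config(seed = 3, genome_length = 20000, n_genes = 0,
#'                   mu_per_meter = 2e-5)
#' g <- generate_genome(cfg)
#' tr <- generate_architecture(7, seed = 3, age = 100)
#' sim <- simulate_somatic_mutations(g, tr, cfg)
#' fit <- fit_mutation_rates(sim$matrix, tr, callable_sites = 20000)
#' coef(fit)
#' @export
fit_mutation_rates <- function(x, tree, callable_sites, age = NULL,
                               ci_method = c("edge", "pairs"),
                               conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(tree, "physical_tree"))
  if (callable_sites <= 0) stop("`callable_sites` must be positive", call. = FALSE)
  if (is.null(age)) age <- tree$age
  tips <- tree$phylo$tip.label
  if (inherits(x, "mutation_matrix")) {
    if (!setequal(colnames(x$mat), tips)) {
      stop("mutation matrix samples must match the tree tips", call. = FALSE)
    }
    dsnv <- pairwise_snv_distance(x)[tips, tips]
    M <- colSums(x$mat)[tips]
  } else {
    dsnv <- as.matrix(x)[tips, tips]
    M <- NULL
  }
  dphys <- pairwise_physical_distance(tree)[tips, tips]
  n <- length(tips)
  ij <- which(upper.tri(dphys), arr.ind = TRUE)
  pairs <- data.frame(tip_i = tips[ij[, 1]], tip_j = tips[ij[, 2]],
                      distance_m = dphys[ij], snv_count = dsnv[ij],
                      stringsAsFactors = FALSE)
  reg <- regress_through_origin(pairs$distance_m, pairs$snv_count,
                                conf_level = conf_level)
  b <- reg$slope
  if (ci_method == "edge") {
    phy <- tree$phylo
    sets <- edge_tip_sets(phy)
    sxx <- sum(pairs$distance_m^2)
    w <- vapply(seq_along(sets), function(e) {
      inset <- tips %in% tips[sets[[e]]]
      onpath <- xor(inset[ij[, 1]], inset[ij[, 2]])
      sum(pairs$distance_m[onpath]) / sxx
    }, numeric(1))
    v <- sum(w^2 * max(b, 0) * phy$edge.length)
    zq <- qnorm(1 - (1 - conf_level) / 2)
    slope_se <- sqrt(v)
    slope_ci <- c(b - zq * slope_se, b + zq * slope_se)
  } else {
    slope_se <- reg$se
    slope_ci <- reg$ci
  }
  pm <- rate_per_meter(b, callable_sites, ci = slope_ci)
  out <- list(pairs = pairs, slope = b, slope_se = slope_se,
              slope_ci = slope_ci, ci_method = ci_method,
              pair_reg = reg,
              callable_sites = callable_sites,
              mu_g = pm$mu_g, mu_g_ci = pm$mu_g_ci,
              M = M, age = age, conf_level = conf_level, tree = tree)
  if (!is.null(M) && !is.null(age)) {
    ry <- rate_per_year(M, callable_sites, age, conf_level = conf_level)
    out$mu_y <- ry$mu_y
    out$mu_y_mean <- ry$mean
    out$mu_y_ci <- ry$ci
  }
  structure(out, class = "somatic_rate_fit")
}

#' @export
print.somatic_rate_fit <- function(x, ...) {
  cat("Somatic mutation rate fit (zero-intercept pairwise regression)\n")
  cat(sprintf("  pairs: %d, slope: %.4g SNVs/m (%.0f%% CI %.4g-%.4g, %s)\n",
              nrow(x$pairs), x$slope, 100 * x$conf_level,
              x$slope_ci[1], x$slope_ci[2], x$ci_method))
  cat(sprintf("  callable sites: %s; mu_g = %.3g /nt/m (CI %.3g-%.3g)\n",
              format(x$callable_sites, big.mark = ","), x$mu_g,
              x$mu_g_ci[1], x$mu_g_ci[2]))
  if (!is.null(x$mu_y_mean)) {
    cat(sprintf("  age %.4g yr; mu_y = %.3g /nt/yr (CI %.3g-%.3g)\n",
                x$age, x$mu_y_mean, x$mu_y_ci[1], x$mu_y_ci[2]))
  }
  invisible(x)
}

#' @export
summary.somatic_rate_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.somatic_rate_fit")
}

#' @export
print.summary.somatic_rate_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-tip accumulated SNV counts (M):\n")
  if (!is.null(f$M)) print(f$M) else cat("  (not available)\n")
  cat("\nPairs:\n")
  print(f$pairs)
  invisible(x)
}

#' @export
coef.somatic_rate_fit <- function(object, ...) {
  out <- c(slope = object$slope, mu_per_meter = object$mu_g)
  if (!is.null(object$mu_y_mean)) out <- c(out, mu_per_year = object$mu_y_mean)
  out
}

#' @export
confint.somatic_rate_fit <- function(object, parm, level, ...) {
  rows <- rbind(slope = object$slope_ci, mu_per_meter = object$mu_g_ci)
  if (!is.null(object$mu_y_ci)) rows <- rbind(rows, mu_per_year = object$mu_y_ci)
  colnames(rows) <- c("lower", "upper")
  rows
}

#' @export
fitted.somatic_rate_fit <- function(object, ...) {
  object$slope * object$pairs$distance_m
}

#' @export
residuals.somatic_rate_fit <- function(object, ...) {
  object$pairs$snv_count - fitted(object)
}

#' Predicted SNV counts at given physical distances
#'
#' @param object A `somatic_rate_fit`.
#' @param newdata Optional data frame with a `distance_m` column (or a
#'   numeric vector of distances); defaults to the fitted pairs.
#' @param ... Unused.
#' @return Expected SNV counts `slope * distance`.
#' @export
predict.somatic_rate_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  d <- if (is.data.frame(newdata)) newdata$distance_m else as.numeric(newdata)
  object$slope * d
}

#' @export
plot.somatic_rate_fit <- function(x, ...) {
  plot(x$pairs$distance_m, x$pairs$snv_count,
       xlab = "pairwise physical distance (m)",
       ylab = "somatic SNVs between tips",
       main = "SNV accumulation vs physical distance", ...)
  graphics::abline(a = 0, b = x$slope)
  invisible(x)
}
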