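#' Replication-dependent/independent mutagenesis model
#'
#' Decomposes the per-cell-division mutation rate into a
#' replication-dependent part `alpha` (mutations per site per division)
#' and a replication-independent part `beta * tau` accumulating over the
#' cell cycle of duration `tau` years: `mu = alpha + beta * tau`. The
#' per-year rate is then `r * mu = alpha / tau + beta` with `r = 1/tau`
#' divisions per year; when `beta >> alpha` the per-year rate is
#' clock-like (independent of how fast the organism grows).
#'
#' @param alpha Replication-dependent rate, per site per division (>= 0).
#' @param beta Replication-independent rate, per site per year (>= 0).
#' @param tau Cell-cycle duration in years (> 0).
#' @return An object of class `growth_model`.
#' @examples
#' m <- growth_model(alpha = 0, beta = 1e-9, tau = 0.1)
#' per_year_rate(m)
#' @export
growth_model <- function(alpha, beta, tau) {
  if (alpha < 0 || beta < 0) stop("`alpha` and `beta` must be >= 0", call. = FALSE)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, tau = tau, r = 1 / tau),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf(
    "Growth model: alpha = %.3g /div, beta = %.3g /yr, tau = %.3g yr (r = %.3g /yr)\n",
    x$alpha, x$beta, x$tau, x$r))
  cat(sprintf("  mu (per division) = %.3g, per year = %.3g\n",
              per_division_rate(x), per_year_rate(x)))
  invisible(x)
}

#' Mutation rate per cell division
#'
#' `mu = alpha + beta * tau`.
#'
#' @param params A [growth_model()].
#' @return Per-division rate.
#' @export
per_division_rate <- function(params) {
  stopifnot(inherits(params, "growth_model"))
  params$alpha + params$beta * params$tau
}

#' Mutation rate per year
#'
#' `r * mu = alpha / tau + beta`.
#'
#' @param params A [growth_model()].
#' @return Per-year rate.
#' @export
per_year_rate <- function(params) {
  stopifnot(inherits(params, "growth_model"))
  params$alpha / params$tau + params$beta
}

#' Mutations accumulated by age t
#'
#' `m(t) = (alpha / tau + beta) * t`: linear in absolute time, regardless
#' of growth, whenever the model holds.
#'
#' @param params A [growth_model()].
#' @param t Age in years (>= 0).
#' @return Expected accumulated mutations per site.
#' @export
accumulated_mutations <- function(params, t) {
  stopifnot(inherits(params, "growth_model"))
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  per_year_rate(params) * t
}

#' Predicted slow/fast per-division rate ratio
#'
#' `mu_S / mu_F = (alpha + beta * tau_S) / (alpha + beta * tau_F)` for a
#' slow- and a fast-growing species sharing `alpha` and `beta` but
#' differing in cell-cycle duration. The ratio rises monotonically from 1
#' (pure replication, `beta = 0`) to `tau_S / tau_F` (`beta >> alpha`).
#'
#' @param alpha,beta Shared model components (>= 0, not both 0).
#' @param tau_s,tau_f Cell-cycle durations, years (> 0).
#' @return The ratio.
#' @examples
#' predicted_rate_ratio(0, 1e-9, tau_s = 3.2, tau_f = 1)
#' @export
predicted_rate_ratio <- function(alpha, beta, tau_s, tau_f) {
  if (tau_s <= 0 || tau_f <= 0) stop("`tau` values must be positive", call. = FALSE)
  denom <- alpha + beta * tau_f
  if (denom == 0) stop("alpha and beta cannot both be zero", call. = FALSE)
  (alpha + beta * tau_s) / denom
}

#' Consistency of an observed rate ratio with the model
#'
#' Solves `(1 + x * tau_ratio) / (1 + x) = observed_ratio` for
#' `x = beta * tau_F / alpha`, the replication-independent share. Three
#' regimes: an interior observed ratio in `(1, tau_ratio)` has an exact
#' finite solution; a ratio at or above `tau_ratio` has no finite
#' nonnegative solution and is consistent with the
#' replication-independent-dominated limit (`beta >> alpha`, where the
#' model's supremum is `tau_ratio` itself); a ratio at or below 1 is
#' consistent with replication-dominated or equal rates.
#'
#' @param observed_ratio Observed slow/fast per-meter rate ratio (> 0).
#' @param tau_ratio Cell-cycle duration ratio `tau_S / tau_F` (> 1);
#'   proportional to the inverse growth-rate (MAI) ratio.
#' @return List with `regime` (`"interior"`, `"beta_dominated"`,
#'   `"alpha_dominated"`), `x` (finite solution or `Inf`/0), `gap`
#'   (observed minus supremum, when above), and a `message`.
#' @examples
#' assess_consistency(3.7, 3.2)$regime
#' assess_consistency(2.0, 3.2)$x
#' @export
assess_consistency <- function(observed_ratio, tau_ratio) {
  if (observed_ratio <= 0) stop("`observed_ratio` must be positive", call. = FALSE)
  if (tau_ratio <= 1) stop("`tau_ratio` must exceed 1", call. = FALSE)
  if (observed_ratio >= tau_ratio) {
    return(list(
      regime = "beta_dominated", x = Inf,
      gap = observed_ratio - tau_ratio,
      message = sprintf(paste0(
        "observed ratio %.3g meets or exceeds the model supremum %.3g; ",
        "no finite nonnegative solution, consistent with beta >> alpha ",
        "(limit ratio = tau ratio), gap %.3g"),
        observed_ratio, tau_ratio, observed_ratio - tau_ratio)))
  }
  if (observed_ratio <= 1) {
    x <- if (observed_ratio == 1) 0 else (observed_ratio - 1) /
      (tau_ratio - observed_ratio)
    return(list(
      regime = "alpha_dominated", x = max(x, 0), gap = NULL,
      message = sprintf(
        "observed ratio %.3g <= 1: consistent with alpha-dominated or equal rates",
        observed_ratio)))
  }
  x <- (observed_ratio - 1) / (tau_ratio - observed_ratio)
  list(regime = "interior", x = x, gap = NULL,
       message = sprintf(
         "beta*tauF/alpha = %.6g reproduces the observed ratio %.3g exactly",
         x, observed_ratio))
}
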