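#' @importFrom stats rpois rbinom runif rnorm qt qnorm dbinom binom.test
#'   setNames complete.cases sd dist fitted coef confint predict residuals
#' @importFrom utils head write.table read.table
#' @importFrom graphics abline plot
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reverse complement of short character sequences (CDS-scale);
# genome-scale work goes through Biostrings
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# run expr under a temporary RNG state when seed is non-NULL
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

site_key <- function(df) {
  paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
}

genotype_key <- function(df) {
  paste(df$contig, df$pos, df$ref, df$alt, df$genotype, sep = ":")
}
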