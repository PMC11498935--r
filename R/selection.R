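#' Intergenic regions of an annotated genome
#'
#' The intergenic space is the complement of the union of all gene
#' territories, where each gene's territory extends from 1 kbp upstream
#' of its start codon to 500 bp downstream of its stop codon
#' (strand-aware: upstream is 5' of the start codon), clipped to the
#' contig bounds.
#'
#' @param genome An `annotated_genome`.
#' @return Data frame of intervals (`contig`, `start`, `end`, 1-based
#'   inclusive).
#' @examples
#' g <- structure(list(
#'   seq = c(c1 = strrep("A", 10000)),
#'   genes = data.frame(gene_id = "g1", contig = "c1", start = 2001,
#'                      end = 3000, strand = "+")),
#'   class = "annotated_genome")
#' define_intergenic(g)
#' @export
define_intergenic <- function(genome) {
  out <- lapply(names(genome$seq), function(ctg) {
    L <- nchar(genome$seq[[ctg]])
    g <- genome$genes[genome$genes$contig == ctg, , drop = FALSE]
    if (is.null(g) || !nrow(g)) {
      return(data.frame(contig = ctg, start = 1L, end = L,
                        stringsAsFactors = FALSE))
    }
    up <- ifelse(g$strand == "+", g$start - 1000L, g$start - 500L)
    dn <- ifelse(g$strand == "+", g$end + 500L, g$end + 1000L)
    ir <- IRanges::reduce(IRanges::IRanges(start = pmax(up, 1L),
                                           end = pmin(dn, L)))
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
    if (!length(gaps)) return(NULL)
    data.frame(contig = ctg, start = IRanges::start(gaps),
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Background substitution rates from a genomic region set
#'
#' Per pyrimidine-collapsed substitution class, the observed rate is the
#' number of SNVs of that class falling in the regions divided by the
#' number of region bases at which the class is available (C:G bases for
#' the `C>*` classes, A:T bases for `T>*`).
#'
#' @param snvs Data frame with `contig`, `pos`, `ref`, `alt`.
#' @param regions Data frame of intervals (`contig`, `start`, `end`), or
#'   `NULL` for the whole genome.
#' @param genome An `annotated_genome`.
#' @return An object of class `background_rates`: list with `rate` (six
#'   named rates), `snv_counts`, `eligible_bases`, `source`.
#' @export
background_rates <- function(snvs, regions, genome) {
  whole <- is.null(regions)
  if (!whole && !nrow(regions)) stop("empty region set", call. = FALSE)
  n_cg <- 0
  n_at <- 0
  count_bases <- function(s) {
    tab <- table(factor(strsplit(s, "")[[1]], levels = BASES))
    c(cg = sum(tab[c("C", "G")]), at = sum(tab[c("A", "T")]))
  }
  if (whole) {
    for (s in genome$seq) {
      b <- count_bases(s)
      n_cg <- n_cg + b["cg"]; n_at <- n_at + b["at"]
    }
  } else {
    for (i in seq_len(nrow(regions))) {
      s <- substr(genome$seq[[regions$contig[i]]], regions$start[i],
                  regions$end[i])
      b <- count_bases(s)
      n_cg <- n_cg + b["cg"]; n_at <- n_at + b["at"]
    }
  }
  inside <- if (whole) rep(TRUE, nrow(snvs)) else {
    vapply(seq_len(nrow(snvs)), function(i) {
      r <- regions[regions$contig == snvs$contig[i], , drop = FALSE]
      any(r$start <= snvs$pos[i] & r$end >= snvs$pos[i])
    }, logical(1))
  }
  cls <- collapse_class(snvs$ref, snvs$alt)[inside]
  counts <- table(factor(cls, levels = PYR_SUBS))
  eligible <- setNames(ifelse(startsWith(PYR_SUBS, "C"), n_cg, n_at),
                       PYR_SUBS)
  if (any(counts > 0 & eligible == 0)) {
    stop("observed SNVs in a class with no eligible bases", call. = FALSE)
  }
  rate <- ifelse(eligible > 0, as.numeric(counts) / eligible, 0)
  structure(list(rate = setNames(rate, PYR_SUBS),
                 snv_counts = setNames(as.integer(counts), PYR_SUBS),
                 eligible_bases = eligible,
                 source = if (whole) "whole_genome" else "intergenic"),
            class = "background_rates")
}

# pyrimidine-collapsed six-class label of ref>alt
collapse_class <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, COMPLEMENT[ref], ref)
  a <- ifelse(pur, COMPLEMENT[alt], alt)
  paste0(r, ">", a)
}

#' Enumerate coding mutation opportunities
#'
#' For every CDS position (excluding the terminal stop codon) and each of
#' the three alternative bases, the mutated codon is classified by the
#' standard nuclear codon table as synonymous (same amino acid), nonsense
#' (stop gained) or missense, and binned by the pyrimidine-collapsed
#' substitution class. The total count equals `3 * L_cds` exactly, where
#' `L_cds` is the summed coding length without the terminal stops.
#'
#' @param genome An `annotated_genome` with CDS annotation, or a
#'   character vector of CDS sequences (coding strand, complete ORFs).
#' @return An object of class `opportunity_table`: list with `counts`
#'   (6 classes x 3 types), `L_cds`, and `n_excluded` (CDS dropped for
#'   internal stops or length).
#' @examples
#' enumerate_opportunities(c(g1 = "ATGTGGTAA"))$counts
#' @export
enumerate_opportunities <- function(genome) {
  cds <- if (inherits(genome, "annotated_genome")) cds_sequences(genome)
         else genome
  gc <- Biostrings::GENETIC_CODE
  counts <- matrix(0L, 6L, 3L,
                   dimnames = list(PYR_SUBS,
                                   c("synonymous", "missense", "nonsense")))
  L_cds <- 0L
  n_excl <- 0L
  for (s in cds) {
    n <- nchar(s)
    if (n %% 3 != 0 || n < 6) { n_excl <- n_excl + 1L; next }
    codons <- substring(s, seq(1, n - 2, by = 3), seq(3, n, by = 3))
    aa <- gc[codons]
    if (aa[length(aa)] != "*" || any(aa[-length(aa)] == "*") ||
        anyNA(aa)) {
      n_excl <- n_excl + 1L
      next
    }
    body <- codons[-length(codons)]  # terminal stop excluded
    L_cds <- L_cds + 3L * length(body)
    for (k in seq_along(body)) {
      cod <- body[k]
      for (w in 1:3) {
        ref <- substr(cod, w, w)
        for (alt in setdiff(BASES, ref)) {
          mutated <- cod
          substr(mutated, w, w) <- alt
          type <- switch(classify_codon_change(cod, mutated),
                         synonymous = "synonymous",
                         nonsense = "nonsense",
                         "missense")
          cls <- collapse_class(ref, alt)
          counts[cls, type] <- counts[cls, type] + 1L
        }
      }
    }
  }
  structure(list(counts = counts, L_cds = L_cds, n_excluded = n_excl),
            class = "opportunity_table")
}

#' @export
print.opportunity_table <- function(x, ...) {
  cat(sprintf("Mutation opportunity table (L_cds = %d bp, total = %d)\n",
              x$L_cds, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Expected mutation counts under neutrality
#'
#' `lambda_S = sum_class rate * synonymous opportunities` and
#' `lambda_N = sum_class rate * (missense + nonsense opportunities)`;
#' the expected non-synonymous fraction is
#' `pN = lambda_N / (lambda_S + lambda_N)`.
#'
#' @param table An [enumerate_opportunities()] result.
#' @param rates A [background_rates()] result (or named six-vector).
#' @return List with `lambda_s`, `lambda_n`, `p_nonsyn`.
#' @export
expected_rates <- function(table, rates) {
  stopifnot(inherits(table, "opportunity_table"))
  r <- if (inherits(rates, "background_rates")) rates$rate else rates
  if (!identical(names(r), PYR_SUBS)) {
    r <- r[PYR_SUBS]
    if (anyNA(r)) stop("rates must be named by the six substitution classes",
                       call. = FALSE)
  }
  lam_s <- sum(r * table$counts[, "synonymous"])
  lam_n <- sum(r * (table$counts[, "missense"] + table$counts[, "nonsense"]))
  if (lam_s + lam_n == 0) stop("expected counts are all zero", call. = FALSE)
  list(lambda_s = lam_s, lambda_n = lam_n,
       p_nonsyn = lam_n / (lam_s + lam_n))
}

#' Exact binomial test of neutrality for coding mutations
#'
#' Two-sided exact binomial test of the observed number of
#' non-synonymous mutations against the neutral expectation `p_nonsyn`
#' (probabilities no larger than that of the observed outcome are
#' summed, the convention of the standard exact test).
#'
#' @param observed_nonsyn Observed non-synonymous mutations.
#' @param observed_total Observed classifiable coding mutations, > 0.
#' @param p_nonsyn Neutral expectation in (0, 1).
#' @param sig_level Rejection level (default 0.05).
#' @return An object of class `selection_test`: list with `p_value`,
#'   `reject`, `observed_fraction`, `expected_fraction`, and the inputs.
#' @examples
#' binomial_selection_test(1, 2, 0.5)$p_value
#' @export
binomial_selection_test <- function(observed_nonsyn, observed_total,
                                    p_nonsyn, sig_level = 0.05) {
  if (observed_total <= 0) stop("`observed_total` must be positive", call. = FALSE)
  if (observed_nonsyn < 0 || observed_nonsyn > observed_total) {
    stop("`observed_nonsyn` must be in [0, observed_total]", call. = FALSE)
  }
  if (p_nonsyn <= 0 || p_nonsyn >= 1) {
    stop("`p_nonsyn` must be strictly inside (0, 1)", call. = FALSE)
  }
  ht <- binom.test(observed_nonsyn, observed_total, p = p_nonsyn)
  structure(list(p_value = ht$p.value,
                 reject = ht$p.value < sig_level,
                 observed_nonsyn = observed_nonsyn,
                 observed_total = observed_total,
                 observed_fraction = observed_nonsyn / observed_total,
                 expected_fraction = p_nonsyn,
                 sig_level = sig_level),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat("Exact binomial test of neutral coding mutation\n")
  cat(sprintf("  observed non-synonymous: %d / %d (%.3f); expected %.3f\n",
              x$observed_nonsyn, x$observed_total, x$observed_fraction,
              x$expected_fraction))
  cat(sprintf("  p = %.4g -> %s the neutral null at %.0f%%\n", x$p_value,
              if (x$reject) "reject" else "do not reject",
              100 * x$sig_level))
  invisible(x)
}

#' Full selection test on a set of SNVs
#'
#' Convenience wrapper: derives intergenic (or whole-genome) background
#' rates from the SNVs, enumerates coding opportunities, classifies the
#' coding SNVs, and runs the exact binomial test.
#'
#' @param snvs Data frame with `contig`, `pos`, `ref`, `alt`.
#' @param genome An `annotated_genome` with CDS annotation.
#' @param background `"intergenic"` or `"whole_genome"`.
#' @param sig_level Rejection level.
#' @return A `selection_test` with the `opportunity_table`,
#'   `background_rates` and expectation attached.
#' @export
selection_test <- function(snvs, genome,
                           background = c("intergenic", "whole_genome"),
                           sig_level = 0.05) {
  background <- match.arg(background)
  regions <- if (background == "intergenic") define_intergenic(genome) else NULL
  rates <- background_rates(snvs, regions, genome)
  opp <- enumerate_opportunities(genome)
  exp_r <- expected_rates(opp, rates)
  cons <- vapply(seq_len(nrow(snvs)), function(i)
    consequence_at(genome, snvs$contig[i], snvs$pos[i], snvs$alt[i]),
    character(1))
  coding <- cons %in% c("synonymous", "missense", "nonsense")
  k <- sum(cons %in% c("missense", "nonsense"))
  n <- sum(coding)
  if (n == 0) stop("no coding SNVs to test", call. = FALSE)
  res <- binomial_selection_test(k, n, exp_r$p_nonsyn, sig_level = sig_level)
  res$opportunity <- opp
  res$background <- rates
  res$expectation <- exp_r
  res
}
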