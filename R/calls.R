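HARD_FILTER_ANNOTATIONS <- c("QD", "QUAL", "SOR", "FS", "MQ",
                             "MQRankSum", "ReadPosRankSum")

# draw hard-filter annotations; `fail` rows get one annotation pushed
# past its removal threshold
draw_annotations <- function(n, fail = rep(FALSE, n)) {
  ann <- data.frame(
    QD = runif(n, 5, 35),
    QUAL = runif(n, 60, 2000),
    SOR = runif(n, 0.2, 3.0),
    FS = runif(n, 0, 20),
    MQ = runif(n, 41, 60),
    MQRankSum = rnorm(n, 0, 2),
    ReadPosRankSum = rnorm(n, 0, 2))
  bad <- which(fail)
  if (length(bad)) {
    which_ann <- sample(HARD_FILTER_ANNOTATIONS, length(bad), replace = TRUE)
    for (i in seq_along(bad)) {
      r <- bad[i]
      ann[r, which_ann[i]] <- switch(which_ann[i],
        QD = runif(1, 0, 1.9), QUAL = runif(1, 0, 29),
        SOR = runif(1, 4.1, 8), FS = runif(1, 61, 120),
        MQ = runif(1, 10, 39), MQRankSum = runif(1, -20, -12.6),
        ReadPosRankSum = runif(1, -15, -8.1))
    }
  }
  ann
}

#' Simulate per-sample, per-replicate variant call tables
#'
#' Emulates the output of a dual-caller, triple-threshold calling run on
#' two biological replicates per sample, at the call-table level (reads
#' themselves are never simulated; caller behaviour is represented by
#' per-site error rates and annotation mixtures). True mutations are
#' dropped per replicate with probability `fn_rate`; spurious calls are
#' injected per site and replicate with probability `fp_rate`; depth and
#' the seven GATK-style hard-filter annotations are drawn from
#' configurable pass/fail mixtures.
#'
#' @param sim Result of [simulate_somatic_mutations()] (or a
#'   [mutation_matrix()]).
#' @param genome The generating genome (for spurious-call alleles).
#' @param config A [sim_config()].
#' @param base_label Label of the mutation-free base sample included in
#'   the per-site support table.
#' @param seed Optional seed overriding `config$seed + 1`.
#' @return A list with
#'   `calls`: one row per call record (sample, replicate, caller,
#'     threshold set, site, genotype, depth, annotations, `is_true`), and
#'   `support`: per candidate site x sample read support (high-quality
#'     reads and alt-supporting reads in each replicate), covering all
#'     samples including the base.
#' @export
simulate_call_tables <- function(sim, genome, config, base_label = "0",
                                 seed = NULL) {
  mm <- if (inherits(sim, "mutation_matrix")) sim else sim$matrix
  stopifnot(inherits(mm, "mutation_matrix"),
            inherits(genome, "annotated_genome"),
            inherits(config, "sim_config"))
  contig <- names(genome$seq)[1]
  seq1 <- genome$seq[[contig]]
  G <- nchar(seq1)
  samples <- mm$samples
  with_seed_if(if (is.null(seed)) config$seed + 1L else seed, {
    recs <- list()
    for (s in samples) {
      true_idx <- which(mm$mat[, s])
      for (r in 1:2) {
        det <- true_idx[runif(length(true_idx)) >= config$fn_rate]
        n_fp <- rbinom(1L, G, config$fp_rate)
        fp_pos <- integer(0)
        if (n_fp > 0) {
          fp_pos <- sample.int(G, n_fp)
          fp_pos <- setdiff(fp_pos, mm$sites$pos)
        }
        n_det <- length(det)
        if (n_det + length(fp_pos) == 0) next
        fp_ref <- if (length(fp_pos)) substring(seq1, fp_pos, fp_pos) else
          character(0)
        fp_alt <- vapply(fp_ref, function(b) sample(setdiff(BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
        recs[[length(recs) + 1L]] <- data.frame(
          sample = s, replicate = r,
          contig = contig,
          pos = c(mm$sites$pos[det], fp_pos),
          ref = c(mm$sites$ref[det], fp_ref),
          alt = c(mm$sites$alt[det], fp_alt),
          genotype = c(mm$sites$genotype[det],
                       rep("het", length(fp_pos))),
          is_true = rep(c(TRUE, FALSE), c(n_det, length(fp_pos))),
          stringsAsFactors = FALSE)
      }
    }
    base <- if (length(recs)) do.call(rbind, recs) else
      data.frame(sample = character(0), replicate = integer(0),
                 contig = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 genotype = character(0), is_true = logical(0))
    n <- nrow(base)
    base$depth <- rpois(n, config$mean_depth)
    fail <- runif(n) < config$fail_annotation_frac
    base <- cbind(base, draw_annotations(n, fail))

    # expand over callers and threshold sets (the simulator models both
    # callers and all thresholds as seeing the same read evidence)
    calls <- do.call(rbind, lapply(c("A", "B"), function(cl) {
      do.call(rbind, lapply(c("T40", "T30", "T20"), function(th) {
        out <- base
        out$caller <- cl
        out$threshold_set <- th
        out
      }))
    }))
    rownames(calls) <- NULL

    # per-site read support for every sample (including the base) at
    # every candidate site
    cand <- unique(base[, c("contig", "pos")])
    all_samples <- c(samples, base_label)
    support <- expand.grid(pos = cand$pos, sample = all_samples,
                           stringsAsFactors = FALSE)
    support$contig <- contig
    ns <- nrow(support)
    d1 <- rpois(ns, config$mean_depth)
    d2 <- rpois(ns, config$mean_depth)
    support$hq_rep1 <- rbinom(ns, d1, 0.97)
    support$hq_rep2 <- rbinom(ns, d2, 0.97)
    carrier <- matrix(FALSE, ns, 1)
    key_mm <- paste(mm$sites$pos)
    carry_lookup <- mm$mat
    rownames(carry_lookup) <- key_mm
    is_true_site <- support$pos %in% mm$sites$pos
    is_carrier <- logical(ns)
    idx <- which(is_true_site & support$sample != base_label)
    if (length(idx)) {
      is_carrier[idx] <- carry_lookup[cbind(as.character(support$pos[idx]),
                                            support$sample[idx])]
    }
    gt <- rep("het", ns)
    gt[is_true_site] <- mm$sites$genotype[match(support$pos[is_true_site],
                                                mm$sites$pos)]
    p_alt <- ifelse(gt == "hom", 0.95, 0.5)
    support$supp_rep1 <- ifelse(is_carrier,
                                pmax(1L, rbinom(ns, support$hq_rep1, p_alt)), 0L)
    support$supp_rep2 <- ifelse(is_carrier,
                                pmax(1L, rbinom(ns, support$hq_rep2, p_alt)), 0L)
    # spurious calls get weak, replicate-specific support
    fp_rec <- base[!base$is_true, c("pos", "sample", "replicate")]
    if (nrow(fp_rec)) {
      for (i in seq_len(nrow(fp_rec))) {
        j <- which(support$pos == fp_rec$pos[i] &
                     support$sample == fp_rec$sample[i])
        col <- if (fp_rec$replicate[i] == 1) "supp_rep1" else "supp_rep2"
        support[j, col] <- pmax(1L, rbinom(1L, 4L, 0.5))
      }
    }
    support <- support[, c("contig", "pos", "sample", "hq_rep1", "hq_rep2",
                           "supp_rep1", "supp_rep2")]
    list(calls = calls, support = support)
  })
}

#' Simulate fixed inter-individual SNVs under purifying selection
#'
#' Places `n_sites` fixed differences uniformly on the genome; candidate
#' non-synonymous (missense or nonsense) changes are rejected and redrawn
#' with probability `nonsyn_removal_prob`, emulating purifying selection
#' of tunable strength on transmitted mutations.
#'
#' @param genome An `annotated_genome`.
#' @param n_sites Number of SNVs to emit (>= 1).
#' @param nonsyn_removal_prob Rejection probability for non-synonymous
#'   candidates, in `[0, 1]`.
#' @param seed Optional seed.
#' @return Data frame with `contig`, `pos`, `ref`, `alt`, `consequence`
#'   (`synonymous`, `missense`, `nonsense` or `noncoding`).
#' @export
simulate_interindividual_snvs <- function(genome, n_sites,
                                          nonsyn_removal_prob = 0,
                                          seed = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (n_sites < 1) stop("`n_sites` must be >= 1", call. = FALSE)
  stopifnot_scalar_prob(nonsyn_removal_prob, "nonsyn_removal_prob")
  contig <- names(genome$seq)[1]
  seq1 <- genome$seq[[contig]]
  G <- nchar(seq1)
  with_seed_if(seed, {
    out <- vector("list", n_sites)
    used <- integer(0)
    for (i in seq_len(n_sites)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 10000L) {
          stop("cannot place SNVs: no neutral capacity left", call. = FALSE)
        }
        pos <- sample.int(G, 1L)
        if (pos %in% used) next
        ref <- substring(seq1, pos, pos)
        alt <- sample(setdiff(BASES, ref), 1L)
        cons <- consequence_at(genome, contig, pos, alt)
        if (cons %in% c("missense", "nonsense") &&
            runif(1) < nonsyn_removal_prob) next
        break
      }
      used <- c(used, pos)
      out[[i]] <- data.frame(contig = contig, pos = pos, ref = ref,
                             alt = alt, consequence = cons,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    res[order(res$pos), , drop = FALSE]
  })
}

# coding consequence of a single-base change; "noncoding" outside CDS
consequence_at <- function(genome, contig, pos, alt) {
  g <- genome$genes
  hit <- which(g$contig == contig & g$start <= pos & g$end >= pos)
  if (!length(hit)) return("noncoding")
  g <- g[hit[1], ]
  seq1 <- genome$seq[[contig]]
  if (g$strand == "+") {
    offset <- pos - g$start
    cb_alt <- alt
  } else {
    offset <- g$end - pos
    cb_alt <- COMPLEMENT[[alt]]
  }
  codon_i <- offset %/% 3L
  within <- offset %% 3L
  if (g$strand == "+") {
    cod_start <- g$start + 3L * codon_i
    codon <- substr(seq1, cod_start, cod_start + 2L)
  } else {
    cod_end <- g$end - 3L * codon_i
    codon <- revcomp(substr(seq1, cod_end - 2L, cod_end))
  }
  mutated <- codon
  substr(mutated, within + 1L, within + 1L) <- cb_alt
  classify_codon_change(codon, mutated)
}

classify_codon_change <- function(from, to) {
  gc <- Biostrings::GENETIC_CODE
  aa_from <- gc[[from]]
  aa_to <- gc[[to]]
  if (aa_from == aa_to) return("synonymous")
  if (aa_to == "*") return("nonsense")
  if (aa_from == "*") return("stop_lost")
  "missense"
}
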