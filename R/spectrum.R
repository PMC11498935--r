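PYR_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution classes
#'
#' Pyrimidine-centered class labels in the conventional (COSMIC) order:
#' substitution-major (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`), then
#' 5' and 3' flanking base, each in `A`, `C`, `G`, `T` order.
#'
#' @return Character vector of 96 labels such as `"A[C>T]G"`.
#' @export
spectrum_classes <- function() {
  unlist(lapply(PYR_SUBS, function(s) {
    as.vector(t(outer(BASES, BASES, function(f, t3)
      paste0(f, "[", s, "]", t3))))
  }))
}

#' Classify a substitution into its trinucleotide-context class
#'
#' Takes the bases immediately 5' and 3' of the mutated site; if the
#' reference base is a purine, the triplet and the substitution are
#' reverse-complemented so every class is pyrimidine-centered (C>T and
#' G>A on the other strand are the same class, C:G>T:A).
#'
#' @param genome An `annotated_genome`.
#' @param contig Contig name.
#' @param pos 1-based position (not at a contig boundary).
#' @param ref,alt Reference and alternative base; `ref` must match the
#'   genome.
#' @return One of the 96 labels of [spectrum_classes()], or `NA` with a
#'   warning if a flanking base is unavailable or not ACGT.
#' @examples
#' g <- structure(list(seq = c(c1 = "AACGT"), genes = NULL),
#'                class = "annotated_genome")
#' classify_context(g, "c1", 3, "C", "T")
#' @export
classify_context <- function(genome, contig, pos, ref, alt) {
  contig <- rep_len(contig, length(pos))
  out <- character(length(pos))
  for (i in seq_along(pos)) {
    seq1 <- genome$seq[[contig[i]]]
    n <- nchar(seq1)
    p <- pos[i]
    if (p <= 1 || p >= n) {
      warning("site at contig boundary excluded from spectrum", call. = FALSE)
      out[i] <- NA_character_
      next
    }
    triplet <- substr(seq1, p - 1L, p + 1L)
    if (substr(triplet, 2L, 2L) != ref[i]) {
      stop(sprintf("reference mismatch at %s:%d (genome %s, given %s)",
                   contig[i], p, substr(triplet, 2L, 2L), ref[i]),
           call. = FALSE)
    }
    if (grepl("[^ACGT]", triplet)) {
      warning("non-ACGT flank excluded from spectrum", call. = FALSE)
      out[i] <- NA_character_
      next
    }
    out[i] <- collapse_context(triplet, alt[i])
  }
  out
}

# strand-collapse a (triplet, alt) pair to its pyrimidine-centered label
collapse_context <- function(triplet, alt) {
  center <- substr(triplet, 2L, 2L)
  if (center %in% c("A", "G")) {
    triplet <- revcomp(triplet)
    alt <- COMPLEMENT[[alt]]
    center <- substr(triplet, 2L, 2L)
  }
  paste0(substr(triplet, 1L, 1L), "[", center, ">", alt, "]",
         substr(triplet, 3L, 3L))
}

#' Pyrimidine-centered triplet content of a genome
#'
#' Counts every overlapping width-3 window (windows containing non-ACGT
#' characters are skipped); purine-centered windows are credited to
#' their reverse complement, giving the 32 pyrimidine-centered triplet
#' opportunity counts used for spectrum normalization.
#'
#' @param genome An `annotated_genome` (all contigs are pooled).
#' @return Named integer vector over the 32 pyrimidine-centered triplets.
#' @examples
#' g <- structure(list(seq = c(c1 = "ACGT"), genes = NULL),
#'                class = "annotated_genome")
#' genome_triplet_counts(g)[["ACG"]]
#' @export
genome_triplet_counts <- function(genome) {
  dna <- Biostrings::DNAStringSet(unname(genome$seq))
  tf <- colSums(Biostrings::trinucleotideFrequency(dna))
  trip <- names(tf)
  center <- substr(trip, 2L, 2L)
  canon <- ifelse(center %in% c("C", "T"), trip,
                  vapply(trip, revcomp, character(1)))
  counts <- tapply(tf, canon, sum)
  all32 <- sort(unique(ifelse(substr(names(tf), 2, 2) %in% c("C", "T"),
                              names(tf),
                              vapply(names(tf), revcomp, character(1)))))
  out <- setNames(as.integer(counts[all32]), all32)
  out[is.na(out)] <- 0L
  out
}

#' Mutational spectrum over the 96 trinucleotide classes
#'
#' Classifies each SNV into its context class and forms the spectrum.
#' With `normalize = "opportunity"` (default) the per-class mutation
#' count is divided by the genome count of its reference triplet and the
#' result renormalized to sum to one; `"raw"` skips the opportunity
#' division (the scale on which the COSMIC reference signatures are
#' defined, since those are human-genome triplet fractions).
#'
#' @param snvs Data frame with `contig`, `pos`, `ref`, `alt`.
#' @param genome An `annotated_genome`.
#' @param normalize `"opportunity"` or `"raw"`.
#' @return An object of class `spectrum_vector`: list with `values`
#'   (96 fractions summing to 1), `raw_counts`, `opportunity`,
#'   `normalize`, and `n_excluded` (boundary/N sites dropped).
#' @export
mutation_spectrum <- function(snvs, genome,
                              normalize = c("opportunity", "raw")) {
  normalize <- match.arg(normalize)
  if (!nrow(snvs)) stop("no SNVs to classify", call. = FALSE)
  cls <- classify_context(genome, snvs$contig, snvs$pos, snvs$ref, snvs$alt)
  n_excl <- sum(is.na(cls))
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("no classifiable SNVs", call. = FALSE)
  classes <- spectrum_classes()
  counts <- table(factor(cls, levels = classes))
  counts <- setNames(as.integer(counts), classes)
  opp_triplet <- genome_triplet_counts(genome)
  trip_of <- paste0(substr(classes, 1, 1), substr(classes, 3, 3),
                    substr(classes, 7, 7))
  opp <- setNames(as.numeric(opp_triplet[trip_of]), classes)
  if (any(counts > 0 & (is.na(opp) | opp == 0))) {
    stop("observed mutation in a triplet class with zero genome opportunity",
         call. = FALSE)
  }
  vals <- if (normalize == "opportunity") {
    v <- ifelse(opp > 0, counts / opp, 0)
    v / sum(v)
  } else {
    counts / sum(counts)
  }
  structure(list(values = setNames(as.numeric(vals), classes),
                 raw_counts = counts, opportunity = opp,
                 normalize = normalize, n_excluded = n_excl),
            class = "spectrum_vector")
}

#' @export
print.spectrum_vector <- function(x, ...) {
  top <- sort(x$values, decreasing = TRUE)[1:5]
  cat(sprintf("Mutational spectrum (%s-normalized), %d mutations\n",
              x$normalize, sum(x$raw_counts)))
  cat("  top classes:",
      paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' CpG enrichment of somatic SNVs
#'
#' Fold-change of the fraction of SNVs whose mutated base lies in a CpG
#' dinucleotide (a C followed by G, on either strand) over the fraction
#' of genome positions in CpG context.
#'
#' @param snvs Data frame with `contig`, `pos`, `ref`, `alt`.
#' @param genome An `annotated_genome`.
#' @return List with `fold`, `snv_cpg_fraction`, `genome_cpg_fraction`.
#' @export
cpg_enrichment <- function(snvs, genome) {
  if (!nrow(snvs)) stop("no SNVs", call. = FALSE)
  n_cpg_genome <- 0L
  n_acgt <- 0L
  for (s in genome$seq) {
    cg <- gregexpr("CG", s, fixed = TRUE)[[1]]
    n_cg <- if (cg[1] == -1L) 0L else length(cg)
    n_cpg_genome <- n_cpg_genome + 2L * n_cg
    n_acgt <- n_acgt + nchar(s) - lengths(regmatches(
      s, gregexpr("[^ACGT]", s)))
  }
  if (n_cpg_genome == 0) stop("genome contains no CpG dinucleotides", call. = FALSE)
  in_cpg <- vapply(seq_len(nrow(snvs)), function(i) {
    s <- genome$seq[[snvs$contig[i]]]
    p <- snvs$pos[i]
    ref <- substr(s, p, p)
    (ref == "C" && p < nchar(s) && substr(s, p + 1L, p + 1L) == "G") ||
      (ref == "G" && p > 1L && substr(s, p - 1L, p - 1L) == "C")
  }, logical(1))
  snv_frac <- mean(in_cpg)
  genome_frac <- n_cpg_genome / n_acgt
  list(fold = snv_frac / genome_frac,
       snv_cpg_fraction = snv_frac,
       genome_cpg_fraction = genome_frac)
}

#' Cosine similarity between a spectrum and a signature
#'
#' @param a,b Numeric 96-vectors (or `spectrum_vector` objects) in the
#'   same class order; nonnegative, not all zero.
#' @return Similarity in `[0, 1]`.
#' @examples
#' cosine_similarity(c(1, 0, 1), c(1, 0, 1))
#' @export
cosine_similarity <- function(a, b) {
  va <- if (inherits(a, "spectrum_vector")) a$values else as.numeric(a)
  vb <- if (inherits(b, "spectrum_vector")) b$values else as.numeric(b)
  if (length(va) != length(vb)) stop("vector lengths differ", call. = FALSE)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("zero vector has no direction", call. = FALSE)
  sum(va * vb) / (na * nb)
}

#' Signed difference of two spectra
#'
#' Per-class `a - b`; sums to zero when both inputs are normalized.
#'
#' @param a,b `spectrum_vector` objects (or named 96-vectors) with
#'   matching class order.
#' @return Named numeric vector of 96 signed differences.
#' @export
spectrum_difference <- function(a, b) {
  va <- if (inherits(a, "spectrum_vector")) a$values else a
  vb <- if (inherits(b, "spectrum_vector")) b$values else b
  if (!identical(names(va), names(vb))) {
    stop("spectrum class orders do not match", call. = FALSE)
  }
  va - vb
}

#' Read a mutational signature matrix
#'
#' Expects a TSV with 96 rows (class labels in the first column, in
#' [spectrum_classes()] order) and one column per signature, each column
#' summing to one.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, 96 x signatures, rownames = class labels.
#' @export
read_signature_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labs
  if (nrow(m) != 96) stop("signature matrix must have 96 rows", call. = FALSE)
  if (!identical(labs, spectrum_classes())) {
    stop("signature rows must follow the standard 96-class order", call. = FALSE)
  }
  if (any(m < 0)) stop("signature values must be nonnegative", call. = FALSE)
  m
}

#' Cosine similarity of a spectrum to each signature column
#'
#' @param spectrum A `spectrum_vector`.
#' @param signatures Matrix from [read_signature_matrix()].
#' @return Named numeric vector of similarities.
#' @export
signature_similarity <- function(spectrum, signatures) {
  vapply(colnames(signatures), function(s)
    cosine_similarity(spectrum, signatures[, s]), numeric(1))
}
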