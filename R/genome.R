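#' Generate an annotated diploid genome
#'
#' Draws a random single-contig genome at the configured GC content and
#' packs `n_genes` single-exon protein-coding genes into it. Every CDS
#' starts with ATG, ends with a stop codon, and contains no internal stop
#' (codons are sampled from the 61 sense codons with probabilities implied
#' by the base composition). Genes are placed in non-overlapping windows
#' with at least 1 kb upstream and 500 bp downstream of clearance, so the
#' intergenic complement used by the selection test is well defined.
#'
#' @param config A [sim_config()].
#' @return An object of class `annotated_genome`: a list with `seq`
#'   (named character vector of contig sequences) and `genes` (data frame
#'   with `gene_id`, `contig`, `start`, `end`, `strand`; 1-based inclusive
#'   CDS coordinates).
#' @examples
#' g <- generate_genome(sim_config(seed = 1, genome_length = 30000,
#'                                 n_genes = 3, mu_per_meter = 1e-6))
#' nrow(g$genes)
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$genome_length
  n <- config$n_genes
  need <- n * (config$mean_cds_length + 3000L)
  if (n > 0 && G < need) {
    stop(sprintf(
      "cannot pack %d genes of mean CDS %d bp into %d bp (need >= %d)",
      n, config$mean_cds_length, G, need), call. = FALSE)
  }
  with_seed_if(config$seed, {
    gc <- config$gc_content
    base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seq_vec <- sample(BASES, G, replace = TRUE, prob = base_prob)

    genes <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    if (n > 0) {
      codon_tab <- sense_codon_probs(base_prob)
      stops <- c("TAA", "TAG", "TGA")
      stop_prob <- codon_prob_of(stops, base_prob)
      slot <- G %/% n
      starts <- integer(n)
      ends <- integer(n)
      strands <- character(n)
      for (i in seq_len(n)) {
        ncod <- max(3L, round(config$mean_cds_length / 3 * runif(1, 0.8, 1.2)))
        len <- 3L * ncod
        lo <- (i - 1L) * slot + 1001L
        hi <- i * slot - 500L - len
        if (hi < lo) stop("gene does not fit its placement window; increase genome_length",
                          call. = FALSE)
        st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        body <- sample(codon_tab$codon, ncod - 2L, replace = TRUE,
                       prob = codon_tab$prob)
        cds <- paste0("ATG", paste(body, collapse = ""),
                      sample(stops, 1L, prob = stop_prob / sum(stop_prob)))
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") cds else revcomp(cds)
        seq_vec[st:(st + len - 1L)] <- strsplit(ins, "")[[1]]
        starts[i] <- st
        ends[i] <- st + len - 1L
        strands[i] <- strand
      }
      genes <- data.frame(
        gene_id = sprintf("gene_%03d", seq_len(n)),
        contig = "contig_1",
        start = starts, end = ends, strand = strands,
        stringsAsFactors = FALSE)
    }
    structure(list(
      seq = c(contig_1 = paste(seq_vec, collapse = "")),
      genes = genes,
      config = config
    ), class = "annotated_genome")
  })
}

# probabilities of the 61 sense codons under independent base draws
sense_codon_probs <- function(base_prob) {
  codons <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                  1L, paste, collapse = "")
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  p <- codon_prob_of(codons, base_prob)
  list(codon = codons, prob = p / sum(p))
}

codon_prob_of <- function(codons, base_prob) {
  vapply(strsplit(codons, ""), function(b) prod(base_prob[b]), numeric(1))
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("Annotated genome: %d contig(s), %s bp, %d gene(s)\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Extract CDS sequences (coding strand)
#'
#' @param genome An `annotated_genome`.
#' @return Named character vector of CDS sequences, reverse-complemented
#'   for minus-strand genes so each reads 5'->3' in coding orientation.
#' @export
cds_sequences <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (nrow(genome$genes) == 0) return(character(0))
  out <- vapply(seq_len(nrow(genome$genes)), function(i) {
    g <- genome$genes[i, ]
    s <- substr(genome$seq[[g$contig]], g$start, g$end)
    if (g$strand == "-") revcomp(s) else s
  }, character(1))
  names(out) <- genome$genes$gene_id
  out
}

#' Write a genome to FASTA and GFF3
#'
#' @param genome An `annotated_genome`.
#' @param fasta,gff Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta = NULL, gff = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(genome$seq)
    Biostrings::writeXStringSet(dna, filepath = fasta)
  }
  if (!is.null(gff)) {
    g <- genome$genes
    if (nrow(g)) {
      gr <- GenomicRanges::GRanges(
        seqnames = g$contig,
        ranges = IRanges::IRanges(start = g$start, end = g$end),
        strand = g$strand,
        type = "CDS",
        phase = 0L,
        ID = paste0(g$gene_id, ".cds"),
        Parent = g$gene_id)
      rtracklayer::export(gr, gff, format = "gff3")
    } else {
      writeLines("##gff-version 3", gff)
    }
  }
  invisible(c(fasta = fasta, gff = gff))
}

#' Read a genome from FASTA (optionally with GFF3 CDS annotation)
#'
#' @param fasta Path to a FASTA file.
#' @param gff Optional path to a GFF3 file with CDS features.
#' @return An `annotated_genome`.
#' @export
read_genome <- function(fasta, gff = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  genes <- data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (!is.null(gff)) {
    gr <- rtracklayer::import(gff, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    if (length(gr)) {
      parent <- if (!is.null(gr$Parent) && all(lengths(gr$Parent) > 0)) {
        vapply(gr$Parent, `[`, character(1), 1L)
      } else if (!is.null(gr$ID)) as.character(gr$ID) else
        sprintf("gene_%03d", seq_along(gr))
      genes <- data.frame(
        gene_id = parent,
        contig = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(seq = setNames(as.character(dna), names(dna)),
                 genes = genes, config = NULL),
            class = "annotated_genome")
}
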