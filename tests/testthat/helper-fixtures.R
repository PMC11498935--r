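# shared fixture builders; everything is generated in code at test time

tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, genome_length = 50000L, n_genes = 5L,
               mean_cds_length = 300L, mu_per_meter = 1e-5)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a hand-built annotated genome with a known sequence
toy_genome <- function(seq, genes = NULL) {
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
  }
  structure(list(seq = c(contig_1 = seq), genes = genes, config = NULL),
            class = "annotated_genome")
}

# a call-record data frame with passing annotations unless overridden
make_records <- function(n, sample = "1", replicate = 1L, caller = "A",
                         threshold_set = "T40", pos = seq_len(n) * 10L,
                         ref = "A", alt = "T", genotype = "het", ...) {
  df <- data.frame(sample = sample, replicate = replicate, caller = caller,
                   threshold_set = threshold_set, contig = "contig_1",
                   pos = pos, ref = ref, alt = alt, genotype = genotype,
                   depth = 30L,
                   QD = 20, QUAL = 500, SOR = 1, FS = 5, MQ = 50,
                   MQRankSum = 0, ReadPosRankSum = 0,
                   stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# brute-force path distance between two tips by LCA over parent chains
brute_tip_distance <- function(phy, i, j) {
  parent <- integer(max(phy$edge))
  plen <- numeric(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  plen[phy$edge[, 2]] <- phy$edge.length
  chain <- function(v) {
    out <- v
    while (parent[v] != 0) { v <- parent[v]; out <- c(out, v) }
    out
  }
  ai <- chain(i); aj <- chain(j)
  lca <- ai[ai %in% aj][1]
  depth <- function(v, stop_at) {
    s <- 0
    while (v != stop_at) { s <- s + plen[v]; v <- parent[v] }
    s
  }
  depth(i, lca) + depth(j, lca)
}

# independent brute-force translation of a CDS with the standard code
brute_translate <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds)
  vapply(seq(1, n - 2, by = 3), function(i) gc[[substr(cds, i, i + 2)]],
         character(1))
}
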