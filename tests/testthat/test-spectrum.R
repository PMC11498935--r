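test_that("context classification keeps pyrimidine centers and collapses strands", {
  g <- toy_genome("AACGT")
  expect_equal(classify_context(g, "contig_1", 3, "C", "T"), "A[C>T]G")
  g2 <- toy_genome("ACGTA")
  # center G>A at position 3 of CGT: reverse complement -> A[C>T]G
  expect_equal(classify_context(g2, "contig_1", 3, "G", "A"), "A[C>T]G")
  expect_error(classify_context(g, "contig_1", 3, "G", "T"), "mismatch")
  expect_warning(out <- classify_context(g, "contig_1", 1, "A", "T"),
                 "boundary")
  expect_true(is.na(out))
})

test_that("all 192 strand-specific contexts map exactly 2-to-1 onto 96 classes", {
  BASES <- c("A", "C", "G", "T")
  combos <- expand.grid(f = BASES, c = BASES, t = BASES,
                        stringsAsFactors = FALSE)
  labels <- character(0)
  for (i in seq_len(nrow(combos))) {
    trip <- paste0(combos$f[i], combos$c[i], combos$t[i])
    for (alt in setdiff(BASES, combos$c[i])) {
      labels <- c(labels, somatree:::collapse_context(trip, alt))
    }
  }
  expect_length(labels, 192)
  tab <- table(labels)
  expect_length(tab, 96)
  expect_true(all(tab == 2))
  expect_setequal(names(tab), spectrum_classes())
})

test_that("genome triplet counting matches a naive sliding window", {
  expect_equal(genome_triplet_counts(toy_genome("ACGT"))[["ACG"]], 2L)
  aaa <- genome_triplet_counts(toy_genome("AAAA"))
  expect_equal(aaa[["TTT"]], 2L)
  # windows containing N are skipped
  withN <- genome_triplet_counts(toy_genome("ACNGT"))
  expect_equal(sum(withN), 0L)
  # random sequence vs brute-force dictionary count
  set.seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  counts <- genome_triplet_counts(toy_genome(s))
  oracle <- new.env()
  for (i in 1:(nchar(s) - 2)) {
    trip <- substr(s, i, i + 2)
    if (substr(trip, 2, 2) %in% c("A", "G")) trip <- somatree:::revcomp(trip)
    oracle[[trip]] <- (if (is.null(oracle[[trip]])) 0L else oracle[[trip]]) + 1L
  }
  for (trip in names(counts)) {
    expect_equal(counts[[trip]],
                 if (is.null(oracle[[trip]])) 0L else oracle[[trip]],
                 info = trip)
  }
})

test_that("spectra are normalized, order-invariant distributions", {
  g <- generate_genome(tiny_config(seed = 41, genome_length = 30000L,
                                   n_genes = 0L))
  set.seed(41)
  n <- 300
  pos <- sample(2:29999, n)
  ref <- substring(g$seq[[1]], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  snvs <- data.frame(contig = "contig_1", pos = pos, ref = ref, alt = alt)
  sp <- mutation_spectrum(snvs, g)
  expect_equal(sum(sp$values), 1, tolerance = 1e-12)
  expect_true(all(sp$values >= 0))
  expect_equal(sum(sp$raw_counts), n)
  sp2 <- mutation_spectrum(snvs[sample(n), ], g)
  expect_equal(sp2$values, sp$values)
  # single SNV: all mass in one class
  one <- mutation_spectrum(snvs[1, ], g)
  expect_equal(max(one$values), 1)
  # raw mode divides by mutation count only
  raw <- mutation_spectrum(snvs, g, normalize = "raw")
  expect_equal(unname(raw$values), unname(raw$raw_counts / n))
})

test_that("a CpG C>T excess dominates the simulated spectrum", {
  cfg <- tiny_config(seed = 42, genome_length = 100000L, n_genes = 0L,
                     mu_per_meter = 3e-5, cpg_ct_multiplier = 10)
  g <- generate_genome(cfg)
  tr <- generate_architecture(4, seed = 42)
  sim <- suppressWarnings(simulate_somatic_mutations(g, tr, cfg))
  sp <- suppressWarnings(mutation_spectrum(sim$matrix$sites, g))
  cpg_ct <- c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")
  expect_gt(sum(sp$values[cpg_ct]), 0.5)
})

test_that("CpG enrichment matches a hand computation on a toy genome", {
  # genome ACGTACGTAA: CpG positions 2,3,6,7 -> genome fraction 0.4
  g <- toy_genome("ACGTACGTAA")
  snvs <- data.frame(contig = "contig_1", pos = c(2L, 6L, 4L, 9L),
                     ref = c("C", "C", "T", "A"), alt = "A")
  ce <- cpg_enrichment(snvs, g)
  expect_equal(ce$genome_cpg_fraction, 0.4)
  expect_equal(ce$snv_cpg_fraction, 0.5)
  expect_equal(ce$fold, 1.25)
  # SNV fraction equal to the genome fraction gives fold 1
  snvs2 <- data.frame(contig = "contig_1", pos = c(2L, 3L, 4L, 9L, 10L),
                      ref = c("C", "G", "T", "A", "A"), alt = "T")
  expect_equal(cpg_enrichment(snvs2, g)$fold, 1)
  expect_error(cpg_enrichment(snvs[0, ], g), "no SNVs")
})

test_that("cosine similarity follows the direct formula", {
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  set.seed(13)
  for (rep in 1:5) {
    a <- runif(96); b <- runif(96)
    expect_equal(cosine_similarity(a, b),
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    # symmetry and scale invariance
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_equal(cosine_similarity(3 * a, b), cosine_similarity(a, b))
  }
})

test_that("spectrum differences are signed and sum to zero", {
  g <- generate_genome(tiny_config(seed = 44, genome_length = 20000L,
                                   n_genes = 0L))
  set.seed(44)
  mk <- function(n) {
    pos <- sample(2:19999, n)
    ref <- substring(g$seq[[1]], pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1), USE.NAMES = FALSE)
    data.frame(contig = "contig_1", pos = pos, ref = ref, alt = alt)
  }
  a <- mutation_spectrum(mk(150), g)
  b <- mutation_spectrum(mk(200), g)
  d <- spectrum_difference(a, b)
  expect_equal(sum(d), 0, tolerance = 1e-12)
  expect_equal(unname(d), unname(a$values - b$values))
  expect_equal(unname(spectrum_difference(a, a)), rep(0, 96))
})

test_that("signature matrices load and score against a spectrum", {
  # build a clock-like toy signature (CpG C>T) and a flat one
  classes <- spectrum_classes()
  sig1 <- setNames(rep(1e-4, 96), classes)
  sig1[grepl("\\[C>T\\]G", classes)] <- 0.2
  sig1 <- sig1 / sum(sig1)
  sig2 <- setNames(rep(1 / 96, 96), classes)
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(class = classes, SBS1like = sig1, Flat = sig2),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_signature_matrix(path)
  expect_equal(dim(m), c(96L, 2L))
  cfg <- tiny_config(seed = 45, genome_length = 80000L, n_genes = 0L,
                     mu_per_meter = 3e-5, cpg_ct_multiplier = 10)
  g <- generate_genome(cfg)
  tr <- generate_architecture(4, seed = 45)
  sim <- suppressWarnings(simulate_somatic_mutations(g, tr, cfg))
  sp <- mutation_spectrum(sim$matrix$sites, g, normalize = "raw")
  simil <- signature_similarity(sp, m)
  # the deamination-driven spectrum resembles the clock-like signature most
  expect_gt(simil[["SBS1like"]], simil[["Flat"]])
})
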