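test_that("intergenic regions are the strand-aware complement of gene territories", {
  g <- toy_genome(strrep("A", 10000),
                  genes = data.frame(gene_id = "g1", contig = "contig_1",
                                     start = 2001L, end = 3000L,
                                     strand = "+"))
  ig <- define_intergenic(g)
  expect_equal(ig$start, c(1L, 3501L))
  expect_equal(ig$end, c(1000L, 10000L))
  # minus strand: upstream means 3' side in genome coordinates
  gm <- toy_genome(strrep("A", 10000),
                   genes = data.frame(gene_id = "g1", contig = "contig_1",
                                      start = 2001L, end = 3000L,
                                      strand = "-"))
  igm <- define_intergenic(gm)
  expect_equal(igm$start, c(1L, 4001L))
  expect_equal(igm$end, c(1500L, 10000L))
  # random annotations match a brute-force per-base mask
  set.seed(14)
  for (rep in 1:3) {
    L <- 20000L
    n <- 6
    st <- sort(sample(seq(1000, L - 2000, by = 100), n))
    genes <- data.frame(gene_id = paste0("g", 1:n), contig = "contig_1",
                        start = st, end = st + sample(200:900, n),
                        strand = sample(c("+", "-"), n, TRUE))
    gr <- toy_genome(strrep("A", L), genes)
    ig2 <- define_intergenic(gr)
    mask <- rep(TRUE, L)
    for (i in 1:n) {
      lo <- if (genes$strand[i] == "+") genes$start[i] - 1000L else
        genes$start[i] - 500L
      hi <- if (genes$strand[i] == "+") genes$end[i] + 500L else
        genes$end[i] + 1000L
      mask[max(1, lo):min(L, hi)] <- FALSE
    }
    got <- rep(FALSE, L)
    for (i in seq_len(nrow(ig2))) got[ig2$start[i]:ig2$end[i]] <- TRUE
    expect_identical(got, mask)
  }
})

test_that("codon opportunity counts match brute-force codon-table lookups", {
  # ATG: all 9 neighbors are missense
  atg <- enumerate_opportunities(c(g = "ATGATGTAA"))
  # first two codons are ATG; brute-force the expectation per codon
  expect_equal(sum(atg$counts), 18L)
  expect_equal(sum(atg$counts[, "synonymous"]), 0L)
  expect_equal(sum(atg$counts[, "nonsense"]), 0L)
  # TGG: exactly two of nine neighbors are stops (TAG, TGA)
  tgg <- enumerate_opportunities(c(g = "ATGTGGTAA"))
  tgg_only <- tgg$counts - atg$counts / 2
  expect_equal(sum(tgg_only[, "nonsense"]), 2L)
  # exhaustive cross-check of one random CDS against a naive loop
  set.seed(15)
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA")), 30, TRUE)
  cds <- paste0("ATG", paste(body, collapse = ""), "TGA")
  got <- enumerate_opportunities(c(g = cds))
  oracle <- matrix(0L, 6, 3, dimnames = dimnames(got$counts))
  ncod <- nchar(cds) / 3 - 1  # terminal stop excluded
  for (k in seq_len(ncod)) {
    cod <- substr(cds, 3 * k - 2, 3 * k)
    for (w in 1:3) {
      ref <- substr(cod, w, w)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        mut <- cod; substr(mut, w, w) <- alt
        aa0 <- Biostrings::GENETIC_CODE[[cod]]
        aa1 <- Biostrings::GENETIC_CODE[[mut]]
        type <- if (aa0 == aa1) "synonymous" else if (aa1 == "*") "nonsense"
                else "missense"
        pyr <- if (ref %in% c("A", "G")) {
          comp <- c(A = "T", C = "G", G = "C", T = "A")
          paste0(comp[[ref]], ">", comp[[alt]])
        } else paste0(ref, ">", alt)
        oracle[pyr, type] <- oracle[pyr, type] + 1L
      }
    }
  }
  expect_identical(got$counts, oracle)
})

test_that("opportunity totals equal 3 * L_cds for arbitrary CDS sets", {
  set.seed(16)
  for (rep in 1:4) {
    g <- generate_genome(tiny_config(seed = rep, genome_length = 40000L,
                                     n_genes = sample(3:8, 1)))
    opp <- enumerate_opportunities(g)
    expect_identical(sum(opp$counts), opp$L_cds * 3L)
    expect_gt(opp$L_cds, 0L)
  }
  # malformed CDS are excluded, and logged
  bad <- enumerate_opportunities(c(ok = "ATGAAATAA", short = "ATG",
                                   internal_stop = "ATGTAAAAATAA"))
  expect_equal(bad$n_excluded, 2L)
  expect_equal(bad$L_cds, 6L)
})

test_that("the whole codon table has the classical synonymous share", {
  # enumerate all 64 codons x 9 neighbors with the brute-force oracle
  codons <- names(Biostrings::GENETIC_CODE)
  syn <- 0L; tot <- 0L
  for (cod in codons) {
    for (w in 1:3) {
      ref <- substr(cod, w, w)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        mut <- cod; substr(mut, w, w) <- alt
        tot <- tot + 1L
        if (Biostrings::GENETIC_CODE[[cod]] == Biostrings::GENETIC_CODE[[mut]])
          syn <- syn + 1L
      }
    }
  }
  expect_equal(tot, 576L)
  expect_gt(syn / tot, 0.20)
  expect_lt(syn / tot, 0.28)
})

test_that("background rates divide class counts by eligible bases", {
  # constructed toy: 100 C:G bases among 400, 2 C>T SNVs
  s <- paste0(strrep("C", 50), strrep("G", 50), strrep("A", 150),
              strrep("T", 150))
  g <- toy_genome(s)
  snvs <- data.frame(contig = "contig_1", pos = c(10L, 60L, 200L),
                     ref = c("C", "G", "A"), alt = c("T", "A", "C"))
  br <- background_rates(snvs, NULL, g)
  # C>T includes the G>A on the other strand
  expect_equal(br$rate[["C>T"]], 2 / 100)
  expect_equal(br$rate[["T>G"]], 1 / 300)  # A>C collapses to T>G
  expect_equal(br$source, "whole_genome")
  # restricted to a region the A>C site falls outside
  br2 <- background_rates(snvs, data.frame(contig = "contig_1", start = 1L,
                                           end = 100L), g)
  expect_equal(br2$rate[["C>T"]], 2 / 100)
  expect_equal(br2$rate[["T>G"]], 0)
  expect_equal(br2$source, "intergenic")
  # no SNVs -> all-zero rates
  expect_true(all(background_rates(snvs[0, ], NULL, g)$rate == 0))
})

test_that("recovered background class rates match the simulated mix", {
  cfg <- tiny_config(seed = 17, genome_length = 100000L, n_genes = 0L,
                     mu_per_meter = 3e-5, cpg_ct_multiplier = 6)
  g <- generate_genome(cfg)
  tr <- generate_architecture(4, seed = 17)
  sim <- suppressWarnings(simulate_somatic_mutations(g, tr, cfg))
  br <- background_rates(sim$matrix$sites, NULL, g)
  # the deamination excess must surface as a dominant C>T rate
  expect_gt(br$rate[["C>T"]], 2 * max(br$rate[setdiff(names(br$rate), "C>T")]))
})

test_that("expected rates reduce correctly in degenerate cases", {
  g <- generate_genome(tiny_config(seed = 18, genome_length = 40000L,
                                   n_genes = 5L))
  opp <- enumerate_opportunities(g)
  # uniform rates cancel: pN is the raw non-synonymous share
  uni <- setNames(rep(1e-3, 6), rownames(opp$counts))
  er <- expected_rates(opp, uni)
  expect_equal(er$p_nonsyn,
               sum(opp$counts[, c("missense", "nonsense")]) / sum(opp$counts))
  # rates concentrated on one class give that class's share
  one <- setNames(c(1e-3, 0, 0, 0, 0, 0), rownames(opp$counts))
  er1 <- expected_rates(opp, one)
  cls <- opp$counts["C>A", ]
  expect_equal(er1$p_nonsyn, sum(cls[c("missense", "nonsense")]) / sum(cls))
  # random tables match a direct weighted sum
  set.seed(19)
  r <- setNames(runif(6, 1e-4, 1e-2), rownames(opp$counts))
  er2 <- expected_rates(opp, r)
  lam_s <- sum(r * opp$counts[, "synonymous"])
  lam_n <- sum(r * (opp$counts[, "missense"] + opp$counts[, "nonsense"]))
  expect_equal(er2$lambda_s, lam_s)
  expect_equal(er2$lambda_n, lam_n)
  expect_equal(er2$p_nonsyn, lam_n / (lam_s + lam_n))
})

test_that("the exact binomial test follows the standard two-sided convention", {
  expect_equal(binomial_selection_test(1, 2, 0.5)$p_value, 1)
  expect_equal(binomial_selection_test(0, 10, 0.5)$p_value, 2 * 0.5^10)
  expect_error(binomial_selection_test(1, 0, 0.5), "positive")
  expect_error(binomial_selection_test(3, 2, 0.5), "observed_nonsyn")
  expect_error(binomial_selection_test(1, 2, 0), "strictly inside")
  # agrees with binom.test on random cases
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(20:200, 1); p <- runif(1, 0.2, 0.8); k <- rbinom(1, n, p)
    expect_equal(binomial_selection_test(k, n, p)$p_value,
                 binom.test(k, n, p)$p.value)
  }
})

test_that("the full selection test runs on simulated somatic SNVs", {
  cfg <- tiny_config(seed = 21, genome_length = 120000L, n_genes = 25L,
                     mean_cds_length = 900L, mu_per_meter = 2e-5)
  g <- generate_genome(cfg)
  tr <- generate_architecture(7, seed = 21)
  sim <- suppressWarnings(simulate_somatic_mutations(g, tr, cfg))
  st <- selection_test(sim$matrix$sites, g)
  expect_s3_class(st, "selection_test")
  expect_true(st$p_value >= 0 && st$p_value <= 1)
  expect_true(st$expected_fraction > 0 && st$expected_fraction < 1)
  # neutral somatic mutations should rarely reject; mainly assert coherence
  expect_equal(st$observed_total >= st$observed_nonsyn, TRUE)
  st2 <- selection_test(sim$matrix$sites, g, background = "whole_genome")
  expect_equal(st2$background$source, "whole_genome")
})
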