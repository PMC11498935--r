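test_that("hard filters use strict removal inequalities at the boundaries", {
  # below QD threshold -> removed; exactly at every threshold -> retained
  low_qd <- make_records(1, QD = 1.9)
  expect_equal(nrow(apply_hard_filters(low_qd)), 0L)
  boundary <- make_records(1, QD = 2.0, QUAL = 30.0, SOR = 4.0, FS = 60.0,
                           MQ = 40.0, MQRankSum = -12.5,
                           ReadPosRankSum = -8.0)
  expect_equal(nrow(apply_hard_filters(boundary)), 1L)
  # missing annotation fails conservatively and is logged
  nas <- make_records(2, MQ = c(NA, 50))
  kept <- apply_hard_filters(nas)
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "n_missing_annotation"), 1L)
})

test_that("hard filters equal a brute-force row-wise predicate", {
  set.seed(31)
  n <- 400
  rec <- make_records(n,
                      QD = runif(n, 0, 6), QUAL = runif(n, 0, 90),
                      SOR = runif(n, 0, 8), FS = runif(n, 0, 120),
                      MQ = runif(n, 20, 60), MQRankSum = runif(n, -20, 5),
                      ReadPosRankSum = runif(n, -12, 5))
  kept <- apply_hard_filters(rec)
  oracle <- rec[sapply(seq_len(n), function(i) {
    r <- rec[i, ]
    r$QD >= 2 && r$QUAL >= 30 && r$SOR <= 4 && r$FS <= 60 && r$MQ >= 40 &&
      r$MQRankSum >= -12.5 && r$ReadPosRankSum >= -8
  }), ]
  expect_equal(kept$pos, oracle$pos)
})

test_that("replicate and caller intersections behave as keyed set operations", {
  a <- make_records(5, replicate = 1L)
  b <- make_records(5, replicate = 2L)
  expect_equal(nrow(intersect_replicates(a, b)), 5L)          # idempotence
  disj <- make_records(5, replicate = 2L, pos = 1000L + 1:5 * 10L)
  expect_equal(nrow(intersect_replicates(a, disj)), 0L)       # disjoint
  expect_error(intersect_replicates(a, make_records(2, sample = "2")),
               "same sample")
  # genotype is part of the key: het vs hom at the same site do not match
  hom <- make_records(5, replicate = 2L, genotype = "hom")
  expect_equal(nrow(intersect_replicates(a, hom)), 0L)
  # random overlap equals a brute-force key intersection
  set.seed(7)
  p1 <- sample(1:300, 120); p2 <- sample(1:300, 120)
  r1 <- make_records(120, pos = p1)
  r2 <- make_records(120, replicate = 2L, pos = p2)
  expect_setequal(intersect_replicates(r1, r2)$pos, intersect(p1, p2))
  r2c <- make_records(120, caller = "B", pos = p2)
  expect_setequal(intersect_callers(r1, r2c)$pos, intersect(p1, p2))
  expect_equal(nrow(intersect_callers(r1, r1[0, ])), 0L)
})

test_that("threshold pooling is a provenance-tracking union", {
  t40 <- make_records(4, threshold_set = "T40", pos = c(10, 20, 30, 40))
  t30 <- make_records(3, threshold_set = "T30", pos = c(30, 40, 50))
  t20 <- make_records(1, threshold_set = "T20", pos = 60)
  pooled <- pool_thresholds(list(T40 = t40, T30 = t30, T20 = t20))
  expect_setequal(pooled$pos, c(10, 20, 30, 40, 50, 60))
  expect_equal(pooled$thresholds_detected[pooled$pos == 30], "T30,T40")
  expect_equal(pooled$thresholds_detected[pooled$pos == 60], "T20")
  # identical sets collapse to one copy; disjoint sets add up
  expect_equal(nrow(pool_thresholds(list(T40 = t40, T30 = t40, T20 = t40))),
               4L)
  set.seed(11)
  ps <- lapply(1:3, function(i) sample(1:200, 80))
  pooled2 <- pool_thresholds(list(T40 = make_records(80, pos = ps[[1]]),
                                  T30 = make_records(80, pos = ps[[2]]),
                                  T20 = make_records(80, pos = ps[[3]])))
  expect_setequal(pooled2$pos, Reduce(union, ps))
})

test_that("support filters enforce coverage and replicate read support", {
  cand <- make_records(3, pos = c(100L, 200L, 300L))
  support <- expand.grid(pos = c(100L, 200L, 300L), sample = c("1", "2", "0"),
                         stringsAsFactors = FALSE)
  support$contig <- "contig_1"
  support$hq_rep1 <- 20L; support$hq_rep2 <- 20L
  support$supp_rep1 <- 0L; support$supp_rep2 <- 0L
  carrier <- support$sample == "1"
  support$supp_rep1[carrier] <- 10L; support$supp_rep2[carrier] <- 10L

  # all passing
  expect_equal(nrow(apply_support_filters(cand, support)), 3L)
  # hq_reads 4 in one sample at site 200 -> that site removed
  s2 <- support; s2$hq_rep2[s2$pos == 200 & s2$sample == "0"] <- 4L
  expect_setequal(apply_support_filters(cand, s2)$pos, c(100L, 300L))
  # boundary: exactly 5 hq reads is enough
  s3 <- support; s3$hq_rep1[s3$pos == 200 & s3$sample == "2"] <- 5L
  expect_equal(nrow(apply_support_filters(cand, s3)), 3L)
  # carrier with (2, 1) alt reads -> removed; (2, 2) -> retained
  s4 <- support
  s4$supp_rep1[s4$pos == 100 & s4$sample == "1"] <- 2L
  s4$supp_rep2[s4$pos == 100 & s4$sample == "1"] <- 1L
  expect_setequal(apply_support_filters(cand, s4)$pos, c(200L, 300L))
  s5 <- support
  s5$supp_rep1[s5$pos == 100 & s5$sample == "1"] <- 2L
  s5$supp_rep2[s5$pos == 100 & s5$sample == "1"] <- 2L
  expect_equal(nrow(apply_support_filters(cand, s5)), 3L)
  # missing support rows for a sample -> site rejected
  s6 <- support[!(support$pos == 300 & support$sample == "2"), ]
  expect_setequal(apply_support_filters(cand, s6)$pos, c(100L, 200L))
})

test_that("homozygous collapsing emits one event per site", {
  cs <- make_records(10, genotype = rep(c("het", "hom"), 5))
  mm <- collapse_homozygous(cs)
  expect_equal(nrow(mm$mat), 10L)
  expect_equal(sum(mm$sites$genotype == "hom"), 5L)
  # a site carried hom by two samples is still a single event
  two <- rbind(make_records(1, sample = "1", genotype = "hom"),
               make_records(1, sample = "2", genotype = "hom"))
  mm2 <- collapse_homozygous(two)
  expect_equal(nrow(mm2$mat), 1L)
  expect_true(all(mm2$mat[1, c("1", "2")]))
  # conflicting genotypes warn and fall back to het
  confl <- rbind(make_records(1, sample = "1", genotype = "het"),
                 make_records(1, sample = "2", genotype = "hom"))
  expect_warning(mm3 <- collapse_homozygous(confl), "conflicting")
  expect_equal(mm3$sites$genotype, "het")
  # event count equals distinct site count on random mixed input
  set.seed(5)
  rnd <- make_records(60, sample = sample(c("1", "2", "3"), 60, TRUE),
                      pos = sample(1:30, 60, TRUE) * 10L,
                      genotype = "het")
  rnd <- rnd[!duplicated(rnd[c("sample", "pos")]), ]
  mm4 <- collapse_homozygous(rnd)
  expect_equal(nrow(mm4$mat), length(unique(rnd$pos)))
})

test_that("discovery filters only ever remove records", {
  cfg <- tiny_config(genome_length = 40000L, n_genes = 0L,
                     mu_per_meter = 2e-5, fp_rate = 5e-4, fn_rate = 0.2,
                     fail_annotation_frac = 0.2)
  g <- generate_genome(cfg)
  tr <- generate_architecture(4, seed = 12)
  sim <- simulate_somatic_mutations(g, tr, cfg)
  tab <- simulate_call_tables(sim, g, cfg)
  cs <- tab$calls[tab$calls$sample == "1" & tab$calls$caller == "A" &
                    tab$calls$threshold_set == "T40", ]
  r1 <- cs[cs$replicate == 1, ]
  h1 <- apply_hard_filters(r1)
  expect_lte(nrow(h1), nrow(r1))
  expect_true(all(paste(h1$pos, h1$alt) %in% paste(r1$pos, r1$alt)))
  i12 <- intersect_replicates(h1, apply_hard_filters(cs[cs$replicate == 2, ]))
  expect_lte(nrow(i12), nrow(h1))
})

test_that("noiseless end-to-end discovery reproduces the truth exactly", {
  cfg <- tiny_config(genome_length = 60000L, n_genes = 6L,
                     mu_per_meter = 1.5e-5, fp_rate = 0, fn_rate = 0,
                     loss_prob = 0)
  g <- generate_genome(cfg)
  tr <- generate_architecture(7, seed = 13)
  sim <- simulate_somatic_mutations(g, tr, cfg)
  tab <- simulate_call_tables(sim, g, cfg)
  mm <- discover_somatic(tab$calls, tab$support,
                         samples = tr$phylo$tip.label)
  expect_identical(mm$sites, sim$matrix$sites)
  expect_identical(mm$mat[, tr$phylo$tip.label],
                   sim$matrix$mat[, tr$phylo$tip.label])
})

test_that("false positives surviving replicate intersection scale as fp^2", {
  fp <- 0.02
  cfg <- tiny_config(genome_length = 200000L, n_genes = 0L,
                     mu_per_meter = 0, fp_rate = fp)
  g <- generate_genome(cfg)
  tr <- generate_architecture(2, topology = "star", branch_lengths = 1)
  sim <- simulate_somatic_mutations(g, tr, cfg)
  mm <- mutation_matrix(sim$matrix$sites,
                        sim$matrix$mat[, tr$phylo$tip.label, drop = FALSE])
  tab <- simulate_call_tables(mm, g, cfg)
  cs <- tab$calls[tab$calls$sample == "1" & tab$calls$caller == "A" &
                    tab$calls$threshold_set == "T40", ]
  surv <- intersect_replicates(cs[cs$replicate == 1, ],
                               cs[cs$replicate == 2, ])
  # per-site survival = fp^2 * P(same alt twice | both called) = fp^2 / 3
  lam <- cfg$genome_length * fp^2 / 3
  expect_gte(nrow(surv), qpois(0.005, lam))
  expect_lte(nrow(surv), qpois(0.995, lam))
})

test_that("inter-individual filters apply window, run and depth rules", {
  th <- filter_thresholds()
  depth <- rep(30L, 5000L)
  cand <- data.frame(contig = "contig_1",
                     pos = c(500L, 850L, 852L, 2000L, 3000L, 4000L))
  # indel at 700: 500 is 200 away (kept at this stage), 850 is 150 away
  # (removed), 852 is 152 away (retained)
  out <- filter_interindividual(cand, indel_sites = 700L,
                                depth_track = depth, thresholds = th)
  expect_false(850L %in% out$pos)
  expect_true(all(c(500L, 852L) %in% out$pos))
  # boundary: exactly 151 bp from the indel is still removed (inclusive)
  out151 <- filter_interindividual(data.frame(contig = "c", pos = 851L),
                                   indel_sites = 700L, depth_track = depth)
  expect_equal(nrow(out151), 0L)
  # zero-depth run of 11 sites excludes 151 bp flanks; run of 10 does not
  d11 <- depth; d11[2000:2010] <- 0L
  o11 <- filter_interindividual(data.frame(contig = "c",
                                           pos = c(1900L, 2160L, 2200L)),
                                indel_sites = integer(0), depth_track = d11)
  expect_setequal(o11$pos, 2200L)
  d10 <- depth; d10[2000:2009] <- 0L
  o10 <- filter_interindividual(data.frame(contig = "c", pos = 1900L),
                                indel_sites = integer(0), depth_track = d10)
  expect_equal(o10$pos, 1900L)
  # depth bounds: below 5 or above d + 3*sqrt(d) removed; "linear" mode = 4d
  dd <- rep(30L, 100L); dd[10] <- 4L; dd[20] <- 30L + 17L + 1L  # > 30+3*sqrt(30)
  cand2 <- data.frame(contig = "c", pos = c(10L, 20L, 30L))
  o2 <- filter_interindividual(cand2, integer(0), dd)
  expect_setequal(o2$pos, 30L)
  o3 <- filter_interindividual(cand2, integer(0), dd,
                               filter_thresholds(depth_upper = "linear"))
  expect_setequal(o3$pos, c(20L, 30L))
  expect_error(filter_interindividual(cand2, integer(0), integer(0)),
               "empty depth track")
})

test_that("inter-individual filtering equals a brute-force interval mask", {
  set.seed(21)
  L <- 3000L
  depth <- rpois(L, 20)
  depth[sample(1:L, 50)] <- 0L
  indels <- sort(sample(1:L, 5))
  cand <- data.frame(contig = "c", pos = sort(sample(1:L, 200)))
  out <- filter_interindividual(cand, indels, depth)
  # oracle: build a per-base removal mask
  mask <- rep(FALSE, L)
  for (i in indels) mask[max(1, i - 151):min(L, i + 151)] <- TRUE
  r <- rle(depth == 0)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1
  for (k in which(r$values & r$lengths > 10)) {
    mask[max(1, s[k] - 151):min(L, e[k] + 151)] <- TRUE
  }
  d <- mean(depth)
  ok <- !mask[cand$pos] & depth[cand$pos] >= 5 &
    depth[cand$pos] <= d + 3 * sqrt(d)
  expect_equal(out$pos, cand$pos[ok])
})
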