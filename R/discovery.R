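#' Hard-filter and support-filter thresholds
#'
#' Central container for every numeric threshold of the discovery
#' pipeline. Removal conditions are strict inequalities (a record exactly
#' at a threshold is retained), matching the GATK-style filter
#' expressions `QD < 2.0`, `QUAL < 30.0`, `SOR > 4.0`, `FS > 60.0`,
#' `MQ < 40.0`, `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`.
#'
#' @param qd_min,qual_min,mq_min,mqranksum_min,readpos_min Lower bounds.
#' @param sor_max,fs_max Upper bounds.
#' @param min_hq_reads Minimum high-quality (MQ > 20) reads required in
#'   every sample at a candidate site.
#' @param min_replicate_support Minimum alt-supporting reads required of
#'   a carrier in each biological replicate ("more than one read").
#' @param indel_window Exclusion window around indels, bp (inclusive).
#' @param zero_depth_run Zero-depth runs longer than this many
#'   consecutive sites trigger flank exclusion.
#' @param depth_min Minimum depth for inter-individual SNVs.
#' @param depth_upper `"sqrt"` for an upper bound of `d + 3*sqrt(d)`
#'   (mean depth plus three Poisson standard deviations) or `"linear"`
#'   for `4d`.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(qd_min = 2.0, qual_min = 30.0, sor_max = 4.0,
                              fs_max = 60.0, mq_min = 40.0,
                              mqranksum_min = -12.5, readpos_min = -8.0,
                              min_hq_reads = 5L, min_replicate_support = 2L,
                              indel_window = 151L, zero_depth_run = 10L,
                              depth_min = 5L,
                              depth_upper = c("sqrt", "linear")) {
  depth_upper <- match.arg(depth_upper)
  th <- list(qd_min = qd_min, qual_min = qual_min, sor_max = sor_max,
             fs_max = fs_max, mq_min = mq_min,
             mqranksum_min = mqranksum_min, readpos_min = readpos_min,
             min_hq_reads = as.integer(min_hq_reads),
             min_replicate_support = as.integer(min_replicate_support),
             indel_window = as.integer(indel_window),
             zero_depth_run = as.integer(zero_depth_run),
             depth_min = as.integer(depth_min),
             depth_upper = depth_upper)
  num <- unlist(th[1:12])
  if (any(!is.finite(num))) stop("all thresholds must be finite", call. = FALSE)
  structure(th, class = "filter_thresholds")
}

#' Apply GATK-style hard filters to call records
#'
#' A record is retained iff `QD >= 2.0`, `QUAL >= 30.0`, `SOR <= 4.0`,
#' `FS <= 60.0`, `MQ >= 40.0`, `MQRankSum >= -12.5` and
#' `ReadPosRankSum >= -8.0` (defaults; see [filter_thresholds()]).
#' A missing (`NA`) annotation fails its filter — conservative hard-filter
#' semantics — and the number of such rejections is reported as the
#' `n_missing_annotation` attribute.
#'
#' @param records Data frame of call records containing the seven
#'   annotation columns.
#' @param thresholds A [filter_thresholds()].
#' @return The retained records, with attributes `n_removed` and
#'   `n_missing_annotation`.
#' @export
apply_hard_filters <- function(records, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  miss <- setdiff(HARD_FILTER_ANNOTATIONS, names(records))
  if (length(miss)) {
    stop("missing annotation columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- with(records,
             QD >= thresholds$qd_min &
               QUAL >= thresholds$qual_min &
               SOR <= thresholds$sor_max &
               FS <= thresholds$fs_max &
               MQ >= thresholds$mq_min &
               MQRankSum >= thresholds$mqranksum_min &
               ReadPosRankSum >= thresholds$readpos_min)
  has_na <- !complete.cases(records[HARD_FILTER_ANNOTATIONS])
  ok[is.na(ok)] <- FALSE
  ok[has_na] <- FALSE
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!ok)
  attr(out, "n_missing_annotation") <- sum(has_na)
  out
}

check_same <- function(a, b, col, what) {
  ua <- unique(a[[col]]); ub <- unique(b[[col]])
  if (length(ua) > 1 || length(ub) > 1 || (length(ua) && length(ub) &&
                                           ua != ub)) {
    stop(sprintf("call sets must come from the same %s", what), call. = FALSE)
  }
}

#' Intersect the two biological replicates of a sample
#'
#' Keeps call records identical in both replicates, keyed on
#' (contig, position, ref, alt, genotype) — a heterozygous call in one
#' replicate does not match a homozygous call in the other.
#'
#' @param rep1,rep2 Call-record data frames from the same sample (and the
#'   same caller/threshold set).
#' @return The records of `rep1` whose key also occurs in `rep2`.
#' @export
intersect_replicates <- function(rep1, rep2) {
  check_same(rep1, rep2, "sample", "sample")
  if ("caller" %in% names(rep1)) check_same(rep1, rep2, "caller", "caller")
  out <- rep1[genotype_key(rep1) %in% genotype_key(rep2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect the call sets of two variant callers
#'
#' Same keying as [intersect_replicates()]: a site must be called, with
#' the same alleles and genotype, by both callers.
#'
#' @param caller_a,caller_b Call-record data frames from the same sample.
#' @return The records of `caller_a` whose key also occurs in `caller_b`.
#' @export
intersect_callers <- function(caller_a, caller_b) {
  check_same(caller_a, caller_b, "sample", "sample")
  out <- caller_a[genotype_key(caller_a) %in% genotype_key(caller_b), ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool call sets across calling thresholds
#'
#' Key-level union of the per-threshold call sets (duplicates removed);
#' the thresholds under which each site was detected are retained in a
#' `thresholds_detected` column.
#'
#' @param sets Named list of call-record data frames (e.g. `T40`, `T30`,
#'   `T20`).
#' @return One data frame with each key once.
#' @export
pool_thresholds <- function(sets) {
  sets <- Filter(function(s) nrow(s) > 0, sets)
  if (!length(sets)) {
    return(data.frame())
  }
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(sets))
  all <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    s$.src <- nm[i]
    s
  }))
  key <- genotype_key(all)
  prov <- tapply(all$.src, key, function(z) paste(sort(unique(z)),
                                                  collapse = ","))
  first <- !duplicated(key)
  out <- all[first, , drop = FALSE]
  out$thresholds_detected <- as.character(prov[key[first]])
  out$.src <- NULL
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply read-support filters across all samples
#'
#' A candidate site is removed if any sample (including the base) has
#' fewer than `min_hq_reads` high-quality reads in either replicate, or
#' if any variant-carrying sample fails to reach
#' `min_replicate_support` alt-supporting reads in *both* biological
#' replicates. Sites with no support data for some sample are rejected.
#'
#' @param candidates Pooled candidate records over all samples (must have
#'   `sample`, `contig`, `pos`, `ref`, `alt`, `genotype`).
#' @param support Per-site, per-sample support table with columns
#'   `contig`, `pos`, `sample`, `hq_rep1`, `hq_rep2`, `supp_rep1`,
#'   `supp_rep2` covering every sample at every candidate site.
#' @param thresholds A [filter_thresholds()].
#' @return The surviving candidate records.
#' @export
apply_support_filters <- function(candidates, support,
                                  thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (!nrow(candidates)) return(candidates)
  skey <- paste(support$contig, support$pos)
  ckey_site <- paste(candidates$contig, candidates$pos)
  hq_min_site <- tapply(pmin(support$hq_rep1, support$hq_rep2), skey, min)
  n_samples <- length(unique(support$sample))
  n_per_site <- tapply(support$sample, skey, function(z) length(unique(z)))

  bad_sites <- character(0)
  # (1) every sample must have >= min_hq_reads high-quality reads
  covered <- names(hq_min_site)[!is.na(hq_min_site) &
                                  hq_min_site >= thresholds$min_hq_reads &
                                  n_per_site == n_samples]
  bad_sites <- setdiff(unique(ckey_site), covered)
  # (2) every carrier needs >= min_replicate_support alt reads in both reps
  carrier_key <- paste(candidates$contig, candidates$pos, candidates$sample)
  sup_key <- paste(support$contig, support$pos, support$sample)
  mi <- match(carrier_key, sup_key)
  weak <- is.na(mi) |
    support$supp_rep1[mi] < thresholds$min_replicate_support |
    support$supp_rep2[mi] < thresholds$min_replicate_support
  bad_sites <- union(bad_sites, ckey_site[weak])
  out <- candidates[!(ckey_site %in% bad_sites), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sites_removed") <- length(intersect(bad_sites,
                                                   unique(ckey_site)))
  out
}

#' Collapse calls into a mutation matrix, one event per site
#'
#' Builds the sites x samples presence/absence matrix. Homozygous calls
#' contribute a single mutation event (a second hit at the same site is
#' more plausibly a genotyping artefact than a recurrent mutation).
#' Conflicting genotypes among carriers at one site trigger a warning and
#' the site is treated as heterozygous.
#'
#' @param callset Final per-sample candidate records (`sample`, `contig`,
#'   `pos`, `ref`, `alt`, `genotype`).
#' @param samples Sample (tip) labels defining the matrix columns;
#'   defaults to those present in `callset`.
#' @return A [mutation_matrix()].
#' @export
collapse_homozygous <- function(callset, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(callset$sample))
  if (!nrow(callset)) {
    return(mutation_matrix(
      data.frame(contig = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), genotype = character(0)),
      matrix(FALSE, 0, length(samples),
             dimnames = list(NULL, samples))))
  }
  key <- site_key(callset)
  usites <- !duplicated(key)
  sites <- callset[usites, c("contig", "pos", "ref", "alt"), drop = FALSE]
  ukey <- key[usites]
  gt <- vapply(split(callset$genotype, key)[ukey], function(z) {
    u <- unique(z)
    if (length(u) > 1) {
      warning("conflicting genotypes among carriers; treating site as het",
              call. = FALSE)
      return("het")
    }
    u
  }, character(1))
  sites$genotype <- unname(gt)
  mat <- matrix(FALSE, nrow(sites), length(samples),
                dimnames = list(NULL, samples))
  mat[cbind(match(key, ukey), match(callset$sample, samples))] <- TRUE
  ord <- order(sites$contig, sites$pos, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  mutation_matrix(sites, mat[ord, , drop = FALSE])
}

#' Run the full somatic SNV discovery pipeline
#'
#' Per sample, caller and threshold set: hard filters, then replicate
#' intersection; per threshold set: caller intersection; then pooling
#' across threshold sets; then the cross-sample read-support filters; and
#' finally homozygous collapsing into a [mutation_matrix()].
#'
#' @param calls Call records as produced by [simulate_call_tables()] (or
#'   assembled from VCFs via [read_calls_vcf()]).
#' @param support Per-site, per-sample support table.
#' @param thresholds A [filter_thresholds()].
#' @param samples Optional sample labels for the matrix columns.
#' @return A [mutation_matrix()].
#' @export
discover_somatic <- function(calls, support,
                             thresholds = filter_thresholds(),
                             samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  per_sample <- lapply(samples, function(s) {
    cs <- calls[calls$sample == s, , drop = FALSE]
    if (!nrow(cs)) return(cs[0, , drop = FALSE])
    per_threshold <- lapply(c("T40", "T30", "T20"), function(th) {
      per_caller <- lapply(c("A", "B"), function(cl) {
        sub <- cs[cs$threshold_set == th & cs$caller == cl, , drop = FALSE]
        r1 <- apply_hard_filters(sub[sub$replicate == 1, , drop = FALSE],
                                 thresholds)
        r2 <- apply_hard_filters(sub[sub$replicate == 2, , drop = FALSE],
                                 thresholds)
        if (!nrow(r1) || !nrow(r2)) return(r1[0, , drop = FALSE])
        intersect_replicates(r1, r2)
      })
      if (!nrow(per_caller[[1]]) || !nrow(per_caller[[2]])) {
        return(per_caller[[1]][0, , drop = FALSE])
      }
      intersect_callers(per_caller[[1]], per_caller[[2]])
    })
    names(per_threshold) <- c("T40", "T30", "T20")
    pool_thresholds(per_threshold)
  })
  cand <- do.call(rbind, Filter(nrow, per_sample))
  if (is.null(cand) || !nrow(cand)) {
    return(collapse_homozygous(calls[0, c("sample", "contig", "pos", "ref",
                                          "alt", "genotype")],
                               samples = samples))
  }
  kept <- apply_support_filters(cand, support, thresholds)
  collapse_homozygous(kept[, c("sample", "contig", "pos", "ref", "alt",
                               "genotype")], samples = samples)
}

#' Filters for inter-individual SNV candidates
#'
#' Applies, in order: (1) removal of SNVs within `indel_window` bp
#' (inclusive) of an indel; (2) removal of SNVs within `indel_window` bp
#' of any site belonging to a run of more than `zero_depth_run`
#' consecutive zero-depth sites; (3) removal of SNVs with depth below
#' `depth_min` or above the upper bound (`d + 3*sqrt(d)` by default, or
#' `4d` with `depth_upper = "linear"`, where `d` is the mean depth over
#' all sites of the track, computed before any removal).
#'
#' @param candidates Data frame of candidate SNVs with `contig`, `pos`.
#' @param indel_sites Integer positions of indels (same contig).
#' @param depth_track Integer vector of per-site depths covering the
#'   whole contig (`depth_track[pos]` is the depth at `pos`).
#' @param thresholds A [filter_thresholds()].
#' @return The surviving candidates, with an attribute `removed_by`
#'   giving per-stage removal counts.
#' @export
filter_interindividual <- function(candidates, indel_sites, depth_track,
                                   thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (!length(depth_track)) stop("empty depth track", call. = FALSE)
  if (!nrow(candidates)) return(candidates)
  if (any(candidates$pos > length(depth_track))) {
    stop("depth track does not cover all candidate positions", call. = FALSE)
  }
  w <- thresholds$indel_window
  removed <- c(indel = 0L, zero_run = 0L, depth = 0L)

  near_any <- function(pos, anchors) {
    if (!length(anchors)) return(rep(FALSE, length(pos)))
    sa <- sort(anchors)
    i <- findInterval(pos, sa)
    lo <- ifelse(i >= 1, pos - sa[pmax(i, 1L)], Inf)
    hi <- ifelse(i < length(sa), sa[pmin(i + 1L, length(sa))] - pos, Inf)
    pmin(lo, hi) <= w
  }

  drop1 <- near_any(candidates$pos, indel_sites)
  removed["indel"] <- sum(drop1)
  cand <- candidates[!drop1, , drop = FALSE]

  zero <- depth_track == 0
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths > thresholds$zero_depth_run)
  run_sites <- unlist(lapply(long, function(k) starts[k]:ends[k]),
                      use.names = FALSE)
  drop2 <- near_any(cand$pos, run_sites)
  removed["zero_run"] <- sum(drop2)
  cand <- cand[!drop2, , drop = FALSE]

  d <- mean(depth_track)
  upper <- if (thresholds$depth_upper == "sqrt") d + 3 * sqrt(d) else 4 * d
  dp <- depth_track[cand$pos]
  drop3 <- dp < thresholds$depth_min | dp > upper
  removed["depth"] <- sum(drop3)
  out <- cand[!drop3, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_by") <- removed
  attr(out, "mean_depth") <- d
  attr(out, "depth_upper_bound") <- upper
  out
}
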