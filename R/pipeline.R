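#' Write call records to VCF v4.2
#'
#' One file per sample/replicate/caller; records are the unique sites of
#' that combination with the hard-filter annotations and the detecting
#' threshold sets in INFO, and the genotype in the sample column.
#'
#' @param calls Call-record data frame ([simulate_call_tables()] layout).
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_call_tables <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combos <- unique(calls[, c("sample", "replicate", "caller")])
  files <- character(0)
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    sub <- calls[calls$sample == cb$sample & calls$replicate == cb$replicate &
                   calls$caller == cb$caller, , drop = FALSE]
    key <- genotype_key(sub)
    ts <- tapply(sub$threshold_set, key, function(z)
      paste(sort(unique(z)), collapse = ","))
    first <- sub[!duplicated(key), , drop = FALSE]
    first$ts <- as.character(ts[key[!duplicated(key)]])
    first <- first[order(first$contig, first$pos), , drop = FALSE]
    path <- file.path(dir, sprintf("%s_rep%d_caller%s.vcf",
                                   cb$sample, cb$replicate, cb$caller))
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=somatree",
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Qual by depth\">",
      "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
      "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
      "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
      "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
      "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read pos rank sum\">",
      "##INFO=<ID=TS,Number=.,Type=String,Description=\"Detecting threshold sets\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
              cb$sample))
    body <- if (nrow(first)) sprintf(
      "%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tDP=%d;QD=%.3f;SOR=%.3f;FS=%.3f;MQ=%.3f;MQRankSum=%.3f;ReadPosRankSum=%.3f;TS=%s\tGT\t%s",
      first$contig, first$pos, first$ref, first$alt, first$QUAL,
      first$depth, first$QD, first$SOR, first$FS, first$MQ,
      first$MQRankSum, first$ReadPosRankSum, first$ts,
      ifelse(first$genotype == "hom", "1/1", "0/1")) else character(0)
    writeLines(c(hdr, body), path)
    files <- c(files, path)
  }
  files
}

#' Read a somatree call-table VCF
#'
#' Parses one per-sample/replicate/caller VCF (as written by
#' [write_call_tables()]) back into call records, expanding the TS INFO
#' field into one record per detecting threshold set.
#'
#' @param path VCF path.
#' @return Call-record data frame.
#' @export
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sample <- colnames(v@gt)[2]
  fn <- basename(path)
  replicate <- as.integer(sub(".*_rep(\\d+)_.*", "\\1", fn))
  caller <- sub(".*_caller([A-Z])\\.vcf$", "\\1", fn)
  getinfo <- function(key, as = "numeric") {
    vcfR::extract.info(v, element = key, as.numeric = as == "numeric")
  }
  gt <- sub(":.*", "", v@gt[, 2])
  base <- data.frame(
    sample = sample, replicate = replicate, caller = caller,
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    genotype = ifelse(gt == "1/1", "hom", "het"),
    depth = as.integer(getinfo("DP")),
    QD = getinfo("QD"), QUAL = as.numeric(fix$QUAL),
    SOR = getinfo("SOR"), FS = getinfo("FS"), MQ = getinfo("MQ"),
    MQRankSum = getinfo("MQRankSum"),
    ReadPosRankSum = getinfo("ReadPosRankSum"),
    ts = getinfo("TS", as = "character"),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    th <- strsplit(base$ts[i], ",")[[1]]
    r <- base[rep(i, length(th)), , drop = FALSE]
    r$threshold_set <- th
    r
  }))
  out$ts <- NULL
  rownames(out) <- NULL
  out
}

#' Write a mutation matrix as a presence/absence TSV
#'
#' @param matrix A [mutation_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mutation_matrix <- function(matrix, path) {
  df <- cbind(matrix$sites, as.data.frame(matrix$mat * 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Chains the stages simulate, discover, njtree, rates, spectrum,
#' selection and model on synthetic data, writing each stage's artifacts
#' in standard formats (FASTA, GFF3, VCF, Newick, TSV, JSON) under
#' `out_dir`, plus a run manifest with seeds and file hashes. Re-running
#' with an identical configuration reproduces identical artifacts.
#'
#' @param config A [sim_config()], or the path to a YAML file of
#'   [sim_config()] arguments.
#' @param out_dir Output directory.
#' @param stages Subset of
#'   `c("simulate", "discover", "njtree", "rates", "spectrum",
#'   "selection", "model")`; later stages require the earlier ones in
#'   the same run.
#' @param tree Optional [physical_tree()]; by default a seven-tip
#'   architecture is generated from the configuration seed.
#' @param callable_sites Callable sites for rate estimation (defaults to
#'   the simulated genome length).
#' @param age Tree age in years for the per-year rate.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "discover", "njtree",
                                    "rates", "spectrum", "selection",
                                    "model"),
                         tree = NULL, callable_sites = NULL, age = 100) {
  if (is.character(config)) {
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "somatree",
                   version = as.character(utils::packageVersion("somatree")),
                   seed = config$seed, stages = stages, outputs = list())
  art <- function(stage, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]],
                                    setNames(unname(tools::md5sum(path)),
                                             basename(path)))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  genome <- sim <- tables <- mm <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      genome <<- generate_genome(config)
      if (is.null(tree)) {
        tree <<- generate_architecture(7L, seed = config$seed, age = age)
      }
      sim <<- simulate_somatic_mutations(genome, tree, config)
      tables <<- simulate_call_tables(sim, genome, config)
      write_genome(genome, fasta = file.path(out_dir, "genome.fasta"),
                   gff = file.path(out_dir, "genome.gff3"))
      write_newick(tree$phylo, file.path(out_dir, "architecture.nwk"))
      jsonlite::write_json(
        list(mu_per_meter = sim$truth$mu_per_meter,
             n_mutations = nrow(sim$truth$true_mutations),
             true_mutations = sim$truth$true_mutations),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      vdir <- file.path(out_dir, "calls")
      write_call_tables(tables$calls, vdir)
      write.table(tables$support, file.path(out_dir, "support.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      art("simulate", file.path(out_dir, "genome.fasta"))
      art("simulate", file.path(out_dir, "genome.gff3"))
      art("simulate", file.path(out_dir, "architecture.nwk"))
      art("simulate", file.path(out_dir, "truth.json"))
      art("simulate", file.path(out_dir, "support.tsv"))
    })
  }
  if ("discover" %in% stages) {
    run_stage("discover", function() {
      mm <<- discover_somatic(tables$calls, tables$support,
                              samples = tree$phylo$tip.label)
      write_mutation_matrix(mm, file.path(out_dir, "somatic_snvs.tsv"))
      art("discover", file.path(out_dir, "somatic_snvs.tsv"))
    })
  }
  if ("njtree" %in% stages) {
    run_stage("njtree", function() {
      d <- pairwise_snv_distance(mm)
      write.table(d, file.path(out_dir, "snv_distances.tsv"), sep = "\t",
                  quote = FALSE)
      nj <- neighbor_joining(d)
      write_newick(nj, file.path(out_dir, "nj_tree.nwk"))
      cong <- topology_congruence(nj, tree)
      jsonlite::write_json(cong, file.path(out_dir, "congruence.json"),
                           auto_unbox = TRUE, digits = NA)
      art("njtree", file.path(out_dir, "nj_tree.nwk"))
      art("njtree", file.path(out_dir, "congruence.json"))
    })
  }
  fit <- NULL
  if ("rates" %in% stages) {
    run_stage("rates", function() {
      R <- if (is.null(callable_sites)) config$genome_length else callable_sites
      fit <<- fit_mutation_rates(mm, tree, callable_sites = R, age = age)
      rates_df <- data.frame(
        quantity = c("slope_snv_per_m", "mu_per_meter", "mu_per_year_mean"),
        value = c(fit$slope, fit$mu_g,
                  if (is.null(fit$mu_y_mean)) NA else fit$mu_y_mean),
        ci_low = c(fit$slope_ci[1], fit$mu_g_ci[1],
                   if (is.null(fit$mu_y_ci)) NA else fit$mu_y_ci[1]),
        ci_high = c(fit$slope_ci[2], fit$mu_g_ci[2],
                    if (is.null(fit$mu_y_ci)) NA else fit$mu_y_ci[2]))
      write.table(rates_df, file.path(out_dir, "rates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      art("rates", file.path(out_dir, "rates.tsv"))
    })
  }
  if ("spectrum" %in% stages) {
    run_stage("spectrum", function() {
      sp <- mutation_spectrum(mm$sites, genome)
      df <- data.frame(class = names(sp$values), fraction = sp$values,
                       raw_count = as.integer(sp$raw_counts))
      write.table(df, file.path(out_dir, "spectrum.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cpg <- cpg_enrichment(mm$sites, genome)
      jsonlite::write_json(cpg, file.path(out_dir, "cpg_enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      art("spectrum", file.path(out_dir, "spectrum.tsv"))
      art("spectrum", file.path(out_dir, "cpg_enrichment.json"))
    })
  }
  if ("selection" %in% stages) {
    run_stage("selection", function() {
      st <- tryCatch(selection_test(mm$sites, genome),
                     error = function(e) NULL)
      res <- if (is.null(st)) list(note = "too few coding SNVs to test") else
        list(p_value = st$p_value, reject = st$reject,
             observed_nonsyn = st$observed_nonsyn,
             observed_total = st$observed_total,
             expected_fraction = st$expected_fraction)
      jsonlite::write_json(res, file.path(out_dir, "selection.json"),
                           auto_unbox = TRUE, digits = NA)
      art("selection", file.path(out_dir, "selection.json"))
    })
  }
  if ("model" %in% stages) {
    run_stage("model", function() {
      rep <- assess_consistency(3.7, 3.2)
      jsonlite::write_json(
        list(observed_ratio = 3.7, tau_ratio = 3.2, regime = rep$regime,
             gap = rep$gap, message = rep$message),
        file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
      art("model", file.path(out_dir, "model.json"))
    })
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
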