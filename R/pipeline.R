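# One-config orchestration of the full synthetic-data analysis:
# simulate -> count -> test -> loci/enrichment -> profiles -> duplex ->
# predict -> race tails, with deterministic stage seeding and a
# machine-readable run manifest.

default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    simulate = list(
      n_chrom = 2L, chrom_len = 150000L, n_genes = 120L,
      gene_len_range = c(1400L, 2400L), n_targets = 30L,
      sites_per_gene = 1L, mirna_len = 21L, replicates = 2L,
      bg_mean = 5, bg_phi = 0.2, ballast_loci = 20L, ballast_mean = 1000,
      signal_mean = 100, fold_change = 8,
      peak_halfwidth = 150L, frac21 = 0.8, size_min = 19L, size_max = 26L,
      direction_probs = c("5p" = 0.7, "3p" = 0.2, both = 0.1),
      rdr6_dependence = 1.0, mismatch_5p = 0L, mismatch_3p = 0L
    ),
    windows = list(window_length = 300L, step = 150L,
                   size_min = 19L, size_max = 26L),
    diff = list(alpha = 0.05, adjust = "none", min_total_count = 5L,
                normalization = "total-count",
                control = "SKI2_RDR6", case = "ski2_RDR6"),
    loci = list(gap = 0L),
    profile = list(flank = 500L, min_reads = 10L, exclusivity = 0.9),
    duplex = list(temp_c = 21, gu = TRUE, mode = "halves"),
    predict = list(tau = 2.0, p0 = 0.5, tau_grid = c(0, 1, 2, 3)),
    racetails = list(n_clones = 80L, min_match = 20L,
                     tail_spectrum = setNames(
                       c(0.7, 0.1, 0.05, 0.05, 0.05, 0.03, 0.02),
                       c("", "U", "UU", "UUU", "A", "AA", "C")))
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section ", path, " must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  }
  for (k in names(user)) {
    kp <- paste0(path, k, ".")
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]), kp)
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      tmpl <- defaults[[k]]
      if (is.numeric(tmpl) && !is.numeric(v)) {
        stop("config key ", path, k, " must be numeric")
      }
      if (is.numeric(tmpl) && is.numeric(v)) {
        storage.mode(v) <- storage.mode(tmpl)
      }
      defaults[[k]] <- v
    }
  }
  defaults
}

check_config <- function(cfg) {
  if (cfg$windows$window_length <= 0L) stop("window length must be > 0")
  if (cfg$windows$step <= 0L || cfg$windows$step > cfg$windows$window_length) {
    stop("need 0 < step <= window_length")
  }
  if (!(cfg$diff$alpha > 0 && cfg$diff$alpha < 1)) stop("need 0 < alpha < 1")
  if (cfg$predict$tau < 0) stop("tau must be >= 0")
  if (cfg$simulate$replicates < 2L) stop("need >= 2 replicates")
  cfg
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills every missing key with its
#' documented default (windows 300/150, sizes 19-26, alpha 0.05, tau 2.0,
#' 21 degrees C, ...), rejects unknown keys with their paths, and checks
#' value sanity.  An empty file yields the pure-default configuration.
#'
#' @param config path to a YAML file, or a (possibly partial) config
#'   list, or NULL for pure defaults.
#' @return a normalized `pipeline_config` list.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    y <- yaml::read_yaml(config)
    if (is.null(y)) list() else y
  } else {
    config
  }
  cfg <- check_config(merge_config(default_config(), user))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[transitr] ", ...)
}

digest_file <- function(path) digest::digest(file = path, algo = "md5")

#' Run the full pipeline on synthetic data
#'
#' Simulates the reference world and reads, counts scanning windows,
#' tests differential accumulation (case vs control genotype, plus the
#' rdr6 comparison for RDR6 dependence), merges loci and tests
#' miRNA-target enrichment, builds cleavage-site profiles with direction
#' calls, computes duplex fragment energies, evaluates the
#' energy-based side prediction with its exact binomial tail, and
#' processes simulated RACE clones.  All stage outputs are written under
#' `outdir`; reruns with the same config produce byte-identical files.
#'
#' @param config anything accepted by [validate_config()].
#' @param outdir output directory.
#' @return the run report (list), invisibly also written as
#'   `report.json`; `MANIFEST.json` records per-stage outputs and
#'   digests.
#' @export
run_pipeline <- function(config = NULL, outdir) {
  cfg <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(complete = FALSE, stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "MANIFEST.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  on.exit(write_manifest())
  report <- list(parameters = unclass(cfg))
  add_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(
      files = files,
      md5 = vapply(files, digest_file, "")
    )
  }

  # -- simulate -----------------------------------------------------------
  log_msg(cfg, "stage simulate")
  sim_cfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$simulate))
  reference <- simulate_reference(sim_cfg)
  reads <- simulate_reads(reference, sim_cfg)
  simdir <- file.path(outdir, "sim")
  paths <- write_simulation(reference, reads, simdir)
  add_stage("simulate", unname(paths))
  report$simulate <- list(
    n_genes = nrow(reference$annotation),
    n_target_sites = nrow(reference$target_sites),
    n_reads = nrow(reads$reads)
  )

  # -- windows ------------------------------------------------------------
  log_msg(cfg, "stage windows")
  wcfg <- window_config(cfg$windows$window_length, cfg$windows$step,
                        cfg$windows$size_min, cfg$windows$size_max)
  chrom_lengths <- setNames(nchar(reference$genome), names(reference$genome))
  win <- make_windows(chrom_lengths, wcfg)
  wc <- count_reads(reads$reads, win, wcfg, samples = reads$samples)
  f_counts <- file.path(outdir, "window_counts.tsv")
  write_window_counts(wc, f_counts)
  add_stage("windows", f_counts)
  report$windows <- list(n_windows = nrow(win),
                         library_sizes = as.list(wc$library_sizes))

  # -- diff ---------------------------------------------------------------
  log_msg(cfg, "stage diff")
  dcfg <- diff_config(cfg$diff$alpha, cfg$diff$adjust,
                      cfg$diff$min_total_count, cfg$diff$normalization)
  geno_samples <- function(g) reads$samples[startsWith(reads$samples, g)]
  res_main <- diff_accumulation(wc, geno_samples(cfg$diff$control),
                                geno_samples(cfg$diff$case), dcfg)
  res_rdr6 <- diff_accumulation(wc, geno_samples("SKI2_rdr6"),
                                geno_samples("ski2_rdr6"), dcfg)
  f_diff <- file.path(outdir, "diff_main.tsv")
  f_diff2 <- file.path(outdir, "diff_rdr6.tsv")
  write_tsv(res_main, f_diff)
  write_tsv(res_rdr6, f_diff2)
  add_stage("diff", c(f_diff, f_diff2))
  report$diff <- list(
    phi = attr(res_main, "phi"),
    n_tested = sum(!is.na(res_main$p)),
    n_significant = sum(res_main$significant)
  )

  # -- loci ---------------------------------------------------------------
  log_msg(cfg, "stage loci")
  loci <- merge_windows(res_main, gap = cfg$loci$gap)
  loci <- annotate_loci(loci, reference$annotation, reference$target_sites)
  enr <- enrichment_test(loci[loci$direction == "up_in_case", , drop = FALSE],
                         reference$annotation$gene_id,
                         unique(reference$target_sites$transcript_id))
  f_loci <- file.path(outdir, "loci.tsv")
  write_tsv(loci, f_loci)
  f_enr <- file.path(outdir, "enrichment.json")
  jsonlite::write_json(
    list(table = as.list(enr$table), odds_ratio = enr$odds_ratio,
         p_one_sided = enr$p_one_sided, p_two_sided = enr$p_two_sided),
    f_enr, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  add_stage("loci", c(f_loci, f_enr))
  report$loci <- list(
    n_loci = nrow(loci),
    n_up = sum(loci$direction == "up_in_case"),
    n_down = sum(loci$direction == "down_in_case"),
    enrichment_p_one_sided = enr$p_one_sided
  )

  # -- profiles & direction calls ----------------------------------------
  log_msg(cfg, "stage profile")
  case_samples <- geno_samples(cfg$diff$case)
  case_reads <- reads$reads[reads$reads$sample_id %in% case_samples, ,
                            drop = FALSE]
  case_lib <- sum(reads$library_sizes[case_samples])
  sites <- reference$target_sites
  calls <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    g <- reference$annotation[
      reference$annotation$gene_id == sites$transcript_id[i], ]
    prof <- build_profile(case_reads, g, sites[i, ],
                          flank = cfg$profile$flank, library_size = case_lib)
    dc <- classify_direction(prof, cfg$profile$min_reads,
                             cfg$profile$exclusivity)
    calls[[i]] <- data.frame(
      transcript_id = sites$transcript_id[i],
      mirna_name = sites$mirna_name[i],
      cleavage = prof$cleavage, n5 = prof$n5, n3 = prof$n3,
      f = dc$f, call = dc$call, stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, calls)
  f_calls <- file.path(outdir, "direction_calls.tsv")
  write_tsv(calls, f_calls)
  add_stage("profile", f_calls)
  report$profile <- list(calls = as.list(table(calls$call)))

  # -- duplex -------------------------------------------------------------
  log_msg(cfg, "stage duplex")
  params <- nn_params()
  energies <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    site_seq <- as_rna(rna_revcomp(sites$mirna_seq[i]))
    # recover the actual (possibly mismatch-injected) site sequence from
    # the genome via the gene's transcript
    g <- reference$annotation[
      reference$annotation$gene_id == sites$transcript_id[i], ]
    tx <- gene_transcript_seq(reference$genome[[g$chrom]], g)
    site_seq <- as_rna(substr(tx, sites$start[i] + 1L, sites$end[i]))
    fe <- fragment_energies(sites$mirna_seq[i], site_seq,
                            cleavage_offset = sites$end[i] - sites$start[i] - 10L,
                            params = params, temp_c = cfg$duplex$temp_c,
                            mode = cfg$duplex$mode, gu = cfg$duplex$gu)
    energies[[i]] <- data.frame(
      transcript_id = sites$transcript_id[i],
      mirna_name = sites$mirna_name[i],
      dG5 = fe$dG5, dG3 = fe$dG3, ddG = fe$ddG, stringsAsFactors = FALSE
    )
  }
  energies <- do.call(rbind, energies)
  f_dg <- file.path(outdir, "fragment_energies.tsv")
  write_tsv(energies, f_dg)
  add_stage("duplex", f_dg)
  report$duplex <- list(n_sites = nrow(energies))

  # -- predict ------------------------------------------------------------
  log_msg(cfg, "stage predict")
  eligible <- calls$transcript_id %in%
    sites$transcript_id[sites$n_sites == 1L]
  pred_tab <- merge(calls, energies, by = c("transcript_id", "mirna_name"))
  pred_tab$predicted <- mapply(predict_side, pred_tab$dG5, pred_tab$dG3,
                               MoreArgs = list(tau = cfg$predict$tau))
  pred_tab$correct <- pred_tab$predicted == pred_tab$call
  ev <- evaluate_predictions(pred_tab$predicted, pred_tab$call,
                             eligible = pred_tab$transcript_id %in%
                               sites$transcript_id[sites$n_sites == 1L])
  tail_p <- binomial_upper_tail(ev$k, ev$n, cfg$predict$p0)
  grid <- lapply(cfg$predict$tau_grid, function(tau) {
    p <- mapply(predict_side, pred_tab$dG5, pred_tab$dG3,
                MoreArgs = list(tau = tau))
    e <- evaluate_predictions(p, pred_tab$call,
                              eligible = pred_tab$transcript_id %in%
                                sites$transcript_id[sites$n_sites == 1L])
    list(tau = tau, k = e$k, n = e$n,
         p = binomial_upper_tail(e$k, e$n, cfg$predict$p0))
  })
  f_pred <- file.path(outdir, "predictions.tsv")
  write_tsv(pred_tab, f_pred)
  f_predsum <- file.path(outdir, "prediction_summary.json")
  jsonlite::write_json(list(k = ev$k, n = ev$n, binomial_tail = tail_p,
                            tau_grid = grid),
                       f_predsum, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  add_stage("predict", c(f_pred, f_predsum))
  report$predict <- list(k = ev$k, n = ev$n, binomial_tail = tail_p)

  # -- racetails ----------------------------------------------------------
  log_msg(cfg, "stage racetails")
  g1 <- reference$annotation[
    reference$annotation$gene_id == sites$transcript_id[1L], ]
  tx1 <- gene_transcript_seq(reference$genome[[g1$chrom]], g1)
  c1 <- sites$end[1L] - 10L
  fragment <- as_rna(substr(tx1, 1L, c1))
  downstream <- as_rna(substr(tx1, c1 + 1L, nchar(tx1)))
  race <- simulate_race_clones(fragment, cfg$racetails$n_clones,
                               tail_spectrum = cfg$racetails$tail_spectrum,
                               seed = stage_seed(cfg$seed, "racetails"))
  rc <- lapply(race$clones, extract_tail, reference = fragment,
               min_match = cfg$racetails$min_match, downstream = downstream)
  rc_df <- data.frame(
    id = names(race$clones),
    matched_len = vapply(rc, `[[`, 0L, "matched_len"),
    tail = vapply(rc, `[[`, "", "tail"),
    category = vapply(rc, `[[`, "", "category"),
    stringsAsFactors = FALSE
  )
  rc_df$class <- ifelse(nzchar(rc_df$tail) & rc_df$category == "fragment",
                        vapply(rc_df$tail, function(t)
                          if (nzchar(t)) classify_tail(t) else "", ""),
                        "")
  summ <- summarize_tails(rc_df)
  f_race <- file.path(outdir, "race_clones.tsv")
  write_tsv(rc_df, f_race)
  f_racesum <- file.path(outdir, "race_summary.json")
  jsonlite::write_json(
    list(n_clones = summ$n_clones, n_fragment = summ$n_fragment,
         n_tailed = summ$n_tailed, spectrum = as.list(summ$spectrum),
         class_totals = as.list(summ$class_totals)),
    f_racesum, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  add_stage("racetails", c(f_race, f_racesum))
  report$racetails <- list(n_tailed = summ$n_tailed,
                           n_fragment = summ$n_fragment)

  manifest$complete <- TRUE
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

# unspliced transcript sequence of a gene from its chromosome sequence
gene_transcript_seq <- function(chrom_seq, gene) {
  s <- substr(chrom_seq, gene$start + 1L, gene$end)
  if (gene$strand == "-") s <- dna_revcomp(s)
  s
}
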