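#' Default desk-scale benchmark configuration
#'
#' Bundles simulation and experiment parameters for the end-to-end runs: a
#' K-haplotype panel over M markers (10% of haplotypes in a mildly diverged
#' subpopulation), `n_eval` evaluation individuals simulated to
#' `source_coverage` for gold-standard calling and downsampled for
#' imputation input, and optional background "ancient" individuals at mixed
#' coverages that enlarge the joint study sample.
#'
#' @param seed root seed; with the configuration it fully determines every
#'   emitted number.
#' @param K,M,theta_sim,rho_scale,eps,delta,transition_fraction,chrom_length,n_diverged,divergence
#'   see [sim_config()].
#' @param n_eval number of evaluation individuals.
#' @param n_background number of background study individuals for joint mode.
#' @param background_coverages coverages recycled over background individuals.
#' @param source_coverage depth of the gold-standard source reads.
#' @param study_theta miscopy rate of the study-individual mosaics.
#' @param hmm_theta miscopy probability of the imputation HMM.
#' @param min_gp posterior probability threshold of the in-depth filter.
#' @param segment_size,overlap imputation windowing (see [plan_windows()]).
#' @param joint_iterations panel-augmentation passes in joint mode.
#' @param n_modern size of the synthetic modern panel for the reference PCA.
#' @return A `bench_config` list.
#' @export
benchmark_config <- function(seed = 1L, K = 200L, M = 20000L, n_eval = 5L,
                             n_background = 0L,
                             background_coverages = c(0.5, 1, 2, 4),
                             source_coverage = 30,
                             study_theta = 0.001,
                             theta_sim = 0.02, rho_scale = 5e-7,
                             eps = 0.01, delta = 0.02,
                             transition_fraction = 2 / 3,
                             chrom_length = 2e7,
                             n_diverged = round(K / 10), divergence = 0.02,
                             hmm_theta = 1e-3, min_gp = 0.99,
                             segment_size = 50000L, overlap = 25000L,
                             joint_iterations = 2L, n_modern = 60L) {
  cfg <- as.list(environment())
  cfg$sim <- sim_config(K = K, M = M, N = n_eval, theta_sim = theta_sim,
                        rho_scale = rho_scale, coverage = source_coverage,
                        eps = eps, delta = delta,
                        transition_fraction = transition_fraction,
                        chrom_length = chrom_length, n_diverged = n_diverged,
                        divergence = divergence, seed = seed)
  if (cfg$min_gp <= 0 || cfg$min_gp > 1) stop("min_gp must lie in (0, 1]")
  if (cfg$n_eval < 1L) stop("n_eval must be >= 1")
  class(cfg) <- "bench_config"
  cfg
}

#' Simulate the benchmark data set
#'
#' Generates the panel, the evaluation individuals with their high-coverage
#' source reads and gold-standard calls, and (if configured) the background
#' study individuals with genotype likelihoods at their own coverages,
#' already deamination-filtered.
#'
#' @param cfg a [benchmark_config()].
#' @return A `bench_data` list: `cfg`, `panel`, `truth`, `hq_pileups`,
#'   `truth_calls`, `maf`, `background` (NULL or list with `truth`,
#'   `pileups`, `gl`).
#' @export
simulate_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "bench_config"))
  panel <- generate_panel(cfg$sim)
  truth <- sample_study_individuals(panel, cfg$n_eval,
                                    theta_sim = cfg$study_theta,
                                    divergence_rate = 0,
                                    seed = child_seed(cfg$seed, "eval"))
  hq <- simulate_reads(truth, panel$markers, cfg$sim,
                       coverage = cfg$source_coverage, stage = "reads-eval")
  calls <- call_hq_truth(hq, cfg$eps)
  background <- NULL
  if (cfg$n_background > 0L) {
    bg_truth <- sample_study_individuals(panel, cfg$n_background,
                                         theta_sim = cfg$study_theta,
                                         divergence_rate = 0,
                                         seed = child_seed(cfg$seed, "background"))
    covs <- rep_len(cfg$background_coverages, cfg$n_background)
    bg_pile <- simulate_reads(bg_truth, panel$markers, cfg$sim,
                              coverage = covs, stage = "reads-background")
    bg_gl <- compute_gl(bg_pile, cfg$eps)
    bg_gl <- apply_site_mask(bg_gl, deamination_site_filter(panel$markers, bg_gl))
    background <- list(truth = bg_truth, pileups = bg_pile, gl = bg_gl)
  }
  structure(list(cfg = cfg, panel = panel, truth = truth, hq_pileups = hq,
                 truth_calls = calls, maf = panel$markers$maf,
                 background = background),
            class = "bench_data")
}

#' One imputation run of the evaluation individuals
#'
#' Downsample the gold-standard source reads to `coverage`, compute genotype
#' likelihoods, apply the deamination site filter, and impute against the
#' chosen panel, either individually or jointly with the background study
#' sample.
#'
#' @param bench a `bench_data`.
#' @param coverage target coverage of the imputation input.
#' @param panel_mode `"FULL"` (all panel haplotypes) or `"SUBSET"` (the
#'   `"main"` population only, emulating a smaller population-specific
#'   panel).
#' @param joint impute the study sample jointly (panel augmentation) or each
#'   individual alone.
#' @return List with `imputed` (evaluation individuals only), `downsampled`
#'   pileups, filtered `gl`, deamination `kept` masks, and the overlap
#'   `mask`.
#' @export
impute_run <- function(bench, coverage, panel_mode = c("FULL", "SUBSET"),
                       joint = TRUE) {
  stopifnot(inherits(bench, "bench_data"))
  panel_mode <- match.arg(panel_mode)
  cfg <- bench$cfg
  if (any(coverage > bench$hq_pileups$realized_coverage)) {
    stop("coverage level exceeds the simulated source coverage")
  }
  ds <- downsample(bench$hq_pileups, coverage,
                   seed = child_seed(cfg$seed, paste0("ds-", format(coverage))))
  gl <- compute_gl(ds, cfg$eps)
  kept <- deamination_site_filter(bench$panel$markers, gl)
  glf <- apply_site_mask(gl, kept)
  ipanel <- if (panel_mode == "FULL") bench$panel else
    subset_panel(bench$panel, "main")
  params <- hmm_params(ipanel, theta = cfg$hmm_theta)
  if (joint) {
    gl_all <- c(glf, if (is.null(bench$background)) NULL else bench$background$gl)
    res <- impute_joint(gl_all, ipanel, params,
                        iterations = cfg$joint_iterations,
                        segment_size = cfg$segment_size,
                        overlap = cfg$overlap)[seq_len(cfg$n_eval)]
  } else {
    res <- lapply(glf, impute_individual, panel = ipanel, params = params,
                  segment_size = cfg$segment_size, overlap = cfg$overlap)
  }
  list(imputed = res, downsampled = ds, gl = glf, kept = kept,
       mask = split_overlap(ds, bench$truth_calls),
       coverage = coverage, panel_mode = panel_mode, joint = joint)
}

imputed_gt_matrix <- function(imputed, mask, kept = NULL) {
  t(vapply(seq_along(imputed), function(i) {
    g <- imputed[[i]]$best_gt
    g[!mask$has_truth[i, ]] <- NA_integer_
    if (!is.null(kept)) g[!kept[[i]]] <- NA_integer_
    g
  }, integer(length(imputed[[1]]$best_gt))))
}

config_table <- data.frame(
  config = 1:3,
  panel_mode = c("SUBSET", "SUBSET", "FULL"),
  joint = c(FALSE, TRUE, TRUE))

#' Compare reference-panel / study-sample configurations
#'
#' Runs the three imputation configurations (1: population-subset panel,
#' single-sample; 2: subset panel, joint study sample; 3: full panel, joint)
#' at 1x coverage, unfiltered, and reports overlap-stratified concordance and
#' the MAF-binned heterozygote discordance curve per configuration.
#'
#' @param cfg a [benchmark_config()].
#' @param configs subset of `c(1, 2, 3)` to run.
#' @param bench optional pre-simulated `bench_data` (reused across calls).
#' @param out_dir optional directory for TSV reports.
#' @return List with `concordance` and `het_discordance` data.frames (with a
#'   `config` column) and the per-config run objects in `runs`.
#' @export
run_config_comparison <- function(cfg, configs = 1:3, bench = NULL,
                                  out_dir = NULL) {
  if (!all(configs %in% 1:3)) stop("unknown configuration id")
  if (is.null(bench)) bench <- simulate_benchmark(cfg)
  conc <- list()
  curves <- list()
  runs <- list()
  for (id in configs) {
    row <- config_table[config_table$config == id, ]
    run <- impute_run(bench, 1.0, panel_mode = row$panel_mode,
                      joint = row$joint)
    cc <- concordance(run$imputed, bench$truth_calls, run$mask)
    cc$config <- id
    hd <- het_discordance_by_maf(run$imputed, bench$truth_calls, bench$maf,
                                 mask = run$mask)
    hd$config <- id
    conc[[as.character(id)]] <- cc
    curves[[as.character(id)]] <- hd
    runs[[as.character(id)]] <- run
  }
  out <- list(concordance = do.call(rbind, conc),
              het_discordance = do.call(rbind, curves), runs = runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(out$concordance, file.path(out_dir, "config_concordance.tsv"))
    write_tsv(out$het_discordance,
              file.path(out_dir, "config_het_discordance.tsv"))
    write_run_record(cfg, out_dir,
                     c("config_concordance.tsv", "config_het_discordance.tsv"))
  }
  out
}

#' Coverage sweep
#'
#' For every coverage level, downsample, recompute likelihoods and the
#' deamination filter, impute with configuration-2 semantics (subset panel,
#' joint study sample), and report unfiltered concordance, the
#' reference-affinity difference curve, and the nonoverlapping-site
#' fraction.
#'
#' @param cfg a [benchmark_config()].
#' @param levels coverage levels; must not exceed the simulated source
#'   coverage.
#' @param bench optional pre-simulated `bench_data`.
#' @param out_dir optional directory for TSV reports.
#' @return List with `concordance`, `affinity`, `overlap` data.frames (each
#'   with a `coverage` column) and the run objects.
#' @export
run_coverage_sweep <- function(cfg,
                               levels = c(0.10, 0.25, 0.50, 0.75, 1.00,
                                          1.25, 1.50, 1.75, 2.00),
                               bench = NULL, out_dir = NULL) {
  if (length(levels) == 0L || any(levels <= 0)) {
    stop("coverage levels must be positive")
  }
  if (is.null(bench)) bench <- simulate_benchmark(cfg)
  if (any(levels > bench$hq_pileups$realized_coverage)) {
    stop("coverage level exceeds the simulated source coverage")
  }
  conc <- list()
  aff <- list()
  ovl <- list()
  runs <- list()
  for (lev in levels) {
    run <- impute_run(bench, lev, panel_mode = "SUBSET", joint = TRUE)
    cc <- concordance(run$imputed, bench$truth_calls, run$mask)
    cc$coverage <- lev
    imput_gt <- imputed_gt_matrix(run$imputed, run$mask)
    ad <- affinity_difference_curve(bench$truth_calls$gt, imput_gt,
                                    bench$panel, bench$maf)
    ad$coverage <- lev
    ov <- data.frame(
      individual = seq_len(cfg$n_eval),
      coverage = lev,
      nonoverlapping_fraction = vapply(seq_len(cfg$n_eval), function(i) {
        ht <- run$mask$has_truth[i, ]
        mean(!run$mask$overlapping[i, ht])
      }, numeric(1)))
    key <- format(lev)
    conc[[key]] <- cc
    aff[[key]] <- ad
    ovl[[key]] <- ov
    runs[[key]] <- run
  }
  out <- list(concordance = do.call(rbind, conc),
              affinity = do.call(rbind, aff),
              overlap = do.call(rbind, ovl), runs = runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(out$concordance, file.path(out_dir, "sweep_concordance.tsv"))
    write_tsv(out$affinity, file.path(out_dir, "sweep_affinity_difference.tsv"))
    write_tsv(out$overlap, file.path(out_dir, "sweep_overlap_fraction.tsv"))
    write_run_record(cfg, out_dir,
                     c("sweep_concordance.tsv", "sweep_affinity_difference.tsv",
                       "sweep_overlap_fraction.tsv"))
  }
  out
}

#' In-depth filtered analysis with PCA comparison
#'
#' Configuration-3 imputation at 1x with the minimum posterior genotype
#' probability filter: per-genotype-class concordance before and after
#' filtering, the filtered MAF-binned heterozygote discordance with retained
#' fractions, and the principal-component comparison of gold-standard,
#' imputed and low-coverage genotypes projected by known data regression
#' onto a synthetic modern reference PCA.
#'
#' @param cfg a [benchmark_config()].
#' @param bench optional pre-simulated `bench_data`.
#' @param run optional pre-computed configuration-3 run at 1x.
#' @param out_dir optional directory for TSV reports.
#' @return List with `concordance_filtered`, `concordance_unfiltered`,
#'   `het_discordance`, `retained`, `pca_distances`, `projections`, `run`.
#' @export
run_indepth <- function(cfg, bench = NULL, run = NULL, out_dir = NULL) {
  if (is.null(bench)) bench <- simulate_benchmark(cfg)
  if (is.null(run)) run <- impute_run(bench, 1.0, panel_mode = "FULL",
                                      joint = TRUE)
  filt <- gp_filter(run$imputed, cfg$min_gp, maf = bench$maf)
  mask_f <- run$mask
  for (i in seq_len(cfg$n_eval)) {
    mask_f$has_truth[i, ] <- mask_f$has_truth[i, ] & filt$kept[[i]]
  }
  cc_unf <- concordance(run$imputed, bench$truth_calls, run$mask)
  cc_fil <- concordance(run$imputed, bench$truth_calls, mask_f)
  hd <- het_discordance_by_maf(run$imputed, bench$truth_calls, bench$maf,
                               mask = run$mask, kept = filt$kept)

  # synthetic modern panel for the reference PCA, drawn from the same
  # simulated reference population
  modern <- sample_study_individuals(bench$panel, cfg$n_modern,
                                     theta_sim = cfg$study_theta,
                                     divergence_rate = 0,
                                     seed = child_seed(cfg$seed, "modern"))
  model <- fit_reference_pca(modern$genotypes, d = 2L)
  proj <- lapply(seq_len(cfg$n_eval), function(i) {
    hq_gt <- bench$truth_calls$gt[i, ]
    imp_gt <- run$imputed[[i]]$best_gt
    imp_gt[!filt$kept[[i]]] <- NA_integer_
    lik <- run$gl[[i]]
    low_gt <- max.col(t(lik$lik), ties.method = "first") - 1L
    low_gt[lik$missing] <- NA_integer_
    list(hq = kdr_project(hq_gt, model, "HQ"),
         imputed = kdr_project(imp_gt, model, "imputed"),
         lowcov = kdr_project(low_gt, model, "low-coverage"))
  })
  dist <- compare_distances(lapply(proj, `[[`, "hq"),
                            lapply(proj, `[[`, "imputed"),
                            lapply(proj, `[[`, "lowcov"))
  out <- list(concordance_filtered = cc_fil, concordance_unfiltered = cc_unf,
              het_discordance = hd, retained = filt$retained,
              retained_by_bin = filt$by_bin,
              pca_distances = dist, projections = proj, run = run,
              kept = filt$kept)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(out$concordance_filtered,
              file.path(out_dir, "indepth_concordance_filtered.tsv"))
    write_tsv(out$concordance_unfiltered,
              file.path(out_dir, "indepth_concordance_unfiltered.tsv"))
    write_tsv(out$het_discordance,
              file.path(out_dir, "indepth_het_discordance.tsv"))
    write_tsv(out$retained, file.path(out_dir, "indepth_retained.tsv"))
    proj_df <- do.call(rbind, lapply(seq_along(proj), function(i) {
      do.call(rbind, lapply(proj[[i]], function(p) {
        data.frame(individual = i, label = p$label,
                   PC1 = p$coords[1], PC2 = p$coords[2],
                   n_observed = p$n_observed)
      }))
    }))
    write_tsv(proj_df, file.path(out_dir, "indepth_pca_scores.tsv"))
    write_tsv(out$pca_distances, file.path(out_dir, "indepth_pca_distances.tsv"))
    write_run_record(cfg, out_dir,
                     c("indepth_concordance_filtered.tsv",
                       "indepth_concordance_unfiltered.tsv",
                       "indepth_het_discordance.tsv", "indepth_retained.tsv",
                       "indepth_pca_scores.tsv", "indepth_pca_distances.tsv"))
  }
  out
}

# provenance record: configuration digest, seed, version, timestamp, manifest
write_run_record <- function(cfg, out_dir, files) {
  plain <- cfg[setdiff(names(cfg), "sim")]
  digest <- sum(utf8ToInt(paste(deparse(plain), collapse = ""))) %% 1e9
  rec <- data.frame(
    key = c("config_digest", "seed", "package_version", "timestamp",
            rep("file", length(files))),
    value = c(digest, cfg$seed,
              as.character(utils::packageVersion("paleoimpute")),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), files))
  write_tsv(rec, file.path(out_dir, "run_record.tsv"))
}
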