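vcf_header <- function(extra = character()) {
  c("##fileformat=VCFv4.2",
    "##source=paleoimpute",
    '##contig=<ID=1>',
    extra)
}

vcf_fixed_cols <- function(markers) {
  paste(markers$chrom, markers$pos, ".", markers$ref, markers$alt,
        ".", "PASS", ".", sep = "\t")
}

#' Write a phased haplotype panel as VCF 4.2
#'
#' Panel individuals are consecutive haplotype pairs, emitted as phased GT
#' (`|` separator) with the estimated panel allele frequency in INFO/AF.
#'
#' @param panel a `haplotype_panel`.
#' @param path output file path.
#' @export
write_panel_vcf <- function(panel, path) {
  H <- panel$haplotypes
  n_ind <- nrow(H) / 2L
  gt <- matrix(paste(H[seq(1L, nrow(H), 2L), ], H[seq(2L, nrow(H), 2L), ],
                     sep = "|"),
               nrow = n_ind)
  f1 <- colMeans(H)
  samples <- paste0("panel", seq_len(n_ind))
  lines <- c(
    vcf_header(c('##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(paste(panel$markers$chrom, panel$markers$pos, ".",
                panel$markers$ref, panel$markers$alt, ".", "PASS",
                sprintf("AF=%.6g", f1), "GT", sep = "\t"),
          apply(gt, 2L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-individual genotype likelihoods as VCF 4.2
#'
#' GL is emitted log10-scaled with standard field semantics; DP carries the
#' read depth. Missing sites get `./.` genotypes and flat GL.
#'
#' @param gl a `gl_matrix`.
#' @param pileup_row list with `n_ref`, `n_alt` vectors for this individual
#'   (or NULL for unknown depth).
#' @param markers marker data.frame.
#' @param path output file path.
#' @param sample sample name.
#' @export
write_gl_vcf <- function(gl, markers, path, sample = "sample1",
                         pileup_row = NULL) {
  lik <- pmax(gl$lik, 1e-300)
  gl10 <- sprintf("%.4f,%.4f,%.4f",
                  log10(lik[1L, ]), log10(lik[2L, ]), log10(lik[3L, ]))
  dp <- if (is.null(pileup_row)) rep(".", ncol(gl$lik)) else
    pileup_row$n_ref + pileup_row$n_alt
  lines <- c(
    vcf_header(c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 '##FORMAT=<ID=GL,Number=G,Type=Float,Description="Genotype likelihood, log10">',
                 '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"),
    paste(vcf_fixed_cols(markers), "GT:GL:DP",
          paste("./.", gl10, dp, sep = ":"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write gold-standard truth calls as VCF 4.2
#'
#' @param truth a `truth_calls`.
#' @param pileup the high-coverage `pileup_columns` the calls came from
#'   (supplies AD).
#' @param markers marker data.frame.
#' @param path output file path.
#' @param samples sample names.
#' @export
write_truth_vcf <- function(truth, pileup, markers, path,
                            samples = paste0("ind", seq_len(nrow(truth$gt)))) {
  gt_str <- c("0/0", "0/1", "1/1")
  cols <- vapply(seq_len(nrow(truth$gt)), function(i) {
    g <- truth$gt[i, ]
    paste(ifelse(is.na(g), "./.", gt_str[g + 1L]),
          truth$dp[i, ],
          paste(pileup$n_ref[i, ], pileup$n_alt[i, ], sep = ","),
          sprintf("%.1f", truth$qual[i, ]), sep = ":")
  }, character(ncol(truth$gt)))
  lines <- c(
    vcf_header(c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
                 '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
                 '##FORMAT=<ID=GQ,Number=1,Type=Float,Description="Phred-scaled call confidence">')),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(vcf_fixed_cols(markers), "GT:DP:AD:GQ",
          apply(cols, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write imputed genotypes as VCF 4.2 with GT, GP and DS
#'
#' @param imp an `imputed_genotypes`.
#' @param markers marker data.frame.
#' @param path output file path.
#' @param sample sample name.
#' @export
write_imputed_vcf <- function(imp, markers, path, sample = "sample1") {
  gt_str <- c("0/0", "0/1", "1/1")[imp$best_gt + 1L]
  gp <- sprintf("%.4f,%.4f,%.4f", imp$gp[1L, ], imp$gp[2L, ], imp$gp[3L, ])
  lines <- c(
    vcf_header(c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Posterior genotype probability">',
                 '##FORMAT=<ID=DS,Number=A,Type=Float,Description="Alt dosage">')),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"),
    paste(vcf_fixed_cols(markers), "GT:GP:DS",
          paste(gt_str, gp, sprintf("%.4f", imp$dosage), sep = ":"),
          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write pileup counts as TSV
#'
#' Long format: chrom, pos, individual, n_ref, n_alt.
#'
#' @param pileup a `pileup_columns`.
#' @param markers marker data.frame.
#' @param path output file path.
#' @export
write_pileup_tsv <- function(pileup, markers, path) {
  n_ind <- nrow(pileup$n_ref)
  df <- data.frame(
    chrom = rep(markers$chrom, each = n_ind),
    pos = rep(markers$pos, each = n_ind),
    individual = rep(seq_len(n_ind), times = nrow(markers)),
    n_ref = as.vector(pileup$n_ref),
    n_alt = as.vector(pileup$n_alt))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as tab-separated text
#' @param df data frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [benchmark_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `bench_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(benchmark_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(benchmark_config, vals)
}
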