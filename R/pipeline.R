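#' Pipeline run configuration
#'
#' Collects every input path and stage parameter of the scan pipeline so a
#' run is fully described (and reproducible) by one object; each command
#' writes a JSON manifest echoing it along with per-stage counts.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for every stochastic stage.
#' @param vcf,popmap_path,scaffolds_path Input paths for scan/report stages
#'   (defaults point at the files [cmd_simulate()] writes into `out_dir`).
#' @param focal,ref Focal and reference population labels.
#' @param sigma_bp Gaussian kernel sigma in bp (default 25000).
#' @param z_cut Diversity-ratio Z threshold (default 5).
#' @param alpha Bootstrap p threshold for smoothed-FST outliers
#'   (default 1e-5).
#' @param B_max Maximum bootstrap replicates (default 1e7).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @param min_len,min_snps XP-EHH scaffold filters (defaults 3e5, 20).
#' @param top_fraction XP-EHH outlier tail fraction (default 0.01).
#' @param merge_gap Region merge gap in bp (default 5e4).
#' @param clamp_negative_fst Clamp negative per-site FST at zero
#'   (default `FALSE`).
#' @param sim A [sim_config()] for [cmd_simulate()] (its seed is forced to
#'   `seed`).
#' @param cpg_fasta,cpg_positions_path,methylation_path Inputs for
#'   [cmd_cpg()].
#' @param fold Methylation fold-change threshold (default 4).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       vcf = file.path(out_dir, "sim.vcf"),
                       popmap_path = file.path(out_dir, "popmap.tsv"),
                       scaffolds_path = file.path(out_dir, "scaffolds.tsv"),
                       focal = "PAG", ref = "GO",
                       sigma_bp = 25000, z_cut = 5, alpha = 1e-5,
                       B_max = 1e7, cutoff = 0.05, min_len = 3e5,
                       min_snps = 20, top_fraction = 0.01, merge_gap = 5e4,
                       clamp_negative_fst = FALSE,
                       sim = sim_config(seed = seed),
                       cpg_fasta = file.path(out_dir, "cpg_haplotypes.fasta"),
                       cpg_positions_path = file.path(out_dir, "cpg_positions.tsv"),
                       methylation_path = file.path(out_dir, "methylation.tsv"),
                       fold = 4) {
  if (identical(focal, ref)) stop("focal and reference population must differ")
  stopifnot(sigma_bp > 0, z_cut > 0, alpha > 0, alpha < 1, B_max >= 100,
            cutoff > 0, cutoff < 1, top_fraction > 0, top_fraction < 1,
            merge_gap >= 0, fold > 0)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), vcf = vcf,
                 popmap_path = popmap_path, scaffolds_path = scaffolds_path,
                 focal = focal, ref = ref, sigma_bp = sigma_bp,
                 z_cut = z_cut, alpha = alpha, B_max = B_max,
                 cutoff = cutoff, min_len = min_len, min_snps = min_snps,
                 top_fraction = top_fraction, merge_gap = merge_gap,
                 clamp_negative_fst = clamp_negative_fst, sim = sim,
                 cpg_fasta = cpg_fasta,
                 cpg_positions_path = cpg_positions_path,
                 methylation_path = methylation_path, fold = fold),
            class = "run_config")
}

write_manifest <- function(cfg, stage, counts, path) {
  keep <- setdiff(names(cfg), "sim")
  m <- list(tool = "sweepscanr",
            version = as.character(utils::packageVersion("sweepscanr")),
            stage = stage, config = cfg[keep],
            sim = if (stage == "simulate") unclass(cfg$sim) else NULL,
            counts = counts)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# each stage writes to "<file>.quarantine" and promotes everything at the
# end, so a failed stage never leaves a partial file under its final name
stage_files <- function(out_dir, names) {
  final <- file.path(out_dir, names)
  stats::setNames(paste0(final, ".quarantine"), names)
}

promote <- function(tmp) {
  for (f in tmp) {
    if (file.exists(f)) file.rename(f, sub("\\.quarantine$", "", f))
  }
}

write_track <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- formatC(df[[j]], format = "g",
                                            digits = 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Simulate a dataset and write it as pipeline input files
#'
#' Writes a phased VCF, popmap TSV, scaffold-length TSV, the sweep truth
#' interval (when present) and a manifest into `out_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the simulated dataset list.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(cfg$sim)
  tmp <- stage_files(cfg$out_dir, c("sim.vcf", "popmap.tsv", "scaffolds.tsv",
                                    "truth.tsv", "manifest_simulate.json"))
  write_vcf(tmp[["sim.vcf"]], sim$variants, sim$haplotypes, sim$scaffolds)
  write_popmap(sim$pm, tmp[["popmap.tsv"]])
  write_scaffold_lengths(sim$scaffolds, tmp[["scaffolds.tsv"]])
  if (!is.null(sim$truth)) {
    write_regions(sim$truth, tmp[["truth.tsv"]], dialect = "tsv")
  }
  write_manifest(cfg, "simulate",
                 list(n_snps = nrow(sim$variants),
                      n_samples = length(sim$haplotypes$sample_ids),
                      n_scaffolds = length(sim$scaffolds)),
                 tmp[["manifest_simulate.json"]])
  promote(tmp)
  invisible(sim)
}

#' Run the three-test selective-sweep scan
#'
#' Executes, in order: per-site FST -> Gaussian smoothing -> bootstrap
#' outlier null; per-population variant-site pi -> smoothing -> log2-ratio
#' Z scores; XP-EHH over filtered scaffolds; then merges each test's
#' flagged SNPs into regions and intersects the three region sets. All
#' tracks and region sets are written as TSV so any stage can be inspected
#' or re-entered independently.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all tracks and region sets.
#' @export
cmd_scan <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (f in c(cfg$vcf, cfg$popmap_path, cfg$scaffolds_path)) {
    if (!file.exists(f)) stop("missing input: ", f)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_vcf(cfg$vcf, haplotypes = TRUE)
  pm <- read_popmap(cfg$popmap_path, vcf_samples = dat$haplotypes$sample_ids,
                    pops = c(cfg$focal, cfg$ref))
  scaffolds <- read_scaffold_lengths(cfg$scaffolds_path)
  check_scaffolds(scaffolds, dat$variants)

  # FST scan
  set.seed(cfg$seed)
  fst <- fst_per_site(dat$variants, dat$genotypes, pm,
                      c(cfg$focal, cfg$ref),
                      clamp_negative = cfg$clamp_negative_fst)
  fst_def <- fst[fst$defined, c("scaffold", "pos", "value")]
  sm_fst <- gaussian_smooth(fst_def, sigma_bp = cfg$sigma_bp)
  sm_fst <- bootstrap_outlier_pvalues(sm_fst, B_max = cfg$B_max,
                                      alpha = cfg$alpha)

  # pi-ratio scan (identical centers: sites defined in both populations)
  pi_f <- pi_variant_site(dat$variants, dat$genotypes, pm, cfg$focal)
  pi_r <- pi_variant_site(dat$variants, dat$genotypes, pm, cfg$ref)
  both <- pi_f$defined & pi_r$defined
  sm_pi_f <- gaussian_smooth(pi_f[both, c("scaffold", "pos", "value")],
                             sigma_bp = cfg$sigma_bp)
  sm_pi_r <- gaussian_smooth(pi_r[both, c("scaffold", "pos", "value")],
                             sigma_bp = cfg$sigma_bp)
  z <- pi_ratio_zscore(sm_pi_f, sm_pi_r, z_cut = cfg$z_cut)

  # XP-EHH scan
  hap_f <- hap_subset(dat$haplotypes, samples = pm$sample[pm$pop == cfg$focal])
  hap_r <- hap_subset(dat$haplotypes, samples = pm$sample[pm$pop == cfg$ref])
  xp <- xpehh_scan(hap_f, hap_r, dat$variants, scaffolds,
                   cutoff = cfg$cutoff, min_len = cfg$min_len,
                   min_snps = cfg$min_snps, top_fraction = cfg$top_fraction)

  reg_fst <- call_regions(sm_fst[sm_fst$outlier, c("scaffold", "pos")],
                          merge_gap = cfg$merge_gap)
  reg_pi <- call_regions(z[z$outlier, c("scaffold", "pos")],
                         merge_gap = cfg$merge_gap)
  reg_xp <- call_regions(xp[xp$outlier, c("scaffold", "pos")],
                         merge_gap = cfg$merge_gap)
  combined <- intersect_tests(reg_fst, reg_pi, reg_xp)

  tmp <- stage_files(cfg$out_dir,
                     c("fst_track.tsv", "pi_track.tsv", "z_track.tsv",
                       "xpehh_track.tsv", "regions_fst.tsv",
                       "regions_pi.tsv", "regions_xpehh.tsv",
                       "combined_regions.tsv", "manifest_scan.json"))
  write_track(data.frame(sm_fst)[, c("scaffold", "pos", "value", "smoothed",
                                     "p", "B_used", "outlier")],
              tmp[["fst_track.tsv"]])
  write_track(data.frame(scaffold = sm_pi_f$scaffold, pos = sm_pi_f$pos,
                         pi_focal = sm_pi_f$value,
                         pi_focal_smoothed = sm_pi_f$smoothed,
                         pi_ref = sm_pi_r$value,
                         pi_ref_smoothed = sm_pi_r$smoothed),
              tmp[["pi_track.tsv"]])
  write_track(z, tmp[["z_track.tsv"]])
  write_track(data.frame(xp)[, c("scaffold", "pos", "ihh_focal", "ihh_ref",
                                 "raw", "normalized", "outlier", "censored")],
              tmp[["xpehh_track.tsv"]])
  write_regions(reg_fst, tmp[["regions_fst.tsv"]])
  write_regions(reg_pi, tmp[["regions_pi.tsv"]])
  write_regions(reg_xp, tmp[["regions_xpehh.tsv"]])
  write_regions(combined, tmp[["combined_regions.tsv"]])
  write_manifest(cfg, "scan",
                 list(n_snps = nrow(dat$variants),
                      n_skipped_records = dat$n_skipped,
                      n_fst_defined = nrow(sm_fst),
                      n_pi_centers = nrow(sm_pi_f),
                      n_xpehh_cores = nrow(xp),
                      n_fst_outliers = sum(sm_fst$outlier),
                      n_z_outliers = sum(z$outlier),
                      n_xpehh_outliers = sum(xp$outlier),
                      xpehh_outlier_threshold = attr(xp, "outlier_threshold"),
                      n_regions_fst = nrow(reg_fst),
                      n_regions_pi = nrow(reg_pi),
                      n_regions_xpehh = nrow(reg_xp),
                      n_combined_regions = nrow(combined)),
                 tmp[["manifest_scan.json"]])
  promote(tmp)
  invisible(list(fst = sm_fst, pi_focal = sm_pi_f, pi_ref = sm_pi_r, z = z,
                 xpehh = xp, regions_fst = reg_fst, regions_pi = reg_pi,
                 regions_xpehh = reg_xp, combined = combined))
}

#' Summarize combined candidate regions
#'
#' Re-runs the scan stages in memory (tracks are cheap relative to the
#' bootstrap, which is not needed here) and writes a per-region report of
#' the headline statistics for every combined region found by [cmd_scan()].
#'
#' @param cfg A [run_config()].
#' @param scan Optional result of [cmd_scan()] to reuse; otherwise region
#'   and track files are read back from `out_dir`.
#' @return Invisibly, the report `data.frame`.
#' @export
cmd_report <- function(cfg, scan = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  dat <- read_vcf(cfg$vcf, haplotypes = TRUE)
  pm <- read_popmap(cfg$popmap_path, vcf_samples = dat$haplotypes$sample_ids,
                    pops = c(cfg$focal, cfg$ref))
  if (is.null(scan)) {
    combined <- read_regions(file.path(cfg$out_dir, "combined_regions.tsv"))
    fst <- utils::read.table(file.path(cfg$out_dir, "fst_track.tsv"),
                             header = TRUE, sep = "\t")
    pit <- utils::read.table(file.path(cfg$out_dir, "pi_track.tsv"),
                             header = TRUE, sep = "\t")
    zt <- utils::read.table(file.path(cfg$out_dir, "z_track.tsv"),
                            header = TRUE, sep = "\t")
    xpt <- utils::read.table(file.path(cfg$out_dir, "xpehh_track.tsv"),
                             header = TRUE, sep = "\t")
    sm_fst <- fst
    sm_pi_f <- data.frame(scaffold = pit$scaffold, pos = pit$pos,
                          value = pit$pi_focal,
                          smoothed = pit$pi_focal_smoothed)
    sm_pi_r <- data.frame(scaffold = pit$scaffold, pos = pit$pos,
                          value = pit$pi_ref, smoothed = pit$pi_ref_smoothed)
  } else {
    combined <- scan$combined
    sm_fst <- scan$fst
    sm_pi_f <- scan$pi_focal
    sm_pi_r <- scan$pi_ref
    zt <- scan$z
    xpt <- scan$xpehh
  }
  rows <- lapply(seq_len(nrow(combined)), function(i) {
    summarize_region(combined[i, ], sm_fst, sm_pi_f, sm_pi_r, zt, xpt,
                     haps = dat$haplotypes, pm = pm,
                     variants = dat$variants)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), start = integer(), end = integer())
  tmp <- stage_files(cfg$out_dir, c("region_report.tsv",
                                    "manifest_report.json"))
  write_track(report, tmp[["region_report.tsv"]])
  write_manifest(cfg, "report", list(n_regions = nrow(report)),
                 tmp[["manifest_report.json"]])
  promote(tmp)
  invisible(report)
}

#' Run the CpG intactness and methylation outlier analysis
#'
#' Reads per-haplotype locus sequences (FASTA, record ids
#' `"<sample>_<phase>"`), CpG positions (TSV: `locus`, `position`), the
#' popmap, and a per-position mean-methylation table (TSV: `position`,
#' `mean_focal`, `mean_ref`); writes intactness counts, per-site exact-test
#' results, and the methylation correlation/fold-change screen.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `counts`, `tests`, `meth`.
#' @export
cmd_cpg <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (f in c(cfg$cpg_fasta, cfg$cpg_positions_path, cfg$methylation_path,
              cfg$popmap_path)) {
    if (!file.exists(f)) stop("missing input: ", f)
  }
  seqs <- Biostrings::readDNAStringSet(cfg$cpg_fasta)
  pos_tab <- utils::read.table(cfg$cpg_positions_path, header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  meth <- utils::read.table(cfg$methylation_path, header = TRUE, sep = "\t")
  pm <- read_popmap(cfg$popmap_path, pops = c(cfg$focal, cfg$ref))
  counts <- do.call(rbind, lapply(unique(pos_tab$locus), function(lc) {
    cpg_intactness(seqs, pos_tab$position[pos_tab$locus == lc], pm,
                   locus = lc)
  }))
  tests <- cpg_selection_test(counts)
  screen <- methylation_outliers(meth, fold = cfg$fold)
  tmp <- stage_files(cfg$out_dir, c("cpg_counts.tsv", "cpg_tests.tsv",
                                    "methylation_screen.tsv",
                                    "manifest_cpg.json"))
  write_track(counts, tmp[["cpg_counts.tsv"]])
  write_track(tests, tmp[["cpg_tests.tsv"]])
  write_track(screen$table, tmp[["methylation_screen.tsv"]])
  write_manifest(cfg, "cpg",
                 list(n_sites = nrow(tests),
                      n_significant = sum(tests$p < 0.05),
                      methylation_r2 = screen$r2,
                      n_fold_outliers = sum(screen$table$outlier)),
                 tmp[["manifest_cpg.json"]])
  promote(tmp)
  invisible(list(counts = counts, tests = tests, meth = screen))
}
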