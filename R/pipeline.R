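# End-to-end analysis runs: density, spacing and population-genomics
# stages, each writing deterministic TSV report tables. Re-running with the
# same config and seed reproduces byte-identical outputs.

#' Assemble and validate a run configuration
#'
#' Precedence is caller's responsibility (pass explicit values); every
#' value used, plus the config MD5, is recorded in each report's header
#' lines so runs are traceable.
#'
#' @param repeatmasker Path to a RepeatMasker `.out` file.
#' @param fasta Genome FASTA path.
#' @param gff Gene annotation GFF3/GTF path.
#' @param vcf All-sites VCF path.
#' @param chrom_sizes Optional chromosome-size table (defaults to FASTA
#'   lengths).
#' @param outdir Output directory for report tables.
#' @param window Window size in bases (>= 10,000; default 100,000).
#' @param young_max,old_min,old_max Divergence thresholds (percent) for
#'   the young/old TE classes.
#' @param boot_reps Bootstrap replicates for chromosome CIs (default 1000).
#' @param seed Integer seed for all resampling.
#' @param exclude_chroms Chromosomes excluded from every table (e.g. `"Z"`
#'   for the population-genomics stage, where sex chromosomes follow their
#'   own dynamics).
#' @param fdr_family Label recording which tests form one FDR family.
#' @param sfs_n_target Haploid size for SFS projection (`NULL` = the
#'   median called-allele number over variant sites).
#' @return List of class `chromte_config`.
#' @export
run_config <- function(repeatmasker = NULL, fasta = NULL, gff = NULL,
                       vcf = NULL, chrom_sizes = NULL, outdir = tempdir(),
                       window = 100000, young_max = 5, old_min = 5,
                       old_max = 10, boot_reps = 1000, seed = 1,
                       exclude_chroms = character(0),
                       fdr_family = "per-analysis", sfs_n_target = NULL) {
  if (window < 10000) stop("window must be at least 10,000 bases")
  if (young_max <= 0 || old_max < old_min) stop("invalid age thresholds")
  cfg <- as.list(environment())
  class(cfg) <- "chromte_config"
  cfg
}

config_md5 <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(names(config),
                   vapply(config, function(x) paste(deparse(x),
                                                    collapse = ""),
                          character(1)), sep = "="), tf)
  unname(tools::md5sum(tf))
}

provenance <- function(config) {
  c(sprintf("chromTE %s", as.character(utils::packageVersion("chromTE"))),
    sprintf("seed=%d window=%d boot_reps=%d young_max=%g old_min=%g old_max=%g",
            config$seed, as.integer(config$window),
            as.integer(config$boot_reps), config$young_max, config$old_min,
            config$old_max),
    sprintf("fdr_family=%s exclude_chroms=%s config_md5=%s",
            config$fdr_family,
            if (length(config$exclude_chroms)) {
              paste(config$exclude_chroms, collapse = ",")
            } else "none",
            config_md5(config)))
}

check_inputs <- function(config, needed) {
  for (nm in needed) {
    p <- config[[nm]]
    if (is.null(p)) stop("config is missing required input: ", nm)
    if (is.character(p) && !file.exists(p)) {
      stop("missing input file for ", nm, ": ", p)
    }
  }
}

#' Run the windowed density analysis
#'
#' Computes per-window repeat density (interval-union), GC content and CDS
#' density; chromosome-level means with percentile-bootstrap CIs; repeat
#' density per TE class and for young copies only; Spearman/FDR
#' correlations of each chromosome statistic against chromosome length;
#' and a multiple regression of repeat density on length, GC and CDS
#' density. Writes `windows_density.tsv`, `chromosome_density.tsv`,
#' `te_class_density.tsv`, `density_correlations.tsv`,
#' `density_regression.tsv` under `config$outdir`.
#'
#' @param config A [run_config()] with `repeatmasker`, `fasta`, `gff`.
#' @param te_class Optional single TE class restricting the analysis.
#' @return Invisibly, a list with every table.
#' @export
run_density_analysis <- function(config, te_class = NULL) {
  check_inputs(config, c("repeatmasker", "fasta", "gff"))
  hdr <- provenance(config)
  sizes <- if (is.null(config$chrom_sizes)) {
    load_chrom_sizes(config$fasta)
  } else load_chrom_sizes(config$chrom_sizes)
  sizes <- sizes[!(sizes$chrom %in% config$exclude_chroms), , drop = FALSE]
  rec <- read_repeatmasker(config$repeatmasker)
  rec <- filter_te_records(rec, drop_non_te = TRUE)
  if (!is.null(te_class)) rec <- filter_te_records(rec,
                                                   keep_classes = te_class)
  rec <- rec[rec$chrom %in% sizes$chrom, , drop = FALSE]
  win <- make_windows(sizes, window = config$window)
  win <- repeat_density(win, rec, chrom_sizes = sizes)
  win <- gc_content(win, config$fasta)
  win <- cds_density(win, config$gff)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(win, file.path(config$outdir, "windows_density.tsv"), hdr)

  summ <- Reduce(function(a, b) merge(a, b, by = "chrom"), list(
    stats_rename(chromosome_summary(win, "repeat_density",
                                    B = config$boot_reps,
                                    seed = config$seed), "repeat_density"),
    stats_rename(chromosome_summary(win, "gc", B = config$boot_reps,
                                    seed = config$seed + 1), "gc"),
    stats_rename(chromosome_summary(win, "cds_density",
                                    B = config$boot_reps,
                                    seed = config$seed + 2), "cds_density")
  ))
  summ <- merge(sizes, summ, by = "chrom")
  write_tsv(summ, file.path(config$outdir, "chromosome_density.tsv"), hdr)

  cls_rows <- lapply(sort(unique(rec$te_class)), function(cl) {
    r <- rec[rec$te_class == cl, , drop = FALSE]
    cov <- covered_per_window(
      data.frame(chrom = sizes$chrom, start = 0, end = sizes$length), r)
    data.frame(chrom = sizes$chrom, te_class = cl,
               density = cov / sizes$length, stringsAsFactors = FALSE)
  })
  young <- rec[classify_age(rec$divergence, config$young_max,
                            config$old_min, config$old_max) == "young", ,
               drop = FALSE]
  cov_y <- covered_per_window(
    data.frame(chrom = sizes$chrom, start = 0, end = sizes$length), young)
  cls_tab <- rbind(do.call(rbind, cls_rows),
                   data.frame(chrom = sizes$chrom, te_class = "young_all",
                              density = cov_y / sizes$length,
                              stringsAsFactors = FALSE))
  write_tsv(cls_tab, file.path(config$outdir, "te_class_density.tsv"), hdr)

  cors <- correlate_across_chromosomes(
    summ[, c("chrom", "mean_repeat_density", "mean_gc",
             "mean_cds_density")],
    c("mean_repeat_density", "mean_gc", "mean_cds_density"),
    sizes, exclude_chroms = config$exclude_chroms
  )
  write_tsv(cors, file.path(config$outdir, "density_correlations.tsv"), hdr)

  reg <- tryCatch(
    ols_regression(
      summ$mean_repeat_density,
      data.frame(chrom_length = summ$length, gc = summ$mean_gc,
                 cds_density = summ$mean_cds_density)
    ),
    error = function(e) {
      message("regression skipped: ", conditionMessage(e))
      NULL
    }
  )
  reg_tab <- if (is.null(reg)) {
    data.frame(term = NA_character_, estimate = NA_real_,
               std_error = NA_real_, t_value = NA_real_, p_value = NA_real_,
               r_squared = NA_real_)
  } else {
    cbind(reg$coefficients, r_squared = reg$r_squared)
  }
  write_tsv(reg_tab, file.path(config$outdir, "density_regression.tsv"), hdr)

  invisible(list(windows = win, chromosomes = summ, te_class = cls_tab,
                 correlations = cors, regression = reg))
}

stats_rename <- function(cs, stat) {
  out <- cs[, c("chrom", "mean_stat", "ci_low", "ci_high", "n_windows")]
  names(out) <- c("chrom", paste0("mean_", stat), paste0("ci_low_", stat),
                  paste0("ci_high_", stat), paste0("n_windows_", stat))
  out
}

#' Run the inter-TE spacing analysis
#'
#' Per-chromosome mean adjacent distances for young and old TEs, their
#' ratio, and Spearman/FDR correlations of each against chromosome length.
#' Writes `spacing.tsv` and `spacing_correlations.tsv`.
#'
#' @param config A [run_config()] with `repeatmasker` and `fasta` or
#'   `chrom_sizes`.
#' @return Invisibly, a list with both tables.
#' @export
run_spacing_analysis <- function(config) {
  check_inputs(config, "repeatmasker")
  hdr <- provenance(config)
  sizes <- if (is.null(config$chrom_sizes)) {
    check_inputs(config, "fasta")
    load_chrom_sizes(config$fasta)
  } else load_chrom_sizes(config$chrom_sizes)
  sizes <- sizes[!(sizes$chrom %in% config$exclude_chroms), , drop = FALSE]
  rec <- read_repeatmasker(config$repeatmasker)
  rec <- filter_te_records(rec, drop_non_te = TRUE)
  rec <- rec[rec$chrom %in% sizes$chrom, , drop = FALSE]
  sp <- spacing_by_chromosome(rec, young_max = config$young_max,
                              old_min = config$old_min,
                              old_max = config$old_max)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(sp, file.path(config$outdir, "spacing.tsv"), hdr)
  cors <- correlate_across_chromosomes(
    sp, c("mean_dist_young", "mean_dist_old", "ratio_young_over_old"),
    sizes, exclude_chroms = config$exclude_chroms
  )
  write_tsv(cors, file.path(config$outdir, "spacing_correlations.tsv"), hdr)
  invisible(list(spacing = sp, correlations = cors))
}

#' Run the population-genomics analysis
#'
#' Classifies coding-site degeneracy (writing 0D/4D BED files), computes
#' windowed and chromosome-level pi for all sites and for the 0D and 4D
#' subsets (ratio-of-sums within windows, window means per chromosome),
#' the 0D/4D ratio, folded synonymous/nonsynonymous spectra with a
#' genome-wide and per-chromosome gamma-DFE fit, and correlations of every
#' per-chromosome statistic against chromosome length. Writes `pi.tsv`,
#' `sfs.tsv`, `dfe.tsv`, `popgen_correlations.tsv`, `sites_0d.bed`,
#' `sites_4d.bed`.
#'
#' @param config A [run_config()] with `vcf`, `fasta`, `gff`.
#' @param exclude_bed Optional BED of low-quality sites to drop.
#' @return Invisibly, a list with every table.
#' @export
run_popgen_analysis <- function(config, exclude_bed = NULL) {
  check_inputs(config, c("vcf", "fasta", "gff"))
  hdr <- provenance(config)
  sizes <- if (is.null(config$chrom_sizes)) {
    load_chrom_sizes(config$fasta)
  } else load_chrom_sizes(config$chrom_sizes)
  sizes <- sizes[!(sizes$chrom %in% config$exclude_chroms), , drop = FALSE]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  degmap <- classify_degeneracy(config$fasta, config$gff)
  bed0 <- degeneracy_bed(degmap, "0D",
                         path = file.path(config$outdir, "sites_0d.bed"))
  bed4 <- degeneracy_bed(degmap, "4D",
                         path = file.path(config$outdir, "sites_4d.bed"))

  vcf <- read_allsites_vcf(config$vcf)
  keep <- vcf$chrom %in% sizes$chrom
  vcf <- list(chrom = vcf$chrom[keep], pos = vcf$pos[keep],
              ref = vcf$ref[keep], alt = vcf$alt[keep],
              gt = vcf$gt[keep, , drop = FALSE])
  win <- make_windows(sizes, window = config$window)
  pi_all <- pi_windows(vcf, win, exclude_bed = exclude_bed)
  pi_0d <- pi_windows(vcf, win, site_mask = bed0, exclude_bed = exclude_bed)
  pi_4d <- pi_windows(vcf, win, site_mask = bed4, exclude_bed = exclude_bed)
  ratio <- chromosome_pi_ratio(pi_0d$chromosomes, pi_4d$chromosomes)
  pi_tab <- merge(merge(
    stats::setNames(pi_all$chromosomes[, c("chrom", "pi", "n_windows")],
                    c("chrom", "pi_all", "n_windows")),
    ratio, by = "chrom"), sizes, by = "chrom")
  write_tsv(pi_tab, file.path(config$outdir, "pi.tsv"), hdr)

  is_var <- !is.na(vcf$alt) & vcf$alt %in% BASES
  snps <- data.frame(chrom = vcf$chrom, pos = vcf$pos, ref = vcf$ref,
                     alt = vcf$alt, stringsAsFactors = FALSE)
  effects <- rep("other", nrow(snps))
  idx <- build_cds_index(config$fasta, config$gff)
  effects[is_var] <- classify_snp_effect(snps[is_var, , drop = FALSE],
                                         cds_index = idx)
  st <- site_allele_stats(vcf$gt)
  n_target <- config$sfs_n_target
  if (is.null(n_target)) {
    vk <- st$k[is_var]
    n_target <- if (length(vk)) as.integer(stats::median(vk)) else 0L
  }
  sfs <- build_folded_sfs(vcf, effects, n_target,
                          L_syn = sum(degmap$label == "4D"),
                          L_nonsyn = sum(degmap$label == "0D"))
  sfs_tab <- data.frame(class = seq_along(sfs$syn$counts),
                        syn_count = sfs$syn$counts,
                        nonsyn_count = sfs$nonsyn$counts,
                        L_syn = sfs$syn$L, L_nonsyn = sfs$nonsyn$L,
                        n = n_target)
  write_tsv(sfs_tab, file.path(config$outdir, "sfs.tsv"), hdr)

  fit_row <- function(label, fit) {
    if (is.null(fit)) {
      data.frame(scope = label, beta = NA_real_, Es = NA_real_,
                 S_mean = NA_real_, log_likelihood = NA_real_,
                 neutral_boundary = NA, stringsAsFactors = FALSE)
    } else {
      data.frame(scope = label, beta = fit$beta, Es = fit$Es,
                 S_mean = fit$S_mean, log_likelihood = fit$log_likelihood,
                 neutral_boundary = fit$neutral_boundary,
                 stringsAsFactors = FALSE)
    }
  }
  safe_fit <- function(syn, nonsyn) {
    tryCatch(fit_gamma_dfe(syn, nonsyn), error = function(e) NULL)
  }
  global_fit <- safe_fit(sfs$syn, sfs$nonsyn)
  dfe_rows <- list(fit_row("genome", global_fit))
  for (ch in sizes$chrom) {
    sel <- vcf$chrom == ch
    sub <- list(chrom = vcf$chrom[sel], pos = vcf$pos[sel],
                ref = vcf$ref[sel], alt = vcf$alt[sel],
                gt = vcf$gt[sel, , drop = FALSE])
    f <- tryCatch({
      s <- build_folded_sfs(sub, effects[sel], n_target)
      fit_gamma_dfe(s$syn, s$nonsyn)
    }, error = function(e) NULL)
    dfe_rows[[length(dfe_rows) + 1]] <- fit_row(ch, f)
  }
  dfe_tab <- do.call(rbind, dfe_rows)
  write_tsv(dfe_tab, file.path(config$outdir, "dfe.tsv"), hdr)

  cor_stats <- c("pi_all", "pi_0d", "pi_4d", "ratio_0d_4d")
  per_chrom <- merge(pi_tab[, setdiff(names(pi_tab), "length")],
                     stats::setNames(dfe_tab[dfe_tab$scope != "genome",
                                             c("scope", "Es")],
                                     c("chrom", "Es")),
                     by = "chrom", all.x = TRUE)
  if (sum(is.finite(per_chrom$Es)) >= 3) cor_stats <- c(cor_stats, "Es")
  usable <- vapply(cor_stats, function(v) {
    sum(is.finite(per_chrom[[v]])) >= 3
  }, logical(1))
  if (any(!usable)) {
    message("correlation skipped for ",
            paste(cor_stats[!usable], collapse = ", "),
            ": fewer than 3 chromosomes with defined values")
  }
  cors <- correlate_across_chromosomes(per_chrom, cor_stats[usable], sizes,
                                       exclude_chroms = config$exclude_chroms)
  write_tsv(cors, file.path(config$outdir, "popgen_correlations.tsv"), hdr)

  invisible(list(pi = pi_tab, pi_windows = pi_all$windows, sfs = sfs_tab,
                 dfe = dfe_tab, correlations = cors, degeneracy = degmap))
}
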