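# Ground-truth simulator: determinism, conservation, format validity,
# truth recovery.

small_params <- function(seed = 1, ...) {
  te_landscape_params(chrom_lengths = c(300e3, 200e3, 120e3),
                      ins_rate_old = 150, ins_rate_young = 80,
                      del_rate = 0.2, del_exp = 0, genes_per_mb = 25,
                      seed = seed, ...)
}

test_that("the same seed reproduces the landscape exactly", {
  a <- simulate_te_landscape(small_params(5))
  b <- simulate_te_landscape(small_params(5))
  expect_identical(a$te, b$te)
  expect_identical(a$chrom_sizes, b$chrom_sizes)
  c2 <- simulate_te_landscape(small_params(6))
  expect_false(identical(a$te, c2$te))
})

test_that("chromosome length balances deletions and insertions", {
  sim <- simulate_te_landscape(small_params(9))
  for (tc in sim$truth$per_chrom) {
    expect_equal(tc$final_length,
                 tc$initial_length - tc$deleted_bases +
                   tc$young_inserted_bases)
  }
  sizes <- sim$chrom_sizes
  expect_equal(sizes$length,
               vapply(sim$truth$per_chrom, `[[`, numeric(1),
                      "final_length"))
  # TE intervals stay inside the realized chromosome and never overlap
  for (ch in sizes$chrom) {
    te <- sim$te[sim$te$chrom == ch, ]
    te <- te[order(te$start), ]
    expect_true(all(te$end <= sizes$length[sizes$chrom == ch]))
    expect_true(all(te$start[-1] >= te$end[-nrow(te)]))
  }
})

test_that("a silent young epoch leaves no low-divergence records", {
  p <- small_params(3)
  p$ins_rate_young <- 0
  sim <- simulate_te_landscape(p)
  expect_true(all(sim$te$divergence >= 5))
})

test_that("divergences respect the epoch intervals", {
  sim <- simulate_te_landscape(small_params(4))
  young <- sim$te$divergence[sim$te$epoch == "young"]
  old <- sim$te$divergence[sim$te$epoch == "old"]
  expect_true(all(young < 5))
  expect_true(all(old >= 5 & old <= 10))
})

test_that("emitted files parse through every reader", {
  dir <- file.path(tempdir(), "simfiles")
  sim <- simulate_te_landscape(small_params(8), dir = dir,
                               emit_sequence = TRUE)
  rec <- read_repeatmasker(sim$files[["out"]])
  expect_equal(nrow(rec), nrow(sim$te))
  expect_equal(rec$start, sim$te$start)
  fa <- Biostrings::readDNAStringSet(sim$files[["fasta"]])
  expect_equal(unname(Biostrings::width(fa)), sim$chrom_sizes$length)
  ann <- rtracklayer::import(sim$files[["gff"]])
  expect_true(sum(ann$type == "CDS") >= nrow(sim$genes))
  # CDS models are valid: the degeneracy classifier accepts them all
  expect_no_warning(deg <- classify_degeneracy(sim$files[["fasta"]],
                                               sim$files[["gff"]]))
  expect_true(all(c("0D", "4D") %in% deg$label))
  truth <- jsonlite::read_json(sim$files[["truth"]])
  expect_equal(length(truth$per_chrom), 3)
})

test_that("population samples recover the generating theta", {
  dir <- file.path(tempdir(), "simpop")
  sim <- simulate_te_landscape(
    te_landscape_params(chrom_lengths = c(80e3, 60e3), ins_rate_old = 100,
                        ins_rate_young = 50, genes_per_mb = 0, seed = 2),
    dir = dir, emit_sequence = TRUE)
  pp <- popgen_params(theta = 0.008, n_diploids = 8, missing_rate = 0.05,
                      seed = 31)
  pg <- simulate_popgen(pp, sim, vcf_path = file.path(dir, "p.vcf"))
  win <- make_windows(sim$chrom_sizes, window = 20e3)
  pi <- pi_windows(pg$vcf, win)
  # 140 kb at theta 0.008: ratio-of-sums should sit within ~10% of truth
  pooled <- sum(pi$windows$n_diffs) / sum(pi$windows$n_comparisons)
  expect_gt(pooled, 0.008 * 0.85)
  expect_lt(pooled, 0.008 * 1.15)
  # truth record suffices to recompute the realized variant count
  expect_equal(sum(vapply(pg$truth$per_chrom, `[[`, numeric(1),
                          "n_variant")),
               sum(!is.na(read_allsites_vcf(pg$vcf)$alt) &
                     read_allsites_vcf(pg$vcf)$alt != "."))
})

test_that("selection suppresses diversity at 0-fold sites", {
  dir <- file.path(tempdir(), "simsel")
  sim <- simulate_te_landscape(
    te_landscape_params(chrom_lengths = c(100e3), ins_rate_old = 50,
                        ins_rate_young = 20, del_rate = 0.1, del_exp = 0,
                        genes_per_mb = 120, seed = 12),
    dir = dir, emit_sequence = TRUE)
  pp <- popgen_params(theta = 0.008, n_diploids = 8, dfe_beta = 0.3,
                      dfe_Es = 500, missing_rate = 0, seed = 13)
  pg <- simulate_popgen(pp, sim, vcf_path = file.path(dir, "p.vcf"))
  deg <- pg$site_classes
  win <- make_windows(sim$chrom_sizes, window = 100e3)
  p0 <- pi_windows(pg$vcf, win, site_mask = degeneracy_bed(deg, "0D"))
  p4 <- pi_windows(pg$vcf, win, site_mask = degeneracy_bed(deg, "4D"))
  expect_lt(p0$chromosomes$pi, p4$chromosomes$pi)
})

test_that("the fixture suite is deterministic and self-consistent", {
  d1 <- file.path(tempdir(), "fxa")
  d2 <- file.path(tempdir(), "fxb")
  f1 <- make_fixture_suite(d1, seed = 21, chrom_lengths = c(60e3, 40e3,
                                                            25e3),
                           n_diploids = 4)
  f2 <- make_fixture_suite(d2, seed = 21, chrom_lengths = c(60e3, 40e3,
                                                            25e3),
                           n_diploids = 4)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     info = nm)
  }
  d3 <- file.path(tempdir(), "fxc")
  f3 <- make_fixture_suite(d3, seed = 22, chrom_lengths = c(60e3, 40e3,
                                                            25e3),
                           n_diploids = 4)
  expect_false(identical(readLines(f1[["vcf"]]), readLines(f3[["vcf"]])))
  # headers identical across seeds, bodies differ
  h1 <- grep("^##", readLines(f1[["vcf"]]), value = TRUE)
  h3 <- grep("^##", readLines(f3[["vcf"]]), value = TRUE)
  expect_identical(h1[1], h3[1])
})
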