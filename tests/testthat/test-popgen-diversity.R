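# Codon degeneracy, SNP effects, and missing-data-aware diversity.

test_that("canonical codons classify as expected through the full path", {
  # gene = GCT TGG ATT plus a stop; third of GCT is 4D, all of TGG 0D,
  # third of ATT is 3-fold ("other")
  fx <- single_gene_fixture("GCTTGGATTTAA")
  deg <- classify_degeneracy(fx$fasta, fx$gff)
  lab <- deg$label[order(deg$pos)]
  expect_equal(lab[3], "4D")
  expect_equal(lab[4:6], rep("0D", 3))
  expect_equal(lab[9], "other")
})

test_that("reverse-strand genes classify on the reverse complement", {
  cds <- "ATGGCTTGGGCGTAA"
  plus <- single_gene_fixture(cds, strand = "+")
  minus <- single_gene_fixture(cds, strand = "-")
  dp <- classify_degeneracy(plus$fasta, plus$gff)
  dm <- classify_degeneracy(minus$fasta, minus$gff)
  # position i of the CDS maps to offset+i on '+' and to end-1-i on '-'
  dp <- dp[order(dp$pos), ]
  dm <- dm[order(dm$pos, decreasing = TRUE), ]
  expect_equal(dp$label, dm$label)
})

test_that("invalid transcripts are skipped with warnings", {
  fx <- single_gene_fixture("ATGGC")  # length not divisible by 3
  expect_warning(expect_error(classify_degeneracy(fx$fasta, fx$gff),
                              "no valid CDS"), "divisible")
  fx2 <- single_gene_fixture("ATGTAACCCGGG")  # internal stop
  expect_warning(expect_error(classify_degeneracy(fx2$fasta, fx2$gff),
                              "no valid CDS"), "stop")
})

test_that("conflicting labels across overlapping transcripts are flagged", {
  # two transcripts over the same bases with a frame shift of 1 codon
  seqs <- list(chrA = paste0("AAAA", "ATGGCTGCTGCTGCATAA", "TTTT"))
  fa <- write_fasta(seqs)
  gff <- write_gff3_fixture(data.frame(
    chrom = "chrA", start = c(5, 9), end = c(22, 20), strand = "+",
    phase = 0L, tx = c("t1", "t2"), stringsAsFactors = FALSE
  ))
  deg <- classify_degeneracy(fa, gff)
  expect_true(any(deg$label == "conflicting"))
  bed <- degeneracy_bed(deg, "4D")
  conf_pos <- deg$pos[deg$label == "conflicting"]
  expect_false(any(bed$start %in% conf_pos))
})

test_that("SNP effects follow codon substitution", {
  fx <- single_gene_fixture("GCTTGGATTTAA", offset = 10)
  eff <- classify_snp_effect(
    data.frame(chrom = "chrA",
               pos = c(13, 12, 5, 13),   # GCT 3rd, GCT 2nd, intron/outside
               ref = c("T", "C", "C", "TT"),
               alt = c("C", "A", "A", "C"), stringsAsFactors = FALSE),
    genome = fx$fasta, annotation = fx$gff)
  expect_equal(eff, c("synonymous", "nonsynonymous", "other", "other"))
})

test_that("the worked diversity example gives 4/60 exactly", {
  gt <- rbind(c("0/0", "1/1"),
              matrix("0/0", nrow = 9, ncol = 2))
  path <- write_vcf_fixture("chr1", 1:10, rep("A", 10),
                            c("T", rep(".", 9)), gt)
  win <- data.frame(chrom = "chr1", start = 0, end = 10)
  res <- pi_windows(path, win)
  expect_equal(res$windows$pi, 4 / 60)
  expect_equal(res$windows$n_diffs, 4)
  expect_equal(res$windows$n_comparisons, 60)
  expect_equal(res$chromosomes$pi, 4 / 60)
})

test_that("ratio-of-sums equals naive pairwise difference on full calls", {
  for (s in 1:8) {
    sim <- random_fullcall_vcf(n_dip = sample(2:8, 1),
                               L = sample(100:800, 1), seed = 100 + s)
    win <- data.frame(chrom = "chr1", start = 0, end = sim$L)
    got <- pi_windows(sim$path, win)$windows$pi
    expect_equal(got, naive_pi(sim$hap), tolerance = 1e-12)
  }
})

test_that("missing genotypes shrink comparisons, not the estimator", {
  gt <- rbind(c("0/1", "./."),
              c("./.", "./."),
              c("0/0", "0/0"))
  path <- write_vcf_fixture("chr1", 1:3, rep("A", 3), c("T", "T", "."), gt)
  win <- data.frame(chrom = "chr1", start = 0, end = 3)
  res <- pi_windows(path, win)
  # site 1: k=2 alleles 0,1 -> 1 diff / 1 comparison; site 2 contributes
  # nothing; site 3: 6 comparisons, 0 diffs
  expect_equal(res$windows$n_diffs, 1)
  expect_equal(res$windows$n_comparisons, 7)
  expect_equal(res$windows$pi, 1 / 7)
})

test_that("pi is invariant to sample order and REF/ALT relabeling", {
  sim <- random_fullcall_vcf(n_dip = 5, L = 300, seed = 321)
  win <- data.frame(chrom = "chr1", start = 0, end = 300)
  base <- pi_windows(sim$path, win)$windows$pi
  # swap allele labels 0<->1 and permute samples
  hap <- 1L - sim$hap
  gt <- matrix("", nrow = 300, ncol = 5)
  for (d in 1:5) gt[, d] <- paste(hap[2 * d - 1, ], hap[2 * d, ], sep = "/")
  gt <- gt[, c(3, 1, 5, 2, 4)]
  path <- write_vcf_fixture("chr1", 1:300, rep("T", 300),
                            ifelse(colSums(hap) > 0, "A", "."), gt)
  expect_equal(pi_windows(path, win)$windows$pi, base, tolerance = 1e-12)
})

test_that("site masks and exclusion BEDs select contributing sites", {
  gt <- rbind(c("0/1", "0/1"),
              c("0/1", "0/1"),
              c("0/0", "0/0"))
  path <- write_vcf_fixture("chr1", 1:3, rep("A", 3), c("T", "T", "."), gt)
  win <- data.frame(chrom = "chr1", start = 0, end = 3)
  mask <- data.frame(chrom = "chr1", start = 0, end = 1)  # site 1 only
  res <- pi_windows(path, win, site_mask = mask)
  expect_equal(res$windows$n_sites, 1)
  excl <- data.frame(chrom = "chr1", start = 0, end = 2)  # drop sites 1-2
  res2 <- pi_windows(path, win, exclude_bed = excl)
  expect_equal(res2$windows$pi, 0)
  expect_error(pi_windows(path, data.frame(chrom = "nope", start = 0,
                                           end = 3)), "absent")
})

test_that("chromosome 0D/4D ratio handles the neutral and missing cases", {
  p0 <- data.frame(chrom = c("c1", "c2", "c3"),
                   pi = c(0.002, 0.004, 0.001))
  p4 <- data.frame(chrom = c("c1", "c2", "c3"),
                   pi = c(0.008, 0.004, 0))
  r <- chromosome_pi_ratio(p0, p4)
  expect_equal(r$ratio_0d_4d, c(0.25, 1, NA))
})
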