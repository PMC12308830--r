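# Window tiling, densities, bootstrap summaries, telomere profile.

test_that("trailing partial windows are kept only at >= half window", {
  w <- make_windows(c(chr1 = 250000), window = 100000)
  expect_equal(w$start, c(0, 100000, 200000))
  expect_equal(w$end, c(100000, 200000, 250000))
  expect_equal(nrow(make_windows(c(chr1 = 100000), window = 100000)), 1)
  expect_equal(nrow(make_windows(c(chr1 = 249999), window = 100000)), 2)
  expect_error(make_windows(data.frame(chrom = "x", length = 0)), "length")
})

test_that("repeat density uses the interval union", {
  w <- make_windows(c(chr1 = 100000), window = 100000)
  te <- make_te_df("chr1", 0, 10000, 1)
  expect_equal(repeat_density(w, te)$repeat_density, 0.1)
  te2 <- make_te_df("chr1", c(99, 149), c(200, 250), c(1, 1))
  expect_equal(repeat_density(w, te2)$repeat_density, 151 / 100000)
  expect_equal(repeat_density(w, te2[0, , drop = FALSE])$repeat_density, 0)
  expect_error(
    repeat_density(w, make_te_df("chr1", 99999, 100100, 1),
                   chrom_sizes = c(chr1 = 100000)),
    "beyond chromosome end")
})

test_that("windowed union coverage matches a per-base bitmap oracle", {
  set.seed(7)
  for (rep in 1:15) {
    L <- 5000
    n <- sample(1:30, 1)
    starts <- sample(0:(L - 60), n, replace = TRUE)
    ends <- starts + sample(10:300, n, replace = TRUE)
    ends <- pmin(ends, L)
    te <- make_te_df("chr1", starts, ends, rep(1, n))
    w <- make_windows(c(chr1 = L), window = 1000)
    got <- repeat_density(w, te)
    for (i in seq_len(nrow(w))) {
      expect_equal(got$covered_bases[i],
                   bitmap_covered(starts, ends, w$start[i], w$end[i]))
    }
  }
})

test_that("coverage is conserved across windows and order-invariant", {
  set.seed(11)
  L <- 8000
  starts <- sample(0:(L - 200), 40, replace = TRUE)
  ends <- pmin(starts + sample(20:150, 40, replace = TRUE), L)
  te <- make_te_df("chr1", starts, ends, rep(1, 40))
  w <- make_windows(c(chr1 = L), window = 1000)
  d1 <- repeat_density(w, te)
  expect_equal(sum(d1$covered_bases), bitmap_covered(starts, ends, 0, L))
  perm <- te[sample(nrow(te)), , drop = FALSE]
  expect_equal(repeat_density(w, perm)$repeat_density, d1$repeat_density)
})

test_that("GC excludes ambiguous bases from the denominator", {
  fa <- write_fasta(list(chr1 = "GGCCAATT", chr2 = "GGNN", chr3 = "NNNN"))
  w <- data.frame(chrom = c("chr1", "chr2", "chr3"), start = 0,
                  end = c(8, 4, 4))
  g <- gc_content(w, fa)
  expect_equal(g$gc, c(0.5, 1.0, NA))
  expect_equal(g$n_effective_bases, c(8L, 2L, 0L))
  expect_error(gc_content(data.frame(chrom = "zz", start = 0, end = 4), fa),
               "missing from FASTA")
})

test_that("soft-masked lowercase counts normally for GC", {
  fa <- write_fasta(list(chr1 = "ggccAATT"))
  w <- data.frame(chrom = "chr1", start = 0, end = 8)
  expect_equal(gc_content(w, fa)$gc, 0.5)
})

test_that("CDS density unions isoforms and splits at window boundaries", {
  gff <- write_gff3_fixture(data.frame(
    chrom = "chr1",
    start = c(1, 1, 900),        # two isoforms share [1,500]; CDS spans
    end = c(500, 500, 1400),     # the 1000-boundary
    strand = "+", phase = 0L,
    tx = c("t1", "t2", "t3"), stringsAsFactors = FALSE
  ))
  w <- make_windows(c(chr1 = 2000), window = 1000)
  d <- cds_density(w, gff)
  # oracle: bitmap over the union of [0,500) and [899,1400)
  expect_equal(d$cds_density[1],
               bitmap_covered(c(0, 899), c(500, 1400), 0, 1000) / 1000)
  expect_equal(d$cds_density[2],
               bitmap_covered(c(0, 899), c(500, 1400), 1000, 2000) / 1000)
  gff_empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff_empty)
  expect_error(cds_density(w, gff_empty), "CDS")
})

test_that("bootstrap summary collapses on degenerate inputs", {
  w <- data.frame(chrom = "c1", x = rep(0.3, 20))
  cs <- chromosome_summary(w, "x", B = 200, seed = 1)
  expect_equal(cs$mean_stat, 0.3)
  expect_equal(cs$ci_low, 0.3)
  expect_equal(cs$ci_high, 0.3)
  w1 <- data.frame(chrom = "c1", x = 0.42)
  cs1 <- chromosome_summary(w1, "x", B = 200, seed = 1)
  expect_equal(cs1$ci_low, 0.42)
  expect_equal(cs1$ci_high, 0.42)
  expect_error(chromosome_summary(data.frame(chrom = "c1", x = NA_real_),
                                  "x"), "usable")
})

test_that("bootstrap CI narrows as windows accumulate", {
  set.seed(3)
  widths <- vapply(c(10, 100, 1000), function(n) {
    w <- data.frame(chrom = "c", x = rnorm(n, 0.4, 0.05))
    cs <- chromosome_summary(w, "x", B = 400, seed = 9)
    cs$ci_high - cs$ci_low
  }, numeric(1))
  expect_true(widths[1] > widths[2])
  expect_true(widths[2] > widths[3])
})

test_that("bootstrap resampling is reproducible under a seed", {
  w <- data.frame(chrom = "c", x = rnorm(50, 0.4, 0.05))
  a <- chromosome_summary(w, "x", B = 300, seed = 17)
  b <- chromosome_summary(w, "x", B = 300, seed = 17)
  expect_identical(a, b)
})

test_that("telomere profile flags end-proximal enrichment", {
  sizes <- data.frame(chrom = c("c1", "c2"), length = c(10000, 8000))
  te <- rbind(make_te_df("c1", c(0, 9500), c(400, 10000), c(1, 1)),
              make_te_df("c2", c(100, 7600), c(500, 8000), c(1, 1)))
  prof <- telomere_profile(te, sizes, bin = 1000)
  expect_true(prof$repeat_density[1] > max(prof$repeat_density[-1]))
  empty <- telomere_profile(te[0, , drop = FALSE], sizes, bin = 1000)
  expect_true(all(empty$covered_bases == 0))
  expect_error(telomere_profile(te, sizes, bin = 5000), "half")
})
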