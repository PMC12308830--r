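# Synthetic genomes with known truth: two-epoch TE insertion, NAHR-like
# deletion of inter-TE unique sequence between the epochs, gene annotations,
# and site-independent population samples with per-chromosome theta and a
# gamma DFE acting on 0-fold coding sites. Every statistic the analysis
# pipeline computes can be recomputed from the returned truth record.

#' Parameters of the synthetic TE landscape
#'
#' Insertion rates are per Mb and may depend on (initial) chromosome length
#' through a power law `rate * (L/1e6)^exp`; the deletion fraction applied
#' to each inter-TE gap between the old and young epochs is
#' `del_rate * (L/del_ref_length)^del_exp`, clamped to `[0, del_max]`.
#' With `del_exp < 0` smaller chromosomes lose more inter-TE sequence —
#' the NAHR-like mechanism: recombination between closely spaced homologous
#' elements preferentially deletes the unique sequence between them, and
#' small chromosomes recombine more per Mb. Defaults give 20 chromosomes
#' spanning 5-30 Mb, insertion rates independent of length (80 and 40
#' copies/Mb for the old and young epochs, lognormal copy lengths around
#' 0.7 kb), a deletion fraction of 0.3 at the 10-Mb reference, and
#' divergences drawn uniformly from \[0,5)% (young) and \[5,10\]% (old).
#'
#' @param chrom_lengths Integer vector of initial chromosome lengths (bp).
#' @param ins_rate_old,ins_exp_old Old-epoch insertion rate law.
#' @param ins_rate_young,ins_exp_young Young-epoch insertion rate law.
#' @param del_rate,del_exp,del_ref_length,del_max Deletion fraction law.
#' @param te_len_meanlog,te_len_sdlog Lognormal TE copy length parameters.
#' @param young_div,old_div Divergence sampling intervals (percent).
#' @param genes_per_mb Gene density for the synthetic annotation.
#' @param gc Background GC fraction of emitted sequence.
#' @param seed Integer seed driving all randomness.
#' @return List of class `te_landscape_params`.
#' @export
te_landscape_params <- function(chrom_lengths = round(seq(5e6, 30e6,
                                                          length.out = 20)),
                                ins_rate_old = 80, ins_exp_old = 0,
                                ins_rate_young = 40, ins_exp_young = 0,
                                del_rate = 0.3, del_exp = -1,
                                del_ref_length = 1e7, del_max = 0.9,
                                te_len_meanlog = log(600),
                                te_len_sdlog = 0.7,
                                young_div = c(0, 5), old_div = c(5, 10),
                                genes_per_mb = 10, gc = 0.38, seed = 1) {
  stopifnot(all(chrom_lengths > 0), ins_rate_old >= 0, ins_rate_young >= 0,
            del_rate >= 0, del_max >= 0, del_max <= 1, gc > 0, gc < 1)
  structure(as.list(environment()), class = "te_landscape_params")
}

TE_CLASS_TABLE <- data.frame(
  te_class = c("LINE", "LINE", "LINE", "SINE", "LTR", "LTR", "DNA", "DNA",
               "RC"),
  te_family = c("L1", "RTE", "CR1", "tRNA", "Gypsy", "Copia", "hAT",
                "TcMar", "Helitron"),
  weight = c(0.28, 0.16, 0.12, 0.10, 0.08, 0.06, 0.09, 0.06, 0.05),
  stringsAsFactors = FALSE
)

# One chromosome in coordinate space. Returns the final TE table, gene
# table and the per-chromosome truth entries.
sim_chrom_coords <- function(ch, L, par) {
  Lmb <- L / 1e6
  lam_old <- par$ins_rate_old * Lmb^par$ins_exp_old
  lam_young <- par$ins_rate_young * Lmb^par$ins_exp_young
  n_old <- rpois(1, lam_old * Lmb)
  old_len <- if (n_old > 0) {
    pmax(50, round(rlnorm(n_old, par$te_len_meanlog, par$te_len_sdlog)))
  } else integer(0)
  if (sum(old_len) >= 0.8 * L) {
    stop("expected TE footprint exceeds chromosome length on ", ch)
  }
  uniq <- L - sum(old_len)
  gaps <- if (n_old > 0) {
    br <- diff(c(0, sort(runif(n_old)), 1))
    g <- floor(br * uniq)
    g[n_old + 1] <- uniq - sum(g[seq_len(n_old)])
    g
  } else uniq
  delta <- min(max(par$del_rate * (L / par$del_ref_length)^par$del_exp, 0),
               par$del_max)
  del <- rbinom(length(gaps), gaps, delta)
  gaps2 <- gaps - del
  L2 <- sum(gaps2) + sum(old_len)
  n_young <- rpois(1, lam_young * (L2 / 1e6))
  young_len <- if (n_young > 0) {
    pmax(50, round(rlnorm(n_young, par$te_len_meanlog, par$te_len_sdlog)))
  } else integer(0)
  U <- sum(gaps2)
  off <- if (n_young > 0) sort(runif(n_young, 0, U)) else numeric(0)
  cg <- cumsum(gaps2)
  gap_idx <- findInterval(off, cg) + 1L
  # items in final order: young copies sit inside their gap at `off`;
  # the old copy t follows gap t (within = Inf sorts it after the young
  # copies of its gap)
  item_gap <- c(gap_idx, seq_len(n_old))
  item_within <- c(off, rep(Inf, n_old))
  item_len <- c(young_len, old_len)
  item_epoch <- c(rep("young", n_young), rep("old", n_old))
  item_ub <- c(off, cg[seq_len(n_old)])  # unique bases preceding the item
  if (length(item_len) == 0) {
    te <- list(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), divergence = numeric(0),
               class_idx = integer(0), score = numeric(0),
               epoch = character(0))
    truth <- list(chrom = ch, initial_length = L, final_length = L2,
                  deleted_bases = sum(del), young_inserted_bases = 0,
                  n_old = 0L, n_young = 0L, delta = delta,
                  lambda_old = lam_old, lambda_young = lam_young)
    return(list(te = te, truth = truth, final_length = L2))
  }
  o <- order(item_gap, item_within)
  lens <- item_len[o]
  starts <- floor(item_ub[o]) + c(0, cumsum(lens))[seq_along(lens)]
  epoch <- item_epoch[o]
  nt <- length(epoch)
  div <- numeric(nt)
  yng <- epoch == "young"
  div[yng] <- runif(sum(yng), par$young_div[1], par$young_div[2])
  div[!yng] <- runif(sum(!yng), par$old_div[1], par$old_div[2])
  ci <- sample(nrow(TE_CLASS_TABLE), nt, replace = TRUE,
               prob = TE_CLASS_TABLE$weight)
  Lf <- L2 + sum(young_len)
  te <- list(
    chrom = rep(ch, nt), start = starts, end = starts + lens,
    strand = sample(c("+", "-"), nt, replace = TRUE),
    divergence = round(div, 1), class_idx = ci,
    score = round(runif(nt, 200, 5000)), epoch = epoch
  )
  truth <- list(chrom = ch, initial_length = L, final_length = Lf,
                deleted_bases = sum(del),
                young_inserted_bases = sum(young_len),
                n_old = n_old, n_young = n_young, delta = delta,
                lambda_old = lam_old, lambda_young = lam_young)
  list(te = te, truth = truth, final_length = Lf)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

empty_genes <- function() {
  data.frame(gene_id = character(0), tx_id = character(0),
             chrom = character(0), strand = character(0),
             exon_rank = integer(0), start = numeric(0), end = numeric(0),
             phase = integer(0), cds_len = integer(0),
             exon1_len = integer(0), stringsAsFactors = FALSE)
}

sim_genes <- function(ch, Lf, par) {
  n_genes <- if (par$genes_per_mb > 0) {
    rpois(1, par$genes_per_mb * Lf / 1e6)
  } else 0L
  if (n_genes == 0) return(empty_genes())
  cds_len <- 3 * sample(100:400, n_genes, replace = TRUE)
  two_exon <- runif(n_genes) < 0.3
  intron <- ifelse(two_exon, sample(100:2000, n_genes, replace = TRUE), 0)
  span <- cds_len + intron
  starts <- sort(round(runif(n_genes, 0, pmax(1, Lf - max(span) - 1))))
  keep <- rep(TRUE, n_genes)
  last_end <- -1
  for (i in seq_len(n_genes)) {
    if (starts[i] <= last_end) keep[i] <- FALSE
    else last_end <- starts[i] + span[i]
  }
  idx <- which(keep)
  m <- length(idx)
  if (m == 0) return(empty_genes())
  gid <- sprintf("%s_g%03d", ch, seq_len(m))
  strand <- sample(c("+", "-"), m, replace = TRUE)
  cl <- cds_len[idx]
  st <- starts[idx]
  intr <- intron[idx]
  two <- two_exon[idx]
  # exon-1 length (genomic order) for two-exon genes: a codon-interior or
  # codon-boundary split anywhere in the middle of the CDS
  e1 <- 3 * (30 + floor(runif(m) * (cl / 3 - 60))) + sample(0:2, m,
                                                            replace = TRUE)
  e1 <- pmin(pmax(e1, 3), cl - 3)
  e1[!two] <- cl[!two]
  tr_len1 <- ifelse(strand == "+", e1, cl - e1)
  phase2 <- (3L - tr_len1 %% 3L) %% 3L  # phase of translation-second exon
  # genomic-order phases: '+' -> (0, phase2); '-' -> (phase2, 0)
  ph1 <- ifelse(strand == "+", 0L, phase2)
  ph2 <- ifelse(strand == "+", phase2, 0L)
  one_rows <- if (any(!two)) data.frame(
    gene_id = gid[!two], tx_id = paste0(gid[!two], ".t1"),
    chrom = rep(ch, sum(!two)),
    strand = strand[!two], exon_rank = 1L, start = st[!two],
    end = st[!two] + cl[!two], phase = 0L, cds_len = cl[!two],
    exon1_len = cl[!two], stringsAsFactors = FALSE
  ) else empty_genes()
  two_rows <- if (any(two)) data.frame(
    gene_id = rep(gid[two], each = 2),
    tx_id = rep(paste0(gid[two], ".t1"), each = 2),
    chrom = rep(ch, 2 * sum(two)),
    strand = rep(strand[two], each = 2),
    exon_rank = rep(1:2, sum(two)),
    start = as.numeric(rbind(st[two], st[two] + e1[two] + intr[two])),
    end = as.numeric(rbind(st[two] + e1[two],
                           st[two] + cl[two] + intr[two])),
    phase = as.integer(rbind(ph1[two], ph2[two])),
    cds_len = rep(cl[two], each = 2),
    exon1_len = rep(e1[two], each = 2),
    stringsAsFactors = FALSE
  ) else empty_genes()
  out <- rbind(one_rows, two_rows)
  out[order(out$start, out$exon_rank), , drop = FALSE]
}

# Random coding sequence: ATG + non-stop codons + TAA.
random_cds <- function(len) {
  ncod <- len / 3
  all_codons <- names(Biostrings::GENETIC_CODE)
  pool <- setdiff(all_codons, STOP_CODONS)
  mid <- sample(pool, ncod - 2, replace = TRUE)
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

build_chrom_sequence <- function(ch, Lf, te, genes, motifs, par) {
  s <- sample(BASES, Lf, replace = TRUE,
              prob = c((1 - par$gc) / 2, par$gc / 2, par$gc / 2,
                       (1 - par$gc) / 2))
  te_c <- te[te$chrom == ch, , drop = FALSE]
  for (i in seq_len(nrow(te_c))) {
    len <- te_c$end[i] - te_c$start[i]
    motif <- motifs[[te_c$te_family[i]]]
    body <- rep_len(motif, len)
    nmut <- round(len * te_c$divergence[i] / 100)
    if (nmut > 0) {
      pos <- sample(len, nmut)
      body[pos] <- sample(BASES, nmut, replace = TRUE)
    }
    s[(te_c$start[i] + 1):te_c$end[i]] <- body
  }
  g_c <- genes[genes$chrom == ch, , drop = FALSE]
  for (tx in unique(g_c$tx_id)) {
    ex <- g_c[g_c$tx_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cs <- random_cds(ex$cds_len[1])
    genomic <- if (ex$strand[1] == "+") cs else revcomp_chr(cs)
    offset <- 0
    for (e in seq_len(nrow(ex))) {
      w <- ex$end[e] - ex$start[e]
      piece <- substring(genomic, offset + 1, offset + w)
      s[(ex$start[e] + 1):ex$end[e]] <- strsplit(piece, "")[[1]]
      offset <- offset + w
    }
  }
  paste(s, collapse = "")
}

write_gff3 <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    ch <- g$chrom[1]
    strand <- g$strand[1]
    gs <- as.integer(min(g$start) + 1)
    ge <- as.integer(max(g$end))
    tx <- g$tx_id[1]
    writeLines(c(
      sprintf("%s\tchromTE_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s", ch, gs, ge,
              strand, gid),
      sprintf("%s\tchromTE_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              ch, gs, ge, strand, tx, gid),
      sprintf("%s\tchromTE_sim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
              g$chrom, as.integer(g$start + 1), as.integer(g$end), strand,
              as.integer(g$phase), tx, tx)
    ), con)
  }
  invisible(path)
}

#' Simulate a TE landscape with size-dependent insertion and deletion
#'
#' Per chromosome: old-epoch TE copies are placed uniformly (broken-stick
#' gaps) at the old-epoch rate; each inter-TE gap then loses a
#' Binomial(gap, delta(L)) number of bases (the NAHR-like deletion acts
#' only on unique sequence, never on TE bodies); young-epoch copies are
#' then inserted uniformly over the remaining unique sequence, adding
#' their length. Divergences are drawn from the young/old intervals, and a
#' gene annotation with valid CDS models (no internal stops, phase-aware,
#' some two-exon) is laid on top. Optionally emits FASTA / RepeatMasker
#' `.out` / GFF3 / chromosome-size TSV / truth JSON files.
#'
#' @param params A [te_landscape_params()] object.
#' @param dir Optional output directory (created if needed).
#' @param emit_sequence Whether to build and write genome sequence
#'   (expensive for many-Mb genomes; coordinate-only simulation is enough
#'   for density/spacing statistics).
#' @return List with `te` (annotation data.frame incl. `epoch`), `genes`,
#'   `chrom_sizes` (final lengths), `truth` (all generating parameters and
#'   per-chromosome realizations), `sequences` (`DNAStringSet` or NULL),
#'   and `files` (paths written).
#' @export
simulate_te_landscape <- function(params = te_landscape_params(),
                                  dir = NULL,
                                  emit_sequence = !is.null(dir)) {
  stopifnot(inherits(params, "te_landscape_params"))
  with_seed(params$seed, {
    chroms <- sprintf("chr%02d", seq_along(params$chrom_lengths))
    sims <- lapply(seq_along(chroms), function(i) {
      sim_chrom_coords(chroms[i], params$chrom_lengths[i], params)
    })
    col <- function(nm) unlist(lapply(sims, function(s) s$te[[nm]]),
                               use.names = FALSE)
    ci <- col("class_idx")
    te <- data.frame(
      chrom = col("chrom"), start = col("start"), end = col("end"),
      strand = col("strand"), divergence = col("divergence"),
      pct_del = 0, pct_ins = 0,
      repeat_name = paste0(TE_CLASS_TABLE$te_family[ci], "-syn"),
      te_class = TE_CLASS_TABLE$te_class[ci],
      te_family = TE_CLASS_TABLE$te_family[ci],
      score = col("score"),
      id = if (length(ci)) as.character(seq_along(ci)) else character(0),
      overlap_flag = FALSE, epoch = col("epoch"),
      stringsAsFactors = FALSE
    )
    sizes <- data.frame(chrom = chroms,
                        length = vapply(sims, `[[`, numeric(1),
                                        "final_length"),
                        stringsAsFactors = FALSE)
    genes <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      sim_genes(chroms[i], sizes$length[i], params)
    }))
    motifs <- lapply(stats::setNames(unique(TE_CLASS_TABLE$te_family),
                                     unique(TE_CLASS_TABLE$te_family)),
                     function(f) sample(BASES, 5000, replace = TRUE))
    sequences <- NULL
    if (emit_sequence) {
      seqs <- vapply(seq_along(chroms), function(i) {
        build_chrom_sequence(chroms[i], sizes$length[i], te, genes, motifs,
                             params)
      }, character(1))
      sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
    }
    truth <- list(
      params = params[setdiff(names(params), character(0))],
      per_chrom = lapply(sims, `[[`, "truth")
    )
    files <- character(0)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out_path <- file.path(dir, "repeats.out")
      write_repeatmasker(te, out_path)
      gff_path <- file.path(dir, "genes.gff3")
      write_gff3(genes, gff_path)
      sizes_path <- file.path(dir, "chrom_sizes.tsv")
      write_tsv(sizes, sizes_path)
      truth_path <- file.path(dir, "truth_landscape.json")
      jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
      files <- c(out = out_path, gff = gff_path, sizes = sizes_path,
                 truth = truth_path)
      if (emit_sequence) {
        fa_path <- file.path(dir, "genome.fa")
        Biostrings::writeXStringSet(sequences, fa_path)
        files <- c(files, fasta = fa_path)
      }
    }
    list(te = te, genes = genes, chrom_sizes = sizes, truth = truth,
         sequences = sequences, files = files)
  })
}

#' Parameters of the synthetic population sample
#'
#' @param theta Per-site nucleotide diversity; a single value or a vector
#'   named by chromosome. Must lie in (0, 0.1).
#' @param n_diploids Number of diploid individuals sampled.
#' @param dfe_beta,dfe_Es Gamma DFE (shape, mean |4Ns|) acting on 0-fold
#'   coding sites; 4-fold and noncoding sites evolve neutrally.
#' @param missing_rate Per-genotype missing probability in [0, 1).
#' @param seed Integer seed.
#' @return List of class `popgen_params`.
#' @export
popgen_params <- function(theta = 0.006, n_diploids = 8, dfe_beta = 0.3,
                          dfe_Es = 500, missing_rate = 0.03, seed = 1) {
  stopifnot(all(theta > 0), all(theta < 0.1), n_diploids >= 2,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "popgen_params")
}

#' Simulate an all-sites population VCF with known truth
#'
#' Every site of every chromosome is emitted. Neutral sites (noncoding and
#' 4-fold degenerate) segregate with probability `theta * sum(1/i)` and
#' sample allele counts proportional to the neutral `1/i` spectrum, so the
#' expected per-site pairwise diversity equals `theta` exactly; 0-fold
#' sites use the gamma-DFE mixture spectrum instead. Genotypes pair the
#' `2n` simulated alleles and are masked at the missing rate. Sites are
#' independent (no linkage): the windowed diversity, SFS and DFE
#' statistics consumed downstream do not require linkage disequilibrium.
#'
#' @param params A [popgen_params()] object.
#' @param genome Landscape list from [simulate_te_landscape()] (sequences
#'   used for REF alleles when present), a `DNAStringSet`/FASTA path, or a
#'   chromosome-size table (REF alleles then drawn at random).
#' @param annotation Optional GFF3 path/`GRanges`; with sequence available
#'   the 0D/4D site classes are derived via [classify_degeneracy()].
#' @param vcf_path Output VCF path (plain text).
#' @param truth_path Optional JSON truth output.
#' @return List with `vcf`, `truth` (per-chromosome theta, class site
#'   counts, variant allele counts) and `site_classes` (data.frame of 0D/4D
#'   positions used).
#' @export
simulate_popgen <- function(params, genome, annotation = NULL,
                            vcf_path, truth_path = NULL) {
  stopifnot(inherits(params, "popgen_params"))
  sequences <- NULL
  if (is.list(genome) && !is.null(genome$chrom_sizes)) {
    sizes <- genome$chrom_sizes
    sequences <- genome$sequences
    if (is.null(annotation) && !is.null(genome$genes) &&
        nrow(genome$genes) > 0 && !is.null(sequences)) {
      annotation <- genes_to_granges(genome$genes)
    }
  } else if (methods::is(genome, "DNAStringSet") ||
             (is.character(genome) && file.exists(genome) &&
              grepl("\\.(fa|fasta|fna)(\\.gz)?$", genome))) {
    sequences <- load_genome(genome)
    sizes <- load_chrom_sizes(sequences)
  } else {
    sizes <- load_chrom_sizes(genome)
  }
  degmap <- NULL
  if (!is.null(annotation) && !is.null(sequences)) {
    degmap <- classify_degeneracy(sequences, annotation)
  }
  theta <- params$theta
  if (is.null(names(theta))) {
    theta <- stats::setNames(rep(theta, length.out = nrow(sizes)),
                             sizes$chrom)
  }
  N2 <- 2L * params$n_diploids
  H <- sum(1 / seq_len(N2 - 1))
  u_neut <- 1 / seq_len(N2 - 1)
  u_sel <- expected_unfolded_sfs_gamma(params$dfe_beta, params$dfe_Es, N2)
  with_seed(params$seed, {
    con <- file(vcf_path, open = "wt")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s,length=%d>", sizes$chrom,
              as.integer(sizes$length)),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT",
              sprintf("S%02d", seq_len(params$n_diploids))),
            collapse = "\t")
    ), con)
    truth_chrom <- list()
    for (ci in seq_len(nrow(sizes))) {
      ch <- sizes$chrom[ci]
      L <- as.integer(sizes$length[ci])
      th <- unname(theta[ch])
      if (!is.finite(th)) stop("no theta for chromosome ", ch)
      cls <- rep("neutral", L)
      if (!is.null(degmap)) {
        dm <- degmap[degmap$chrom == ch, , drop = FALSE]
        cls[dm$pos[dm$label == "0D"] + 1L] <- "0D"
        cls[dm$pos[dm$label == "4D"] + 1L] <- "4D"
      }
      p_neut <- th * H
      p_sel <- th * sum(u_sel)
      if (max(p_neut, p_sel) >= 1) stop("theta too large for sample size")
      is_sel <- cls == "0D"
      u <- runif(L)
      variant <- (is_sel & u < p_sel) | (!is_sel & u < p_neut)
      vi <- which(variant)
      counts <- integer(length(vi))
      if (length(vi)) {
        sel_v <- is_sel[vi]
        counts[sel_v] <- sample(N2 - 1, sum(sel_v), replace = TRUE,
                                prob = u_sel)
        counts[!sel_v] <- sample(N2 - 1, sum(!sel_v), replace = TRUE,
                                 prob = u_neut)
      }
      refs <- if (!is.null(sequences)) {
        strsplit(as.character(sequences[[ch]]), "")[[1]]
      } else {
        sample(BASES, L, replace = TRUE)
      }
      alts <- rep(".", L)
      if (length(vi)) {
        alts[vi] <- vapply(refs[vi], function(b) {
          sample(setdiff(BASES, toupper(b)), 1)
        }, character(1))
      }
      gt <- matrix("0/0", nrow = L, ncol = params$n_diploids)
      for (j in seq_along(vi)) {
        al <- integer(N2)
        al[sample(N2, counts[j])] <- 1L
        gt[vi[j], ] <- paste(al[seq(1, N2, 2)], al[seq(2, N2, 2)],
                             sep = "/")
      }
      if (params$missing_rate > 0) {
        miss <- matrix(runif(L * params$n_diploids) < params$missing_rate,
                       nrow = L)
        gt[miss] <- "./."
      }
      body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                      ch, seq_len(L), toupper(refs), alts,
                      do.call(function(...) paste(..., sep = "\t"),
                              lapply(seq_len(params$n_diploids),
                                     function(s) gt[, s])))
      writeLines(body, con)
      truth_chrom[[ch]] <- list(
        chrom = ch, theta = th, n_sites = L,
        n_sites_0d = sum(cls == "0D"), n_sites_4d = sum(cls == "4D"),
        n_variant = length(vi),
        variant_pos = vi, variant_count = counts
      )
    }
    truth <- list(params = unclass(params), n_haploid = N2,
                  dfe = list(beta = params$dfe_beta, Es = params$dfe_Es),
                  per_chrom = truth_chrom)
    if (!is.null(truth_path)) {
      jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    }
    site_classes <- if (!is.null(degmap)) degmap else NULL
    list(vcf = vcf_path, truth = truth, site_classes = site_classes)
  })
}

# genes data.frame (simulator layout) -> GRanges with CDS features carrying
# Parent and phase, as rtracklayer would import them.
genes_to_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- genes$phase
  S4Vectors::mcols(gr)$Parent <- S4Vectors::List(as.list(genes$tx_id))
  gr
}

#' Write a deterministic miniature dataset exercising every reader/writer
#'
#' Builds a small three-chromosome genome (TE landscape, genes, sequence),
#' a population sample, and writes FASTA, RepeatMasker `.out`, GFF3,
#' all-sites VCF, chromosome-size TSV and truth JSON files. The same seed
#' always produces byte-identical outputs.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param chrom_lengths Initial chromosome lengths (kept small so the
#'   suite builds in seconds).
#' @param n_diploids Diploid sample size for the VCF.
#' @return Named character vector of file paths, invisibly a list with the
#'   in-memory objects attached as attributes.
#' @export
make_fixture_suite <- function(dir, seed = 1,
                               chrom_lengths = c(120e3, 80e3, 50e3),
                               n_diploids = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lp <- te_landscape_params(
    chrom_lengths = chrom_lengths,
    ins_rate_old = 250, ins_rate_young = 150,
    del_rate = 0.15, del_exp = 0,
    genes_per_mb = 40, seed = seed
  )
  land <- simulate_te_landscape(lp, dir = dir, emit_sequence = TRUE)
  pp <- popgen_params(theta = 0.006, n_diploids = n_diploids,
                      missing_rate = 0.03, seed = seed + 101)
  pg <- simulate_popgen(pp, land, vcf_path = file.path(dir, "popgen.vcf"),
                        truth_path = file.path(dir, "truth_popgen.json"))
  files <- c(land$files, vcf = pg$vcf,
             truth_popgen = file.path(dir, "truth_popgen.json"))
  structure(files, landscape = land, popgen = pg)
}
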