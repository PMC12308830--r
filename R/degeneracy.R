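# Codon-degeneracy classification of coding sites (0-fold / 4-fold) and
# synonymous/nonsynonymous SNP effect calls, derived directly from the
# standard genetic code, CDS features and the genome sequence.

BASES <- c("A", "C", "G", "T")

# n_syn[codon, pos]: number of the 3 alternative bases at `pos` that leave
# the encoded amino acid unchanged. 3 -> 4D, 0 -> 0D, else other.
degeneracy_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      codons <- names(gc)
      m <- matrix(0L, nrow = length(codons), ncol = 3,
                  dimnames = list(codons, NULL))
      for (cd in codons) {
        for (p in 1:3) {
          alts <- BASES[BASES != substr(cd, p, p)]
          n <- 0L
          for (b in alts) {
            alt <- cd
            substr(alt, p, p) <- b
            if (gc[[alt]] == gc[[cd]]) n <- n + 1L
          }
          m[cd, p] <- n
        }
      }
      tab <<- m
    }
    tab
  }
})

codon_degeneracy_label <- function(nsyn) {
  ifelse(nsyn == 3L, "4D", ifelse(nsyn == 0L, "0D", "other"))
}

# Build the per-transcript CDS model used by both the degeneracy map and
# the SNP-effect classifier. Transcripts whose CDS length is not a multiple
# of 3 after phase adjustment, or which contain an internal stop codon, are
# skipped with a warning.
#
# Returns a list of transcripts, each with: id, chrom, strand,
# genomic_pos (1-based, in translation order), seq (coding-strand
# character vector, same order).
build_cds_index <- function(genome, annotation) {
  genome <- load_genome(genome)
  ann <- load_annotation(annotation)
  cds <- ann[!is.na(ann$type) & ann$type == "CDS"]
  if (length(cds) == 0) stop("annotation contains no CDS features")
  mc <- S4Vectors::mcols(cds)
  tx_id <- if ("Parent" %in% names(mc) && any(lengths(mc$Parent) > 0)) {
    vapply(as.list(mc$Parent), function(p) {
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
  } else if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("ID" %in% names(mc)) {
    as.character(mc$ID)
  } else {
    stop("CDS features carry neither Parent nor transcript_id")
  }
  gcode <- Biostrings::GENETIC_CODE
  out <- list()
  for (tx in unique(tx_id)) {
    seg <- cds[tx_id == tx]
    seg <- seg[order(GenomicRanges::start(seg))]
    strand <- as.character(GenomicRanges::strand(seg)[1])
    ch <- as.character(GenomicRanges::seqnames(seg)[1])
    if (!ch %in% names(genome)) {
      warning("transcript ", tx, " on chromosome absent from FASTA; skipped")
      next
    }
    pos <- unlist(lapply(seq_along(seg), function(i) {
      seq.int(GenomicRanges::start(seg)[i], GenomicRanges::end(seg)[i])
    }))
    sq <- paste(vapply(seq_along(seg), function(i) {
      as.character(Biostrings::subseq(genome[[ch]],
                                      GenomicRanges::start(seg)[i],
                                      GenomicRanges::end(seg)[i]))
    }, character(1)), collapse = "")
    if (strand == "-") {
      sq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
      pos <- rev(pos)
    }
    ph <- S4Vectors::mcols(seg)$phase
    first_seg <- if (strand == "-") length(seg) else 1L
    phase <- if (!is.null(ph) && !is.na(ph[first_seg])) {
      as.integer(ph[first_seg])
    } else 0L
    if (phase > 0) {
      pos <- pos[-seq_len(phase)]
      sq <- substring(sq, phase + 1)
    }
    if (nchar(sq) %% 3 != 0) {
      warning("CDS length of ", tx, " not divisible by 3 after phase; skipped")
      next
    }
    ncod <- nchar(sq) / 3
    codons <- substring(sq, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    valid <- codons %in% names(gcode)
    aas <- rep(NA_character_, ncod)
    aas[valid] <- unname(gcode[codons[valid]])
    if (ncod > 1 && any(aas[seq_len(ncod - 1)] == "*", na.rm = TRUE)) {
      warning("premature stop codon in ", tx, "; skipped")
      next
    }
    out[[tx]] <- list(id = tx, chrom = ch, strand = strand,
                      genomic_pos = pos,
                      seq = strsplit(sq, "")[[1]],
                      codons = codons)
  }
  if (length(out) == 0) stop("no valid CDS transcript could be built")
  out
}

#' Classify coding positions by codon degeneracy
#'
#' Every CDS base is labeled by the number of synonymous changes among its
#' three alternative bases: all three synonymous gives 4-fold degenerate
#' (`"4D"`), none gives 0-fold (`"0D"`), anything in between `"other"`.
#' Positions covered by overlapping transcripts that disagree are labeled
#' `"conflicting"` and excluded from the 0D/4D site sets. Reverse-strand
#' CDS are evaluated on the reverse complement; ambiguous-base codons are
#' left unlabeled.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param annotation GFF3/GTF path or `GRanges` with CDS features carrying
#'   strand and phase.
#' @return data.frame with `chrom`, `pos` (0-based), `label` in
#'   `{"0D", "4D", "other", "conflicting"}` and `n_transcripts`.
#' @seealso [degeneracy_bed()] to export 0D/4D site sets as BED.
#' @export
classify_degeneracy <- function(genome, annotation) {
  idx <- build_cds_index(genome, annotation)
  lut <- degeneracy_lookup()
  per_tx <- lapply(idx, function(tx) {
    n <- length(tx$seq)
    cod_i <- (seq_len(n) - 1) %/% 3 + 1
    pos_i <- (seq_len(n) - 1) %% 3 + 1
    keep <- tx$codons[cod_i] %in% rownames(lut)
    lab <- rep(NA_character_, n)
    lab[keep] <- codon_degeneracy_label(
      lut[cbind(match(tx$codons[cod_i[keep]], rownames(lut)), pos_i[keep])]
    )
    data.frame(chrom = tx$chrom, pos = tx$genomic_pos - 1L, label = lab,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_tx)
  all <- all[!is.na(all$label), , drop = FALSE]
  key <- paste(all$chrom, all$pos, sep = ":")
  nlab <- tapply(all$label, key, function(x) length(unique(x)))
  ntx <- tapply(all$label, key, length)
  lab1 <- tapply(all$label, key, function(x) x[1])
  keys <- names(lab1)
  sp <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(sp, `[`, character(1), 1),
    pos = as.integer(vapply(sp, `[`, character(1), 2)),
    label = ifelse(nlab[keys] > 1, "conflicting", lab1[keys]),
    n_transcripts = as.integer(ntx[keys]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Export a degeneracy site class as BED intervals
#'
#' @param degmap data.frame from [classify_degeneracy()].
#' @param label Site class to export (`"0D"` or `"4D"`); conflicting sites
#'   are never exported.
#' @param path Optional output path; when given, a 3-column BED file
#'   (0-based half-open) is written.
#' @return data.frame with `chrom`, `start`, `end` (one base per row).
#' @export
degeneracy_bed <- function(degmap, label = c("4D", "0D"), path = NULL) {
  label <- match.arg(label)
  d <- degmap[degmap$label == label, , drop = FALSE]
  bed <- data.frame(chrom = d$chrom, start = d$pos, end = d$pos + 1L,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) write_bed(bed, path)
  bed
}

#' Classify SNPs as synonymous or nonsynonymous
#'
#' The alternate allele is substituted into the reference codon of each
#' transcript covering the site; an unchanged amino acid is synonymous,
#' a changed one (including stop gain/loss) nonsynonymous. Indels, sites
#' outside any valid CDS, and sites where overlapping transcripts disagree
#' are `"other"`.
#'
#' @param snps data.frame with columns `chrom`, `pos` (1-based, as in a
#'   VCF), `ref`, `alt`.
#' @param genome FASTA path or `DNAStringSet`.
#' @param annotation GFF3/GTF path or `GRanges`; alternatively pass a
#'   prebuilt index via `cds_index` to amortize construction.
#' @param cds_index Optional result of the internal CDS model builder.
#' @return Character vector (`"synonymous"`, `"nonsynonymous"`, `"other"`)
#'   aligned with the rows of `snps`.
#' @export
classify_snp_effect <- function(snps, genome = NULL, annotation = NULL,
                                cds_index = NULL) {
  if (is.null(cds_index)) cds_index <- build_cds_index(genome, annotation)
  gcode <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # per-chromosome position -> list of (tx, offset)
  lookup <- new.env(parent = emptyenv())
  for (tx in cds_index) {
    keys <- paste0(tx$chrom, ":", tx$genomic_pos)
    for (i in seq_along(keys)) {
      hit <- list(tx = tx, i = i)
      cur <- lookup[[keys[i]]]
      lookup[[keys[i]]] <- c(cur, list(hit))
    }
  }
  vapply(seq_len(nrow(snps)), function(r) {
    ref <- toupper(snps$ref[r])
    alt <- toupper(snps$alt[r])
    if (nchar(ref) != 1 || nchar(alt) != 1 ||
        !(ref %in% BASES) || !(alt %in% BASES)) {
      return("other")
    }
    hits <- lookup[[paste0(snps$chrom[r], ":", snps$pos[r])]]
    if (is.null(hits)) return("other")
    calls <- vapply(hits, function(h) {
      tx <- h$tx
      i <- h$i
      ref_c <- if (tx$strand == "-") comp[[ref]] else ref
      alt_c <- if (tx$strand == "-") comp[[alt]] else alt
      if (tx$seq[i] != ref_c) return(NA_character_)  # ref mismatch
      ci <- (i - 1) %/% 3
      codon <- tx$codons[ci + 1]
      if (!codon %in% names(gcode)) return(NA_character_)
      new <- codon
      substr(new, (i - 1) %% 3 + 1, (i - 1) %% 3 + 1) <- alt_c
      if (gcode[[new]] == gcode[[codon]]) "synonymous" else "nonsynonymous"
    }, character(1))
    calls <- calls[!is.na(calls)]
    if (length(calls) == 0) return("other")
    if (length(unique(calls)) > 1) return("other")
    calls[1]
  }, character(1))
}
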