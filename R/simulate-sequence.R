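# Droplet simulator (sequence mode).
#
# Generates actual reads against a small synthetic genome so the full
# pipeline (alignment-free here: reads are emitted with known placement)
# can be exercised end to end: genome FASTA, donor VCF, peaks BED,
# paired FASTQ per modality, and optionally a SAM of the true alignments
# (handy for testing the pileup without an external aligner; no
# pre-installed package writes SAM records from scratch, so the few
# tab-separated lines are emitted directly). Molecule structure (droplet
# composition, ambient fractions, coverage, peak logic, splice states,
# sequencing error) follows the same distributions as abstract mode; the
# number of SNPs a read overlaps now arises from its placement rather
# than from a Poisson draw.

#' Generate a synthetic genome with SNPs, genes, and peaks
#'
#' Random genome of `n_chrom` chromosomes of `chrom_len` bp; SNPs every
#' ~`snp_spacing` bp (ref = genome base, alt = a different base); genes of
#' `gene_len` bp with 1..`n_isoforms_max` isoforms (exon subsets of a
#' three-exon structure; the unspliced form is the full pre-mRNA); peaks
#' of `peak_len` bp. Genes and peaks are placed on disjoint grids.
#'
#' @param cfg a [simConfig()] (geometry fields are used).
#' @return list: `genome` (DNAStringSet), `snps` (data.table), `genes`
#'   (data.table with exon structure), `peaks` (GRanges).
#' @export
makeSyntheticGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  ba <- c("A", "C", "G", "T")
  chroms <- sprintf("chrS%d", seq_len(cfg$n_chrom))
  genome <- DNAStringSet(vapply(seq_len(cfg$n_chrom), function(i)
    paste(sample(ba, cfg$chrom_len, replace = TRUE), collapse = ""),
    character(1)))
  names(genome) <- chroms

  snps <- rbindlist(lapply(chroms, function(ch) {
    pos <- seq(cfg$snp_spacing, cfg$chrom_len - 1L, by = cfg$snp_spacing)
    pos <- pos + sample.int(200L, length(pos), replace = TRUE) - 100L
    pos <- pos[pos >= 1L & pos <= cfg$chrom_len]
    data.table(chrom = ch, pos = as.integer(pos))
  }))
  gseq <- genome
  snps[, ref := vapply(seq_len(.N), function(k)
    as.character(subseq(gseq[[chrom[k]]], pos[k], pos[k])), character(1))]
  snps[, alt := vapply(ref, function(r) sample(setdiff(ba, r), 1L),
                       character(1))]
  snps[, variant := paste(chrom, pos, ref, alt, sep = ":")]

  # genes and peaks on disjoint coarse grids
  slot_len <- cfg$gene_len + cfg$peak_len + 200L
  genes <- rbindlist(lapply(chroms, function(ch) {
    starts <- seq(1L, cfg$chrom_len - slot_len, by = slot_len)
    data.table(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + cfg$gene_len - 1L))
  }))
  if (nrow(genes) < cfg$n_genes)
    stop("genome too small for ", cfg$n_genes, " genes; increase ",
         "chrom_len or reduce n_genes")
  genes <- genes[sample.int(nrow(genes), cfg$n_genes)]
  genes[, gene := sprintf("gene%05d", .I)]
  genes[, n_iso := sample.int(cfg$n_isoforms_max, .N, replace = TRUE)]
  el <- (genes$end - genes$start + 1L) %/% 3L
  genes[, `:=`(e1s = start, e1e = start + el - 1L,
               e2s = start + el, e2e = start + 2L * el - 1L,
               e3s = start + 2L * el, e3e = end)]

  peaks <- rbindlist(lapply(chroms, function(ch) {
    starts <- seq(cfg$gene_len + 101L, cfg$chrom_len - slot_len,
                  by = slot_len)
    data.table(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + cfg$peak_len - 1L))
  }))
  if (nrow(peaks) < cfg$n_peaks)
    stop("genome too small for ", cfg$n_peaks, " peaks")
  peaks <- peaks[sample.int(nrow(peaks), cfg$n_peaks)]
  list(genome = genome, snps = snps, genes = genes,
       peaks = GRanges(peaks$chrom, IRanges(peaks$start, peaks$end)))
}

# exon subsets per isoform index (1 = all, 2 = skip middle, 3 = skip last)
.iso_exons <- function(gene_row, iso) {
  ex <- rbind(c(gene_row$e1s, gene_row$e1e),
              c(gene_row$e2s, gene_row$e2e),
              c(gene_row$e3s, gene_row$e3e))
  keep <- switch(iso, `1` = 1:3, `2` = c(1L, 3L), `3` = 1:2)
  ex[keep, , drop = FALSE]
}

# map a transcript-coordinate window [t0, t0 + len - 1] through an exon
# chain to genomic blocks
.tx_to_genome <- function(exons, t0, len) {
  widths <- exons[, 2L] - exons[, 1L] + 1L
  offs <- cumsum(c(0L, widths))
  t1 <- t0 + len - 1L
  blocks <- NULL
  for (k in seq_len(nrow(exons))) {
    lo <- max(t0, offs[k] + 1L)
    hi <- min(t1, offs[k + 1L])
    if (lo <= hi)
      blocks <- rbind(blocks, c(exons[k, 1L] + (lo - offs[k] - 1L),
                                exons[k, 1L] + (hi - offs[k] - 1L)))
  }
  blocks
}

#' Simulate reads against a synthetic genome (sequence mode)
#'
#' Generates the full experiment as in [simulateExperiment()], but with
#' every molecule realized as read sequence: RNA molecules are single-end
#' reads placed uniformly on a (spliced or unspliced) isoform of the
#' sampled gene; ATAC molecules are read pairs around a fragment placed
#' in the sampled peak (intra) or uniformly on the genome (inter), with
#' an insert sampled uniformly from `insert_range`. Overlapped SNPs are
#' set to an allele drawn from the origin's frequency, then each base is
#' flipped to a random nucleotide with probability `error_rate`.
#'
#' Writes `genome.fa`, `donors.vcf.gz`, `peaks.bed`, FASTQ files
#' (`rna_R1` barcode+UMI, `rna_R2` cDNA; `atac_R1`/`atac_R2` genomic,
#' `atac_BC` barcode), `truth.tsv`, and optionally the true alignments as
#' SAM (one file per modality) for aligner-free pileup testing.
#'
#' @param cfg a [simConfig()]; keep droplet counts and coverage small
#'   (reads are materialized in memory).
#' @param dir output directory.
#' @param seed RNG seed (optional).
#' @param write_sam also write true-alignment SAM files (default TRUE).
#' @return list: `files` (paths), `molecules` (the truth-side
#'   [MoleculeTable-class] implied by the read placements), `truth`
#'   ([SimTruth-class]), `pool` (genotypes on the genome SNPs),
#'   `barcode_seqs` (barcode id to 16-mer map).
#' @export
simulateReads <- function(cfg, dir, seed = NULL, write_sam = TRUE) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (!is.null(seed)) set.seed(seed)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  ba <- c("A", "C", "G", "T")
  geno <- makeSyntheticGenome(cfg)
  snps <- geno$snps
  # HWE genotypes on the genome SNPs
  p <- runif(nrow(snps), cfg$maf_range[1], cfg$maf_range[2])
  donors <- sprintf("donor%02d", seq_len(cfg$n_donors))
  g <- matrix(rbinom(nrow(snps) * cfg$n_donors, 2L,
                     rep(p, cfg$n_donors)) / 2,
              nrow(snps), cfg$n_donors, dimnames = list(snps$variant,
                                                        donors))
  gr <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L),
                ref = snps$ref, alt = snps$alt)
  names(gr) <- snps$variant
  gm <- dropMonomorphic(GenotypeMatrix(g, gr))
  g <- gammaMatrix(gm)
  vr <- variantRanges(gm)
  ap <- cfg$donor_ambient_props %||% rep(1 / cfg$n_donors, cfg$n_donors)
  ga_true <- setNames(as.vector(g %*% ap), rownames(g))
  prof <- list(rna = local({
    m <- matrix(rgamma(cfg$n_cell_types * cfg$n_genes, 1),
                cfg$n_cell_types); m / rowSums(m) }),
    atac = local({
      m <- matrix(rgamma(cfg$n_cell_types * cfg$n_peaks, 1),
                  cfg$n_cell_types); m / rowSums(m) }))

  truth <- sampleDropletStructure(cfg, donors)
  bc_seqs <- setNames(
    vapply(seq_len(nrow(truth)), function(i)
      paste(sample(ba, 16L, replace = TRUE), collapse = ""),
      character(1)),
    truth$barcode)
  while (anyDuplicated(bc_seqs)) {
    du <- duplicated(bc_seqs)
    bc_seqs[du] <- vapply(seq_len(sum(du)), function(i)
      paste(sample(ba, 16L, replace = TRUE), collapse = ""), character(1))
  }

  L <- cfg$read_len
  qual_chr <- strrep(rawToChar(as.raw(33L + cfg$qual)), L)
  vtab <- data.table(chrom = as.character(seqnames(vr)), pos = start(vr),
                     ref = mcols(vr)$ref, alt = mcols(vr)$alt,
                     variant = names(vr))
  setkey(vtab, chrom, pos)

  mutate_read <- function(sq, gstart_in_read, alleles, refs, alts) {
    for (k in seq_along(gstart_in_read)) {
      b <- if (alleles[k] == 1L) alts[k] else refs[k]
      substr(sq, gstart_in_read[k], gstart_in_read[k]) <- b
    }
    nerr <- rbinom(1L, nchar(sq), cfg$error_rate)
    if (nerr > 0L) {
      posn <- sample.int(nchar(sq), nerr)
      for (pp in posn) substr(sq, pp, pp) <- sample(ba, 1L)
    }
    sq
  }

  rna_recs <- list(); atac_recs <- list()
  mol_calls <- list(); cov_rows <- list(); origin_rows <- list()
  truth[, droplet := .I]
  sam_rna <- list(); sam_atac <- list()
  ga_seq <- geno$genome

  for (d in seq_len(nrow(truth))) {
    row <- truth[d]
    for (mod in c("RNA", "ATAC")) {
      M <- if (mod == "RNA") row$m_rna else row$m_atac
      if (M == 0) next
      amb <- runif(M) < row$alpha_true
      pick2 <- runif(M) < 0.5
      orig <- ifelse(amb, 0L,
                     ifelse(row$n_nuclei == 2L & pick2,
                            match(row$donor2, donors),
                            match(row$donor1, donors)))
      ct <- ifelse(amb, 0L, ifelse(row$n_nuclei == 2L & pick2,
                                   row$cell_type2, row$cell_type1))
      n_intra_draw <- runif(M) < row$p_peak
      for (m in seq_len(M)) {
        o <- orig[m]
        pmat <- if (mod == "RNA") prof$rna else prof$atac
        pv <- if (o == 0L || is.na(ct[m]) || ct[m] == 0L)
          colMeans(pmat) else pmat[ct[m], ]
        feat <- sample.int(length(pv), 1L, prob = pv)
        if (mod == "RNA") {
          gene <- geno$genes[feat]
          iso <- sample.int(gene$n_iso, 1L)
          spl <- runif(1L) < if (o == 0L) cfg$spliced_prob_amb else
            cfg$spliced_prob_cell
          exons <- if (spl) .iso_exons(gene, iso) else
            matrix(c(gene$start, gene$end), 1L)
          txlen <- sum(exons[, 2L] - exons[, 1L] + 1L)
          rl <- min(L, txlen)
          t0 <- sample.int(max(txlen - rl + 1L, 1L), 1L)
          blocks <- .tx_to_genome(exons, t0, rl)
          region <- "na"
          chrom <- gene$chrom
        } else {
          ins <- round(runif(1L, cfg$insert_range[1], cfg$insert_range[2]))
          flen <- 2L * L + as.integer(ins)
          if (n_intra_draw[m]) {
            pk <- geno$peaks[feat]
            chrom <- as.character(seqnames(pk))
            lo <- max(1L, start(pk) - L)
            hi <- max(lo, min(end(pk), cfg$chrom_len - flen))
            fs <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          } else {
            chrom <- sample(names(ga_seq), 1L)
            fs <- sample.int(cfg$chrom_len - flen, 1L)
          }
          fe <- fs + flen - 1L
          blocks <- rbind(c(fs, fs + L - 1L), c(fe - L + 1L, fe))
          region <- if (n_intra_draw[m]) "intra" else "inter"
        }
        # SNPs under the sequenced blocks
        ch_m <- chrom
        hits <- rbindlist(lapply(seq_len(nrow(blocks)), function(k) {
          sel <- vtab$chrom == ch_m & vtab$pos >= blocks[k, 1L] &
            vtab$pos <= blocks[k, 2L]
          vtab[sel]
        }))
        alle <- if (nrow(hits)) {
          pa <- if (o == 0L) ga_true[match(hits$variant, names(ga_true))]
          else g[match(hits$variant, rownames(g)), o]
          as.integer(runif(nrow(hits)) < pa)
        } else integer(0)

        # realize read sequences with alleles + error
        mk_seq <- function(bs, be) {
          sq <- as.character(subseq(ga_seq[[chrom]], bs, be))
          sel <- which(hits$pos >= bs & hits$pos <= be)
          mutate_read(sq, hits$pos[sel] - bs + 1L, alle[sel],
                      hits$ref[sel], hits$alt[sel])
        }
        mol_id <- paste0(mod, d, ".", m)
        if (mod == "RNA") {
          seqs <- vapply(seq_len(nrow(blocks)), function(k)
            mk_seq(blocks[k, 1L], blocks[k, 2L]), character(1))
          cdna <- paste(seqs, collapse = "")
          umi <- paste(sample(ba, 12L, replace = TRUE), collapse = "")
          rid <- sprintf("@rna:%d:%d", d, m)
          rna_recs[[length(rna_recs) + 1L]] <- c(
            rid, paste0(bc_seqs[[row$barcode]], umi),
            strrep("I", 28L), cdna,
            substr(qual_chr, 1L, nchar(cdna)))
          if (write_sam) {
            cig <- if (nrow(blocks) == 1L)
              paste0(nchar(cdna), "M") else
                paste0(blocks[1, 2] - blocks[1, 1] + 1L, "M",
                       blocks[2, 1] - blocks[1, 2] - 1L, "N",
                       blocks[2, 2] - blocks[2, 1] + 1L, "M")
            sam_rna[[length(sam_rna) + 1L]] <- paste(
              sub("^@", "", rid), 0L, chrom, blocks[1, 1], 60L, cig,
              "*", 0L, 0L, cdna, substr(qual_chr, 1L, nchar(cdna)),
              paste0("CB:Z:", row$barcode),
              paste0("UB:Z:", umi), sep = "\t")
          }
        } else {
          s1 <- mk_seq(blocks[1, 1L], blocks[1, 2L])
          s2r <- mk_seq(blocks[2, 1L], blocks[2, 2L])
          s2 <- as.character(reverseComplement(DNAStringSet(s2r))[[1L]])
          rid <- sprintf("@atac:%d:%d", d, m)
          atac_recs[[length(atac_recs) + 1L]] <- c(
            rid, s1, qual_chr, s2, qual_chr, bc_seqs[[row$barcode]],
            strrep("I", 16L))
          if (write_sam) {
            fs <- blocks[1, 1L]; fe <- blocks[2, 2L]
            tl <- fe - fs + 1L
            nm <- sub("^@", "", rid)
            tag <- paste0("CB:Z:", row$barcode)
            sam_atac[[length(sam_atac) + 1L]] <- c(
              paste(nm, 99L, chrom, fs, 60L, paste0(L, "M"), "=",
                    fe - L + 1L, tl, s1, qual_chr, tag, sep = "\t"),
              paste(nm, 147L, chrom, fe - L + 1L, 60L, paste0(L, "M"),
                    "=", fs, -tl, s2r, qual_chr, tag, sep = "\t"))
          }
        }
        # truth-side molecule table record: read the emitted base back
        # from the realized (error-containing) sequence, keeping only
        # ref/alt matches, exactly as a pileup would
        if (nrow(hits)) {
          got <- character(nrow(hits))
          for (k in seq_len(nrow(hits))) {
            blk <- which(hits$pos[k] >= blocks[, 1L] &
                           hits$pos[k] <= blocks[, 2L])[1L]
            off <- hits$pos[k] - blocks[blk, 1L] + 1L
            sq <- if (mod == "RNA") seqs[blk] else
              if (blk == 1L) s1 else s2r
            got[k] <- substr(sq, off, off)
          }
          al2 <- ifelse(got == hits$ref, 0L,
                        ifelse(got == hits$alt, 1L, NA_integer_))
          keep <- !is.na(al2)
          if (any(keep))
            mol_calls[[length(mol_calls) + 1L]] <- data.table(
              barcode = row$barcode, modality = mod, molecule = mol_id,
              region = region, variant = hits$variant[keep],
              allele = as.integer(al2[keep]), qual = as.numeric(cfg$qual))
        }
        cov_rows[[length(cov_rows) + 1L]] <- data.table(
          barcode = row$barcode, modality = mod, region = region)
        origin_rows[[length(origin_rows) + 1L]] <- data.table(
          barcode = row$barcode, modality = mod, molecule = mol_id,
          origin = o, spliced = NA, feature = feat)
      }
    }
  }

  files <- .write_sequence_outputs(dir, geno, gm, rna_recs, atac_recs,
                                   sam_rna, sam_atac, write_sam, truth,
                                   cfg)
  cov <- rbindlist(cov_rows)[, .(n_molecules = .N),
                             by = c("barcode", "modality", "region")]
  mt <- MoleculeTable(calls = if (length(mol_calls))
    rbindlist(mol_calls) else data.table(), coverage = cov)
  truth[, droplet := NULL]
  st <- new("SimTruth", droplets = truth,
            origins = rbindlist(origin_rows),
            params = list(config = cfg, donors = donors,
                          pi_a_true = setNames(ap, donors)))
  list(files = files, molecules = mt, truth = st,
       pool = list(genotypes = gm, profiles = prof),
       barcode_seqs = bc_seqs)
}

.write_sequence_outputs <- function(dir, geno, gm, rna_recs, atac_recs,
                                    sam_rna, sam_atac, write_sam, truth,
                                    cfg) {
  files <- c(genome = file.path(dir, "genome.fa"),
             vcf = file.path(dir, "donors.vcf.gz"),
             peaks = file.path(dir, "peaks.bed"),
             truth = file.path(dir, "truth.tsv"))
  writeXStringSet(geno$genome, files[["genome"]])
  writeGenotypesVcf(gm, files[["vcf"]])
  pk <- geno$peaks
  # BED is 0-based half-open
  data.table::fwrite(data.table(as.character(seqnames(pk)),
                                start(pk) - 1L, end(pk)),
                     files[["peaks"]], sep = "\t", col.names = FALSE)
  fwrite(truth, files[["truth"]], sep = "\t")

  wfq <- function(recs, idx, path) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    for (r in recs)
      writeLines(c(r[1L], r[idx[1L]], "+", r[idx[2L]]), con)
    path
  }
  if (length(rna_recs)) {
    files["rna_R1"] <- wfq(rna_recs, c(2L, 3L),
                           file.path(dir, "rna_R1.fastq.gz"))
    files["rna_R2"] <- wfq(rna_recs, c(4L, 5L),
                           file.path(dir, "rna_R2.fastq.gz"))
  }
  if (length(atac_recs)) {
    files["atac_R1"] <- wfq(atac_recs, c(2L, 3L),
                            file.path(dir, "atac_R1.fastq.gz"))
    files["atac_R2"] <- wfq(atac_recs, c(4L, 5L),
                            file.path(dir, "atac_R2.fastq.gz"))
    files["atac_BC"] <- wfq(atac_recs, c(6L, 7L),
                            file.path(dir, "atac_BC.fastq.gz"))
  }
  if (write_sam) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", names(geno$genome), "\tLN:",
                    Biostrings::width(geno$genome)))
    if (length(sam_rna)) {
      files["sam_rna"] <- file.path(dir, "rna.sam")
      writeLines(c(hdr, unlist(sam_rna)), files[["sam_rna"]])
    }
    if (length(sam_atac)) {
      files["sam_atac"] <- file.path(dir, "atac.sam")
      writeLines(c(hdr, unlist(sam_atac)), files[["sam_atac"]])
    }
  }
  files
}
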