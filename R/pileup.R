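# MoleculeTable construction: BAM pileup, TSV interchange, region selection.
#
# A molecule is the deduplicated unit of evidence: RNA reads sharing a
# (cell barcode, UMI) pair form one molecule; ATAC reads collapse to
# deduplicated fragments (barcode, chrom, start, end). Each molecule
# contributes at most one base call per overlapping SNP (duplicate reads
# are collapsed by majority consensus), mirroring the likelihood's product
# over variant sites within a molecule.

#' Pile up variant-overlapping base calls from a BAM file
#'
#' Extracts deduplicated molecules and their base calls at the SNPs of a
#' [GenotypeMatrix-class]. Secondary, supplementary, duplicate-flagged and
#' unmapped alignments are skipped, as are reads below `min_mapq`. Bases
#' matching neither the ref nor the alt allele, or below `min_base_qual`,
#' are skipped. When duplicate reads of a molecule disagree at a SNP the
#' majority allele wins; ties are broken by highest base quality and
#' remaining ties are dropped.
#'
#' For ATAC, read pairs are collapsed to fragments (chrom, start, end);
#' a fragment is labeled `intra` if it overlaps any peak interval by at
#' least 1 bp, `inter` otherwise (`na` when no peaks are supplied). Tn5
#' offsets (+4/-5) are not applied unless `tn5_shift = TRUE`; they are
#' irrelevant at SNP-overlap granularity.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param gm a [GenotypeMatrix-class]; only its SNPs are piled up.
#' @param modality "RNA" or "ATAC".
#' @param barcode_tag cell barcode tag (default "CB").
#' @param umi_tag UMI tag, required for RNA (default "UB").
#' @param peaks `GRanges` of ATAC peaks, or a BED path (0-based half-open,
#'   converted on import), or `NULL`.
#' @param min_base_qual minimum Phred base quality for a call (default 20).
#' @param min_mapq minimum mapping quality (default 20).
#' @param whitelist optional character vector (or path to a one-per-line
#'   file) of candidate barcodes; others are skipped.
#' @param tn5_shift apply +4/-5 Tn5 offsets to ATAC fragment ends.
#' @return A [MoleculeTable-class].
#' @export
pileupBam <- function(bam, gm, modality = c("RNA", "ATAC"),
                      barcode_tag = "CB", umi_tag = "UB", peaks = NULL,
                      min_base_qual = 20, min_mapq = 20, whitelist = NULL,
                      tn5_shift = FALSE) {
  modality <- match.arg(modality)
  stopifnot(is(gm, "GenotypeMatrix"))
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  bai <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(bai))) stop("BAM index (.bai) not found for: ", bam)
  if (modality == "RNA" && (is.null(umi_tag) || !nzchar(umi_tag)))
    stop("umi_tag is required for RNA pileup")
  if (is.character(peaks) && length(peaks) == 1L)
    peaks <- rtracklayer::import(peaks)
  if (is.character(whitelist) && length(whitelist) == 1L &&
      file.exists(whitelist))
    whitelist <- readLines(whitelist)

  tags <- if (modality == "RNA") c(barcode_tag, umi_tag) else barcode_tag
  param <- ScanBamParam(
    flag = scanBamFlag(isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE,
                       isDuplicate = FALSE, isUnmappedQuery = FALSE),
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual",
             "mapq"),
    tag = tags)
  res <- scanBam(bam, param = param)[[1L]]
  n <- length(res$pos)
  cb <- res$tag[[barcode_tag]]
  if (is.null(cb)) cb <- rep(NA_character_, n)
  reads <- data.table(
    qname = res$qname, rname = as.character(res$rname), pos = res$pos,
    cigar = res$cigar, mapq = res$mapq, barcode = cb,
    seq = as.character(res$seq), qual = as.character(res$qual))
  if (modality == "RNA") {
    um <- res$tag[[umi_tag]]
    reads[, umi := if (is.null(um)) NA_character_ else um]
  }
  n_no_cb <- sum(is.na(reads$barcode))
  if (n_no_cb > 0)
    warning(n_no_cb, " read(s) without ", barcode_tag, " tag skipped")
  reads <- reads[!is.na(barcode)]
  reads <- reads[is.na(mapq) | mapq >= min_mapq]
  if (!is.null(whitelist)) reads <- reads[barcode %in% whitelist]
  if (modality == "RNA") {
    n_no_umi <- sum(is.na(reads$umi))
    if (n_no_umi > 0)
      warning(n_no_umi, " RNA read(s) without ", umi_tag, " tag skipped")
    reads <- reads[!is.na(umi)]
  }
  if (nrow(reads) == 0L)
    return(MoleculeTable(calls = data.table(), coverage = data.table(
      barcode = character(), modality = character(), region = character(),
      n_molecules = integer())))

  blocks <- .cigar_blocks(reads$cigar, reads$pos)
  # reads rows are reordered by later merges; keep sequence/quality lookup
  # by the original (filtered) row index used in `blocks`
  seq_by_idx <- reads$seq
  qual_by_idx <- reads$qual
  reads[, read_idx := .I]

  # molecule identity
  if (modality == "RNA") {
    reads[, mol_key := paste(barcode, umi, sep = "|")]
    reads[, region := "na"]
  } else {
    # fragment span per qname+barcode over both mates' aligned blocks
    bl <- blocks[, .(rstart = min(rstart), rend = max(rend)),
                 by = "read_idx"]
    reads <- merge(reads, bl, by = "read_idx", all.x = TRUE)
    frag <- reads[, .(fstart = min(rstart), fend = max(rend),
                      rname = rname[1L]),
                  by = c("barcode", "qname")]
    if (tn5_shift) frag[, `:=`(fstart = fstart + 4L, fend = fend - 5L)]
    frag[, mol_key := paste(barcode, rname, fstart, fend, sep = "|")]
    reads <- merge(reads, frag[, .(barcode, qname, mol_key, fstart, fend)],
                   by = c("barcode", "qname"))
    if (!is.null(peaks)) {
      fr <- unique(frag[, .(mol_key, rname, fstart, fend)])
      gr <- GRanges(fr$rname, IRanges(fr$fstart, fr$fend))
      fr[, region := ifelse(overlapsAny(gr, peaks), "intra", "inter")]
      reads <- merge(reads, fr[, .(mol_key, region)], by = "mol_key")
    } else reads[, region := "na"]
  }

  # base calls at SNP-overlapping positions
  vr <- variantRanges(gm)
  vtab <- data.table(variant = names(vr), chrom = as.character(seqnames(vr)),
                     vpos = start(vr), ref = mcols(vr)$ref,
                     alt = mcols(vr)$alt)
  blocks <- merge(blocks, reads[, .(read_idx, rname)], by = "read_idx")
  setnames(blocks, "rname", "chrom")
  calls <- blocks[vtab, on = .(chrom, rstart <= vpos, rend >= vpos),
                  nomatch = NULL,
                  .(read_idx, variant, vpos = i.vpos, qoff = i.vpos,
                    ref, alt)]
  if (nrow(calls)) {
    # recover query offset: qstart + (vpos - rstart); re-join block info
    bl2 <- blocks[, .(read_idx, rstart, rend, qstart)]
    calls <- bl2[calls,
                 on = .(read_idx, rstart <= vpos, rend >= vpos),
                 nomatch = NULL,
                 .(read_idx, variant, qpos = qstart + (i.vpos - x.rstart),
                   ref, alt, vpos = i.vpos)]
    calls[, base := substr(seq_by_idx[read_idx], qpos, qpos)]
    calls[, bq := as.integer(charToRaw(paste(
      substr(qual_by_idx[read_idx], qpos, qpos), collapse = ""))) - 33L]
    calls[, allele := ifelse(base == ref, 0L,
                             ifelse(base == alt, 1L, NA_integer_))]
    calls <- calls[!is.na(allele) & bq >= min_base_qual]
    ridx <- data.table::setkey(
      reads[, .(read_idx, barcode, mol_key, region)], read_idx)
    calls[, `:=`(barcode = ridx$barcode[read_idx],
                 mol_key = ridx$mol_key[read_idx],
                 region = ridx$region[read_idx])]
    # consensus per (molecule, variant): majority, tie -> max quality,
    # remaining tie -> dropped
    cons <- calls[, .(n = .N, q = max(bq)),
                  by = c("barcode", "mol_key", "region", "variant", "allele")]
    setorder(cons, barcode, mol_key, variant, -n, -q, allele)
    top <- cons[, head(.SD, 2L), by = c("barcode", "mol_key", "variant")]
    top[, rank := seq_len(.N), by = c("barcode", "mol_key", "variant")]
    w <- data.table::dcast(top, barcode + mol_key + variant ~ rank,
                           value.var = c("n", "q", "allele", "region"))
    if (!"n_2" %in% names(w)) w[, `:=`(n_2 = NA_integer_, q_2 = NA_real_)]
    w <- w[is.na(n_2) | n_1 > n_2 | (n_1 == n_2 & q_1 > q_2)]
    calls <- w[, .(barcode, modality = modality, molecule = mol_key,
                   region = region_1, variant, allele = allele_1,
                   qual = as.numeric(q_1))]
  } else {
    calls <- data.table(barcode = character(), modality = character(),
                        molecule = character(), region = character(),
                        variant = character(), allele = integer(),
                        qual = numeric())
  }

  cov <- unique(reads[, .(barcode, mol_key, region)])[,
    .(n_molecules = .N), by = c("barcode", "region")]
  cov[, modality := modality]
  MoleculeTable(calls = calls,
                coverage = cov[, .(barcode, modality, region, n_molecules)])
}

# Decompose CIGARs into aligned blocks on the reference with the query
# offset of each block start. M/=/X consume both; I/S consume query;
# D/N consume reference; H/P consume neither.
.cigar_blocks <- function(cigar, pos) {
  out <- vector("list", length(cigar))
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  for (r in seq_along(cigar)) {
    ln <- as.integer(lens[[r]]); op <- ops[[r]]
    rpos <- pos[r]; qpos <- 1L
    rs <- integer(0); re <- integer(0); qs <- integer(0)
    for (k in seq_along(op)) {
      o <- op[k]; l <- ln[k]
      if (o %in% c("M", "=", "X")) {
        rs <- c(rs, rpos); re <- c(re, rpos + l - 1L); qs <- c(qs, qpos)
        rpos <- rpos + l; qpos <- qpos + l
      } else if (o %in% c("I", "S")) qpos <- qpos + l
      else if (o %in% c("D", "N")) rpos <- rpos + l
    }
    out[[r]] <- data.table(read_idx = r, rstart = rs, rend = re,
                           qstart = qs)
  }
  rbindlist(out)
}

#' Filter molecules by ATAC peak region
#'
#' `region_mode = "intra"` drops ATAC inter-peak molecules (both their base
#' calls and their contribution to coverage); RNA molecules are untouched.
#' `"all"` keeps everything. Inter-peak ATAC fragments are enriched for
#' ambient origin in real data, so intra-only demultiplexing can be
#' preferable there; simulated data with region-constant ambient fractions
#' are typically analysed with `"all"`.
#'
#' @param mt a [MoleculeTable-class].
#' @param region_mode "intra" or "all".
#' @return A [MoleculeTable-class].
#' @export
selectMolecules <- function(mt, region_mode = c("all", "intra")) {
  region_mode <- match.arg(region_mode)
  stopifnot(is(mt, "MoleculeTable"))
  if (region_mode == "all") return(mt)
  keep_call <- !(mt@calls$modality == "ATAC" & mt@calls$region == "inter")
  keep_cov <- !(mt@coverage$modality == "ATAC" &
                  mt@coverage$region == "inter")
  MoleculeTable(calls = mt@calls[keep_call],
                coverage = mt@coverage[keep_cov])
}

#' Count molecules and informative molecules for one barcode
#'
#' @param mt a [MoleculeTable-class].
#' @param barcode a barcode.
#' @param modality "RNA" or "ATAC".
#' @return Named numeric vector: `n_molecules` (all molecules),
#'   `n_informative` (molecules with at least one base call),
#'   `n_base_calls`. Zeros for an absent barcode.
#' @export
countInformative <- function(mt, barcode, modality) {
  stopifnot(is(mt, "MoleculeTable"))
  bc <- barcode; mod <- modality
  cv <- mt@coverage[barcode == bc & modality == mod]
  cl <- mt@calls[barcode == bc & modality == mod]
  c(n_molecules = sum(cv$n_molecules),
    n_informative = data.table::uniqueN(cl$molecule) * (nrow(cl) > 0),
    n_base_calls = nrow(cl))
}

#' Write a MoleculeTable to its TSV interchange format
#'
#' One row per base call (columns `barcode`, `modality`, `molecule_id`,
#' `region`, `variant_id`, `allele`, `qual`); molecules without base calls
#' are written once with `.` in the last three columns. Gz compression is
#' selected by a `.gz` suffix.
#'
#' @param mt a [MoleculeTable-class].
#' @param path output TSV (or TSV.gz) path.
#' @return The path, invisibly.
#' @export
writeMoleculeTable <- function(mt, path) {
  stopifnot(is(mt, "MoleculeTable"))
  cl <- mt@calls
  inf <- cl[, .(n_inf = data.table::uniqueN(molecule)),
            by = c("barcode", "modality", "region")]
  cv <- merge(mt@coverage, inf, by = c("barcode", "modality", "region"),
              all.x = TRUE)
  cv[is.na(n_inf), n_inf := 0L]
  cv[, n_uninf := n_molecules - n_inf]
  un <- cv[n_uninf > 0]
  uninf <- if (nrow(un)) un[rep(seq_len(.N), n_uninf),
                            .(barcode, modality, region)] else NULL
  if (!is.null(uninf)) {
    uninf[, molecule_id := paste0("u", seq_len(.N)),
          by = c("barcode", "modality")]
    uninf[, `:=`(variant_id = ".", allele = ".", qual = ".")]
  }
  body <- cl[, .(barcode, modality, molecule_id = as.character(molecule),
                 region, variant_id = variant,
                 allele = as.character(allele), qual = as.character(qual))]
  out <- rbindlist(list(body,
                        uninf[, .(barcode, modality, molecule_id, region,
                                  variant_id, allele, qual)]),
                   use.names = TRUE)
  setorder(out, barcode, modality, molecule_id, variant_id)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a MoleculeTable from its TSV interchange format
#'
#' @param path TSV (or TSV.gz) written by [writeMoleculeTable()] or by the
#'   simulator.
#' @return A [MoleculeTable-class].
#' @export
readMoleculeTable <- function(path) {
  if (!file.exists(path)) stop("molecule table not found: ", path)
  cc <- list(character = c("barcode", "modality", "molecule_id", "region",
                           "variant_id", "allele", "qual"))
  tb <- if (grepl("\\.gz$", path)) {
    gz <- Sys.which("gzip")
    if (nzchar(gz)) {
      fread(cmd = paste(gz, "-dc", shQuote(path)), sep = "\t",
            colClasses = cc)
    } else {
      as.data.table(utils::read.delim(gzfile(path),
                                      colClasses = "character"))
    }
  } else fread(path, sep = "\t", colClasses = cc)
  need <- c("barcode", "modality", "molecule_id", "region", "variant_id",
            "allele", "qual")
  if (!all(need %in% names(tb)))
    stop("molecule table must have columns: ", paste(need, collapse = ", "))
  cov <- unique(tb[, .(barcode, modality, molecule_id, region)])[,
    .(n_molecules = .N), by = c("barcode", "modality", "region")]
  cl <- tb[variant_id != "."]
  calls <- cl[, .(barcode, modality, molecule = molecule_id, region,
                  variant = variant_id, allele = as.integer(allele),
                  qual = as.numeric(qual))]
  MoleculeTable(calls = calls, coverage = cov)
}

#' Restrict a MoleculeTable to the variants of a genotype panel
#'
#' Drops base calls at variants absent from `gm` (molecules remain and
#' may become uninformative), as a pileup run against that panel would
#' have produced. Used when fitting with a reduced donor set: subsetting
#' donors re-applies the monomorphic filter, so the variant panel
#' shrinks.
#'
#' @param mt a [MoleculeTable-class].
#' @param gm a [GenotypeMatrix-class].
#' @return A [MoleculeTable-class].
#' @export
restrictToVariants <- function(mt, gm) {
  stopifnot(is(mt, "MoleculeTable"), is(gm, "GenotypeMatrix"))
  MoleculeTable(calls = mt@calls[variant %in% variantIds(gm)],
                coverage = mt@coverage)
}
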