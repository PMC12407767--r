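library(data.table)

# build an indexed BAM from SAM lines written in code
make_bam <- function(lines, chrom = "c1", len = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, lines), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

Q40 <- strrep("I", 10)   # Phred 40
Q20 <- strrep("5", 10)   # Phred 20
Q02 <- strrep("#", 10)   # Phred 2

rna_read <- function(qname, cb, umi, pos, seq, qual = Q40) {
  paste(qname, 0L, "c1", pos, 60L, "10M", "*", 0L, 0L, seq, qual,
        paste0("CB:Z:", cb), paste0("UB:Z:", umi), sep = "\t")
}

atac_pair <- function(qname, cb, pos1, pos2, seq1, seq2) {
  tl <- pos2 + 10L - pos1
  c(paste(qname, 99L, "c1", pos1, 60L, "10M", "=", pos2, tl, seq1, Q40,
          paste0("CB:Z:", cb), sep = "\t"),
    paste(qname, 147L, "c1", pos2, 60L, "10M", "=", pos1, -tl, seq2,
          Q40, paste0("CB:Z:", cb), sep = "\t"))
}

# SNPs at c1:100..500 (ref A, alt T); base at read offset pos 100 - 96 + 1
seq_with <- function(base, at = 5L) {
  s <- strrep("C", 10)
  substr(s, at, at) <- base
  s
}

test_that("RNA pileup: UMI dedup, consensus, quality and allele filters", {
  gm <- toy_gm3()
  lines <- c(
    rna_read("r1a", "BC1", "U1", 96L, seq_with("T")),  # alt call
    rna_read("r1b", "BC1", "U1", 96L, seq_with("T")),  # duplicate read
    rna_read("r2", "BC1", "U2", 196L, seq_with("A")),  # ref call
    # consensus: majority T at first, then A majority after third read
    rna_read("r3a", "BC1", "U3", 296L, seq_with("T")),
    rna_read("r3b", "BC1", "U3", 296L, seq_with("A"), Q20),
    rna_read("r3c", "BC1", "U3", 296L, seq_with("A"), Q20),
    # exact tie (same count, same max quality): dropped
    rna_read("r4a", "BC1", "U4", 396L, seq_with("T")),
    rna_read("r4b", "BC1", "U4", 396L, seq_with("A")),
    # below min_base_qual: no call, molecule still counted
    rna_read("r5", "BC1", "U5", 96L, seq_with("T"), Q02),
    # base matching neither allele: skipped
    rna_read("r6", "BC1", "U6", 196L, seq_with("G")))
  bam <- make_bam(lines)
  mt <- pileupBam(bam, gm, "RNA")
  cl <- moleculeCalls(mt)
  expect_equal(countInformative(mt, "BC1", "RNA"),
               c(n_molecules = 6, n_informative = 3, n_base_calls = 3))
  u1 <- cl[molecule == "BC1|U1"]
  expect_equal(nrow(u1), 1L)          # duplicates collapse to one call
  expect_equal(u1$allele, 1L)
  expect_equal(u1$qual, 40)
  expect_equal(cl[molecule == "BC1|U2"]$allele, 0L)
  expect_equal(cl[molecule == "BC1|U3"]$allele, 0L)  # majority wins
  expect_false("BC1|U4" %in% cl$molecule)            # tie dropped
  expect_true(all(cl$region == "na"))
})

test_that("RNA reads missing tags are skipped with a counted warning", {
  gm <- toy_gm3()
  no_cb <- paste("x1", 0L, "c1", 96L, 60L, "10M", "*", 0L, 0L,
                 seq_with("T"), Q40, "UB:Z:U9", sep = "\t")
  bam <- make_bam(c(rna_read("ok", "BC1", "U1", 96L, seq_with("T")),
                    no_cb))
  expect_warning(mt <- pileupBam(bam, gm, "RNA"), "1 read")
  expect_equal(unname(countInformative(mt, "BC1", "RNA")[["n_molecules"]]),
               1)
})

test_that("ATAC pileup: fragments, peak labels, and dedup idempotence", {
  gm <- toy_gm3()
  peaks <- GenomicRanges::GRanges("c1", IRanges::IRanges(90, 200))
  lines <- c(
    atac_pair("q1", "BC2", 96L, 150L, seq_with("T"), strrep("C", 10)),
    # duplicate fragment, different read name: collapses
    atac_pair("q2", "BC2", 96L, 150L, seq_with("T"), strrep("C", 10)),
    # fragment fully outside peaks -> inter
    atac_pair("q3", "BC2", 396L, 450L, seq_with("A"), strrep("C", 10)))
  bam <- make_bam(lines)
  mt <- pileupBam(bam, gm, "ATAC", peaks = peaks)
  cv <- moleculeCoverage(mt)
  expect_equal(cv[region == "intra"]$n_molecules, 1L)
  expect_equal(cv[region == "inter"]$n_molecules, 1L)
  cl <- moleculeCalls(mt)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl[region == "intra"]$allele, 1L)
  expect_equal(cl[region == "inter"]$allele, 0L)

  # duplicating every read changes nothing
  bam2 <- make_bam(c(lines, gsub("^q", "p", lines)))
  mt2 <- pileupBam(bam2, gm, "ATAC", peaks = peaks)
  expect_equal(moleculeCoverage(mt2)[order(region)],
               cv[order(region)])
  setorderv(cl, names(cl))
  cl2 <- moleculeCalls(mt2)
  setorderv(cl2, names(cl2))
  expect_equal(cl2$variant, cl$variant)
  expect_equal(cl2$allele, cl$allele)

  # region labels partition ATAC molecules
  expect_equal(sum(cv$n_molecules),
               sum(cv[region %in% c("intra", "inter")]$n_molecules))
})

test_that("pileup error contracts", {
  gm <- toy_gm3()
  expect_error(pileupBam(tempfile(fileext = ".bam"), gm, "RNA"),
               "not found")
  bam <- make_bam(rna_read("r", "BC1", "U1", 96L, seq_with("T")))
  file.remove(paste0(bam, ".bai"))
  expect_error(pileupBam(bam, gm, "RNA"), "index")
  bam2 <- make_bam(rna_read("r", "BC1", "U1", 96L, seq_with("T")))
  expect_error(pileupBam(bam2, gm, "RNA", umi_tag = NULL), "umi_tag")
})

test_that("selectMolecules filters ATAC inter-peak molecules only", {
  mols <- c(
    lapply(1:10, function(i) list(barcode = "b", modality = "ATAC",
                                  molecule = paste0("a", i),
                                  region = "intra",
                                  calls = data.frame(
                                    variant = "c1:100:A:T", allele = 1,
                                    qual = 30))),
    lapply(1:5, function(i) list(barcode = "b", modality = "ATAC",
                                 molecule = paste0("e", i),
                                 region = "inter",
                                 calls = data.frame(
                                   variant = "c1:200:A:T", allele = 0,
                                   qual = 30))),
    list(list(barcode = "b", modality = "RNA", molecule = "r1",
              region = "na",
              calls = data.frame(variant = "c1:300:A:T", allele = 1,
                                 qual = 30))))
  mt <- toy_mt(mols)
  # mode all is the identity
  expect_equal(moleculeCoverage(selectMolecules(mt, "all")),
               moleculeCoverage(mt))
  intra <- selectMolecules(mt, "intra")
  cv <- moleculeCoverage(intra)
  expect_equal(cv[modality == "ATAC"]$n_molecules, 10L)
  expect_equal(cv[modality == "RNA"]$n_molecules, 1L)  # RNA untouched
  expect_false("inter" %in% moleculeCalls(intra)$region)
})

test_that("countInformative counts molecules, informative, calls", {
  mols <- list(
    list(barcode = "b", modality = "RNA", molecule = "m1", region = "na",
         calls = data.frame(variant = c("c1:100:A:T", "c1:200:A:T"),
                            allele = c(1, 0), qual = 30)),
    list(barcode = "b", modality = "RNA", molecule = "m2", region = "na",
         calls = NULL),
    list(barcode = "b", modality = "RNA", molecule = "m3", region = "na",
         calls = NULL))
  mt <- toy_mt(mols)
  expect_equal(countInformative(mt, "b", "RNA"),
               c(n_molecules = 3, n_informative = 1, n_base_calls = 2))
  expect_equal(countInformative(mt, "absent", "RNA"),
               c(n_molecules = 0, n_informative = 0, n_base_calls = 0))
})

test_that("molecule table TSV round-trip is lossless", {
  sim <- small_sim(seed = 5, n_cellular = 30, n_empty = 60,
                   coverage_mean = 150)
  mt <- sim$molecules
  path <- file.path(tempdir(), "mt.tsv.gz")
  writeMoleculeTable(mt, path)
  mt2 <- readMoleculeTable(path)
  cv1 <- moleculeCoverage(mt)[order(barcode, modality, region)]
  cv2 <- moleculeCoverage(mt2)[order(barcode, modality, region)]
  expect_equal(cv2$n_molecules, cv1$n_molecules)
  cl1 <- moleculeCalls(mt)[order(barcode, modality, molecule, variant)]
  cl2 <- moleculeCalls(mt2)[order(barcode, modality, molecule, variant)]
  expect_equal(cl2$variant, cl1$variant)
  expect_equal(cl2$allele, cl1$allele)
  expect_equal(cl2$qual, cl1$qual)
  expect_equal(cl2$region, cl1$region)
})
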