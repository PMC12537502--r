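test_that("Tn5 strand shift places integration sites at +4 / -5", {
  expect_equal(shift_tn5(100L, 150L, "+")$pos, 104L)
  expect_equal(shift_tn5(120L, 200L, "-")$pos, 194L)
  # out-of-range positions are rejected with a warning
  expect_warning(res <- shift_tn5(0L, 2L, "-", chrom_len = 3L))
  expect_true(is.na(res$pos))
  expect_equal(res$n_rejected, 1L)
})

test_that("genomic context classes follow the gene-distance rules", {
  genes <- data.frame(chrom = "chr1", start = c(1800L, 2500L),
                      end = c(3000L, 4000L), strand = "+",
                      gene_id = c("g1", "g2"))
  g1 <- genes[1, ]
  g2 <- genes[2, ]
  expect_equal(classify_context(
    data.frame(chrom = "chr1", start = 1500L, end = 2000L), g1)$context,
    "genic")
  # boundary-inclusive 2 kb: gap of exactly 2000 is proximal
  expect_equal(classify_context(
    data.frame(chrom = "chr1", start = 0L, end = 500L), g2)$context,
    "proximal")
  expect_equal(classify_context(
    data.frame(chrom = "chr1", start = 0L, end = 500L),
    data.frame(chrom = "chr1", start = 2501L, end = 4000L, strand = "+",
               gene_id = "g3"))$context, "distal")
  # unannotated chromosome -> distal with flag
  res <- classify_context(
    data.frame(chrom = "chrX", start = 0L, end = 500L), genes)
  expect_equal(res$context, "distal")
  expect_true(res$no_annotation)
})

test_that("nucleus QC enforces documented strict/non-strict boundaries", {
  base <- data.frame(barcode = "b", depth = 5000L, tss_frac = 0.5,
                     frip = 0.5, organelle_frac = 0)
  cells <- do.call(rbind, replicate(30, base, simplify = FALSE))
  cells$barcode <- paste0("b", 1:30)
  # depth 999 removed, 1000 kept (inclusive minimum)
  cells$depth[1] <- 999L
  cells$depth[2] <- 1000L
  # exact thresholds for tss/frip are strict
  cells$tss_frac[3] <- 0.2
  cells$frip[4] <- 0.1
  out <- qc_filter_nuclei(cells)
  expect_false("b1" %in% out$barcode)
  expect_true("b2" %in% out$barcode)
  expect_false("b3" %in% out$barcode)
  expect_false("b4" %in% out$barcode)
  expect_true(all(out$pass_qc))
  # output is a subset of input
  expect_true(all(out$barcode %in% cells$barcode))
  # cap retains top cells by depth
  many <- data.frame(barcode = paste0("c", 1:50),
                     depth = 1000L + seq_len(50), tss_frac = 0.5,
                     frip = 0.5, organelle_frac = 0)
  capped <- qc_filter_nuclei(many, max_cells = 10L)
  expect_equal(nrow(capped), 10L)
  expect_true(all(capped$depth >= 1041L))
  expect_equal(nrow(qc_filter_nuclei(many[0, ])), 0L)
})

test_that("interval algebra matches brute-force oracles on random sets", {
  set.seed(42)
  for (rep in 1:5) {
    a <- random_intervals(150)
    b <- random_intervals(180)
    expect_equal(iv_overlaps_any(a, b), overlap_oracle(a, b))
    nr <- iv_nearest(a, b)
    expect_equal(nr$distance, nearest_oracle(a, b))
  }
  # merge: total covered bases equal union computed by brute force
  a <- random_intervals(100, chroms = "chr1", len = 2000L)
  m <- iv_merge(a)
  cov <- logical(3000)
  for (i in seq_len(nrow(a))) cov[(a$start[i] + 1):a$end[i]] <- TRUE
  expect_equal(sum(m$end - m$start), sum(cov))
  expect_true(all(m$start[-1] > m$end[-nrow(m)]))
})

test_that("format round-trips are lossless and GFF3 converts coordinates", {
  tmp <- withr::local_tempdir()
  bed <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 100L),
                    end = c(500L, 900L))
  p <- file.path(tmp, "x.bed")
  write_bed(bed, p)
  expect_equal(read_bed(p), bed)
  expect_equal(readLines(p)[1], "chr1\t0\t500")

  genes <- data.frame(chrom = "chr1", start = 99L, end = 200L,
                      strand = "-", gene_id = "gA")
  g <- file.path(tmp, "x.gff3")
  write_gff3_genes(genes, g)
  back <- read_gff3_genes(g)
  expect_equal(back, genes)
  # GFF3 on disk is 1-based inclusive
  expect_match(readLines(g)[2], "\t100\t200\t")

  fr <- data.frame(chrom = "chr1", start = c(10L, 50L), end = c(110L, 200L),
                   barcode = c("bc1", "bc2"), count = c(3L, 1L))
  f <- file.path(tmp, "frags.tsv")
  write_fragments(fr, f)
  rt <- read_fragments(f)
  expect_equal(as.data.frame(rt), fr)
  ins <- fragments_to_insertions(rt)
  # a count-3 row contributes 3 fragment events = 6 insertions
  expect_equal(nrow(ins), 2L * sum(fr$count))
  expect_setequal(unique(ins$pos[ins$barcode == "bc1"]), c(10L, 109L))

  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(2, 1), x = c(5, 2),
                            dims = c(3, 2),
                            dimnames = list(paste0("r", 1:3), c("a", "b")))
  pre <- file.path(tmp, "mat")
  write_sparse_triplet(m, pre)
  m2 <- read_sparse_triplet(pre)
  expect_equal(as.matrix(m2), as.matrix(m))
})

test_that("JASPAR PFM reader normalizes counts into probability columns", {
  tmp <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 testmotif",
               "A [ 10  0  5 ]",
               "C [  0 10  5 ]",
               "G [  0  0  5 ]",
               "T [  0  0  5 ]"), tmp)
  lib <- read_jaspar_pfm(tmp)
  expect_equal(names(lib), "MA0001.1")
  pwm <- lib[[1]]$pwm
  expect_equal(colSums(pwm), rep(1, 3), ignore_attr = TRUE)
  expect_equal(motif_consensus(lib[[1]]), "ACA")
})

test_that("loop linking joins ACR-bin / promoter-bin pairs and dedups", {
  loops <- data.frame(chrom1 = "chr1", start1 = 0L, end1 = 5000L,
                      chrom2 = "chr1", start2 = 10000L, end2 = 15000L)
  acrs <- data.frame(chrom = "chr1", start = 100L, end = 600L,
                     cell_type = "CT1")
  genes <- data.frame(chrom = "chr1", start = 11000L, end = 12000L,
                      strand = "+", gene_id = "g1")
  sg <- data.frame(gene_id = "g1", cell_type = "CT1")
  links <- link_loops(loops, acrs, genes, sg)
  expect_equal(nrow(links), 1L)
  expect_equal(links$gene_id, "g1")
  expect_true(links$celltype_match)
  # gene too far: promoter outside partner bin
  genes2 <- transform(genes, start = 20000L, end = 21000L)
  expect_equal(nrow(link_loops(loops, acrs, genes2, sg)), 0L)
  # ACR overlapping both bins of a self-loop links once
  self_loop <- data.frame(chrom1 = "chr1", start1 = 10000L, end1 = 15000L,
                          chrom2 = "chr1", start2 = 10000L, end2 = 15000L)
  acr2 <- data.frame(chrom = "chr1", start = 10050L, end = 10550L,
                     cell_type = "CT1")
  links2 <- link_loops(self_loop, acr2, genes, sg)
  expect_equal(nrow(links2), 1L)
  # wrong bin width errors
  bad <- transform(loops, end1 = 4000L)
  expect_error(link_loops(bad, acrs, genes, sg), "resolution")
})
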