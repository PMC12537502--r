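test_that("reference generator is seed-deterministic and plants motifs", {
  lib <- list(motif_pattern("GArepeat", "GAGAGAGA"))
  s1 <- simulate_reference(n_chrom = 1L, chrom_len = 1e5,
                           cell_types = six_types, n_peaks = 10L,
                           motif_library = lib, motif_sites_per = 5L,
                           seed = 7L)
  s2 <- simulate_reference(n_chrom = 1L, chrom_len = 1e5,
                           cell_types = six_types, n_peaks = 10L,
                           motif_library = lib, motif_sites_per = 5L,
                           seed = 7L)
  expect_identical(as.character(s1$ref$seq), as.character(s2$ref$seq))
  expect_identical(s1$truth$planted_peaks, s2$truth$planted_peaks)
  # direct string search finds every planted site at its position
  chr <- as.character(s1$ref$seq[[1]])
  for (i in seq_len(nrow(s1$truth$motif_sites))) {
    pos <- s1$truth$motif_sites$pos[i]
    expect_equal(substr(chr, pos + 1, pos + 8), "GAGAGAGA")
  }
  # planted peaks lie within the genome and have the declared context
  pk <- s1$truth$planted_peaks
  expect_true(all(pk$end <= s1$ref$chrom_sizes[pk$chrom]))
  ctx <- classify_context(pk, s1$genes)
  expect_equal(ctx$context, pk$context)
})

test_that("planted context proportions stay inside the multinomial envelope", {
  s <- simulate_reference(n_chrom = 2L, chrom_len = 1e6,
                          cell_types = six_types, n_peaks = 150L,
                          context_ratio = c(0.19, 0.52, 0.29), seed = 3L)
  tab <- table(factor(s$truth$planted_peaks$context,
                      c("genic", "proximal", "distal")))
  n <- sum(tab)
  # marginal binomial 99.5% envelope per class (joint > 98.5%)
  for (k in seq_along(tab)) {
    p <- c(0.19, 0.52, 0.29)[k]
    lo <- qbinom(0.0025, n, p)
    hi <- qbinom(0.9975, n, p)
    expect_gte(tab[[k]], lo)
    expect_lte(tab[[k]], hi)
  }
})

test_that("fragment generator conserves depth and honours the snr mixture", {
  fx <- small_sim(seed = 11L, cells_per_type = 40L, depth_mean = 200)
  ins <- fx$fr$insertions
  cells <- fx$fr$cells
  expect_equal(nrow(ins), sum(cells$depth))
  expect_true(all(ins$pos >= 0))
  expect_true(all(ins$pos < fx$sim$ref$chrom_sizes[ins$chrom]))
  # in-peak fraction per cell type within binomial 99.9% bounds of the
  # closed-form mixture weight
  peaks <- fx$sim$truth$planted_peaks
  decoys <- fx$sim$truth$decoy_peaks
  L <- sum(as.numeric(fx$sim$ref$chrom_sizes))
  snr <- 5
  for (ty in c("CT1", "CT4")) {
    active <- rbind(
      peaks[peaks$class %in% c("broad", paste0("specific:", ty)),
            c("chrom", "start", "end")],
      decoys[, c("chrom", "start", "end")])
    P <- sum(active$end - active$start)
    p_exp <- snr * P / (snr * P + (L - P))
    ins_t <- ins[ins$cell_type == ty]
    inside <- iv_overlaps_any(
      data.frame(chrom = ins_t$chrom, start = ins_t$pos,
                 end = ins_t$pos + 1L), active)
    n <- length(inside)
    # background insertions can also land in peaks by chance
    p_tot <- p_exp + (1 - p_exp) * P / L
    expect_gte(sum(inside), qbinom(5e-4, n, p_tot))
    expect_lte(sum(inside), qbinom(1 - 5e-4, n, p_tot))
  }
})

test_that("epigenome generator plants silencers, nucleosomes and BMRs", {
  fx <- small_sim(seed = 5L)
  sim <- simulate_epigenome(fx$sim, frac_silencer = 0.5, n_bmr = 8L,
                            bmr_windows = 5L, seed = 6L)
  peaks <- sim$truth$planted_peaks
  sil <- peaks[peaks$peak_id %in% sim$truth$silencer_acrs, ]
  expect_gt(nrow(sil), 0)
  expect_true(all(sil$class == "broad"))
  # every silencer ACR is inside an H3K27me3 domain
  expect_true(all(iv_overlaps_any(sil, sim$h3k27me3)))
  # every silencer ACR sequence contains at least one PRE pattern
  pre <- lapply(names(pre_motif_patterns()), function(nm)
    motif_pattern(nm, pre_motif_patterns()[[nm]]))
  seqs <- vapply(seq_len(nrow(sil)), function(i) {
    as.character(Biostrings::subseq(sim$ref$seq[[sil$chrom[i]]],
                                    sil$start[i] + 1L, sil$end[i]))
  }, "")
  hits <- scan_motifs(seqs, pre)
  expect_true(all(rowSums(hits$matrix) >= 1))
  # frac_silencer = 0 -> no silencers
  sim0 <- simulate_epigenome(small_sim(seed = 5L)$sim, frac_silencer = 0,
                             seed = 6L)
  expect_length(sim0$truth$silencer_acrs, 0)
  # planted BMRs exceed the global mean in >= 3 consecutive windows
  gm <- mean(sim$methyl$level)
  for (i in seq_len(nrow(sim$truth$bmr_truth))) {
    b <- sim$truth$bmr_truth[i, ]
    w <- sim$methyl[sim$methyl$chrom == b$chrom &
                      sim$methyl$start >= b$start &
                      sim$methyl$end <= b$end, ]
    expect_gte(nrow(w), 3L)
    expect_true(all(w$level > gm))
  }
  # nucleosome calls cover decoy peaks
  expect_true(all(iv_overlaps_any(sim$truth$decoy_peaks, sim$nucleosomes)))
})

test_that("species-pair generator controls core survival by class", {
  fx <- small_sim(seed = 21L, n_peaks = 30L, chrom_len = 1e5)
  sp <- simulate_species_pair(fx$sim, divergence = 0, seed = 22L)
  truth <- sp$conservation_truth
  peaks <- fx$sim$truth$planted_peaks
  # divergence 0: shared/variable spans are identical outside inversions
  same_blocks <- sp$blocks[sp$blocks$orientation == "same", ]
  for (i in which(truth$class != "species_specific")) {
    inb <- which(same_blocks$chromA == peaks$chrom[i] &
                   same_blocks$startA <= peaks$start[i] &
                   same_blocks$endA >= peaks$end[i])
    if (!length(inb)) next
    a <- as.character(Biostrings::subseq(fx$sim$ref$seq[[peaks$chrom[i]]],
                                         peaks$start[i] + 1L, peaks$end[i]))
    bchrom <- same_blocks$chromB[inb[1]]
    b <- as.character(Biostrings::subseq(sp$genome_b[[bchrom]],
                                         peaks$start[i] + 1L, peaks$end[i]))
    expect_identical(a, b)
  }
  # species-specific spans share no 20-mer with the original (k-mer scan)
  kmers <- function(x, k = 20L) {
    n <- nchar(x)
    if (n < k) return(character(0))
    vapply(seq_len(n - k + 1L), function(i) substr(x, i, i + k - 1L), "")
  }
  sp2 <- simulate_species_pair(fx$sim, divergence = 0.1, seed = 23L)
  truth2 <- sp2$conservation_truth
  blocks2 <- sp2$blocks
  for (i in which(truth2$class == "species_specific")) {
    b <- blocks2[blocks2$chromA == peaks$chrom[i] &
                   blocks2$startA <= peaks$start[i] &
                   blocks2$endA >= peaks$end[i], ][1, ]
    a_seq <- as.character(Biostrings::subseq(
      fx$sim$ref$seq[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i]))
    b_seq <- as.character(sp2$genome_b[[b$chromB]])
    expect_length(intersect(kmers(a_seq), kmers(b_seq)), 0L)
  }
  # class proportions match the request (all mass on one class)
  sp3 <- simulate_species_pair(fx$sim,
                               class_probs = c(shared = 1, variable = 0,
                                               species_specific = 0),
                               seed = 24L)
  expect_true(all(sp3$conservation_truth$class == "shared"))
  expect_equal(nrow(sp3$acrs_b), nrow(peaks))
})

test_that("trajectory generator plants recoverable pseudotime shifts", {
  tr <- simulate_trajectories(n_motifs = 12L, n_cells = 200L,
                              delta = 0.3, noise_sd = 0, seed = 9L)
  truth <- tr$shift_truth
  # conserved motifs: interpolated curves nearly identical, DTW distance ~ 0
  ca <- interpolate_scale(tr$A$dev, tr$A$pseudotime)
  cb <- interpolate_scale(tr$B$dev, tr$B$pseudotime)
  cons <- which(truth$label == "conserved")[1]
  expect_lt(dtw_distance(ca[cons, ], cb[cons, ])$distance, 10)
  d_cons <- dtw_distance(ca[cons, ], cb[cons, ])$distance
  sh <- which(truth$label != "conserved")
  if (length(sh)) {
    d_shift <- dtw_distance(ca[sh[1], ], cb[sh[1], ])$distance
    expect_gt(d_shift, d_cons)
  }
  # half-maximum crossing of a shiftEarlyA motif occurs ~delta earlier in A
  ea <- which(truth$label == "shiftEarlyA")
  if (length(ea)) {
    m <- ea[1]
    half_cross <- function(curve, pt) {
      target <- (max(curve) + min(curve)) / 2
      idx <- which(abs(curve - target) == min(abs(curve - target)))[1]
      pt[idx]
    }
    ha <- half_cross(tr$A$dev[m, ], tr$A$pseudotime)
    hb <- half_cross(tr$B$dev[m, ], tr$B$pseudotime)
    # half-max crossing estimate carries grid/range bias of order the cell
    # spacing plus sigmoid truncation at the pseudotime boundary
    expect_equal(hb - ha, 0.3, tolerance = 0.2)
  }
})
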