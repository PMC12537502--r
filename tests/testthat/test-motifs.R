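test_that("PWM threshold DP equals exhaustive enumeration (<= 8 bp motifs)", {
  set.seed(50)
  bg <- rep(0.25, 4)
  res <- 1e-3  # same discretization as the DP
  for (L in c(5L, 6L, 8L)) {
    counts <- matrix(rexp(4 * L), 4, L)
    m <- motif_pwm("m", counts * 50)
    Si <- round(log2(m$pwm / bg) / res)  # per-column discretized scores
    # enumerate all 4^L words
    words <- as.matrix(expand.grid(rep(list(1:4), L)))
    scores_d <- rowSums(matrix(
      Si[cbind(c(words), rep(seq_len(L), each = nrow(words)))],
      nrow(words), L)) * res
    p_set <- if (L == 8L) c(1e-2, 1e-4, 1e-5) else c(1e-2, 1e-3)
    for (p_t in p_set) {
      dp <- pwm_score_threshold(m$pwm, p_t, bg, resolution = res)
      sorted <- sort(unique(scores_d))
      tails <- vapply(sorted, function(s) mean(scores_d >= s - 1e-9), 0)
      k <- which(tails <= p_t)[1]
      if (is.na(k)) {
        expect_equal(dp$threshold, Inf)
      } else {
        expect_equal(dp$threshold, sorted[k], tolerance = 2e-3)
        expect_equal(dp$pvalue, tails[k], tolerance = 1e-9)
      }
    }
  }
})

test_that("scanning finds consensus sites on both strands and IUPAC patterns", {
  # a 10 bp consensus: an 8 bp motif cannot attain p <= 1e-5 under the
  # uniform background (even the best word has probability 4^-8 > 1e-5)
  m <- pwm_from_consensus("mot", "ACGTACGTAC")
  cons <- "ACGTACGTAC"
  seq_fwd <- paste0(random_dna(30), cons, random_dna(30))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  seq_rev <- paste0(random_dna(30), rc, random_dna(30))
  res <- scan_motifs(c(f = seq_fwd, r = seq_rev), list(m))
  expect_true(res$matrix["f", "mot"])
  expect_true(res$matrix["r", "mot"])
  expect_true(any(res$hits$seq_id == "f" & res$hits$pos == 30 &
                    res$hits$strand == "+"))
  expect_true(any(res$hits$seq_id == "r" & res$hits$strand == "-"))
  # GA-repeat pattern
  ga <- motif_pattern("GArepeat", "GAGAGAGA")
  res2 <- scan_motifs(c(a = "TTGAGAGAGATT", b = strrep("C", 20)), list(ga))
  expect_true(res2$matrix["a", "GArepeat"])
  expect_false(res2$matrix["b", "GArepeat"])
  # motif longer than sequence -> no hits
  res3 <- scan_motifs(c(s = "ACG"), list(m))
  expect_false(any(res3$matrix))
})

test_that("scanning is reverse-complement symmetric in total hit count", {
  set.seed(51)
  m <- pwm_from_consensus("mot", "TGACGTCA", major = 0.9)
  seqs <- vapply(1:20, function(i) random_dna(300), "")
  names(seqs) <- paste0("s", 1:20)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  names(rc) <- names(seqs)
  h1 <- scan_motifs(seqs, list(m), p_thresh = 1e-3)
  h2 <- scan_motifs(rc, list(m), p_thresh = 1e-3)
  expect_equal(nrow(h1$hits), nrow(h2$hits))
  expect_equal(sum(h1$matrix), sum(h2$matrix))
})

test_that("control sets are length-matched, placed in allowed space, off-target", {
  genome <- list(mappable = data.frame(chrom = "chr1", start = 0L,
                                       end = 100000L))
  targets <- data.frame(chrom = "chr1",
                        start = c(1000L, 5000L, 9000L),
                        end = c(1500L, 5500L, 9300L))
  sets <- simulate_control_regions(targets, genome, n = 20L, seed = 52L)
  for (s in sets) {
    expect_setequal(s$end - s$start, c(500L, 500L, 300L))
    expect_false(any(iv_overlaps_any(s, targets)))
    expect_true(all(s$start >= 0 & s$end <= 100000L))
  }
  # exclusion pins controls into the remaining window
  excl <- data.frame(chrom = "chr1", start = 0L, end = 90000L)
  sets2 <- simulate_control_regions(targets, genome, n = 5L,
                                    exclusions = excl, seed = 53L)
  for (s in sets2) expect_true(all(s$start >= 90000L))
  # mean capture of a uniformly scattered feature tracks its density
  set.seed(54)
  feat <- data.frame(chrom = "chr1",
                     start = sort(sample.int(99000L, 200L)))
  feat$end <- feat$start + 50L
  ratios <- vapply(simulate_control_regions(targets, genome, n = 100L,
                                            seed = 55L),
                   capture_ratio, 0, features = feat)
  # each 500 bp control overlaps a 50 bp feature with p ~ 1-exp(-dens*550)
  # (approximate: ignores feature clumping and the off-target constraint)
  p_hit <- 1 - exp(-200 / 1e5 * 550)
  # ~3 sigma for 300 control intervals, plus slack for the approximation
  expect_lt(abs(mean(ratios) - p_hit), 0.09)
})

test_that("binomial enrichment equals the exact closed form", {
  r <- binomial_enrichment(50, 100, rep(0.3, 100))
  oracle <- sum(dbinom(50:100, 100, 0.3))
  expect_equal(r$p, oracle, tolerance = 1e-12)
  expect_equal(r$p, 2.1e-5, tolerance = 0.05)
  # k/n equal to p0 is unremarkable; k = 0 gives p = 1
  expect_gt(binomial_enrichment(30, 100, rep(0.3, 100))$p, 0.3)
  expect_equal(binomial_enrichment(0, 100, rep(0.3, 100))$p, 1)
  # degenerate p0 clamped and flagged
  d <- binomial_enrichment(5, 100, rep(0, 100))
  expect_true(d$clamped)
  expect_gt(d$p0, 0)
})

test_that("family hypergeometric test matches closed forms", {
  hits <- matrix(FALSE, 20, 2,
                 dimnames = list(sprintf("a%02d", 1:20), c("m1", "m2")))
  hits[1:8, "m1"] <- TRUE
  universe <- rownames(hits)
  fam <- list(F1 = "m1", F2 = "m2")
  # all-success tail: k = n, K < N -> p = C(K,n)/C(N,n)
  target <- rownames(hits)[1:5]
  res <- family_hypergeom(target, universe, fam, hits)
  expect_equal(res$p[res$family == "F1"],
               choose(8, 5) / choose(20, 5), tolerance = 1e-12)
  # K = 0 -> p = 1; k = 0 -> p = 1
  expect_equal(res$p[res$family == "F2"], 1)
  res2 <- family_hypergeom(rownames(hits)[9:12], universe, fam, hits)
  expect_equal(res2$p[res2$family == "F1"], 1)
  # exact oracle via dhyper sums on random configurations
  set.seed(56)
  for (r in 1:20) {
    h <- matrix(runif(20) < 0.4, 20, 1, dimnames = list(universe, "m1"))
    targ <- sample(universe, 7)
    got <- family_hypergeom(targ, universe, list(F = "m1"), h)$p
    K <- sum(h)
    k <- sum(h[targ, ])
    expect_equal(got, sum(dhyper(k:min(K, 7), K, 20 - K, 7)),
                 tolerance = 1e-12)
  }
})

test_that("NB enrichment recovers a planted coefficient and controls the null", {
  set.seed(57)
  n_ct <- 3L
  n_cells <- 200L
  ann <- rep(paste0("CT", 1:n_ct), each = n_cells)
  nonzero <- rpois(length(ann), 800) + 100
  n_motifs <- 15L
  beta1 <- 0.5
  counts <- matrix(0L, n_motifs, length(ann),
                   dimnames = list(sprintf("m%02d", 1:n_motifs), NULL))
  for (m in seq_len(n_motifs)) {
    eta <- log(20) + beta1 * (ann == "CT1") + 0.3 * log(nonzero)
    counts[m, ] <- rnbinom(length(ann), mu = exp(eta - mean(0.3 *
      log(nonzero))), size = 10)
  }
  res <- nb_enrichment(counts, ann, nonzero, downsample = 150L, seed = 58L)
  b1 <- res$beta[res$cell_type == "CT1"]
  expect_equal(mean(b1), beta1, tolerance = 0.1)
  expect_true(all(res$enriched[res$cell_type == "CT1"]))
  # permuted labels: almost nothing passes
  res_null <- nb_enrichment(counts, sample(ann), nonzero,
                            downsample = 150L, seed = 59L)
  expect_lte(mean(res_null$enriched), 0.05)
  # identical counts -> beta 0
  flat <- matrix(5L, 2, length(ann),
                 dimnames = list(c("f1", "f2"), NULL))
  res_flat <- nb_enrichment(flat, ann, rep(100, length(ann)),
                            downsample = 100L, seed = 60L)
  expect_equal(max(abs(res_flat$beta)), 0, tolerance = 1e-8)
})
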