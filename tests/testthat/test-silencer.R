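test_that("accessibility calls require all three criteria", {
  counts <- matrix(100, 2, 6, dimnames = list(c("a1", "a2"), six_types))
  max_cov <- matrix(1000, 2, 6, dimnames = dimnames(counts))
  lib <- rep(1e6, 6)
  acc <- accessible_call_matrix(counts, max_cov, lib)
  expect_true(all(acc))
  # count 19 fails the integration-site minimum
  c2 <- counts
  c2[1, 1] <- 19
  acc2 <- accessible_call_matrix(c2, max_cov, lib)
  expect_false(acc2[1, 1])
  # normalized coverage at exactly the threshold fails (strict >)
  mc3 <- max_cov
  mc3[2, 2] <- 2       # 2 / 1e6 * 1e6 = 2, not > 2
  acc3 <- accessible_call_matrix(counts, mc3, lib)
  expect_false(acc3[2, 2])
  # monotone in counts and coverage
  c4 <- counts + 50
  mc4 <- max_cov + 50
  expect_true(all(accessible_call_matrix(c4, mc4, lib) >= acc))
})

test_that("H3K27me3 breadth rules reproduce the n-1 / n-2 thresholds", {
  mk <- function(nacc, n) {
    acc <- matrix(FALSE, 1, n, dimnames = list("a1", paste0("T", 1:n)))
    acc[1, seq_len(nacc)] <- TRUE
    acrs <- data.frame(acr_id = "a1", chrom = "chr1", start = 0L,
                       end = 500L)
    dom <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
    classify_h3k27me3_acrs(acrs, acc, dom)
  }
  # n = 6: accessible in 5 -> broad; in 2 -> specific; in 3/4 intermediate
  expect_equal(mk(5, 6)$breadth, "broad")
  expect_equal(mk(2, 6)$breadth, "cell-type-specific")
  expect_equal(mk(3, 6)$breadth, "intermediate")
  # n = 12: n-2 rule -> 10 accessible is broad; < 4 specific
  expect_equal(mk(10, 12)$breadth, "broad")
  expect_equal(mk(3, 12)$breadth, "cell-type-specific")
  # association flank: domain 400 bp away is associated, 600 bp is not
  acrs <- data.frame(acr_id = "a1", chrom = "chr1", start = 2000L,
                     end = 2500L)
  acc <- matrix(TRUE, 1, 6, dimnames = list("a1", six_types))
  near <- data.frame(chrom = "chr1", start = 2900L, end = 3500L)
  far <- data.frame(chrom = "chr1", start = 3101L, end = 3500L)
  expect_equal(classify_h3k27me3_acrs(acrs, acc, near)$h3k27me3_status,
               "associated")
  expect_equal(classify_h3k27me3_acrs(acrs, acc, far)$h3k27me3_status,
               "absent")
})

test_that("silencer-gene links respect the upstream window and body cover", {
  genes <- data.frame(chrom = "chr1", start = 10000L, end = 12000L,
                      strand = "+", gene_id = "g1")
  mk_annot <- function(status) {
    data.frame(acr_id = "a1", h3k27me3_status = status, n_accessible = 6,
               breadth = "broad", candidate_silencer = status ==
                 "associated")
  }
  dom_full <- data.frame(chrom = "chr1", start = 9000L, end = 13000L)
  expr <- matrix(1, 1, 6, dimnames = list("g1", six_types))
  # ACR with a 500 bp gap to the TSS links; a 400 bp gap does not
  acr500 <- data.frame(chrom = "chr1", start = 9000L, end = 9500L)
  acr400 <- data.frame(chrom = "chr1", start = 9100L, end = 9600L)
  l1 <- link_and_compare_expression(mk_annot("associated"), acr500, genes,
                                    dom_full, expr)
  expect_equal(nrow(l1$links), 1L)
  l2 <- link_and_compare_expression(mk_annot("associated"), acr400, genes,
                                    dom_full, expr)
  expect_equal(nrow(l2$links), 0L)
  # gene-body cover 0.49 excludes the silencer link
  dom_half <- data.frame(chrom = "chr1", start = 10000L, end = 10980L)
  l3 <- link_and_compare_expression(mk_annot("associated"), acr500, genes,
                                    dom_half, expr)
  expect_equal(nrow(l3$links), 0L)
})

test_that("silenced genes test lower than matched controls", {
  set.seed(20)
  n <- 40L
  genes <- data.frame(chrom = "chr1",
                      start = 20000L * seq_len(2 * n),
                      end = 20000L * seq_len(2 * n) + 2000L,
                      strand = "+",
                      gene_id = sprintf("g%03d", seq_len(2 * n)))
  # one broad ACR 1 kb upstream of each gene; first n associated
  acrs <- data.frame(chrom = "chr1", start = genes$start - 1500L,
                     end = genes$start - 1000L)
  annot <- data.frame(acr_id = sprintf("a%03d", seq_len(2 * n)),
                      h3k27me3_status = rep(c("associated", "absent"),
                                            each = n),
                      n_accessible = 6, breadth = "broad",
                      candidate_silencer = rep(c(TRUE, FALSE), each = n))
  doms <- data.frame(chrom = "chr1", start = genes$start[1:n] - 2000L,
                     end = genes$end[1:n] + 2000L)
  expr <- matrix(rexp(2 * n * 6, 1), 2 * n, 6,
                 dimnames = list(genes$gene_id, six_types))
  expr[1:n, ] <- expr[1:n, ] / 4   # silenced genes shrunk 4x
  res <- link_and_compare_expression(annot, acrs, genes, doms, expr,
                                     seed = 21L)
  expect_equal(nrow(res$tests), 6L)
  expect_true(all(res$tests$p < 0.01))
})

test_that("BMR caller equals the reference scan on random tracks", {
  bmr_oracle <- function(w) {
    gm <- mean(w$level)
    out <- list()
    i <- 1
    n <- nrow(w)
    while (i <= n) {
      j <- i
      while (j <= n && w$level[j] > gm && w$chrom[j] == w$chrom[i] &&
               (j == i || w$start[j] == w$end[j - 1])) j <- j + 1
      if (j - i >= 3) {
        out[[length(out) + 1L]] <- data.frame(chrom = w$chrom[i],
                                              start = w$start[i],
                                              end = w$end[j - 1])
      }
      i <- max(j, i + 1)
    }
    if (!length(out)) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    do.call(rbind, out)
  }
  # hand fixtures
  w3 <- data.frame(chrom = "chr1", start = c(0L, 500L, 1000L),
                   end = c(500L, 1000L, 1500L), level = 0.9)
  w3 <- rbind(w3, data.frame(chrom = "chr1", start = 1500L, end = 2000L,
                             level = 0.1))
  b <- call_bmrs(w3)
  expect_equal(nrow(b), 1L)
  expect_equal(b$end - b$start, 1500L)
  # two qualifying windows only -> nothing
  w2 <- data.frame(chrom = "chr1", start = c(0L, 500L, 1000L),
                   end = c(500L, 1000L, 1500L), level = c(0.9, 0.9, 0.0))
  expect_equal(nrow(call_bmrs(w2)), 0L)
  # all-equal track -> nothing (strict >)
  we <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(500L, 1000L),
                   level = 0.5)
  expect_equal(nrow(call_bmrs(we)), 0L)
  # randomized tracks vs oracle
  set.seed(30)
  for (r in 1:50) {
    nw <- 40L
    w <- data.frame(chrom = rep(c("chr1", "chr2"), each = nw / 2),
                    start = rep((0:(nw / 2 - 1)) * 500L, 2))
    w$end <- w$start + 500L
    w$level <- runif(nw)
    expect_equal(call_bmrs(w), bmr_oracle(w), ignore_attr = TRUE)
  }
})

test_that("planted silencer ACRs are recovered from the epigenome layers", {
  fx <- small_sim(seed = 41L, n_peaks = 50L, cells_per_type = 80L,
                  depth_mean = 150)
  sim <- simulate_epigenome(fx$sim, frac_silencer = 0.6, seed = 42L)
  peaks <- sim$truth$planted_peaks
  acrs <- data.frame(acr_id = peaks$peak_id, chrom = peaks$chrom,
                     start = peaks$start, end = peaks$end)
  ins <- fx$fr$insertions
  counts <- matrix(0, nrow(acrs), 6, dimnames = list(acrs$acr_id, six_types))
  for (ty in six_types) {
    it <- ins[ins$cell_type == ty]
    counts[, ty] <- iv_count_points(acrs, data.frame(chrom = it$chrom,
                                                     pos = it$pos))
  }
  max_cov <- acr_max_coverage(acrs, ins, sim$ref$chrom_sizes)
  lib <- as.numeric(table(ins$cell_type)[six_types])
  acc <- accessible_call_matrix(counts, max_cov, lib)
  annot <- classify_h3k27me3_acrs(acrs, acc, sim$h3k27me3)
  truth_sil <- acrs$acr_id %in% sim$truth$silencer_acrs
  # nearly all planted silencers classified (associated, broad)
  expect_gte(mean(annot$candidate_silencer[truth_sil]), 0.95)
  # non-silencer broad peaks essentially never flagged
  other_broad <- peaks$class == "broad" & !truth_sil
  if (any(other_broad)) {
    expect_lte(mean(annot$candidate_silencer[other_broad]), 0.05)
  }
})
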