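# Shared fixtures, built in code at test time.

six_types <- paste0("CT", 1:6)

# small simulated atlas reused across tests; regenerated per call so tests
# can vary the seed
small_sim <- function(seed = 1L, n_peaks = 60L, n_decoy = 6L,
                      chrom_len = 2e5, cells_per_type = 120L,
                      depth_mean = 300, snr = 5) {
  sim <- simulate_reference(n_chrom = 2L, chrom_len = chrom_len,
                            cell_types = six_types, n_peaks = n_peaks,
                            frac_broad = 0.4, n_decoy = n_decoy,
                            seed = seed)
  plan <- setNames(rep(cells_per_type, length(six_types)), six_types)
  fr <- simulate_fragments(sim, plan, depth_mean = depth_mean,
                           snr = snr, seed = seed + 1L)
  list(sim = sim, fr = fr)
}

# brute-force O(n*m) interval overlap oracle
overlap_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, logical(1))
}

# brute-force nearest-gap oracle (NA when no interval on the chromosome)
nearest_oracle <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    j <- which(b$chrom == a$chrom[i])
    if (!length(j)) return(NA_integer_)
    gaps <- pmax(0L, pmax(b$start[j] - a$end[i], a$start[i] - b$end[j]))
    # overlapping intervals have gap 0
    ov <- b$start[j] < a$end[i] & a$start[i] < b$end[j]
    gaps[ov] <- 0L
    as.integer(min(gaps))
  }, integer(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), len = 10000L) {
  s <- sample.int(len - 100L, n, replace = TRUE)
  w <- sample.int(80L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = s,
             end = s + w)
}

# tiny PWM from a consensus string with some tolerance
pwm_from_consensus <- function(id, cons, major = 0.85) {
  codes <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  L <- length(codes)
  m <- matrix((1 - major) / 3, 4, L)
  m[cbind(codes, seq_len(L))] <- major
  motif_pwm(id, m * 100, pseudocount = 0)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
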