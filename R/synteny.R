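# Syntenic-block preparation, short-word local alignment with
# Karlin-Altschul E-values, cross-species ACR conservation classes, and
# cell-type retention.

#' Alignment parameters for short-sequence seed-and-extend alignment
#'
#' Defaults mirror short-nucleotide BLAST settings: word size 7, +1/-1
#' match/mismatch, affine gap costs 5 (open) and 2 (extend), E-value cutoff
#' 1e-3 and a 20 nt minimum alignment length. `lambda` is the
#' Karlin-Altschul parameter; for +1/-1 scoring on a uniform background it
#' is exactly ln 3 (see [karlin_lambda()]). `K` defaults to 0.62; E-value
#' ranking does not depend on it.
#'
#' @param word_size exact-match seed length (>= 4).
#' @param match,mismatch match reward and mismatch penalty.
#' @param gap_open,gap_extend positive affine gap costs.
#' @param e_max E-value cutoff.
#' @param min_len minimum alignment length (strict: length must exceed it).
#' @param lambda Karlin-Altschul lambda.
#' @param K Karlin-Altschul K.
#' @param xdrop X-drop termination parameter.
#' @param max_ext maximum gapped extension length per side.
#' @return parameter list.
#' @export
align_params <- function(word_size = 7L, match = 1, mismatch = -1,
                         gap_open = 5, gap_extend = 2, e_max = 1e-3,
                         min_len = 20L, lambda = log(3), K = 0.62,
                         xdrop = 12, max_ext = 400L) {
  stopifnot(word_size >= 4, e_max > 0)
  list(word_size = word_size, match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend, e_max = e_max,
       min_len = min_len, lambda = lambda, K = K, xdrop = xdrop,
       max_ext = max_ext)
}

#' Karlin-Altschul lambda for a match/mismatch score on a background
#'
#' Solves sum_ij p_i p_j exp(lambda * s_ij) = 1 numerically. For +1/-1
#' scoring on the uniform background the analytic solution is
#' exp(lambda)/4 + 3 exp(-lambda)/4 = 1, i.e. lambda = ln 3.
#'
#' @param match,mismatch scores (default +1/-1).
#' @param bg background base probabilities (default uniform).
#' @return lambda.
#' @export
karlin_lambda <- function(match = 1, mismatch = -1, bg = rep(0.25, 4)) {
  p_match <- sum(bg^2)
  f <- function(l) p_match * exp(l * match) +
    (1 - p_match) * exp(l * mismatch) - 1
  uniroot(f, c(1e-8, 10), tol = 1e-12)$root
}

#' Karlin-Altschul E-value of a raw alignment score
#' @param score raw score.
#' @param m,n effective sequence lengths (raw lengths; no edge correction).
#' @param params [align_params()].
#' @return E-value.
#' @export
karlin_evalue <- function(score, m, n, params = align_params()) {
  params$K * m * n * exp(-params$lambda * score)
}

#' Validate syntenic blocks for one-to-one mapping and extract sequences
#'
#' Pairs where one species' interval overlaps another block's interval
#' (many-to-one in either direction) are dropped and counted. Sequences of
#' inverted blocks are reverse complemented on the B side so that
#' alignment is always plus-strand; hit coordinates are lifted back
#' through the orientation by [classify_conservation()].
#'
#' @param blocks block table (see [read_blocks()]).
#' @param genome_a,genome_b named DNAStringSet genomes.
#' @return list with `blocks` (validated), `subject_seq` (named character,
#'   aligned orientation), `n_dropped`.
#' @export
prepare_blocks <- function(blocks, genome_a, genome_b) {
  dup_over <- function(chrom, start, end) {
    n <- length(start)
    bad <- rep(FALSE, n)
    if (n > 1) {
      iv <- data.frame(chrom = chrom, start = start, end = end)
      pr <- iv_overlap_pairs(iv, iv)
      pr <- pr[pr$query != pr$subject, , drop = FALSE]
      bad[unique(c(pr$query, pr$subject))] <- TRUE
    }
    bad
  }
  badA <- dup_over(blocks$chromA, blocks$startA, blocks$endA)
  badB <- dup_over(blocks$chromB, blocks$startB, blocks$endB)
  drop <- badA | badB
  kept <- blocks[!drop, , drop = FALSE]
  subject_seq <- vapply(seq_len(nrow(kept)), function(i) {
    s <- as.character(Biostrings::subseq(genome_b[[kept$chromB[i]]],
                                         kept$startB[i] + 1L,
                                         kept$endB[i]))
    if (kept$orientation[i] == "inverted") .revcomp_chr(s) else s
  }, "")
  names(subject_seq) <- kept$block_id
  list(blocks = kept, subject_seq = subject_seq, n_dropped = sum(drop))
}

#' Align an ACR sequence against a syntenic block sequence
#'
#' Exact `word_size`-mer seeds, ungapped X-drop extension, then affine-gap
#' extension from both segment ends; non-overlapping locally optimal hits
#' are kept when E <= `e_max` and alignment length > `min_len`. Both query
#' orientations are scanned.
#'
#' @param query ACR sequence (character).
#' @param subject block sequence (character).
#' @param params [align_params()].
#' @param filter apply the E-value/length filters (default TRUE).
#' @return data.frame of hits: qstart, qend, sstart, send (0-based
#'   half-open in the given sequences), strand, score, length, identity
#'   (over the ungapped core), evalue.
#' @export
align_acr <- function(query, subject, params = align_params(),
                      filter = TRUE) {
  m <- nchar(query)
  n <- nchar(subject)
  empty <- data.frame(qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), score = numeric(0),
                      length = integer(0), identity = numeric(0),
                      evalue = numeric(0))
  if (m == 0 || n == 0) return(empty)
  s_min <- log(params$K * m * n / params$e_max) / params$lambda
  min_ungapped <- max(params$word_size * params$match,
                      floor(s_min) - 4)
  run <- function(q, strand) {
    h <- .seed_extend_align_cpp(q, subject, params$word_size,
                                params$match, params$mismatch,
                                params$gap_open, params$gap_extend,
                                params$xdrop, min_ungapped, params$max_ext)
    if (nrow(h) == 0) return(NULL)
    if (strand == "-") {
      qs <- m - h$qend
      h$qend <- m - h$qstart
      h$qstart <- qs
    }
    h$strand <- strand
    h
  }
  hits <- rbind(run(query, "+"), run(.revcomp_chr(query), "-"))
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits$length <- pmax(hits$qend - hits$qstart, hits$send - hits$sstart)
  hits$identity <- hits$core_ident / hits$core_len
  hits$evalue <- karlin_evalue(hits$score, m, n, params)
  hits <- hits[order(hits$evalue, hits$sstart), , drop = FALSE]
  if (filter) {
    hits <- hits[hits$evalue <= params$e_max & hits$length > params$min_len,
                 , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits[, c("qstart", "qend", "sstart", "send", "strand", "score", "length",
           "identity", "evalue")]
}

# lift a subject-space interval (aligned orientation) to B genome coords
.lift_hit <- function(block, sstart, send) {
  len <- block$endB - block$startB
  if (block$orientation == "same") {
    c(block$startB + sstart, block$startB + send)
  } else {
    c(block$startB + len - send, block$startB + len - sstart)
  }
}

#' Classify cross-species conservation of ACRs inside syntenic blocks
#'
#' Each query ACR is aligned only against its own syntenic block. With a
#' passing hit that overlaps (>= 1 bp, after lifting through the block
#' orientation) a partner-species ACR the class is `shared`; with a
#' passing hit but no partner overlap it is `variable`; with no passing
#' hit it is `species_specific`. ACRs outside every block are reported
#' separately as non-syntenic.
#'
#' @param acrs_a species-A ACRs (acr_id, chrom, start, end).
#' @param genome_a species-A genome (DNAStringSet).
#' @param prep output of [prepare_blocks()].
#' @param acrs_b species-B ACRs (chrom, start, end, acr_id, optionally
#'   cell_type).
#' @param params [align_params()].
#' @return data.frame: acr_id, syntenic, class, best hit columns, partner
#'   acr_id and cell type for shared calls.
#' @export
classify_conservation <- function(acrs_a, genome_a, prep, acrs_b,
                                  params = align_params()) {
  blocks <- prep$blocks
  out <- lapply(seq_len(nrow(acrs_a)), function(i) {
    row <- data.frame(acr_id = acrs_a$acr_id[i], syntenic = FALSE,
                      class = NA_character_, score = NA_real_,
                      length = NA_integer_, evalue = NA_real_,
                      hit_chrom = NA_character_, hit_start = NA_integer_,
                      hit_end = NA_integer_, partner = NA_character_,
                      partner_cell_type = NA_character_,
                      stringsAsFactors = FALSE)
    bi <- which(blocks$chromA == acrs_a$chrom[i] &
                  blocks$startA <= acrs_a$start[i] &
                  blocks$endA >= acrs_a$end[i])
    if (!length(bi)) return(row)
    bi <- bi[1]
    row$syntenic <- TRUE
    q <- as.character(Biostrings::subseq(genome_a[[acrs_a$chrom[i]]],
                                         acrs_a$start[i] + 1L,
                                         acrs_a$end[i]))
    hits <- align_acr(q, prep$subject_seq[[blocks$block_id[bi]]], params)
    if (nrow(hits) == 0) {
      row$class <- "species_specific"
      return(row)
    }
    lifted <- t(vapply(seq_len(nrow(hits)), function(k) {
      .lift_hit(blocks[bi, ], hits$sstart[k], hits$send[k])
    }, numeric(2)))
    hit_iv <- data.frame(chrom = blocks$chromB[bi],
                         start = lifted[, 1], end = lifted[, 2])
    ov <- iv_overlap_pairs(hit_iv, acrs_b)
    best <- 1L  # hits sorted by evalue
    if (nrow(ov)) {
      row$class <- "shared"
      k <- ov$query[1]
      row$partner <- acrs_b$acr_id[ov$subject[1]]
      if ("cell_type" %in% names(acrs_b)) {
        row$partner_cell_type <- acrs_b$cell_type[ov$subject[1]]
      }
      best <- k
    } else {
      row$class <- "variable"
    }
    row$score <- hits$score[best]
    row$length <- hits$length[best]
    row$evalue <- hits$evalue[best]
    row$hit_chrom <- blocks$chromB[bi]
    row$hit_start <- as.integer(lifted[best, 1])
    row$hit_end <- as.integer(lifted[best, 2])
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cell-type retention of shared cell-type-specific ACRs
#'
#' For each shared query ACR that is cell-type-specific in species A:
#' `retained` when the partner ACR is specific to the identical cell type,
#' `broadened` when the partner is broad, `switched` otherwise (the
#' partner's cell types are recorded), `unknown` when the partner is
#' unlabeled.
#'
#' @param calls output of [classify_conservation()].
#' @param labels_a data.frame (acr_id, label, specific_types) for species A
#'   (see [label_acr_specificity()]).
#' @param labels_b same for species B, keyed by partner acr_id.
#' @return data.frame: acr_id, partner, own_type, partner_type, outcome.
#' @export
celltype_retention <- function(calls, labels_a, labels_b) {
  shared <- calls[calls$class %in% "shared", , drop = FALSE]
  la <- labels_a[match(shared$acr_id, labels_a$acr_id), ]
  spec <- !is.na(la$label) & la$label == "cell-type-specific"
  shared <- shared[spec, , drop = FALSE]
  la <- la[spec, , drop = FALSE]
  lb <- labels_b[match(shared$partner, labels_b$acr_id), ]
  outcome <- character(nrow(shared))
  for (i in seq_len(nrow(shared))) {
    if (is.na(lb$label[i])) {
      outcome[i] <- "unknown"
    } else if (lb$label[i] == "broad") {
      outcome[i] <- "broadened"
    } else {
      a_types <- strsplit(la$specific_types[i], ",")[[1]]
      b_types <- strsplit(lb$specific_types[i], ",")[[1]]
      outcome[i] <- if (length(intersect(a_types, b_types)))
        "retained" else "switched"
    }
  }
  data.frame(acr_id = shared$acr_id, partner = shared$partner,
             own_type = la$specific_types,
             partner_type = ifelse(is.na(lb$label), NA, lb$specific_types),
             outcome = outcome, stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap enrichment of one region set in another via simulated nulls
#'
#' Observed statistic: fraction of `a` regions overlapping `b`. Null:
#' mean fraction over `n_sim` length-matched placements of `a` in the
#' sampling space. p: exact one-tailed binomial upper tail. When
#' `fisher = TRUE` a 2x2 Fisher test of the contingency
#' (a vs background regions) x (overlaps b or not) is also returned.
#'
#' @param a,b interval data frames.
#' @param genome list with `mappable`.
#' @param n_sim number of simulated placements (default 100).
#' @param exclusions optional intervals removed from the sampling space.
#' @param seed integer seed.
#' @param fisher also run a Fisher test against the pooled null sets.
#' @return list: observed, null_mean, k, n, p (binomial), fisher_p
#'   (optional).
#' @export
region_overlap_enrichment <- function(a, b, genome, n_sim = 100L,
                                      exclusions = NULL, seed = 1L,
                                      fisher = FALSE) {
  k <- sum(iv_overlaps_any(a, b))
  n <- nrow(a)
  sets <- simulate_control_regions(a, genome, n = n_sim,
                                   exclusions = exclusions, seed = seed)
  null_ratios <- vapply(sets, capture_ratio, 0, features = b)
  bt <- binomial_enrichment(k, n, null_ratios)
  out <- list(observed = k / n, null_mean = mean(null_ratios), k = k, n = n,
              p = bt$p)
  if (fisher) {
    null_k <- sum(vapply(sets, function(s) sum(iv_overlaps_any(s, b)), 0))
    null_n <- n * n_sim
    tab <- matrix(c(k, n - k, null_k, null_n - null_k), 2)
    out$fisher_p <- stats::fisher.test(tab,
                                       alternative = "greater")$p.value
  }
  out
}
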