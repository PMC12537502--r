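# Motif models, PWM scanning with an exact discretized-score p-value
# threshold, IUPAC pattern matching, length-matched control regions, and
# the three enrichment tests (negative-binomial regression, exact binomial
# against simulated nulls, family-level hypergeometric).

#' Construct a PWM motif model from a count (or probability) matrix
#'
#' @param id motif identifier.
#' @param name display name.
#' @param counts 4 x L matrix with rows A, C, G, T.
#' @param pseudocount total pseudocount added per column (default 0.8).
#' @return motif model list (id, name, kind = "pwm", pwm with columns
#'   summing to 1).
#' @export
motif_pwm <- function(id, counts, name = id, pseudocount = 0.8) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4)
  rownames(counts) <- c("A", "C", "G", "T")
  pwm <- sweep(counts + pseudocount / 4, 2, colSums(counts) + pseudocount,
               "/")
  list(id = id, name = name, kind = "pwm", pwm = pwm)
}

#' Construct an IUPAC pattern motif model
#' @param id motif identifier.
#' @param pattern non-empty IUPAC string.
#' @param name display name.
#' @param family optional family label.
#' @return motif model list.
#' @export
motif_pattern <- function(id, pattern, name = id, family = NA_character_) {
  stopifnot(nchar(pattern) > 0,
            all(strsplit(pattern, "")[[1]] %in%
                  names(Biostrings::IUPAC_CODE_MAP)))
  list(id = id, name = name, kind = "pattern", pattern = pattern,
       family = family)
}

#' Consensus sequence of a motif model
#' @param m motif model.
#' @return character consensus (per-column argmax for PWMs).
#' @export
motif_consensus <- function(m) {
  if (m$kind == "pattern") return(iupac_consensus(m$pattern))
  paste0(rownames(m$pwm)[apply(m$pwm, 2, which.max)], collapse = "")
}

#' Exact PWM score threshold for a target p-value
#'
#' Computes the full distribution of the log-likelihood-ratio score under
#' the background model by dynamic programming over scores discretized at
#' `resolution`, and returns the smallest score s with
#' P(score >= s | background) <= `p_thresh`.
#'
#' @param pwm 4 x L probability matrix.
#' @param p_thresh target p-value (default 1e-5).
#' @param bg background base probabilities (A, C, G, T; default uniform).
#' @param resolution score discretization step (default 1e-3).
#' @return list with `threshold` (on the log2-odds scale) and `pvalue`
#'   (the attained tail probability).
#' @export
pwm_score_threshold <- function(pwm, p_thresh = 1e-5,
                                bg = rep(0.25, 4), resolution = 1e-3) {
  S <- log2(pwm / bg)
  Si <- round(S / resolution)        # integer scores, 4 x L
  L <- ncol(Si)
  # dist[k] = P(partial score == cur_lo + k - 1), grown column by column
  dist <- 1
  cur_lo <- 0L
  for (j in seq_len(L)) {
    col <- Si[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(dist) - 1L + max(col)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
    cur_lo <- new_lo
  }
  scores <- (cur_lo + seq_along(dist) - 1L) * resolution
  tail_p <- rev(cumsum(rev(dist)))
  # smallest attainable score (positive mass) whose tail is within p_thresh
  ok <- which(tail_p <= p_thresh & dist > 0)
  if (!length(ok)) {
    return(list(threshold = Inf, pvalue = 0))
  }
  k <- ok[1]
  list(threshold = scores[k], pvalue = tail_p[k])
}

.base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# sliding-window log2-odds scores of a PWM over one sequence (plus strand)
.pwm_scan_scores <- function(seq_chr, S) {
  L <- ncol(S)
  n <- nchar(seq_chr)
  if (n < L) return(numeric(0))
  code <- .base_codes[strsplit(seq_chr, "")[[1]]]
  n_win <- n - L + 1L
  total <- numeric(n_win)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n_win - 1L)]
    sj <- S[cbind(cj, j)]
    sj[is.na(cj)] <- -Inf
    total <- total + sj
  }
  total
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan sequences for motif hits
#'
#' PWM motifs are scanned on both strands with the exact score threshold
#' from [pwm_score_threshold()] at `p_thresh`; pattern motifs are matched
#' by IUPAC expansion on both strands. Returns individual hits and a
#' binarized sequence-by-motif matrix.
#'
#' @param seqs named character vector or DNAStringSet of sequences.
#' @param motifs list of motif models.
#' @param p_thresh PWM hit p-value threshold (default 1e-5).
#' @param bg background base probabilities (default uniform).
#' @param resolution score discretization step shared by the threshold DP
#'   and the scan (default 1e-3), so the two are exactly consistent.
#' @return list with `hits` (seq_id, motif, pos 0-based, strand, score) and
#'   `matrix` (logical sequence x motif).
#' @export
scan_motifs <- function(seqs, motifs, p_thresh = 1e-5, bg = rep(0.25, 4),
                        resolution = 1e-3) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  hit_rows <- list()
  mat <- matrix(FALSE, length(seqs), length(motifs),
                dimnames = list(ids, vapply(motifs, `[[`, "", "id")))
  for (m in motifs) {
    if (m$kind == "pwm") {
      # scan with the same discretized scores the threshold DP uses
      S <- round(log2(m$pwm / bg) / resolution) * resolution
      thr <- pwm_score_threshold(m$pwm, p_thresh, bg,
                                 resolution = resolution)$threshold
      for (si in seq_along(seqs)) {
        for (strand in c("+", "-")) {
          sq <- if (strand == "+") seqs[[si]] else .revcomp_chr(seqs[[si]])
          sc <- .pwm_scan_scores(sq, S)
          pos <- which(sc >= thr)
          if (length(pos)) {
            L <- ncol(S)
            p0 <- if (strand == "+") pos - 1L else
              nchar(seqs[[si]]) - (pos - 1L) - L
            hit_rows[[length(hit_rows) + 1L]] <- data.frame(
              seq_id = ids[si], motif = m$id, pos = p0, strand = strand,
              score = sc[pos], stringsAsFactors = FALSE)
            mat[si, m$id] <- TRUE
          }
        }
      }
    } else {
      pat <- Biostrings::DNAString(m$pattern)
      ss <- Biostrings::DNAStringSet(seqs)
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
        mm <- Biostrings::vmatchPattern(p, ss, fixed = FALSE)
        cnt <- S4Vectors::elementNROWS(mm)
        for (si in which(cnt > 0)) {
          st <- Biostrings::startIndex(mm)[[si]]
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            seq_id = ids[si], motif = m$id, pos = st - 1L, strand = strand,
            score = NA_real_, stringsAsFactors = FALSE)
          mat[si, m$id] <- TRUE
        }
      }
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(seq_id = character(0), motif = character(0),
               pos = integer(0), strand = character(0), score = numeric(0))
  list(hits = hits, matrix = mat)
}

#' Simulate length-matched control region sets
#'
#' Each control set reproduces the exact width multiset of the target
#' regions, placed uniformly in mappable space minus exclusions, rejecting
#' placements that overlap the targets.
#'
#' @param targets target interval data frame.
#' @param genome list with `mappable` (interval data frame).
#' @param n number of control sets (default 100).
#' @param exclusions optional interval data frame removed from the
#'   sampling space.
#' @param seed integer seed.
#' @param max_tries rejection-sampling retries per interval.
#' @return list of `n` interval data frames.
#' @export
simulate_control_regions <- function(targets, genome, n = 100L,
                                     exclusions = NULL, seed = 1L,
                                     max_tries = 200L) {
  set.seed(seed)
  space <- genome$mappable
  if (!is.null(exclusions) && nrow(exclusions)) {
    space <- iv_setdiff(space, exclusions)
  }
  if (sum(space$end - space$start) < sum(targets$end - targets$start)) {
    stop("sampling space smaller than total target length")
  }
  widths <- targets$end - targets$start
  lapply(seq_len(n), function(s) {
    out <- sample_intervals_in_space(widths, space)
    bad <- which(iv_overlaps_any(out, targets))
    tries <- 0L
    while (length(bad) && tries < max_tries) {
      out[bad, ] <- sample_intervals_in_space(widths[bad], space)
      bad <- which(iv_overlaps_any(out, targets))
      tries <- tries + 1L
    }
    if (length(bad)) stop("control placement space exhausted")
    out
  })
}

#' Fraction of intervals in a set that capture a feature set
#' @param set interval data frame.
#' @param features interval data frame.
#' @return numeric fraction in [0, 1].
#' @export
capture_ratio <- function(set, features) {
  if (nrow(set) == 0) return(NA_real_)
  mean(iv_overlaps_any(set, features))
}

#' Exact binomial enrichment test against simulated null sets
#'
#' The hypothesized success probability is the mean capture ratio over the
#' null sets; the test is the one-tailed (greater) exact binomial upper
#' tail with k = targets capturing the feature, n = number of targets.
#'
#' @param k number of target regions capturing the feature.
#' @param n number of target regions.
#' @param null_ratios capture ratios of the null/control sets.
#' @return list with `p`, `p0` (possibly clamped), `clamped` flag.
#' @export
binomial_enrichment <- function(k, n, null_ratios) {
  p0 <- mean(null_ratios)
  clamped <- FALSE
  eps <- 1 / (length(null_ratios) * n)
  if (p0 <= 0 || p0 >= 1) {
    p0 <- min(max(p0, eps), 1 - eps)
    clamped <- TRUE
  }
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  list(p = p, p0 = p0, clamped = clamped)
}

#' Negative-binomial regression motif enrichment per cell type
#'
#' Cells are downsampled to `downsample` per cell type (with replacement
#' and a flag when a type is smaller). For each (motif, cell type) the
#' motif's per-cell count is modelled as
#' log mu = b0 + b1 * 1[cell in type] + b2 * log(nonzero entries), with NB
#' errors: a Poisson fit provides method-of-moments dispersion, then the
#' model is refit once with that dispersion. b1 is the enrichment score;
#' p-values are Wald, BH-adjusted across motifs within each cell type.
#' Enriched motifs satisfy q < `q_cut` and b1 > `beta_cut`.
#'
#' @param motif_counts motif x cell count matrix.
#' @param annotations cell-type label per cell (columns of `motif_counts`).
#' @param nonzero per-cell number of nonzero entries in the peak matrix.
#' @param downsample cells per cell type (default 412).
#' @param q_cut,beta_cut enrichment cutoffs (defaults 0.01, 0.05).
#' @param seed integer seed.
#' @param types cell types to fit (default: all); the downsampled cell set
#'   always spans every annotation so the "rest" group is unchanged.
#' @return data.frame: motif, cell_type, beta, fold_change, p, q, enriched,
#'   poisson_fallback.
#' @export
nb_enrichment <- function(motif_counts, annotations, nonzero,
                          downsample = 412L, q_cut = 0.01, beta_cut = 0.05,
                          seed = 1L, types = NULL) {
  set.seed(seed)
  motif_counts <- as.matrix(motif_counts)
  all_types <- sort(unique(annotations))
  if (is.null(types)) types <- all_types
  # downsample each type once; the same cell subset is used for every motif
  idx <- unlist(lapply(all_types, function(ty) {
    cand <- which(annotations == ty)
    if (length(cand) >= downsample) sample(cand, downsample) else
      sample(cand, downsample, replace = TRUE)
  }))
  ann <- annotations[idx]
  lognz <- log(pmax(nonzero[idx], 1))
  out <- list()
  for (ty in types) {
    ind <- as.integer(ann == ty)
    res <- lapply(rownames(motif_counts), function(mo) {
      y <- motif_counts[mo, idx]
      fit0 <- tryCatch(glm(y ~ ind + lognz, family = poisson()),
                       error = function(e) NULL)
      if (is.null(fit0)) {
        return(data.frame(motif = mo, cell_type = ty, beta = NA_real_,
                          fold_change = NA_real_, p = NA_real_,
                          poisson_fallback = TRUE))
      }
      mu <- fitted(fit0)
      # method-of-moments dispersion: var = mu + mu^2 / theta
      num <- sum((y - mu)^2 - mu)
      den <- sum(mu^2)
      theta <- if (num > 0 && den > 0) den / num else Inf
      fallback <- FALSE
      if (is.finite(theta) && theta > 0 && theta < 1e6) {
        fit <- tryCatch(glm(y ~ ind + lognz,
                            family = MASS::negative.binomial(theta)),
                        error = function(e) NULL)
        if (is.null(fit)) {
          fit <- fit0
          fallback <- TRUE
        }
      } else {
        fit <- fit0
        fallback <- TRUE
      }
      cf <- summary(fit)$coefficients
      beta <- cf["ind", "Estimate"]
      p <- cf["ind", 4]
      data.frame(motif = mo, cell_type = ty, beta = beta,
                 fold_change = exp(beta), p = p,
                 poisson_fallback = fallback, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, res)
    tab$q <- p.adjust(tab$p, method = "BH")
    tab$enriched <- !is.na(tab$q) & tab$q < q_cut & tab$beta > beta_cut
    out[[ty]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Family-level hypergeometric motif enrichment
#'
#' For family F with K universe ACRs containing any F motif and k of the n
#' target ACRs containing one, p = P(X >= k) for
#' X ~ Hypergeometric(N, K, n).
#'
#' @param target_ids ACR ids of the target set (subset of universe).
#' @param universe_ids all ACR ids.
#' @param families named list mapping family -> motif ids.
#' @param hit_matrix logical ACR x motif matrix (rownames = ACR ids).
#' @return data.frame: family, N, K, n, k, p.
#' @export
family_hypergeom <- function(target_ids, universe_ids, families,
                             hit_matrix) {
  stopifnot(all(target_ids %in% universe_ids))
  N <- length(universe_ids)
  n <- length(target_ids)
  rows <- lapply(names(families), function(fam) {
    motifs <- intersect(families[[fam]], colnames(hit_matrix))
    has <- if (length(motifs)) {
      rowSums(hit_matrix[, motifs, drop = FALSE]) > 0
    } else setNames(rep(FALSE, nrow(hit_matrix)), rownames(hit_matrix))
    K <- sum(has[universe_ids])
    k <- sum(has[target_ids])
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(family = fam, N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
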