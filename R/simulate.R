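# Seeded synthetic-data generators. Every input the pipeline consumes can be
# produced here with planted ground truth (peak classes, silencer ACRs,
# conservation classes, trajectory shifts), so each downstream stage has a
# recoverable signal to test against.
#
# Genome layout: chromosomes are tiled into 10 kb units. Each unit carries a
# gene body at [4000, 5500) and three candidate 500 bp peak slots chosen so
# that their genomic context is unambiguous: distal at [500, 1000) (>2 kb
# from any gene), proximal at [2500, 3000) (1 kb gap to the gene start) and
# genic at [4500, 5000) (inside the gene body).

.UNIT <- 10000L
.SLOTS <- list(distal = c(500L, 1000L), proximal = c(2500L, 3000L),
               genic = c(4500L, 5000L))

#' Default IUPAC patterns for the six PRE-associated motif classes
#'
#' Polycomb response elements (PREs) in plants are associated with six short
#' sequence classes: CTCC, CCG, G-box, GA-repeat, AC-rich and Telobox. The
#' exact definitions are replaceable assets; these defaults mirror the
#' literature names.
#'
#' @return named character vector of IUPAC patterns.
#' @export
pre_motif_patterns <- function() {
  c(CTCC = "CTCCTCC", CCG = "CCGCCGCCG", Gbox = "CACGTG",
    GArepeat = "GAGAGAGA", ACrich = "ACACACACAC", Telobox = "AAACCCTA")
}

#' Pick one concrete base for each IUPAC code (deterministic)
#' @param pattern IUPAC string.
#' @return ACGT string of the same length.
#' @keywords internal
iupac_consensus <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(pattern, "")[[1]],
                function(ch) substr(map[[ch]], 1, 1), ""), collapse = "")
}

#' Simulate a reference genome with planted peaks, genes and motif sites
#'
#' Background sequence is i.i.d. uniform over A/C/G/T (which keeps the
#' aligner's Karlin-Altschul lambda exactly ln 3 for +1/-1 scoring). Genes
#' are non-overlapping; planted peaks are 500 bp and assigned
#' genic/proximal/distal contexts in a configurable ratio (default
#' 19/52/29). Decoy peaks receive signal in all cell types but are later
#' covered by nucleosome calls and large fragments so the ACR filters can be
#' exercised.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len length of each chromosome in bp (>= 50 kb).
#' @param cell_types character vector of cell-type labels.
#' @param n_peaks number of planted true peaks.
#' @param frac_broad fraction of planted peaks accessible in all cell types.
#' @param n_decoy number of decoy (nucleosomal) peaks.
#' @param context_ratio length-3 numeric (genic, proximal, distal) summing
#'   to 1.
#' @param motif_library optional list of motif models; `motif_sites_per`
#'   consensus copies of each are embedded in background sequence.
#' @param motif_sites_per planted sites per motif.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list with `ref` (chrom_sizes, seq, mappable, exons), `genes`,
#'   and `truth` (planted_peaks, decoy_peaks, motif_sites, seed).
#' @export
simulate_reference <- function(n_chrom = 2L, chrom_len = 1e6, cell_types,
                               n_peaks = 100L, frac_broad = 0.4,
                               n_decoy = 0L,
                               context_ratio = c(0.19, 0.52, 0.29),
                               motif_library = NULL, motif_sites_per = 0L,
                               seed = 1L) {
  stopifnot(chrom_len >= 5e4, abs(sum(context_ratio) - 1) < 1e-8)
  set.seed(seed)
  chrom_len <- as.integer(chrom_len)
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_sizes <- setNames(rep(chrom_len, n_chrom), chroms)
  seqs <- vapply(chroms, function(ch) {
    paste0(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
           collapse = "")
  }, "")

  units_per_chrom <- chrom_len %/% .UNIT - 1L
  units <- data.frame(
    chrom = rep(chroms, each = units_per_chrom),
    offset = rep(seq_len(units_per_chrom) - 1L, n_chrom) * .UNIT
  )
  n_units <- nrow(units)
  genes <- data.frame(
    chrom = units$chrom,
    start = units$offset + 4000L,
    end = units$offset + 5500L,
    strand = sample(c("+", "-"), n_units, replace = TRUE),
    gene_id = sprintf("gene%05d", seq_len(n_units)),
    stringsAsFactors = FALSE
  )

  # each unit offers one slot per context; draw units without replacement
  # within each context pool
  ctx <- sample(c("genic", "proximal", "distal"), n_peaks, replace = TRUE,
                prob = context_ratio)
  n_distal_needed <- sum(ctx == "distal") + n_decoy
  if (any(table(factor(ctx, c("genic", "proximal", "distal"))) > n_units) ||
        n_distal_needed > n_units) {
    stop("requested elements exceed genome capacity")
  }
  pool <- list(genic = sample(n_units), proximal = sample(n_units),
               distal = sample(n_units))
  taken <- c(genic = 0L, proximal = 0L, distal = 0L)
  mk_peak <- function(u, context) {
    sl <- .SLOTS[[context]]
    data.frame(chrom = units$chrom[u], start = units$offset[u] + sl[1],
               end = units$offset[u] + sl[2], context = context,
               stringsAsFactors = FALSE)
  }
  peak_units <- integer(n_peaks)
  for (i in seq_len(n_peaks)) {
    taken[ctx[i]] <- taken[ctx[i]] + 1L
    peak_units[i] <- pool[[ctx[i]]][taken[ctx[i]]]
  }
  peaks <- do.call(rbind, Map(mk_peak, peak_units, ctx))
  n_broad <- round(frac_broad * n_peaks)
  classes <- c(rep("broad", n_broad),
               paste0("specific:",
                      sample(cell_types, n_peaks - n_broad, replace = TRUE)))
  peaks$class <- sample(classes)
  peaks$strength <- 1
  peaks$peak_id <- sprintf("peak%04d", seq_len(n_peaks))

  decoys <- NULL
  if (n_decoy > 0) {
    du <- pool$distal[taken["distal"] + seq_len(n_decoy)]
    decoys <- do.call(rbind, Map(mk_peak, du, rep("distal", n_decoy)))
    decoys$peak_id <- sprintf("decoy%04d", seq_len(n_decoy))
  }

  motif_sites <- NULL
  if (!is.null(motif_library) && motif_sites_per > 0) {
    # the [6000, 9000) strip of every unit never hosts genes or peaks
    free_units <- seq_len(n_units)
    rows <- list()
    for (m in motif_library) {
      cons <- if (m$kind == "pattern") iupac_consensus(m$pattern) else
        motif_consensus(m)
      w <- nchar(cons)
      us <- sample(free_units, motif_sites_per)
      pos <- units$offset[us] + 6000L +
        sample.int(3000L - w, motif_sites_per, replace = TRUE)
      for (k in seq_len(motif_sites_per)) {
        ch <- units$chrom[us[k]]
        substr(seqs[[ch]], pos[k] + 1L, pos[k] + w) <- cons
        rows[[length(rows) + 1L]] <- data.frame(
          motif = m$id, chrom = ch, pos = pos[k], strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    motif_sites <- do.call(rbind, rows)
  }

  seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- chroms
  ref <- list(
    chrom_sizes = chrom_sizes,
    seq = seqs,
    mappable = data.frame(chrom = chroms, start = 0L, end = chrom_len),
    exons = genes[, c("chrom", "start", "end")]
  )
  list(ref = ref, genes = genes,
       truth = list(planted_peaks = peaks, decoy_peaks = decoys,
                    motif_sites = motif_sites, cell_types = cell_types,
                    seed = seed))
}

#' Simulate per-barcode Tn5 insertions from planted truth
#'
#' Per-cell depth is negative binomial. Each insertion falls inside a peak
#' active for the cell's type with probability `snr * P / (snr * P + (L - P))`
#' (P = active peak bp, L = genome bp), i.e. the in-peak insertion rate is
#' `snr` times the background rate. Broad peaks and decoys are active in all
#' cell types; specific peaks only in their own. Fragment sizes are bimodal:
#' subnucleosomal (mode ~80 bp) inside true peaks, nucleosomal (>150 bp)
#' inside decoy peaks.
#'
#' @param sim output of [simulate_reference()].
#' @param cell_plan named integer vector: cells per cell type.
#' @param depth_mean mean insertions per cell.
#' @param depth_size negative-binomial size (dispersion) parameter.
#' @param snr in-peak to background insertion rate ratio (> 1).
#' @param seed integer seed.
#' @return list with `insertions` (data.table: chrom, pos, barcode,
#'   frag_size, cell_type) and `cells` (barcode, cell_type, depth, QC
#'   metrics).
#' @export
simulate_fragments <- function(sim, cell_plan, depth_mean = 500,
                               depth_size = 5, snr = 5, seed = 1L) {
  stopifnot(snr > 1)
  if (!all(names(cell_plan) %in% sim$truth$cell_types)) {
    stop("unknown cell type in plan")
  }
  set.seed(seed)
  ref <- sim$ref
  truth <- sim$truth
  L <- sum(as.numeric(ref$chrom_sizes))
  peaks <- truth$planted_peaks
  decoys <- truth$decoy_peaks
  all_peaks <- rbind(peaks[, c("chrom", "start", "end", "class")],
                     if (!is.null(decoys))
                       cbind(decoys[, c("chrom", "start", "end")],
                             class = "decoy"))
  out_ins <- vector("list", length(cell_plan))
  out_cells <- vector("list", length(cell_plan))
  for (ti in seq_along(cell_plan)) {
    type <- names(cell_plan)[ti]
    n_cells <- cell_plan[[ti]]
    active <- all_peaks$class %in% c("broad", "decoy") |
      all_peaks$class == paste0("specific:", type)
    ap <- all_peaks[active, , drop = FALSE]
    widths <- ap$end - ap$start
    P <- sum(widths)
    p_peak <- snr * P / (snr * P + (L - P))
    depth <- rnbinom(n_cells, mu = depth_mean, size = depth_size)
    depth <- pmax(depth, 10L)
    bc <- sprintf("%s_bc%04d", type, seq_len(n_cells))
    N <- sum(depth)
    in_peak <- runif(N) < p_peak
    n_in <- sum(in_peak)
    pos <- integer(N)
    chrom <- character(N)
    fsize <- integer(N)
    if (n_in > 0) {
      pk <- sample(nrow(ap), n_in, replace = TRUE, prob = widths)
      pos[in_peak] <- ap$start[pk] +
        floor(runif(n_in) * widths[pk])
      chrom[in_peak] <- ap$chrom[pk]
      is_decoy <- ap$class[pk] == "decoy"
      fsize[in_peak] <- ifelse(is_decoy,
        pmin(pmax(round(rnorm(n_in, 220, 20)), 160L), 320L),
        pmin(pmax(round(rnorm(n_in, 80, 15)), 30L), 140L))
    }
    n_bg <- N - n_in
    if (n_bg > 0) {
      gpos <- floor(runif(n_bg) * L)
      cum <- cumsum(as.numeric(ref$chrom_sizes))
      ci <- findInterval(gpos, c(0, cum), rightmost.closed = FALSE)
      pos[!in_peak] <- as.integer(gpos - c(0, cum)[ci])
      chrom[!in_peak] <- names(ref$chrom_sizes)[ci]
      sub <- runif(n_bg) < 0.5
      fsize[!in_peak] <- ifelse(sub,
        pmin(pmax(round(rnorm(n_bg, 80, 15)), 30L), 140L),
        pmin(pmax(round(rnorm(n_bg, 220, 30)), 160L), 400L))
    }
    ins <- data.table::data.table(
      chrom = chrom, pos = pos,
      barcode = rep(bc, depth),
      frag_size = fsize, cell_type = type)
    out_ins[[ti]] <- ins
    out_cells[[ti]] <- data.frame(
      barcode = bc, cell_type = type, depth = depth,
      tss_frac = pmin(pmax(rnorm(n_cells, 0.35, 0.05), 0), 1),
      frip = pmin(pmax(rnorm(n_cells, 0.3, 0.05), 0), 1),
      organelle_frac = pmin(pmax(rnorm(n_cells, 0.01, 0.005), 0), 1),
      stringsAsFactors = FALSE)
  }
  ins <- data.table::rbindlist(out_ins)
  data.table::setkey(ins, chrom, pos)
  list(insertions = ins, cells = do.call(rbind, out_cells))
}

#' Simulate the epigenomic layers: H3K27me3 domains, nucleosome calls and
#' methylation windows
#'
#' A chosen fraction of planted broad peaks is embedded inside H3K27me3
#' domains; these become the planted candidate silencers and each receives
#' one planted PRE-class motif consensus written into the genome sequence.
#' Nucleosome intervals are placed over a configurable fraction of decoy
#' peaks. Methylation windows tile the genome at 500 bp with planted broad
#' methylation regions (BMRs) of consecutive high-level windows.
#'
#' @param sim output of [simulate_reference()] (its `ref$seq` is modified to
#'   carry the planted PRE motifs; the updated `sim` is returned).
#' @param frac_silencer fraction of broad peaks made silencer candidates.
#' @param frac_decoy_nuc fraction of decoy peaks covered by nucleosome calls.
#' @param n_bmr number of planted BMRs.
#' @param bmr_windows windows per planted BMR (>= 3).
#' @param bmr_level methylation level inside planted BMRs.
#' @param bg_level mean background methylation level.
#' @param window methylation window size in bp.
#' @param domain_pad H3K27me3 domain extension beyond the peak (bp); kept
#'   below the spacing between peak slots so domains never creep within
#'   the association flank of a neighbouring non-silencer peak.
#' @param seed integer seed.
#' @return updated `sim` plus `h3k27me3`, `nucleosomes`, `methyl` (chrom,
#'   start, end, level) and truth entries `silencer_acrs`, `bmr_truth`.
#' @export
simulate_epigenome <- function(sim, frac_silencer = 0.5, frac_decoy_nuc = 1,
                               n_bmr = 10L, bmr_windows = 5L,
                               bmr_level = 0.9, bg_level = 0.1,
                               window = 500L, domain_pad = 400L, seed = 1L) {
  stopifnot(frac_silencer >= 0, frac_silencer <= 1, bmr_windows >= 3)
  set.seed(seed)
  truth <- sim$truth
  peaks <- truth$planted_peaks
  broad_idx <- which(peaks$class == "broad")
  n_sil <- round(frac_silencer * length(broad_idx))
  sil_idx <- if (n_sil > 0) sort(sample(broad_idx, n_sil)) else integer(0)
  h3k <- if (length(sil_idx)) {
    iv_merge(data.frame(chrom = peaks$chrom[sil_idx],
                        start = pmax(0L, peaks$start[sil_idx] - domain_pad),
                        end = peaks$end[sil_idx] + domain_pad))
  } else data.frame(chrom = character(0), start = integer(0), end = integer(0))

  pre <- pre_motif_patterns()
  if (length(sil_idx)) {
    seq_chr <- as.character(sim$ref$seq)
    pick <- sample(length(pre), length(sil_idx), replace = TRUE)
    for (k in seq_along(sil_idx)) {
      i <- sil_idx[k]
      cons <- iupac_consensus(pre[[pick[k]]])
      w <- nchar(cons)
      s <- peaks$start[i] + (peaks$end[i] - peaks$start[i] - w) %/% 2L
      substr(seq_chr[[peaks$chrom[i]]], s + 1L, s + w) <- cons
    }
    nm <- names(sim$ref$seq)
    sim$ref$seq <- Biostrings::DNAStringSet(seq_chr)
    names(sim$ref$seq) <- nm
  }

  nuc <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
  decoys <- truth$decoy_peaks
  if (!is.null(decoys) && nrow(decoys) > 0 && frac_decoy_nuc > 0) {
    nd <- round(frac_decoy_nuc * nrow(decoys))
    di <- sort(sample(nrow(decoys), nd))
    nuc <- decoys[di, c("chrom", "start", "end")]
  }

  # methylation windows tiling each chromosome
  meth <- do.call(rbind, lapply(names(sim$ref$chrom_sizes), function(ch) {
    nw <- sim$ref$chrom_sizes[[ch]] %/% window
    data.frame(chrom = ch, start = (seq_len(nw) - 1L) * window,
               end = seq_len(nw) * window,
               level = rbeta(nw, bg_level * 20, (1 - bg_level) * 20),
               stringsAsFactors = FALSE)
  }))
  bmr_truth <- NULL
  if (n_bmr > 0) {
    rows <- list()
    used <- rep(FALSE, nrow(meth))
    for (b in seq_len(n_bmr)) {
      for (try in 1:100) {
        i0 <- sample(nrow(meth) - bmr_windows, 1L)
        idx <- i0:(i0 + bmr_windows - 1L)
        same <- length(unique(meth$chrom[idx])) == 1L
        pad <- c(max(1, i0 - 1), min(nrow(meth), i0 + bmr_windows))
        if (same && !any(used[min(pad):max(pad)])) break
      }
      used[idx] <- TRUE
      meth$level[idx] <- pmin(pmax(rnorm(bmr_windows, bmr_level, 0.02), 0), 1)
      rows[[b]] <- data.frame(chrom = meth$chrom[i0],
                              start = meth$start[i0],
                              end = meth$end[i0 + bmr_windows - 1L])
    }
    bmr_truth <- do.call(rbind, rows)
  }

  sim$h3k27me3 <- h3k
  sim$nucleosomes <- nuc
  sim$methyl <- meth
  sim$truth$silencer_acrs <- peaks$peak_id[sil_idx]
  sim$truth$bmr_truth <- bmr_truth
  sim
}

#' Simulate a second species genome inside syntenic blocks
#'
#' Species B is produced by copying each syntenic block of species A and
#' substituting bases at rate `divergence` outside conserved cores
#' (insertions/deletions are not modelled so that planted coordinates lift
#' exactly). Planted peaks of A are assigned conservation classes:
#' `shared` keeps an identical core of `core_len` bp and gets an accessible
#' partner ACR in B; `variable` keeps the core but no partner ACR;
#' `species_specific` has its whole span randomized in B. Some blocks can be
#' inverted (reverse complemented) to exercise coordinate lifting.
#'
#' @param sim output of [simulate_reference()] for species A.
#' @param divergence per-base substitution rate in [0, 1).
#' @param class_probs probabilities for (shared, variable, species_specific).
#' @param retain_prob probability that a shared specific ACR keeps its cell
#'   type in species B (otherwise it switches to a random other type).
#' @param core_len conserved core length (>= 20 bp).
#' @param blocks_per_chrom syntenic blocks per chromosome.
#' @param n_inverted number of blocks emitted in inverted orientation.
#' @param seed integer seed.
#' @return list with `genome_b`, `chrom_sizes_b`, `blocks`,
#'   `acrs_b` (accessible partner ACRs with cell types), and
#'   `conservation_truth` (acr_id, class, partner_cell_type, retained).
#' @export
simulate_species_pair <- function(sim, divergence = 0.1,
                                  class_probs = c(shared = 1 / 3,
                                                  variable = 1 / 3,
                                                  species_specific = 1 / 3),
                                  retain_prob = 0.8, core_len = 40L,
                                  blocks_per_chrom = 2L, n_inverted = 1L,
                                  seed = 1L) {
  stopifnot(divergence >= 0, divergence < 1, core_len >= 20)
  set.seed(seed)
  ref <- sim$ref
  peaks <- sim$truth$planted_peaks
  cell_types <- sim$truth$cell_types
  classes <- sample(names(class_probs), nrow(peaks), replace = TRUE,
                    prob = class_probs)

  # mutate a copy of each chromosome
  bases <- c("A", "C", "G", "T")
  seq_b <- lapply(names(ref$chrom_sizes), function(ch) {
    s <- strsplit(as.character(ref$seq[[ch]]), "")[[1]]
    n <- length(s)
    mut <- which(runif(n) < divergence)
    if (length(mut)) {
      repl <- bases[(match(s[mut], bases) - 1L + sample(1:3, length(mut),
                                                       replace = TRUE)) %% 4L + 1L]
      s[mut] <- repl
    }
    s
  })
  names(seq_b) <- names(ref$chrom_sizes)

  # restore cores / ablate species-specific spans
  truth_rows <- list()
  acrs_b <- list()
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    s <- peaks$start[i]
    e <- peaks$end[i]
    cls <- classes[i]
    a_chars <- strsplit(as.character(
      Biostrings::subseq(ref$seq[[ch]], s + 1L, e)), "")[[1]]
    if (cls %in% c("shared", "variable")) {
      c0 <- s + (e - s - core_len) %/% 2L
      seq_b[[ch]][(c0 + 1L):(c0 + core_len)] <-
        a_chars[(c0 - s + 1L):(c0 - s + core_len)]
    } else {
      seq_b[[ch]][(s + 1L):e] <- sample(bases, e - s, replace = TRUE)
    }
    partner_ct <- NA_character_
    retained <- NA
    if (cls == "shared") {
      if (startsWith(peaks$class[i], "specific:")) {
        own <- sub("specific:", "", peaks$class[i])
        retained <- runif(1) < retain_prob
        partner_ct <- if (retained) own else
          sample(setdiff(cell_types, own), 1L)
      } else {
        partner_ct <- "broad"
        retained <- TRUE
      }
      acrs_b[[length(acrs_b) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e,
        acr_id = paste0("B_", peaks$peak_id[i]),
        cell_type = partner_ct, stringsAsFactors = FALSE)
    }
    truth_rows[[i]] <- data.frame(
      acr_id = peaks$peak_id[i], class = cls,
      partner_cell_type = partner_ct, retained = retained,
      stringsAsFactors = FALSE)
  }

  # blocks: equal partitions of each chromosome, same coordinates in B
  blocks <- do.call(rbind, lapply(names(ref$chrom_sizes), function(ch) {
    len <- ref$chrom_sizes[[ch]]
    bs <- floor(seq(0, len, length.out = blocks_per_chrom + 1L))
    data.frame(chromA = ch, startA = bs[-length(bs)], endA = bs[-1],
               chromB = sub("chr", "chrB", ch),
               startB = bs[-length(bs)], endB = bs[-1],
               stringsAsFactors = FALSE)
  }))
  blocks$block_id <- sprintf("block%03d", seq_len(nrow(blocks)))
  blocks$orientation <- "same"
  if (n_inverted > 0) {
    inv <- sample(nrow(blocks), min(n_inverted, nrow(blocks)))
    blocks$orientation[inv] <- "inverted"
  }

  # assemble B chromosomes; inverted blocks are reverse complemented in place
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  genome_b <- list()
  for (ch in names(seq_b)) {
    v <- seq_b[[ch]]
    bl <- blocks[blocks$chromA == ch & blocks$orientation == "inverted", ,
                 drop = FALSE]
    for (k in seq_len(nrow(bl))) {
      idx <- (bl$startA[k] + 1L):bl$endA[k]
      v[idx] <- rev(unname(comp[v[idx]]))
    }
    genome_b[[sub("chr", "chrB", ch)]] <- paste0(v, collapse = "")
  }
  genome_b <- Biostrings::DNAStringSet(unlist(genome_b))
  acrs_b <- if (length(acrs_b)) do.call(rbind, acrs_b) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               acr_id = character(0), cell_type = character(0))
  # partner ACR coordinates live on the B chromosome names, lifted through
  # the block orientation
  if (nrow(acrs_b)) {
    lifted <- lift_through_blocks(acrs_b, blocks)
    acrs_b$chrom <- lifted$chrom
    acrs_b$start <- lifted$start
    acrs_b$end <- lifted$end
  }
  list(genome_b = genome_b,
       chrom_sizes_b = setNames(Biostrings::width(genome_b), names(genome_b)),
       blocks = blocks, acrs_b = acrs_b,
       conservation_truth = do.call(rbind, truth_rows))
}

#' Lift species-A intervals to species-B coordinates through syntenic blocks
#' @param iv interval data frame in species-A coordinates.
#' @param blocks block table (see [read_blocks()]).
#' @return data.frame of lifted intervals (chrom, start, end); NA rows when
#'   the interval is not contained in a block.
#' @export
lift_through_blocks <- function(iv, blocks) {
  out <- data.frame(chrom = rep(NA_character_, nrow(iv)),
                    start = NA_integer_, end = NA_integer_)
  for (i in seq_len(nrow(iv))) {
    b <- blocks[blocks$chromA == iv$chrom[i] &
                  blocks$startA <= iv$start[i] &
                  blocks$endA >= iv$end[i], , drop = FALSE]
    if (nrow(b) == 0) next
    b <- b[1, ]
    off <- iv$start[i] - b$startA
    w <- iv$end[i] - iv$start[i]
    if (b$orientation == "same") {
      out$chrom[i] <- b$chromB
      out$start[i] <- b$startB + off
      out$end[i] <- b$startB + off + w
    } else {
      out$chrom[i] <- b$chromB
      out$end[i] <- b$endB - off
      out$start[i] <- b$endB - off - w
    }
  }
  out
}

#' Simulate paired pseudotime motif-deviation trajectories for two species
#'
#' Each motif follows a sigmoid deviation profile along pseudotime.
#' `conserved` motifs share the profile in both species; `shiftEarlyA`
#' motifs reach their half-maximum `delta` pseudotime units earlier in
#' species A (and vice versa for `shiftEarlyB`). Gaussian noise is added.
#'
#' @param n_motifs number of motifs.
#' @param n_cells cells per species.
#' @param shift_probs probabilities for (conserved, shiftEarlyA,
#'   shiftEarlyB).
#' @param delta pseudotime lag for shifted motifs, in (0, 1).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return list with `A` and `B` (each: species, pseudotime, dev matrix
#'   motif x cell) and `shift_truth` (motif, label, delta).
#' @export
simulate_trajectories <- function(n_motifs = 30L, n_cells = 300L,
                                  shift_probs = c(conserved = 0.5,
                                                  shiftEarlyA = 0.25,
                                                  shiftEarlyB = 0.25),
                                  delta = 0.3, noise_sd = 0.1, seed = 1L) {
  stopifnot(delta > 0, delta < 1)
  set.seed(seed)
  labels <- sample(names(shift_probs), n_motifs, replace = TRUE,
                   prob = shift_probs)
  t0 <- runif(n_motifs, 0.4, 0.6)
  slope <- runif(n_motifs, 8, 12)
  amp <- sample(c(-1, 1), n_motifs, replace = TRUE)
  motifs <- sprintf("motif%03d", seq_len(n_motifs))
  make_species <- function(lead_label) {
    pt <- sort(runif(n_cells))
    dev <- matrix(0, n_motifs, n_cells, dimnames = list(motifs, NULL))
    for (m in seq_len(n_motifs)) {
      shift <- if (labels[m] == lead_label) delta else 0
      dev[m, ] <- amp[m] / (1 + exp(-slope[m] * (pt + shift - t0[m])))
      if (noise_sd > 0) dev[m, ] <- dev[m, ] + rnorm(n_cells, 0, noise_sd)
    }
    list(pseudotime = pt, dev = dev)
  }
  A <- c(species = "A", make_species("shiftEarlyA"))
  B <- c(species = "B", make_species("shiftEarlyB"))
  list(A = A, B = B,
       shift_truth = data.frame(motif = motifs, label = labels,
                                delta = ifelse(labels == "conserved", 0, delta),
                                stringsAsFactors = FALSE))
}
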