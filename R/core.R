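# Core single-base operations: Tn5 strand shift, genomic-context classes,
# nucleus quality control, and Hi-C loop linking.

#' Shift aligned read ends to Tn5 integration sites
#'
#' ATAC-seq reads start 4 bp (plus strand) or 5 bp (minus strand) away from
#' the actual transposase integration site. Plus-strand reads are shifted
#' +4 from their 5' end (`read_start`); minus-strand reads are shifted -5
#' from their 5' end, which under the half-open convention is `read_end - 1`.
#'
#' @param read_start,read_end 0-based half-open read coordinates (vectors).
#' @param strand character vector of "+"/"-".
#' @param chrom_len chromosome length(s); positions falling outside
#'   `[0, chrom_len)` are rejected.
#' @return list with `pos` (integer, NA for rejected records) and
#'   `n_rejected`.
#' @export
shift_tn5 <- function(read_start, read_end, strand, chrom_len = Inf) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  pos <- ifelse(strand == "+", read_start + 4L, read_end - 1L - 5L)
  bad <- pos < 0 | pos >= chrom_len
  n_rej <- sum(bad)
  if (n_rej > 0) {
    warning(n_rej, " shifted position(s) outside chromosome; rejected")
    pos[bad] <- NA_integer_
  }
  list(pos = as.integer(pos), n_rejected = n_rej)
}

#' Classify ACRs by genomic context relative to gene models
#'
#' An ACR is `genic` when it overlaps a gene body by at least 1 bp,
#' `proximal` when the edge-to-edge distance to the nearest gene is at most
#' `proximal_bp` (boundary-inclusive), and `distal` otherwise. ACRs on
#' chromosomes absent from the annotation are `distal` and flagged.
#'
#' @param acrs interval data frame of ACRs.
#' @param genes gene models (chrom, start, end, strand, gene_id).
#' @param proximal_bp distance cutoff in bp (default 2000).
#' @return data.frame with `context`, `nearest_gene`, `distance` (signed:
#'   negative when the ACR lies 5'-ward of the gene on the chromosome, i.e.
#'   entirely left of the gene start), and `no_annotation` flag.
#' @export
classify_context <- function(acrs, genes, proximal_bp = 2000L) {
  n <- nrow(acrs)
  out <- data.frame(context = rep("distal", n),
                    nearest_gene = NA_character_,
                    distance = NA_integer_,
                    no_annotation = FALSE,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  on_chrom <- acrs$chrom %in% unique(genes$chrom)
  out$no_annotation <- !on_chrom
  nr <- iv_nearest(acrs, genes)
  has <- !is.na(nr$distance)
  out$nearest_gene[has] <- genes$gene_id[nr$nearest[has]]
  sign_left <- rep(1L, n)
  idx <- which(has)
  left <- acrs$end[idx] <= genes$start[nr$nearest[idx]]
  sign_left[idx[left]] <- -1L
  out$distance[has] <- nr$distance[has] * sign_left[has]
  genic <- iv_overlaps_any(acrs, genes)
  out$context[genic] <- "genic"
  out$distance[genic & has] <- 0L
  prox <- !genic & has & nr$distance <= proximal_bp
  out$context[prox] <- "proximal"
  out
}

#' Filter nuclei on quality-control metrics
#'
#' Keeps barcodes with at least `min_depth` Tn5 integration sites, a TSS
#' fraction strictly above `tss_min`, a FRiP strictly above `frip_min`, and
#' an organelle read fraction no more than two standard deviations above the
#' library mean. At most `max_cells` barcodes are retained, ranked by depth.
#'
#' @param cells data.frame with `barcode`, `depth`, `tss_frac`, `frip`,
#'   `organelle_frac` (missing organelle column is treated as all-zero).
#' @param min_depth minimum Tn5 integration sites (default 1000, inclusive).
#' @param max_cells library cap (default 16000).
#' @param tss_min strict lower bound on TSS fraction (default 0.2).
#' @param frip_min strict lower bound on FRiP (default 0.1).
#' @param organelle_sds one-sided organelle cutoff in library SDs (default 2).
#' @return the input with a logical `pass_qc` column, subset to passing rows.
#' @export
qc_filter_nuclei <- function(cells, min_depth = 1000L, max_cells = 16000L,
                             tss_min = 0.2, frip_min = 0.1, organelle_sds = 2) {
  if (nrow(cells) == 0) {
    cells$pass_qc <- logical(0)
    return(cells)
  }
  org <- if ("organelle_frac" %in% names(cells)) cells$organelle_frac else
    rep(0, nrow(cells))
  org_cut <- mean(org) + organelle_sds * sd(org)
  if (is.na(org_cut)) org_cut <- Inf
  pass <- cells$depth >= min_depth &
    cells$tss_frac > tss_min &
    cells$frip > frip_min &
    org <= org_cut
  kept <- cells[pass, , drop = FALSE]
  if (nrow(kept) > max_cells) {
    kept <- kept[order(-kept$depth), , drop = FALSE][seq_len(max_cells), ,
                                                     drop = FALSE]
  }
  kept$pass_qc <- TRUE
  rownames(kept) <- NULL
  kept
}

#' Promoter intervals (2 kb upstream of the TSS)
#' @param genes gene models with strand.
#' @param upstream bp upstream of the TSS (default 2000).
#' @return interval data frame with gene_id.
#' @export
gene_promoters <- function(genes, upstream = 2000L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - upstream), genes$end)
  end <- ifelse(plus, genes$start, genes$end + upstream)
  data.frame(chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Link distal cell-type-specific ACRs to genes through chromatin loops
#'
#' A loop links an ACR to a gene when one loop anchor bin overlaps the ACR
#' and the partner bin overlaps the gene's promoter (2 kb upstream of the
#' TSS). Both anchor orders are considered and duplicate (ACR, gene) pairs
#' are collapsed.
#'
#' @param loops data.frame from [read_bedpe()] (chrom1,start1,end1,
#'   chrom2,start2,end2); bins must all have width `resolution`.
#' @param acrs distal cell-type-specific ACRs; a `cell_type` column is used
#'   for the match flag if present.
#' @param genes gene models.
#' @param specific_genes optional data.frame (gene_id, cell_type) of
#'   cell-type-specific genes; when given, links are restricted to them and
#'   `celltype_match` compares ACR and gene cell types.
#' @param resolution loop bin width in bp (default 5000).
#' @return data.frame of links: acr (row index), gene_id, celltype_match.
#' @export
link_loops <- function(loops, acrs, genes, specific_genes = NULL,
                       resolution = 5000L) {
  widths <- c(loops$end1 - loops$start1, loops$end2 - loops$start2)
  if (length(widths) && any(widths != resolution)) {
    stop("loop bin width differs from configured resolution ", resolution)
  }
  proms <- gene_promoters(genes)
  if (!is.null(specific_genes)) {
    proms <- proms[proms$gene_id %in% specific_genes$gene_id, , drop = FALSE]
  }
  binsA <- data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
  binsB <- data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  hit_one_side <- function(bins_acr, bins_prom) {
    pa <- iv_overlap_pairs(bins_acr, acrs)      # loop idx -> acr idx
    pp <- iv_overlap_pairs(bins_prom, proms)    # loop idx -> promoter idx
    m <- merge(pa, pp, by = "query")
    data.frame(acr = m$subject.x, gene_id = proms$gene_id[m$subject.y])
  }
  links <- rbind(hit_one_side(binsA, binsB), hit_one_side(binsB, binsA))
  links <- unique(links)
  if (nrow(links)) {
    gmatch <- rep(NA, nrow(links))
    if (!is.null(specific_genes) && "cell_type" %in% names(acrs)) {
      gct <- specific_genes$cell_type[match(links$gene_id, specific_genes$gene_id)]
      gmatch <- !is.na(gct) & acrs$cell_type[links$acr] == gct
    }
    links$celltype_match <- gmatch
  } else {
    links$celltype_match <- logical(0)
  }
  rownames(links) <- NULL
  links
}
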