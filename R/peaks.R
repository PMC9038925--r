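#' Construct a peak set
#'
#' A peak set is the universe of genomic intervals that every count matrix in
#' the pipeline indexes into. Coordinates are BED-style: 0-based, half-open.
#' Peaks are stored sorted by (chrom, start) and carry stable identifiers.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start < end` (0-based, half-open).
#' @param peak_id optional character vector of unique identifiers; generated
#'   as `peak_00001, ...` in sorted order when missing.
#' @return A `data.frame` of class `peak_set` with columns
#'   `chrom, start, end, peak_id`.
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  bad <- which(!(start < end))
  if (length(bad)) {
    id <- if (!is.null(peak_id)) peak_id[bad[1]] else paste0("row ", bad[1])
    stop("malformed interval (start >= end) at ", id)
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  if (is.null(peak_id)) {
    df$peak_id <- sprintf("peak_%05d", seq_len(nrow(df)))
  } else {
    df$peak_id <- as.character(peak_id)[ord]
    if (anyDuplicated(df$peak_id)) stop("peak ids must be unique")
  }
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    peak_id = peaks$peak_id)
}

#' Merge per-sample peak calls into a master peak set
#'
#' Implements bedtools-merge semantics: intervals that overlap by at least
#' one base pair, or that are bookended (touching), are merged into one.
#' The presence matrix records which samples contributed at least one
#' interval overlapping each merged peak.
#'
#' @param per_sample_peaks named list of `peak_set` objects (or data.frames
#'   with `chrom,start,end`), one per sample.
#' @return list with `peaks` (merged `peak_set`) and `presence`
#'   (binary matrix, merged peaks x samples).
#' @export
merge_peak_calls <- function(per_sample_peaks) {
  stopifnot(is.list(per_sample_peaks), length(per_sample_peaks) >= 1)
  samples <- names(per_sample_peaks)
  if (is.null(samples)) samples <- paste0("sample_", seq_along(per_sample_peaks))
  sets <- lapply(per_sample_peaks, function(p) {
    if (!inherits(p, "peak_set"))
      p <- peak_set(p$chrom, p$start, p$end, p$peak_id)
    p
  })
  gr_list <- lapply(sets, peaks_to_granges)
  all_gr <- do.call(c, unname(gr_list))
  # min.gapwidth = 1 merges overlapping and bookended intervals (bedtools -d 0)
  merged <- GenomicRanges::reduce(all_gr, min.gapwidth = 1L)
  merged <- GenomicRanges::sort(merged)
  out <- peak_set(as.character(GenomicRanges::seqnames(merged)),
                  GenomicRanges::start(merged) - 1L,
                  GenomicRanges::end(merged))
  merged_gr <- peaks_to_granges(out)
  presence <- matrix(0L, nrow = nrow(out), ncol = length(sets),
                     dimnames = list(out$peak_id, samples))
  for (j in seq_along(sets)) {
    hits <- GenomicRanges::findOverlaps(merged_gr, gr_list[[j]])
    presence[unique(S4Vectors::queryHits(hits)), j] <- 1L
  }
  list(peaks = out, presence = presence)
}

#' Gene annotation table
#'
#' @param gene_id,chrom,strand,tss vectors describing one gene per row;
#'   `tss` is the transcription start site (0-based coordinate),
#'   `strand` is `+` or `-`.
#' @param tts optional transcription termination sites.
#' @return `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, tts = NULL) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand), tss = as.numeric(tss),
                   stringsAsFactors = FALSE)
  df$tts <- if (is.null(tts)) NA_real_ else as.numeric(tts)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Signed peak-midpoint to TSS distance
#'
#' Distance is measured from the peak midpoint, `floor((start+end)/2)`, to
#' the TSS, signed in the gene's transcriptional orientation: positive
#' downstream of the TSS, negative upstream.
#' @keywords internal
signed_tss_distance <- function(mid, tss, strand) {
  ifelse(strand == "+", mid - tss, tss - mid)
}

#' Annotate peaks with their nearest gene and regulatory class
#'
#' Each peak is assigned its nearest gene by absolute midpoint-to-TSS
#' distance (ties broken by lexicographically smaller gene id), and a
#' region class: promoter when the signed distance lies in
#' `promoter_window` (default -1000..+100 bp, strand-oriented), distal
#' regulatory element (DRE) when the absolute distance lies in
#' `(dre_window[1], dre_window[2]]` (default 3 kb..500 kb), otherwise
#' "other". Peaks further than `dre_window[2]` from any TSS, or on
#' chromosomes without genes, are "other".
#'
#' @param peaks a `peak_set`.
#' @param genes a `gene_annotation`.
#' @param promoter_window numeric length 2, signed bp around the TSS.
#' @param dre_window numeric length 2, absolute bp bounds (exclusive lower,
#'   inclusive upper).
#' @return data.frame: `peak_id, nearest_gene_id, tss_distance, region_class`.
#' @export
annotate_peaks <- function(peaks, genes,
                           promoter_window = c(-1000, 100),
                           dre_window = c(3000, 500000)) {
  n <- nrow(peaks)
  out <- data.frame(peak_id = peaks$peak_id,
                    nearest_gene_id = NA_character_,
                    tss_distance = NA_real_,
                    region_class = "other",
                    stringsAsFactors = FALSE)
  if (nrow(genes) == 0) {
    warning("empty gene set: all peaks classed 'other'")
    return(out)
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    gn <- which(genes$chrom == ch)
    if (!length(gn)) next
    # all-pairs |distance| per chromosome; tie-break on smaller gene_id by
    # ordering gene columns by id so the first minimum wins
    gord <- gn[order(genes$gene_id[gn])]
    d_abs <- abs(outer(mid[pk], genes$tss[gord], "-"))
    best <- max.col(-d_abs, ties.method = "first")
    gene_idx <- gord[best]
    d_signed <- signed_tss_distance(mid[pk], genes$tss[gene_idx],
                                    genes$strand[gene_idx])
    out$nearest_gene_id[pk] <- genes$gene_id[gene_idx]
    out$tss_distance[pk] <- d_signed
    cls <- rep("other", length(pk))
    cls[d_signed >= promoter_window[1] & d_signed <= promoter_window[2]] <- "promoter"
    is_dre <- abs(d_signed) > dre_window[1] & abs(d_signed) <= dre_window[2] &
      cls != "promoter"
    cls[is_dre] <- "DRE"
    out$region_class[pk] <- cls
  }
  beyond <- !is.na(out$tss_distance) & abs(out$tss_distance) > dre_window[2]
  out$region_class[beyond] <- "other"
  out
}

#' Classify peaks into seven genomic features
#'
#' Assigns each peak one of TSS, TTS, 5'UTR, 3'UTR, exon, intron or
#' intergenic by overlap, resolved in that priority order. The TSS window
#' equals the promoter window; the TTS window defaults to +/-100 bp around
#' the termination site.
#'
#' @param peaks a `peak_set`.
#' @param genes a `gene_annotation` (needs `tts` for TTS calls).
#' @param exons optional data.frame `gene_id, start, end` (0-based half-open).
#' @param utr5,utr3 optional data.frames `gene_id, start, end`.
#' @param tss_window,tts_window signed bp windows.
#' @return character vector of feature classes, one per peak.
#' @export
classify_genomic_features <- function(peaks, genes, exons = NULL,
                                      utr5 = NULL, utr3 = NULL,
                                      tss_window = c(-1000, 100),
                                      tts_window = c(-100, 100)) {
  pk <- peaks_to_granges(peaks)
  cls <- rep("intergenic", nrow(peaks))

  window_gr <- function(center, strand, win, chrom) {
    # win is a signed 0-based inclusive window around center; convert to
    # 1-based closed GRanges coordinates
    lo <- ifelse(strand == "+", center + win[1], center - win[2])
    hi <- ifelse(strand == "+", center + win[2], center - win[1])
    keep <- !is.na(center)
    GenomicRanges::GRanges(chrom[keep],
      IRanges::IRanges(pmax(lo[keep], 0) + 1, pmax(hi[keep] + 1, 1)))
  }
  interval_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    GenomicRanges::GRanges(df$chrom,
      IRanges::IRanges(df$start + 1L, df$end))
  }
  mark <- function(cls, gr, label) {
    if (is.null(gr) || length(gr) == 0) return(cls)
    # disjoint chromosome sets are legitimate (e.g. gene-free contigs)
    hit <- unique(S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(pk, gr))))
    hit <- hit[cls[hit] == "intergenic"]
    cls[hit] <- label
    cls
  }

  add_chrom <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    if (!"chrom" %in% names(df))
      df$chrom <- genes$chrom[match(df$gene_id, genes$gene_id)]
    df
  }
  exons <- add_chrom(exons); utr5 <- add_chrom(utr5); utr3 <- add_chrom(utr3)

  cls <- mark(cls, window_gr(genes$tss, genes$strand, tss_window, genes$chrom), "TSS")
  if (any(!is.na(genes$tts)))
    cls <- mark(cls, window_gr(genes$tts, genes$strand, tts_window, genes$chrom), "TTS")
  cls <- mark(cls, interval_gr(utr5), "5'UTR")
  cls <- mark(cls, interval_gr(utr3), "3'UTR")
  cls <- mark(cls, interval_gr(exons), "exon")
  # intron = inside the gene body but nothing above
  if (any(!is.na(genes$tts))) {
    body_lo <- pmin(genes$tss, genes$tts, na.rm = TRUE)
    body_hi <- pmax(genes$tss, genes$tts, na.rm = TRUE)
    ok <- !is.na(genes$tts)
    body <- GenomicRanges::GRanges(genes$chrom[ok],
      IRanges::IRanges(body_lo[ok] + 1, pmax(body_hi[ok], body_lo[ok] + 1)))
    cls <- mark(cls, body, "intron")
  }
  cls
}
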