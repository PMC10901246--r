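#' Reverse complement of DNA strings
#'
#' @param x Character vector over A/C/G/T/N (case preserved by Biostrings).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract strand-oriented promoter sequences around TSSs
#'
#' For a plus-strand gene with (0-based) TSS `t` the genomic slice
#' `[t - upstream, t + downstream)` is returned; for a minus-strand gene the
#' reverse complement of `[t - downstream, t + upstream)`, so that every
#' returned sequence reads 5'->3' in the gene's direction with the TSS at
#' offset `upstream`. Windows running off a contig edge are truncated (never
#' padded) and flagged; TSSs outside their contig are skipped with a warning.
#'
#' @param genome Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param tss Path to a BED6 file, or a data frame with columns `contig`,
#'   `start`, `end`, `gene`, `strand` (BED convention: 0-based half-open;
#'   the TSS is `start` on `+`, `end - 1` on `-`).
#' @param upstream,downstream Window extent in bp (defaults 2000 and 1000,
#'   i.e. the 2 kb promoter upstream plus 1 kb downstream of the TSS).
#' @return A tibble with columns `gene`, `sequence`, `contig`, `tss`,
#'   `strand`, `promoter_start`, `promoter_end` (contig coordinates of the
#'   extracted slice, 0-based half-open) and `truncated`; contig lengths are
#'   attached as attribute `contig_lengths`.
#' @export
extract_promoters <- function(genome, tss, upstream = 2000L, downstream = 1000L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  ctg_len <- setNames(Biostrings::width(genome), sub("\\s.*$", "", names(genome)))
  names(genome) <- sub("\\s.*$", "", names(genome))

  tss_tbl <- .as_tss_tbl(tss)
  res <- vector("list", nrow(tss_tbl))
  skipped <- 0L
  for (i in seq_len(nrow(tss_tbl))) {
    g <- tss_tbl$gene[i]
    contig <- tss_tbl$contig[i]
    strand <- tss_tbl$strand[i]
    if (!contig %in% names(ctg_len)) {
      skipped <- skipped + 1L
      next
    }
    len <- ctg_len[[contig]]
    t0 <- if (strand == "-") tss_tbl$end[i] - 1L else tss_tbl$start[i]
    if (t0 < 0L || t0 >= len) {
      skipped <- skipped + 1L
      next
    }
    win <- if (strand == "-") c(t0 - downstream, t0 + upstream) else c(t0 - upstream, t0 + downstream)
    lo <- max(win[1], 0L)
    hi <- min(win[2], len)
    truncated <- lo != win[1] || hi != win[2]
    s <- as.character(Biostrings::subseq(genome[[contig]], start = lo + 1L, end = hi))
    if (strand == "-") s <- revcomp(s)
    res[[i]] <- tibble(
      gene = g, sequence = s, contig = contig, tss = t0, strand = strand,
      promoter_start = lo, promoter_end = hi, truncated = truncated
    )
  }
  if (skipped > 0L) {
    warn(sprintf("extract_promoters: skipped %d TSS record(s) outside their contig", skipped))
  }
  out <- bind_rows(res)
  attr(out, "contig_lengths") <- ctg_len
  out
}

.as_tss_tbl <- function(tss) {
  if (is.character(tss) && length(tss) == 1L) {
    gr <- rtracklayer::import(tss, format = "BED")
    tibble(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      gene = if (!is.null(gr$name)) gr$name else paste0("region_", seq_along(gr)),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+")
    )
  } else {
    tss <- as_tibble(tss)
    need <- c("contig", "start", "end", "gene", "strand")
    if (!all(need %in% names(tss))) {
      abort(paste("tss table needs columns:", paste(need, collapse = ", ")))
    }
    tss
  }
}
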