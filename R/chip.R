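#' Per-peak ChIP enrichment over input
#'
#' Counts IP and input fragments overlapping each peak ([count_regions()]
#' rule) and computes the fold enrichment on library-normalized counts with
#' a pseudocount of 1 added to each normalized count:
#' `fc = (ip_cpm + 1) / (input_cpm + 1)` where `cpm = count / lib * 1e6`.
#'
#' @param ip,input Fragment tibbles (`contig`, `start`, `end`).
#' @param peaks Peak tibble (`contig`, `start`, `end`), e.g. called
#'   externally or the simulator's truth peaks.
#' @param lib_ip,lib_input Library sizes; default the fragment counts.
#' @return `peaks` with `ip_count`, `input_count`, `fc` columns; library
#'   sizes as attributes.
#' @export
peak_enrichment <- function(ip, input, peaks, lib_ip = nrow(ip), lib_input = nrow(input)) {
  if (lib_ip <= 0 || lib_input <= 0) {
    abort("peak_enrichment: empty IP or input library")
  }
  out <- count_regions(ip, peaks) |> rename(ip_count = "count")
  out$input_count <- count_regions(input, peaks)$count
  out$fc <- (out$ip_count / lib_ip * 1e6 + 1) / (out$input_count / lib_input * 1e6 + 1)
  attr(out, "lib_ip") <- lib_ip
  attr(out, "lib_input") <- lib_input
  out
}

#' Assign peaks to genes within a TSS window and summarize per-gene maxFC
#'
#' A peak is assigned to a gene when any part of it lies within
#' `[TSS - window, TSS + window)` (`mode = "overlap"`, the inclusive
#' reading) or when its summit (midpoint) does (`mode = "summit"`). Per gene
#' the maximum fold enrichment over assigned peaks (maxFC) is reported;
#' genes with no in-window peak are absent from the table.
#'
#' @param peaks A [peak_enrichment()] result (needs `contig`, `start`,
#'   `end`, `fc`).
#' @param tss TSS tibble or BED path (see [extract_promoters()]).
#' @param window Half-window around the TSS in bp (default 5000).
#' @param mode Peak-to-window membership rule.
#' @return Tibble with `gene`, `max_fc`, `peak_start`, `peak_end` (the
#'   contributing peak), `n_peaks`.
#' @export
genes_with_peaks <- function(peaks, tss, window = 5000L, mode = c("overlap", "summit")) {
  mode <- match.arg(mode)
  stopifnot(all(c("contig", "start", "end", "fc") %in% names(peaks)))
  tss <- .as_tss_tbl(tss)
  tss$pos <- ifelse(tss$strand == "-", tss$end - 1L, tss$start)
  win <- GenomicRanges::GRanges(
    tss$contig, IRanges::IRanges(tss$pos - window + 1L, tss$pos + window)
  )
  pk <- if (mode == "summit") {
    mids <- floor((peaks$start + peaks$end) / 2)
    GenomicRanges::GRanges(peaks$contig, IRanges::IRanges(mids + 1L, mids + 1L))
  } else {
    GenomicRanges::GRanges(peaks$contig, IRanges::IRanges(peaks$start + 1L, peaks$end))
  }
  hits <- GenomicRanges::findOverlaps(pk, win, minoverlap = 1L)
  if (length(hits) == 0L) {
    return(tibble(
      gene = character(), max_fc = numeric(),
      peak_start = integer(), peak_end = integer(), n_peaks = integer()
    ))
  }
  assigned <- tibble(
    gene = tss$gene[S4Vectors::subjectHits(hits)],
    fc = peaks$fc[S4Vectors::queryHits(hits)],
    peak_start = peaks$start[S4Vectors::queryHits(hits)],
    peak_end = peaks$end[S4Vectors::queryHits(hits)]
  )
  assigned |>
    group_by(.data$gene) |>
    summarise(
      max_fc = max(.data$fc),
      peak_start = .data$peak_start[which.max(.data$fc)],
      peak_end = .data$peak_end[which.max(.data$fc)],
      n_peaks = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$gene)
}

#' Overlap report between two TF target-gene tables
#'
#' @param table_a,table_b [genes_with_peaks()] results (or any tibbles with
#'   a `gene` column), e.g. the target sets of two ChIPped TFs.
#' @param name_a,name_b Labels for the report.
#' @return One-row tibble: `n_a`, `n_b`, `n_shared`, `pct_of_a`, `pct_of_b`
#'   (percentages rounded to one decimal).
#' @export
target_overlap <- function(table_a, table_b, name_a = "A", name_b = "B") {
  a <- unique(if (is.data.frame(table_a)) table_a$gene else table_a)
  b <- unique(if (is.data.frame(table_b)) table_b$gene else table_b)
  shared <- length(intersect(a, b))
  tibble(
    set_a = name_a, set_b = name_b,
    n_a = length(a), n_b = length(b), n_shared = shared,
    pct_of_a = if (length(a) > 0) round(100 * shared / length(a), 1) else 0,
    pct_of_b = if (length(b) > 0) round(100 * shared / length(b), 1) else 0
  )
}
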