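#' Tn5 cut-site profile from an ATAC fragment set
#'
#' Each fragment `[start, end)` (0-based half-open) contributes two
#' insertion events at the standard Tn5 offsets: `start + 4` and `end - 5`.
#' Cut positions falling outside their contig are dropped and counted.
#'
#' @param fragments Tibble with columns `contig`, `start`, `end` (additional
#'   columns such as `condition`/`replicate` are ignored, so replicates can
#'   be pooled by row-binding before the call).
#' @param contig_lengths Named integer vector of contig lengths. If `NULL`,
#'   inferred from `max(end)` per contig with a warning.
#' @return An object of class `cut_profile`: list with `counts` (named list
#'   of per-base integer vectors, position `p` stored at index `p + 1`),
#'   `total` insertions, `n_fragments`, `n_dropped` and `norm_factor`
#'   (insertions-per-million scaling, `1e6 / total`).
#' @export
cut_sites <- function(fragments, contig_lengths = NULL) {
  stopifnot(all(c("contig", "start", "end") %in% names(fragments)))
  if (nrow(fragments) > 0 && any(fragments$start >= fragments$end)) {
    abort("cut_sites: fragments must satisfy start < end")
  }
  if (is.null(contig_lengths)) {
    warn("cut_sites: contig lengths not supplied; inferring from max(end)")
    contig_lengths <- vapply(
      split(fragments$end, fragments$contig), max, numeric(1)
    )
  }
  counts <- list()
  dropped <- 0L
  for (ctg in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ctg]])
    sel <- fragments$contig == ctg
    cuts <- c(fragments$start[sel] + 4L, fragments$end[sel] - 5L)
    keep <- cuts >= 0L & cuts < len
    dropped <- dropped + sum(!keep)
    counts[[ctg]] <- tabulate(cuts[keep] + 1L, nbins = len)
  }
  dropped <- dropped + sum(!fragments$contig %in% names(contig_lengths)) * 2L
  total <- sum(vapply(counts, sum, numeric(1)))
  structure(
    list(
      counts = counts, total = total, n_fragments = nrow(fragments),
      n_dropped = dropped,
      norm_factor = if (total > 0) 1e6 / total else NA_real_
    ),
    class = "cut_profile"
  )
}

#' @export
print.cut_profile <- function(x, ...) {
  cat(sprintf(
    "<cut_profile> %d contig(s), %d fragments, %d insertions (%d dropped)\n",
    length(x$counts), x$n_fragments, x$total, x$n_dropped
  ))
  invisible(x)
}

# per-contig cumulative sums, cached computation for window means
.profile_cumsum <- function(profile) {
  lapply(profile$counts, function(v) c(0, cumsum(v)))
}

# sum of counts over [lo, hi) 0-based, clipped to the contig; returns the
# clipped width too
.window_sum <- function(cs, lo, hi, len) {
  lo2 <- pmin(pmax(lo, 0L), len)
  hi2 <- pmin(pmax(hi, 0L), len)
  w <- pmax(hi2 - lo2, 0L)
  s <- ifelse(w > 0, cs[hi2 + 1L] - cs[lo2 + 1L], 0)
  list(sum = s, width = w, clipped = (lo2 != lo) | (hi2 != hi))
}

#' Footprint score of motif sites in a cut-site profile
#'
#' The score contrasts depth-normalized insertion density in the flanks with
#' the motif center: `log2((mean flank + 1) / (mean center + 1))`, means in
#' insertions-per-million per bp over `flank` bp on each side of the site
#' (excluding the motif itself). A uniform profile scores 0; protein
#' occupancy (central depletion inside open chromatin) scores positive.
#' Windows truncated at a contig edge are computed on the available bases
#' and flagged.
#'
#' @param profile A [cut_sites()] profile (replicates of a condition are
#'   typically pooled).
#' @param sites Tibble with columns `contig`, `start`, `width` (site extent,
#'   0-based contig coordinates); extra columns are carried through.
#' @param flank Flank width in bp on each side (default 50).
#' @return `sites` with added columns `center_mean`, `flank_mean` (both
#'   normalized), `score` and `clipped`.
#' @export
footprint_score <- function(profile, sites, flank = 50L) {
  stopifnot(inherits(profile, "cut_profile"))
  stopifnot(all(c("contig", "start", "width") %in% names(sites)))
  nf <- profile$norm_factor
  out <- vector("list", length(profile$counts))
  cs_all <- .profile_cumsum(profile)
  res <- sites
  res$center_mean <- NA_real_
  res$flank_mean <- NA_real_
  res$clipped <- NA
  for (ctg in unique(sites$contig)) {
    sel <- which(sites$contig == ctg)
    if (!ctg %in% names(profile$counts)) {
      abort(sprintf("footprint_score: contig '%s' absent from the profile", ctg))
    }
    cs <- cs_all[[ctg]]
    len <- length(profile$counts[[ctg]])
    s <- sites$start[sel]
    w <- sites$width[sel]
    ctr <- .window_sum(cs, s, s + w, len)
    lf <- .window_sum(cs, s - flank, s, len)
    rf <- .window_sum(cs, s + w, s + w + flank, len)
    fl_width <- lf$width + rf$width
    res$center_mean[sel] <- ifelse(ctr$width > 0, ctr$sum / ctr$width * nf, 0)
    res$flank_mean[sel] <- ifelse(fl_width > 0, (lf$sum + rf$sum) / fl_width * nf, 0)
    res$clipped[sel] <- ctr$clipped | lf$clipped | rf$clipped
  }
  if (any(res$clipped)) {
    warn(sprintf(
      "footprint_score: %d site window(s) truncated at a contig edge",
      sum(res$clipped)
    ))
  }
  res$score <- log2((res$flank_mean + 1) / (res$center_mean + 1))
  res
}

#' Differential footprint between two conditions
#'
#' Scores the same site list in both profiles and reports per-site deltas
#' `score_a - score_b` plus a per-promoter (per gene x PWM) aggregate, by
#' default the maximum delta over that PWM's sites in the promoter (a single
#' occupied site is evidence enough; `aggregate = "mean"` is available).
#'
#' @param profile_a,profile_b [cut_sites()] profiles for the two conditions
#'   (e.g. Tspan8-positive vs Tspan8-negative).
#' @param sites Site tibble with `contig`, `start`, `width` and, for the
#'   promoter aggregate, `gene` and `pwm` columns (see [scan_sites()] mapped
#'   to contig coordinates, or [sim_sites()] on synthetic data).
#' @inheritParams footprint_score
#' @param aggregate `"max"` (default) or `"mean"` per promoter.
#' @return List with `sites` (per-site scores and `delta`) and `promoters`
#'   (per gene x PWM `delta`).
#' @export
differential_footprint <- function(profile_a, profile_b, sites, flank = 50L,
                                   aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(profile_a) || is.null(profile_b)) {
    abort("differential_footprint: both condition profiles are required")
  }
  sa <- footprint_score(profile_a, sites, flank = flank)
  sb <- footprint_score(profile_b, sites, flank = flank)
  sites_out <- sa
  sites_out$score_a <- sa$score
  sites_out$score_b <- sb$score
  sites_out$score <- NULL
  sites_out$delta <- sites_out$score_a - sites_out$score_b
  promoters <- NULL
  if (all(c("gene", "pwm") %in% names(sites_out))) {
    agg_fun <- if (aggregate == "max") max else mean
    promoters <- sites_out |>
      group_by(.data$gene, .data$pwm) |>
      summarise(delta = agg_fun(.data$delta), n_sites = dplyr::n(), .groups = "drop")
  }
  list(sites = sites_out, promoters = promoters)
}

#' Recovery AUC of target promoters ranked by differential footprint
#'
#' Promoters are ranked by decreasing footprint delta (ties by gene id) and
#' the recovery AUC of the target promoters (e.g. TRA gene promoters) is
#' computed with the [recovery_auc()] machinery.
#'
#' @param promoter_deltas Tibble with `gene` and `delta` columns (one PWM's
#'   promoters, see [differential_footprint()]).
#' @param targets Target gene set.
#' @inheritParams recovery_auc
#' @return A `recovery_curve` object (see [recovery_auc()]).
#' @export
differential_footprint_auc <- function(promoter_deltas, targets, depth = 1000L) {
  stopifnot(all(c("gene", "delta") %in% names(promoter_deltas)))
  ord <- order(-promoter_deltas$delta, promoter_deltas$gene, method = "radix")
  ranked <- promoter_deltas$gene[ord]
  depth <- min(depth, length(ranked))
  recovery_auc(ranked, targets, depth = depth)
}

#' Count fragments overlapping regions
#'
#' A fragment counts once in every region it overlaps by at least 1 bp
#' (0-based half-open coordinates; abutting intervals do not overlap).
#'
#' @param fragments Tibble with `contig`, `start`, `end`.
#' @param regions Tibble with `contig`, `start`, `end` and optionally
#'   `region` ids.
#' @return `regions` with an added `count` column.
#' @export
count_regions <- function(fragments, regions) {
  stopifnot(all(c("contig", "start", "end") %in% names(fragments)))
  stopifnot(all(c("contig", "start", "end") %in% names(regions)))
  fr <- GenomicRanges::GRanges(
    fragments$contig, IRanges::IRanges(fragments$start + 1L, fragments$end)
  )
  rg <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start + 1L, regions$end)
  )
  ov <- GenomicRanges::countOverlaps(rg, fr, minoverlap = 1L)
  out <- as_tibble(regions)
  out$count <- as.integer(ov)
  out
}

#' Count-based differential accessibility between two conditions
#'
#' A self-contained substitute for a full count-model engine: per region,
#' `log2FC = log2((cA/libA * 1e6 + 1) / (cB/libB * 1e6 + 1))` and a two-sided
#' exact binomial test of `cA` successes in `cA + cB` trials at
#' `p0 = libA / (libA + libB)`, BH-adjusted across regions. Regions with
#' `cA + cB = 0` get `p = 1`.
#'
#' @param counts_a,counts_b Integer vectors of per-region fragment counts
#'   (same region order), e.g. from [count_regions()].
#' @param lib_a,lib_b Library sizes (total fragments) of the two samples.
#' @param regions Optional region tibble bound onto the result.
#' @return Tibble with `count_a`, `count_b`, `log2fc`, `p`, `q`.
#' @export
diff_access <- function(counts_a, counts_b, lib_a, lib_b, regions = NULL) {
  if (length(counts_a) != length(counts_b)) {
    abort("diff_access: count vectors must have equal length")
  }
  if (lib_a <= 0 || lib_b <= 0) abort("diff_access: library sizes must be positive")
  na <- counts_a / lib_a * 1e6
  nb <- counts_b / lib_b * 1e6
  log2fc <- log2((na + 1) / (nb + 1))
  p0 <- lib_a / (lib_a + lib_b)
  n <- counts_a + counts_b
  p <- vapply(seq_along(n), function(i) {
    if (n[i] == 0L) return(1)
    binom.test(counts_a[i], n[i], p = p0)$p.value
  }, numeric(1))
  out <- tibble(
    count_a = as.integer(counts_a), count_b = as.integer(counts_b),
    log2fc = log2fc, p = p, q = p.adjust(p, method = "BH")
  )
  if (!is.null(regions)) out <- dplyr::bind_cols(as_tibble(regions), out)
  out
}

#' Annotate regions with their nearest TSS
#'
#' Distance is measured from the region midpoint (`floor((start + end) / 2)`)
#' to the nearest TSS, signed in the gene's reading direction (negative =
#' upstream of the TSS). Regions whose signed distance falls in
#' `[-promoter_upstream, promoter_downstream)` are classified `"promoter"`,
#' all others `"distal"`. Equidistant TSSs resolve to the lexicographically
#' smaller gene id.
#'
#' @param regions Tibble with `contig`, `start`, `end`.
#' @param tss Tibble with `contig`, `start`, `end`, `gene`, `strand` (BED
#'   convention, as in [extract_promoters()]).
#' @param promoter_upstream,promoter_downstream Promoter window bounds
#'   (defaults 2000 and 1000 bp).
#' @return `regions` with added `gene`, `distance`, `class` columns.
#' @export
nearest_gene <- function(regions, tss, promoter_upstream = 2000L,
                         promoter_downstream = 1000L) {
  tss <- .as_tss_tbl(tss)
  if (nrow(tss) == 0L) abort("nearest_gene: empty TSS table")
  tss$pos <- ifelse(tss$strand == "-", tss$end - 1L, tss$start)
  out <- as_tibble(regions)
  out$gene <- NA_character_
  out$distance <- NA_real_
  mid <- floor((regions$start + regions$end) / 2)
  for (i in seq_len(nrow(regions))) {
    cand <- tss[tss$contig == regions$contig[i], ]
    if (nrow(cand) == 0L) next
    d_abs <- abs(cand$pos - mid[i])
    best <- which(d_abs == min(d_abs))
    if (length(best) > 1L) best <- best[order(cand$gene[best])][1]
    out$gene[i] <- cand$gene[best]
    out$distance[i] <- if (cand$strand[best] == "-") {
      cand$pos[best] - mid[i]
    } else {
      mid[i] - cand$pos[best]
    }
  }
  out$class <- ifelse(
    !is.na(out$distance) &
      out$distance >= -promoter_upstream & out$distance < promoter_downstream,
    "promoter", "distal"
  )
  out
}

#' Binned signal matrix around region centers
#'
#' Mean depth-normalized insertions per bp in `bin`-bp bins across
#' `+/- flank` bp of each region center (`floor` midpoint), the layout used
#' for signal heatmaps (default 300 bins of 10 bp over +/- 1.5 kb). Bins
#' extending beyond the contig are zero-filled and the region flagged.
#'
#' @inheritParams footprint_score
#' @param regions Tibble with `contig`, `start`, `end`.
#' @param flank Half-window in bp (default 1500).
#' @param bin Bin width in bp (default 10).
#' @return A numeric matrix, regions x bins, with attribute `clipped`
#'   (logical per region).
#' @export
signal_matrix <- function(profile, regions, flank = 1500L, bin = 10L) {
  stopifnot(inherits(profile, "cut_profile"))
  n_bins <- as.integer(2L * flank / bin)
  cs_all <- .profile_cumsum(profile)
  m <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  clipped <- logical(nrow(regions))
  nf <- profile$norm_factor
  for (i in seq_len(nrow(regions))) {
    ctg <- regions$contig[i]
    if (!ctg %in% names(profile$counts)) {
      abort(sprintf("signal_matrix: contig '%s' absent from the profile", ctg))
    }
    cs <- cs_all[[ctg]]
    len <- length(profile$counts[[ctg]])
    center <- floor((regions$start[i] + regions$end[i]) / 2)
    lo <- center - flank + bin * (seq_len(n_bins) - 1L)
    ws <- .window_sum(cs, lo, lo + bin, len)
    m[i, ] <- ws$sum / bin * nf
    clipped[i] <- any(ws$clipped)
  }
  if (any(clipped)) {
    warn(sprintf("signal_matrix: %d region(s) extend past a contig edge; zero-filled", sum(clipped)))
  }
  attr(m, "clipped") <- clipped
  m
}

#' Write a cut-site profile as bedGraph
#'
#' @param profile A [cut_sites()] profile.
#' @param path Output file.
#' @param normalized Write insertions-per-million instead of raw counts.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, normalized = FALSE) {
  stopifnot(inherits(profile, "cut_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(profile$counts)) {
    v <- profile$counts[[ctg]]
    if (normalized) v <- v * profile$norm_factor
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (!any(nz)) next
    writeLines(
      sprintf("%s\t%d\t%d\t%g", ctg, starts[nz], ends[nz], r$values[nz]),
      con
    )
  }
  invisible(path)
}
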