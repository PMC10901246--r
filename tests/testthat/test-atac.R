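test_that("cut sites follow the +4/-5 Tn5 convention", {
  fr <- tibble::tibble(contig = "chr1", start = c(100L, 0L), end = c(200L, 6L))
  prof <- cut_sites(fr, c(chr1 = 300L))
  expect_equal(which(prof$counts$chr1 > 0) - 1L, c(1L, 4L, 104L, 195L))
  expect_equal(prof$total, 4L)
  expect_equal(prof$total, 2L * nrow(fr) - prof$n_dropped)

  # off-contig cut positions are dropped and counted
  prof2 <- cut_sites(tibble::tibble(contig = "chr1", start = -10L, end = 100L), c(chr1 = 300L))
  expect_equal(prof2$n_dropped, 1L)
  expect_equal(prof2$total, 1L)

  expect_error(cut_sites(tibble::tibble(contig = "c", start = 5L, end = 5L), c(c = 10L)), "start < end")
  expect_warning(cut_sites(fr, NULL), "inferring")
})

test_that("footprint score is 0 on uniform profiles and matches its formula", {
  prof <- fake_profile(rep(2L, 1000))
  site <- tibble::tibble(contig = "chr1", start = 400L, width = 20L)
  sc <- footprint_score(prof, site)
  expect_equal(sc$score, 0)
  expect_false(sc$clipped)

  # flank mean 8, center mean 2 in normalized units -> log2(9/3)
  counts <- rep(8L, 200)
  counts[76:125] <- 2L
  prof2 <- fake_profile(counts, norm_factor = 1)
  sc2 <- footprint_score(prof2, tibble::tibble(contig = "chr1", start = 75L, width = 50L))
  expect_equal(sc2$center_mean, 2)
  expect_equal(sc2$flank_mean, 8)
  expect_equal(sc2$score, log2(9 / 3))
})

test_that("footprint score is invariant to global depth rescaling", {
  set.seed(3)
  counts <- rpois(2000, 5)
  prof1 <- fake_profile(counts)
  prof5 <- fake_profile(counts * 5L)
  sites <- tibble::tibble(contig = "chr1", start = c(300L, 900L, 1500L), width = 12L)
  expect_equal(footprint_score(prof1, sites)$score, footprint_score(prof5, sites)$score)
})

test_that("edge-truncated footprint windows are flagged, not padded", {
  prof <- fake_profile(rep(3L, 100))
  expect_warning(
    sc <- footprint_score(prof, tibble::tibble(contig = "chr1", start = 10L, width = 10L)),
    "truncated"
  )
  expect_true(sc$clipped)
  expect_true(is.finite(sc$score))
})

test_that("differential footprint deltas: zero on identical profiles, antisymmetric", {
  set.seed(9)
  counts <- rpois(3000, 4)
  pa <- fake_profile(counts)
  sites <- tibble::tibble(
    gene = paste0("g", 1:4), pwm = "m", contig = "chr1",
    start = c(200L, 800L, 1500L, 2300L), width = 10L
  )
  d0 <- differential_footprint(pa, pa, sites)
  expect_true(all(d0$sites$delta == 0))
  expect_true(all(d0$promoters$delta == 0))

  pb <- fake_profile(rpois(3000, 4))
  dab <- differential_footprint(pa, pb, sites)
  dba <- differential_footprint(pb, pa, sites)
  expect_equal(dab$sites$delta, -dba$sites$delta)

  expect_error(differential_footprint(pa, NULL, sites), "required")
})

test_that("a site bound in one condition only yields a positive delta", {
  counts_open <- rep(10L, 500)
  counts_bound <- counts_open
  counts_bound[201:220] <- 0L # d = 1 over the site
  pa <- fake_profile(counts_bound, norm_factor = 1)
  pb <- fake_profile(counts_open, norm_factor = 1)
  site <- tibble::tibble(gene = "g", pwm = "m", contig = "chr1", start = 200L, width = 20L)
  d <- differential_footprint(pa, pb, site)
  expect_gt(d$sites$delta, 0)
  expect_equal(d$sites$score_b, 0)
})

test_that("per-promoter aggregation takes the max (or mean) over sites", {
  pa <- fake_profile(c(rep(10L, 300), rep(0L, 0)), norm_factor = 1)
  counts_b <- rep(10L, 300)
  counts_b[101:110] <- 2L
  pb <- fake_profile(counts_b, norm_factor = 1)
  sites <- tibble::tibble(
    gene = "g1", pwm = "m", contig = "chr1",
    start = c(50L, 100L), width = 10L
  )
  d <- differential_footprint(pb, pa, sites)
  expect_equal(d$promoters$delta, max(d$sites$delta))
  dm <- differential_footprint(pb, pa, sites, aggregate = "mean")
  expect_equal(dm$promoters$delta, mean(d$sites$delta))
})

test_that("differential footprint AUC under iid-noise deltas sits at the permutation null", {
  set.seed(17)
  genes <- paste0("g", sprintf("%04d", 1:600))
  targets <- sample(genes, 60)
  depth <- 300
  aucs <- replicate(300, {
    pd <- tibble::tibble(gene = genes, delta = rnorm(600))
    differential_footprint_auc(pd, targets, depth = depth)$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - null_auc_mean(600, depth)), 3 * se)
})

test_that("fragments count once per overlapped region, half-open", {
  fr <- tibble::tibble(contig = "chr1", start = c(100L, 100L, 150L), end = c(200L, 200L, 260L))
  reg <- tibble::tibble(
    contig = "chr1", start = c(150L, 200L, 0L), end = c(300L, 300L, 150L)
  )
  cnt <- count_regions(fr[1, ], reg)$count
  expect_equal(cnt, c(1L, 0L, 1L)) # overlap; abutment; left-overlap
  # one fragment spanning two regions is counted in both
  spanning <- tibble::tibble(contig = "chr1", start = 140L, end = 210L)
  reg2 <- tibble::tibble(contig = "chr1", start = c(100L, 150L), end = c(150L, 250L))
  expect_equal(count_regions(spanning, reg2)$count, c(1L, 1L))
})

test_that("region counts are conserved on a tiling with contained fragments", {
  set.seed(4)
  starts <- sort(sample(0:990, 50)) * 10L
  fr <- tibble::tibble(contig = "chr1", start = starts, end = starts + 9L)
  tiles <- tibble::tibble(
    contig = "chr1", start = seq(0L, 9990L, by = 10L), end = seq(10L, 10000L, by = 10L)
  )
  expect_equal(sum(count_regions(fr, tiles)$count), nrow(fr))
})

test_that("diff_access reproduces its closed-form examples", {
  da <- diff_access(c(50L, 90L), c(50L, 10L), 1e6, 1e6)
  expect_equal(da$log2fc[1], 0)
  expect_equal(da$p[1], 1)
  expect_equal(da$log2fc[2], log2(91 / 11))
  expect_true(all(da$q >= da$p - 1e-12))
  expect_error(diff_access(1L, 1L, 0, 10), "positive")

  # zero-count region gets p = 1, finite lfc
  da0 <- diff_access(0L, 0L, 1e6, 1e6)
  expect_equal(da0$p, 1)
  expect_equal(da0$log2fc, 0)
})

test_that("nearest_gene classifies promoter vs distal with signed distances", {
  tss <- tibble::tibble(
    contig = "chr1", start = c(5000L, 40000L), end = c(5001L, 40001L),
    gene = c("gA", "gB"), strand = c("+", "+")
  )
  reg <- tibble::tibble(
    contig = "chr1",
    start = c(4000L, 14500L, 5100L), end = c(4500L, 15500L, 5200L)
  )
  ann <- nearest_gene(reg, tss)
  expect_equal(ann$gene[1], "gA")
  expect_equal(ann$distance[1], -750) # upstream
  expect_equal(ann$class[1], "promoter")
  expect_equal(ann$class[2], "distal") # 10 kb from gA
  expect_equal(ann$class[3], "promoter") # +150 downstream

  # strand-aware sign: region downstream of a minus-strand TSS is upstream
  tss_m <- tibble::tibble(contig = "chr1", start = 5000L, end = 5001L, gene = "gм", strand = "-")
  ann_m <- nearest_gene(reg[1, ], tss_m)
  expect_equal(ann_m$distance, 750)

  # equidistant TSSs resolve to the smaller gene id
  tss2 <- tibble::tibble(
    contig = "chr1", start = c(1000L, 3000L), end = c(1001L, 3001L),
    gene = c("zz", "aa"), strand = "+"
  )
  mid_reg <- tibble::tibble(contig = "chr1", start = 1995L, end = 2005L)
  expect_equal(nearest_gene(mid_reg, tss2)$gene, "aa")

  expect_error(nearest_gene(reg, tss[0, ]), "empty")
})

test_that("signal matrix bins mean normalized insertions around region centers", {
  prof <- fake_profile(rep(4L, 6000), norm_factor = 1)
  reg <- tibble::tibble(contig = "chr1", start = 2999L, end = 3000L)
  m <- signal_matrix(prof, reg)
  expect_equal(dim(m), c(1L, 300L))
  expect_true(all(m == 4))

  # odd-length region: center = floor(midpoint)
  reg_odd <- tibble::tibble(contig = "chr1", start = 1000L, end = 1005L)
  expect_equal(floor((1000 + 1005) / 2), 1002)
  m2 <- signal_matrix(prof, reg_odd, flank = 20L, bin = 10L)
  expect_equal(dim(m2), c(1L, 4L))

  # row sums conserve windowed insertion totals / bin
  set.seed(12)
  prof2 <- fake_profile(rpois(6000, 3), norm_factor = 1)
  m3 <- signal_matrix(prof2, reg, flank = 1500L, bin = 10L)
  win_total <- sum(prof2$counts$chr1[(2999 - 1500 + 1):(2999 + 1500)])
  expect_equal(sum(m3) * 10, win_total)

  # off-contig windows are zero-filled and flagged
  expect_warning(m4 <- signal_matrix(prof, tibble::tibble(contig = "chr1", start = 0L, end = 2L)), "edge")
  expect_true(attr(m4, "clipped"))
})

test_that("bedGraph output round-trips through rtracklayer", {
  prof <- fake_profile(c(0L, 0L, 3L, 3L, 1L, 0L))
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(prof, path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  expect_equal(sum(gr$score * GenomicRanges::width(gr)), prof$total)
})
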