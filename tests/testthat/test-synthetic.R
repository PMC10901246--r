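test_that("config invariants are enforced", {
  expect_error(sim_config(footprint_depth = 1.2), "footprint_depth")
  expect_error(sim_config(n_tra = 50, n_genes = 10), "n_tra")
  expect_error(sim_config(planted_tfs = "NotInPanel"), "subset of tf_panel")
  expect_error(sim_config(planted_tfs = "Ehf", active_tfs = "Klf4"), "subset of planted")
  expect_error(sim_config(lambda_bg = -1), "non-negative")
  expect_error(sim_config(n_conditions = 3), "2 or 4")
})

test_that("p_plant edge cases plant exactly zero or n_tra sites", {
  cfg0 <- sim_config(n_genes = 50, n_tra = 10, p_plant = 0, seed = 2)
  expect_equal(nrow(simulate_promoters(cfg0)$truth$planted_sites), 0L)

  cfg1 <- sim_config(
    n_genes = 120, n_tra = 100, p_plant = 1,
    tf_panel = c("Ehf", "Klf4"), planted_tfs = "Ehf", seed = 2
  )
  truth <- simulate_promoters(cfg1)$truth
  expect_equal(nrow(truth$planted_sites), 100L)
  expect_equal(sort(unique(truth$planted_sites$gene)), sort(sim_tra_genes(cfg1)))
})

test_that("ground truth is internally consistent", {
  cfg <- sim_config(n_genes = 60, n_tra = 20, seed = 9, p_plant = 0.8,
                    active_tfs = c("Ehf", "Elf3"))
  sp <- simulate_promoters(cfg)
  st <- sp$truth$planted_sites
  expect_true(all(st$offset >= 0 & st$offset <= cfg$promoter_len - st$width))
  expect_true(all(sp$truth$active_tfs %in% cfg$planted_tfs))
  # active TFs' sites are bound in the Tspan8-positive condition, others never
  expect_true(all(st$bound[st$tf %in% cfg$active_tfs] == "tspan8pos"))
  expect_true(all(st$bound[!st$tf %in% cfg$active_tfs] == ""))
  # planted subsequences are present in the promoter strings
  for (i in which(st$strand == "+")[1:5]) {
    seq <- sp$promoters$sequence[sp$promoters$gene == st$gene[i]]
    win <- substr(seq, st$offset[i] + 1, st$offset[i] + st$width[i])
    p <- simulate_pwms(cfg$tf_panel, seed = cfg$seed)[[st$tf[i]]]
    expect_gt(likelihood_ratio(p, win), 1)
  }
})

test_that("a PWM wider than the promoter is rejected", {
  cfg <- sim_config(n_genes = 10, n_tra = 2, promoter_len = 9, seed = 1,
                    tf_panel = "Ehf", planted_tfs = "Ehf")
  wide <- list(Ehf = rand_pwm(30, "Ehf"))
  expect_error(simulate_promoters(cfg, wide), "wider than the promoter")
})

test_that("identical seed and config give byte-identical written outputs", {
  cfg <- sim_config(n_genes = 12, n_tra = 4, seed = 7, n_reps = 2)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_sim(simulate_screen_data(cfg, chip = TRUE), d1)
  write_sim(simulate_screen_data(cfg, chip = TRUE), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
      label = f
    )
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("full depletion (d = 1) zeroes insertions over bound sites", {
  cfg <- sim_config(
    n_genes = 30, n_tra = 10, p_plant = 1, footprint_depth = 1,
    tf_panel = c("Ehf", "Klf4"), planted_tfs = "Ehf", seed = 3
  )
  sp <- simulate_promoters(cfg)
  fr <- simulate_atac(cfg, sp$truth, sp$promoters)
  prof <- cut_sites(
    fr[fr$condition == "tspan8pos", ],
    attr(sp$promoters, "contig_lengths")
  )
  st <- sp$truth$planted_sites
  at_sites <- unlist(lapply(seq_len(nrow(st)), function(i) {
    prof$counts$chrS[(st$contig_start[i] + 1):(st$contig_start[i] + st$width[i])]
  }))
  expect_equal(sum(at_sites), 0L)
  # and the unbound condition keeps the open rate there
  prof_b <- cut_sites(
    fr[fr$condition == "tspan8neg", ],
    attr(sp$promoters, "contig_lengths")
  )
  at_b <- unlist(lapply(seq_len(nrow(st)), function(i) {
    prof_b$counts$chrS[(st$contig_start[i] + 1):(st$contig_start[i] + st$width[i])]
  }))
  expect_gt(sum(at_b), 0L)
})

test_that("d = 0 leaves bound-site rates at lambda_open within Poisson error", {
  cfg <- sim_config(
    n_genes = 60, n_tra = 30, p_plant = 1, footprint_depth = 0,
    tf_panel = c("Ehf", "Klf4"), planted_tfs = "Ehf", seed = 4
  )
  sp <- simulate_promoters(cfg)
  fr <- simulate_atac(cfg, sp$truth, sp$promoters)
  n_reps <- cfg$n_reps
  prof <- cut_sites(fr[fr$condition == "tspan8pos", ], attr(sp$promoters, "contig_lengths"))
  st <- sp$truth$planted_sites
  at_sites <- unlist(lapply(seq_len(nrow(st)), function(i) {
    prof$counts$chrS[(st$contig_start[i] + 1):(st$contig_start[i] + st$width[i])]
  }))
  m <- mean(at_sites) / n_reps
  se <- sqrt(cfg$lambda_open * n_reps / length(at_sites)) / n_reps
  expect_lt(abs(m - cfg$lambda_open), 3 * se)
})

test_that("open/closed per-base rate ratio tracks lambda_open/lambda_bg", {
  cfg <- sim_config(
    n_genes = 40, n_tra = 10, lambda_bg = 0.05, lambda_open = 0.5,
    planted_tfs = character(0), n_reps = 1, seed = 1
  )
  sp <- simulate_promoters(cfg)
  fr <- simulate_atac(cfg, sp$truth, sp$promoters)
  prof <- cut_sites(fr[fr$condition == "tspan8pos", ], attr(sp$promoters, "contig_lengths"))
  v <- prof$counts$chrS
  open_idx <- unlist(lapply(seq_len(nrow(sp$promoters)), function(i) {
    (sp$promoters$promoter_start[i] + 200):(sp$promoters$promoter_end[i] - 200)
  }))
  closed_idx <- setdiff(seq(400, length(v) - 400), # avoid contig-edge clamping
    unlist(lapply(seq_len(nrow(sp$promoters)), function(i) {
      (sp$promoters$promoter_start[i] - 200):(sp$promoters$promoter_end[i] + 200)
    }))
  )
  mo <- mean(v[open_idx])
  mc <- mean(v[closed_idx])
  ratio <- mo / mc
  se_ratio <- ratio * sqrt(1 / sum(v[open_idx]) + 1 / sum(v[closed_idx]))
  expect_lt(abs(ratio - 10), 3 * se_ratio)
})

test_that("fragment/insertion conservation holds exactly", {
  cfg <- sim_config(n_genes = 20, n_tra = 5, seed = 8, n_reps = 1)
  sp <- simulate_promoters(cfg)
  fr <- simulate_atac(cfg, sp$truth, sp$promoters)
  one <- fr[fr$condition == "tspan8pos" & fr$replicate == 1, ]
  prof <- cut_sites(one, attr(sp$promoters, "contig_lengths"))
  expect_equal(prof$total, 2 * nrow(one))
  expect_equal(prof$n_dropped, 0L)
  # fragment lengths follow the pairing construction: d in [30,150] plus 9
  expect_true(all(one$end - one$start >= 39 & one$end - one$start <= 159))
})

test_that("expression nulls and shifts behave as configured", {
  # null: almost no gene exceeds |lfc| > 1 at nb_mean 100, 5 reps
  cfg <- sim_config(
    n_genes = 800, n_tra = 0, planted_tfs = character(0),
    de_lfc = 0, nb_mean = 100, n_reps = 5, seed = 21
  )
  ex <- simulate_expression(cfg, simulate_promoters(cfg)$truth)
  g <- ex$samples$group
  lfc <- log2(rowMeans(ex$counts[, g == "tspan8pos"]) / rowMeans(ex$counts[, g == "tspan8neg"]))
  expect_lt(mean(abs(lfc) > 1), 0.01)

  # active TF recovers de_lfc = 2 within +/- 0.5 at nb_mean 200, 5 reps
  cfg2 <- sim_config(
    n_genes = 300, n_tra = 20, planted_tfs = "Ehf", de_lfc = 2,
    nb_mean = 200, n_reps = 5, seed = 22
  )
  ex2 <- simulate_expression(cfg2, simulate_promoters(cfg2)$truth)
  g2 <- ex2$samples$group
  l2 <- log2(mean(ex2$counts["Ehf", g2 == "tspan8pos"]) / mean(ex2$counts["Ehf", g2 == "tspan8neg"]))
  expect_lt(abs(l2 - 2), 0.5)

  # dispersion -> 0 approaches the Poisson variance/mean limit
  cfg3 <- sim_config(
    n_genes = 1500, n_tra = 0, planted_tfs = character(0),
    nb_dispersion = 0, de_lfc = 0, n_reps = 5, seed = 23
  )
  ex3 <- simulate_expression(cfg3, simulate_promoters(cfg3)$truth)
  vm <- apply(ex3$counts, 1, var) / rowMeans(ex3$counts)
  expect_lt(abs(mean(vm) - 1), 0.05)

  expect_equal(ncol(ex$counts), nrow(ex$samples))
  expect_true(all(c("sample", "condition", "group", "replicate") %in% names(ex$samples)))
})

test_that("null ChIP (chip_enrich = 1) shows no site enrichment", {
  cfg <- sim_config(
    n_genes = 100, n_tra = 30, p_plant = 1, chip_enrich = 1,
    tf_panel = c("Ehf", "Klf4"), planted_tfs = "Ehf", seed = 6
  )
  sp <- simulate_promoters(cfg)
  ch <- simulate_chip(cfg, sp$truth, sp$promoters, tfs = "Ehf")
  ip <- ch$fragments[ch$fragments$role == "ip", ]
  input <- ch$fragments[ch$fragments$role == "input", ]
  pk <- ch$peaks
  ca <- count_regions(ip, pk)$count
  cb <- count_regions(input, pk)$count
  diff <- mean(ca) - mean(cb)
  se <- sqrt(var(ca) / length(ca) + var(cb) / length(cb))
  expect_lt(abs(diff), 3 * se)
})

test_that("a TF with no bound sites is indistinguishable from input genome-wide", {
  cfg <- sim_config(
    n_genes = 300, n_tra = 60, p_plant = 1,
    tf_panel = c("Ehf", "Elf3"), planted_tfs = "Ehf", seed = 1
  )
  sp <- simulate_promoters(cfg)
  ch <- simulate_chip(cfg, sp$truth, sp$promoters, tfs = "Elf3") # never bound
  ip <- ch$fragments[ch$fragments$role == "ip", ]
  input <- ch$fragments[ch$fragments$role == "input", ]
  expect_equal(nrow(ch$peaks), 0L)
  L <- attr(sp$promoters, "contig_lengths")[["chrS"]]
  wins <- tibble::tibble(
    contig = "chrS",
    start = seq(0L, L - 20000L, by = 20000L),
    end = seq(20000L, L, by = 20000L)
  )
  pe <- peak_enrichment(ip, input, wins)
  expect_lt(max(abs(log2(pe$fc))), 1)
})
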