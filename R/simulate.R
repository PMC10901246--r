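#' Configuration of the synthetic mTEC screen generator
#'
#' Bundles every tunable of the simulator: universe and TRA-list sizes,
#' promoter geometry, the PWM panel with its planted and active subsets,
#' Tn5 insertion rates for closed and open chromatin, the fractional
#' footprint depletion at bound sites, ChIP IP-over-input enrichment,
#' negative-binomial expression parameters and the replicate layout.
#'
#' The TRA list is the first `n_tra` gene ids and doubles as the true-DE
#' target set: planted motif sites live in TRA promoters, TRA promoters are
#' the open-chromatin set, and TRA genes carry the expression shift in the
#' Tspan8-positive subset.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_tra Number of TRA genes (the first `n_tra` ids).
#' @param promoter_len Promoter length in bp (2000 upstream + 1000
#'   downstream of the TSS).
#' @param spacer Spacer between promoters on the synthetic contig (bp).
#' @param tf_panel PWM/TF identifiers of the scanned panel.
#' @param planted_tfs Panel subset whose motifs are planted in TRA
#'   promoters.
#' @param active_tfs Planted subset actually bound (footprinted, ChIP
#'   enriched, expression-shifted) in the Tspan8-positive conditions;
#'   defaults to `planted_tfs`.
#' @param p_plant Probability that a TRA promoter carries a site of each
#'   planted TF.
#' @param lambda_bg Mean Tn5 insertions per bp in closed chromatin (the
#'   inter-promoter spacers).
#' @param lambda_open Mean insertions per bp in open chromatin: the
#'   promoters of the gene universe (all universe genes are expressed and
#'   their promoters accessible; differential footprints arise only from
#'   bound-site depletion, not from differential openness).
#' @param footprint_depth Fractional insertion depletion `d` in `[0, 1]`
#'   across bound motif positions.
#' @param chip_enrich IP-over-input rate multiplier at bound sites.
#' @param chip_halo Half-width of the ChIP-enriched zone around a bound
#'   site (bp); the truth peaks are these zones.
#' @param nb_mean Mean expression count.
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param de_lfc log2 fold change applied to TRA genes and active TFs in
#'   the Tspan8-positive conditions.
#' @param n_reps Replicates per condition.
#' @param n_conditions 2 (Tspan8 +/-) or 4 (Tspan8 +/- x MHCII lo/hi).
#' @param mixed_strands Place genes on random strands instead of all `+`.
#' @param background Base composition of background sequence (A,C,G,T).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, n_tra = 100L, promoter_len = 3000L,
                       spacer = 1000L,
                       tf_panel = c("Ehf", "Elf3", "Elf5", "Klf1", "Klf4", "Fezf2", "Ets1", "Sp1"),
                       planted_tfs = c("Ehf", "Elf3", "Klf4"),
                       active_tfs = NULL,
                       p_plant = 0.9, lambda_bg = 0.02, lambda_open = 0.5,
                       footprint_depth = 0.5, chip_enrich = 8, chip_halo = 500L,
                       nb_mean = 100, nb_dispersion = 0.1, de_lfc = 2,
                       n_reps = 3L, n_conditions = 2L, mixed_strands = FALSE,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed = 1L) {
  if (is.null(active_tfs)) active_tfs <- planted_tfs
  cfg <- list(
    n_genes = as.integer(n_genes), n_tra = as.integer(n_tra),
    promoter_len = as.integer(promoter_len), spacer = as.integer(spacer),
    tf_panel = tf_panel, planted_tfs = planted_tfs, active_tfs = active_tfs,
    p_plant = p_plant, lambda_bg = lambda_bg, lambda_open = lambda_open,
    footprint_depth = footprint_depth, chip_enrich = chip_enrich,
    chip_halo = as.integer(chip_halo),
    nb_mean = nb_mean, nb_dispersion = nb_dispersion, de_lfc = de_lfc,
    n_reps = as.integer(n_reps), n_conditions = as.integer(n_conditions),
    mixed_strands = isTRUE(mixed_strands),
    background = .check_background(background), seed = as.integer(seed)
  )
  if (cfg$footprint_depth < 0 || cfg$footprint_depth > 1) {
    abort("footprint_depth must lie in [0, 1]")
  }
  if (any(c(cfg$lambda_bg, cfg$lambda_open, cfg$chip_enrich, cfg$nb_mean, cfg$nb_dispersion) < 0)) {
    abort("rates must be non-negative")
  }
  if (cfg$n_tra > cfg$n_genes) abort("n_tra must not exceed n_genes")
  if (!all(cfg$planted_tfs %in% cfg$tf_panel)) abort("planted_tfs must be a subset of tf_panel")
  if (!all(cfg$active_tfs %in% cfg$planted_tfs)) abort("active_tfs must be a subset of planted_tfs")
  if (!cfg$n_conditions %in% c(2L, 4L)) abort("n_conditions must be 2 or 4")
  if (cfg$p_plant < 0 || cfg$p_plant > 1) abort("p_plant must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Condition labels of a simulation config
#' @param config A [sim_config()].
#' @return Character vector of condition names; Tspan8-positive conditions
#'   (the bound/DE group) come first.
#' @export
sim_conditions <- function(config) {
  if (config$n_conditions == 2L) {
    c("tspan8pos", "tspan8neg")
  } else {
    c("tspan8pos_lo", "tspan8pos_hi", "tspan8neg_lo", "tspan8neg_hi")
  }
}

.bound_conditions <- function(config) {
  grep("^tspan8pos", sim_conditions(config), value = TRUE)
}

.gene_ids <- function(config) sprintf("g%05d", seq_len(config$n_genes))

#' TRA gene list of a simulation config
#' @param config A [sim_config()].
#' @return Character vector, the first `n_tra` gene ids.
#' @export
sim_tra_genes <- function(config) .gene_ids(config)[seq_len(config$n_tra)]

# stream-specific seed below 2^31
.sim_seed <- function(seed, k) {
  as.integer((as.numeric(seed %% 1000003L) * 2039 + k) %% 2147483629)
}

#' Random informative PWMs for a TF panel
#'
#' Each position has one dominant base with probability `info`, the rest
#' sharing the remainder; widths cycle through `widths` across the panel.
#'
#' @param tf_panel Motif identifiers.
#' @param widths Candidate motif widths, recycled over the panel.
#' @param info Probability of the dominant base per position.
#' @param seed Integer seed.
#' @return Named list of [pwm()] objects.
#' @export
simulate_pwms <- function(tf_panel, widths = c(10L, 11L, 9L, 12L, 10L), info = 0.9,
                          seed = 1L) {
  set.seed(.sim_seed(seed, 7L))
  widths <- rep_len(as.integer(widths), length(tf_panel))
  pwms <- lapply(seq_along(tf_panel), function(i) {
    w <- widths[i]
    dom <- sample.int(4L, w, replace = TRUE)
    probs <- matrix((1 - info) / 3, nrow = w, ncol = 4)
    probs[cbind(seq_len(w), dom)] <- info
    pwm(probs, id = tf_panel[i], pseudocount = 0)
  })
  names(pwms) <- tf_panel
  pwms
}

#' Simulate promoters with planted motif sites
#'
#' Generates i.i.d. background promoters at the configured base composition
#' and, for every TRA (true-DE) gene and planted TF, plants with probability
#' `p_plant` one site sampled from the PWM, on a Bernoulli(0.5) strand, at a
#' uniform non-overlapping offset. Promoters are laid end-to-end on one
#' synthetic contig (`chrS`) separated by spacers. Every planted site is
#' recorded in the ground truth together with the conditions in which it is
#' bound (sites of active TFs are bound in the Tspan8-positive conditions).
#'
#' @param config A [sim_config()].
#' @param pwms Named list of [pwm()] covering `config$tf_panel` (default
#'   [simulate_pwms()] on the panel).
#' @return List with `promoters` (tibble as in [extract_promoters()], with
#'   attribute `contig_lengths`) and `truth` (class `ground_truth`: list
#'   with `planted_sites`, `true_de_genes`, `active_tfs`, `contrast`).
#' @export
simulate_promoters <- function(config, pwms = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(pwms)) pwms <- simulate_pwms(config$tf_panel, seed = config$seed)
  if (!all(config$tf_panel %in% names(pwms))) {
    abort("pwms must cover every id in config$tf_panel")
  }
  widths <- vapply(pwms[config$tf_panel], `[[`, integer(1), "width")
  if (any(widths > config$promoter_len)) {
    abort("a PWM is wider than the promoter window")
  }
  plen <- config$promoter_len
  n <- config$n_genes
  genes <- .gene_ids(config)
  tra <- sim_tra_genes(config)

  set.seed(.sim_seed(config$seed, 11L))
  # promoter sequences as integer codes 1..4 = A,C,G,T (rows = genes)
  codes <- matrix(
    sample.int(4L, n * plen, replace = TRUE, prob = config$background),
    nrow = n, byrow = TRUE
  )
  strands <- if (config$mixed_strands) {
    sample(c("+", "-"), n, replace = TRUE)
  } else {
    rep("+", n)
  }

  bound_in <- paste(.bound_conditions(config), collapse = ",")
  site_rows <- list()
  for (tf in config$planted_tfs) {
    p <- pwms[[tf]]
    w <- p$width
    planted <- tra[runif(length(tra)) < config$p_plant]
    for (g in planted) {
      gi <- match(g, genes)
      used <- site_rows[vapply(site_rows, function(s) s$gene == g, logical(1))]
      off <- NA_integer_
      for (try in 1:50) {
        cand <- sample.int(plen - w + 1L, 1L) - 1L
        clash <- any(vapply(used, function(s) {
          cand < s$offset + s$width && s$offset < cand + w
        }, logical(1)))
        if (!clash) {
          off <- cand
          break
        }
      }
      if (is.na(off)) next
      site_seq <- vapply(seq_len(w), function(j) {
        sample.int(4L, 1L, prob = p$probs[j, ])
      }, integer(1))
      strand <- if (runif(1) < 0.5) "+" else "-"
      ins <- if (strand == "-") rev(5L - site_seq) else site_seq
      codes[gi, (off + 1L):(off + w)] <- ins
      site_rows[[length(site_rows) + 1L]] <- list(
        gene = g, tf = tf, offset = off, strand = strand, width = w,
        bound = if (tf %in% config$active_tfs) bound_in else ""
      )
    }
  }

  pitch <- plen + config$spacer
  starts <- config$spacer + (seq_len(n) - 1L) * pitch
  contig_len <- config$spacer + n * pitch
  base_chr <- c(65L, 67L, 71L, 84L) # A C G T
  seqs <- vapply(seq_len(n), function(i) intToUtf8(base_chr[codes[i, ]]), character(1))

  up <- as.integer(floor(2 * plen / 3)) # TSS offset: 2 kb upstream of 3 kb
  promoters <- tibble(
    gene = genes, sequence = seqs, contig = "chrS",
    tss = ifelse(strands == "-", starts + (plen - up), starts + up),
    strand = strands,
    promoter_start = starts, promoter_end = starts + plen,
    truncated = FALSE
  )
  attr(promoters, "contig_lengths") <- c(chrS = contig_len)

  sites <- if (length(site_rows) > 0) {
    bind_rows(lapply(site_rows, as_tibble))
  } else {
    tibble(
      gene = character(), tf = character(), offset = integer(),
      strand = character(), width = integer(), bound = character()
    )
  }
  if (nrow(sites) > 0) {
    gi <- match(sites$gene, genes)
    sites$contig <- "chrS"
    sites$contig_start <- ifelse(
      strands[gi] == "-",
      starts[gi] + plen - sites$offset - sites$width,
      starts[gi] + sites$offset
    )
  } else {
    sites$contig <- character()
    sites$contig_start <- integer()
  }

  truth <- structure(
    list(
      planted_sites = sites,
      true_de_genes = tra,
      active_tfs = config$active_tfs,
      contrast = .bound_conditions(config)[1]
    ),
    class = "ground_truth"
  )
  list(promoters = promoters, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d planted sites, %d true-DE genes, active TFs: %s\n",
    nrow(x$planted_sites), length(x$true_de_genes),
    if (length(x$active_tfs)) paste(x$active_tfs, collapse = ", ") else "(none)"
  ))
  invisible(x)
}

#' Planted sites of one or all TFs as a footprint site table
#'
#' @param truth A `ground_truth` (see [simulate_promoters()]).
#' @param tf Optional TF id filter.
#' @return Tibble with `gene`, `pwm`, `contig`, `start`, `width`, `bound`.
#' @export
sim_sites <- function(truth, tf = NULL) {
  s <- truth$planted_sites
  if (!is.null(tf)) s <- s[s$tf %in% tf, ]
  tibble(
    gene = s$gene, pwm = s$tf, contig = s$contig,
    start = s$contig_start, width = s$width, bound = s$bound
  )
}

# Inhomogeneous-Poisson fragment synthesis. `rate` is the per-base cut rate
# (index i = 0-based position i - 1); anchors are drawn at rate/2 and each
# anchor is paired with a partner cut at +/- Uniform(30, 150) bp accepted by
# thinning against `cap` (a pointwise upper bound of `rate` over the +/-150
# neighborhood), so both fragment ends follow the field and total cuts are
# twice the fragment count.
.sim_fragments <- function(rate, cap, seed) {
  L <- length(rate)
  set.seed(seed)
  rate2 <- rate
  rate2[c(1:5, (L - 4L):L)] <- 0 # keep +4/-5 cut recovery on-contig
  anchors <- rep.int(seq_len(L), rpois(L, rate2 / 2))
  n <- length(anchors)
  if (n == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  anchors <- anchors[sample.int(n)] # decorrelate position from pairing order
  partner <- integer(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    d <- sample(30:150, length(todo), replace = TRUE)
    s <- sample(c(-1L, 1L), length(todo), replace = TRUE)
    q <- anchors[todo] + s * d
    ok <- q >= 6L & q <= L - 5L
    acc <- ok
    acc[ok] <- runif(sum(ok)) < rate[q[ok]] / cap[anchors[todo][ok]]
    partner[todo[acc]] <- q[acc]
    todo <- todo[!acc]
  }
  c1 <- pmin(anchors, partner) - 1L # 0-based cut positions
  c2 <- pmax(anchors, partner) - 1L
  tibble(start = c1 - 4L, end = c2 + 5L)
}

# rate/cap construction shared by ATAC and ChIP synthesis
.dilate_cap <- function(base_rate, intervals, value, L, pad = 150L) {
  cap <- rep(base_rate, L)
  if (nrow(intervals) > 0) {
    for (i in seq_len(nrow(intervals))) {
      lo <- max(intervals$start[i] - pad, 0L) + 1L
      hi <- min(intervals$end[i] + pad, L)
      cap[lo:hi] <- pmax(cap[lo:hi], value)
    }
  }
  cap
}

#' Simulate ATAC fragments per condition and replicate
#'
#' Per-base Tn5 insertion rates are `lambda_open` inside gene promoters
#' (open chromatin of the expressed universe) and `lambda_bg` in the
#' spacers; positions covered by a site bound in the condition have their
#' rate multiplied by `1 - footprint_depth`. Fragments are interval pairs
#' whose `+4/-5` cut sites reproduce the simulated insertion positions
#' exactly (see [cut_sites()]).
#'
#' @inheritParams simulate_promoters
#' @param truth,promoters Output of [simulate_promoters()].
#' @return Tibble of fragments with `condition`, `replicate`, `contig`,
#'   `start`, `end` (BED 0-based half-open).
#' @export
simulate_atac <- function(config, truth, promoters) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  L <- attr(promoters, "contig_lengths")[["chrS"]]
  open_iv <- tibble(start = promoters$promoter_start, end = promoters$promoter_end)

  base_rate <- rep(config$lambda_bg, L)
  if (nrow(open_iv) > 0) {
    for (i in seq_len(nrow(open_iv))) {
      base_rate[(open_iv$start[i] + 1L):open_iv$end[i]] <- config$lambda_open
    }
  }
  cap <- .dilate_cap(config$lambda_bg, open_iv, max(config$lambda_open, config$lambda_bg), L)
  cap <- pmax(cap, base_rate)

  sites <- truth$planted_sites
  out <- list()
  k <- 0L
  for (cond in sim_conditions(config)) {
    rate <- base_rate
    b <- sites[vapply(strsplit(sites$bound, ","), function(x) cond %in% x, logical(1)), ]
    if (nrow(b) > 0) {
      for (i in seq_len(nrow(b))) {
        idx <- (b$contig_start[i] + 1L):(b$contig_start[i] + b$width[i])
        rate[idx] <- rate[idx] * (1 - config$footprint_depth)
      }
    }
    for (rep_i in seq_len(config$n_reps)) {
      k <- k + 1L
      fr <- .sim_fragments(rate, cap, .sim_seed(config$seed, 20L + k))
      fr$contig <- "chrS"
      fr$condition <- cond
      fr$replicate <- rep_i
      out[[k]] <- fr
    }
  }
  bind_rows(out) |> select("condition", "replicate", "contig", "start", "end")
}

#' Simulate an expression count matrix
#'
#' Counts are negative binomial with mean `nb_mean` and dispersion
#' `nb_dispersion` (Poisson when 0). TRA (true-DE) genes and active TFs have
#' their mean multiplied by `2^de_lfc` in the Tspan8-positive conditions.
#' The gene universe is the simulated genes plus one row per panel TF.
#'
#' @inheritParams simulate_atac
#' @return List with `counts` (gene x sample integer matrix), `samples`
#'   (tibble `sample`, `condition`, `group`, `replicate`).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  genes <- c(.gene_ids(config), config$tf_panel)
  conds <- sim_conditions(config)
  samples <- tidyr::expand_grid(condition = conds, replicate = seq_len(config$n_reps)) |>
    mutate(
      sample = paste0(.data$condition, "_r", .data$replicate),
      group = ifelse(startsWith(.data$condition, "tspan8pos"), "tspan8pos", "tspan8neg")
    ) |>
    select("sample", "condition", "group", "replicate")

  up <- c(truth$true_de_genes, truth$active_tfs)
  mu <- matrix(config$nb_mean, nrow = length(genes), ncol = nrow(samples),
    dimnames = list(genes, samples$sample)
  )
  shift_cols <- samples$group == "tspan8pos"
  mu[genes %in% up, shift_cols] <- mu[genes %in% up, shift_cols] * 2^config$de_lfc

  set.seed(.sim_seed(config$seed, 101L))
  counts <- if (config$nb_dispersion > 0) {
    matrix(
      rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
  } else {
    matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu), dimnames = dimnames(mu))
  }
  list(counts = counts, samples = samples)
}

#' Simulate ChIP IP and input fragments per TF
#'
#' Input fragments are uniform at `lambda_bg`; IP fragments have the rate
#' multiplied by `chip_enrich` over the `+/- chip_halo` zone around every
#' bound site of the TF. The enriched zones double as the truth peak set.
#'
#' @inheritParams simulate_atac
#' @param tfs TFs to ChIP (default the planted panel subset).
#' @return List with `fragments` (tibble `tf`, `role` in ip/input,
#'   `contig`, `start`, `end`) and `peaks` (tibble `tf`, `contig`, `start`,
#'   `end`).
#' @export
simulate_chip <- function(config, truth, promoters, tfs = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (is.null(tfs)) tfs <- config$planted_tfs
  L <- attr(promoters, "contig_lengths")[["chrS"]]
  frags <- list()
  peaks <- list()
  base_cap <- rep(config$lambda_bg, L)
  for (k in seq_along(tfs)) {
    tf <- tfs[k]
    b <- truth$planted_sites
    b <- b[b$tf == tf & b$bound != "", ]
    zones <- if (nrow(b) > 0) {
      tibble(
        start = pmax(b$contig_start - config$chip_halo, 0L),
        end = pmin(b$contig_start + b$width + config$chip_halo, L)
      )
    } else {
      tibble(start = integer(), end = integer())
    }
    rate_ip <- rep(config$lambda_bg, L)
    if (nrow(zones) > 0) {
      for (i in seq_len(nrow(zones))) {
        rate_ip[(zones$start[i] + 1L):zones$end[i]] <- config$lambda_bg * config$chip_enrich
      }
    }
    cap_ip <- .dilate_cap(
      config$lambda_bg, zones, config$lambda_bg * max(config$chip_enrich, 1), L
    )
    ip <- .sim_fragments(rate_ip, pmax(cap_ip, rate_ip), .sim_seed(config$seed, 200L + 2L * k))
    input <- .sim_fragments(rep(config$lambda_bg, L), base_cap, .sim_seed(config$seed, 201L + 2L * k))
    ip$contig <- "chrS"
    input$contig <- "chrS"
    ip$tf <- tf
    input$tf <- tf
    ip$role <- "ip"
    input$role <- "input"
    frags[[length(frags) + 1L]] <- ip
    frags[[length(frags) + 1L]] <- input
    if (nrow(zones) > 0) {
      peaks[[length(peaks) + 1L]] <- tibble(
        tf = tf, contig = "chrS", start = zones$start, end = zones$end
      )
    }
  }
  list(
    fragments = bind_rows(frags) |> select("tf", "role", "contig", "start", "end"),
    peaks = if (length(peaks) > 0) bind_rows(peaks) else tibble(tf = character(), contig = character(), start = integer(), end = integer())
  )
}

#' Assemble the synthetic contig sequence
#'
#' Concatenates spacer sequence (i.i.d. at the configured composition) and
#' the promoter slices (reverse-complemented for minus-strand genes) into
#' the `chrS` contig, so that [extract_promoters()] on the result
#' reproduces the simulated promoter set.
#'
#' @inheritParams simulate_atac
#' @return A [Biostrings::DNAStringSet] with one contig `chrS`.
#' @export
sim_genome <- function(config, promoters) {
  L <- attr(promoters, "contig_lengths")[["chrS"]]
  set.seed(.sim_seed(config$seed, 13L))
  contig <- sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = config$background)
  for (i in seq_len(nrow(promoters))) {
    s <- promoters$sequence[i]
    if (promoters$strand[i] == "-") s <- revcomp(s)
    idx <- (promoters$promoter_start[i] + 1L):promoters$promoter_end[i]
    contig[idx] <- strsplit(s, "")[[1]]
  }
  out <- Biostrings::DNAStringSet(paste(contig, collapse = ""))
  names(out) <- "chrS"
  out
}

#' Run the full generator
#'
#' @inheritParams simulate_promoters
#' @param chip Also simulate ChIP fragments (slower; default FALSE).
#' @return List with `config`, `pwms`, `promoters`, `truth`, `atac`
#'   (fragment tibble), `expression`, and optionally `chip`.
#' @export
simulate_screen_data <- function(config, pwms = NULL, chip = FALSE) {
  if (is.null(pwms)) pwms <- simulate_pwms(config$tf_panel, seed = config$seed)
  pr <- simulate_promoters(config, pwms)
  out <- list(
    config = config, pwms = pwms,
    promoters = pr$promoters, truth = pr$truth,
    atac = simulate_atac(config, pr$truth, pr$promoters),
    expression = simulate_expression(config, pr$truth)
  )
  if (chip) out$chip <- simulate_chip(config, pr$truth, pr$promoters)
  out
}

#' Write a simulated data set to plain-text files
#'
#' Emits `promoters.fa`, `tss.bed` (BED6), `atac_<cond>_<rep>.bed` (BED3),
#' `chip_<tf>_{ip,input}.bed`, `counts.tsv`, `tra_genes.txt` and
#' `truth.json`. Identical config and seed give byte-identical files.
#'
#' @param sim Output of [simulate_screen_data()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- sim$promoters
  fa <- Biostrings::DNAStringSet(setNames(pr$sequence, pr$gene))
  Biostrings::writeXStringSet(fa, file.path(dir, "promoters.fa"))
  write.table(
    data.frame(pr$contig, pr$tss, pr$tss + 1L, pr$gene, 0L, pr$strand),
    file.path(dir, "tss.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  for (key in unique(paste(sim$atac$condition, sim$atac$replicate))) {
    parts <- strsplit(key, " ")[[1]]
    sel <- sim$atac$condition == parts[1] & sim$atac$replicate == as.integer(parts[2])
    write.table(
      sim$atac[sel, c("contig", "start", "end")],
      file.path(dir, sprintf("atac_%s_%s.bed", parts[1], parts[2])),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  if (!is.null(sim$chip)) {
    for (tf in unique(sim$chip$fragments$tf)) {
      for (role in c("ip", "input")) {
        sel <- sim$chip$fragments$tf == tf & sim$chip$fragments$role == role
        write.table(
          sim$chip$fragments[sel, c("contig", "start", "end")],
          file.path(dir, sprintf("chip_%s_%s.bed", tf, role)),
          sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
        )
      }
    }
  }
  counts <- sim$expression$counts
  write.table(
    data.frame(gene = rownames(counts), counts, check.names = FALSE),
    file.path(dir, "counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(sim_tra_genes(sim$config), file.path(dir, "tra_genes.txt"))
  jsonlite::write_json(
    list(
      planted_sites = sim$truth$planted_sites,
      true_de_genes = sim$truth$true_de_genes,
      active_tfs = sim$truth$active_tfs,
      contrast = sim$truth$contrast
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
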