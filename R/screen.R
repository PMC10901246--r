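#' Differential expression between two sample groups
#'
#' Moderated t-statistics (limma, trend on log2 counts-per-million + 1) for
#' the contrast `group_a - group_b`, with BH-adjusted q-values and mean
#' abundance per group. Library sizes are TMM-corrected (edgeR) so that an
#' asymmetric block of shifted genes does not induce composition bias in
#' the remainder. With equal effective transcript lengths, as in the
#' synthetic data, CPM and TPM coincide, so `avg_log2tpm_*` columns are on
#' the log2(TPM + 1) scale used by the screen's expression criteria.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Character/factor of length `ncol(counts)`.
#' @param group_a,group_b The two group labels to contrast (default the
#'   first two unique labels).
#' @return Tibble with `gene`, `log2fc`, `p`, `q`, `avg_log2tpm_a`,
#'   `avg_log2tpm_b`.
#' @export
diff_expression <- function(counts, groups, group_a = NULL, group_b = NULL) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (is.null(group_a)) group_a <- lev[1]
  if (is.null(group_b)) group_b <- lev[2]
  sel <- groups %in% c(group_a, group_b)
  counts <- counts[, sel, drop = FALSE]
  groups <- groups[sel]
  eff_lib <- colSums(counts) * edgeR::calcNormFactors(counts)
  logcpm <- log2(t(t(counts) / eff_lib) * 1e6 + 1)
  design <- cbind(b = 1, a_vs_b = as.integer(groups == group_a))
  fit <- limma::eBayes(limma::lmFit(logcpm, design), trend = TRUE)
  tt <- limma::topTable(fit, coef = "a_vs_b", number = Inf, sort.by = "none")
  tibble(
    gene = rownames(counts),
    log2fc = tt$logFC,
    p = tt$P.Value,
    q = tt$adj.P.Val,
    avg_log2tpm_a = rowMeans(logcpm[, groups == group_a, drop = FALSE]),
    avg_log2tpm_b = rowMeans(logcpm[, groups == group_b, drop = FALSE])
  )
}

#' Thresholds of the four-criteria candidate screen
#'
#' Defaults: a TF counts as expressed at mean log2(TPM + 1) >= 1
#' (criterion IV); its motif is enriched at TBA z >= 1 (criterion II); its
#' footprint is occupied when the differential-footprint recovery AUC
#' exceeds the permutation-null mean (criterion III); and its targets are
#' expressed when at least one occupied target gene is differential at
#' BH q < 0.05 (criterion I).
#'
#' @param tf_expr_min Minimum mean log2(TPM + 1) of the TF.
#' @param tba_z_min Minimum TBA enrichment z-score.
#' @param de_q_max Maximum BH q for a target gene to count as
#'   differentially expressed.
#' @param min_lr Motif-match likelihood-ratio threshold for footprint
#'   sites.
#' @param depth Recovery-AUC rank cutoff.
#' @return Named list of thresholds.
#' @export
screen_thresholds <- function(tf_expr_min = 1, tba_z_min = 1, de_q_max = 0.05,
                              min_lr = 10, depth = 1000L) {
  list(
    tf_expr_min = tf_expr_min, tba_z_min = tba_z_min, de_q_max = de_q_max,
    min_lr = min_lr, depth = as.integer(depth)
  )
}

#' Integrate the four evidence layers into a ranked candidate-TF table
#'
#' Combines motif enrichment (TBA z-scores), differential-footprint AUC,
#' TF expression and target-gene differential expression into one record per
#' TF with the four criteria flags and a combined rank: TFs passing all four
#' flags first, ordered by decreasing footprint AUC, then decreasing TBA z;
#' the remaining TFs follow in the same order. A TF missing an evidence
#' layer is emitted with `incomplete = TRUE` (never dropped) and cannot
#' pass.
#'
#' @param enrichment Tibble `pwm`, `auc`, `z` (see [tba_enrichment()]).
#' @param footprint Tibble `pwm`, `fp_auc`, `fp_null_mean` (AUC of
#'   differential footprint recovery of the target promoters and the
#'   expectation of its permutation null, see
#'   [differential_footprint_auc()] and [null_auc_mean()]).
#' @param de [diff_expression()] result for the subset contrast.
#' @param targets Tibble `pwm`, `gene`: the footprint-occupied target genes
#'   per PWM.
#' @param tra_genes TRA gene list (splits target counts).
#' @param pwm_tf Tibble `pwm`, `tf` mapping motifs to TF gene ids; default
#'   identity.
#' @param thresholds See [screen_thresholds()].
#' @return A tibble of class `candidate_screen`, one row per TF: evidence
#'   columns, flags `flag_target_de`, `flag_motif`, `flag_footprint`,
#'   `flag_tf_expr`, `pass`, `incomplete` and `rank`.
#' @export
candidate_screen <- function(enrichment, footprint, de, targets, tra_genes = character(),
                             pwm_tf = NULL, thresholds = screen_thresholds()) {
  stopifnot(all(c("pwm", "z") %in% names(enrichment)))
  stopifnot(all(c("pwm", "fp_auc", "fp_null_mean") %in% names(footprint)))
  if (is.null(pwm_tf)) {
    ids <- union(union(enrichment$pwm, footprint$pwm), unique(targets$pwm))
    pwm_tf <- tibble(pwm = sort(ids), tf = sort(ids))
  }
  missing_tf <- setdiff(pwm_tf$tf, de$gene)
  if (length(missing_tf) > 0) {
    abort(paste(
      "candidate_screen: TF(s) absent from the expression universe:",
      paste(missing_tf, collapse = ", ")
    ))
  }

  tgt <- as_tibble(targets)
  tgt <- left_join(tgt, de[, c("gene", "log2fc", "q")], by = "gene")
  tgt_sum <- tgt |>
    group_by(.data$pwm) |>
    summarise(
      n_targets_tra = sum(.data$gene %in% tra_genes),
      n_targets_nontra = sum(!.data$gene %in% tra_genes),
      any_target_de = any(.data$q < thresholds$de_q_max, na.rm = TRUE),
      .groups = "drop"
    )

  rec <- pwm_tf |>
    left_join(enrichment[, c("pwm", "z")], by = "pwm") |>
    rename(tba_z = "z") |>
    left_join(footprint[, c("pwm", "fp_auc", "fp_null_mean")], by = "pwm") |>
    left_join(
      de |>
        select(tf = "gene", tf_expr_log2tpm = "avg_log2tpm_a", tf_log2fc = "log2fc"),
      by = "tf"
    ) |>
    left_join(tgt_sum, by = "pwm") |>
    mutate(
      n_targets_tra = ifelse(is.na(.data$n_targets_tra), 0L, .data$n_targets_tra),
      n_targets_nontra = ifelse(is.na(.data$n_targets_nontra), 0L, .data$n_targets_nontra),
      any_target_de = !is.na(.data$any_target_de) & .data$any_target_de,
      flag_target_de = .data$any_target_de,
      flag_motif = !is.na(.data$tba_z) & .data$tba_z >= thresholds$tba_z_min,
      flag_footprint = !is.na(.data$fp_auc) & .data$fp_auc > .data$fp_null_mean,
      flag_tf_expr = !is.na(.data$tf_expr_log2tpm) &
        .data$tf_expr_log2tpm >= thresholds$tf_expr_min,
      incomplete = is.na(.data$tba_z) | is.na(.data$fp_auc) | is.na(.data$tf_expr_log2tpm),
      pass = !.data$incomplete & .data$flag_target_de & .data$flag_motif &
        .data$flag_footprint & .data$flag_tf_expr
    ) |>
    select(-"any_target_de") |>
    arrange(desc(.data$pass), desc(.data$fp_auc), desc(.data$tba_z), .data$tf) |>
    mutate(rank = row_number())
  class(rec) <- c("candidate_screen", class(rec))
  attr(rec, "thresholds") <- thresholds
  rec
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat(sprintf(
    "<candidate_screen> %d TFs, %d passing all four criteria\n",
    nrow(x), sum(x$pass)
  ))
  NextMethod()
}

#' Target-gene counts by expression direction and TRA status
#'
#' For one TF's footprint-occupied targets, counts genes by the sign of
#' their expression log2 fold change and TRA membership.
#'
#' @param targets Tibble `pwm`, `gene` (occupied targets, one TF or many).
#' @param de [diff_expression()] result.
#' @param tra_genes TRA gene list.
#' @return Tibble per `pwm`: `n_up_tra`, `n_up_nontra`, `n_down_tra`,
#'   `n_down_nontra`, `n_total`.
#' @export
target_fc_summary <- function(targets, de, tra_genes = character()) {
  tgt <- as_tibble(targets) |>
    left_join(de[, c("gene", "log2fc")], by = "gene") |>
    mutate(
      tra = .data$gene %in% tra_genes,
      up = !is.na(.data$log2fc) & .data$log2fc >= 0
    )
  tgt |>
    group_by(.data$pwm) |>
    summarise(
      n_up_tra = sum(.data$up & .data$tra),
      n_up_nontra = sum(.data$up & !.data$tra),
      n_down_tra = sum(!.data$up & .data$tra),
      n_down_nontra = sum(!.data$up & !.data$tra),
      n_total = dplyr::n(),
      .groups = "drop"
    )
}

#' Run the whole screen on a simulated data set
#'
#' Wires the modules end-to-end on [simulate_screen_data()] output: TBA
#' scoring of all promoters against the panel, recovery-AUC enrichment of
#' the TRA list, motif-site footprint scoring on pooled per-condition cut
#' profiles, differential-footprint recovery AUC per PWM, differential
#' expression of the subset contrast, and the four-criteria candidate
#' table. Occupied targets of a PWM are genes whose promoter's best site
#' delta is positive.
#'
#' @param sim Output of [simulate_screen_data()].
#' @param thresholds See [screen_thresholds()].
#' @return Object of class `tec_screen`: list with `candidates`,
#'   `enrichment`, `footprint`, `de`, `targets`, `truth`, `config`.
#' @export
run_screen <- function(sim, thresholds = screen_thresholds()) {
  cfg <- sim$config
  tra <- sim_tra_genes(cfg)
  depth <- min(thresholds$depth, cfg$n_genes)

  tba_tbl <- tba_table(sim$promoters, sim$pwms, background = cfg$background)
  enrich <- tba_enrichment(tba_tbl, tra, depth = depth)

  sites <- scan_sites(sim$promoters, sim$pwms,
    min_lr = thresholds$min_lr, background = cfg$background
  )
  conds <- sim_conditions(cfg)
  cond_a <- grep("^tspan8pos", conds, value = TRUE)[1]
  cond_b <- grep("^tspan8neg", conds, value = TRUE)[1]
  ctg_len <- attr(sim$promoters, "contig_lengths")
  prof_a <- cut_sites(sim$atac[sim$atac$condition == cond_a, ], ctg_len)
  prof_b <- cut_sites(sim$atac[sim$atac$condition == cond_b, ], ctg_len)

  # map promoter-relative hits to contig coordinates
  pr <- sim$promoters
  gi <- match(sites$gene, pr$gene)
  sites$contig <- pr$contig[gi]
  sites$start <- ifelse(
    pr$strand[gi] == "-",
    pr$promoter_end[gi] - sites$offset - sites$width,
    pr$promoter_start[gi] + sites$offset
  )
  dfp <- differential_footprint(prof_a, prof_b, sites)

  fp <- dfp$promoters |>
    group_by(.data$pwm) |>
    summarise(
      fp_auc = tryCatch(
        suppressWarnings(
          differential_footprint_auc(dplyr::pick("gene", "delta"), tra, depth = depth)$auc
        ),
        error = function(e) NA_real_ # no TRA promoter carries a site
      ),
      fp_null_mean = null_auc_mean(dplyr::n(), depth = depth),
      .groups = "drop"
    )

  de <- diff_expression(
    sim$expression$counts, sim$expression$samples$group, "tspan8pos", "tspan8neg"
  )
  targets <- dfp$promoters |>
    filter(.data$delta > 0) |>
    select("pwm", "gene")

  cand <- candidate_screen(
    enrich, fp, de, targets,
    tra_genes = tra, thresholds = thresholds
  )
  structure(
    list(
      candidates = cand, enrichment = enrich, footprint = fp, de = de,
      targets = targets, truth = sim$truth, config = cfg
    ),
    class = "tec_screen"
  )
}

#' @export
print.tec_screen <- function(x, ...) {
  cat(sprintf(
    "<tec_screen> %d genes, %d PWMs; top candidates: %s\n",
    x$config$n_genes, nrow(x$candidates),
    paste(utils::head(x$candidates$tf, 3), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.tec_screen <- function(x, ...) as_tibble(x$candidates)

#' @export
glance.tec_screen <- function(x, ...) {
  tibble(
    n_tfs = nrow(x$candidates),
    n_pass = sum(x$candidates$pass),
    top_tf = x$candidates$tf[1],
    top_fp_auc = x$candidates$fp_auc[1],
    n_de_genes = sum(x$de$q < attr(x$candidates, "thresholds")$de_q_max, na.rm = TRUE)
  )
}
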