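#' Rank genes by TBA score for one PWM
#'
#' Decreasing TBA; ties broken by gene id ascending, so the order is a
#' deterministic function of the scores alone (row order of the input is
#' irrelevant).
#'
#' @param tba_tbl A tibble from [tba_table()] (column `gene` plus one column
#'   per PWM).
#' @param pwm Column (PWM id) to rank by.
#' @return Character vector of gene ids, best-scoring first.
#' @export
rank_genes <- function(tba_tbl, pwm) {
  if (!pwm %in% names(tba_tbl)) {
    abort(sprintf("PWM column '%s' not present in the TBA table", pwm))
  }
  ord <- order(-tba_tbl[[pwm]], tba_tbl$gene, method = "radix")
  tba_tbl$gene[ord]
}

#' Recovery curve and AUC of a target gene set along a ranking
#'
#' `recovered[x]` is the fraction of the target set found at rank `<= x`.
#' The AUC averages the curve over the first `depth` ranks, so instantaneous
#' recovery of the whole target set tends to 1 and an empty overlap gives 0.
#' Targets absent from the ranked universe are dropped before computing the
#' curve; a depth larger than the universe is clipped with a warning.
#'
#' @param ranked Character vector of gene ids, best first (see
#'   [rank_genes()]).
#' @param targets Character vector, the target gene set (non-empty after
#'   intersection with `ranked`).
#' @param depth Rank cutoff for the AUC (default 1000).
#' @return An object of class `recovery_curve`: list with `curve` (tibble
#'   `rank`, `recovered`), `auc`, `depth`, `n_targets`.
#' @examples
#' rc <- recovery_auc(paste0("g", 1:2000), paste0("g", 1:10), depth = 1000)
#' rc$auc # 0.9955
#' @export
recovery_auc <- function(ranked, targets, depth = 1000L) {
  targets <- unique(targets)
  targets <- targets[targets %in% ranked]
  if (length(targets) == 0L) {
    abort("recovery_auc: no target genes present in the ranked universe")
  }
  if (depth < 1L) abort("depth must be >= 1")
  if (depth > length(ranked)) {
    warn(sprintf(
      "depth %d exceeds universe size %d; clipping", depth, length(ranked)
    ))
    depth <- length(ranked)
  }
  hits <- cumsum(ranked %in% targets) / length(targets)
  curve <- tibble(rank = seq_len(depth), recovered = hits[seq_len(depth)])
  structure(
    list(
      curve = curve, auc = mean(curve$recovered),
      depth = as.integer(depth), n_targets = length(targets)
    ),
    class = "recovery_curve"
  )
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf(
    "<recovery_curve> %d targets, depth %d, AUC %.4f\n",
    x$n_targets, x$depth, x$auc
  ))
  invisible(x)
}

#' Expected recovery AUC under a random ranking
#'
#' The mean of [recovery_auc()] when target positions are exchangeable
#' (equivalently, the mean over rank permutations): `(depth + 1) / (2 n)`
#' for a universe of `n` genes.
#'
#' @param n_universe Number of genes in the ranked universe.
#' @param depth Rank cutoff.
#' @return Scalar expectation.
#' @export
null_auc_mean <- function(n_universe, depth = 1000L) {
  depth <- min(depth, n_universe)
  (depth + 1) / (2 * n_universe)
}

#' Standardize AUCs across a PWM panel
#'
#' Converts per-PWM AUC values into z-scores using the panel mean and
#' population standard deviation, so the panel itself is the calibration:
#' `mean(z) = 0`, `sd_pop(z) = 1`. A degenerate panel (all AUCs equal) gets
#' all-zero z with a `degenerate` flag.
#'
#' @param aucs Named numeric vector (names = PWM ids) or a tibble with
#'   columns `pwm` and `auc`.
#' @return Tibble with columns `pwm`, `auc`, `z` and attribute `degenerate`.
#' @export
auc_zscores <- function(aucs) {
  if (is.data.frame(aucs)) {
    stopifnot(all(c("pwm", "auc") %in% names(aucs)))
    tbl <- as_tibble(aucs[c("pwm", "auc")])
  } else {
    if (is.null(names(aucs))) abort("aucs must be named by PWM id")
    tbl <- tibble(pwm = names(aucs), auc = unname(aucs))
  }
  n <- nrow(tbl)
  if (n < 2L) abort("auc_zscores needs at least 2 PWMs")
  mu <- mean(tbl$auc)
  sd_pop <- sqrt(mean((tbl$auc - mu)^2))
  degenerate <- sd_pop == 0
  if (degenerate) {
    warn("auc_zscores: zero standard deviation across the panel; all z set to 0")
    tbl$z <- rep(0, n)
  } else {
    tbl$z <- (tbl$auc - mu) / sd_pop
  }
  attr(tbl, "degenerate") <- degenerate
  tbl
}

#' Recovery-curve enrichment of a target set for every PWM in a TBA table
#'
#' Ranks genes per PWM by TBA ([rank_genes()]), computes the recovery AUC of
#' `targets` over the first `depth` ranks, and standardizes the AUCs across
#' the panel ([auc_zscores()]).
#'
#' @inheritParams rank_genes
#' @inheritParams recovery_auc
#' @return Tibble with columns `pwm`, `auc`, `z`.
#' @export
tba_enrichment <- function(tba_tbl, targets, depth = 1000L) {
  ids <- setdiff(names(tba_tbl), "gene")
  aucs <- vapply(
    ids,
    function(p) recovery_auc(rank_genes(tba_tbl, p), targets, depth = depth)$auc,
    numeric(1)
  )
  auc_zscores(aucs)
}

#' @export
tidy.recovery_curve <- function(x, ...) x$curve

#' @export
glance.recovery_curve <- function(x, ...) {
  tibble(auc = x$auc, depth = x$depth, n_targets = x$n_targets)
}
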