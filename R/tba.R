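.check_background <- function(background) {
  if (length(background) != 4L || any(!is.finite(background)) || any(background <= 0)) {
    abort("background must be 4 strictly positive base probabilities (A,C,G,T)")
  }
  background / sum(background)
}

#' Empirical 0-order background from promoter sequences
#'
#' @param promoters Tibble with a `sequence` column (see
#'   [extract_promoters()]) or a character vector of sequences.
#' @return Named numeric vector of A,C,G,T frequencies (N ignored).
#' @export
base_background <- function(promoters) {
  seqs <- if (is.data.frame(promoters)) promoters$sequence else promoters
  f <- colSums(Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), c("A", "C", "G", "T")))
  f / sum(f)
}

# log likelihood-ratio matrices for forward and reverse-complement scanning
.logratio_mats <- function(pwm, background) {
  bg <- .check_background(background)
  lf <- log(sweep(pwm$probs, 2, bg, "/"))
  w <- nrow(lf)
  lr <- lf[w:1, 4:1, drop = FALSE] # reverse positions, complement bases
  list(lf = lf, lr = lr)
}

#' Likelihood ratio of a PWM on a single window
#'
#' The product over motif positions of `p_pwm(base) / p_bg(base)`. Windows
#' containing any non-ACGT character score 0.
#'
#' @param pwm A [pwm()] object.
#' @param window Character scalar of length exactly `pwm$width`.
#' @param background Base probabilities (A,C,G,T), default uniform.
#' @return A non-negative scalar.
#' @examples
#' p <- pwm(matrix(rep(c(1, 0, 0, 0), 2), nrow = 2, byrow = TRUE), pseudocount = 0)
#' likelihood_ratio(p, "AA") # (1 / 0.25)^2 = 16
#' @export
likelihood_ratio <- function(pwm, window, background = rep(0.25, 4)) {
  stopifnot(inherits(pwm, "pwm"))
  bg <- .check_background(background)
  ch <- strsplit(toupper(window), "")[[1]]
  if (length(ch) != pwm$width) {
    abort(sprintf(
      "window length %d does not match PWM width %d",
      length(ch), pwm$width
    ))
  }
  idx <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(0)
  prod(pwm$probs[cbind(seq_along(idx), idx)] / bg[idx])
}

#' Total binding affinity of a promoter for one PWM
#'
#' TBA is the sum, over every window start of the promoter, of the larger of
#' the two strand likelihood ratios of that window (forward window vs its
#' reverse complement). Summation is on the linear likelihood-ratio scale by
#' default; `log_scale = TRUE` sums per-window log likelihood ratios instead
#' (a sensitivity-analysis variant, not the default statistic).
#'
#' @inheritParams likelihood_ratio
#' @param sequence Promoter sequence (character scalar).
#' @param log_scale Sum log-LRs instead of LRs.
#' @return A non-negative scalar (log-scale TBA may be negative). Promoters
#'   shorter than the PWM width score 0 with a warning.
#' @export
tba <- function(pwm, sequence, background = rep(0.25, 4), log_scale = FALSE) {
  stopifnot(inherits(pwm, "pwm"), is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < pwm$width) {
    warn(sprintf("promoter shorter than PWM '%s' width; TBA set to 0", pwm$id))
    return(0)
  }
  m <- .logratio_mats(pwm, background)
  res <- .scan_pwm_cpp(sequence, m$lf, m$lr, Inf, FALSE)
  if (log_scale) res$tba_log[1] else res$tba[1]
}

#' TBA scores for a promoter set against a PWM panel
#'
#' @param promoters Tibble with `gene` and `sequence` columns (see
#'   [extract_promoters()]), or a named character vector of sequences.
#' @param pwms List of [pwm()] objects (see [read_pwm()]).
#' @inheritParams tba
#' @return A tibble, one row per gene, one column per PWM id, all entries
#'   non-negative.
#' @export
tba_table <- function(promoters, pwms, background = rep(0.25, 4), log_scale = FALSE) {
  pr <- .as_promoter_seqs(promoters)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  out <- tibble(gene = pr$gene)
  for (p in pwms) {
    if (any(nchar(pr$sequence) < p$width)) {
      warn(sprintf("promoter(s) shorter than PWM '%s'; TBA set to 0 there", p$id))
    }
    m <- .logratio_mats(p, background)
    res <- .scan_pwm_cpp(pr$sequence, m$lf, m$lr, Inf, FALSE)
    out[[p$id]] <- res$tba
  }
  out
}

#' Motif match sites in promoters above a likelihood-ratio threshold
#'
#' Scans both strands of every promoter and reports windows whose best-strand
#' likelihood ratio reaches `min_lr` (default 10, the match threshold used
#' when selecting sites for footprint scoring).
#'
#' @inheritParams tba_table
#' @param min_lr Minimum likelihood ratio for a reported site.
#' @return Tibble with `gene`, `pwm`, `offset` (0-based window start within
#'   the promoter, read in gene orientation), `strand` (`+` forward match,
#'   `-` reverse-complement match), `width`, `lr`.
#' @export
scan_sites <- function(promoters, pwms, min_lr = 10, background = rep(0.25, 4)) {
  pr <- .as_promoter_seqs(promoters)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  rows <- lapply(pwms, function(p) {
    m <- .logratio_mats(p, background)
    res <- .scan_pwm_cpp(pr$sequence, m$lf, m$lr, min_lr, TRUE)
    tibble(
      gene = pr$gene[res$hit_seq],
      pwm = p$id,
      offset = res$hit_pos,
      strand = ifelse(res$hit_strand > 0, "+", "-"),
      width = p$width,
      lr = res$hit_lr
    )
  })
  bind_rows(rows)
}

.as_promoter_seqs <- function(promoters) {
  if (is.data.frame(promoters)) {
    stopifnot(all(c("gene", "sequence") %in% names(promoters)))
    promoters
  } else {
    if (is.null(names(promoters))) {
      abort("promoters must be a data frame or a named character vector")
    }
    tibble(gene = names(promoters), sequence = unname(promoters))
  }
}
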