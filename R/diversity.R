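#' Shannon-Weaver diversity of expression proportions
#'
#' `H = -sum(p * log(p))` with `0 * log(0) = 0`. Counts are renormalized to
#' proportions; the natural log is the default (`base = 2` available).
#'
#' @param x Non-negative counts or proportions.
#' @param base Logarithm base (default `exp(1)`, nats).
#' @return Scalar in `[0, log(length(x))]`.
#' @export
shannon_index <- function(x, base = exp(1)) {
  p <- .as_proportions(x)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Inverse Simpson diversity (effective gene number)
#'
#' `D = 1 / sum(p^2)`; ranges from 1 (one gene holds all mass) to
#' `length(x)` (uniform).
#'
#' @inheritParams shannon_index
#' @return Scalar in `[1, length(x)]`.
#' @export
inverse_simpson <- function(x) {
  p <- .as_proportions(x)
  1 / sum(p^2)
}

.as_proportions <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("diversity indices need finite, non-negative counts or proportions")
  }
  s <- sum(x)
  if (s == 0) abort("diversity indices are undefined for all-zero counts")
  x / s
}

#' Expression diversity per sample and gene category, with a group test
#'
#' Computes Shannon and inverse-Simpson diversity of within-category
#' expression proportions for every sample, over the categories `all`, `TRA`
#' and `non-TRA`, and compares two sample groups (e.g. knockout vs control)
#' by the difference of per-sample means with a label-permutation p-value.
#' Empty categories are skipped with a warning.
#'
#' @param counts Gene x sample count matrix (rownames = gene ids).
#' @param groups Factor/character of length `ncol(counts)` with exactly two
#'   levels for the comparison (e.g. `"ctrl"`, `"ko"`); `NULL` skips the
#'   test.
#' @param tra_genes Character vector of TRA gene ids.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional seed for the permutation draw.
#' @return An object of class `diversity_result`: list with `values`
#'   (tibble `sample`, `group`, `category`, `shannon`, `inv_simpson`) and
#'   `comparison` (tibble `category`, `index`, `diff`, `p`; `NULL` without
#'   groups). `tidy()` returns the values, `glance()` the comparison.
#' @export
diversity_by_category <- function(counts, groups = NULL, tra_genes = character(),
                                  n_perm = 1000L, seed = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("counts must have gene ids as rownames")
  cats <- list(
    all = rownames(counts),
    TRA = intersect(rownames(counts), tra_genes),
    `non-TRA` = setdiff(rownames(counts), tra_genes)
  )
  empty <- names(cats)[lengths(cats) == 0L]
  if (length(empty) > 0L) {
    warn(paste("diversity_by_category: skipping empty categories:", paste(empty, collapse = ", ")))
    cats <- cats[lengths(cats) > 0L]
  }
  samples <- colnames(counts)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(counts)))
  vals <- list()
  for (cat_name in names(cats)) {
    sub <- counts[cats[[cat_name]], , drop = FALSE]
    ok <- colSums(sub) > 0
    if (!all(ok)) {
      warn(sprintf("diversity_by_category: %d sample(s) with zero counts in '%s' skipped", sum(!ok), cat_name))
    }
    vals[[cat_name]] <- tibble(
      sample = samples[ok],
      group = if (!is.null(groups)) as.character(groups)[ok] else NA_character_,
      category = cat_name,
      shannon = unname(apply(sub[, ok, drop = FALSE], 2, shannon_index)),
      inv_simpson = unname(apply(sub[, ok, drop = FALSE], 2, inverse_simpson))
    )
  }
  values <- bind_rows(vals)
  comparison <- NULL
  if (!is.null(groups)) {
    lev <- unique(as.character(groups))
    if (length(lev) != 2L) abort("diversity_by_category: groups must have exactly two levels")
    if (!is.null(seed)) set.seed(seed)
    comparison <- list_rbind(lapply(names(cats), function(cat_name) {
      v <- values[values$category == cat_name, ]
      list_rbind(lapply(c("shannon", "inv_simpson"), function(ix) {
        x <- v[[ix]]
        g <- v$group
        obs <- mean(x[g == lev[1]]) - mean(x[g == lev[2]])
        perm <- vapply(seq_len(n_perm), function(i) {
          gp <- sample(g)
          mean(x[gp == lev[1]]) - mean(x[gp == lev[2]])
        }, numeric(1))
        tibble(
          category = cat_name, index = ix, diff = obs,
          p = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
        )
      }))
    }))
  }
  structure(
    list(values = values, comparison = comparison),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result>\n")
  print(x$values, n = 6)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' @export
tidy.diversity_result <- function(x, ...) x$values

#' @export
glance.diversity_result <- function(x, ...) {
  if (is.null(x$comparison)) tibble() else x$comparison
}

#' Knockout effect size from mean cell counts
#'
#' Fold change `mean_ctrl / mean_ko` rounded to one decimal and percent
#' reduction `100 * (mean_ctrl - mean_ko) / mean_ctrl` rounded to the
#' nearest integer, the summary used for FACS population counts.
#'
#' @param mean_ctrl,mean_ko Positive mean counts (vectorized).
#' @param population Optional population labels.
#' @return Tibble with `population`, `mean_ctrl`, `mean_ko`, `fold_change`,
#'   `pct_reduction`.
#' @examples
#' ko_effect(1861, 527, "Dclk1+ Tuft-mTEC") # fold change 3.5
#' @export
ko_effect <- function(mean_ctrl, mean_ko, population = NA_character_) {
  if (any(!is.finite(mean_ctrl)) || any(!is.finite(mean_ko)) ||
    any(mean_ctrl <= 0) || any(mean_ko <= 0)) {
    abort("ko_effect: means must be positive")
  }
  tibble(
    population = population,
    mean_ctrl = mean_ctrl,
    mean_ko = mean_ko,
    fold_change = round(mean_ctrl / mean_ko, 1),
    pct_reduction = round(100 * (mean_ctrl - mean_ko) / mean_ctrl)
  )
}
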