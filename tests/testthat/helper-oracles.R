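# Brute-force double-strand TBA oracle: enumerate windows with substr and
# score each strand through likelihood_ratio(). Deliberately naive and
# independent of the compiled scanner.
naive_tba <- function(pwm, sequence, background = rep(0.25, 4), log_scale = FALSE) {
  w <- pwm$width
  n <- nchar(sequence)
  if (n < w) return(0)
  total <- 0
  for (i in seq_len(n - w + 1L)) {
    win <- substr(sequence, i, i + w - 1L)
    lr <- max(
      likelihood_ratio(pwm, win, background),
      likelihood_ratio(pwm, revcomp(win), background)
    )
    total <- total + if (log_scale) log(lr) else lr
  }
  total
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

rand_pwm <- function(width, id = "p") {
  m <- matrix(stats::rgamma(width * 4, shape = 1), nrow = width)
  pwm(m / rowSums(m), id = id, pseudocount = 0.01)
}

# fabricate a cut_profile directly (unit tests of the scoring arithmetic)
fake_profile <- function(counts, contig = "chr1", norm_factor = NULL) {
  total <- sum(counts)
  structure(
    list(
      counts = setNames(list(counts), contig), total = total,
      n_fragments = total / 2, n_dropped = 0L,
      norm_factor = if (is.null(norm_factor)) 1e6 / total else norm_factor
    ),
    class = "cut_profile"
  )
}
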