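#' Construct a position weight matrix
#'
#' A PWM is stored as a `W x 4` matrix of per-position base probabilities
#' (columns `A`, `C`, `G`, `T`). Count matrices are converted to
#' probabilities after adding `pseudocount` to every cell, so that no
#' affinity is exactly zero unless `pseudocount = 0`.
#'
#' @param mat Numeric `W x 4` matrix of counts or probabilities, rows =
#'   motif positions, columns in A, C, G, T order.
#' @param id Motif identifier.
#' @param pseudocount Mass added to each cell before per-position
#'   normalization (default 0.01).
#' @return An object of class `pwm`: list with `id`, `probs`, `width`,
#'   `pseudocount`.
#' @examples
#' m <- matrix(c(10, 0, 0, 0), nrow = 1)
#' pwm(m, "A_only", pseudocount = 0)
#' @export
pwm <- function(mat, id = "pwm", pseudocount = 0.01) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) {
    abort(sprintf("PWM '%s': expected 4 columns (A,C,G,T), got %d", id, ncol(mat)))
  }
  if (nrow(mat) < 1L) abort(sprintf("PWM '%s': width must be >= 1", id))
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort(sprintf("PWM '%s': entries must be finite and non-negative", id))
  }
  mat <- mat + pseudocount
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    abort(sprintf("PWM '%s': a position has zero total mass (use pseudocount > 0)", id))
  }
  probs <- mat / rs
  dimnames(probs) <- list(NULL, c("A", "C", "G", "T"))
  structure(
    list(id = id, probs = probs, width = nrow(probs), pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  width %d  pseudocount %g\n", x$id, x$width, x$pseudocount))
  print(round(x$probs, 3))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The most probable base at each position; ties resolved in A,C,G,T order.
#'
#' @param x A [pwm()] object.
#' @return A character scalar of length `x$width`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(colnames(x$probs)[apply(x$probs, 1, which.max)], collapse = "")
}

#' Read PWMs from a JASPAR-style or tabular file
#'
#' Two plain-text layouts are supported. `jaspar`: a `>id` header followed by
#' four lines `A [ n n ... ]`, `C [...]`, `G [...]`, `T [...]` (brackets
#' optional). `tab`: a `>id` header followed by one whitespace-separated row
#' of four numbers (A C G T) per motif position. Values may be counts or
#' probabilities; both are pseudocounted and renormalized per position.
#'
#' @param path File to read.
#' @param format `"jaspar"` or `"tab"`.
#' @inheritParams pwm
#' @return A named list of [pwm()] objects.
#' @export
read_pwm <- function(path, format = c("jaspar", "tab"), pseudocount = 0.01) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  lines <- lines[keep]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    abort(sprintf("%s: no '>' motif headers found", path))
  }
  bounds <- c(headers, length(lines) + 1L)
  pwms <- vector("list", length(headers))
  for (k in seq_along(headers)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block_lines <- idx[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    id <- sub("^>\\s*", "", lines[headers[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    mat <- if (format == "jaspar") {
      .parse_jaspar_block(block, block_lines, path)
    } else {
      .parse_tab_block(block, block_lines, path)
    }
    pwms[[k]] <- pwm(mat, id = id, pseudocount = pseudocount)
  }
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  pwms
}

.parse_num_row <- function(line, lineno, path) {
  stripped <- gsub("[][]", " ", line)
  stripped <- sub("^\\s*[ACGTacgt]\\s+", " ", stripped)
  vals <- suppressWarnings(as.numeric(strsplit(trimws(stripped), "\\s+")[[1]]))
  if (any(is.na(vals))) {
    abort(sprintf("%s line %d: non-numeric matrix entry", path, lineno))
  }
  vals
}

.parse_jaspar_block <- function(block, linenos, path) {
  if (length(block) != 4L) {
    abort(sprintf(
      "%s near line %d: expected 4 base rows (A,C,G,T), got %d",
      path, linenos[1], length(block)
    ))
  }
  rows <- lapply(seq_along(block), function(i) .parse_num_row(block[i], linenos[i], path))
  w <- lengths(rows)
  if (length(unique(w)) != 1L) {
    abort(sprintf("%s line %d: ragged matrix rows", path, linenos[1]))
  }
  t(do.call(rbind, rows)) # -> W x 4
}

.parse_tab_block <- function(block, linenos, path) {
  rows <- lapply(seq_along(block), function(i) {
    v <- .parse_num_row(block[i], linenos[i], path)
    if (length(v) != 4L) {
      abort(sprintf("%s line %d: expected 4 columns (A,C,G,T), got %d", path, linenos[i], length(v)))
    }
    v
  })
  do.call(rbind, rows)
}

#' Write PWMs to a plain-text file
#'
#' Writes base probabilities at full double precision so that a
#' `read_pwm(..., pseudocount = 0)` round trip reproduces them exactly.
#'
#' @param pwms A [pwm()] object or list of them.
#' @param path Output file.
#' @param format `"jaspar"` (four `A [...]` rows) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path, format = c("jaspar", "tab")) {
  format <- match.arg(format)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    if (format == "jaspar") {
      for (b in c("A", "C", "G", "T")) {
        writeLines(
          sprintf("%s [ %s ]", b, paste(format(p$probs[, b], digits = 17), collapse = " ")),
          con
        )
      }
    } else {
      writeLines(apply(p$probs, 1, function(r) paste(format(r, digits = 17), collapse = "\t")), con)
    }
  }
  invisible(path)
}
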