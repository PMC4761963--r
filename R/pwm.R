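#' Position weight matrix
#'
#' Constructs a position weight matrix (PWM) object from a width x 4 matrix of
#' per-position base frequencies. The information vector
#' \eqn{I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))} (with \eqn{0\ln 0 := 0}) and the
#' 5-position core (the consecutive window of maximal summed information) are
#' derived at construction time and stored on the object.
#'
#' @param id Single string identifying the matrix.
#' @param freq Numeric matrix, one row per motif position, columns A, C, G, T.
#'   Rows must be nonnegative and sum to 1 within `1e-9`.
#' @param tf_names Character vector of transcription-factor names associated
#'   with the matrix (used when linking binding sites to coding genes).
#' @return An object of class `"pwm"`: a list with elements `id`, `tf_names`,
#'   `freq`, `info` (information vector), `core_start` (1-based index of the
#'   first of the 5 core positions) and `width`.
#' @examples
#' f <- matrix(c(1, 0, 0, 0,
#'               0, 1, 0, 0,
#'               .5, .5, 0, 0,
#'               .25, .25, .25, .25,
#'               0, 0, 0, 1), ncol = 4, byrow = TRUE)
#' m <- pwm("M1", f)
#' m$info
#' consensus(m)
#' @export
pwm <- function(id, freq, tf_names = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  freq <- as.matrix(freq)
  if (ncol(freq) != 4L) stop("`freq` must have 4 columns (A, C, G, T)")
  if (nrow(freq) < 5L) {
    stop("PWM '", id, "' has width ", nrow(freq),
         "; at least 5 positions are required for the core")
  }
  colnames(freq) <- DNA_BASES
  rownames(freq) <- NULL
  info <- information_vector(freq)
  structure(
    list(id = id, tf_names = as.character(tf_names), freq = freq,
         info = info, core_start = core_start(info), width = nrow(freq)),
    class = "pwm"
  )
}

#' Per-position information vector of a frequency matrix
#'
#' Computes \eqn{I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))} for every row, the
#' information-content weight used in MATCH-style similarity scoring. A uniform
#' row scores 0; a degenerate row (one base with probability 1) scores
#' \eqn{\ln 4}.
#'
#' @param freq Width x 4 matrix of base frequencies; rows must be nonnegative
#'   and sum to 1 within `1e-9`.
#' @return Numeric vector of per-position weights, all `>= 0`.
#' @export
information_vector <- function(freq) {
  freq <- as.matrix(freq)
  if (any(freq < 0)) stop("frequencies must be nonnegative")
  rs <- rowSums(freq)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("each frequency row must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  term <- freq * log(4 * freq)
  term[freq == 0] <- 0
  pmax(rowSums(term), 0)
}

# 1-based start of the 5 consecutive positions maximizing summed information;
# ties broken leftmost.
core_start <- function(info, core_width = 5L) {
  w <- length(info)
  stopifnot(w >= core_width)
  sums <- vapply(seq_len(w - core_width + 1L),
                 function(i) sum(info[i:(i + core_width - 1L)]), numeric(1))
  which.max(sums)
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(width", x$width, ")\n")
  if (length(x$tf_names)) cat("  TFs:", paste(x$tf_names, collapse = ", "), "\n")
  cat("  core positions:", x$core_start, "-", x$core_start + 4L, "\n")
  cat("  consensus:", consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The per-position argmax base (ties broken in A, C, G, T order).
#'
#' @param x A [pwm()] object.
#' @return A single string of the PWM's width.
#' @export
consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$freq, 1L, which.max)], collapse = "")
}

# anticonsensus: per-position argmin base (used in tests/examples)
anticonsensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$freq, 1L, which.min)], collapse = "")
}
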