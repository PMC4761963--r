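# MATCH-style similarity scoring: information-weighted window scores normalized
# to [0,1] against the best and worst attainable windows of the matrix.

# Per-PWM scoring constants, computed once per scan. The min/max normalizers
# are accumulated position by position in the same order as window scores, so
# a consensus window reaches mss = 1 exactly (no summation-order drift).
pwm_score_parts <- function(pwm) {
  wI <- pwm$info
  contrib <- pwm$freq * wI                      # width x 4: I(i) * f(i, b)
  cmin <- unname(apply(contrib, 1L, min))       # also the 'N' contribution
  cmax <- unname(apply(contrib, 1L, max))
  core <- pwm$core_start:(pwm$core_start + 4L)
  hi <- lo <- hic <- loc <- 0
  for (i in seq_len(pwm$width)) {
    hi <- hi + cmax[i]; lo <- lo + cmin[i]
    if (i >= core[1] && i <= core[5]) {
      hic <- hic + cmax[i]; loc <- loc + cmin[i]
    }
  }
  list(contrib = contrib, cmin = cmin, cmax = cmax, core = core,
       max = hi, min = lo, core_max = hic, core_min = loc)
}

normalize_score <- function(current, lo, hi) {
  if (hi - lo <= 0) return(rep(0, length(current)))
  (current - lo) / (hi - lo)
}

#' Matrix and core similarity scores of one window
#'
#' Scores a single window of the PWM's width: the matrix similarity score (MSS)
#' is the information-weighted sum \eqn{\sum_i I(i) f(i, b_i)} rescaled to
#' `[0, 1]` between the minimal and maximal attainable window scores; the core
#' similarity score (CSS) is the same quantity restricted to the 5 core
#' positions. `N` bases contribute the row minimum, so ambiguity can never
#' create a hit.
#'
#' @param pwm A [pwm()] object.
#' @param window String of exactly the PWM's width over `A,C,G,T,N`.
#' @return Named numeric vector `c(mss = , css = )`, both in `[0, 1]`.
#' @examples
#' m <- pwm("M1", matrix(c(.7,.1,.1,.1, .1,.7,.1,.1, .1,.1,.7,.1,
#'                         .1,.1,.1,.7, .7,.1,.1,.1), ncol = 4, byrow = TRUE))
#' match_score(m, consensus(m))  # mss = css = 1
#' @export
match_score <- function(pwm, window) {
  stopifnot(inherits(pwm, "pwm"), is.character(window), length(window) == 1L)
  codes <- match(strsplit(toupper(window), "", fixed = TRUE)[[1]], DNA_BASES)
  if (length(codes) != pwm$width) {
    stop("window length ", length(codes), " != PWM width ", pwm$width)
  }
  bad <- setdiff(strsplit(toupper(window), "", fixed = TRUE)[[1]],
                 c(DNA_BASES, "N"))
  if (length(bad)) stop("window contains invalid bases: ", paste(bad, collapse = ""))
  p <- pwm_score_parts(pwm)
  cur <- cur_core <- 0
  for (i in seq_len(pwm$width)) {
    v <- if (is.na(codes[i])) p$cmin[i] else unname(p$contrib[i, codes[i]])
    cur <- cur + v
    if (i >= p$core[1] && i <= p$core[5]) cur_core <- cur_core + v
  }
  if (p$max - p$min <= 0 || p$core_max - p$core_min <= 0) {
    warning("PWM '", pwm$id, "' has a zero score range ",
            "(uniform positions); affected scores set to 0")
  }
  c(mss = normalize_score(cur, p$min, p$max),
    css = normalize_score(cur_core, p$core_min, p$core_max))
}

# Vectorized plus-strand scoring of every window of `codes` (integer base
# codes, NA = N). Returns list(mss=, css=) over L - w + 1 windows.
score_all_windows <- function(parts, width, codes) {
  L <- length(codes)
  nw <- L - width + 1L
  cur <- numeric(nw)
  cur_core <- numeric(nw)
  core <- parts$core
  for (i in seq_len(width)) {
    b <- codes[i:(i + nw - 1L)]
    v <- unname(parts$contrib[i, ])[b]
    v[is.na(v)] <- parts$cmin[i]
    cur <- cur + v
    if (i >= core[1] && i <= core[5]) cur_core <- cur_core + v
  }
  list(mss = if (parts$max - parts$min > 0) (cur - parts$min) / (parts$max - parts$min) else rep(0, nw),
       css = if (parts$core_max - parts$core_min > 0)
         (cur_core - parts$core_min) / (parts$core_max - parts$core_min) else rep(0, nw),
       degenerate = parts$max - parts$min <= 0 || parts$core_max - parts$core_min <= 0)
}

#' Scan a promoter sequence with one PWM
#'
#' Scores every window of the PWM's width on both strands (the minus strand
#' scores the reverse complement) and reports windows passing both score
#' cutoffs. Positions are 0-based, half-open, always on the plus strand, so the
#' output is directly BED-compatible.
#'
#' @param pwm A [pwm()] object.
#' @param promoter A single sequence string (A/C/G/T/N).
#' @param mss_cutoff,css_cutoff Minimum matrix / core similarity score in
#'   `[0, 1]` for a window to be reported.
#' @param gene_id Identifier recorded in the `gene_id` column.
#' @return A data frame with columns `gene_id`, `pwm_id`, `start`, `end`
#'   (0-based half-open, plus strand), `strand` (`"+"`/`"-"`), `mss`, `css`,
#'   sorted by `start` then strand. A promoter shorter than the PWM width
#'   yields zero rows.
#' @export
scan_pwm <- function(pwm, promoter, mss_cutoff = 0.85, css_cutoff = 0.90,
                     gene_id = "promoter") {
  stopifnot(inherits(pwm, "pwm"),
            mss_cutoff >= 0, mss_cutoff <= 1, css_cutoff >= 0, css_cutoff <= 1)
  empty <- data.frame(gene_id = character(), pwm_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      mss = numeric(), css = numeric(),
                      stringsAsFactors = FALSE)
  w <- pwm$width
  seq_up <- toupper(promoter)
  L <- nchar(seq_up)
  if (L < w) return(empty)
  parts <- pwm_score_parts(pwm)
  code_of <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
  fwd <- score_all_windows(parts, w, code_of(seq_up))
  rev <- score_all_windows(parts, w, code_of(reverse_complement(seq_up)))
  if (fwd$degenerate) {
    warning("PWM '", pwm$id, "' has a zero score range; all scores set to 0")
  }
  nw <- L - w + 1L
  # window j (1-based) on the reverse complement starts at plus-strand
  # 0-based position L - w - (j - 1)
  hits <- rbind(
    data.frame(start = 0:(nw - 1L), strand = "+",
               mss = fwd$mss, css = fwd$css, stringsAsFactors = FALSE),
    data.frame(start = L - w - (0:(nw - 1L)), strand = "-",
               mss = rev$mss, css = rev$css, stringsAsFactors = FALSE)
  )
  keep <- hits$mss >= mss_cutoff & hits$css >= css_cutoff
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  data.frame(gene_id = gene_id, pwm_id = pwm$id,
             start = as.integer(hits$start),
             end = as.integer(hits$start + w),
             strand = hits$strand, mss = hits$mss, css = hits$css,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan a set of promoters with a collection of PWMs
#'
#' @param pwms List of [pwm()] objects.
#' @param promoters Named character vector of promoter sequences (names are
#'   gene ids), as produced by [simulate_promoters()] or [read_promoters()].
#' @inheritParams scan_pwm
#' @return One data frame of hits in the [scan_pwm()] layout.
#' @export
scan_promoters <- function(pwms, promoters, mss_cutoff = 0.85, css_cutoff = 0.90) {
  stopifnot(length(promoters) > 0, !is.null(names(promoters)),
            all(nzchar(names(promoters))))
  res <- vector("list", length(pwms) * length(promoters))
  k <- 0L
  for (p in pwms) {
    for (g in names(promoters)) {
      k <- k + 1L
      res[[k]] <- scan_pwm(p, promoters[[g]], mss_cutoff, css_cutoff, gene_id = g)
    }
  }
  do.call(rbind, res)
}

#' Write motif hits as a BED6 table
#'
#' One line per hit: gene id as the chromosome field, 0-based half-open
#' coordinates, PWM id as name, `round(1000 * mss)` as score, strand.
#'
#' @param hits Hit data frame from [scan_pwm()]/[scan_promoters()].
#' @param file Output path.
#' @export
write_hits_bed <- function(hits, file) {
  bed <- data.frame(hits$gene_id, hits$start, hits$end, hits$pwm_id,
                    as.integer(round(1000 * hits$mss)), hits$strand)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
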