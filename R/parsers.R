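# Flat-file readers for the two common PWM text dialects. Count matrices are
# converted to frequencies with a pseudocount of 0.01 per cell before row
# normalization, so zero-count cells never force -Inf information weights.

PWM_PSEUDOCOUNT <- 0.01

counts_to_freq <- function(counts, pseudocount = PWM_PSEUDOCOUNT) {
  counts <- as.matrix(counts) + pseudocount
  counts / rowSums(counts)
}

#' Read PWMs from a TRANSFAC-dialect flat file
#'
#' Parses records of the form `DE <id> [tf names...]`, a `PO`/`P0` column
#' header, numbered count rows (`01 ... NN`, optionally ending with a consensus
#' letter), terminated by `XX` and/or `//`. Counts receive a pseudocount of
#' 0.01 per cell and are row-normalized to frequencies.
#'
#' @param file Path to the flat file.
#' @return A named list of [pwm()] objects (names are matrix ids).
#' @export
read_transfac <- function(file) {
  lines <- readLines(file, warn = FALSE)
  pwms <- list()
  id <- NULL; tf <- character(); rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (!length(rows)) stop("TRANSFAC record '", id, "' has no count rows")
    counts <- do.call(rbind, rows)
    pwms[[id]] <<- pwm(id, counts_to_freq(counts), tf_names = tf)
    id <<- NULL; tf <<- character(); rows <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tag <- sub("^(\\S+).*$", "\\1", ln)
    if (tag == "DE") {
      flush()
      parts <- strsplit(ln, "\\s+")[[1]][-1]
      if (!length(parts)) stop("DE line without a matrix id")
      id <- parts[1]
      tf <- parts[-1]
    } else if (tag %in% c("PO", "P0")) {
      next
    } else if (grepl("^[0-9]+$", tag)) {
      nums <- strsplit(ln, "\\s+")[[1]][-1]
      nums <- suppressWarnings(as.numeric(nums))
      nums <- nums[!is.na(nums)]
      if (length(nums) < 4L) stop("count row with fewer than 4 values: '", ln, "'")
      rows[[length(rows) + 1L]] <- nums[1:4]
    } else if (tag %in% c("XX", "//")) {
      flush()
    }
    # other tags (AC, ID, BF, ...) are tolerated and ignored
  }
  flush()
  if (!length(pwms)) stop("no PWM records found in '", file, "'")
  pwms
}

#' Read PWMs from a JASPAR-style counts file
#'
#' Parses records headed by `><id> [name]` followed by four lines of counts,
#' one per base, in `A [ ... ]` or bare `A ...` form. Counts receive a
#' pseudocount of 0.01 per cell and are row-normalized.
#'
#' @param file Path to the JASPAR text file.
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records (no '>' headers) in '", file, "'")
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- list()
  for (k in seq_along(starts)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[starts[k]]), "\\s+")[[1]]
    id <- hdr[1]
    tf <- hdr[-1]
    body <- lines[(starts[k] + 1L):ends[k]]
    base_rows <- list()
    for (ln in body) {
      b <- toupper(sub("^([ACGTacgt]).*$", "\\1", ln))
      if (!b %in% DNA_BASES) next
      nums <- gsub("[^0-9eE+. -]", " ", sub("^[ACGTacgt]", "", ln))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      base_rows[[b]] <- vals[!is.na(vals)]
    }
    if (length(base_rows) != 4L) {
      stop("JASPAR record '", id, "' does not have 4 base rows")
    }
    counts <- cbind(A = base_rows$A, C = base_rows$C,
                    G = base_rows$G, T = base_rows$T)
    pwms[[id]] <- pwm(id, counts_to_freq(counts), tf_names = tf)
  }
  pwms
}
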