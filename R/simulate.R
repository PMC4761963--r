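# Synthetic-data generator: promoters with planted consensus motifs and
# expression driven by a known linear model over binding-site counts, so every
# downstream stage of the pipeline has ground truth.

#' Ground truth for a synthetic promoter study
#'
#' Records everything the generator needs and everything a test harness must
#' know afterwards: the planted motif occurrences per gene, the true
#' regression coefficients of the expression model, and the noise level.
#'
#' @param gene_ids Character vector of gene identifiers (no duplicates).
#' @param promoter_length Promoter length in bases.
#' @param planted_hits Named list (one element per gene id, missing genes get
#'   no plants) of data frames with columns `pwm_id`, `position` (0-based
#'   start on the plus strand) and `strand` (`"+"`/`"-"`).
#' @param true_coefficients Named numeric vector of regression coefficients,
#'   one per PWM id; every planted PWM must appear here.
#' @param intercept Intercept of the log2-scale expression model.
#' @param noise_sd Replicate noise standard deviation (log2 scale), `> 0`
#'   unless exactly 0 for noiseless checks.
#' @param seed Integer seed; each generator operation derives its own
#'   independent stream from it.
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(gene_ids, promoter_length, planted_hits = list(),
                            true_coefficients, intercept = 0, noise_sd = 0.5,
                            seed = 1L) {
  stopifnot(!anyDuplicated(gene_ids), promoter_length >= 1,
            is.numeric(true_coefficients), !is.null(names(true_coefficients)),
            noise_sd >= 0)
  stray_genes <- setdiff(names(planted_hits), gene_ids)
  if (length(stray_genes)) {
    stop("planted_hits name genes outside gene_ids: ",
         paste(utils::head(stray_genes, 5), collapse = ", "))
  }
  for (g in names(planted_hits)) {
    ph <- planted_hits[[g]]
    stopifnot(all(c("pwm_id", "position", "strand") %in% names(ph)))
    unknown <- setdiff(ph$pwm_id, names(true_coefficients))
    if (length(unknown)) {
      stop("gene '", g, "' plants PWMs without a true coefficient: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(gene_ids = as.character(gene_ids),
                 promoter_length = as.integer(promoter_length),
                 planted_hits = planted_hits,
                 true_coefficients = true_coefficients,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  n_plants <- sum(vapply(x$planted_hits, nrow, integer(1)))
  cat("synthetic_truth:", length(x$gene_ids), "genes, promoter length",
      x$promoter_length, "\n  ", n_plants, "planted hits,",
      length(x$true_coefficients), "coefficients, noise_sd", x$noise_sd, "\n")
  invisible(x)
}

#' Simulate a collection of random PWMs
#'
#' Each matrix has a dominant base per position (argmax probability above
#' background 0.25), so its consensus is attainable with probability greater
#' than a random window's, and rows normalized to 1.
#'
#' @param n_motifs Number of matrices (`>= 1`).
#' @param width_range Integer pair (or single width); widths are drawn
#'   uniformly from the range. Minimum width 5 (the 5-long core must exist).
#' @param seed Integer seed.
#' @return Named list of [pwm()] objects with ids `M01, M02, ...` and TF
#'   names `TF01, TF02, ...`.
#' @export
simulate_pwms <- function(n_motifs, width_range = c(6L, 10L), seed = 1L) {
  stopifnot(n_motifs >= 1)
  width_range <- as.integer(range(width_range))
  if (width_range[1] < 5L) {
    stop("PWM widths below 5 are not allowed: the 5-position core must exist")
  }
  with_local_seed(derive_seed(seed, 101L), {
    fmt <- paste0("%0", max(2L, nchar(n_motifs)), "d")
    widths <- seq(width_range[1], width_range[2])
    pwms <- lapply(seq_len(n_motifs), function(k) {
      w <- widths[sample.int(length(widths), 1L)]
      freq <- t(vapply(seq_len(w), function(i) {
        a <- stats::rgamma(4, shape = 0.7) + 0.02
        a[sample.int(4, 1)] <- a[sample.int(4, 1)] + 2.5
        f <- a / sum(a)
        # guarantee a consensus base above background
        while (max(f) <= 0.26) {
          f[which.max(f)] <- f[which.max(f)] + 0.1
          f <- f / sum(f)
        }
        f
      }, numeric(4)))
      pwm(sprintf(paste0("M", fmt), k), freq,
          tf_names = sprintf(paste0("TF", fmt), k))
    })
    names(pwms) <- vapply(pwms, function(p) p$id, character(1))
    pwms
  })
}

#' Simulate promoter sequences with planted consensus motifs
#'
#' Background bases are i.i.d. uniform over A/C/G/T; at each planted hit the
#' PWM's consensus (reverse-complemented for minus-strand plants) overwrites
#' the background at the stated 0-based position. Overlapping plants on one
#' promoter are an error naming the gene.
#'
#' @param truth A [synthetic_truth()].
#' @param pwms Named list of [pwm()] objects covering every planted PWM id.
#' @return Named character vector of promoter sequences, in `gene_ids` order.
#' @export
simulate_promoters <- function(truth, pwms) {
  stopifnot(inherits(truth, "synthetic_truth"))
  widths <- vapply(pwms, function(p) p$width, integer(1))
  L <- truth$promoter_length
  for (g in names(truth$planted_hits)) {
    ph <- truth$planted_hits[[g]]
    if (!nrow(ph)) next
    unknown <- setdiff(ph$pwm_id, names(pwms))
    if (length(unknown)) {
      stop("gene '", g, "': planted PWM(s) not in `pwms`: ",
           paste(unknown, collapse = ", "))
    }
    w <- widths[ph$pwm_id]
    if (any(ph$position < 0) || any(ph$position + w > L)) {
      stop("gene '", g, "': planted hit outside the promoter ",
           "(positions must satisfy 0 <= position <= length - width)")
    }
    o <- order(ph$position)
    starts <- ph$position[o]; ends <- starts + w[o]
    if (nrow(ph) > 1 && any(starts[-1] < ends[-nrow(ph)])) {
      stop("gene '", g, "': overlapping planted hits")
    }
  }
  with_local_seed(derive_seed(truth$seed, 202L), {
    out <- vapply(truth$gene_ids, function(g) {
      bases <- sample(DNA_BASES, L, replace = TRUE)
      ph <- truth$planted_hits[[g]]
      if (!is.null(ph) && nrow(ph)) {
        for (j in seq_len(nrow(ph))) {
          p <- pwms[[ph$pwm_id[j]]]
          word <- consensus(p)
          if (ph$strand[j] == "-") word <- reverse_complement(word)
          idx <- (ph$position[j] + 1L):(ph$position[j] + p$width)
          bases[idx] <- strsplit(word, "", fixed = TRUE)[[1]]
        }
      }
      paste(bases, collapse = "")
    }, character(1))
    names(out) <- truth$gene_ids
    out
  })
}

# True planted-hit count matrix (genes x PWMs) implied by the truth object.
planted_counts <- function(truth, pwm_ids = names(truth$true_coefficients)) {
  m <- matrix(0, length(truth$gene_ids), length(pwm_ids),
              dimnames = list(truth$gene_ids, pwm_ids))
  for (g in names(truth$planted_hits)) {
    ph <- truth$planted_hits[[g]]
    if (!nrow(ph)) next
    tab <- table(factor(ph$pwm_id, levels = pwm_ids))
    m[g, ] <- m[g, ] + as.numeric(tab)
  }
  m
}

#' Simulate replicate expression from a linear TFBS model
#'
#' For gene \eqn{g} and each replicate, the log2-scale response is
#' \eqn{intercept + \sum_m RC_m \cdot feature(g,m) + N(0, noise\_sd)} and the
#' stored abundance is \eqn{2^{response} - 1}, clipped at 0 — the inverse of
#' the `log2(x + 1)` transform applied downstream. Replicates differ only by
#' noise.
#'
#' @param truth A [synthetic_truth()] supplying coefficients, intercept,
#'   noise level and seed.
#' @param features A [feature_matrix()] whose rows align with
#'   `truth$gene_ids` (typically the planted counts or a scan of the
#'   simulated promoters).
#' @param n_replicates Number of replicates (`>= 2`; downstream differential
#'   tests need replication).
#' @param condition Condition name used in sample ids
#'   (`<condition>_<replicate>`).
#' @return An [expression_matrix()] with one condition.
#' @export
simulate_expression <- function(truth, features, n_replicates = 4L,
                                condition = "S1") {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(features, "feature_matrix"))
  if (n_replicates < 2) {
    stop("n_replicates must be >= 2: differential tests need replication")
  }
  if (!identical(rownames(features$values), truth$gene_ids)) {
    stop("feature rows must align with truth$gene_ids")
  }
  rc <- truth$true_coefficients
  shared <- intersect(colnames(features$values), names(rc))
  mu <- truth$intercept +
    as.vector(features$values[, shared, drop = FALSE] %*% rc[shared])
  # per-condition stream: offset by a stable hash of the condition name
  cond_offset <- sum(utf8ToInt(condition)) %% 1000L
  vals <- with_local_seed(derive_seed(truth$seed, 303L + cond_offset), {
    resp <- matrix(stats::rnorm(length(mu) * n_replicates, mean = mu,
                                sd = truth$noise_sd),
                   nrow = length(mu), ncol = n_replicates)
    pmax(2^resp - 1, 0)
  })
  rownames(vals) <- truth$gene_ids
  colnames(vals) <- paste(condition, seq_len(n_replicates), sep = "_")
  expression_matrix(vals)
}

#' Combine expression matrices over the same genes
#'
#' @param ... [expression_matrix()] objects with identical gene sets
#'   (conditions are concatenated).
#' @return A single [expression_matrix()].
#' @export
combine_expression <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1)
  g <- rownames(mats[[1]]$values)
  for (m in mats) {
    if (!identical(rownames(m$values), g)) stop("gene sets differ")
  }
  expression_matrix(do.call(cbind, lapply(mats, function(m) m$values)))
}

#' Write / read the synthetic ground truth as JSON
#'
#' @param truth A [synthetic_truth()].
#' @param file Path.
#' @return `read_truth()` returns a [synthetic_truth()].
#' @export
write_truth <- function(truth, file) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- unclass(truth)
  # named atomic vectors lose their names in JSON arrays; store as an object
  out$true_coefficients <- as.list(truth$true_coefficients)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  plants <- lapply(x$planted_hits, function(ph) {
    data.frame(pwm_id = as.character(ph$pwm_id),
               position = as.integer(ph$position),
               strand = as.character(ph$strand), stringsAsFactors = FALSE)
  })
  synthetic_truth(x$gene_ids, x$promoter_length, plants,
                  unlist(x$true_coefficients), x$intercept, x$noise_sd, x$seed)
}

#' Simulate a complete two-condition promoter study
#'
#' Generates one set of promoters (shared motif layout across conditions) and
#' expression for a control plus two treatment conditions whose log2
#' responses follow condition-specific linear models over the planted
#' binding-site counts. This is the ground-truth scenario used throughout the
#' package's tests: known coefficients, known plants, uniform background.
#'
#' @param n_genes Number of genes.
#' @param pwms Named list of [pwm()] objects, or `NULL` to simulate
#'   `n_pwms` of them.
#' @param n_pwms Number of PWMs when `pwms` is `NULL`.
#' @param promoter_length Promoter length in bases.
#' @param coefficients Named list of named coefficient vectors, one element
#'   per treatment condition (e.g. `list(A = c(M01 = 2), B = c(M01 = -2))`).
#'   The control condition always has all-zero coefficients.
#' @param intercept Baseline log2 expression (shared by all conditions).
#' @param noise_sd Replicate noise SD on the log2 scale.
#' @param n_replicates Replicates per condition.
#' @param hit_prob Per gene and PWM, plants are drawn `Binomial(2, hit_prob)`
#'   at uniformly chosen non-overlapping positions and random strands.
#' @param control Name of the control condition.
#' @param seed Integer seed controlling plants, promoters and noise.
#' @return List with elements `pwms`, `truths` (one [synthetic_truth()] per
#'   condition), `promoters`, `planted` (true count matrix), and `expr` (the
#'   combined [expression_matrix()] over all conditions).
#' @export
simulate_study <- function(n_genes = 300L, pwms = NULL, n_pwms = 10L,
                           promoter_length = 500L,
                           coefficients = list(A = c(M01 = 2), B = c(M02 = -2)),
                           intercept = 4, noise_sd = 0.5, n_replicates = 4L,
                           hit_prob = 0.25, control = "ctrl", seed = 1L) {
  if (is.null(pwms)) pwms <- simulate_pwms(n_pwms, c(6L, 10L), seed = seed)
  pwm_ids <- names(pwms)
  for (cf in coefficients) {
    unknown <- setdiff(names(cf), pwm_ids)
    if (length(unknown)) stop("coefficients for unknown PWMs: ",
                              paste(unknown, collapse = ", "))
  }
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  widths <- vapply(pwms, function(p) p$width, integer(1))
  plants <- with_local_seed(derive_seed(seed, 404L), {
    out <- list()
    for (g in gene_ids) {
      copies <- stats::rbinom(length(pwm_ids), size = 2L, prob = hit_prob)
      total <- sum(copies)
      if (!total) next
      ids <- rep(pwm_ids, copies)
      # place plants left to right with random gaps, never overlapping
      need <- sum(widths[ids])
      if (need > promoter_length) {
        stop("promoter_length too small for the requested plant density")
      }
      ids <- sample(ids)
      gaps <- stats::runif(total + 1L)
      gaps <- floor(gaps / sum(gaps) * (promoter_length - need))
      pos <- integer(total); cur <- 0L
      for (j in seq_len(total)) {
        cur <- cur + gaps[j]
        pos[j] <- cur
        cur <- cur + widths[ids[j]]
      }
      out[[g]] <- data.frame(pwm_id = ids, position = as.integer(pos),
                             strand = sample(c("+", "-"), total, replace = TRUE),
                             stringsAsFactors = FALSE)
    }
    out
  })
  all_coefs <- c(stats::setNames(list(stats::setNames(numeric(0), character(0))),
                                 control),
                 coefficients)
  truths <- lapply(names(all_coefs), function(cn) {
    rc <- stats::setNames(numeric(length(pwm_ids)), pwm_ids)
    rc[names(all_coefs[[cn]])] <- all_coefs[[cn]]
    synthetic_truth(gene_ids, promoter_length, plants, rc,
                    intercept = intercept, noise_sd = noise_sd, seed = seed)
  })
  names(truths) <- names(all_coefs)
  promoters <- simulate_promoters(truths[[1]], pwms)
  planted <- planted_counts(truths[[1]], pwm_ids)
  feats <- feature_matrix(planted)
  exprs <- lapply(names(truths), function(cn) {
    simulate_expression(truths[[cn]], feats, n_replicates, condition = cn)
  })
  list(pwms = pwms, truths = truths, promoters = promoters, planted = planted,
       expr = do.call(combine_expression, exprs))
}
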