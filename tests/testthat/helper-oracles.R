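# Independent reference implementations used to cross-check the package.
# Each oracle is written from the definition, not from the package's code
# path: naive loops, exhaustive enumeration, closed forms.

# --- PWM / scoring oracles --------------------------------------------------

random_pwm <- function(id, width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freq <- t(vapply(seq_len(width), function(i) {
    a <- rgamma(4, shape = 0.6) + 0.01
    a[sample.int(4, 1)] <- a[sample.int(4, 1)] + 2
    a / sum(a)
  }, numeric(4)))
  pwm(id, freq)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Naive three-loop MATCH score of one window, straight from the definition.
naive_match_score <- function(freq, window) {
  bases <- strsplit(window, "")[[1]]
  w <- nrow(freq)
  info <- numeric(w)
  for (i in seq_len(w)) {
    s <- 0
    for (b in 1:4) if (freq[i, b] > 0) s <- s + freq[i, b] * log(4 * freq[i, b])
    info[i] <- s
  }
  # leftmost max-information 5-window = core
  best <- -Inf; core <- 1
  for (i in seq_len(w - 4)) {
    s <- sum(info[i:(i + 4)])
    if (s > best + 1e-15) { best <- s; core <- i }
  }
  score_of <- function(pos_set) {
    cur <- 0; lo <- 0; hi <- 0
    for (i in pos_set) {
      bi <- match(bases[i], c("A", "C", "G", "T"))
      contrib <- if (is.na(bi)) min(info[i] * freq[i, ]) else info[i] * freq[i, bi]
      cur <- cur + unname(contrib)
      lo <- lo + min(info[i] * freq[i, ])
      hi <- hi + max(info[i] * freq[i, ])
    }
    if (hi - lo <= 0) 0 else (cur - lo) / (hi - lo)
  }
  c(mss = score_of(seq_len(w)), css = score_of(core:(core + 4)))
}

naive_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Score every window on both strands, emit hits above cutoffs.
naive_scan <- function(pwm_obj, promoter, mss_cutoff, css_cutoff) {
  w <- pwm_obj$width
  L <- nchar(promoter)
  out <- list()
  if (L >= w) {
    for (start0 in 0:(L - w)) {
      win <- substr(promoter, start0 + 1, start0 + w)
      for (strand in c("+", "-")) {
        sc <- naive_match_score(pwm_obj$freq,
                                if (strand == "+") win else naive_revcomp(win))
        if (sc["mss"] >= mss_cutoff && sc["css"] >= css_cutoff) {
          out[[length(out) + 1]] <- data.frame(
            start = start0, strand = strand,
            mss = unname(sc["mss"]), css = unname(sc["css"]))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      mss = numeric(), css = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), ]
}

# --- hypergeometric oracle --------------------------------------------------

# Upper-tail P(X >= k) by direct summation of the hypergeometric pmf.
brute_hyper_tail <- function(k, size_a, size_b, universe_n) {
  total <- 0
  for (i in 0:min(size_a, size_b)) {
    if (i >= k) {
      total <- total + choose(size_a, i) * choose(universe_n - size_a, size_b - i)
    }
  }
  total / choose(universe_n, size_b)
}

# --- best-subset oracle -----------------------------------------------------

# Enumerate every subset with lm(), straight BIC formula; returns the winning
# id set under smaller-then-lexicographic tie-breaking.
oracle_best_subset <- function(x, y, max_size) {
  ids <- colnames(x)
  n <- length(y)
  best <- list(crit = Inf, sel = character(0))
  all_subsets <- list(character(0))
  for (k in seq_len(max_size)) {
    cmb <- combn(ids, k, simplify = FALSE)
    all_subsets <- c(all_subsets, cmb)
  }
  for (sel in all_subsets) {
    df <- data.frame(y = y, x[, sel, drop = FALSE], check.names = FALSE)
    f <- lm(y ~ ., data = df)
    if (any(is.na(coef(f)))) next
    rss <- sum(resid(f)^2)
    crit <- n * log(rss / n) + (length(sel) + 1) * log(n)
    if (crit < best$crit - 1e-10) best <- list(crit = crit, sel = sel)
  }
  best
}

# --- network fixtures ---------------------------------------------------------

fixture_network <- function(seed, n_tf = 4, n_gene = 8, p = 0.4) {
  set.seed(seed)
  tfs <- paste0("TF", seq_len(n_tf))
  genes <- paste0("g", seq_len(n_gene))
  pick <- which(matrix(runif(n_tf * n_gene), n_tf) < p, arr.ind = TRUE)
  edges <- data.frame(tf = tfs[pick[, 1]], gene = genes[pick[, 2]],
                      stringsAsFactors = FALSE)
  promreg:::new_network(edges, tfs = tfs,
                        gene_labels = setNames(rep("A", n_gene), genes))
}

# order-independent comparable form of a network
net_signature <- function(net) {
  e <- net$edges[order(net$edges$tf, net$edges$gene), ]
  rownames(e) <- NULL
  list(edges = e, tfs = sort(net$tf_nodes$tf),
       genes = sort(net$gene_nodes$gene))
}

# --- misc fixtures ----------------------------------------------------------

toy_features <- function(n = 40, m = 4, seed = 1, ids = sprintf("M%02d", 1:m)) {
  set.seed(seed)
  x <- matrix(rpois(n * m, 1), n, m, dimnames = list(sprintf("g%03d", 1:n), ids))
  x
}

# Deterministic expression fixture reproducing the study's printed partition
# counts: 875 shared + 695 unique = 1570 up-regulated, of which 382 DUGs
# (162 A-dependent, 220 B-dependent), in a universe of 2000 genes.
partition_count_fixture <- function() {
  n_shared <- 875; n_uA <- 185; n_dugA <- 162; n_uB <- 128; n_dugB <- 220
  n_null <- 430
  meansA <- c(rep(40, n_shared), rep(12, n_uA), rep(50, n_dugA),
              rep(7, n_uB), rep(8, n_dugB), rep(4, n_null))
  meansB <- c(rep(40, n_shared), rep(7, n_uA), rep(8, n_dugA),
              rep(12, n_uB), rep(50, n_dugB), rep(4, n_null))
  n <- length(meansA)
  genes <- sprintf("g%04d", seq_len(n))
  jitter <- c(-0.02, 0, 0.02, 0.01)  # deterministic replicate pattern
  reps <- function(mu, cond) {
    vals <- outer(mu, 1 + jitter)
    colnames(vals) <- paste(cond, 1:4, sep = "_")
    vals
  }
  vals <- cbind(reps(rep(4, n), "ctrl"), reps(meansA, "A"), reps(meansB, "B"))
  rownames(vals) <- genes
  expression_matrix(vals)
}
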