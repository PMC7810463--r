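# Independent brute-force oracles. These deliberately re-derive each
# operation from its definition by a different route than the package code.

# Interval merge by repeated pairwise fusion to a fixpoint (gap-0 fuse).
oracle_merge <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) df[i, c("chrom", "start", "end")])
  repeat {
    fused <- FALSE
    for (i in seq_along(rows)) {
      if (fused) break
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom && a$start <= b$end && b$start <= a$end) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end))
          rows[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Extension by 1-bp alternating growth, right first (odd remainder right),
# redirecting to the other side at a chromosome edge.
oracle_extend <- function(start, end, chrom_size, min_length) {
  side_right <- TRUE
  while (end - start < min_length) {
    if (side_right) {
      if (end < chrom_size) end <- end + 1 else start <- start - 1
    } else {
      if (start > 0) start <- start - 1 else end <- end + 1
    }
    side_right <- !side_right
  }
  c(start = start, end = end)
}

# Benjamini-Hochberg step-up from the definition, explicit loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  s <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * s[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# 2x2 chi-square, cell-by-cell loop.
oracle_chisq <- function(tab, yates = FALSE) {
  n <- sum(tab)
  stat <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      dev <- abs(tab[i, j] - e)
      d <- dev - if (yates) min(0.5, dev) else 0
      stat <- stat + d^2 / e
    }
  }
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Naive motif scanning: per-offset substring comparison with its own
# IUPAC table and reverse complement.
oracle_iupac <- c(
  A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG", W = "AT",
  K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_scan_consensus <- function(sequence, consensus) {
  L <- nchar(consensus)
  n <- nchar(sequence)
  hits <- list()
  matches_at <- function(window, pat) {
    for (k in seq_len(nchar(pat))) {
      sub_base <- substr(window, k, k)
      allowed <- strsplit(oracle_iupac[[substr(pat, k, k)]], "")[[1]]
      if (sub_base == "N" || !(sub_base %in% allowed)) return(FALSE)
    }
    TRUE
  }
  if (n >= L) {
    for (off in 0:(n - L)) {
      window <- substr(sequence, off + 1, off + L)
      if (matches_at(window, consensus)) {
        hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "+")
      }
      if (matches_at(window, oracle_revcomp(consensus))) {
        hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "-")
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(), strand = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

oracle_scan_pwm <- function(sequence, pwm, threshold, background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(pwm)
  n <- nchar(sequence)
  max_score <- sum(apply(log2(pwm / background), 2, max))
  score_of <- function(window, mat) {
    s <- 0
    for (k in seq_len(L)) {
      b <- match(substr(window, k, k), bases)
      if (is.na(b)) return(-Inf)
      s <- s + log2(mat[b, k] / background[b])
    }
    s
  }
  rc <- pwm[4:1, L:1, drop = FALSE]
  hits <- list()
  if (n >= L) {
    for (off in 0:(n - L)) {
      window <- substr(sequence, off + 1, off + L)
      for (st in c("+", "-")) {
        sc <- score_of(window, if (st == "+") pwm else rc)
        if (sc >= threshold * max_score) {
          hits[[length(hits) + 1]] <- data.frame(offset = off, strand = st, score = sc)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(offset = integer(), strand = character(), score = numeric()))
  }
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(50, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
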