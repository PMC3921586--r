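# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles rather than sharing code
# with the package implementation.

# per-base overlap accounting: mark each base of a small genome with the
# first class (in precedence order) that covers it, then count query bases
oracle_overlap <- function(query, annotation, genome_len,
                           precedence = c("LTR", "LINE", "SINE", "DNA")) {
  classes <- unique(c(intersect(precedence, annotation$label),
                      setdiff(annotation$label, precedence)))
  owner <- rep(NA_character_, genome_len)   # 1-based position -> class
  for (cl in classes) {
    rows <- annotation[annotation$label == cl, ]
    for (i in seq_len(nrow(rows))) {
      span <- (rows$start[i] + 1):rows$end[i]
      owner[span][is.na(owner[span])] <- cl
    }
  }
  covered <- rep(FALSE, genome_len)
  for (i in seq_len(nrow(query))) covered[(query$start[i] + 1):query$end[i]] <- TRUE
  sapply(classes, function(cl) sum(covered & !is.na(owner) & owner == cl))
}

# exhaustive per-offset, per-strand PWM scoring
oracle_scan_pwm <- function(pwm, seq) {
  bases <- c("A", "C", "G", "T")
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  w <- ncol(pwm$log_odds)
  L <- nchar(seq)
  out <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (o in 1:(L - w + 1)) {
      win <- substr(s, o, o + w - 1)
      v <- match(strsplit(win, "")[[1]], bases)
      sc <- if (anyNA(v)) -Inf else sum(sapply(1:w, function(j) pwm$log_odds[v[j], j]))
      start <- if (strand == "+") o - 1 else L - w - o + 1
      out <- rbind(out, data.frame(start = start, strand = strand, score = sc))
    }
  }
  out
}

# exact Fisher by enumeration of all tables with fixed margins
oracle_fisher <- function(a, b, c, d, alternative = "greater") {
  m1 <- a + b; n1 <- a + c; N <- a + b + c + d
  ks <- max(0, m1 + n1 - N):min(m1, n1)
  pr <- sapply(ks, function(k) {
    choose(n1, k) * choose(N - n1, m1 - k) / choose(N, m1)
  })
  if (alternative == "greater") {
    sum(pr[ks >= a])
  } else {
    p_obs <- pr[ks == a]
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
}

# naive UPGMA: cluster distance recomputed as the mean over all original
# leaf pairs (no running update formula); same lexicographic tie-break
oracle_upgma_ages <- function(D) {
  ids <- rownames(D)
  clusters <- as.list(ids)
  heights <- rep(0, length(ids))
  age <- stats::setNames(rep(NA_real_, length(ids)), ids)
  merge_heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
      key <- paste(sort(c(paste(sort(clusters[[i]]), collapse = "|"),
                          paste(sort(clusters[[j]]), collapse = "|"))), collapse = "~")
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 && key < best$key)) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    h <- best$d / 2
    merge_heights <- c(merge_heights, h)
    for (leaf in c(clusters[[best$i]], clusters[[best$j]])) {
      if (is.na(age[leaf])) age[leaf] <- h
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(ages = age[ids], root = max(merge_heights),
       heights = sort(merge_heights))
}

# exhaustive window check for the C2H2 pattern on a protein string
oracle_c2h2 <- function(protein) {
  v <- strsplit(protein, "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  out <- NULL
  for (i in seq_along(v)) for (s1 in 2:4) for (s2 in 3:5) {
    len <- 16 + s1 + s2
    if (i + len - 1 > length(v)) next
    win <- v[i:(i + len - 1)]
    anchors <- c(1, s1 + 2, s1 + 15, len)
    if (win[1] == "C" && win[s1 + 2] == "C" &&
        win[s1 + 15] == "H" && win[len] == "H" &&
        all(win %in% aa)) {
      out <- rbind(out, data.frame(prot_start = i, s1 = s1, s2 = s2, length = len))
    }
  }
  out
}

random_intervals <- function(n, genome_len, max_w = 500,
                             labels = c("LTR", "LINE", "SINE", "DNA")) {
  w <- sample(10:max_w, n, replace = TRUE)
  s <- sample.int(genome_len - max_w, n, replace = TRUE) - 1
  genomic_intervals(rep("chr1", n), s, s + w,
                    label = sample(labels, n, replace = TRUE))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# big test annotation used by the enrichment recovery checks:
# four repeat classes at 8% genome share each, 5 kb elements
peak_test_annotation <- function(G = 5e7, n_per = 800, w = 5000) {
  n <- n_per * 4
  genomic_intervals(rep("chr1", n),
                    seq(0, G - w - 1, length.out = n),
                    seq(0, G - w - 1, length.out = n) + w,
                    label = rep(c("LTR", "LINE", "SINE", "DNA"), n_per))
}

# match scan hits back to planted motifs by >= 50% reciprocal overlap
match_truth <- function(hits, truth) {
  vapply(seq_len(nrow(hits)), function(i) {
    mid <- floor((hits$start[i] + hits$end[i]) / 2)
    w <- which(truth$start <= mid & truth$end > mid & truth$chrom == hits$chrom[i])
    if (length(w) == 1) w else NA_integer_
  }, integer(1))
}

planted_recall <- function(hits, truth) {
  mean(vapply(seq_len(nrow(truth)), function(i) {
    ov <- pmin(hits$end, truth$end[i]) - pmax(hits$start, truth$start[i])
    any(ov > 0.5 * (truth$end[i] - truth$start[i]) &
          ov > 0.5 * (hits$end - hits$start))
  }, logical(1)))
}
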