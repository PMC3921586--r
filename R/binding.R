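BASES <- c("A", "C", "G", "T")

#' Default table-driven zinc-finger recognition code
#'
#' A deterministic, table-driven linear code mapping the residue at each
#' C2H2 recognition-helix position (-1, 2, 3, 6) to a base-probability
#' vector for the subsite position it contacts. It is a deliberately
#' simple, documented stand-in behind the stable predictor interface:
#' any per-position residue-to-base table (including one distilled from a
#' trained model) can be supplied wherever a `code` argument appears.
#'
#' In the default code, helix position 6 determines the 5' base of a
#' finger's 3-bp subsite, position 3 the middle base and position -1 the
#' 3' base; N, D, R and Q specify A, C, G and T near-deterministically,
#' K and S are softer, and any residue absent from the table contributes
#' a uniform column. Helix position 2 (a cross-strand contact) is carried
#' in the interface but unused by the default code.
#'
#' @return A tibble `position`, `residue`, `A`, `C`, `G`, `T` (rows sum
#'   to 1).
#' @export
default_recognition_code <- function() {
  one <- function(res, p) tibble(residue = res, A = p[1], C = p[2], G = p[3], T = p[4])
  rows <- dplyr::bind_rows(
    one("N", c(0.97, 0.01, 0.01, 0.01)),
    one("D", c(0.01, 0.97, 0.01, 0.01)),
    one("R", c(0.01, 0.01, 0.97, 0.01)),
    one("Q", c(0.01, 0.01, 0.01, 0.97)),
    one("K", c(0.15, 0.05, 0.75, 0.05)),
    one("S", c(0.40, 0.20, 0.20, 0.20)),
    one("E", c(0.05, 0.75, 0.05, 0.15))
  )
  tidyr::crossing(position = c(-1, 3, 6), rows)
}

code_column <- function(code, position, residue) {
  row <- code[code$position == position & code$residue == residue, , drop = FALSE]
  if (nrow(row) == 0) return(stats::setNames(rep(0.25, 4), BASES))
  p <- as.numeric(row[1, BASES])
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("malformed recognition code row at position ", position,
         ", residue ", residue, call. = FALSE)
  }
  stats::setNames(p, BASES)
}

#' One finger's 3-bp position weight matrix
#'
#' @param spec Character vector of 4 residues at helix positions
#'   (-1, 2, 3, 6), in that order, or a single 4-letter string.
#' @param code Recognition-code tibble (see
#'   [default_recognition_code()]).
#' @return A 4 x 3 probability matrix (rows `A,C,G,T`; columns 5' to 3').
#' @examples
#' # helix 6 = R (G at 5'), helix 3 = N (A in the middle), helix -1 = D (C at 3')
#' finger_to_pwm(c("D", "A", "N", "R"))
#' @export
finger_to_pwm <- function(spec, code = default_recognition_code()) {
  if (length(spec) == 1 && nchar(spec) == 4) spec <- strsplit(spec, "", fixed = TRUE)[[1]]
  if (length(spec) != 4) stop("a finger spec is 4 residues (helix -1, 2, 3, 6)", call. = FALSE)
  if (!all(c("position", "residue", BASES) %in% names(code))) {
    stop("malformed recognition code table", call. = FALSE)
  }
  names(spec) <- c("m1", "p2", "p3", "p6")
  pwm <- cbind(code_column(code, 6, spec[["p6"]]),   # 5' base
               code_column(code, 3, spec[["p3"]]),   # middle base
               code_column(code, -1, spec[["m1"]]))  # 3' base
  rownames(pwm) <- BASES
  pwm
}

#' Tandem position weight matrix
#'
#' Concatenates finger PWMs in reverse finger order (the C2H2 array binds
#' DNA antiparallel: the N-terminal finger contacts the 3' subsite). The
#' score threshold defaults to `threshold_frac` of the maximum attainable
#' log-odds score.
#'
#' @param fingers List (or character vector) of finger specs, N- to
#'   C-terminal.
#' @param code Recognition-code tibble.
#' @param threshold_frac Fraction of the maximal score used as the site
#'   threshold (default 0.8).
#' @param pseudocount Probability floor added before the log-odds
#'   transform (default 0.01).
#' @return An object of class `tandem_pwm`: list with `pwm` (4 x 3F
#'   probability matrix), `log_odds`, `threshold`, `max_score`,
#'   `consensus`.
#' @export
tandem_to_pwm <- function(fingers, code = default_recognition_code(),
                          threshold_frac = 0.8, pseudocount = 0.01) {
  if (is.character(fingers)) fingers <- as.list(fingers)
  if (length(fingers) < 2) stop("a tandem needs >= 2 fingers", call. = FALSE)
  mats <- lapply(rev(fingers), finger_to_pwm, code = code)
  pwm <- do.call(cbind, mats)
  colnames(pwm) <- NULL
  prob <- apply(pwm + pseudocount, 2, function(p) p / sum(p))
  lo <- log2(prob / 0.25)
  max_score <- sum(apply(lo, 2, max))
  # an uninformative (non-positive information) PWM has no meaningful
  # threshold: no site can qualify as strongly bound
  out <- list(
    pwm = pwm, log_odds = lo,
    max_score = max_score,
    threshold = if (max_score > 0) threshold_frac * max_score else Inf,
    consensus = paste(BASES[apply(pwm, 2, which.max)], collapse = ""),
    n_fingers = length(fingers)
  )
  class(out) <- "tandem_pwm"
  out
}

#' @export
print.tandem_pwm <- function(x, ...) {
  cat("Tandem PWM:", x$n_fingers, "fingers, width", ncol(x$pwm),
      "bp, consensus", x$consensus, "\n")
  cat("max log-odds score", format(x$max_score, digits = 4),
      "; threshold", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Scan a sequence with a tandem PWM
#'
#' Log-odds scoring against a uniform background at every offset on both
#' strands; sites at or above the threshold are returned sorted by
#' descending score, then coordinate.
#'
#' @param pwm A `tandem_pwm` from [tandem_to_pwm()].
#' @param seq DNA string (length >= PWM width).
#' @param threshold Score threshold; defaults to the PWM's own.
#' @return A tibble `start`, `end` (0-based half-open), `strand`,
#'   `score`, `site`.
#' @export
scan_pwm <- function(pwm, seq, threshold = pwm$threshold) {
  stopifnot(inherits(pwm, "tandem_pwm"))
  seq <- toupper(seq)
  w <- ncol(pwm$log_odds)
  L <- nchar(seq)
  if (L < w) stop("sequence shorter than PWM width", call. = FALSE)
  score_strand <- function(s, strand) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(v, BASES)
    n_off <- L - w + 1
    scores <- vapply(seq_len(n_off), function(o) {
      cols <- idx[o:(o + w - 1)]
      if (anyNA(cols)) return(-Inf)  # N in window: unscored
      sum(pwm$log_odds[cbind(cols, seq_len(w))])
    }, numeric(1))
    if (strand == "+") {
      tibble(start = seq_len(n_off) - 1, strand = strand, score = scores,
             site = substring(s, seq_len(n_off), seq_len(n_off) + w - 1))
    } else {
      # offset o on the reverse strand covers genomic [L - w - o + 1, L - o + 1)
      tibble(start = L - w - seq_len(n_off) + 1, strand = strand, score = scores,
             site = substring(s, seq_len(n_off), seq_len(n_off) + w - 1))
    }
  }
  hits <- dplyr::bind_rows(score_strand(seq, "+"),
                           score_strand(revcomp(seq), "-"))
  hits$end <- hits$start + w
  hits <- hits[hits$score >= threshold, c("start", "end", "strand", "score", "site")]
  dplyr::arrange(hits, dplyr::desc(.data$score), .data$start, .data$strand)
}

# strand-canonical k-mer: lexicographic min of the k-mer and its
# reverse complement
canonical_kmer <- function(kmer) {
  rc <- revcomp(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1)
  kmers <- substring(seq, starts, starts + k - 1)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]  # IUPAC ambiguity (N etc.) excluded
  unique(canonical_kmer(kmers))
}

#' Family-specific k-mers in ERV family consensus sequences
#'
#' Finds k-mers (canonicalised over strand) present in a family's
#' consensus and in at most `max_other` other families' consensi.
#' Positions containing ambiguity codes are excluded from matching.
#'
#' @param consensi Named character vector: family id -> consensus DNA.
#' @param k K-mer length (`k >= 6`).
#' @param max_other Maximum number of other families allowed to share the
#'   k-mer (default 0: strictly family-specific).
#' @return A tibble `family`, `kmer`, `n_other`.
#' @export
family_specific_motifs <- function(consensi, k, max_other = 0) {
  stopifnot(length(consensi) >= 2, k >= 6)
  too_short <- names(consensi)[nchar(consensi) < k]
  if (length(too_short) > 0) {
    message("consensus shorter than k skipped: ", paste(too_short, collapse = ", "))
    consensi <- consensi[nchar(consensi) >= k]
  }
  sets <- lapply(consensi, kmer_set, k = k)
  counts <- table(unlist(sets))
  purrr::map_dfr(names(sets), function(fam) {
    km <- sets[[fam]]
    n_other <- as.integer(counts[km]) - 1L
    keep <- n_other <= max_other
    tibble(family = fam, kmer = km[keep], n_other = n_other[keep])
  })
}

#' Predict candidate ERV repressors among zinc-finger tandems
#'
#' For each tandem, builds the PWM implied by its finger specs and asks
#' whether any family-specific motif scores at or above the tandem's
#' threshold under [scan_pwm()]. Reported pairs are ranked by score within
#' each family; by default the top 4 per family are kept. Families without
#' specific motifs (or without a strongly bound tandem) are simply absent.
#'
#' @param tandems Tibble with columns `tandem` (id), `chrom`, and
#'   `fingers` (list-column of finger-spec vectors, or a `;`-separated
#'   string column).
#' @param consensi Named character vector of family consensus sequences.
#' @param code Recognition-code tibble.
#' @param top_n Pairs reported per family (default 4).
#' @param max_other Specificity bound passed to
#'   [family_specific_motifs()].
#' @param threshold_frac Passed to [tandem_to_pwm()].
#' @return A tibble `tandem`, `chrom`, `family`, `motif`, `score`.
#' @export
predict_repressors <- function(tandems, consensi, code = default_recognition_code(),
                               top_n = 4, max_other = 0, threshold_frac = 0.8) {
  stopifnot(nrow(tandems) > 0, length(consensi) > 0)
  fingers <- tandems$fingers
  if (is.character(fingers)) fingers <- strsplit(fingers, ";", fixed = TRUE)
  widths <- 3 * lengths(fingers)
  out <- purrr::map_dfr(sort(unique(widths)), function(w) {
    motifs <- family_specific_motifs(consensi, k = w, max_other = max_other)
    if (nrow(motifs) == 0) return(tibble())
    idx <- which(widths == w)
    # width-k motifs admit a single offset per strand: score them by
    # direct log-odds lookup (equivalent to scan_pwm on the k-mer)
    fmat <- matrix(match(unlist(strsplit(motifs$kmer, "", fixed = TRUE)), BASES),
                   nrow = nrow(motifs), byrow = TRUE)
    rmat <- matrix(match(unlist(strsplit(revcomp(motifs$kmer), "", fixed = TRUE)),
                         BASES),
                   nrow = nrow(motifs), byrow = TRUE)
    purrr::map_dfr(idx, function(i) {
      pwm <- tandem_to_pwm(fingers[[i]], code = code, threshold_frac = threshold_frac)
      lo <- pwm$log_odds
      score_rows <- function(mat) {
        sc <- numeric(nrow(mat))
        for (j in seq_len(w)) sc <- sc + lo[cbind(mat[, j], j)]
        sc
      }
      best <- pmax(score_rows(fmat), score_rows(rmat))
      keep <- which(best >= pwm$threshold)
      if (length(keep) == 0) return(tibble())
      tibble(tandem = tandems$tandem[i], chrom = tandems$chrom[i],
             family = motifs$family[keep], motif = motifs$kmer[keep],
             score = best[keep])
    })
  })
  if (nrow(out) == 0) return(tibble(tandem = character(), chrom = character(),
                                    family = character(), motif = character(),
                                    score = numeric()))
  out <- dplyr::group_by(out, .data$family)
  out <- dplyr::slice_max(out, .data$score, n = top_n, with_ties = FALSE)
  dplyr::arrange(dplyr::ungroup(out), .data$family, dplyr::desc(.data$score))
}
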