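#' Six-frame translation with exact coordinate maps
#'
#' Translates a DNA sequence in all six reading frames (three offsets on
#' each strand). Codons containing ambiguity letters (e.g. `N`) translate
#' to `X`; stop codons to `*`. The companion [protein_to_genomic()] maps a
#' protein window in any frame back to its exact genomic interval.
#'
#' @param seq A single DNA string over `A,C,G,T,N`.
#' @return A tibble with columns `strand` (`"+"`/`"-"`), `frame` (0, 1, 2)
#'   and `protein`.
#' @examples
#' six_frame_translate("ATGAAA")
#' @export
six_frame_translate <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(dna, frame) {
    n <- length(dna) - frame
    n <- n - n %% 3
    if (n < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(dna, start = frame + 1, width = n),
      if.fuzzy.codon = "X"
    ))
  }
  tibble(
    strand  = rep(c("+", "-"), each = 3),
    frame   = rep(0:2, 2),
    protein = c(vapply(0:2, function(f) one(fwd, f), character(1)),
                vapply(0:2, function(f) one(rev, f), character(1)))
  )
}

#' Map a protein window back to genomic coordinates
#'
#' @param prot_start 1-based first amino-acid position of the window.
#' @param prot_len Window length in amino acids.
#' @param frame Frame offset (0, 1, 2).
#' @param strand `"+"` or `"-"`.
#' @param seq_len Length of the translated DNA sequence in bp.
#' @return Numeric vector `c(start, end)`, 0-based half-open genomic
#'   coordinates; length is always `3 * prot_len`.
#' @export
protein_to_genomic <- function(prot_start, prot_len, frame, strand, seq_len) {
  g0 <- frame + 3 * (prot_start - 1)    # 0-based offset on translated strand
  g1 <- g0 + 3 * prot_len
  if (strand == "+") c(g0, g1) else c(seq_len - g1, seq_len - g0)
}

# Exhaustive C2H2 match enumeration on one protein string.
# Pattern: C-x(2,4)-C-x(12)-H-x(3,5)-H, 21-25 aa total. Spacer residues may
# be any of the 20 amino acids or X; the anchor positions must be literal
# C/H (X never matches an anchor) and a stop ('*') breaks any match.
c2h2_matches <- function(protein) {
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  np <- length(v)
  out <- list()
  if (np < 21) {
    return(tibble(prot_start = integer(), s1 = integer(), s2 = integer(),
                  length = integer()))
  }
  valid <- v %in% strsplit("ACDEFGHIKLMNPQRSTVWYX", "", fixed = TRUE)[[1]]
  # cumulative count of invalid residues for O(1) window checks
  bad_cum <- c(0, cumsum(!valid))
  window_clean <- function(i, j) (bad_cum[j + 1] - bad_cum[i]) == 0
  k <- 0
  res <- vector("list", 9)
  for (s1 in 2:4) {
    for (s2 in 3:5) {
      len <- 16 + s1 + s2
      imax <- np - len + 1
      if (imax < 1) next
      i <- seq_len(imax)
      ok <- v[i] == "C" & v[i + s1 + 1] == "C" &
        v[i + s1 + 14] == "H" & v[i + s1 + s2 + 15] == "H"
      i <- i[ok]
      if (length(i) > 0) {
        clean <- vapply(i, function(ii) window_clean(ii, ii + len - 1), logical(1))
        i <- i[clean]
      }
      if (length(i) > 0) {
        k <- k + 1
        res[[k]] <- tibble(prot_start = i, s1 = s1, s2 = s2, length = len)
      }
    }
  }
  if (k == 0) {
    return(tibble(prot_start = integer(), s1 = integer(), s2 = integer(),
                  length = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(res[seq_len(k)]), .data$prot_start, dplyr::desc(.data$length))
}

#' Find C2H2 zinc-finger motifs in a protein sequence
#'
#' Reports every match of the C2H2 consensus `C-x(2,4)-C-x(12)-H-x(3,5)-H`
#' (21 to 25 amino acids), including overlapping matches; `X` never matches
#' an anchor cysteine/histidine and a stop codon breaks a match.
#'
#' @param protein Protein string (one frame of a translation).
#' @param frame,strand,seq_length Frame metadata used to attach genomic
#'   coordinates (see [protein_to_genomic()]); omit to get protein
#'   coordinates only.
#' @return A tibble with one row per match: `prot_start`, `s1`, `s2`
#'   (spacer lengths), `length`, `protein_seq`, and when frame metadata is
#'   supplied, `start`, `end`, `strand`, `frame` (genomic, 0-based
#'   half-open).
#' @examples
#' find_c2h2("YKCEECGKAFNRSSNLTKHKRIH")
#' @export
find_c2h2 <- function(protein, frame = NULL, strand = NULL, seq_length = NULL) {
  m <- c2h2_matches(protein)
  m$protein_seq <- if (nrow(m) == 0) character(0) else
    substring(protein, m$prot_start, m$prot_start + m$length - 1)
  if (!is.null(frame)) {
    coords <- t(vapply(seq_len(nrow(m)), function(i) {
      protein_to_genomic(m$prot_start[i], m$length[i], frame, strand, seq_length)
    }, numeric(2)))
    if (nrow(m) == 0) coords <- matrix(numeric(0), ncol = 2)
    m$start <- coords[, 1]
    m$end <- coords[, 2]
    m$strand <- strand
    m$frame <- frame
  }
  m
}

#' Scan a genome for C2H2 motifs in all six frames
#'
#' Translates every chromosome in six frames, enumerates all C2H2 motif
#' matches, and (by default) resolves overlaps to the non-overlapping set
#' via [resolve_overlaps()].
#'
#' @param genome Named character vector of DNA sequences (see
#'   [read_fasta()]).
#' @param resolve Resolve overlapping hits (default `TRUE`).
#' @return A tibble of motif hits: `chrom`, `start`, `end`, `strand`,
#'   `frame`, `prot_start`, `s1`, `s2`, `protein_seq`.
#' @export
scan_zf <- function(genome, resolve = TRUE) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  hits <- purrr::map_dfr(names(genome), function(chrom) {
    L <- nchar(genome[[chrom]])
    frames <- six_frame_translate(genome[[chrom]])
    purrr::pmap_dfr(frames, function(strand, frame, protein) {
      h <- find_c2h2(protein, frame = frame, strand = strand, seq_length = L)
      if (nrow(h) > 0) h$chrom <- chrom
      h
    })
  })
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), frame = integer(),
                  prot_start = integer(), s1 = integer(), s2 = integer(),
                  protein_seq = character()))
  }
  hits <- dplyr::select(hits, "chrom", "start", "end", "strand", "frame",
                        "prot_start", "s1", "s2", "protein_seq")
  if (resolve) hits <- resolve_overlaps(hits)
  hits
}

#' Resolve overlapping motif hits to a non-overlapping set
#'
#' Greedy selection from the left: hits are ordered by ascending genomic
#' start, then longer first, then `+` strand first, and a hit is retained
#' iff it does not overlap any previously retained hit (on either strand).
#'
#' @param hits Motif-hit tibble (needs `chrom`, `start`, `end`, `strand`).
#' @return The retained, pairwise-disjoint subset, in genomic order.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- dplyr::arrange(hits, .data$chrom, .data$start,
                         dplyr::desc(.data$end - .data$start),
                         factor(.data$strand, levels = c("+", "-", ".")))
  keep <- logical(nrow(hits))
  frontier <- -Inf
  cur_chrom <- ""
  for (i in seq_len(nrow(hits))) {
    if (hits$chrom[i] != cur_chrom) {
      cur_chrom <- hits$chrom[i]
      frontier <- -Inf
    }
    if (hits$start[i] >= frontier) {
      keep[i] <- TRUE
      frontier <- hits$end[i]
    }
  }
  hits[keep, ]
}

#' Group motif hits into tandems
#'
#' A tandem is a maximal run of two or more C2H2 motifs on the same strand
#' of the same chromosome in which every consecutive genomic gap (end of
#' one hit to start of the next) is strictly less than `max_gap` base
#' pairs. Singletons are kept as hits but carry `tandem_id = NA`.
#'
#' @param hits Non-overlapping motif-hit tibble.
#' @param max_gap Gap threshold in bp, exclusive (default 200: gaps of
#'   exactly 200 bp split a tandem).
#' @return `hits` with an added `tandem_id` column, ordered by
#'   chromosome, strand and start.
#' @export
group_tandems <- function(hits, max_gap = 200) {
  if (nrow(hits) == 0) {
    hits$tandem_id <- character(0)
    return(hits)
  }
  hits <- dplyr::arrange(hits, .data$chrom, .data$strand, .data$start)
  hits <- dplyr::group_by(hits, .data$chrom, .data$strand)
  hits <- dplyr::mutate(hits,
    gap = .data$start - dplyr::lag(.data$end),
    run = cumsum(is.na(.data$gap) | .data$gap >= max_gap)
  )
  hits <- dplyr::group_by(hits, .data$chrom, .data$strand, .data$run)
  hits <- dplyr::mutate(hits,
    tandem_id = if (dplyr::n() >= 2) {
      paste0(.data$chrom[1], ":", .data$strand[1], ":",
             format_coord(min(.data$start)))
    } else {
      NA_character_
    }
  )
  dplyr::select(dplyr::ungroup(hits), -"gap", -"run")
}

#' Assign motif hits to genes by midpoint containment
#'
#' A hit is assigned to every gene whose interval contains the hit's
#' genomic midpoint; hits outside all genes get `gene_id = NA` and still
#' count toward chromosome totals.
#'
#' @param hits Motif-hit tibble.
#' @param genes Interval tibble of genes with gene ids in `label`.
#' @return `hits` with an added `gene_id` column (one row per hit-gene
#'   pair; hits in overlapping genes are duplicated).
#' @export
assign_genes <- function(hits, genes) {
  validate_intervals(genes, "gene")
  if (nrow(hits) == 0) {
    hits$gene_id <- character(0)
    return(hits)
  }
  mid <- floor((hits$start + hits$end) / 2)
  pts <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(mid + 1, mid + 1))
  gr  <- intervals_to_granges(genes)
  ov  <- GenomicRanges::findOverlaps(pts, gr, ignore.strand = TRUE)
  assigned <- hits[S4Vectors::queryHits(ov), ]
  assigned$gene_id <- genes$label[S4Vectors::subjectHits(ov)]
  orphans <- hits[setdiff(seq_len(nrow(hits)), unique(S4Vectors::queryHits(ov))), ]
  if (nrow(orphans) > 0) orphans$gene_id <- NA_character_
  dplyr::arrange(dplyr::bind_rows(assigned, orphans),
                 .data$chrom, .data$start, .data$gene_id)
}

#' Per-gene and per-chromosome motif counts
#'
#' @param assigned Output of [assign_genes()].
#' @return For `count_hits_by_gene()`, a tibble `gene_id`, `n_hits`
#'   (intergenic hits excluded); for `count_hits_by_chrom()`, a tibble
#'   `chrom`, `n_hits` partitioning all distinct hits.
#' @export
count_hits_by_gene <- function(assigned) {
  x <- dplyr::filter(assigned, !is.na(.data$gene_id))
  dplyr::count(x, .data$gene_id, name = "n_hits")
}

#' @rdname count_hits_by_gene
#' @export
count_hits_by_chrom <- function(assigned) {
  x <- dplyr::distinct(assigned, .data$chrom, .data$start, .data$end, .data$strand)
  dplyr::count(x, .data$chrom, name = "n_hits")
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Extract motif DNA in a fixed, pattern-anchored alignment
#'
#' Every C2H2 hit is written into a 75-nt frame anchored on the consensus:
#' one codon per anchor residue, the variable spacers right-padded with gap
#' codons (`---`) to their maximum lengths (4 and 5 codons). Gap positions
#' are ignored pairwise by [pairwise_p()], which makes mismatch fractions
#' well defined without a multiple alignment.
#'
#' @param hits Motif-hit tibble with `s1`, `s2` columns (from [scan_zf()]).
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of 75-nt aligned DNA strings (coding strand),
#'   named by `chrom:start-end:strand`.
#' @export
aligned_motif_dna <- function(hits, genome) {
  stopifnot(all(c("s1", "s2") %in% names(hits)))
  out <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    dna <- substr(genome[[hits$chrom[i]]], hits$start[i] + 1, hits$end[i])
    if (hits$strand[i] == "-") dna <- revcomp(dna)
    s1 <- hits$s1[i]; s2 <- hits$s2[i]
    # codon blocks: C | s1 | C | 12 | H | s2 | H
    cuts <- cumsum(c(1, s1, 1, 12, 1, s2, 1)) * 3
    starts <- c(1, head(cuts, -1) + 1)
    blocks <- substring(dna, starts, cuts)
    pad1 <- strrep("-", 3 * (4 - s1))
    pad2 <- strrep("-", 3 * (5 - s2))
    out[i] <- paste0(blocks[1], blocks[2], pad1, blocks[3], blocks[4],
                     blocks[5], blocks[6], pad2, blocks[7])
  }
  names(out) <- paste0(hits$chrom, ":", format_coord(hits$start), "-",
                       format_coord(hits$end), ":", hits$strand)
  out
}
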