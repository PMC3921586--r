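#' Genomic interval tibbles
#'
#' All interval-valued data in kznfevo travel as tibbles with the columns
#' `chrom` (chromosome name), `start`, `end` (0-based, half-open, so
#' `end - start` is the length in base pairs), `strand` (`"+"`, `"-"` or
#' `"."`) and `label` (a free-text class such as `"LTR"`, `"LINE"`,
#' `"SINE"`, `"DNA"`, or a gene id). This is the BED convention, kept
#' unchanged end to end; any 1-based display is formatting only.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors of 0-based half-open coordinates.
#' @param strand Strand, recycled; one of `"+"`, `"-"`, `"."`.
#' @param label Class label, recycled; `NA` allowed.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `label`.
#' @examples
#' genomic_intervals("chr19", 100, 200, label = "LTR")
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", label = NA_character_) {
  out <- tibble(
    chrom  = as.character(chrom),
    start  = as.numeric(start),
    end    = as.numeric(end),
    strand = rep_len(as.character(strand), length(chrom)),
    label  = rep_len(as.character(label), length(chrom))
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s at row %d: need 0 <= start < end (got start=%s, end=%s)",
      what, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])
    ), call. = FALSE)
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  invisible(x)
}

#' Read a BED3/BED6 file as an interval tibble
#'
#' Coordinates are kept in BED's native 0-based half-open convention.
#' The BED `name` column (column 4) is mapped to `label`.
#'
#' @param path Path to a BED file. Lines starting with `#` and UCSC
#'   `track`/`browser` lines are skipped.
#' @return A tibble of intervals (see [genomic_intervals()]) with an extra
#'   `score` column when the input is BED5+.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tLTR", f)
#' read_bed(f)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", idx[which(nf < 3)[1]]),
         call. = FALSE)
  }
  col <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, character(1))
  start <- suppressWarnings(as.numeric(col(2)))
  end   <- suppressWarnings(as.numeric(col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad), call. = FALSE)
  }
  badc <- which(!(start >= 0 & start < end))
  if (length(badc) > 0) {
    stop(sprintf("invalid interval at line %d: start >= end", idx[badc[1]]), call. = FALSE)
  }
  out <- tibble(
    chrom  = col(1),
    start  = start,
    end    = end,
    strand = ifelse(is.na(col(6)), ".", col(6)),
    label  = col(4)
  )
  score <- col(5)
  if (!all(is.na(score))) out$score <- score
  validate_intervals(out)
  out
}

#' Write an interval tibble as BED
#'
#' BED6 inputs round-trip byte-stably through [read_bed()] / `write_bed()`.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  score <- if ("score" %in% names(x)) as.character(x$score) else rep("0", nrow(x))
  has6 <- ("strand" %in% names(x)) && any(x$strand != "." | !is.na(x$label))
  if (has6) {
    lines <- paste(x$chrom, format_coord(x$start), format_coord(x$end),
                   ifelse(is.na(x$label), ".", x$label), score, x$strand,
                   sep = "\t")
  } else {
    lines <- paste(x$chrom, format_coord(x$start), format_coord(x$end), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read polymorphic deletion records
#'
#' Reads a table of deletion polymorphisms with population allele counts,
#' either as a headered TSV with columns `chrom`, `start`, `end`,
#' `derived_count`, `n`, or as a minimal VCF (CHROM/POS with `END=`, `AC=`,
#' `AN=` INFO keys). Records are filtered to the study's rule: deletion
#' length strictly greater than `min_length` base pairs and
#' `1 <= derived_count < n` (segregating, not fixed). The number of records
#' excluded by each rule is reported via `message()`.
#'
#' @param path Path to a TSV or VCF file.
#' @param min_length Minimum deletion length in bp, exclusive (default 50:
#'   only deletions larger than 50 bp are retained).
#' @return A tibble with columns `chrom`, `start`, `end`, `derived_count`,
#'   `n` (0-based half-open coordinates).
#' @export
read_deletions <- function(path, min_length = 50) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first)) {
    rec <- read_deletions_vcf(path)
  } else {
    rec <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    need <- c("chrom", "start", "end", "derived_count", "n")
    if (!all(need %in% names(rec))) {
      stop("deletion TSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    rec <- rec[, need]
  }
  validate_intervals(rec, "deletion record")
  len_ok  <- (rec$end - rec$start) > min_length
  poly_ok <- rec$derived_count >= 1 & rec$derived_count < rec$n
  n_len  <- sum(!len_ok)
  n_poly <- sum(len_ok & !poly_ok)
  if (n_len > 0)  message(n_len, " record(s) excluded: length <= ", min_length, " bp")
  if (n_poly > 0) message(n_poly, " record(s) excluded: not polymorphic (AC outside [1, n-1])")
  as_tibble(rec[len_ok & poly_ok, ])
}

read_deletions_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  derived_count = numeric(), n = numeric()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8)) stop("malformed VCF record: fewer than 8 fields", call. = FALSE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  info <- vapply(fields, `[`, character(1), 8)
  pos  <- as.numeric(vapply(fields, `[`, character(1), 2))
  endv <- as.numeric(info_get(info, "END"))
  ac   <- as.numeric(info_get(info, "AC"))
  an   <- as.numeric(info_get(info, "AN"))
  if (anyNA(endv) || anyNA(ac) || anyNA(an)) {
    stop("minimal VCF requires END=, AC= and AN= INFO fields on every record",
         call. = FALSE)
  }
  tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = pos - 1,       # VCF POS is 1-based; [POS-1, END) half-open
    end = endv,
    derived_count = ac,
    n = an
  )
}

#' Read and write species trees (Newick)
#'
#' Thin, validating wrappers around [ape::read.tree()] /
#' [ape::write.tree()]. `read_species_tree()` requires unique leaf names
#' and (by default) a fully bifurcating rooted tree. Round-tripping
#' preserves topology and branch lengths.
#'
#' @param path Path to a Newick file.
#' @param require_binary Require a rooted binary tree (default `TRUE`).
#' @return An [ape::phylo] object.
#' @export
read_species_tree <- function(path, require_binary = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: could not read a tree from ", path, call. = FALSE)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names in tree", call. = FALSE)
  if (require_binary && !ape::is.binary(tr)) stop("tree is not fully bifurcating", call. = FALSE)
  tr
}

#' @rdname read_species_tree
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read and write FASTA sequence maps
#'
#' Sequences are returned as a named character vector, uppercased;
#' duplicate headers and empty records are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA header in ", path, call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty FASTA record in ", path, call. = FALSE)
  seqs
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a tab-separated table with '#' comments
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

# interval tibble -> GRanges (1-based closed internally; BED kept outside)
intervals_to_granges <- function(x) {
  validate_intervals(x)
  strand <- if ("strand" %in% names(x)) x$strand else "."
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand
  )
}
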