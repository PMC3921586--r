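#' Base-pair overlap of intervals by annotation class
#'
#' Counts, for each annotation class, the number of query base pairs
#' covered by that class. Overlapping annotation of the same class is
#' merged first; bases covered by two different classes are assigned once,
#' to the class earliest in `precedence` (remaining classes follow in
#' order of appearance). Overlapping query intervals are merged before
#' counting, so `total_bp` is the distinct base-pair footprint of the
#' query.
#'
#' @param query Interval tibble (e.g. ChIP peaks).
#' @param annotation Interval tibble with class labels in `label`
#'   (e.g. RepeatMasker-style repeat classes).
#' @param precedence Character vector giving the class priority for doubly
#'   annotated bases. Default `c("LTR", "LINE", "SINE", "DNA")`.
#' @return A `class_overlap` tibble with columns `label`, `overlap_bp`,
#'   `total_bp` and `fraction = overlap_bp / total_bp`.
#' @examples
#' peaks <- genomic_intervals("chr1", 100, 200)
#' ann <- genomic_intervals("chr1", 150, 250, label = "LTR")
#' overlap_by_class(peaks, ann)
#' @export
overlap_by_class <- function(query, annotation,
                             precedence = c("LTR", "LINE", "SINE", "DNA")) {
  validate_intervals(query, "query")
  validate_intervals(annotation, "annotation")
  missing_chr <- setdiff(unique(query$chrom), unique(annotation$chrom))
  if (length(missing_chr) > 0) {
    warning("chromosome(s) in query absent from annotation (zero overlap): ",
            paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  q <- GenomicRanges::reduce(intervals_to_granges(query), ignore.strand = TRUE)
  total_bp <- sum(GenomicRanges::width(q))
  classes <- unique(c(intersect(precedence, annotation$label),
                      setdiff(annotation$label, precedence)))
  claimed <- GenomicRanges::GRanges()
  rows <- purrr::map_dfr(classes, function(cl) {
    ann <- GenomicRanges::reduce(
      intervals_to_granges(annotation[annotation$label == cl, ]),
      ignore.strand = TRUE
    )
    if (length(claimed) > 0) {
      ann <- GenomicRanges::setdiff(ann, claimed, ignore.strand = TRUE)
      claimed <<- GenomicRanges::reduce(suppressWarnings(c(claimed, ann)),
                                        ignore.strand = TRUE)
    } else {
      claimed <<- ann
    }
    ov <- suppressWarnings(GenomicRanges::intersect(q, ann, ignore.strand = TRUE))
    tibble(label = cl, overlap_bp = sum(GenomicRanges::width(ov)))
  })
  out <- dplyr::mutate(rows, total_bp = total_bp,
                       fraction = .data$overlap_bp / total_bp)
  class(out) <- c("class_overlap", class(out))
  out
}

#' Build a class-overlap table directly from printed totals
#'
#' Convenience constructor for working with published base-pair totals
#' rather than raw intervals (e.g. reported Mbp per repeat class within a
#' peak set).
#'
#' @param overlap_bp Named numeric vector of per-class overlap base pairs.
#' @param total_bp Total query base pairs.
#' @return A `class_overlap` tibble (see [overlap_by_class()]).
#' @examples
#' class_overlap_table(c(LTR = 1.64e6), total_bp = 8900411)
#' @export
class_overlap_table <- function(overlap_bp, total_bp) {
  stopifnot(!is.null(names(overlap_bp)), total_bp > 0)
  out <- tibble(label = names(overlap_bp),
                overlap_bp = as.numeric(overlap_bp),
                total_bp = as.numeric(total_bp),
                fraction = as.numeric(overlap_bp) / as.numeric(total_bp))
  class(out) <- c("class_overlap", class(out))
  out
}

#' Fold enrichment of peak classes over a background
#'
#' Per class, the ratio of the class's fraction of peak base pairs to its
#' fraction of background (accessible-chromatin) base pairs. A null model
#' of random binding within accessible chromatin gives fold 1.
#'
#' @param peak_table,background_table `class_overlap` tibbles from
#'   [overlap_by_class()] (or [class_overlap_table()]).
#' @return A tibble `label`, `peak_fraction`, `background_fraction`,
#'   `fold`, `infinite` (flag for zero background with nonzero peak
#'   fraction).
#' @export
fold_enrichment <- function(peak_table, background_table) {
  j <- dplyr::inner_join(
    dplyr::select(peak_table, "label", peak_fraction = "fraction"),
    dplyr::select(background_table, "label", background_fraction = "fraction"),
    by = "label"
  )
  dplyr::mutate(j,
    fold = dplyr::if_else(.data$background_fraction > 0,
                          .data$peak_fraction / .data$background_fraction,
                          ifelse(.data$peak_fraction > 0, Inf, NaN)),
    infinite = .data$background_fraction == 0 & .data$peak_fraction > 0
  )
}

#' Mutant-vs-wild-type peak retention on an annotation class
#'
#' Measures how much of the wild-type binding signal on a repeat class
#' survives in a mutant peak set. At `level = "bp"` (primary, matching
#' Mbp-scale reporting) the fraction is: class-annotated base pairs within
#' the intersection of mutant and wild-type peaks, divided by
#' class-annotated base pairs within wild-type peaks. At `level = "sites"`
#' it is the fraction of class-overlapping wild-type peaks that intersect
#' a mutant peak.
#'
#' @param wt_peaks,mt_peaks Interval tibbles of wild-type and mutant peaks.
#' @param annotation Class-labelled interval tibble.
#' @param class Class label to score (e.g. `"LTR"`).
#' @param level `"bp"` (default) or `"sites"`.
#' @return A fraction in `[0, 1]`.
#' @export
retention_fraction <- function(wt_peaks, mt_peaks, annotation, class,
                               level = c("bp", "sites")) {
  level <- match.arg(level)
  ann <- GenomicRanges::reduce(
    intervals_to_granges(annotation[annotation$label == class, ]),
    ignore.strand = TRUE
  )
  wt <- GenomicRanges::reduce(intervals_to_granges(wt_peaks), ignore.strand = TRUE)
  mt <- GenomicRanges::reduce(intervals_to_granges(mt_peaks), ignore.strand = TRUE)
  if (level == "bp") {
    wt_class <- GenomicRanges::intersect(wt, ann, ignore.strand = TRUE)
    denom <- sum(GenomicRanges::width(wt_class))
    if (denom == 0) stop("no wild-type peak bases on class ", class, call. = FALSE)
    both <- GenomicRanges::intersect(GenomicRanges::intersect(mt, wt, ignore.strand = TRUE),
                                     ann, ignore.strand = TRUE)
    sum(GenomicRanges::width(both)) / denom
  } else {
    on_class <- IRanges::overlapsAny(wt, ann, ignore.strand = TRUE)
    if (!any(on_class)) stop("no wild-type peaks on class ", class, call. = FALSE)
    hit_mt <- IRanges::overlapsAny(wt[on_class], mt, ignore.strand = TRUE)
    mean(hit_mt)
  }
}

#' LTR share of peak base pairs
#'
#' The percentage of a peak set's base pairs annotated as LTR elements,
#' rounded to the nearest integer percent for reporting.
#'
#' @param table A `class_overlap` tibble containing an LTR row.
#' @param class Class to report (default `"LTR"`).
#' @return Integer-valued percent.
#' @examples
#' ltr_share_of_peaks(class_overlap_table(c(LTR = 1.64e6), 8900411))
#' @export
ltr_share_of_peaks <- function(table, class = "LTR") {
  row <- table[table$label == class, ]
  if (nrow(row) != 1) stop("table must contain exactly one ", class, " row", call. = FALSE)
  round(100 * row$overlap_bp / row$total_bp)
}

#' KRAB-domain fraction bracket on zinc-finger genes
#'
#' From counts of KRAB domains (total on protein-coding genes, on genes
#' carrying at least one C2H2 motif, and on genes explicitly annotated as
#' zinc-finger genes), computes the bracket of the fraction of KRAB
#' domains residing on zinc-finger transcription-factor genes: the lower
#' bound uses the conservative annotated-gene count, the upper bound the
#' motif-bearing count.
#'
#' @param n_total Total KRAB domains on genes.
#' @param n_on_zf_motif_genes KRAB domains on genes with >= 1 C2H2 motif.
#' @param n_on_annotated_znf KRAB domains on annotated zinc-finger genes.
#' @return A tibble with `lower_pct` and `upper_pct` (integer percent).
#' @examples
#' krab_fraction_bracket(793, 753, 635)
#' @export
krab_fraction_bracket <- function(n_total, n_on_zf_motif_genes, n_on_annotated_znf) {
  stopifnot(n_total > 0,
            n_on_annotated_znf <= n_on_zf_motif_genes,
            n_on_zf_motif_genes <= n_total)
  tibble(
    lower_pct = round(100 * n_on_annotated_znf / n_total),
    upper_pct = round(100 * n_on_zf_motif_genes / n_total)
  )
}

#' @export
autoplot.class_overlap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$label, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "repeat class", y = "% of base pairs") +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot
#'
#' @param folds Output of [fold_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(folds) {
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$label, y = .data$fold)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "repeat class", y = "fold enrichment over accessible chromatin") +
    ggplot2::theme_minimal()
}
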