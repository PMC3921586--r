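#' Default primate species tree
#'
#' A fixed rooted binary tree over seven primates (human plus six
#' non-human primates) used as the dating scaffold for ERV-family
#' invasions and tandem affinity gains. Branch lengths are abstract epoch
#' units, not years.
#'
#' @return An [ape::phylo] object with leaves `human`, `chimp`,
#'   `gorilla`, `orangutan`, `gibbon`, `macaque`, `marmoset`.
#' @export
primate_tree <- function() {
  ape::read.tree(text = paste0(
    "((((((human:1,chimp:1):1,gorilla:2):1,orangutan:3):1,",
    "gibbon:4):1,macaque:5):1,marmoset:6);"
  ))
}

# canonical label of the branch above `node`: sorted leaf names of its clade
branch_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  leaves <- ape::extract.clade(tree, node)$tip.label
  paste(sort(leaves), collapse = "+")
}

#' All branch labels of a tree
#'
#' Branches are named by the sorted, `+`-joined leaf set of the clade
#' below them; a terminal branch is named by its leaf.
#'
#' @param tree An [ape::phylo] object.
#' @return Character vector of branch labels (one per edge, plus the root
#'   branch).
#' @export
branch_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nodes <- c(seq_len(ntip), (ntip + 1):(ntip + tree$Nnode))
  vapply(nodes, function(nd) branch_label(tree, nd), character(1))
}

#' Date an ERV family's invasion on the species tree
#'
#' Under single-gain parsimony, the invasion branch is the branch above
#' the most recent common ancestor of all species carrying the family.
#' Absences inside that clade are tolerated as losses and counted.
#'
#' @param presence Named 0/1 (or logical) vector over every leaf of
#'   `tree`.
#' @param tree An [ape::phylo] species tree.
#' @param focal Leaf that must carry the family (default `"human"`).
#' @return A one-row tibble `branch`, `n_present`, `n_losses`.
#' @export
date_family <- function(presence, tree, focal = "human") {
  tips <- tree$tip.label
  if (!all(tips %in% names(presence))) {
    stop("presence must be defined for every leaf of the tree", call. = FALSE)
  }
  present <- tips[as.logical(presence[tips])]
  if (length(present) == 0) stop("family present in no leaf", call. = FALSE)
  if (!(focal %in% present)) {
    stop("family absent from the focal species (", focal, ")", call. = FALSE)
  }
  if (length(present) == 1) {
    node <- which(tips == present)
  } else {
    node <- ape::getMRCA(tree, present)
  }
  clade <- if (node <= length(tips)) tips[node] else ape::extract.clade(tree, node)$tip.label
  losses <- setdiff(clade, present)
  if (length(losses) > 0) {
    message("losses within the invasion clade: ", paste(losses, collapse = ", "))
  }
  tibble(branch = branch_label(tree, node),
         n_present = length(present), n_losses = length(losses))
}

#' Date the gain of a tandem's binding affinity
#'
#' The gain branch is the branch above the most recent common ancestor of
#' the species whose predicted motif set contains the focal (human)
#' tandem's target motif.
#'
#' @param motif_sets Named list: species -> character vector of predicted
#'   bound motifs.
#' @param target_motif The focal tandem's target motif.
#' @param tree Species tree.
#' @param focal Focal species (default `"human"`); an error is raised if
#'   its own set lacks `target_motif`.
#' @return A one-row tibble `branch`, `n_present`, `n_losses`.
#' @export
date_affinity_gain <- function(motif_sets, target_motif, tree, focal = "human") {
  tips <- tree$tip.label
  if (!all(tips %in% names(motif_sets))) {
    stop("motif_sets must cover every leaf of the tree", call. = FALSE)
  }
  if (!(target_motif %in% motif_sets[[focal]])) {
    stop("target motif absent from the focal species' own predictions", call. = FALSE)
  }
  presence <- vapply(tips, function(sp) target_motif %in% motif_sets[[sp]], logical(1))
  date_family(stats::setNames(as.numeric(presence), tips), tree, focal = focal)
}

# parent/child adjacency between two branch labels on a tree
branches_adjacent <- function(tree, b1, b2) {
  if (b1 == b2) return(TRUE)
  labs <- branch_labels(tree)
  ntip <- length(tree$tip.label)
  n1 <- which(labs == b1); n2 <- which(labs == b2)
  if (length(n1) != 1 || length(n2) != 1) {
    stop("branch label not on tree: ", if (length(n1) != 1) b1 else b2, call. = FALSE)
  }
  parent <- function(nd) {
    e <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(e) == 0) NA_integer_ else e
  }
  identical(parent(n1), as.integer(n2)) || identical(parent(n2), as.integer(n1))
}

#' Keep repressor pairs whose gain and invasion are contemporaneous
#'
#' A (tandem, family) pair is retained when the tandem's affinity-gain
#' branch matches the family's invasion branch exactly (`mode =
#' "strict"`) or is an adjacent (parent/child) branch (`mode =
#' "relaxed"`, requires `tree`).
#'
#' @param pairs Tibble with columns `tandem` and `family`.
#' @param tandem_epochs Tibble `tandem`, `branch` (from
#'   [date_affinity_gain()]).
#' @param family_epochs Tibble `family`, `branch` (from [date_family()]).
#' @param mode `"strict"` (default) or `"relaxed"`.
#' @param tree Species tree (needed for `mode = "relaxed"`).
#' @return The retained subset of `pairs`, with `tandem_branch` and
#'   `family_branch` columns added.
#' @export
contemporaneous_filter <- function(pairs, tandem_epochs, family_epochs,
                                   mode = c("strict", "relaxed"), tree = NULL) {
  mode <- match.arg(mode)
  j <- dplyr::inner_join(pairs,
                         dplyr::select(tandem_epochs, "tandem", tandem_branch = "branch"),
                         by = "tandem")
  j <- dplyr::inner_join(j,
                         dplyr::select(family_epochs, "family", family_branch = "branch"),
                         by = "family")
  if (nrow(j) < nrow(pairs)) {
    stop("epochs missing for some pairs", call. = FALSE)
  }
  if (mode == "strict") {
    dplyr::filter(j, .data$tandem_branch == .data$family_branch)
  } else {
    if (is.null(tree)) stop("relaxed mode needs the species tree", call. = FALSE)
    keep <- vapply(seq_len(nrow(j)), function(i) {
      branches_adjacent(tree, j$tandem_branch[i], j$family_branch[i])
    }, logical(1))
    j[keep, ]
  }
}

#' Chromosome-19 contingency table for repressor tandems
#'
#' Cross-classifies zinc-finger tandems by location (chromosome 19
#' vs. elsewhere) and predicted-ERV-repressor status. Column totals count
#' all tandems inclusively (the repressor rows are part of the totals, so
#' the reported fraction is repressors over all tandems on that side).
#' Fractions are reported to 2 significant figures as percentages.
#'
#' @param repressor_tandems Character vector of repressor tandem ids
#'   (e.g. from [contemporaneous_filter()]).
#' @param all_tandems Tibble with columns `tandem` and `chrom` covering
#'   every tandem, repressor or not.
#' @param chrom Chromosome of interest (default `"chr19"`).
#' @return A `coev_contingency` object.
#' @export
build_contingency <- function(repressor_tandems, all_tandems, chrom = "chr19") {
  stopifnot(all(c("tandem", "chrom") %in% names(all_tandems)))
  repressor_tandems <- unique(repressor_tandems)
  missing <- setdiff(repressor_tandems, all_tandems$tandem)
  if (length(missing) > 0) {
    stop("repressor tandem(s) missing a chromosome label: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  on19 <- all_tandems$chrom == chrom
  is_rep <- all_tandems$tandem %in% repressor_tandems
  contingency_from_counts(
    a = sum(is_rep & on19), b = sum(is_rep & !on19),
    total_chr19 = sum(on19), total_other = sum(!on19),
    chrom = chrom
  )
}

#' @rdname build_contingency
#' @param a,b Repressor tandem counts on `chrom` and elsewhere.
#' @param total_chr19,total_other Total tandem counts (inclusive of the
#'   repressors).
#' @export
contingency_from_counts <- function(a, b, total_chr19, total_other, chrom = "chr19") {
  stopifnot(a >= 0, b >= 0, total_chr19 >= a, total_other >= b)
  a <- unname(a); b <- unname(b)
  total_chr19 <- unname(total_chr19); total_other <- unname(total_other)
  out <- list(
    a = a, b = b, c = total_chr19 - a, d = total_other - b,
    total_chr19 = total_chr19, total_other = total_other,
    fraction_chr19_pct = signif(100 * a / total_chr19, 2),
    fraction_other_pct = signif(100 * b / total_other, 2),
    chrom = chrom
  )
  class(out) <- "coev_contingency"
  out
}

#' @export
print.coev_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$total_chr19, x$total_other), nrow = 2, byrow = TRUE,
              dimnames = list(c("ERV-binding", "Binding to any sequence"),
                              c(paste("tandems on", x$chrom), "tandems elsewhere")))
  print(m)
  cat(sprintf("Fraction of ERV-binding tandems: %s%% vs %s%%\n",
              format(x$fraction_chr19_pct), format(x$fraction_other_pct)))
  invisible(x)
}

#' @export
tidy.coev_contingency <- function(x, ...) {
  tibble(
    location = rep(c(x$chrom, "other"), 2),
    status = rep(c("repressor", "non_repressor"), each = 2),
    count = c(x$a, x$b, x$c, x$d)
  )
}

#' @export
glance.coev_contingency <- function(x, ...) {
  tibble(a = x$a, b = x$b, total_chr19 = x$total_chr19, total_other = x$total_other,
         fraction_chr19_pct = x$fraction_chr19_pct,
         fraction_other_pct = x$fraction_other_pct,
         p_value = fisher_exact(x)$p_value)
}

#' @export
autoplot.coev_contingency <- function(object, ...) {
  df <- tibble(location = c(object$chrom, "other"),
               pct = c(object$fraction_chr19_pct, object$fraction_other_pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$location, y = .data$pct)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(y = "% of tandems predicted as ERV repressors", x = NULL) +
    ggplot2::theme_minimal()
}

as_counts <- function(table) {
  if (inherits(table, "coev_contingency")) {
    c(a = unname(table$a), b = unname(table$b),
      c = unname(table$c), d = unname(table$d))
  } else if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    c(a = unname(table[1, 1]), b = unname(table[1, 2]),
      c = unname(table[2, 1]), d = unname(table[2, 2]))
  } else {
    stop("table must be a coev_contingency or a 2x2 matrix", call. = FALSE)
  }
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probabilities computed by direct summation
#' of [stats::dhyper()] terms over the support. `alternative = "greater"`
#' sums outcomes with at least the observed top-left count (is the
#' repressor fraction larger on chromosome 19 than elsewhere?);
#' `"two.sided"` sums all outcomes with probability at most that of the
#' observed table. Degenerate margins give p = 1 with a flag.
#'
#' @param table A `coev_contingency` or 2x2 matrix
#'   (rows = repressor/non-repressor, columns = chr19/other).
#' @param alternative `"greater"` (default; directional chr19-excess
#'   hypothesis) or `"two.sided"`.
#' @return A one-row tibble `p_value`, `alternative`, `degenerate`.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  ct <- as_counts(table)
  a <- ct["a"]; b <- ct["b"]; cc <- ct["c"]; d <- ct["d"]
  stopifnot(all(ct >= 0))
  m1 <- a + b            # row total: repressors
  n1 <- a + cc           # column total: chr19
  N <- a + b + cc + d
  if (m1 == 0 || n1 == 0 || m1 == N || n1 == N) {
    return(tibble(p_value = 1, alternative = alternative, degenerate = TRUE))
  }
  support <- max(0, m1 + n1 - N):min(m1, n1)
  probs <- stats::dhyper(support, n1, N - n1, m1)
  if (alternative == "greater") {
    p <- sum(probs[support >= a])
  } else {
    p_obs <- stats::dhyper(a, n1, N - n1, m1)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tibble(p_value = min(1, unname(p)), alternative = alternative, degenerate = FALSE)
}

#' Fisher's exact test under label misclassification
#'
#' Adjusts the chromosome-19 enrichment test for a noisy
#' "ERV-binding" classifier with false-positive rate `alpha` and
#' false-negative rate `beta`, by a seeded parametric bootstrap: each
#' replicate re-draws every tandem's true repressor status from the
#' posterior implied by its observed label (precision for observed
#' positives, the corresponding leak rate for observed negatives, both
#' derived from `alpha`, `beta` and the column's label prevalence),
#' rebuilds the table and records the Fisher p-value; the adjusted
#' p-value is the mean over replicates. With `alpha = beta = 0` the
#' procedure reduces exactly to [fisher_exact()]. When the classifier is
#' uninformative (`alpha + beta = 1`), true labels are re-drawn at the
#' pooled observed rate, and the adjusted p-value saturates near 0.5.
#'
#' @param table A `coev_contingency` or 2x2 matrix.
#' @param alpha,beta False-positive and false-negative rates in `[0, 1)`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param alternative Passed to [fisher_exact()].
#' @return A one-row tibble `p_value`, `alpha`, `beta`, `n_boot`.
#' @export
noisy_fisher <- function(table, alpha = 0, beta = 0, n_boot = 1000, seed = 1L,
                         alternative = "greater") {
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta < 1)
  ct <- as_counts(table)
  if (alpha == 0 && beta == 0) {
    p <- fisher_exact(table, alternative)$p_value
    return(tibble(p_value = p, alpha = alpha, beta = beta, n_boot = n_boot))
  }
  denom <- 1 - alpha - beta
  pooled <- (ct["a"] + ct["b"]) / sum(ct)
  col_rates <- function(n_pos, n_neg) {
    obs_rate <- n_pos / (n_pos + n_neg)
    if (abs(denom) < 1e-12) {
      # uninformative classifier: labels carry no signal, so the true
      # prevalence is the pooled rate on both sides
      pi_true <- unname(pooled)
    } else {
      pi_true <- (obs_rate - alpha) / denom
    }
    if (pi_true < 0 || pi_true > 1) {
      stop("label prevalence inconsistent with alpha/beta (corrected rate outside [0,1])",
           call. = FALSE)
    }
    prec  <- if (obs_rate > 0) pi_true * (1 - beta) / obs_rate else 0
    leak  <- if (obs_rate < 1) pi_true * beta / (1 - obs_rate) else 0
    c(prec = min(1, prec), leak = min(1, leak))
  }
  r19 <- col_rates(ct["a"], ct["c"])
  rot <- col_rates(ct["b"], ct["d"])
  ps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      a_t <- stats::rbinom(1, ct["a"], r19["prec"]) + stats::rbinom(1, ct["c"], r19["leak"])
      b_t <- stats::rbinom(1, ct["b"], rot["prec"]) + stats::rbinom(1, ct["d"], rot["leak"])
      tab <- contingency_from_counts(a_t, b_t, ct["a"] + ct["c"], ct["b"] + ct["d"])
      fisher_exact(tab, alternative)$p_value
    }, numeric(1))
  })
  tibble(p_value = mean(ps), alpha = alpha, beta = beta, n_boot = n_boot)
}
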