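#' Pairwise raw mismatch fractions between aligned sequences
#'
#' Computes, for every pair of equal-length nucleotide strings, the
#' fraction of mismatching positions among positions comparable in both
#' sequences. Positions holding `N` or the gap state `-` in either
#' sequence are ignored pairwise.
#'
#' @param seqs Character vector of equal-length (aligned) DNA strings;
#'   names become matrix dimnames.
#' @return A symmetric matrix of raw mismatch fractions `p` with zero
#'   diagonal.
#' @examples
#' pairwise_p(c(a = "ACGT", b = "ACGA"))
#' @export
pairwise_p <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must be equal length (aligned)", call. = FALSE)
  M <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)), nrow = n, byrow = TRUE)
  code <- matrix(match(M, c("A", "C", "G", "T")), nrow = n)  # NA for N/- etc.
  P <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    xi <- code[i, ]
    for (j in (i + 1):n) {
      xj <- code[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      ncomp <- sum(ok)
      if (ncomp == 0) {
        stop(sprintf("no comparable positions between sequences %d and %d", i, j),
             call. = FALSE)
      }
      P[i, j] <- P[j, i] <- sum(xi[ok] != xj[ok]) / ncomp
    }
  }
  P
}

#' Jukes-Cantor distance correction
#'
#' Converts a raw mismatch fraction `p` to an estimated number of
#' substitutions per site, `d = -(3/4) * log(1 - 4p/3)`. The correction
#' diverges as `p` approaches 0.75, so distances are censored at `d_max`:
#' fully saturated pairs (`p >= 0.75`, warned about) and any corrected
#' distance exceeding `d_max` are reported as `d_max`, keeping the map
#' monotone and downstream tree building total.
#'
#' @param p Numeric vector or matrix of mismatch fractions in `[0, 1)`.
#' @param d_max Censoring value for saturated pairs, in substitutions per
#'   site (default 1.5).
#' @return Corrected distances, same shape as `p`; `d >= p` everywhere.
#' @examples
#' jukes_cantor(0.1)
#' @export
jukes_cantor <- function(p, d_max = 1.5) {
  stopifnot(all(p >= 0), all(p <= 1))
  sat <- p >= 0.75
  d <- p
  d[!sat] <- pmin(-0.75 * log(1 - 4 * p[!sat] / 3), d_max)
  if (any(sat)) {
    warning(sum(sat), " saturated pair(s) (p >= 0.75) censored at d_max = ", d_max,
            call. = FALSE)
    d[sat] <- d_max
  }
  d
}

#' UPGMA tree with duplication ages
#'
#' Average-linkage (UPGMA) agglomeration of a distance matrix. Clusters at
#' distance `D` merge at height `D/2`; distances to a merged cluster are
#' the size-weighted average of its parts. Ties are broken
#' deterministically: among all minimal-distance pairs, the pair whose
#' sorted leaf-name sets come first lexicographically is merged. The
#' height of a leaf's first merge is its duplication age (in the units of
#' the input distances, here fraction of nucleotide substitutions).
#'
#' @param dist A symmetric numeric matrix with zero diagonal and dimnames,
#'   or a [stats::dist] object.
#' @return An object of class `upgma_tree`: list with `phylo` (ultrametric
#'   [ape::phylo]), `ages` (tibble `id`, `age`), `root_height`.
#' @examples
#' D <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(D)$ages
#' @export
upgma <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  n <- nrow(dist)
  if (anyNA(dist)) stop("distance matrix contains NA/NaN", call. = FALSE)
  stopifnot(n >= 2, isTRUE(all.equal(dist, t(dist))), all(diag(dist) == 0))
  ids <- rownames(dist)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  D <- dist
  members <- as.list(ids)              # leaf names per active cluster
  sizes <- rep(1L, n)
  newick <- ids                        # newick fragment per active cluster
  heights <- rep(0, n)                 # height of each active cluster's root
  age <- stats::setNames(rep(NA_real_, n), ids)
  active <- seq_len(n)
  label_of <- function(k) paste(sort(members[[k]]), collapse = "|")
  while (length(active) > 1) {
    m <- length(active)
    sub <- D[active, active, drop = FALSE]
    off <- sub + diag(Inf, m)
    dmin <- min(off)
    cand <- which(off - dmin <= dmin * 1e-12 + 1e-15, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(rc) {
        paste(sort(c(label_of(active[rc[1]]), label_of(active[rc[2]]))), collapse = "~")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- active[cand[1, 1]]; j <- active[cand[1, 2]]
    h <- D[i, j] / 2
    for (leaf in c(members[[i]], members[[j]])) {
      if (is.na(age[leaf])) age[leaf] <- h
    }
    # for leaves merging again later, age stays the FIRST merge height
    bi <- h - heights[i]; bj <- h - heights[j]
    newick[i] <- sprintf("(%s:%.12g,%s:%.12g)", newick[i], bi, newick[j], bj)
    others <- setdiff(active, c(i, j))
    if (length(others) > 0) {
      D[i, others] <- D[others, i] <-
        (sizes[i] * D[i, others] + sizes[j] * D[j, others]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    active <- setdiff(active, j)
  }
  root <- active[1]
  phylo <- ape::read.tree(text = paste0(newick[root], ";"))
  out <- list(
    phylo = phylo,
    ages = tibble(id = ids, age = unname(age[ids])),
    root_height = heights[root]
  )
  class(out) <- "upgma_tree"
  out
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", nrow(x$ages), "leaves, root height",
      format(x$root_height, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.upgma_tree <- function(x, ...) x$ages

#' @export
glance.upgma_tree <- function(x, ...) {
  tibble(n_leaves = nrow(x$ages), root_height = x$root_height,
         mean_age = mean(x$ages$age))
}

#' Duplication age of each motif
#'
#' The age of a motif is the height of its first merge in the UPGMA tree,
#' i.e. half its corrected divergence from its closest relative cluster:
#' the time of the most recent duplication event associated with it.
#'
#' @param tree An `upgma_tree` from [upgma()].
#' @return A tibble `id`, `age` (fraction of nucleotide substitutions).
#' @export
duplication_ages <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  if (nrow(tree$ages) < 2) stop("ages undefined for a single-leaf tree", call. = FALSE)
  tree$ages
}

#' Count-scaled age density curves per group
#'
#' Gaussian kernel density of duplication ages per group, scaled so that
#' the area under each curve equals the number of motifs in the group
#' (so curves for groups of different sizes are directly comparable).
#'
#' @param ages Tibble with columns `age` and `group`.
#' @param bw Kernel bandwidth; default Silverman's rule
#'   ([stats::bw.nrd0()]).
#' @return A tibble `group`, `age`, `density`, `n`.
#' @export
age_density <- function(ages, bw = NULL) {
  stopifnot(all(c("age", "group") %in% names(ages)), all(ages$age >= 0))
  groups <- split(ages$age, ages$group)
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(names(groups)[lengths(groups) > 0], function(g) {
    x <- groups[[g]]
    if (length(x) == 1) {
      d <- stats::density(x, bw = if (is.null(bw)) 0.01 else bw)
    } else {
      d <- if (is.null(bw)) stats::density(x) else stats::density(x, bw = bw)
    }
    tibble(group = g, age = d$x, density = d$y * length(x), n = length(x))
  })
}

#' Age density plot
#'
#' @param dens Output of [age_density()].
#' @return A ggplot object.
#' @export
plot_age_density <- function(dens) {
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$age, y = .data$density,
                                     colour = .data$group)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "age (fraction of nucleotide substitutions)",
                  y = "zinc-finger motifs per unit time") +
    ggplot2::theme_minimal()
}

#' Divergence-based spatial clustering of motifs along a chromosome
#'
#' Cuts an average-linkage hierarchical clustering of the motif divergence
#' matrix into `k` clusters and summarises each cluster's positional
#' distribution as a kernel density normalised to total mass one.
#'
#' @param positions Numeric vector of motif midpoint positions (bp) on one
#'   chromosome, aligned with the rows of `dist`.
#' @param dist Symmetric divergence matrix (see [pairwise_p()] /
#'   [jukes_cantor()]).
#' @param k Number of clusters (`2 <= k <= length(positions)`).
#' @return A list with `clusters` (tibble `id`, `position`, `cluster`) and
#'   `density` (tibble `cluster`, `position`, `density`, unit mass per
#'   cluster).
#' @export
spatial_clusters <- function(positions, dist, k) {
  n <- length(positions)
  stopifnot(nrow(dist) == n)
  if (k > n) stop("k exceeds the number of motifs", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dist), method = "average")
  cl <- stats::cutree(hc, k = k)
  ids <- rownames(dist)
  if (is.null(ids)) ids <- paste0("m", seq_len(n))
  clusters <- tibble(id = ids, position = positions, cluster = factor(cl))
  dens <- purrr::map_dfr(levels(clusters$cluster), function(g) {
    x <- clusters$position[clusters$cluster == g]
    if (length(x) < 2) {
      return(tibble(cluster = g, position = x, density = 1))
    }
    d <- stats::density(x)
    tibble(cluster = g, position = d$x, density = d$y)
  })
  list(clusters = clusters, density = dens)
}

#' Cluster positional-density plot
#'
#' @param sc Output of [spatial_clusters()].
#' @return A ggplot object.
#' @export
plot_spatial_clusters <- function(sc) {
  ggplot2::ggplot(sc$density, ggplot2::aes(x = .data$position, y = .data$density,
                                           colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "chromosome position (bp)", y = "density (unit mass per cluster)") +
    ggplot2::theme_minimal()
}

#' Correlation between physical distance and sequence divergence
#'
#' Rank (Spearman, default) or Pearson correlation between pairwise
#' physical distance `|pos_i - pos_j|` and pairwise divergence `d_ij`,
#' with a one-sided permutation p-value obtained by permuting positions.
#' A positive correlation is the signature of local tandem duplication.
#'
#' @param positions Motif positions (bp) on one chromosome.
#' @param dist Symmetric divergence matrix.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A tibble `estimate`, `p_value`, `method`, `n_perm`.
#' @export
distance_divergence_correlation <- function(positions, dist,
                                            method = c("spearman", "pearson"),
                                            n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  n <- length(positions)
  stopifnot(n >= 3, nrow(dist) == n)
  lower <- lower.tri(dist)
  dvec <- dist[lower]
  if (stats::sd(dvec) == 0) stop("divergences are constant; correlation undefined", call. = FALSE)
  obs_stat <- function(pos) {
    pd <- abs(outer(pos, pos, "-"))[lower]
    stats::cor(pd, dvec, method = method)
  }
  obs <- obs_stat(positions)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) obs_stat(sample(positions)), numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  tibble(estimate = obs, p_value = p, method = method, n_perm = n_perm)
}
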