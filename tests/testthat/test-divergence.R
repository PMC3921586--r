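test_that("pairwise mismatch fractions match per-position counting", {
  P <- pairwise_p(c(a = "ACGT", b = "ACGA"))
  expect_equal(P["a", "b"], 0.25)
  expect_equal(diag(P), c(a = 0, b = 0))
  expect_equal(pairwise_p(c(x = "AAAA", y = "AAAA"))["x", "y"], 0)
  # N and gap positions are ignored pairwise
  P2 <- pairwise_p(c(x = "ACGTN-", y = "ACTT-A"))
  expect_equal(P2["x", "y"], 1 / 4)
  expect_error(pairwise_p(c(x = "NNN", y = "AAA")), "comparable")
  # random 63-mers vs brute-force count
  withr::with_seed(12, {
    for (i in 1:25) {
      s <- c(a = random_dna_str(63), b = random_dna_str(63))
      va <- strsplit(s[["a"]], "")[[1]]; vb <- strsplit(s[["b"]], "")[[1]]
      expect_equal(pairwise_p(s)["a", "b"], mean(va != vb))
    }
  })
})

test_that("Jukes-Cantor correction matches its closed form and censors saturation", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), 0.107326, tolerance = 1e-5)
  expect_equal(jukes_cantor(0.5), 0.823959, tolerance = 1e-5)
  expect_warning(d <- jukes_cantor(c(0.2, 0.8)), "saturated")
  expect_equal(d[2], 1.5)
  # d >= p, monotone, and d - p -> 0 as p -> 0
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) >= 0))
  expect_lt(jukes_cantor(1e-6) - 1e-6, 1e-9)
})

test_that("UPGMA agglomerates the hand example and stays ultrametric", {
  D <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  expect_equal(tr$root_height, 0.3)
  ages <- duplication_ages(tr)
  expect_equal(ages$age[match(c("A", "B", "C"), ages$id)], c(0.1, 0.1, 0.3))
  # identical motifs have age zero
  D0 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(duplication_ages(upgma(D0))$age, c(0, 0))
  expect_error(upgma(matrix(NaN, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "NA")
})

test_that("UPGMA equals an independent naive agglomeration on random instances", {
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(4:8, 1)
      M <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
      M[upper.tri(M)] <- round(runif(n * (n - 1) / 2, 0.05, 1.5), 3)
      M <- M + t(M)
      mine <- upgma(M)
      ora <- oracle_upgma_ages(M)
      expect_equal(mine$ages$age, unname(ora$ages), tolerance = 1e-9)
      expect_equal(mine$root_height, ora$root, tolerance = 1e-9)
      # ultrametric: all leaves equidistant from the root
      depths <- ape::node.depth.edgelength(mine$phylo)
      expect_lt(diff(range(depths[seq_len(n)])), 1e-9)
    }
  })
})

test_that("equal distances give merge heights independent of order", {
  n <- 5
  M <- matrix(0.4, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(M) <- 0
  tr <- upgma(M)
  expect_equal(tr$ages$age, rep(0.2, n))
  expect_equal(tr$root_height, 0.2)
})

test_that("age density curves integrate to their group counts", {
  withr::with_seed(5, {
    ages <- tibble::tibble(age = c(rexp(500, 5), rexp(120, 2)),
                           group = rep(c("chr19", "other"), c(500, 120)))
    dens <- age_density(ages)
    for (g in c("chr19", "other")) {
      d <- dens[dens$group == g, ]
      area <- sum(diff(d$age) * (head(d$density, -1) + tail(d$density, -1)) / 2)
      expect_equal(area, d$n[1], tolerance = 0.01 * d$n[1])
    }
    # single-value group: unit-area bump scaled to 1
    d1 <- age_density(tibble::tibble(age = 0.3, group = "solo"))
    area1 <- sum(diff(d1$age) * (head(d1$density, -1) + tail(d1$density, -1)) / 2)
    expect_equal(area1, 1, tolerance = 0.01)
  })
})

test_that("spatial clustering separates distinct families and handles k = n", {
  withr::with_seed(8, {
    # two sequence families at two loci
    fam1 <- replicate(6, random_dna_str(60))
    fam2 <- replicate(6, random_dna_str(60))
    seqs <- c(vapply(1:6, function(i) fam1[1], ""), vapply(1:6, function(i) fam2[1], ""))
    # perturb within family slightly
    seqs <- vapply(seq_along(seqs), function(i) {
      v <- strsplit(seqs[i], "")[[1]]
      j <- sample(60, 2)
      v[j] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
      paste(v, collapse = "")
    }, "")
    names(seqs) <- paste0("m", 1:12)
    D <- suppressWarnings(jukes_cantor(pairwise_p(seqs)))
    pos <- c(seq(0, 500, length.out = 6), seq(10000, 10500, length.out = 6))
    sc <- spatial_clusters(pos, D, k = 2)
    expect_equal(dplyr::n_distinct(sc$clusters$cluster[1:6]), 1)
    expect_equal(dplyr::n_distinct(sc$clusters$cluster[7:12]), 1)
    expect_false(sc$clusters$cluster[1] == sc$clusters$cluster[7])
    # per-cluster density mass is one
    for (g in levels(sc$clusters$cluster)) {
      d <- sc$density[sc$density$cluster == g, ]
      area <- sum(diff(d$position) * (head(d$density, -1) + tail(d$density, -1)) / 2)
      expect_equal(area, 1, tolerance = 0.02)
    }
    # k = n gives singletons
    scn <- spatial_clusters(pos, D, k = 12)
    expect_equal(dplyr::n_distinct(scn$clusters$cluster), 12)
    expect_error(spatial_clusters(pos, D, k = 13), "exceeds")
  })
})

test_that("distance-divergence correlation detects monotone structure and nulls", {
  # divergence strictly increasing with distance -> rho = 1
  pos <- c(0, 100, 300, 600, 1000)
  D <- abs(outer(pos, pos, "-")) / 1000
  dimnames(D) <- list(paste0("m", 1:5), paste0("m", 1:5))
  r <- distance_divergence_correlation(pos, D, n_perm = 199, seed = 2)
  expect_equal(r$estimate, 1)
  expect_lt(r$p_value, 0.05)
  expect_error(distance_divergence_correlation(pos, matrix(0.5 - diag(0.5, 5), 5), ),
               "constant")
  # independent divergences: null p roughly uniform (coarse check)
  withr::with_seed(9, {
    ps <- replicate(40, {
      n <- 12
      pos <- sort(runif(n, 0, 1e5))
      M <- matrix(0, n, n)
      M[upper.tri(M)] <- runif(n * (n - 1) / 2, 0.1, 1)
      M <- M + t(M)
      distance_divergence_correlation(pos, M, n_perm = 99, seed = 3)$p_value
    })
    expect_gt(mean(ps), 0.25)
    expect_lt(mean(ps), 0.75)
  })
})
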