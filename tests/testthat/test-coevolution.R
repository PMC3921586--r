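tree <- primate_tree()

test_that("family dating follows single-gain parsimony with losses logged", {
  tips <- tree$tip.label
  pres <- function(members) stats::setNames(as.numeric(tips %in% members), tips)
  expect_equal(date_family(pres("human"), tree)$branch, "human")
  expect_equal(date_family(pres(c("human", "chimp", "gorilla")), tree)$branch,
               "chimp+gorilla+human")
  expect_equal(date_family(pres(tips), tree)$branch,
               paste(sort(tips), collapse = "+"))
  # absences inside the clade are losses
  expect_message(d <- date_family(pres(c("human", "gorilla")), tree), "chimp")
  expect_equal(d$branch, "chimp+gorilla+human")
  expect_equal(d$n_losses, 1)
  expect_error(date_family(pres(character(0)), tree), "no leaf")
  expect_error(date_family(pres("chimp"), tree), "focal")
})

test_that("affinity-gain dating mirrors family dating on motif sets", {
  tips <- tree$tip.label
  sets <- stats::setNames(lapply(tips, function(x) character(0)), tips)
  sets$human <- "ACGACGACG"
  expect_equal(date_affinity_gain(sets, "ACGACGACG", tree)$branch, "human")
  all_sets <- stats::setNames(lapply(tips, function(x) "ACGACGACG"), tips)
  expect_equal(date_affinity_gain(all_sets, "ACGACGACG", tree)$branch,
               paste(sort(tips), collapse = "+"))
  expect_error(date_affinity_gain(sets, "TTTTTTTTT", tree), "focal")
})

test_that("the contemporaneous filter keeps exactly the matching pairs", {
  pairs <- tibble::tibble(tandem = c("t1", "t2", "t3"),
                          family = c("f1", "f2", "f3"))
  te <- tibble::tibble(tandem = c("t1", "t2", "t3"),
                       branch = c("human", "chimp+human",
                                  paste(sort(tree$tip.label), collapse = "+")))
  fe <- tibble::tibble(family = c("f1", "f2", "f3"),
                       branch = c("human", "chimp+gorilla+human", "human"))
  kept <- contemporaneous_filter(pairs, te, fe)
  expect_equal(kept$tandem, "t1")
  # relaxed mode admits parent/child branches
  rel <- contemporaneous_filter(pairs, te, fe, mode = "relaxed", tree = tree)
  expect_setequal(rel$tandem, c("t1", "t2"))
  expect_error(contemporaneous_filter(pairs[1:3, ], te[1:2, ], fe), "missing")
})

test_that("simulated planted pairs pass the strict filter exactly", {
  co <- simulate_coevolution(sim_config(seed = 4))
  tr <- co$truth
  # dating the simulated inputs recovers the planted branches
  fams <- unique(tr$family)
  fe <- purrr::map_dfr(fams, function(f) {
    pv <- unlist(co$presence[co$presence$family == f, tree$tip.label])
    dplyr::mutate(date_family(pv, tree), family = f)
  })
  expect_equal(fe$branch, tr$invasion_branch[match(fams, tr$family)])
  te <- purrr::map_dfr(seq_len(nrow(tr)), function(i) {
    dplyr::mutate(
      date_affinity_gain(co$motif_sets[[tr$tandem[i]]], tr$motif[i], tree),
      tandem = tr$tandem[i])
  })
  expect_equal(te$branch, tr$gain_branch)
  kept <- contemporaneous_filter(tr[, c("tandem", "family")], te, fe)
  expect_setequal(kept$tandem, tr$tandem[tr$contemporaneous])
})

test_that("contingency tables reproduce the chromosome-19 census arithmetic", {
  ct <- contingency_from_counts(32, 9, 2492, 1898)
  expect_equal(ct$fraction_chr19_pct, 1.3)
  expect_equal(ct$fraction_other_pct, 0.47)
  expect_equal(ct$c, 2460)
  expect_equal(ct$d, 1889)
  ct0 <- contingency_from_counts(0, 0, 100, 100)
  expect_equal(ct0$fraction_chr19_pct, 0)
  # built from labels
  all_t <- tibble::tibble(tandem = paste0("t", 1:10),
                          chrom = rep(c("chr19", "chr4"), each = 5))
  ct2 <- build_contingency(c("t1", "t2", "t6"), all_t)
  expect_equal(ct2$a, 2)
  expect_equal(ct2$b, 1)
  expect_equal(ct2$total_chr19, 5)
  expect_error(build_contingency("zzz", all_t), "missing")
  td <- tidy(ct)
  expect_equal(sum(td$count), 32 + 9 + 2460 + 1889)
})

test_that("fisher_exact equals enumeration over random small tables", {
  r <- fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE), "greater")
  expect_equal(r$p_value, 17 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))$p_value, 1)
  expect_true(fisher_exact(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))$degenerate)
  withr::with_seed(23, {
    for (i in 1:100) {
      tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
      for (alt in c("greater", "two.sided")) {
        mine <- fisher_exact(tab, alt)$p_value
        ora <- oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2], alt)
        if (sum(tab[1, ]) == 0 || sum(tab[, 1]) == 0 ||
            sum(tab[2, ]) == 0 || sum(tab[, 2]) == 0) next
        expect_equal(mine, ora, tolerance = 1e-12)
      }
      # cross-check against the reference implementation
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        expect_equal(fisher_exact(tab, "greater")$p_value,
                     stats::fisher.test(tab, alternative = "greater")$p.value,
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("fisher_exact(greater) is monotone decreasing in the top-left count", {
  ps <- vapply(20:35, function(a) {
    fisher_exact(contingency_from_counts(a, 41 - a, 2492, 1898))$p_value
  }, 1)
  expect_true(all(diff(ps) < 0))
})

test_that("the noisy-classifier correction reduces, saturates and is seeded", {
  ct <- contingency_from_counts(32, 9, 2492, 1898)
  expect_identical(noisy_fisher(ct, 0, 0)$p_value, fisher_exact(ct)$p_value)
  sat <- noisy_fisher(ct, 0.5, 0.5, n_boot = 400, seed = 2)
  expect_equal(sat$p_value, 0.5, tolerance = 0.12)
  a <- noisy_fisher(ct, 0.002, 0.1, n_boot = 200, seed = 7)
  b <- noisy_fisher(ct, 0.002, 0.1, n_boot = 200, seed = 7)
  expect_identical(a$p_value, b$p_value)
  # inconsistent prevalence errors
  expect_error(noisy_fisher(ct, alpha = 0.3, beta = 0.1), "inconsistent")
})
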