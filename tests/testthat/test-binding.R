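test_that("finger PWMs follow the recognition code with uniform fallback", {
  pwm <- finger_to_pwm(c("D", "A", "N", "R"))  # helix -1, 2, 3, 6
  # helix 6 = R -> G at 5'; helix 3 = N -> A middle; helix -1 = D -> C at 3'
  expect_equal(rownames(pwm)[apply(pwm, 2, which.max)], c("G", "A", "C"))
  expect_equal(colSums(pwm), rep(1, 3), tolerance = 1e-9)
  # residue absent from the table -> uniform column
  pwm2 <- finger_to_pwm(c("W", "W", "W", "W"))
  expect_equal(as.numeric(pwm2), rep(0.25, 12))
  expect_error(finger_to_pwm(c("A", "A")), "4 residues")
  bad_code <- tibble::tibble(position = -1, residue = "N",
                             A = 2, C = 0, G = 0, T = 0)
  expect_error(finger_to_pwm(c("N", "A", "N", "N"), code = bad_code), "malformed")
})

test_that("tandem PWMs concatenate fingers in reverse order", {
  # N-terminal finger decodes GGG, C-terminal decodes AAA:
  # the tandem consensus is AAAGGG (N-terminal finger binds the 3' subsite)
  f_ggg <- c("R", "A", "R", "R")
  f_aaa <- c("N", "A", "N", "N")
  pwm <- tandem_to_pwm(list(f_ggg, f_aaa))
  expect_equal(pwm$consensus, "AAAGGG")
  expect_equal(ncol(pwm$pwm), 6)
  # max score equals the sum of column maxima; threshold is 0.8 of it
  expect_equal(pwm$max_score, sum(apply(pwm$log_odds, 2, max)))
  expect_equal(pwm$threshold, 0.8 * pwm$max_score)
  expect_error(tandem_to_pwm(list(f_ggg)), ">= 2")
})

test_that("PWM scanning equals the exhaustive per-offset oracle", {
  withr::with_seed(14, {
    for (i in 1:100) {
      fingers <- replicate(sample(2:3, 1),
                           sample(c("N", "D", "R", "Q", "K", "S", "E", "W"), 4,
                                  replace = TRUE),
                           simplify = FALSE)
      pwm <- tandem_to_pwm(fingers)
      seq <- random_dna_str(sample(30:60, 1))
      mine <- scan_pwm(pwm, seq, threshold = -Inf)
      ora <- oracle_scan_pwm(pwm, seq)
      mine <- mine[order(mine$start, mine$strand), ]
      ora <- ora[order(ora$start, ora$strand), ]
      expect_equal(mine$score, ora$score, tolerance = 1e-9)
      expect_equal(mine$start, ora$start)
    }
  })
})

test_that("a planted consensus is the top site and scanning is strand-symmetric", {
  pwm <- tandem_to_pwm(list(c("R", "A", "R", "R"), c("N", "A", "N", "N")))
  seq <- paste0("TTTTTTTT", pwm$consensus, "TTTTTTT")
  hits <- scan_pwm(pwm, seq)
  expect_equal(hits$start[1], 8)
  expect_equal(hits$score[1], pwm$max_score)
  rc <- kznfevo:::revcomp(seq)
  hits_rc <- scan_pwm(pwm, rc)
  L <- nchar(seq)
  expect_setequal(paste(L - hits$end, L - hits$start), paste(hits_rc$start, hits_rc$end))
})

test_that("family-specific k-mers are found and shared k-mers excluded", {
  consensi <- c(A = paste0("AAAAAAAAAAAA", "GACGTTCGA", "AAAAAAAAAAAA"),
                B = paste0("AAAAAAAAAAAA", "CCCTGGTAC", "AAAAAAAAAAAA"))
  fsm <- family_specific_motifs(consensi, k = 9)
  canon <- function(x) pmin(x, kznfevo:::revcomp(x))
  expect_true(any(fsm$family == "A" & fsm$kmer == canon("GACGTTCGA")))
  expect_true(any(fsm$family == "B" & fsm$kmer == canon("CCCTGGTAC")))
  # the shared poly-A context is reported for neither family
  expect_false(canon("AAAAAAAAA") %in% fsm$kmer)
  # discovery is invariant under reverse-complementing a consensus
  consensi2 <- consensi
  consensi2[["B"]] <- kznfevo:::revcomp(consensi2[["B"]])
  fsm2 <- family_specific_motifs(consensi2, k = 9)
  expect_setequal(paste(fsm$family, fsm$kmer), paste(fsm2$family, fsm2$kmer))
  expect_message(family_specific_motifs(c(consensi, C = "ACGT"), k = 9), "skipped")
})

test_that("planted repressor pairs are recovered end to end", {
  co <- simulate_coevolution(sim_config(seed = 4))
  tr <- co$truth
  # planted k-mers appear among the family-specific motifs
  fsm <- family_specific_motifs(co$consensi, k = 9)
  canon <- function(x) pmin(x, kznfevo:::revcomp(x))
  expect_true(all(mapply(function(f, m) any(fsm$family == f & fsm$kmer == canon(m)),
                         tr$family, tr$motif)))
  pr <- predict_repressors(co$tandems, co$consensi)
  expect_true(all(paste(tr$tandem, tr$family) %in% paste(pr$tandem, pr$family)))
  # a tandem with uniform PWM yields no pairs
  dull <- tibble::tibble(tandem = "dull", chrom = "chr19",
                         fingers = list(list(rep("W", 4), rep("W", 4), rep("W", 4))))
  expect_equal(nrow(predict_repressors(dull, co$consensi)), 0)
})

test_that("pair recovery degrades gracefully under consensus mutation noise", {
  withr::with_seed(77, {
    co <- simulate_coevolution(sim_config(seed = 15))
    noisy <- vapply(co$consensi, function(s) {
      v <- strsplit(s, "")[[1]]
      j <- which(runif(length(v)) < 0.05)
      v[j] <- sample(c("A", "C", "G", "T"), length(j), replace = TRUE)
      paste(v, collapse = "")
    }, "")
    pr0 <- predict_repressors(co$tandems, co$consensi)
    prn <- predict_repressors(co$tandems, noisy)
    tr <- co$truth
    rec0 <- mean(paste(tr$tandem, tr$family) %in% paste(pr0$tandem, pr0$family))
    recn <- mean(paste(tr$tandem, tr$family) %in% paste(prn$tandem, prn$family))
    expect_gte(rec0, 0.9)
    expect_lte(recn, rec0)
    expect_gt(recn, 0.3)  # 5% noise degrades but does not destroy recovery
  })
})
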