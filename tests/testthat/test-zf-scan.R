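test_that("six-frame translation produces the expected frames", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr$protein[fr$strand == "+" & fr$frame == 0], "MK")
  # reverse-complementing the input swaps the strand frame sets
  fr2 <- six_frame_translate(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("ATGAAA"))))
  expect_setequal(fr2$protein[fr2$strand == "-"], fr$protein[fr$strand == "+"])
  # codons containing N translate to X
  frN <- six_frame_translate("ATGANA")
  expect_equal(substr(frN$protein[frN$strand == "+" & frN$frame == 0], 2, 2), "X")
})

test_that("protein windows map back to exact genomic intervals", {
  # protein offset 1 (0-based) in frame +1 of a 10-mer -> genomic [4, 7)
  expect_equal(protein_to_genomic(2, 1, frame = 1, strand = "+", seq_len = 10),
               c(4, 7))
  # minus strand: first aa of frame 0 covers the last 3 bases
  expect_equal(protein_to_genomic(1, 1, frame = 0, strand = "-", seq_len = 9),
               c(6, 9))
  # genomic length is always 3x protein length
  for (i in 1:20) {
    ps <- sample(1:5, 1); pl <- sample(1:8, 1)
    g <- protein_to_genomic(ps, pl, sample(0:2, 1), sample(c("+", "-"), 1), 100)
    expect_equal(g[2] - g[1], 3 * pl)
  }
})

test_that("C2H2 matching equals the exhaustive window oracle", {
  hit <- find_c2h2("YKCEECGKAFNRSSNLTKHKRIH")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$prot_start, 3)
  expect_equal(hit$length, 21)
  expect_equal(hit$protein_seq, "CEECGKAFNRSSNLTKHKRIH")

  expect_equal(nrow(find_c2h2(strrep("A", 40))), 0)

  # two adjacent fingers yield two disjoint hits
  two <- paste0("CEECGKAFNRSSNLTKHKRIH", "CEECGKAFNRSSNLTKHKRIH")
  hits2 <- find_c2h2(two)
  expect_equal(nrow(hits2), 2)
  expect_true(hits2$prot_start[2] >= hits2$prot_start[1] + hits2$length[1])

  withr::with_seed(42, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]
    for (i in 1:60) {
      prot <- paste(sample(aa, 60, replace = TRUE,
                           prob = c(rep(1, 20), 0.5, 0.3)), collapse = "")
      mine <- find_c2h2(prot)[, c("prot_start", "s1", "s2", "length")]
      ora <- oracle_c2h2(prot)
      if (is.null(ora)) {
        expect_equal(nrow(mine), 0)
      } else {
        expect_equal(nrow(mine), nrow(ora))
        expect_setequal(paste(mine$prot_start, mine$s1, mine$s2),
                        paste(ora$prot_start, ora$s1, ora$s2))
      }
    }
  })
})

test_that("overlap resolution is greedy from the left with documented tie-breaks", {
  h <- tibble::tibble(chrom = "c", start = c(10, 10), end = c(73, 73),
                      strand = c("-", "+"))
  expect_equal(resolve_overlaps(h)$strand, "+")

  h2 <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(63, 163),
                       strand = "+")
  expect_equal(nrow(resolve_overlaps(h2)), 2)

  # staggered chains equal brute-force greedy from the left
  withr::with_seed(7, {
    for (i in 1:30) {
      n <- sample(3:10, 1)
      s <- sort(sample(0:80, n))
      h <- tibble::tibble(chrom = "c", start = s,
                          end = s + sample(c(63, 66, 69, 72, 75), n, replace = TRUE),
                          strand = sample(c("+", "-"), n, replace = TRUE))
      got <- resolve_overlaps(h)
      # brute force: scan sorted candidates, keep if disjoint from all kept
      ord <- order(h$start, -(h$end - h$start), h$strand != "+")
      kept <- integer(0)
      for (k in ord) {
        if (all(h$start[k] >= h$end[kept] | h$end[k] <= h$start[kept])) {
          kept <- c(kept, k)
        }
      }
      expect_setequal(paste(got$start, got$end), paste(h$start[kept], h$end[kept]))
      # retained hits pairwise disjoint
      gs <- got[order(got$start), ]
      if (nrow(gs) > 1) expect_true(all(gs$start[-1] >= gs$end[-nrow(gs)]))
    }
  })
})

test_that("tandem grouping uses a strict <200 bp gap rule", {
  mk <- function(starts, strand = "+") {
    tibble::tibble(chrom = "c", start = starts, end = starts + 63, strand = strand)
  }
  # gaps of 150 -> one 3-finger tandem
  t1 <- group_tandems(mk(c(0, 213, 426)))
  expect_equal(dplyr::n_distinct(t1$tandem_id), 1)
  expect_false(anyNA(t1$tandem_id))
  # gap of 250 -> no tandem
  t2 <- group_tandems(mk(c(0, 313)))
  expect_true(all(is.na(t2$tandem_id)))
  # gap of exactly 200 splits
  t3 <- group_tandems(mk(c(0, 263)))
  expect_true(all(is.na(t3$tandem_id)))
  # gap of 199 joins
  t4 <- group_tandems(mk(c(0, 262)))
  expect_false(anyNA(t4$tandem_id))
  # opposite strands never join
  t5 <- group_tandems(mk(c(0, 100), strand = c("+", "-")))
  expect_true(all(is.na(t5$tandem_id)))
})

test_that("scan of a sequence and its reverse complement mirror exactly", {
  withr::with_seed(3, {
    sim <- simulate_znf_clusters(sim_config(seed = 5, n_clusters = 1,
                                            genes_per_cluster = 2))
    g <- sim$genome
    h <- scan_zf(g)
    L <- nchar(g[[1]])
    g2 <- g
    g2[[1]] <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", g[[1]]), "")[[1]]),
                     collapse = "")
    h2 <- scan_zf(g2)
    expect_equal(nrow(h2), nrow(h))
    expect_setequal(paste(L - h$end, L - h$start), paste(h2$start, h2$end))
    expect_setequal(h2$protein_seq, h$protein_seq)
  })
})

test_that("hits are assigned to genes by midpoint and counted per chromosome", {
  genes <- genomic_intervals(c("c", "c"), c(0, 50), c(40, 120),
                             label = c("g1", "g2"))
  hits <- tibble::tibble(chrom = "c", start = c(5, 60, 200), end = c(35, 90, 230),
                         strand = "+")
  a <- assign_genes(hits, genes)
  expect_equal(sort(count_hits_by_gene(a)$gene_id), c("g1", "g2"))
  expect_equal(count_hits_by_gene(a)$n_hits, c(1, 1))
  expect_equal(count_hits_by_chrom(a)$n_hits, 3)  # intergenic hit still counted
  expect_true(is.na(a$gene_id[a$start == 200]))
})
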