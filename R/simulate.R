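#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' are the study conditions the package is validated under: 45 diploid
#' individuals (90 haplotypes) for deletion polymorphisms; ChIP peak
#' lengths Normal(474, 74) truncated at 50 bp; LTR/LINE binding enriched
#' about sixfold over accessible chromatin with ~3.5-4% mutant retention;
#' eight zinc-finger clusters grown by tandem duplication; and the
#' chromosome-19 tandem census of 2492 vs 1898 with 32 + 9 planted ERV
#' repressors.
#'
#' @param seed Integer seed; fixes every downstream draw.
#' @param genome_length Length (bp) of the peak-simulation genome.
#' @param n_clusters,genes_per_cluster Zinc-finger cluster layout.
#' @param divergence_per_epoch Substitutions per site applied to every
#'   gene copy per duplication epoch (fraction of nucleotide
#'   substitutions); with `genes_per_cluster = 6` the planted duplication
#'   ages span 0.06-0.30 f.n.s., the recent-burst regime.
#' @param seed_finger_divergence Substitutions per site applied to each
#'   finger copy of the seed gene at construction, so paralogous fingers
#'   within a gene are diverged (as in real arrays, whose fingers bind
#'   different subsites) while cross-copy counterparts stay the closest
#'   relatives.
#' @param fingers_min,fingers_max Range of C2H2 motifs per seed gene.
#' @param linker_bp In-gene spacer between fingers (must keep tandem gaps
#'   under 200 bp).
#' @param gene_spacing_bp Intergenic spacer between genes in a cluster.
#' @param cluster_genome_length Optional fixed genome length for the
#'   cluster simulation; an error is raised if the requested clusters do
#'   not fit. `NULL` (default) sizes the genome automatically.
#' @param theta_background,theta_hotspot Scaled deletion rates per
#'   region.
#' @param n_haplotypes Haploid sample size for deletion polymorphisms.
#' @param deletion_length_mean Mean simulated deletion length (bp; all
#'   lengths exceed 50 bp).
#' @param n_peaks,n_open Numbers of ChIP peaks and open-chromatin
#'   intervals.
#' @param open_len Open-chromatin interval length (bp).
#' @param peak_length_mean,peak_length_sd Peak length distribution
#'   (truncated normal, lower bound 50 bp).
#' @param enrichment_factors Named per-class fold weights for peak
#'   placement.
#' @param retention Named per-class mutant peak retention probabilities
#'   (`other` covers unannotated peaks).
#' @param n_families Number of ERV families.
#' @param consensus_length ERV consensus length (bp).
#' @param fingers_per_tandem Fingers per planted repressor tandem (its
#'   binding site spans `3 *` this many bp).
#' @param total_chr19,total_other Total zinc-finger tandems on
#'   chromosome 19 and elsewhere.
#' @param n_chr19_repressors,n_other_repressors Planted contemporaneous
#'   repressor counts by location.
#' @param n_anachronistic Planted repressors whose affinity gain does not
#'   match their target family's invasion epoch.
#' @param erv_invasion_branches Optional named map family -> branch label
#'   (see [branch_labels()]); `NULL` draws branches at random.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 5e7,
                       n_clusters = 8, genes_per_cluster = 6,
                       divergence_per_epoch = 0.06,
                       seed_finger_divergence = 0.1,
                       fingers_min = 4, fingers_max = 12,
                       linker_bp = 30, gene_spacing_bp = 3000,
                       cluster_genome_length = NULL,
                       theta_background = 50, theta_hotspot = 100,
                       n_haplotypes = 90,
                       deletion_length_mean = 500,
                       n_peaks = 10000, n_open = 10000, open_len = 400,
                       peak_length_mean = 474, peak_length_sd = 74,
                       enrichment_factors = c(LTR = 6, LINE = 6, SINE = 1, DNA = 1),
                       retention = c(LTR = 0.035, LINE = 0.04, SINE = 0.04,
                                     DNA = 0.04, other = 0.04),
                       n_families = 41, consensus_length = 300,
                       fingers_per_tandem = 3,
                       total_chr19 = 2492, total_other = 1898,
                       n_chr19_repressors = 32, n_other_repressors = 9,
                       n_anachronistic = 5,
                       erv_invasion_branches = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$genes_per_cluster >= 2, cfg$n_haplotypes >= 2,
            cfg$theta_background >= 0, cfg$theta_hotspot >= 0,
            all(cfg$enrichment_factors >= 0), all(cfg$retention >= 0),
            cfg$fingers_min >= 2, cfg$fingers_max >= cfg$fingers_min,
            cfg$divergence_per_epoch >= 0)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

STOP_CODONS <- c("TAA", "TAG", "TGA")
# codons that would introduce a stop or a stray zinc-coordinating residue
# (C/H) into a coding zinc-finger array; reverted under purifying selection
FORBIDDEN_CODONS <- c(STOP_CODONS, "TGT", "TGC", "CAT", "CAC")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]

# codon table for reverse translation (one row per sense codon)
codons_for_aa <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd)))
  }, character(1))
  split(codons[aa != "*"], aa[aa != "*"])
})

reverse_translate <- function(protein) {
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(v, function(a) sample(codons_for_aa[[a]], 1), character(1)),
        collapse = "")
}

# random C2H2 finger protein: anchors C,C,H,H, spacers drawn from the
# 18 non-anchor amino acids (no stray C/H, keeps the planted pattern clean)
random_finger_protein <- function() {
  s1 <- sample(2:4, 1); s2 <- sample(3:5, 1)
  spacer <- function(k) paste(sample(setdiff(AA20, c("C", "H")), k, replace = TRUE),
                              collapse = "")
  paste0("C", spacer(s1), "C", spacer(12), "H", spacer(s2), "H")
}

# substitute bases at rate `rate` outside `protect` (codon-aligned
# protection), then revert any codon that newly became a stop or a stray
# C/H codon: the genes stay coding and the C2H2 anchor structure stays
# unambiguous (purifying selection on a zinc-finger array)
mutate_coding <- function(seq, rate, protect) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  orig <- v
  idx <- setdiff(seq_along(v), protect)
  hit <- idx[stats::runif(length(idx)) < rate]
  if (length(hit) == 0) return(seq)
  v[hit] <- vapply(v[hit], function(b) sample(setdiff(BASES, b), 1), character(1))
  cod_starts <- unique((hit - 1) %/% 3) * 3 + 1
  for (s in cod_starts) {
    new_cod <- paste(v[s:(s + 2)], collapse = "")
    old_cod <- paste(orig[s:(s + 2)], collapse = "")
    if (new_cod %in% FORBIDDEN_CODONS && !(old_cod %in% FORBIDDEN_CODONS)) {
      v[s:(s + 2)] <- orig[s:(s + 2)]
    }
  }
  paste(v, collapse = "")
}

# DNA-level C2H2 candidate pattern: C and H anchor codons with
# codon-multiple spacers, matching in any frame at its own start offset
C2H2_DNA_REGEX <- paste0(
  "(?=(TG[TC](?:[ACGT]{3}){2,4}TG[TC](?:[ACGT]{3}){12}",
  "CA[TC](?:[ACGT]{3}){3,5}CA[TC]))"
)

count_c2h2_starts <- function(seq) {
  m <- gregexpr(C2H2_DNA_REGEX, seq, perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) 0L else length(m)
}

# TRUE iff the gene sequence scans to exactly its planted fingers:
# n_fingers candidate starts on the coding strand and none on the
# antisense strand (spurious parses would shadow the true one downstream).
# The DNA-level check is conservative: it also counts candidates whose
# spacers contain stop codons, which only triggers extra redraws.
gene_scans_clean <- function(seq, n_fingers) {
  count_c2h2_starts(seq) == n_fingers && count_c2h2_starts(revcomp(seq)) == 0L
}

#' Simulate tandemly duplicated zinc-finger clusters
#'
#' Grows each cluster from a random seed gene of 4-12 C2H2 motifs by
#' iterative segmental duplication: at every epoch one gene copy is
#' duplicated in tandem and then every copy accumulates
#' `divergence_per_epoch` substitutions per site. Substitutions spare the
#' C2H2-critical cysteine/histidine codons and never introduce in-frame
#' stops (purifying selection on a coding zinc-finger array). The true age
#' of a motif is the total divergence accumulated since the most recent
#' duplication event involving its gene.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (named character, chromosome `chr19`),
#'   `genes` (interval tibble; `label` = gene id), `truth` (tibble
#'   `gene_id`, `cluster`, `finger`, `chrom`, `start`, `end`, `strand`,
#'   `true_age`).
#' @export
simulate_znf_clusters <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    clusters <- lapply(seq_len(config$n_clusters), function(cl) {
      n_fingers <- sample(config$fingers_min:config$fingers_max, 1)
      # a cluster is one sequence family: the seed gene is a tandem array of
      # copies of a single founder finger (intragenic duplication)
      # seed gene: tandem array of pre-diverged copies of one founder
      # finger, joined by coding C/H-free linkers (canonical ZNF linkers
      # carry no zinc-coordinating residues). Draws are rejected until the
      # assembled gene scans to exactly its planted fingers: spurious
      # off-frame or antisense C2H2 matches would shadow the true parse.
      n_link_aa <- config$linker_bp %/% 3
      repeat {
        founder <- random_finger_protein()
        linkers <- replicate(n_fingers, reverse_translate(
          paste(sample(setdiff(AA20, c("C", "H")), n_link_aa, replace = TRUE),
                collapse = "")))
        founder_dna <- reverse_translate(founder)
        p_f <- nchar(founder)
        s1_f <- as.integer(regexpr("C", substring(founder, 2), fixed = TRUE)) - 1
        anchors_f <- c(1, s1_f + 2, s1_f + 15, p_f)
        protect_f <- unlist(lapply(anchors_f, function(a) 3 * (a - 1) + 1:3))
        finger_dna <- vapply(seq_len(n_fingers), function(.)
          mutate_coding(founder_dna, config$seed_finger_divergence, protect_f),
          character(1))
        gene_cand <- paste0(linkers, finger_dna, collapse = "")
        if (gene_scans_clean(gene_cand, n_fingers)) break
      }
      fingers <- vapply(finger_dna, function(d)
        as.character(Biostrings::translate(Biostrings::DNAString(d))),
        character(1), USE.NAMES = FALSE)
      gene_seq <- gene_cand
      # finger spans within the gene (0-based), and protected codon offsets
      flen <- nchar(finger_dna)
      starts <- cumsum(c(0, head(flen + config$linker_bp, -1))) + config$linker_bp
      spans <- tibble(finger = seq_len(n_fingers), start = starts,
                      end = starts + flen)
      protect <- unlist(lapply(seq_len(n_fingers), function(k) {
        p <- nchar(fingers[k])
        # anchor aa positions (1-based in protein): 1, s1+2, s1+15, p
        s1 <- regexpr("C", substring(fingers[k], 2), fixed = TRUE)  # next C
        s1 <- as.integer(s1) - 1
        anchors <- c(1, s1 + 2, s1 + 15, p)
        unlist(lapply(anchors, function(a) (spans$start[k] + 3 * (a - 1)) + 1:3))
      }))
      E <- config$genes_per_cluster - 1
      genes <- list(list(seq = gene_seq, age_rounds = rep(E + 1, n_fingers)))
      for (t in seq_len(E)) {
        src <- sample(length(genes), 1)
        rounds_left <- E - t + 1
        genes[[src]]$age_rounds[] <- rounds_left
        genes[[length(genes) + 1]] <- list(seq = genes[[src]]$seq,
                                           age_rounds = rep(rounds_left, n_fingers))
        genes <- lapply(genes, function(g) {
          # reject mutation draws that create spurious C2H2 parses
          for (try in 1:50) {
            prop <- mutate_coding(g$seq, config$divergence_per_epoch, protect)
            if (gene_scans_clean(prop, n_fingers)) {
              g$seq <- prop
              break
            }
          }
          g
        })
      }
      # founders never duplicated again keep age_rounds = E + 1 (older than
      # any within-simulation event); cap at E for reporting
      list(genes = genes, spans = spans, cluster = cl)
    })
    # assemble the chromosome
    pieces <- character(0)
    gene_rows <- list()
    truth_rows <- list()
    pos <- 0
    gid <- 0
    for (cl in clusters) {
      for (g in cl$genes) {
        gid <- gid + 1
        spacer <- random_dna(config$gene_spacing_bp)
        pieces <- c(pieces, spacer)
        pos <- pos + config$gene_spacing_bp
        strand <- sample(c("+", "-"), 1)
        glen <- nchar(g$seq)
        seq_out <- if (strand == "+") g$seq else revcomp(g$seq)
        pieces <- c(pieces, seq_out)
        gene_id <- sprintf("gene%03d", gid)
        gene_rows[[gid]] <- tibble(chrom = "chr19", start = pos, end = pos + glen,
                                   strand = strand, label = gene_id)
        sp <- cl$spans
        if (strand == "+") {
          mstart <- pos + sp$start; mend <- pos + sp$end
        } else {
          mstart <- pos + (glen - sp$end); mend <- pos + (glen - sp$start)
        }
        truth_rows[[gid]] <- tibble(
          gene_id = gene_id, cluster = cl$cluster, finger = sp$finger,
          chrom = "chr19", start = mstart, end = mend, strand = strand,
          true_age = pmin(g$age_rounds, config$genes_per_cluster - 1) *
            config$divergence_per_epoch
        )
        pos <- pos + glen
      }
    }
    pieces <- c(pieces, random_dna(config$gene_spacing_bp))
    pos <- pos + config$gene_spacing_bp
    if (!is.null(config$cluster_genome_length) &&
        config$cluster_genome_length < pos) {
      stop("genome too short to host the requested clusters: need ",
           format_coord(pos), " bp", call. = FALSE)
    }
    genome <- c(chr19 = paste(pieces, collapse = ""))
    list(genome = genome,
         genes = dplyr::bind_rows(gene_rows),
         truth = dplyr::bind_rows(truth_rows))
  })
}

#' Simulate polymorphic deletions with a neutral frequency spectrum
#'
#' Per region of scaled rate `theta`, the number of segregating deletions
#' is Poisson with mean `theta * a_n`, and each deletion's derived count
#' `i` is drawn with probability proportional to `1/i` (the neutral site
#' frequency spectrum). All lengths exceed 50 bp.
#'
#' @param config A [sim_config()].
#' @param regions Interval tibble; a `theta` column sets per-region rates
#'   explicitly, otherwise rows labelled `"hotspot"` get
#'   `theta_hotspot` and all others `theta_background`.
#' @return A list: `deletions` (tibble `chrom`, `start`, `end`,
#'   `derived_count`, `n`), `truth` (regions with their true `theta`).
#' @export
simulate_deletion_polymorphisms <- function(config = sim_config(), regions) {
  stopifnot(inherits(config, "sim_config"))
  validate_intervals(regions, "region")
  n <- config$n_haplotypes
  if (!("theta" %in% names(regions))) {
    lab <- if ("label" %in% names(regions)) regions$label else ""
    regions$theta <- ifelse(!is.na(lab) & lab == "hotspot",
                            config$theta_hotspot, config$theta_background)
  }
  an <- watterson_a(n)
  sfs_p <- (1 / seq_len(n - 1)) / an
  withr::with_seed(config$seed, {
    dels <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
      S <- stats::rpois(1, regions$theta[r] * an)
      if (S == 0) return(tibble())
      len <- 51 + stats::rgeom(S, 1 / (config$deletion_length_mean - 50))
      width <- regions$end[r] - regions$start[r]
      start <- regions$start[r] + floor(stats::runif(S, 0, pmax(1, width - len)))
      tibble(chrom = regions$chrom[r], start = start, end = start + len,
             derived_count = sample(seq_len(n - 1), S, replace = TRUE, prob = sfs_p),
             n = n)
    })
    list(deletions = dels, truth = regions)
  })
}

# class of each position's annotation under precedence (first match wins)
center_class <- function(centers_chrom, centers_pos, annotation, precedence) {
  cls <- rep("other", length(centers_pos))
  classes <- unique(c(intersect(precedence, annotation$label),
                      setdiff(annotation$label, precedence)))
  claimed <- rep(FALSE, length(centers_pos))
  for (cl in classes) {
    ann <- annotation[annotation$label == cl, ]
    if (nrow(ann) == 0) next
    gr <- GenomicRanges::reduce(intervals_to_granges(ann), ignore.strand = TRUE)
    pts <- GenomicRanges::GRanges(centers_chrom,
                                  IRanges::IRanges(centers_pos + 1, centers_pos + 1))
    inside <- IRanges::overlapsAny(pts, gr, ignore.strand = TRUE)
    take <- inside & !claimed
    cls[take] <- cl
    claimed <- claimed | inside
  }
  cls
}

#' Simulate ChIP peaks with class-biased placement
#'
#' Open-chromatin intervals are placed uniformly along the genome. Peak
#' centers land on annotation class `c` with probability proportional to
#' `enrichment_factors[c]` times the class's base-pair share (unannotated
#' DNA has weight 1), and peak lengths are Normal(474, 74) truncated at
#' 50 bp. Mutant peaks are a per-class random retention of the wild-type
#' peaks.
#'
#' @param config A [sim_config()].
#' @param annotation Class-labelled interval tibble covering less than
#'   half of `genome_length`.
#' @return A list: `peaks`, `open_chromatin`, `mt_peaks` (interval
#'   tibbles) and `truth` (the configured factors and retentions).
#' @export
simulate_chip_peaks <- function(config = sim_config(), annotation) {
  stopifnot(inherits(config, "sim_config"))
  validate_intervals(annotation, "annotation")
  G <- config$genome_length
  ann_bp <- sum(annotation$end - annotation$start)
  if (ann_bp >= 0.5 * G) stop("annotation must cover < 50% of the genome", call. = FALSE)
  unknown <- setdiff(names(config$enrichment_factors), unique(annotation$label))
  if (length(unknown) > 0) {
    stop("enrichment factor for unknown class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  chrom <- unique(annotation$chrom)
  if (length(chrom) != 1) stop("single-chromosome annotation expected", call. = FALSE)
  withr::with_seed(config$seed, {
    open_start <- floor(stats::runif(config$n_open, 0, G - config$open_len))
    open <- genomic_intervals(rep(chrom, config$n_open), open_start,
                              open_start + config$open_len)
    # per-class placement weights
    classes <- names(config$enrichment_factors)
    merged <- lapply(classes, function(cl) {
      GenomicRanges::reduce(intervals_to_granges(annotation[annotation$label == cl, ]),
                            ignore.strand = TRUE)
    })
    names(merged) <- classes
    class_bp <- vapply(merged, function(gr) sum(GenomicRanges::width(gr)), numeric(1))
    w <- c(config$enrichment_factors * class_bp, other = G - sum(class_bp))
    pick <- sample(names(w), config$n_peaks, replace = TRUE, prob = w / sum(w))
    centers <- numeric(config$n_peaks)
    for (cl in names(w)) {
      idx <- which(pick == cl)
      if (length(idx) == 0) next
      if (cl == "other") {
        # rejection-sample unannotated positions
        all_ann <- GenomicRanges::reduce(do.call(c, unname(merged)), ignore.strand = TRUE)
        got <- 0
        pos <- numeric(0)
        while (got < length(idx)) {
          cand <- floor(stats::runif(2 * (length(idx) - got), 0, G))
          pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(cand + 1, cand + 1))
          ok <- !IRanges::overlapsAny(pts, all_ann, ignore.strand = TRUE)
          pos <- c(pos, cand[ok])
          got <- length(pos)
        }
        centers[idx] <- pos[seq_along(idx)]
      } else {
        gr <- merged[[cl]]
        widths <- GenomicRanges::width(gr)
        iv <- sample(length(gr), length(idx), replace = TRUE, prob = widths)
        centers[idx] <- GenomicRanges::start(gr)[iv] - 1 +
          floor(stats::runif(length(idx), 0, widths[iv]))
      }
    }
    len <- round(stats::rnorm(config$n_peaks, config$peak_length_mean,
                              config$peak_length_sd))
    while (any(len < 50)) {
      bad <- len < 50
      len[bad] <- round(stats::rnorm(sum(bad), config$peak_length_mean,
                                     config$peak_length_sd))
    }
    start <- pmax(0, centers - floor(len / 2))
    end <- pmin(G, start + len)
    peaks <- genomic_intervals(rep(chrom, config$n_peaks), start, end)
    keep_p <- config$retention[ifelse(pick %in% names(config$retention),
                                      pick, "other")]
    mt <- peaks[stats::runif(config$n_peaks) < keep_p, ]
    # realized per-class fold over a uniform background: the placement
    # weights are renormalized across the genome, so the expected fold is
    # factor / (sum of factor-weighted class shares + unannotated share)
    share <- class_bp / G
    norm <- sum(config$enrichment_factors * share) + (1 - sum(share))
    list(peaks = peaks, open_chromatin = open, mt_peaks = mt,
         truth = list(enrichment_factors = config$enrichment_factors,
                      expected_fold = config$enrichment_factors / norm,
                      retention = config$retention, center_class = pick))
  })
}

#' Simulate coevolving ERV families and zinc-finger repressor tandems
#'
#' Each ERV family is planted on an invasion branch of the species tree
#' (present in exactly that clade's leaves) and carries one
#' family-specific k-mer in its consensus. Planted repressor tandems
#' receive finger specificity residues that decode to their target
#' family's k-mer under [default_recognition_code()], and per-species
#' predicted motif sets whose gain clade matches the invasion clade
#' (contemporaneous pairs) or a different branch (anachronistic pairs).
#' All remaining tandems get random specificities. Tandem totals and
#' planted-repressor counts default to the chromosome-19 census
#' (2492/1898 tandems, 32/9 repressors).
#'
#' @param config A [sim_config()].
#' @param tree Species tree (default [primate_tree()]; needs >= 4
#'   leaves).
#' @return A list: `consensi` (named character), `presence` (tibble,
#'   families x species 0/1), `tandems` (tibble `tandem`, `chrom`,
#'   `fingers` list-column), `motif_sets` (per planted tandem: named list
#'   species -> motifs), `truth` (tibble of planted pairs with
#'   `invasion_branch`, `gain_branch`, `contemporaneous`).
#' @export
simulate_coevolution <- function(config = sim_config(), tree = primate_tree()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(tree$tip.label) < 4) stop("tree needs >= 4 leaves", call. = FALSE)
  tips <- tree$tip.label
  labs <- branch_labels(tree)
  # candidate invasion branches: clades containing the focal human leaf
  human_branches <- labs[vapply(labs, function(b) {
    "human" %in% strsplit(b, "+", fixed = TRUE)[[1]]
  }, logical(1))]
  k <- 3 * config$fingers_per_tandem
  inv_map <- c(A = "N", C = "D", G = "R", T = "Q")  # delta rows of the default code
  kmer_to_fingers <- function(kmer) {
    triplets <- substring(kmer, seq(1, k, 3), seq(3, k, 3))
    # N-terminal finger binds the 3' subsite: reverse triplet order
    lapply(rev(triplets), function(tr) {
      b <- strsplit(tr, "", fixed = TRUE)[[1]]
      c(inv_map[[b[3]]], "A", inv_map[[b[2]]], inv_map[[b[1]]])  # helix -1,2,3,6
    })
  }
  withr::with_seed(config$seed, {
    # One shared retroviral backbone with a fixed family-specific window:
    # every k-mer away from the window is common to all families, so
    # family specificity is attributable to the planted difference.
    backbone <- random_dna(config$consensus_length)
    win_at <- floor((config$consensus_length - k) / 2)
    kmers <- character(config$n_families)
    for (f in seq_len(config$n_families)) {
      repeat {
        cand <- random_dna(k)
        clash <- grepl(cand, backbone, fixed = TRUE) ||
          grepl(revcomp(cand), backbone, fixed = TRUE) ||
          cand %in% kmers || revcomp(cand) %in% kmers
        if (!clash) break
      }
      kmers[f] <- cand
    }
    fam_ids <- sprintf("ERVfam%02d", seq_len(config$n_families))
    consensi <- stats::setNames(paste0(substr(backbone, 1, win_at),
                                       kmers,
                                       substr(backbone, win_at + k + 1,
                                              config$consensus_length)),
                                fam_ids)
    if (is.null(config$erv_invasion_branches)) {
      inv_branch <- sample(human_branches, config$n_families, replace = TRUE)
    } else {
      if (!all(config$erv_invasion_branches %in% labs)) {
        stop("invasion branch absent from tree: ",
             paste(setdiff(config$erv_invasion_branches, labs), collapse = ", "),
             call. = FALSE)
      }
      inv_branch <- rep_len(config$erv_invasion_branches, config$n_families)
    }
    names(inv_branch) <- fam_ids
    presence <- purrr::map_dfr(fam_ids, function(f) {
      clade <- strsplit(inv_branch[[f]], "+", fixed = TRUE)[[1]]
      out <- as.list(stats::setNames(as.integer(tips %in% clade), tips))
      dplyr::bind_cols(tibble(family = f), as_tibble(out))
    })
    # tandems: planted contemporaneous repressors, anachronistic ones, filler
    n_rep <- config$n_chr19_repressors + config$n_other_repressors
    n_total <- config$total_chr19 + config$total_other
    stopifnot(n_rep + config$n_anachronistic <= n_total)
    tandem_ids <- sprintf("tandem%04d", seq_len(n_total))
    chrom <- c(rep("chr19", config$n_chr19_repressors),
               rep("other", config$n_other_repressors),
               rep("chr19", config$total_chr19 - config$n_chr19_repressors),
               rep("other", config$total_other - config$n_other_repressors))
    fam_of <- rep_len(fam_ids, n_rep)
    anach_idx <- n_rep + seq_len(config$n_anachronistic)
    fam_anach <- rep_len(fam_ids, config$n_anachronistic)
    fingers <- vector("list", n_total)
    for (i in seq_len(n_rep)) fingers[[i]] <- kmer_to_fingers(kmers[match(fam_of[i], fam_ids)])
    for (j in seq_along(anach_idx)) {
      fingers[[anach_idx[j]]] <- kmer_to_fingers(kmers[match(fam_anach[j], fam_ids)])
    }
    for (i in setdiff(seq_len(n_total), c(seq_len(n_rep), anach_idx))) {
      fingers[[i]] <- lapply(seq_len(config$fingers_per_tandem), function(.)
        sample(AA20, 4, replace = TRUE))
    }
    tandems <- tibble(tandem = tandem_ids, chrom = chrom, fingers = fingers)
    # per-species motif sets for every planted (contemporaneous or not) tandem
    gain_branch <- character(n_rep + config$n_anachronistic)
    gain_branch[seq_len(n_rep)] <- inv_branch[fam_of]
    for (j in seq_along(anach_idx)) {
      others <- setdiff(human_branches, inv_branch[[fam_anach[j]]])
      gain_branch[n_rep + j] <- sample(others, 1)
    }
    planted_idx <- c(seq_len(n_rep), anach_idx)
    planted_fam <- c(fam_of, fam_anach)
    motif_sets <- lapply(seq_along(planted_idx), function(j) {
      clade <- strsplit(gain_branch[j], "+", fixed = TRUE)[[1]]
      target <- kmers[match(planted_fam[j], fam_ids)]
      stats::setNames(lapply(tips, function(sp) {
        if (sp %in% clade) target else character(0)
      }), tips)
    })
    names(motif_sets) <- tandem_ids[planted_idx]
    truth <- tibble(
      tandem = tandem_ids[planted_idx],
      family = planted_fam,
      chrom = chrom[planted_idx],
      motif = kmers[match(planted_fam, fam_ids)],
      invasion_branch = unname(inv_branch[planted_fam]),
      gain_branch = gain_branch,
      contemporaneous = gain_branch == unname(inv_branch[planted_fam])
    )
    list(consensi = consensi, presence = presence, tandems = tandems,
         motif_sets = motif_sets, truth = truth)
  })
}
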