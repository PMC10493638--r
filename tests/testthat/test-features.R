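# Telomere tract detection, T2T classification, tandem-array scanning and
# NLR genic/intergenic status with cluster summaries.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# spacer sequence guaranteed free of both telomere 7-mers
clean_spacer <- function(n) strrep("AC", ceiling(n / 2)) |> substr(1, n)

chrom_with_tails <- function(copies5, copies3, mid_len = 5000) {
  paste0(strrep("CCCATTT", copies5), clean_spacer(mid_len),
         strrep("TTTAGGG", copies3))
}

as_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

test_that("perfect planted tracts are called with exact lengths", {
  g <- as_genome(chr1 = chrom_with_tails(100, 100))
  calls <- find_telomeres(g)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$end, c("5prime", "3prime"))
  expect_true(all(calls$length_bp == 700))
  expect_true(all(calls$purity == 1))
  expect_equal(calls$start[calls$end == "5prime"], 1)
  expect_equal(calls$stop[calls$end == "3prime"], nchar(chrom_with_tails(100, 100)))
})

test_that("chromosomes without terminal repeats yield no call", {
  g <- as_genome(chr1 = clean_spacer(20000))
  expect_equal(nrow(find_telomeres(g)), 0)
})

test_that("a 6415-copy tract reports 44905 bp", {
  g <- as_genome(chr1 = paste0(clean_spacer(2000), strrep("TTTAGGG", 6415)))
  calls <- find_telomeres(g)
  expect_equal(calls$length_bp, 6415 * 7)
  expect_equal(calls$length_bp, 44905)
  expect_equal(calls$copy_estimate, 6415)
})

test_that("planted tract lengths are recovered exactly over random sizes", {
  set.seed(77)
  for (i in 1:20) {
    k5 <- sample(100:500, 1)
    k3 <- sample(100:500, 1)
    g <- as_genome(chr1 = chrom_with_tails(k5, k3))
    calls <- find_telomeres(g)
    expect_equal(calls$length_bp[calls$end == "5prime"], 7 * k5)
    expect_equal(calls$length_bp[calls$end == "3prime"], 7 * k3)
  }
})

test_that("mismatched units lower purity but keep the tract", {
  units <- rep("TTTAGGG", 200)
  units[c(50, 120)] <- "TTTAGGA"  # two corrupted units inside the tract
  g <- as_genome(chr1 = paste0(clean_spacer(1000), paste(units, collapse = "")))
  calls <- find_telomeres(g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$length_bp, 1400)
  expect_equal(calls$purity, 198 / 200)
})

test_that("tracts below copy or purity thresholds are rejected", {
  g <- as_genome(chr1 = paste0(clean_spacer(1000), strrep("TTTAGGG", 50)))
  expect_equal(nrow(find_telomeres(g, min_copies = 100)), 0)
  expect_equal(find_telomeres(g, min_copies = 40)$copy_estimate, 50)
})

test_that("tracts starting beyond max_offset are not called", {
  g <- as_genome(chr1 = paste0(strrep("TTTAGGG", 150), clean_spacer(20000)))
  # 3' unit sits at the 5' side: not within max_offset of the 3' end and
  # the wrong unit for the 5' end
  expect_equal(nrow(find_telomeres(g, max_offset = 10000)), 0)
})

test_that("T2T classification counts both-ended chromosomes", {
  g <- as_genome(
    chr1 = chrom_with_tails(120, 130),
    chr2 = paste0(clean_spacer(5000), strrep("TTTAGGG", 110)),
    chr3 = clean_spacer(5000)
  )
  calls <- find_telomeres(g)
  cl <- classify_t2t(calls, g)
  expect_equal(cl$per_chromosome$status, c("T2T", "one-ended", "none"))
  expect_equal(cl$counts$n[cl$counts$status == "T2T"], 1L)
})

test_that("simulator telomeres produce the planted T2T count", {
  cfg <- sim_config(seed = 13, n_triads = 10, n_pairs = 2, n_singletons = 3,
                    chrom_length = 150000L,
                    nlr = list(n_genic = 2, n_intergenic = 2,
                               cluster_size = 0))
  sim <- simulate_triploid(cfg)
  for (hap in names(sim$genomes)) {
    cl <- classify_t2t(find_telomeres(sim$genomes[[hap]]),
                       sim$genomes[[hap]])
    expect_true(all(cl$per_chromosome$status == "T2T"))
  }
})

test_that("a planted tandem array is found with its unit and copy number", {
  unit <- rand_dna(135, seed = 5)
  seqc <- paste0(rand_dna(20000), strrep(unit, 1000), rand_dna(20000))
  arr <- find_tandem_arrays(seqc, "chrT", c(130, 140), min_array_bp = 10000)
  expect_gte(nrow(arr), 1)
  top <- arr[1, ]
  expect_equal(top$unit_length, 135L)
  expect_equal(top$copy_number, 1000L, tolerance = 0.01)
  expect_gte(top$array_score, 0.99)
  expect_lte(abs(top$length_bp - 135000L), 270L)
})

test_that("random sequence contains no large tandem array", {
  for (seed in 1:10) {
    seqc <- rand_dna(60000, seed = seed)
    arr <- find_tandem_arrays(seqc, "chrR", c(100, 140),
                              min_array_bp = 10000)
    expect_equal(nrow(arr), 0)
  }
})

test_that("the longest array is the centromere candidate", {
  unit_a <- rand_dna(120, seed = 1)
  unit_b <- rand_dna(120, seed = 2)
  seqc <- paste0(rand_dna(5000), strrep(unit_a, 417), rand_dna(5000),
                 strrep(unit_b, 167), rand_dna(5000))  # ~50 kb and ~20 kb
  g <- as_genome(chr1 = seqc)
  cand <- centromere_candidates(g, c(115, 125), min_array_bp = 10000)
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$length_bp - 417 * 120), 240)
})

test_that("simulator centromeres are recovered as the longest arrays", {
  cfg <- sim_config(seed = 17, n_triads = 6, n_pairs = 0, n_singletons = 0,
                    chrom_length = 120000L, n_chromosomes = 2L,
                    centromere_unit_length = c(130L, 140L),
                    centromere_array_length = c(15000L, 20000L),
                    nlr = list(n_genic = 1, n_intergenic = 1,
                               cluster_size = 0))
  sim <- simulate_triploid(cfg)
  cand <- centromere_candidates(sim$genomes$H1, c(125L, 145L),
                                min_array_bp = 10000)
  truth <- dplyr::filter(sim$truth$centromeres, haplotype == "H1")
  cand <- dplyr::arrange(cand, chrom)
  truth <- dplyr::arrange(truth, chrom)
  expect_equal(nrow(cand), nrow(truth))
  # detected interval covers the planted array almost exactly
  expect_true(all(abs(cand$start - truth$start) <= truth$unit_length))
  expect_true(all(abs(cand$end - truth$end) <= truth$unit_length))
})

test_that("NLR loci are genic iff they overlap a gene span", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(1000L, 5000L), end = c(2000L, 6000L)
  )
  loci <- tibble::tibble(
    chrom = "chr1",
    start = c(1200L, 3000L, 1900L),
    end = c(1400L, 3500L, 5200L),
    name = c("in_gene", "between", "two_genes")
  )
  st <- nlr_status(loci, genes)
  expect_equal(st$status, c("genic", "intergenic", "genic"))
  expect_equal(st$overlapping_gene[1], "gA")
  # two_genes overlaps gA by 101 bp and gB by 201 bp -> gB
  expect_equal(st$overlapping_gene[3], "gB")
  expect_equal(sum(st$status == "genic") + sum(st$status == "intergenic"),
               nrow(loci))

  expect_error(
    nlr_status(dplyr::mutate(loci, chrom = "chrZ"), genes),
    "absent from annotation"
  )
})

test_that("equal overlap ties resolve to the lexicographic gene", {
  genes <- tibble::tibble(
    gene_id = c("gB", "gA"), chrom = "chr1",
    start = c(100L, 300L), end = c(250L, 450L)
  )
  loci <- tibble::tibble(chrom = "chr1", start = 201L, end = 350L,
                         name = "L1")
  st <- nlr_status(loci, genes)  # 50 bp overlap with each
  expect_equal(st$overlapping_gene, "gA")
})

test_that("cluster chaining respects max_gap and min_loci", {
  # 26 loci packed into ~780 kb, none genic: one cluster "0/26"
  starts <- as.integer(seq(43020000, 43800000, length.out = 26))
  loci <- tibble::tibble(chrom = "Chr03", start = starts,
                         end = starts + 2999L,
                         name = sprintf("L%02d", 1:26))
  genes <- tibble::tibble(gene_id = "g1", chrom = "Chr03",
                          start = 1L, end = 1000L)
  st <- nlr_status(loci, genes)
  cl <- cluster_nlr(st, max_gap = 200000L, min_loci = 5L)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$ratio, "0/26")
  expect_equal(cl$n_loci, 26L)
  expect_equal(cl$location_mb, "43.02-43.80")

  # a gap larger than max_gap splits the chain
  st2 <- st
  st2$start[14:26] <- st2$start[14:26] + 500000L
  st2$end[14:26] <- st2$end[14:26] + 500000L
  cl2 <- cluster_nlr(st2, max_gap = 200000L, min_loci = 5L)
  expect_equal(nrow(cl2), 2)
  expect_equal(sum(cl2$n_loci), 26L)

  # too few loci: nothing reported
  cl3 <- cluster_nlr(st[1:4, ], max_gap = 200000L, min_loci = 5L)
  expect_equal(nrow(cl3), 0)
})

test_that("cluster output is order-invariant with disjoint spans", {
  set.seed(3)
  starts <- sort(sample.int(2e6, 30))
  loci <- tibble::tibble(chrom = "chr1", start = starts,
                         end = starts + 1000L,
                         name = sprintf("L%02d", 1:30))
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 1L,
                          end = 10L)
  st <- nlr_status(loci, genes)
  cl <- cluster_nlr(st, max_gap = 100000L, min_loci = 2L)
  shuf <- st[sample(nrow(st)), ]
  cl2 <- cluster_nlr(shuf, max_gap = 100000L, min_loci = 2L)
  expect_equal(cl2, cl)
  if (nrow(cl) > 1) {
    expect_true(all(cl$span_start[-1] > cl$span_end[-nrow(cl)]))
  }
})

test_that("simulator NLR loci recover planted status and the tight cluster", {
  cfg <- sim_config(seed = 23, n_triads = 12, n_pairs = 0, n_singletons = 0,
                    chrom_length = 200000L,
                    nlr = list(n_genic = 5, n_intergenic = 5,
                               cluster_size = 8, cluster_gap = 3000L))
  sim <- simulate_triploid(cfg)
  loci <- dplyr::filter(sim$truth$nlr_loci, haplotype == "H1")
  loci_tbl <- tibble::tibble(chrom = loci$chrom, start = loci$start,
                             end = loci$end,
                             name = sprintf("n%02d", seq_len(nrow(loci))))
  st <- nlr_status(loci_tbl, dplyr::filter(sim$genes, haplotype == "H1"))
  expect_equal(st$status, loci$planted_status)
  # the planted cluster chains together under a tight max_gap
  cl <- cluster_nlr(st, max_gap = 4000L, min_loci = 5L)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_loci, 8L)
  expect_equal(cl$n_genic, 0L)
})
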