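# TPM, the expressed-triad filter, ternary standardization and the
# seven-group nearest-centroid classifier.

test_that("TPM follows the length-normalised formula and sums to 1e6", {
  ct <- tibble::tibble(gene_id = c("a", "b"), length = c(1000L, 1000L),
                       s1 = c(10L, 10L))
  expect_equal(compute_tpm(ct)$s1, c(5e5, 5e5))

  ct2 <- tibble::tibble(gene_id = c("a", "b"), length = c(1000L, 2000L),
                        s1 = c(10L, 10L))
  expect_equal(compute_tpm(ct2)$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  ct3 <- tibble::tibble(gene_id = "a", length = 500L, s1 = 7L)
  expect_equal(compute_tpm(ct3)$s1, 1e6)

  ct4 <- tibble::tibble(gene_id = c("a", "b"), length = c(1000L, 2000L),
                        s1 = c(0L, 0L), s2 = c(3L, 4L))
  expect_warning(tpm4 <- compute_tpm(ct4), "all-zero")
  expect_equal(tpm4$s1, c(0, 0))
  expect_equal(sum(tpm4$s2), 1e6, tolerance = 1e-6)
})

test_that("replicate samples average into per-tissue TPM", {
  tpm <- tibble::tibble(gene_id = "a", length = 100L,
                        root_1 = 10, root_2 = 20, leaf = 5)
  bytis <- tpm_by_tissue(tpm)
  expect_equal(bytis$root, 15)
  expect_equal(bytis$leaf, 5)
})

triad_fixture <- function(tpms) {
  # tpms: named list tissue -> list of c(H1, H2, H3) per triad
  triads <- tibble::tibble(
    triad_id = paste0("t", seq_along(tpms[[1]])),
    H1 = paste0("H1_", seq_along(tpms[[1]])),
    H2 = paste0("H2_", seq_along(tpms[[1]])),
    H3 = paste0("H3_", seq_along(tpms[[1]]))
  )
  rows <- purrr::imap_dfr(tpms, function(vlist, tis) {
    purrr::imap_dfr(vlist, function(v, i) {
      tibble::tibble(triad_id = paste0("t", i), tissue = tis,
                     tpm_H1 = v[1], tpm_H2 = v[2], tpm_H3 = v[3])
    })
  })
  list(triads = triads, expr = rows)
}

test_that("the expression filter uses a strict > 0.5 TPM rule", {
  fx <- triad_fixture(list(
    root = list(c(0.5, 0.5, 0.5), c(0.6, 0, 0)),
    leaf = list(c(0.5, 0.5, 0.5), c(0, 0, 0))
  ))
  filt <- filter_expressed(fx$expr)
  expect_equal(filt$expressed, "t2")  # 0.5 exactly is not expressed
  expect_equal(nrow(filter_expressed(fx$expr[0, ])$flags), 0)
})

test_that("standardization divides by the triad sum and flags zero sums", {
  expr <- tibble::tibble(triad_id = c("t1", "t2", "t3"), tissue = "root",
                         tpm_H1 = c(10, 30, 0), tpm_H2 = c(10, 10, 0),
                         tpm_H3 = c(10, 10, 0))
  std <- standardize_triads(expr)
  expect_equal(std$e_H1, c(1 / 3, 0.6, NA))
  expect_equal(std$e_H2[2], 0.2)
  expect_equal(std$defined, c(TRUE, TRUE, FALSE))
  ok <- std[std$defined, ]
  expect_equal(ok$e_H1 + ok$e_H2 + ok$e_H3, rep(1, 2), tolerance = 1e-9)
})

test_that("tissue combination averages TPM before standardizing", {
  fx <- triad_fixture(list(
    root = list(c(10, 0, 0)),
    leaf = list(c(0, 10, 0))
  ))
  comb <- combine_tissues(fx$expr) |>
    standardize_triads() |>
    dplyr::filter(tissue == "combined")
  expect_equal(c(comb$e_H1, comb$e_H2, comb$e_H3), c(0.5, 0.5, 0))

  # identical vectors in all tissues: combined equals any single tissue
  fx2 <- triad_fixture(list(root = list(c(3, 2, 1)), leaf = list(c(3, 2, 1))))
  comb2 <- combine_tissues(fx2$expr) |> standardize_triads()
  expect_equal(comb2$e_H1[comb2$tissue == "combined"],
               comb2$e_H1[comb2$tissue == "root"])
})

test_that("centroid points classify to their own groups", {
  cen <- bias_centroids()
  rel <- tibble::as_tibble(cen)
  out <- classify_bias(rel)
  expect_equal(out$group, rownames(cen))
  expect_equal(out$distance, rep(0, 7))
})

test_that("classification distances match brute-force computation", {
  rel <- tibble::tibble(e_H1 = 0.5, e_H2 = 0.25, e_H3 = 0.25)
  out <- classify_bias(rel)
  expect_equal(out$group, "balanced")
  expect_equal(out$d_balanced, sqrt(sum((c(0.5, 0.25, 0.25) - 1 / 3)^2)),
               tolerance = 1e-12)
  expect_equal(out$d_balanced, 0.2041, tolerance = 1e-3)
  expect_equal(out$d_H1D, 0.6124, tolerance = 1e-3)
  expect_gte(out$margin, 0)

  # brute-force argmin over the seven centroids on random simplex points
  set.seed(21)
  cen <- bias_centroids()
  for (i in 1:50) {
    v <- stats::runif(3)
    v <- v / sum(v)
    d <- apply(cen, 1, function(cc) sqrt(sum((v - cc)^2)))
    want <- names(d)[which.min(d)]
    got <- classify_bias(tibble::tibble(e_H1 = v[1], e_H2 = v[2],
                                        e_H3 = v[3]))
    expect_equal(got$group, want)
    expect_equal(got$distance, min(d), tolerance = 1e-12)
  }
})

test_that("classification is invariant to overall expression scale", {
  set.seed(33)
  for (i in 1:20) {
    tpm <- stats::runif(3, 0, 50)
    for (c_scale in c(0.01, 1, 250)) {
      a <- standardize_triads(tibble::tibble(
        triad_id = "t", tissue = "x",
        tpm_H1 = tpm[1], tpm_H2 = tpm[2], tpm_H3 = tpm[3]
      )) |> classify_bias()
      b <- standardize_triads(tibble::tibble(
        triad_id = "t", tissue = "x",
        tpm_H1 = c_scale * tpm[1], tpm_H2 = c_scale * tpm[2],
        tpm_H3 = c_scale * tpm[3]
      )) |> classify_bias()
      expect_equal(b$group, a$group)
    }
  }
})

test_that("haplotype permutations permute group labels consistently", {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  relabel <- function(group, perm) {
    if (group == "balanced") return("balanced")
    k <- as.integer(substr(group, 2, 2))
    paste0("H", which(perm == k), substr(group, 3, 3))
  }
  set.seed(55)
  for (i in 1:20) {
    v <- stats::runif(3)
    v <- v / sum(v)
    base <- classify_bias(tibble::tibble(e_H1 = v[1], e_H2 = v[2],
                                         e_H3 = v[3]))
    for (perm in perms) {
      w <- v[perm]
      out <- classify_bias(tibble::tibble(e_H1 = w[1], e_H2 = w[2],
                                          e_H3 = w[3]))
      expect_equal(out$group, relabel(base$group, perm))
    }
  }
})

test_that("undefined relative vectors are rejected by the classifier", {
  std <- standardize_triads(tibble::tibble(
    triad_id = "t", tissue = "x", tpm_H1 = 0, tpm_H2 = 0, tpm_H3 = 0
  ))
  expect_error(classify_bias(std), "undefined|filter")
})

test_that("group summaries count and percentage per tissue", {
  asg <- tibble::tibble(
    triad_id = paste0("t", 1:100), tissue = "root", group = "balanced"
  )
  s <- summarize_groups(asg)
  expect_equal(s$percent[s$group == "balanced"], 100)
  expect_equal(sum(s$percent), 100)
  expect_equal(s$n_expressed_triads[1], 100L)

  expect_warning(
    s2 <- summarize_groups(asg[0, ], tissues = "leaf"),
    "no assigned"
  )
  expect_true(all(s2$n == 0))
})

test_that("biased-gene density windows by span midpoint", {
  triads <- tibble::tibble(triad_id = "t1", H1 = "g1", H2 = "g2", H3 = "g3")
  asg <- tibble::tibble(triad_id = "t1", group = "H1D")
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(149000L, 99001L, 1L),
    end = c(151000L, 101000L, 1000L)
  )
  # g1 midpoint 150000 -> window 2; g2 spans the boundary, midpoint 100000
  # -> window 1; g3 -> chr2 window 1
  d <- biased_gene_density(asg, triads, genes, window = 1e5)
  expect_equal(nrow(d), 3)
  expect_equal(d$window_start[d$chrom == "chr1"], c(0L, 100000L))
  expect_equal(d$n_biased_genes, c(1L, 1L, 1L))

  genes_bad <- dplyr::mutate(genes, chrom = dplyr::if_else(
    gene_id == "g3", "chrX", chrom))
  d2 <- biased_gene_density(asg, triads, genes_bad, window = 1e5)
  expect_equal(sum(d2$n_biased_genes), 3L)

  expect_error(
    biased_gene_density(asg, triads, genes[1:2, ], window = 1e5),
    "without a gene model"
  )
})

test_that("balanced triads under no dispersion classify perfectly", {
  cfg <- sim_config(seed = 3, n_triads = 60,
                    expression = list(concentration = Inf))
  sim <- simulate_triad_truth(cfg)
  counts <- simulate_expression(sim, cfg)
  tpm <- compute_tpm(counts) |> tpm_by_tissue()
  asg <- triad_tpm(tpm, sim$truth$triads |>
                     dplyr::mutate(triad_id = triad_key)) |>
    filter_expressed() |>
    _$triad_expr |>
    combine_tissues() |>
    standardize_triads() |>
    dplyr::filter(defined) |>
    classify_bias()
  comb <- dplyr::filter(asg, tissue == "combined") |>
    dplyr::inner_join(
      sim$truth$triads |> dplyr::select(triad_id = triad_key, category),
      by = "triad_id"
    )
  # Poisson noise is still present, but with centroids planted exactly the
  # vast majority must classify to the planted category
  expect_gte(mean(comb$group == comb$category), 0.95)
})

test_that("classification accuracy degrades as dispersion grows", {
  recover <- function(conc) {
    cfg <- sim_config(seed = 14, n_triads = 300,
                      expression = list(concentration = conc))
    tr <- simulate_triad_truth(cfg)
    counts <- simulate_expression(tr, cfg)
    tpm <- tpm_by_tissue(compute_tpm(counts))
    te <- triad_tpm(tpm, dplyr::mutate(tr$truth$triads,
                                       triad_id = triad_key))
    asg <- filter_expressed(te)$triad_expr |>
      combine_tissues() |>
      standardize_triads() |>
      dplyr::filter(defined) |>
      classify_bias() |>
      dplyr::filter(tissue == "combined") |>
      dplyr::inner_join(
        dplyr::select(tr$truth$triads, triad_id = triad_key, category),
        by = "triad_id"
      )
    mean(asg$group == asg$category)
  }
  acc <- vapply(c(Inf, 30, 3, 1), recover, numeric(1))
  expect_equal(acc[1], 1)              # exact centroids classify perfectly
  expect_true(all(diff(acc) <= 1e-9))  # non-increasing down the grid
  expect_lt(acc[4], acc[1])            # and strictly worse when very noisy
})
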