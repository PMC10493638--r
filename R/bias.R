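# TPM computation, the expressed-triad filter, per-triad standardization to
# ternary coordinates, and the seven-group nearest-centroid classification
# (balanced / dominant / suppressed per haplotype).

#' Transcripts per million from a counts table
#'
#' `TPM_g = (c_g / L_g) / sum_h (c_h / L_h) * 1e6` per sample column. Each
#' sample column sums to 1e6 unless all its counts are zero, in which case
#' the column is all zero and a warning is raised.
#'
#' @param counts Counts tibble (`gene_id`, `length`, one column per sample).
#' @return Tibble of the same shape with TPM values in the sample columns.
#' @export
compute_tpm <- function(counts) {
  if (any(counts$length <= 0)) stop("gene lengths must be positive")
  samp <- setdiff(names(counts), c("gene_id", "length"))
  out <- counts
  for (s in samp) {
    rate <- counts[[s]] / counts$length
    tot <- sum(rate)
    if (tot == 0) {
      warning("sample ", s, " has all-zero counts; TPM set to 0")
      out[[s]] <- rep(0, length(rate))
    } else {
      out[[s]] <- rate / tot * 1e6
    }
  }
  out
}

#' Average replicate samples into per-tissue TPM
#'
#' Sample columns named `<tissue>` or `<tissue>_<replicate>` are averaged
#' per tissue.
#'
#' @param tpm TPM tibble from [compute_tpm()].
#' @return Tibble `gene_id`, `length`, one column per tissue.
#' @export
tpm_by_tissue <- function(tpm) {
  samp <- setdiff(names(tpm), c("gene_id", "length"))
  tissue <- sub("_[^_]*$", "", samp)
  # names with no replicate suffix map to themselves
  tissue[!grepl("_", samp)] <- samp[!grepl("_", samp)]
  out <- tpm[, c("gene_id", "length")]
  for (tis in unique(tissue)) {
    cols <- samp[tissue == tis]
    out[[tis]] <- rowMeans(as.matrix(tpm[, cols, drop = FALSE]))
  }
  out
}

#' Per-triad, per-tissue TPM of the three homoeologs
#'
#' @param tpm_tissue Per-tissue TPM tibble from [tpm_by_tissue()] (or
#'   [compute_tpm()] when samples are tissues).
#' @param triads Triad tibble (`triad_id`, `H1`, `H2`, `H3`).
#' @return Long tibble: `triad_id`, `tissue`, `tpm_H1`, `tpm_H2`, `tpm_H3`.
#' @export
triad_tpm <- function(tpm_tissue, triads) {
  tissues <- setdiff(names(tpm_tissue), c("gene_id", "length"))
  missing <- setdiff(unlist(triads[, c("H1", "H2", "H3")]),
                     tpm_tissue$gene_id)
  if (length(missing) > 0) {
    stop("triad gene(s) absent from TPM table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  idx <- stats::setNames(seq_len(nrow(tpm_tissue)), tpm_tissue$gene_id)
  purrr::map_dfr(tissues, function(tis) {
    v <- tpm_tissue[[tis]]
    tibble::tibble(
      triad_id = triads$triad_id,
      tissue = tis,
      tpm_H1 = v[idx[triads$H1]],
      tpm_H2 = v[idx[triads$H2]],
      tpm_H3 = v[idx[triads$H3]]
    )
  })
}

#' Filter triads to the expressed set
#'
#' A triad is expressed when at least one of its three homoeologs has
#' TPM strictly greater than `threshold` in at least one tissue.
#'
#' @param triad_expr Long triad-TPM tibble from [triad_tpm()].
#' @param threshold TPM threshold (default 0.5; strict inequality).
#' @param per_homoeolog If `TRUE`, additionally flags each homoeolog's own
#'   expressed status in columns `expr_H1..expr_H3`.
#' @return List with `expressed` (vector of expressed triad IDs), `flags`
#'   (per-triad tibble) and the filtered long tibble `triad_expr`.
#' @export
filter_expressed <- function(triad_expr, threshold = 0.5,
                             per_homoeolog = FALSE) {
  flags <- triad_expr |>
    dplyr::group_by(.data$triad_id) |>
    dplyr::summarise(
      expr_H1 = any(.data$tpm_H1 > threshold),
      expr_H2 = any(.data$tpm_H2 > threshold),
      expr_H3 = any(.data$tpm_H3 > threshold),
      .groups = "drop"
    ) |>
    dplyr::mutate(expressed = .data$expr_H1 | .data$expr_H2 | .data$expr_H3)
  if (!per_homoeolog) {
    flags <- dplyr::select(flags, "triad_id", "expressed")
  }
  expressed <- flags$triad_id[flags$expressed]
  list(
    expressed = expressed,
    flags = flags,
    triad_expr = dplyr::filter(triad_expr, .data$triad_id %in% expressed)
  )
}

#' Standardize triad TPM to relative (ternary) coordinates
#'
#' Each homoeolog's TPM is divided by the triad's TPM sum:
#' `e_Hk = TPM_Hk / (TPM_H1 + TPM_H2 + TPM_H3)`. A zero-sum triad/tissue is
#' flagged (`defined = FALSE`) rather than dropped.
#'
#' @param triad_expr Long triad-TPM tibble (`tpm_H1..tpm_H3`).
#' @return The input with columns `e_H1`, `e_H2`, `e_H3` and `defined`.
#' @export
standardize_triads <- function(triad_expr) {
  tot <- triad_expr$tpm_H1 + triad_expr$tpm_H2 + triad_expr$tpm_H3
  defined <- tot > 0
  safe <- ifelse(defined, tot, NA_real_)
  triad_expr |>
    dplyr::mutate(
      e_H1 = .data$tpm_H1 / safe,
      e_H2 = .data$tpm_H2 / safe,
      e_H3 = .data$tpm_H3 / safe,
      defined = defined
    )
}

#' Combine per-tissue TPM into a single cross-tissue profile
#'
#' Aggregates each homoeolog's TPM across tissues (arithmetic mean by
#' default) and appends the result as tissue `"combined"`.
#'
#' @param triad_expr Long triad-TPM tibble.
#' @param method `"mean"` (default), `"sum"` or `"median"`.
#' @return The input with the combined rows appended.
#' @export
combine_tissues <- function(triad_expr, method = c("mean", "sum", "median")) {
  method <- match.arg(method)
  f <- switch(method, mean = mean, sum = sum, median = stats::median)
  combined <- triad_expr |>
    dplyr::filter(.data$tissue != "combined") |>
    dplyr::group_by(.data$triad_id) |>
    dplyr::summarise(
      tissue = "combined",
      tpm_H1 = f(.data$tpm_H1), tpm_H2 = f(.data$tpm_H2),
      tpm_H3 = f(.data$tpm_H3),
      .groups = "drop"
    )
  dplyr::bind_rows(triad_expr, combined)
}

#' Centroids of the seven bias groups in ternary coordinates
#' @return A 7 x 3 matrix, rows named by [bias_groups()].
#' @export
bias_centroids <- function() {
  m <- rbind(
    balanced = c(1, 1, 1) / 3,
    H1D = c(1, 0, 0), H2D = c(0, 1, 0), H3D = c(0, 0, 1),
    H1S = c(0, 1, 1) / 2, H2S = c(1, 0, 1) / 2, H3S = c(1, 1, 0) / 2
  )
  colnames(m) <- c("e_H1", "e_H2", "e_H3")
  m
}

#' Classify triads into the seven bias groups
#'
#' Nearest-centroid classification by Euclidean distance in ternary
#' coordinates: balanced (1/3,1/3,1/3); dominant groups at the vertices;
#' suppressed groups at the opposite edge midpoints (0, 1/2, 1/2 and
#' permutations). Ties go to the first group in
#' `balanced, H1D, H2D, H3D, H1S, H2S, H3S` order. Every defined triad is
#' assigned; there is no no-call band.
#'
#' @param rel Tibble with columns `e_H1`, `e_H2`, `e_H3` (each row summing
#'   to 1); typically from [standardize_triads()]. Rows with
#'   `defined == FALSE` raise an error - filter first.
#' @return The input with `group`, `distance` (to the winning centroid) and
#'   `margin` (runner-up distance minus winning distance), plus the seven
#'   per-centroid distances in columns `d_balanced` .. `d_H3S`.
#' @export
classify_bias <- function(rel) {
  if (!all(c("e_H1", "e_H2", "e_H3") %in% names(rel))) {
    stop("rel must contain columns e_H1, e_H2, e_H3")
  }
  if (!is.null(rel[["defined"]]) && any(!rel$defined)) {
    stop("undefined relative-expression rows present; ",
         "filter zero-sum triads before classification")
  }
  e <- as.matrix(rel[, c("e_H1", "e_H2", "e_H3")])
  if (anyNA(e)) stop("NA in relative expression; filter first")
  cen <- bias_centroids()
  d <- vapply(rownames(cen), function(g) {
    sqrt(colSums((t(e) - cen[g, ])^2))
  }, numeric(nrow(e)))
  d <- matrix(d, nrow = nrow(e),
              dimnames = list(NULL, rownames(cen)))
  win <- apply(d, 1, which.min)  # which.min takes the first on ties
  runner <- vapply(seq_len(nrow(d)), function(i) {
    min(d[i, -win[i]])
  }, numeric(1))
  dist_cols <- tibble::as_tibble(d)
  names(dist_cols) <- paste0("d_", colnames(d))
  dplyr::bind_cols(
    rel,
    tibble::tibble(
      group = bias_groups()[win],
      distance = d[cbind(seq_len(nrow(d)), win)],
      margin = runner - d[cbind(seq_len(nrow(d)), win)]
    ),
    dist_cols
  )
}

#' Per-tissue counts and percentages of the seven bias groups
#'
#' @param assignments Classified tibble from [classify_bias()] carrying
#'   `tissue` and `group`.
#' @param tissues Tissues to summarise (default: those present in
#'   `assignments`; pass explicitly to force zero rows for empty tissues).
#' @return Tibble with one row per tissue and group: `n`, `percent`
#'   (2 decimals) and `n_expressed_triads` per tissue.
#' @export
summarize_groups <- function(assignments,
                             tissues = unique(assignments$tissue)) {
  out <- purrr::map_dfr(tissues, function(tis) {
    sub <- dplyr::filter(assignments, .data$tissue == tis)
    if (nrow(sub) == 0) {
      warning("tissue ", tis, " has no assigned triads")
      return(tibble::tibble(tissue = tis, group = bias_groups(), n = 0L,
                            percent = 0, n_expressed_triads = 0L))
    }
    counts <- table(factor(sub$group, levels = bias_groups()))
    tibble::tibble(
      tissue = tis,
      group = bias_groups(),
      n = as.integer(counts),
      percent = round(100 * as.integer(counts) / nrow(sub), 2),
      n_expressed_triads = nrow(sub)
    )
  })
  out
}

#' Windowed density of non-balanced triad genes along chromosomes
#'
#' Counts genes of non-balanced triads in fixed windows `[1, w]`,
#' `[w+1, 2w]`, ... per chromosome; a gene falls in the window containing
#' its span midpoint.
#'
#' @param assignments Classified tibble with `triad_id` and `group` (one row
#'   per triad, e.g. the combined tissue).
#' @param triads Triad tibble (`triad_id`, `H1`, `H2`, `H3`).
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param window Window size in bp (default 100 kb).
#' @return Tibble `chrom`, `window_start` (0-based, bedgraph style),
#'   `window_end`, `n_biased_genes`.
#' @export
biased_gene_density <- function(assignments, triads, genes, window = 1e5) {
  biased <- assignments |>
    dplyr::filter(.data$group != "balanced") |>
    dplyr::distinct(.data$triad_id) |>
    dplyr::inner_join(triads, by = "triad_id") |>
    tidyr::pivot_longer(c("H1", "H2", "H3"), values_to = "gene_id") |>
    dplyr::select("gene_id")
  gene_pos <- genes |>
    dplyr::semi_join(biased, by = "gene_id")
  unknown <- setdiff(biased$gene_id, genes$gene_id)
  if (length(unknown) > 0) {
    stop("biased gene(s) without a gene model: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  gene_pos |>
    dplyr::mutate(
      midpoint = floor((.data$start + .data$end) / 2),
      win = floor((.data$midpoint - 1) / window)
    ) |>
    dplyr::count(.data$chrom, .data$win, name = "n_biased_genes") |>
    dplyr::transmute(
      .data$chrom,
      window_start = as.integer(.data$win * window),
      window_end = as.integer((.data$win + 1) * window),
      .data$n_biased_genes
    ) |>
    dplyr::arrange(.data$chrom, .data$window_start)
}
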