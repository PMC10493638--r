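# Telomere tract detection and T2T classification, centromere-candidate
# tandem-array detection, and NLR locus genic/intergenic status with
# cluster summaries. Overlap logic is strand-blind throughout.

TELOMERE_UNIT_5P <- "CCCATTT"
TELOMERE_UNIT_3P <- "TTTAGGG"

#' Detect telomere tracts at chromosome ends
#'
#' Scans each chromosome end for a maximal run of the plant telomere
#' seven-mer (CCCATTT read from the 5' end, TTTAGGG toward the 3' end).
#' The tract must begin within `max_offset` bp of the chromosome end but may
#' extend arbitrarily far inward. Mismatched units are tolerated; purity is
#' the fraction of exactly matching 7-mers in the tract, and bases marked N
#' count as mismatches.
#'
#' @param genome A named `DNAStringSet` (one entry per chromosome).
#' @param max_offset Maximum distance (bp) from the chromosome end at which
#'   a tract may start (default 10000).
#' @param min_copies Minimum unit copies for a call (default 100).
#' @param min_purity Minimum fraction of exact unit matches (default 0.9).
#' @return Tibble with `chrom`, `end` (`"5prime"`/`"3prime"`), `start`,
#'   `stop` (1-based closed), `length_bp`, `copy_estimate` and `purity`.
#' @export
find_telomeres <- function(genome, max_offset = 10000L, min_copies = 100L,
                           min_purity = 0.9) {
  purrr::map_dfr(names(genome), function(chrom) {
    seq <- as.character(genome[[chrom]])
    dplyr::bind_rows(
      .telomere_one_end(seq, chrom, "5prime", max_offset, min_copies,
                        min_purity),
      .telomere_one_end(seq, chrom, "3prime", max_offset, min_copies,
                        min_purity)
    )
  })
}

.telomere_one_end <- function(seq, chrom, which_end, max_offset, min_copies,
                              min_purity) {
  unit <- if (which_end == "5prime") TELOMERE_UNIT_5P else TELOMERE_UNIT_3P
  L <- nchar(seq)
  hits <- Biostrings::matchPattern(unit, Biostrings::DNAString(seq))
  starts <- BiocGenerics::start(hits)
  if (length(starts) == 0) return(NULL)
  # chain exact unit matches separated by at most two mismatched units
  max_gap <- 7L * 3L
  breaks <- which(diff(starts) > max_gap)
  chain_id <- cumsum(c(1L, as.integer(diff(starts) > max_gap)))
  chains <- split(starts, chain_id)
  best <- NULL
  for (ch in chains) {
    tract_start <- ch[1]
    tract_stop <- ch[length(ch)] + 6L
    near_end <- if (which_end == "5prime") {
      tract_start - 1L <= max_offset
    } else {
      L - tract_stop <= max_offset
    }
    if (!near_end) next
    len <- tract_stop - tract_start + 1L
    n_units <- round(len / 7)
    purity <- length(ch) / n_units
    if (n_units < min_copies || purity < min_purity) next
    if (is.null(best) || len > best$length_bp) {
      best <- tibble::tibble(
        chrom = chrom, end = which_end,
        start = tract_start, stop = tract_stop,
        length_bp = len, copy_estimate = len / 7, purity = purity
      )
    }
  }
  best
}

#' Classify chromosomes by telomere completeness
#'
#' A chromosome is telomere-to-telomere (T2T) when tracts were called at
#' both ends.
#'
#' @param calls Telomere-call tibble from [find_telomeres()].
#' @param genome The `DNAStringSet` the calls came from (defines the full
#'   chromosome set, so chromosomes with no call are counted).
#' @return List with `per_chromosome` (chrom, status in
#'   `T2T`/`one-ended`/`none`) and `counts` (one row per status).
#' @export
classify_t2t <- function(calls, genome) {
  per_chrom <- tibble::tibble(chrom = names(genome)) |>
    dplyr::left_join(
      calls |>
        dplyr::group_by(.data$chrom) |>
        dplyr::summarise(n_ends = dplyr::n_distinct(.data$end),
                         .groups = "drop"),
      by = "chrom"
    ) |>
    dplyr::mutate(
      n_ends = dplyr::coalesce(.data$n_ends, 0L),
      status = dplyr::case_when(
        .data$n_ends == 2L ~ "T2T",
        .data$n_ends == 1L ~ "one-ended",
        TRUE ~ "none"
      )
    ) |>
    dplyr::select("chrom", "status")
  counts <- per_chrom |>
    dplyr::count(status = factor(.data$status,
                                 levels = c("T2T", "one-ended", "none")),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(status = as.character(.data$status))
  list(per_chromosome = per_chrom, counts = counts)
}

#' Detect tandem-repeat arrays by periodicity scanning
#'
#' For each candidate unit length `u`, finds maximal intervals where the
#' sequence matches itself at lag `u` with at least 80% per-base identity
#' (assessed over rolling windows of length `u`). Overlapping candidate
#' arrays across unit lengths are resolved greedily longest-first (ties:
#' smaller unit, then leftmost). The longest reported array on a chromosome
#' is its centromere candidate.
#'
#' @param seq A DNA string or `DNAString` (one chromosome).
#' @param chrom Chromosome name used in the output.
#' @param unit_length_range Two integers within `[2, 2000]`: the candidate
#'   unit lengths to scan (every length in the range is tried).
#' @param min_array_bp Minimum array length in bp (default 10000).
#' @param min_identity Minimum periodic per-base identity (default 0.8).
#' @return Tibble with `chrom`, `start`, `end`, `length_bp`, `unit_length`,
#'   `unit_sequence` (modal unit), `copy_number`, `array_score`.
#' @export
find_tandem_arrays <- function(seq, chrom = "chr", unit_length_range,
                               min_array_bp = 10000L, min_identity = 0.8) {
  if (length(unit_length_range) != 2 || unit_length_range[1] < 2 ||
      unit_length_range[2] > 2000 || unit_length_range[1] > unit_length_range[2]) {
    stop("unit_length_range must be two increasing integers within [2, 2000]")
  }
  x <- strsplit(toupper(as.character(seq)), "")[[1]]
  L <- length(x)
  cand <- list()
  for (u in seq(unit_length_range[1], unit_length_range[2])) {
    if (L < 2 * u) next
    m <- as.integer(x[seq_len(L - u)] == x[(u + 1):L])
    # rolling fraction of periodic matches over windows of length u
    cs <- c(0L, cumsum(m))
    n_win <- length(m) - u + 1L
    if (n_win < 1) next
    frac <- (cs[(u + 1):(u + n_win)] - cs[seq_len(n_win)]) / u
    good <- frac >= min_identity
    if (!any(good)) next
    r <- rle(good)
    pos_end <- cumsum(r$lengths)
    pos_start <- pos_end - r$lengths + 1L
    for (k in which(r$values)) {
      a <- pos_start[k]                # first window start (match index)
      b <- pos_end[k] + u - 1L         # last match index covered
      s0 <- a                          # sequence interval
      e0 <- min(b + u, L)
      if (e0 - s0 + 1L < min_array_bp) next
      cand[[length(cand) + 1L]] <- list(start = s0, end = e0, u = u)
    }
  }
  if (length(cand) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      length_bp = integer(), unit_length = integer(),
      unit_sequence = character(), copy_number = integer(),
      array_score = numeric()
    ))
  }
  tb <- purrr::map_dfr(cand, tibble::as_tibble) |>
    dplyr::mutate(len = .data$end - .data$start + 1L) |>
    dplyr::arrange(dplyr::desc(.data$len), .data$u, .data$start)
  # greedy non-overlapping selection, longest first
  sel <- list()
  for (i in seq_len(nrow(tb))) {
    s <- tb$start[i]; e <- tb$end[i]
    overlaps <- any(vapply(sel, function(z) s <= z$end && e >= z$start, TRUE))
    if (!overlaps) sel[[length(sel) + 1L]] <- list(start = s, end = e,
                                                   u = tb$u[i])
  }
  purrr::map_dfr(sel, function(z) {
    len <- z$end - z$start + 1L
    n_full <- len %/% z$u
    blocks <- substring(
      paste(x[z$start:z$end], collapse = ""),
      z$u * (seq_len(n_full) - 1L) + 1L,
      z$u * seq_len(n_full)
    )
    modal <- names(sort(table(blocks), decreasing = TRUE))[1]
    mod_chars <- strsplit(modal, "")[[1]]
    score <- mean(vapply(blocks, function(b) {
      mean(strsplit(b, "")[[1]] == mod_chars)
    }, numeric(1)))
    tibble::tibble(
      chrom = chrom, start = z$start, end = z$end, length_bp = len,
      unit_length = z$u, unit_sequence = modal, copy_number = n_full,
      array_score = score
    )
  }) |>
    dplyr::arrange(dplyr::desc(.data$length_bp))
}

#' Centromere candidate per chromosome
#'
#' Runs [find_tandem_arrays()] on every chromosome and reports the longest
#' array per chromosome.
#'
#' @inheritParams find_telomeres
#' @inheritParams find_tandem_arrays
#' @return Tibble with one row per chromosome that has a qualifying array.
#' @export
centromere_candidates <- function(genome, unit_length_range,
                                  min_array_bp = 10000L) {
  purrr::map_dfr(names(genome), function(chrom) {
    arr <- find_tandem_arrays(genome[[chrom]], chrom, unit_length_range,
                              min_array_bp)
    if (nrow(arr) == 0) return(NULL)
    arr[1, ]
  })
}

#' Genic/intergenic status of NLR loci
#'
#' A locus is genic when its interval overlaps any annotated gene span by at
#' least 1 bp (strand-blind); the overlapping gene with the largest overlap
#' is recorded (ties: lexicographically smaller gene ID).
#'
#' @param loci Interval tibble (`chrom`, `start`, `end`, `name`; 1-based
#'   closed, as from [read_bed()]).
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param allowlist Optional character vector of gene IDs; when given, only
#'   overlaps with these genes count as genic.
#' @return Tibble with `locus_id`, `chrom`, `start`, `end`, `status`
#'   (`genic`/`intergenic`) and `overlapping_gene`.
#' @export
nlr_status <- function(loci, genes, allowlist = NULL) {
  bad <- setdiff(unique(loci$chrom), unique(genes$chrom))
  if (length(bad) > 0) {
    stop("NLR locus on chromosome absent from annotation: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(allowlist)) {
    genes <- dplyr::filter(genes, .data$gene_id %in% allowlist)
  }
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    g <- genes[genes$chrom == loci$chrom[i], ]
    ov_start <- pmax(g$start, loci$start[i])
    ov_end <- pmin(g$end, loci$end[i])
    ov <- pmax(0L, ov_end - ov_start + 1L)
    hit <- which(ov > 0)
    if (length(hit) == 0) {
      gene <- NA_character_
    } else {
      best <- hit[order(-ov[hit], g$gene_id[hit])][1]
      gene <- g$gene_id[best]
    }
    tibble::tibble(
      locus_id = loci$name[i], chrom = loci$chrom[i],
      start = loci$start[i], end = loci$end[i],
      status = if (is.na(gene)) "intergenic" else "genic",
      overlapping_gene = gene
    )
  })
}

#' Cluster NLR loci by single-linkage chaining
#'
#' Consecutive loci on a chromosome join a cluster when the gap between them
#' is at most `max_gap` bp; clusters with at least `min_loci` members are
#' reported with their genic/total ratio (the "NLR genes / NLR loci" style
#' summary).
#'
#' @param status NLR status tibble from [nlr_status()].
#' @param max_gap Maximum gap in bp between consecutive cluster members
#'   (default 200000).
#' @param min_loci Minimum cluster size to report (default 5).
#' @return Tibble with `cluster_id`, `chrom`, `span_start`, `span_end`,
#'   `location_mb` (e.g. `"43.02-43.80"`), `n_loci`, `n_genic` and `ratio`
#'   (`"n_genic/n_loci"`).
#' @export
cluster_nlr <- function(status, max_gap = 200000L, min_loci = 5L) {
  sorted <- dplyr::arrange(status, .data$chrom, .data$start, .data$end)
  out <- sorted |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(cummax(.data$end)) - 1L,
      new_cluster = dplyr::coalesce(.data$gap > max_gap, TRUE),
      cluster = cumsum(.data$new_cluster)
    ) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      span_start = min(.data$start), span_end = max(.data$end),
      n_loci = dplyr::n(),
      n_genic = sum(.data$status == "genic"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_loci >= min_loci) |>
    dplyr::arrange(.data$chrom, .data$span_start) |>
    dplyr::mutate(
      cluster_id = sprintf("%s_cluster%d", .data$chrom,
                           stats::ave(rep(1L, dplyr::n()), .data$chrom,
                                      FUN = seq_along)),
      location_mb = sprintf("%.2f-%.2f", .data$span_start / 1e6,
                            .data$span_end / 1e6),
      ratio = sprintf("%d/%d", .data$n_genic, .data$n_loci)
    ) |>
    dplyr::select("cluster_id", "chrom", "span_start", "span_end",
                  "location_mb", "n_loci", "n_genic", "ratio")
  out
}
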