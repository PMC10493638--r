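# Allele-group construction across the three haploid assemblies.
# A triad is a closed reciprocal-best-hit triangle: one gene per haplotype,
# each pair of which are mutual best hits in each other's haplotype.

#' The seven homoeolog-expression-bias group labels
#' @return Character vector `balanced, H1D, H2D, H3D, H1S, H2S, H3S`.
#' @export
bias_groups <- function() {
  c("balanced", "H1D", "H2D", "H3D", "H1S", "H2S", "H3S")
}

#' Best hit per (query, target haplotype)
#'
#' For every query gene and every haplotype other than its own, keeps the
#' single best-scoring subject: highest percent identity, ties broken by bit
#' score then lexicographically smaller subject ID. Hits below the identity
#' or coverage thresholds are dropped first (coverage = alignment length /
#' query protein length).
#'
#' @param hits Hit tibble as returned by [read_hits()].
#' @param gene_map Tibble with `gene_id`, `haplotype` and `length` (protein
#'   length in residues) covering every gene in `hits`.
#' @param min_identity Minimum percent identity (default 60).
#' @param min_coverage Minimum query coverage fraction (default 0.5).
#' @return Tibble with one row per retained (query, target haplotype):
#'   `query_id`, `query_haplotype`, `subject_haplotype`, `subject_id`,
#'   `percent_identity`, `bit_score`.
#' @export
best_hits <- function(hits, gene_map, min_identity = 60, min_coverage = 0.5) {
  hap <- stats::setNames(gene_map$haplotype, gene_map$gene_id)
  len <- stats::setNames(gene_map$length, gene_map$gene_id)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(hap))
  if (length(unknown) > 0) {
    stop("gene(s) with unresolvable haplotype: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  hits |>
    dplyr::mutate(
      query_haplotype = unname(hap[.data$query_id]),
      subject_haplotype = unname(hap[.data$subject_id]),
      coverage = .data$alignment_length / unname(len[.data$query_id])
    ) |>
    dplyr::filter(
      .data$query_haplotype != .data$subject_haplotype,
      .data$percent_identity >= min_identity,
      .data$coverage >= min_coverage
    ) |>
    dplyr::arrange(
      .data$query_id, .data$subject_haplotype,
      dplyr::desc(.data$percent_identity), dplyr::desc(.data$bit_score),
      .data$subject_id
    ) |>
    dplyr::distinct(.data$query_id, .data$subject_haplotype,
                    .keep_all = TRUE) |>
    dplyr::select("query_id", "query_haplotype", "subject_haplotype",
                  "subject_id", "percent_identity", "bit_score")
}

#' Reciprocal best-hit pairs
#'
#' A pair (A, B) is kept iff A's best hit in B's haplotype is B and B's best
#' hit in A's haplotype is A.
#'
#' @param best Best-hit tibble from [best_hits()].
#' @return Tibble with `gene_a`, `gene_b` (lexicographically ordered),
#'   `hap_a`, `hap_b` and `identity` (mean of the two directions).
#' @export
reciprocal_pairs <- function(best) {
  fwd <- best |>
    dplyr::transmute(
      gene_a = pmin(.data$query_id, .data$subject_id),
      gene_b = pmax(.data$query_id, .data$subject_id),
      identity = .data$percent_identity
    )
  pairs <- fwd |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(n_dir = dplyr::n(), identity = mean(.data$identity),
                     .groups = "drop") |>
    dplyr::filter(.data$n_dir == 2L) |>
    dplyr::select(-"n_dir")
  pairs
}

#' Partition a gene inventory into triads, pairs and singletons
#'
#' Triads are closed triangles of reciprocal pairs (one gene per haplotype).
#' Genes linked by exactly one surviving pair form a 2-gene group; the rest
#' are singletons. Open chains (A-B and B-C but no A-C) are resolved by
#' discarding the weaker link (lower identity; ties by lexicographic pair
#' name) so each gene ends up in exactly one class.
#'
#' @param pairs Reciprocal-pair tibble from [reciprocal_pairs()].
#' @param gene_map Gene inventory tibble (`gene_id`, `haplotype`).
#' @return An object of class `allele_partition`: a list with tibbles
#'   `triads` (`triad_id`, `H1`, `H2`, `H3`, `mean_identity`), `pairs`
#'   (`gene_a`, `gene_b`, `identity`) and `singletons` (`gene_id`).
#' @export
build_partition <- function(pairs, gene_map) {
  hap <- stats::setNames(gene_map$haplotype, gene_map$gene_id)
  haps <- sort(unique(gene_map$haplotype))
  if (length(haps) > 3) stop("more than 3 haplotypes in gene inventory")
  p <- pairs |>
    dplyr::mutate(hap_a = unname(hap[.data$gene_a]),
                  hap_b = unname(hap[.data$gene_b]))
  if (anyNA(p$hap_a) || anyNA(p$hap_b)) {
    stop("pair gene absent from gene inventory")
  }

  # adjacency: for each gene, its partner per other haplotype (unique by
  # construction of best_hits: at most one RBH partner per haplotype)
  edges <- dplyr::bind_rows(
    dplyr::transmute(p, gene = .data$gene_a, partner = .data$gene_b,
                     partner_hap = .data$hap_b, identity = .data$identity),
    dplyr::transmute(p, gene = .data$gene_b, partner = .data$gene_a,
                     partner_hap = .data$hap_a, identity = .data$identity)
  )
  key <- paste(edges$gene, edges$partner_hap)
  if (anyDuplicated(key)) {
    dup <- edges$gene[duplicated(key)][1]
    stop("gene ", dup, " has two reciprocal partners in one haplotype; ",
         "upstream multi-mapping must be resolved first")
  }
  link <- stats::setNames(edges$partner, key)
  pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pair_identity <- stats::setNames(p$identity, pair_id(p$gene_a, p$gene_b))

  # closed triangles
  tri <- p |>
    dplyr::filter(.data$hap_a != .data$hap_b) |>
    dplyr::rowwise() |>
    dplyr::mutate(third_hap = setdiff(haps, c(.data$hap_a, .data$hap_b))[1]) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      c_from_a = unname(link[paste(.data$gene_a, .data$third_hap)]),
      c_from_b = unname(link[paste(.data$gene_b, .data$third_hap)])
    ) |>
    dplyr::filter(!is.na(.data$c_from_a),
                  .data$c_from_a == .data$c_from_b)
  triads <- tri |>
    dplyr::rowwise() |>
    dplyr::mutate(members = list(sort(c(.data$gene_a, .data$gene_b,
                                        .data$c_from_a)))) |>
    dplyr::ungroup() |>
    dplyr::mutate(tkey = purrr::map_chr(.data$members, paste,
                                        collapse = "|")) |>
    dplyr::distinct(.data$tkey, .keep_all = TRUE)

  tri_rows <- purrr::map_dfr(triads$members, function(m) {
    h <- unname(hap[m])
    ids <- stats::setNames(m, h)
    mean_id <- mean(c(
      pair_identity[pair_id(m[1], m[2])],
      pair_identity[pair_id(m[1], m[3])],
      pair_identity[pair_id(m[2], m[3])]
    ))
    tibble::tibble(H1 = ids[[haps[1]]], H2 = ids[[haps[2]]],
                   H3 = ids[[haps[3]]], mean_identity = mean_id)
  })
  if (nrow(tri_rows) > 0) {
    in_triad <- unique(c(tri_rows$H1, tri_rows$H2, tri_rows$H3))
    if (anyDuplicated(c(tri_rows$H1, tri_rows$H2, tri_rows$H3))) {
      stop("a gene participates in two triangles; ",
           "upstream multi-mapping must be resolved first")
    }
    tri_rows <- tri_rows |>
      dplyr::arrange(.data$H1) |>
      dplyr::mutate(triad_id = sprintf("triad_%05d", dplyr::row_number()),
                    .before = 1)
  } else {
    tri_rows <- tibble::tibble(triad_id = character(), H1 = character(),
                               H2 = character(), H3 = character(),
                               mean_identity = numeric())
    in_triad <- character()
  }

  # remaining links among non-triad genes; resolve chains weakest-link-first
  rem <- p |>
    dplyr::filter(!.data$gene_a %in% in_triad, !.data$gene_b %in% in_triad) |>
    dplyr::arrange(dplyr::desc(.data$identity), .data$gene_a, .data$gene_b)
  used <- character()
  keep <- logical(nrow(rem))
  for (i in seq_len(nrow(rem))) {
    a <- rem$gene_a[i]; b <- rem$gene_b[i]
    if (!(a %in% used) && !(b %in% used)) {
      keep[i] <- TRUE
      used <- c(used, a, b)
    }
  }
  pair_rows <- rem[keep, c("gene_a", "gene_b", "identity")]

  grouped <- c(in_triad, pair_rows$gene_a, pair_rows$gene_b)
  singles <- tibble::tibble(
    gene_id = sort(setdiff(gene_map$gene_id, grouped))
  )
  out <- list(triads = tri_rows, pairs = tibble::as_tibble(pair_rows),
              singletons = singles, haplotypes = haps,
              n_genes = nrow(gene_map))
  class(out) <- "allele_partition"
  .check_partition(out, gene_map)
  out
}

.check_partition <- function(x, gene_map) {
  members <- c(x$triads$H1, x$triads$H2, x$triads$H3,
               x$pairs$gene_a, x$pairs$gene_b, x$singletons$gene_id)
  if (anyDuplicated(members)) {
    stop("internal error: partition not disjoint")
  }
  if (!setequal(members, gene_map$gene_id)) {
    stop("internal error: partition not exhaustive")
  }
  invisible(x)
}

#' @export
print.allele_partition <- function(x, ...) {
  cat("Allele partition over", x$n_genes, "genes\n")
  cat("  triads:    ", nrow(x$triads), "\n")
  cat("  pairs:     ", nrow(x$pairs), "\n")
  cat("  singletons:", nrow(x$singletons), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an allele partition into one row per gene
#' @param x An `allele_partition`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `class` (triad/pair/singleton), `group_id`.
#' @method tidy allele_partition
#' @export
tidy.allele_partition <- function(x, ...) {
  dplyr::bind_rows(
    x$triads |>
      tidyr::pivot_longer(c("H1", "H2", "H3"), names_to = "haplotype",
                          values_to = "gene_id") |>
      dplyr::transmute(.data$gene_id, class = "triad",
                       group_id = .data$triad_id),
    x$pairs |>
      dplyr::mutate(group_id = paste0("pair_", dplyr::row_number())) |>
      tidyr::pivot_longer(c("gene_a", "gene_b"), values_to = "gene_id") |>
      dplyr::transmute(.data$gene_id, class = "pair", .data$group_id),
    x$singletons |>
      dplyr::transmute(.data$gene_id, class = "singleton",
                       group_id = NA_character_)
  )
}

#' One-row summary of an allele partition
#' @param x An `allele_partition`.
#' @param ... Unused.
#' @return Tibble with group and gene counts.
#' @method glance allele_partition
#' @export
glance.allele_partition <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_genes,
    n_triads = nrow(x$triads),
    n_pairs = nrow(x$pairs),
    n_singletons = nrow(x$singletons),
    n_groups = nrow(x$triads) + nrow(x$pairs) + nrow(x$singletons)
  )
}

#' Anchor allele groups to a reference assembly
#'
#' Annotates each triad with the reference gene that is the best hit of a
#' majority of its members (2 of 3 or 3 of 3); groups with a 1-1-1 split stay
#' unanchored.
#'
#' @param partition An `allele_partition`.
#' @param ref_hits Hit tibble of haplotype proteins (queries) versus the
#'   reference proteome (subjects).
#' @return The partition with a `ref_anchor` column added to `triads`.
#' @export
anchor_to_reference <- function(partition, ref_hits) {
  best_ref <- ref_hits |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$percent_identity),
                   dplyr::desc(.data$bit_score), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  lookup <- stats::setNames(best_ref$subject_id, best_ref$query_id)
  partition$triads$ref_anchor <- purrr::pmap_chr(
    partition$triads[, c("H1", "H2", "H3")],
    function(H1, H2, H3) {
      anchors <- unname(lookup[c(H1, H2, H3)])
      anchors <- anchors[!is.na(anchors)]
      if (length(anchors) == 0) return(NA_character_)
      tab <- sort(table(anchors), decreasing = TRUE)
      if (tab[1] >= 2) names(tab)[1] else NA_character_
    }
  )
  partition
}

#' Summary of expressed triads relative to all allele groups
#'
#' @param n_expressed Number of expressed triads.
#' @param n_groups Total number of allele groups considered.
#' @return Tibble with the expressed percentage (2 decimals) and the
#'   expressed gene count (3 genes per triad).
#' @export
expressed_triad_summary <- function(n_expressed, n_groups) {
  tibble::tibble(
    n_expressed_triads = n_expressed,
    n_groups = n_groups,
    pct_expressed = round(100 * n_expressed / n_groups, 2),
    n_expressed_genes = 3L * n_expressed
  )
}
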