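# Cache for NG86 lookup tables (built once per session on first use).
.ng86_env <- new.env(parent = emptyenv())

.genetic_code <- function() Biostrings::GENETIC_CODE

#' Non-stop codons of the standard genetic code
#' @return Character vector of the 61 sense codons.
#' @keywords internal
.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

.translate_codon <- function(codon) unname(.genetic_code()[codon])

#' Nei-Gojobori synonymous and nonsynonymous site counts for one codon
#'
#' For each of the nine single-nucleotide changes of a codon, the change is
#' synonymous when the encoded amino acid is unchanged; changes that create a
#' stop codon count as nonsynonymous. The synonymous site count is the sum
#' over positions of the synonymous fraction among the three possible changes,
#' so `n_sites + s_sites == 3` for every codon.
#'
#' @param codon A length-3 string over A, C, G, T; must not be a stop codon.
#' @return Named numeric vector with elements `n_sites` and `s_sites`.
#' @examples
#' ng86_sites("TTT") # one third of a synonymous site at position 3
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("codon must be a 3-mer over {A,C,G,T}, got: ", codon)
  }
  gc <- .genetic_code()
  aa <- gc[[codon]]
  if (aa == "*") stop("stop codon has no NG86 site count: ", codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (j in 1:3) {
    ref <- substr(codon, j, j)
    for (b in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, j, j) <- b
      aa2 <- gc[[mut]]
      if (aa2 != "*" && aa2 == aa) s <- s + 1 / 3
    }
  }
  c(n_sites = 3 - s, s_sites = s)
}

#' Nei-Gojobori difference counts for a codon pair
#'
#' Differences are apportioned into synonymous and nonsynonymous steps by
#' averaging over all orderings of the single-nucleotide mutational pathway
#' between the two codons. Pathways passing through a stop codon are
#' excluded; when every pathway is blocked by a stop, all steps are counted
#' as nonsynonymous. `nd + sd` always equals the number of differing
#' positions.
#'
#' @param codon_a,codon_b Length-3 strings over A, C, G, T; neither a stop.
#' @return Named numeric vector with elements `nd` and `sd`.
#' @examples
#' ng86_differences("GGT", "GGC") # one synonymous difference
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (!grepl("^[ACGT]{3}$", cd)) stop("invalid codon: ", cd)
    if (.genetic_code()[[cd]] == "*") stop("stop codon not allowed: ", cd)
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(nd = 0, sd = 0))
  gc <- .genetic_code()
  perms <- .permutations(diff_pos)
  n_tot <- 0
  s_tot <- 0
  n_valid <- 0L
  for (p in perms) {
    cur <- codon_a
    nd <- 0
    sd <- 0
    ok <- TRUE
    for (j in p) {
      nxt <- cur
      substr(nxt, j, j) <- substr(codon_b, j, j)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      n_tot <- n_tot + nd
      s_tot <- s_tot + sd
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(c(nd = k, sd = 0))
  c(nd = n_tot / n_valid, sd = s_tot / n_valid)
}

# All orderings of a small set of positions (k <= 3 here).
.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Build (and cache) lookup tables over the 61 sense codons: per-codon site
# counts and 61x61 nd/sd matrices, so whole-alignment sums are vector lookups.
.ng86_tables <- function() {
  if (!is.null(.ng86_env$tables)) return(.ng86_env$tables)
  codons <- .sense_codons()
  sites <- vapply(codons, ng86_sites, numeric(2))
  n <- length(codons)
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- ng86_differences(codons[i], codons[j])
      nd[i, j] <- d[["nd"]]
      sd[i, j] <- d[["sd"]]
    }
  }
  .ng86_env$tables <- list(
    codons = codons,
    n_sites = sites["n_sites", ],
    s_sites = sites["s_sites", ],
    nd = nd,
    sd = sd
  )
  .ng86_env$tables
}

#' Nei-Gojobori (NG86) Ka and Ks for a codon-aligned sequence pair
#'
#' Computes expected synonymous/nonsynonymous site counts (averaged over the
#' two sequences), observed difference counts apportioned over shortest
#' mutational pathways, and Jukes-Cantor corrected rates
#' `Ka = -3/4 * log(1 - 4/3 * pN)` (likewise for Ks). Codon columns
#' containing a gap (`-`) or an ambiguous base in either sequence are dropped
#' pairwise before counting.
#'
#' @param seq_a,seq_b DNA strings of equal length, a multiple of 3.
#' @return A one-row tibble with columns `n_codons`, `N`, `S`, `Nd`, `Sd`,
#'   `pN`, `pS`, `Ka`, `Ks`, `ka_ks` and `saturated`. `ka_ks` is `NA` when
#'   `Sd == 0` (no synonymous signal) or when a proportion is saturated
#'   (`p >= 3/4`), in which case `saturated` is `TRUE`.
#' @examples
#' pair <- evolve_cds_pair(100, target_ka = 0.02, target_ks = 0.10, seed = 1)
#' compute_kaks(pair$cds_a, pair$cds_b)
#' @export
compute_kaks <- function(seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  }
  if (nchar(seq_a) %% 3 != 0) stop("aligned length must be a multiple of 3")
  cod_a <- .split_codons(seq_a)
  cod_b <- .split_codons(seq_b)
  keep <- grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  cod_a <- cod_a[keep]
  cod_b <- cod_b[keep]
  tb <- .ng86_tables()
  ia <- match(cod_a, tb$codons)
  ib <- match(cod_b, tb$codons)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(cod_a[is.na(ia)], cod_b[is.na(ib)]))
    stop("internal stop codon(s) in alignment: ", paste(bad, collapse = ", "))
  }
  N <- (sum(tb$n_sites[ia]) + sum(tb$n_sites[ib])) / 2
  S <- (sum(tb$s_sites[ia]) + sum(tb$s_sites[ib])) / 2
  Nd <- sum(tb$nd[cbind(ia, ib)])
  Sd <- sum(tb$sd[cbind(ia, ib)])
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  jc <- function(p) {
    if (is.na(p) || p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ka <- jc(pN)
  Ks <- jc(pS)
  saturated <- (!is.na(pN) && pN >= 3 / 4) || (!is.na(pS) && pS >= 3 / 4)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Sd > 0 && Ks > 0) Ka / Ks else NA_real_
  tibble::tibble(
    n_codons = length(cod_a), N = N, S = S, Nd = Nd, Sd = Sd,
    pN = pN, pS = pS, Ka = Ka, Ks = Ks, ka_ks = ratio, saturated = saturated
  )
}

.split_codons <- function(x) {
  n <- nchar(x) %/% 3
  substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' NG86 Ka/Ks for every homoeolog pair of each triad
#'
#' Computes `compute_kaks()` for the three pairwise comparisons (H1-H2,
#' H1-H3, H2-H3) of each triad and summarises each triad by the mean of its
#' defined pairwise Ka/Ks ratios.
#'
#' @param triads Tibble with columns `triad_id`, `H1`, `H2`, `H3` (gene IDs),
#'   as returned by [build_partition()].
#' @param cds Named character vector (or `DNAStringSet`) of CDS sequences,
#'   names matching the gene IDs. Pairs must be length-matched codon
#'   alignments (true for simulator output).
#' @param summary One of `"mean"` (default) or a haplotype pair such as
#'   `"H1-H2"` to represent each triad by a designated pairing.
#' @return Tibble with one row per triad and pair, plus per-triad `ka_ks_triad`.
#' @export
triad_kaks <- function(triads, cds, summary = "mean") {
  cds <- .as_named_character(cds)
  pairs <- list(c("H1", "H2"), c("H1", "H3"), c("H2", "H3"))
  rows <- purrr::map_dfr(pairs, function(p) {
    res <- purrr::map2_dfr(
      cds[triads[[p[1]]]], cds[triads[[p[2]]]],
      compute_kaks
    )
    dplyr::bind_cols(
      tibble::tibble(
        triad_id = triads$triad_id,
        pair = paste(p, collapse = "-"),
        gene_a = triads[[p[1]]],
        gene_b = triads[[p[2]]]
      ),
      res
    )
  })
  triad_means <- rows |>
    dplyr::group_by(.data$triad_id) |>
    dplyr::summarise(
      ka_ks_triad = if (all(is.na(.data$ka_ks))) NA_real_
                    else mean(.data$ka_ks, na.rm = TRUE),
      .groups = "drop"
    )
  if (summary != "mean") {
    designated <- rows |>
      dplyr::filter(.data$pair == summary) |>
      dplyr::select("triad_id", ka_ks_triad = "ka_ks")
    triad_means <- designated
  }
  dplyr::left_join(rows, triad_means, by = "triad_id")
}

.as_named_character <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else {
    out <- x
  }
  if (is.null(names(out))) stop("CDS sequences must be named by gene ID")
  out
}

#' Compare Ka/Ks across homoeolog-expression-bias categories
#'
#' Summarises the distribution of per-triad Ka/Ks within each of the seven
#' bias groups and reports a Wilcoxon rank-sum comparison of balanced versus
#' pooled non-balanced triads as a descriptive statistic.
#'
#' @param kaks Tibble with `triad_id` and `ka_ks_triad` (one row per triad;
#'   extra rows are deduplicated).
#' @param assignments Tibble with `triad_id` and `group`, typically the
#'   combined-tissue classification from [classify_bias()].
#' @return A list with `by_group` (per-category n, mean, median, quartiles)
#'   and `balanced_vs_rest` (medians, W statistic and p-value).
#' @export
kaks_by_group <- function(kaks, assignments) {
  per_triad <- kaks |>
    dplyr::distinct(.data$triad_id, .data$ka_ks_triad) |>
    dplyr::inner_join(
      dplyr::select(assignments, "triad_id", "group"),
      by = "triad_id"
    ) |>
    dplyr::filter(!is.na(.data$ka_ks_triad))
  groups <- bias_groups()
  by_group <- per_triad |>
    dplyr::mutate(group = factor(.data$group, levels = groups)) |>
    dplyr::group_by(.data$group, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$ka_ks_triad),
      median = stats::median(.data$ka_ks_triad),
      q25 = stats::quantile(.data$ka_ks_triad, 0.25, names = FALSE),
      q75 = stats::quantile(.data$ka_ks_triad, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = as.character(.data$group))
  bal <- per_triad$ka_ks_triad[per_triad$group == "balanced"]
  non <- per_triad$ka_ks_triad[per_triad$group != "balanced"]
  test <- if (length(bal) > 0 && length(non) > 0) {
    wt <- stats::wilcox.test(non, bal, alternative = "two.sided", exact = FALSE)
    tibble::tibble(
      median_balanced = stats::median(bal),
      median_non_balanced = stats::median(non),
      W = unname(wt$statistic),
      p_value = wt$p.value
    )
  } else {
    tibble::tibble(
      median_balanced = NA_real_, median_non_balanced = NA_real_,
      W = NA_real_, p_value = NA_real_
    )
  }
  list(by_group = by_group, balanced_vs_rest = test)
}
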