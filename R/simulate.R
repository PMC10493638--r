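# Synthetic triploid-genome generator. Plants allele triads/pairs/singletons
# with controlled coding divergence, telomere tracts, a centromeric tandem
# array per chromosome, NLR loci (genic, intergenic and one clustered block),
# and tissue expression counts with controlled bias-category proportions.
# Everything downstream of the generator is recoverable from its truth table.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_triploid()] and
#' [simulate_expression()]. Defaults describe a small triploid genome whose
#' statistical structure mirrors a phased triploid crop assembly: three
#' haplotypes, per-end telomere tracts of the plant seven-mer, one
#' centromeric tandem array per chromosome, mostly-balanced triad expression
#' over four tissues, and coding divergence under purifying selection
#' (Ka/Ks < 1).
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_chromosomes Chromosomes per haplotype (default 3).
#' @param chrom_length Chromosome length in bp (default 400000).
#' @param n_triads,n_pairs,n_singletons Allele-group counts (defaults 300,
#'   30, 30).
#' @param telomere_copies Integer range of unit copies per chromosome end
#'   (default `c(100, 150)`).
#' @param centromere_unit_length Range of tandem-unit lengths in bp
#'   (default `c(120, 150)`).
#' @param centromere_array_length Range of array lengths in bp (default
#'   `c(20000, 30000)`).
#' @param nlr List: `n_genic`, `n_intergenic` loci per haplotype,
#'   `locus_length` bp, `cluster_size` loci placed as one tight intergenic
#'   cluster and `cluster_gap` bp between its members.
#' @param expression List: `tissues`, `proportions` (named over the seven
#'   bias groups, summing to 1), `concentration` (Dirichlet-style; `Inf`
#'   plants centroids exactly), `library_size` reads per sample,
#'   `noise` (`"poisson"` or `"negative_binomial"`), `overdispersion`
#'   (NB dispersion), `n_replicates` per tissue.
#' @param coding List: `length_codons` range, `target_ka` and `target_ks`
#'   ranges, and `bias_ka_multiplier` applied to the Ka target of
#'   non-balanced triads (default 1 = no effect).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length = 400000L,
                       n_triads = 300L,
                       n_pairs = 30L,
                       n_singletons = 30L,
                       telomere_copies = c(100L, 150L),
                       centromere_unit_length = c(120L, 150L),
                       centromere_array_length = c(20000L, 30000L),
                       nlr = list(),
                       expression = list(),
                       coding = list()) {
  nlr <- utils::modifyList(list(
    n_genic = 15L, n_intergenic = 25L, locus_length = 3000L,
    cluster_size = 10L, cluster_gap = 5000L
  ), nlr)
  expression <- utils::modifyList(list(
    tissues = c("root", "leaf", "flower", "fruit"),
    proportions = c(balanced = 0.52, H1D = 0.04, H2D = 0.04, H3D = 0.04,
                    H1S = 0.12, H2S = 0.12, H3S = 0.12),
    concentration = 100,
    library_size = 2e6,
    noise = "poisson",
    overdispersion = 0.1,
    n_replicates = 1L
  ), expression)
  coding <- utils::modifyList(list(
    length_codons = c(250L, 450L),
    target_ka = c(0.01, 0.05),
    target_ks = c(0.05, 0.20),
    bias_ka_multiplier = 1
  ), coding)
  p <- expression$proportions
  if (!setequal(names(p), bias_groups())) {
    stop("expression$proportions must be named by the seven bias groups")
  }
  if (abs(sum(p) - 1) > 1e-8) stop("expression$proportions must sum to 1")
  if (!expression$noise %in% c("poisson", "negative_binomial")) {
    stop("expression$noise must be poisson or negative_binomial")
  }
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_triads = as.integer(n_triads), n_pairs = as.integer(n_pairs),
    n_singletons = as.integer(n_singletons),
    telomere_copies = as.integer(telomere_copies),
    centromere_unit_length = as.integer(centromere_unit_length),
    centromere_array_length = as.integer(centromere_array_length),
    nlr = nlr, expression = expression, coding = coding
  )
  class(cfg) <- "sim_config"
  cfg
}

.haps <- c("H1", "H2", "H3")

# sample one integer uniformly from [lo, hi]; safe when lo == hi
.sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(seq(as.integer(lo), as.integer(hi)), 1)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_cds <- function(n_codons) {
  paste(sample(.sense_codons(), n_codons, replace = TRUE), collapse = "")
}

.translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))
}

#' Evolve a CDS pair toward target NG86 Ka and Ks
#'
#' Starts from a random stop-free CDS and introduces synonymous and
#' nonsynonymous single-nucleotide substitutions (each in a previously
#' untouched codon, never creating a stop) until the realized NG86 Ka and Ks
#' are within 10% of the targets. A target of 0 means no substitutions of
#' that class.
#'
#' @param length_codons CDS length in codons.
#' @param target_ka,target_ks Target rates (Jukes-Cantor scale).
#' @param seed Integer seed.
#' @param cds_a Optional starting sequence (random when `NULL`).
#' @return List with `cds_a`, `cds_b` and `realized` (the
#'   [compute_kaks()] row for the pair).
#' @export
evolve_cds_pair <- function(length_codons, target_ka, target_ks, seed = 1L,
                            cds_a = NULL) {
  set.seed(seed)
  if (is.null(cds_a)) cds_a <- .random_cds(length_codons)
  codons <- .split_codons(cds_a)
  n_codons <- length(codons)
  tb <- .ng86_tables()
  idx <- match(codons, tb$codons)
  N <- sum(tb$n_sites[idx])
  S <- sum(tb$s_sites[idx])
  p_from_k <- function(k) 3 / 4 * (1 - exp(-4 * k / 3))
  need_nd <- if (target_ka <= 0) 0L else max(1L, round(p_from_k(target_ka) * N))
  need_sd <- if (target_ks <= 0) 0L else max(1L, round(p_from_k(target_ks) * S))
  if (need_nd + need_sd > n_codons) {
    stop("targets unreachable: ", need_nd + need_sd,
         " substitutions needed but only ", n_codons, " codons available")
  }
  gc <- .genetic_code()
  bases <- c("A", "C", "G", "T")
  mutate_codon <- function(codon, type) {
    aa <- gc[[codon]]
    cand <- character()
    for (j in 1:3) {
      for (b in setdiff(bases, substr(codon, j, j))) {
        mut <- codon
        substr(mut, j, j) <- b
        aa2 <- gc[[mut]]
        if (aa2 == "*") next
        if ((type == "syn") == (aa2 == aa)) cand <- c(cand, mut)
      }
    }
    if (length(cand) == 0) return(NA_character_)
    sample(cand, 1)
  }
  codons_b <- codons
  untouched <- sample(seq_len(n_codons))  # random order, used once each
  take <- function(n, type) {
    done <- 0L
    while (done < n && length(untouched) > 0) {
      j <- untouched[1]
      untouched <<- untouched[-1]
      mut <- mutate_codon(codons_b[j], type)
      if (!is.na(mut)) {
        codons_b[j] <<- mut
        done <- done + 1L
      }
    }
    if (done < n) {
      stop("could not place ", n, " ", type, " substitutions (placed ",
           done, ")")
    }
  }
  take(need_sd, "syn")
  take(need_nd, "nonsyn")
  cds_b <- paste(codons_b, collapse = "")
  realized <- compute_kaks(cds_a, cds_b)
  check_band <- function(real, target, label) {
    if (target <= 0) {
      if (real != 0) stop("nonzero realized ", label, " for zero target")
    } else if (abs(real - target) > 0.1 * target) {
      stop("realized ", label, " = ", signif(real, 4),
           " outside 10% of target ", target)
    }
  }
  check_band(realized$Ka, target_ka, "Ka")
  check_band(realized$Ks, target_ks, "Ks")
  list(cds_a = cds_a, cds_b = cds_b, realized = realized)
}

#' Simulate a phased triploid genome with planted truth
#'
#' Generates three haploid assemblies with telomere tracts at both ends of
#' every chromosome, a centromeric tandem array per chromosome, planted
#' allele triads/pairs/singletons with controlled coding divergence, NLR
#' loci (genic, intergenic and one clustered block per haplotype), a
#' similarity hit table computed from true protein identities, and a truth
#' table recording everything that was planted.
#'
#' @param config A [sim_config()].
#' @return A list with `genomes` (named list of `DNAStringSet` per
#'   haplotype), `genes` (gene-model tibble over all haplotypes), `cds` and
#'   `proteins` (named character vectors), `hits` (hit tibble), `gene_map`
#'   (gene inventory with protein lengths) and `truth` (list of tibbles:
#'   `triads`, `pairs`, `singletons`, `telomeres`, `centromeres`,
#'   `nlr_loci`).
#' @export
simulate_triploid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes
  chroms <- sprintf("chr%02d", seq_len(n_chrom))

  # --- plant categories and coding divergence per triad -------------------
  props <- config$expression$proportions[bias_groups()]
  categories <- sample(bias_groups(), config$n_triads, replace = TRUE,
                       prob = props)
  rc <- config$coding
  triad_rows <- list()
  cds_all <- list()
  for (i in seq_len(config$n_triads)) {
    len <- .sample_range(rc$length_codons[1], rc$length_codons[2])
    mult <- if (categories[i] == "balanced") 1 else rc$bias_ka_multiplier
    ka12 <- stats::runif(1, rc$target_ka[1], rc$target_ka[2]) * mult
    ks12 <- stats::runif(1, rc$target_ks[1], rc$target_ks[2])
    ka13 <- stats::runif(1, rc$target_ka[1], rc$target_ka[2]) * mult
    ks13 <- stats::runif(1, rc$target_ks[1], rc$target_ks[2])
    seeds <- sample.int(.Machine$integer.max, 2)
    p12 <- evolve_cds_pair(len, ka12, ks12, seed = seeds[1])
    p13 <- evolve_cds_pair(len, ka13, ks13, seed = seeds[2],
                           cds_a = p12$cds_a)
    ids <- sprintf("%s_g%05d", .haps, i)
    cds_all[[ids[1]]] <- p12$cds_a
    cds_all[[ids[2]]] <- p12$cds_b
    cds_all[[ids[3]]] <- p13$cds_b
    triad_rows[[i]] <- tibble::tibble(
      triad_key = sprintf("planted_%05d", i),
      H1 = ids[1], H2 = ids[2], H3 = ids[3],
      category = categories[i],
      length_codons = len,
      ka_H1H2 = p12$realized$Ka, ks_H1H2 = p12$realized$Ks,
      ka_H1H3 = p13$realized$Ka, ks_H1H3 = p13$realized$Ks
    )
  }
  truth_triads <- dplyr::bind_rows(triad_rows)

  # --- pairs (two haplotypes, round-robin) and singletons -----------------
  hap_pairs <- list(c("H1", "H2"), c("H1", "H3"), c("H2", "H3"))
  pair_rows <- list()
  for (i in seq_len(config$n_pairs)) {
    hp <- hap_pairs[[(i - 1) %% 3 + 1]]
    len <- .sample_range(rc$length_codons[1], rc$length_codons[2])
    ka <- stats::runif(1, rc$target_ka[1], rc$target_ka[2])
    ks <- stats::runif(1, rc$target_ks[1], rc$target_ks[2])
    pp <- evolve_cds_pair(len, ka, ks,
                          seed = sample.int(.Machine$integer.max, 1))
    ids <- sprintf("%s_p%05d", hp, i)
    cds_all[[ids[1]]] <- pp$cds_a
    cds_all[[ids[2]]] <- pp$cds_b
    pair_rows[[i]] <- tibble::tibble(
      pair_key = sprintf("pair_%05d", i),
      gene_a = ids[1], gene_b = ids[2],
      hap_a = hp[1], hap_b = hp[2],
      ka = pp$realized$Ka, ks = pp$realized$Ks
    )
  }
  truth_pairs <- if (length(pair_rows) > 0) dplyr::bind_rows(pair_rows) else
    tibble::tibble(pair_key = character(), gene_a = character(),
                   gene_b = character(), hap_a = character(),
                   hap_b = character(), ka = numeric(), ks = numeric())

  singleton_rows <- list()
  for (i in seq_len(config$n_singletons)) {
    hp <- .haps[(i - 1) %% 3 + 1]
    len <- .sample_range(rc$length_codons[1], rc$length_codons[2])
    id <- sprintf("%s_s%05d", hp, i)
    cds_all[[id]] <- .random_cds(len)
    singleton_rows[[i]] <- tibble::tibble(gene_id = id, haplotype = hp)
  }
  truth_singletons <- if (length(singleton_rows) > 0)
    dplyr::bind_rows(singleton_rows) else
    tibble::tibble(gene_id = character(), haplotype = character())

  cds_all <- unlist(cds_all)
  proteins <- vapply(cds_all, .translate_cds, "")

  # --- hit table from true protein identities -----------------------------
  hits <- .simulated_hits(truth_triads, truth_pairs, proteins)

  # --- assemble chromosomes per haplotype ---------------------------------
  gene_hap <- sub("_.*$", "", names(cds_all))
  genomes <- list()
  gene_tbls <- list()
  tel_rows <- list()
  cen_rows <- list()
  nlr_rows <- list()
  for (hap in .haps) {
    gene_ids <- names(cds_all)[gene_hap == hap]
    asm <- .assemble_haplotype(hap, gene_ids, cds_all, chroms, config)
    genomes[[hap]] <- asm$genome
    gene_tbls[[hap]] <- asm$genes
    tel_rows[[hap]] <- asm$telomeres
    cen_rows[[hap]] <- asm$centromeres
    nlr_rows[[hap]] <- asm$nlr
  }
  genes <- dplyr::bind_rows(gene_tbls)

  gene_map <- tibble::tibble(
    gene_id = names(proteins),
    haplotype = gene_hap,
    length = nchar(proteins)
  )

  list(
    config = config,
    genomes = genomes,
    genes = genes,
    cds = cds_all,
    proteins = proteins,
    hits = hits,
    gene_map = gene_map,
    truth = list(
      triads = truth_triads,
      pairs = truth_pairs,
      singletons = truth_singletons,
      telomeres = dplyr::bind_rows(tel_rows),
      centromeres = dplyr::bind_rows(cen_rows),
      nlr_loci = dplyr::bind_rows(nlr_rows)
    )
  )
}

.protein_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("protein length mismatch")
  100 * mean(ca == cb)
}

.hit_row <- function(q, s, proteins) {
  pid <- .protein_identity(proteins[[q]], proteins[[s]])
  len <- nchar(proteins[[q]])
  tibble::tibble(
    query_id = q, subject_id = s, percent_identity = pid,
    alignment_length = len,
    mismatches = as.integer(round(len * (1 - pid / 100))),
    gap_openings = 0L,
    query_start = 1L, query_end = len, subject_start = 1L, subject_end = len,
    e_value = 0, bit_score = round(2 * len * pid / 100, 1)
  )
}

.simulated_hits <- function(truth_triads, truth_pairs, proteins) {
  out <- list()
  add_pair <- function(a, b) {
    out[[length(out) + 1L]] <<- .hit_row(a, b, proteins)
    out[[length(out) + 1L]] <<- .hit_row(b, a, proteins)
  }
  for (i in seq_len(nrow(truth_triads))) {
    tr <- truth_triads[i, ]
    add_pair(tr$H1, tr$H2)
    add_pair(tr$H1, tr$H3)
    add_pair(tr$H2, tr$H3)
  }
  for (i in seq_len(nrow(truth_pairs))) {
    add_pair(truth_pairs$gene_a[i], truth_pairs$gene_b[i])
  }
  if (length(out) == 0) {
    return(tibble::as_tibble(stats::setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), .hit_cols
    )))
  }
  dplyr::bind_rows(out)
}

# Lay one haplotype out over its chromosomes: telomeres at the exact ends,
# a centromeric array mid-chromosome, genes round-robin, NLR loci as parts
# (intergenic) or sub-intervals of genes (genic), plus one clustered block
# on the first chromosome. Errors when the parts exceed the chromosome.
.assemble_haplotype <- function(hap, gene_ids, cds_all, chroms, config) {
  n_chrom <- length(chroms)
  gene_chrom <- rep(seq_len(n_chrom), length.out = length(gene_ids))
  nlr_cfg <- config$nlr
  n_genic <- nlr_cfg$n_genic
  n_inter <- nlr_cfg$n_intergenic
  genic_targets <- if (n_genic > 0 && length(gene_ids) > 0) {
    sample(gene_ids, min(n_genic, length(gene_ids)))
  } else character()
  inter_chrom <- if (n_inter > 0) {
    rep(seq_len(n_chrom), length.out = n_inter)
  } else integer()

  genome_seqs <- character(n_chrom)
  gene_rows <- list()
  tel_rows <- list()
  cen_rows <- list()
  nlr_parts_rows <- list()

  for (ci in seq_len(n_chrom)) {
    parts <- list()
    add <- function(type, seq, meta = list()) {
      parts[[length(parts) + 1L]] <<- c(list(type = type, seq = seq), meta)
    }
    tel5 <- .sample_range(config$telomere_copies[1], config$telomere_copies[2])
    tel3 <- .sample_range(config$telomere_copies[1], config$telomere_copies[2])
    add("tel5", strrep(TELOMERE_UNIT_5P, tel5), list(copies = tel5))

    cg <- gene_ids[gene_chrom == ci]
    half <- ceiling(length(cg) / 2)
    for (g in cg[seq_len(half)]) add("gene", cds_all[[g]], list(gene_id = g))

    unit_len <- .sample_range(config$centromere_unit_length[1],
                              config$centromere_unit_length[2])
    arr_len <- .sample_range(config$centromere_array_length[1],
                             config$centromere_array_length[2])
    unit <- .random_dna(unit_len)
    n_copies <- ceiling(arr_len / unit_len)
    add("centromere", substr(strrep(unit, n_copies), 1, arr_len),
        list(unit = unit, unit_length = unit_len))

    if (length(cg) > half) {
      for (g in cg[(half + 1):length(cg)]) {
        add("gene", cds_all[[g]], list(gene_id = g))
      }
    }

    # intergenic NLR loci for this chromosome
    n_i <- sum(inter_chrom == ci)
    for (k in seq_len(n_i)) {
      add("nlr", .random_dna(nlr_cfg$locus_length))
    }
    # clustered block on chromosome 1
    if (ci == 1 && nlr_cfg$cluster_size > 0) {
      blk <- character(0)
      offs <- integer(0)
      pos <- 0L
      for (k in seq_len(nlr_cfg$cluster_size)) {
        offs <- c(offs, pos)
        blk <- c(blk, .random_dna(nlr_cfg$locus_length))
        pos <- pos + nlr_cfg$locus_length
        if (k < nlr_cfg$cluster_size) {
          gap <- nlr_cfg$cluster_gap
          blk <- c(blk, .random_dna(gap))
          pos <- pos + gap
        }
      }
      add("nlr_cluster", paste(blk, collapse = ""), list(offsets = offs))
    }

    add("tel3", strrep(TELOMERE_UNIT_3P, tel3), list(copies = tel3))

    part_len <- vapply(parts, function(p) nchar(p$seq), numeric(1))
    n_gaps <- length(parts) - 1L
    leftover <- config$chrom_length - sum(part_len)
    if (leftover < n_gaps) {
      stop("infeasible packing on ", hap, " ", chroms[ci], ": parts need ",
           sum(part_len) + n_gaps, " bp but chrom_length is ",
           config$chrom_length)
    }
    gaps <- rep(leftover %/% n_gaps, n_gaps)
    extra <- leftover - sum(gaps)
    if (extra > 0) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L

    pos <- 1L
    seq_parts <- character(0)
    for (pi in seq_along(parts)) {
      p <- parts[[pi]]
      plen <- nchar(p$seq)
      start <- pos
      end <- pos + plen - 1L
      seq_parts <- c(seq_parts, p$seq)
      pos <- end + 1L
      if (p$type == "gene") {
        gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
          gene_id = p$gene_id, haplotype = hap, chrom = chroms[ci],
          strand = "+", start = start, end = end,
          transcript_id = paste0(p$gene_id, ".t1"),
          protein_id = paste0(p$gene_id, ".t1"),
          cds_length = plen,
          cds = list(tibble::tibble(start = start, end = end))
        )
        if (p$gene_id %in% genic_targets) {
          locus_len <- min(nlr_cfg$locus_length, plen)
          nlr_parts_rows[[length(nlr_parts_rows) + 1L]] <- tibble::tibble(
            haplotype = hap, chrom = chroms[ci],
            start = start, end = start + locus_len - 1L,
            planted_status = "genic", in_cluster = FALSE
          )
        }
      } else if (p$type == "tel5" || p$type == "tel3") {
        tel_rows[[length(tel_rows) + 1L]] <- tibble::tibble(
          haplotype = hap, chrom = chroms[ci],
          which_end = if (p$type == "tel5") "5prime" else "3prime",
          copies = p$copies, start_bp = start, stop_bp = end,
          length_bp = plen
        )
      } else if (p$type == "centromere") {
        cen_rows[[length(cen_rows) + 1L]] <- tibble::tibble(
          haplotype = hap, chrom = chroms[ci], start = start, end = end,
          unit_length = p$unit_length, unit = p$unit, length_bp = plen
        )
      } else if (p$type == "nlr") {
        nlr_parts_rows[[length(nlr_parts_rows) + 1L]] <- tibble::tibble(
          haplotype = hap, chrom = chroms[ci], start = start, end = end,
          planted_status = "intergenic", in_cluster = FALSE
        )
      } else if (p$type == "nlr_cluster") {
        for (off in p$offsets) {
          s0 <- start + off
          nlr_parts_rows[[length(nlr_parts_rows) + 1L]] <- tibble::tibble(
            haplotype = hap, chrom = chroms[ci],
            start = s0, end = s0 + nlr_cfg$locus_length - 1L,
            planted_status = "intergenic", in_cluster = TRUE
          )
        }
      }
      if (pi <= n_gaps) {
        seq_parts <- c(seq_parts, .random_dna(gaps[pi]))
        pos <- pos + gaps[pi]
      }
    }
    genome_seqs[ci] <- paste(seq_parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(genome_seqs)
  names(genome) <- chroms
  attr(genome, "haplotype") <- hap
  list(
    genome = genome,
    genes = dplyr::bind_rows(gene_rows),
    telomeres = dplyr::bind_rows(tel_rows),
    centromeres = dplyr::bind_rows(cen_rows),
    nlr = if (length(nlr_parts_rows) > 0) dplyr::bind_rows(nlr_parts_rows)
          else tibble::tibble()
  )
}

#' Plant triad categories without simulating sequences
#'
#' Generates only the expression-side ground truth - triad gene IDs, planted
#' bias categories and gene lengths - so classifier-recovery experiments can
#' run at large triad counts without evolving coding sequences or assembling
#' chromosomes. The result feeds [simulate_expression()] directly.
#'
#' @param config A [sim_config()].
#' @return A list shaped like a [simulate_triploid()] result but with `cds`
#'   holding gene lengths (bp) instead of sequences.
#' @export
simulate_triad_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  props <- config$expression$proportions[bias_groups()]
  categories <- sample(bias_groups(), config$n_triads, replace = TRUE,
                       prob = props)
  rc <- config$coding
  lens <- 3L * sample(seq(rc$length_codons[1], rc$length_codons[2]),
                      config$n_triads, replace = TRUE)
  triads <- tibble::tibble(
    triad_key = sprintf("planted_%05d", seq_len(config$n_triads)),
    H1 = sprintf("H1_g%05d", seq_len(config$n_triads)),
    H2 = sprintf("H2_g%05d", seq_len(config$n_triads)),
    H3 = sprintf("H3_g%05d", seq_len(config$n_triads)),
    category = categories,
    length_codons = lens %/% 3L
  )
  gene_len <- stats::setNames(
    rep(lens, 3L),
    c(triads$H1, triads$H2, triads$H3)
  )
  list(config = config, truth = list(triads = triads), cds = gene_len)
}

#' Simulate tissue expression counts for a planted truth table
#'
#' Per triad and tissue, a relative-expression vector is drawn from a
#' Dirichlet distribution centred on the planted category's centroid with
#' the configured concentration (`Inf` plants centroids exactly), a triad
#' total abundance is drawn log-normally, expected counts follow from gene
#' length and library size, and Poisson (or negative-binomial) noise is
#' applied. Non-triad genes receive independent log-normal abundance.
#'
#' @param sim Output of [simulate_triploid()] (uses `truth`, `cds`,
#'   `config`).
#' @param config Optional [sim_config()] overriding `sim$config`.
#' @return A counts tibble (`gene_id`, `length`, one column per sample;
#'   sample names are `<tissue>` or `<tissue>_<rep>`).
#' @export
simulate_expression <- function(sim, config = NULL) {
  config <- config %||% sim$config
  ex <- config$expression
  if (ex$library_size <= 0) stop("library size must be positive")
  set.seed(config$seed + 104729L)  # fixed offset stream for expression
  truth <- sim$truth
  gene_len <- if (is.character(sim$cds)) nchar(sim$cds) else sim$cds
  names(gene_len) <- names(sim$cds)
  gene_ids <- names(sim$cds)
  cen <- bias_centroids()
  eps <- 0.3  # Dirichlet floor so vertex centroids stay proper

  n_triads <- nrow(truth$triads)
  other_genes <- setdiff(gene_ids,
                         c(truth$triads$H1, truth$triads$H2, truth$triads$H3))
  samples <- unlist(lapply(ex$tissues, function(tis) {
    if (ex$n_replicates == 1) tis else paste0(tis, "_", seq_len(ex$n_replicates))
  }))
  sample_tissue <- rep(ex$tissues, each = ex$n_replicates)

  counts <- tibble::tibble(gene_id = gene_ids,
                           length = as.integer(gene_len[gene_ids]))
  abund_other <- stats::rlnorm(length(other_genes), log(8), 1)
  abund_triad <- stats::rlnorm(n_triads, log(20), 1)

  for (si in seq_along(samples)) {
    x <- stats::setNames(numeric(length(gene_ids)), gene_ids)
    if (n_triads > 0) {
      rel <- matrix(0, n_triads, 3)
      for (i in seq_len(n_triads)) {
        centroid <- cen[truth$triads$category[i], ]
        if (is.infinite(ex$concentration)) {
          rel[i, ] <- centroid
        } else {
          alpha <- ex$concentration * centroid + eps
          g <- stats::rgamma(3, shape = alpha)
          rel[i, ] <- g / sum(g)
        }
      }
      x[truth$triads$H1] <- abund_triad * rel[, 1]
      x[truth$triads$H2] <- abund_triad * rel[, 2]
      x[truth$triads$H3] <- abund_triad * rel[, 3]
    }
    x[other_genes] <- abund_other
    expected <- ex$library_size * (x * gene_len[gene_ids]) /
      sum(x * gene_len[gene_ids])
    obs <- if (ex$noise == "poisson") {
      stats::rpois(length(expected), expected)
    } else {
      stats::rnbinom(length(expected), mu = expected,
                     size = 1 / ex$overdispersion)
    }
    counts[[samples[si]]] <- as.integer(obs)
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write all simulator artifacts to a directory
#'
#' Writes per-haplotype genome, CDS and protein FASTAs, GFF3 gene models,
#' the hit table, the NLR locus BED files, the counts table, the truth
#' tables (TSV) and a JSON run manifest recording seed and package version.
#'
#' @param sim Output of [simulate_triploid()].
#' @param dir Output directory (created if missing).
#' @param counts Optional counts tibble from [simulate_expression()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, counts = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (hap in names(sim$genomes)) {
    write_fasta(sim$genomes[[hap]], file.path(dir, paste0(hap, ".genome.fa")))
    sel <- sim$gene_map$gene_id[sim$gene_map$haplotype == hap]
    write_fasta(sim$cds[sel], file.path(dir, paste0(hap, ".cds.fa")))
    write_fasta(sim$proteins[sel], file.path(dir, paste0(hap, ".prot.fa")))
    write_gff3(dplyr::filter(sim$genes, .data$haplotype == hap),
               file.path(dir, paste0(hap, ".gff3")))
    nlr <- dplyr::filter(sim$truth$nlr_loci, .data$haplotype == hap)
    if (nrow(nlr) > 0) {
      write_bed(
        tibble::tibble(chrom = nlr$chrom, start = nlr$start, end = nlr$end,
                       name = sprintf("%s_nlr%03d", hap, seq_len(nrow(nlr)))),
        file.path(dir, paste0(hap, ".nlr.bed"))
      )
    }
  }
  write_hits(sim$hits, file.path(dir, "hits.tsv"))
  readr::write_tsv(sim$truth$triads |> dplyr::select(-dplyr::any_of("cds")),
                   file.path(dir, "truth_triads.tsv"))
  readr::write_tsv(sim$truth$telomeres, file.path(dir, "truth_telomeres.tsv"))
  readr::write_tsv(sim$truth$centromeres,
                   file.path(dir, "truth_centromeres.tsv"))
  if (!is.null(counts)) write_counts(counts, file.path(dir, "counts.tsv"))
  manifest <- list(
    tool = "triadbias",
    version = as.character(utils::packageVersion("triadbias")),
    seed = sim$config$seed,
    n_triads = sim$config$n_triads,
    n_pairs = sim$config$n_pairs,
    n_singletons = sim$config$n_singletons,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
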