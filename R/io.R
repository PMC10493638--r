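# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinate convention: 1-based closed intervals everywhere
# (GFF3 style); BED is converted at the boundary. Strand is carried but
# never used to flip coordinates.

#' Read a genome FASTA into a DNAStringSet
#'
#' Sequence IDs are the header token before the first whitespace; lowercase
#' bases are folded to uppercase. Only A, C, G, T and N are accepted.
#'
#' @param path Path to a FASTA file.
#' @param haplotype Optional haplotype label stored as an attribute.
#' @return A [Biostrings::DNAStringSet] with unique names and, when given,
#'   a `haplotype` attribute.
#' @export
read_fasta <- function(path, haplotype = NULL) {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  chars <- toupper(as.character(raw))
  if (any(nchar(chars) == 0)) {
    stop("empty sequence(s) in ", path, ": ",
         paste(ids[nchar(chars) == 0], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("sequence alphabet outside {A,C,G,T,N} in ", path, ": ",
         paste(ids[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- ids
  if (!is.null(haplotype)) attr(out, "haplotype") <- haplotype
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A named `DNAStringSet`, `AAStringSet` or named character
#'   vector.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene, mRNA and CDS features and returns one row per gene with the
#' CDS of its primary transcript (the transcript with the largest total CDS
#' length; ties broken by lexicographically smaller transcript ID). Intervals
#' are kept 1-based closed as written; minus-strand genes are not flipped.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `transcript_id`, `protein_id`, `cds_length` and a list-column
#'   `cds` of tibbles (`start`, `end`) sorted by start.
#' @export
read_gff3 <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    stop("GFF3 line ", lineno[which(nf != 9)[1]], " has ",
         nf[nf != 9][1], " columns (expected 9)")
  }
  m <- do.call(rbind, fields)
  feat <- tibble::tibble(
    line = lineno,
    chrom = m[, 1], type = m[, 3],
    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
    strand = m[, 7], attr = m[, 9]
  )
  get_attr <- function(attr, key) {
    val <- stringr::str_match(attr, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    val
  }
  genes <- feat |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::mutate(gene_id = get_attr(.data$attr, "ID"))
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute")
  mrna <- feat |>
    dplyr::filter(.data$type %in% c("mRNA", "transcript")) |>
    dplyr::mutate(
      transcript_id = get_attr(.data$attr, "ID"),
      gene_parent = get_attr(.data$attr, "Parent"),
      protein_id = get_attr(.data$attr, "protein_id")
    )
  cds <- feat |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::mutate(cds_parent = get_attr(.data$attr, "Parent"))
  unresolved <- !cds$cds_parent %in% mrna$transcript_id
  if (any(unresolved)) {
    stop("CDS without resolvable gene parent at line(s): ",
         paste(cds$line[unresolved], collapse = ", "))
  }
  cds <- dplyr::left_join(
    cds,
    dplyr::select(mrna, "transcript_id", "gene_parent", "protein_id"),
    by = c(cds_parent = "transcript_id")
  )
  orphan <- !cds$gene_parent %in% genes$gene_id
  if (any(orphan)) {
    stop("CDS whose transcript has no gene parent at line(s): ",
         paste(cds$line[orphan], collapse = ", "))
  }
  # primary transcript per gene: longest CDS sum, ties by transcript ID
  per_tx <- cds |>
    dplyr::group_by(gene_id = .data$gene_parent,
                    transcript_id = .data$cds_parent,
                    protein_id = .data$protein_id) |>
    dplyr::summarise(
      cds_length = sum(.data$end - .data$start + 1L),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$cds_length),
                   .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  cds_primary <- cds |>
    dplyr::semi_join(per_tx, by = c(cds_parent = "transcript_id")) |>
    dplyr::arrange(.data$cds_parent, .data$start)
  cds_split <- split(cds_primary[, c("start", "end")], cds_primary$gene_parent)
  cds_tbl <- tibble::tibble(
    gene_id = names(cds_split),
    cds = lapply(cds_split, tibble::as_tibble)
  )
  out <- genes |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end") |>
    dplyr::left_join(
      dplyr::select(per_tx, "gene_id", "transcript_id", "protein_id",
                    "cds_length"),
      by = "gene_id"
    ) |>
    dplyr::left_join(cds_tbl, by = "gene_id") |>
    dplyr::mutate(
      protein_id = dplyr::coalesce(.data$protein_id, .data$transcript_id)
    )
  # validate CDS within gene span, non-overlapping
  for (i in seq_len(nrow(out))) {
    seg <- out$cds[[i]]
    if (is.null(seg)) next
    if (any(seg$start < out$start[i] | seg$end > out$end[i])) {
      stop("CDS outside gene span for gene ", out$gene_id[i])
    }
    if (any(seg$start > seg$end)) {
      stop("CDS with start > end for gene ", out$gene_id[i])
    }
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop("overlapping CDS segments for gene ", out$gene_id[i])
    }
  }
  tibble::as_tibble(out)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features for gene-model tibbles shaped like the
#' output of [read_gff3()].
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, optionally `transcript_id`, `protein_id`, list-column `cds`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- if (!is.null(g[["transcript_id"]]) && !is.na(g$transcript_id)) {
      g$transcript_id
    } else {
      paste0(g$gene_id, ".t1")
    }
    lines <- c(
      lines,
      paste(g$chrom, "triadbias", "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "triadbias", "mRNA", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", tx, ";Parent=", g$gene_id), sep = "\t")
    )
    seg <- g$cds[[1]]
    if (is.null(seg)) seg <- tibble::tibble(start = g$start, end = g$end)
    for (j in seq_len(nrow(seg))) {
      lines <- c(
        lines,
        paste(g$chrom, "triadbias", "CDS", seg$start[j], seg$end[j], ".",
              g$strand, "0", paste0("ID=", tx, ".cds;Parent=", tx), sep = "\t")
      )
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

.hit_cols <- c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatches", "gap_openings",
               "query_start", "query_end", "subject_start", "subject_end",
               "e_value", "bit_score")

#' Read a 12-column tabular similarity-hit table
#'
#' The dialect is the classic 12-column tab-separated protein-search output
#' (query, subject, percent identity, alignment length, mismatches, gap
#' openings, query/subject start/end, e-value, bit score). No filtering is
#' applied at read time.
#'
#' @param path Path to the hits file.
#' @return A tibble with one row per hit.
#' @export
read_hits <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::as_tibble(stats::setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), .hit_cols
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    i <- which(nf != 12)[1]
    stop("hit table line ", i, " has ", nf[i], " columns (expected 12)")
  }
  m <- do.call(rbind, fields)
  out <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_openings = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12])
  )
  if (any(out$percent_identity < 0 | out$percent_identity > 100)) {
    stop("percent identity outside [0,100] in ", path)
  }
  if (any(out$alignment_length < 1)) {
    stop("alignment length < 1 in ", path)
  }
  out
}

#' Write a hits tibble as 12-column tab-separated text
#' @param hits Tibble as returned by [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits[, .hit_cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a BED3+ file into 1-based closed intervals
#'
#' BED half-open 0-based intervals are converted at the boundary to the
#' package-wide 1-based closed convention (start + 1; end unchanged). Columns
#' beyond the fourth (e.g. the BED6 strand) are ignored with a message.
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` (1-based closed) and `name`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(lines) > 0 && any(nf < 3)) {
    stop("BED line ", which(nf < 3)[1], " has fewer than 3 columns")
  }
  if (any(nf > 4)) {
    message("BED columns beyond name (e.g. score/strand) ignored")
  }
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start0 <- as.integer(vapply(fields, `[`, "", 2))
  end0 <- as.integer(vapply(fields, `[`, "", 3))
  if (any(start0 >= end0)) {
    i <- which(start0 >= end0)[1]
    stop("BED line ", i, ": start (", start0[i], ") >= end (", end0[i], ")")
  }
  name <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 4) fields[[i]][4] else paste0(chrom[i], ":", start0[i] + 1L,
                                               "-", end0[i])
  }, "")
  tibble::tibble(chrom = chrom, start = start0 + 1L, end = end0, name = name)
}

#' Write 1-based closed intervals as BED
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based closed) and
#'   optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- tibble::tibble(
    chrom = intervals$chrom,
    start = intervals$start - 1L,
    end = intervals$end
  )
  if (!is.null(intervals[["name"]])) out$name <- intervals$name
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a counts table (gene_id, length, one column per sample)
#'
#' @param path Path to a tab-separated counts file with header
#'   `gene_id`, `length`, then sample labels.
#' @return A tibble; sample columns are integer counts.
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!identical(names(out)[1:2], c("gene_id", "length"))) {
    stop("counts table must start with columns gene_id, length")
  }
  if (anyDuplicated(out$gene_id)) stop("duplicate gene_ids in counts table")
  if (any(out$length <= 0)) stop("non-positive gene length in counts table")
  samp <- names(out)[-(1:2)]
  if (any(vapply(out[samp], function(x) any(x < 0), TRUE))) {
    stop("negative counts in counts table")
  }
  out
}

#' Write a counts table
#' @param counts Tibble as returned by [read_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
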