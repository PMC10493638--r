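# Independent brute-force NG86 oracle, kept deliberately separate from the
# package implementation: translation goes through seqinr, path orderings
# are enumerated from an explicit permutation matrix, and nothing is
# vectorised or table-driven.

.oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_sites <- function(codon) {
  aa <- .oracle_translate(codon)
  syn <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      aa2 <- .oracle_translate(mut)
      if (aa2 != "*" && identical(aa2, aa)) syn <- syn + 1 / 3
    }
  }
  c(n = 3 - syn, s = syn)
}

# explicit permutation matrices for 1, 2 and 3 differing positions
.oracle_perms <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

oracle_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(nd = 0, sd = 0))
  perms <- .oracle_perms[[k]]
  totals <- NULL
  for (r in seq_len(nrow(perms))) {
    cur <- a
    nd <- 0; sd <- 0; blocked <- FALSE
    for (step in perms[r, ]) {
      p <- pos[step]
      nxt <- paste0(substr(cur, 1, p - 1), substr(b, p, p),
                    substr(cur, p + 1, 3))
      if (.oracle_translate(nxt) == "*") { blocked <- TRUE; break }
      if (.oracle_translate(nxt) == .oracle_translate(cur)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    if (!blocked) totals <- rbind(totals, c(nd, sd))
  }
  if (is.null(totals)) return(c(nd = k, sd = 0))
  c(nd = mean(totals[, 1]), sd = mean(totals[, 2]))
}

.oracle_cache <- new.env(parent = emptyenv())

oracle_diffs_cached <- function(a, b) {
  key <- paste0(a, b)
  got <- .oracle_cache[[key]]
  if (is.null(got)) {
    got <- oracle_diffs(a, b)
    .oracle_cache[[key]] <- got
  }
  got
}

oracle_kaks <- function(seq_a, seq_b) {
  n_cod <- nchar(seq_a) %/% 3
  codons_a <- substring(seq_a, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  codons_b <- substring(seq_b, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  N <- 0; S <- 0; Nd <- 0; Sd <- 0
  for (i in seq_len(n_cod)) {
    sa <- oracle_sites(codons_a[i])
    sb <- oracle_sites(codons_b[i])
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    d <- oracle_diffs_cached(codons_a[i], codons_b[i])
    Nd <- Nd + d[["nd"]]
    Sd <- Sd + d[["sd"]]
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd,
       Ka = -3 / 4 * log(1 - 4 / 3 * Nd / N),
       Ks = -3 / 4 * log(1 - 4 / 3 * Sd / S))
}

# sense codons for random test sequences
sense_codons_list <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_cds_pair <- function(n_codons, n_sub, seed) {
  set.seed(seed)
  codons <- sense_codons_list()
  a <- sample(codons, n_codons, replace = TRUE)
  b <- a
  sites <- sample(seq_len(n_codons), min(n_sub, n_codons))
  for (i in sites) {
    repeat {
      cand <- sample(codons, 1)
      if (cand != b[i]) { b[i] <- cand; break }
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
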