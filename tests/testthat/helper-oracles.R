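# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

GLIADIN_AA_POOL <- c(rep("Q", 30), rep("P", 20), rep("F", 8), rep("L", 8),
                     rep("Y", 5), rep("S", 6), rep("V", 5), rep("I", 4),
                     rep("A", 4), rep("G", 3), rep("T", 3), rep("N", 2),
                     "E", "R", "H", "K", "C", "W", "M", "D")

random_protein <- function(n, pool = GLIADIN_AA_POOL) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

random_cds_stop_free <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# all-window exact-match scan: every (sequence, start) occurrence
oracle_scan <- function(protein, patterns) {
  n <- nchar(protein)
  hits <- list()
  for (s in unique(patterns)) {
    L <- nchar(s)
    if (L > n) next
    for (i in seq_len(n - L + 1)) {
      if (substr(protein, i, i + L - 1) == s) {
        hits[[length(hits) + 1]] <- data.frame(sequence = s, start = i)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(sequence = character(), start = integer()) else
    out[order(out$sequence, out$start), ]
}

# every window at Hamming distance exactly one from the pattern
oracle_near_miss <- function(protein, pattern) {
  n <- nchar(protein)
  L <- nchar(pattern)
  out <- list()
  if (n < L) return(data.frame(start = integer()))
  for (i in seq_len(n - L + 1)) {
    w <- substr(protein, i, i + L - 1)
    d <- sum(strsplit(w, "")[[1]] != strsplit(pattern, "")[[1]])
    if (d == 1) out[[length(out) + 1]] <- data.frame(start = i)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer()) else out
}

# exhaustive cleavage-site enumeration digest: all peptides between any two
# boundaries enclosing at most max_missed internal cleavage sites
oracle_digest <- function(protein, max_missed = 2, min_len = 5,
                          residues = c("F", "Y", "W", "L", "M")) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  sites <- integer()
  for (i in seq_len(n - 1)) {
    if (chars[i] %in% residues && chars[i + 1] != "P") sites <- c(sites, i)
  }
  bounds <- c(0, sites, n)
  peps <- character()
  for (a in seq_along(bounds)) {
    for (b in seq_along(bounds)) {
      if (b <= a) next
      internal <- sum(bounds > bounds[a] & bounds < bounds[b] &
                        bounds %in% sites)
      if (internal > max_missed) next
      s <- bounds[a] + 1
      e <- bounds[b]
      if (e - s + 1 < min_len) next
      peps <- c(peps, paste(chars[s:e], collapse = ""))
    }
  }
  sort(peps)
}

# independently transcribed average residue masses for the summation oracle
ORACLE_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

oracle_mass <- function(protein) {
  counts <- table(strsplit(protein, "")[[1]])
  sum(ORACLE_AVG_MASS[names(counts)] * as.numeric(counts)) + 18.0153
}

# 0.001-step grid search for the pH of zero net charge
oracle_pi_grid <- function(protein, pka_set = "bjellqvist") {
  grid <- seq(0, 14, by = 0.001)
  ch <- net_charge(protein, grid, pka_set)
  grid[which.min(abs(ch))]
}

# family-derived helpers -----------------------------------------------------

family_proteins <- function(fam, active_only = TRUE) {
  ids <- names(fam$truth)
  if (active_only) {
    ids <- ids[vapply(fam$truth, function(t) t$status == "full_orf",
                      logical(1))]
  }
  stats::setNames(
    vapply(ids, function(i) {
      suppressWarnings(
        translate_cds(fam$records$sequence[fam$records$id == i]))
    }, character(1)), ids)
}

family_panels <- function(fam) {
  clean <- vapply(fam$truth, function(t) t$status == "full_orf", logical(1))
  types <- vapply(fam$truth, function(t) t$type, character(1))
  lapply(stats::setNames(nm = names(fam$truth)), function(id) {
    ids <- setdiff(names(fam$truth)[clean & types == types[[id]]], id)
    stats::setNames(fam$records$sequence[match(ids, fam$records$id)], ids)
  })
}

# the genes a spot is finally attributed to: its unique gene, or the whole
# ambiguity group when no unique peptide resolves it
assigned_genes <- function(asg) {
  if (isTRUE(asg$unique)) asg$assigned_gene else asg$matched_genes
}

# end-to-end recovery measurement used by tests and the acceptance script
measure_family_recovery <- function(fam) {
  panels <- family_panels(fam)
  n_status <- 0; ok_status <- 0
  n_origin <- 0; ok_origin <- 0
  n_bound <- 0; ok_bound <- 0
  tract_exact <- TRUE
  for (id in names(fam$truth)) {
    t <- fam$truth[[id]]
    nt <- fam$records$sequence[fam$records$id == id]
    res <- classify_orf(nt, panels[[id]])
    n_status <- n_status + 1
    if (res$status == t$status) ok_status <- ok_status + 1
    if (t$status == "pseudo_stop") {
      for (k in seq_len(nrow(t$stop_events))) {
        n_origin <- n_origin + 1
        m <- res$stop_events[res$stop_events$codon_index ==
                               t$stop_events$codon_index[k], ]
        if (nrow(m) == 1 && m$origin == t$stop_events$origin[k]) {
          ok_origin <- ok_origin + 1
        }
      }
    }
    if (t$status == "full_orf") {
      p <- suppressWarnings(translate_cds(nt))
      ann <- segment_domains(p, t$type, gene_id = id)
      for (k in seq_len(nrow(t$boundaries))) {
        d <- ann$domains[ann$domains$label == t$boundaries$label[k], ]
        n_bound <- n_bound + 1
        if (abs(d$start - t$boundaries$start[k]) <= 2 &&
            abs(d$end - t$boundaries$end[k]) <= 2) ok_bound <- ok_bound + 1
        if (t$boundaries$label[k] %in% c("QI", "QII", "IV") &&
            !(d$start == t$boundaries$start[k] &&
              d$end == t$boundaries$end[k])) tract_exact <- FALSE
      }
    }
  }
  list(status = c(ok_status, n_status), origin = c(ok_origin, n_origin),
       boundary = c(ok_bound, n_bound), tract_exact = tract_exact)
}
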