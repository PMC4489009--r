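# Celiac-disease epitope scanning, cysteine skeleton profiling, repeat-unit
# counting, Q:P:F composition, omega-gliadin typing and alpha-gliadin group
# classification. Epitope matching is exact (100% identity); epitopes that
# share one amino-acid sequence under different deamidation contexts are
# reported as a single hit carrying all names.

#' Load the celiac epitope / immunoreactive peptide library
#'
#' The library ships as a TSV fixture with columns `name`, `sequence`,
#' `class` (alpha/gamma/omega) and `note`. Both reported omega
#' hexapeptides (QQPPQQ and QQFPQQ) are retained.
#'
#' @param path Optional path to an alternative library TSV.
#' @return Tibble with the library plus a `length` column.
#' @export
epitope_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "epitope_library.tsv", package = "gliadinR")
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", fileEncoding = "UTF-8")
  stopifnot(all(c("name", "sequence", "class") %in% names(tab)))
  out <- tibble::as_tibble(tab)
  out$length <- nchar(out$sequence)
  out
}

#' Scan a protein for exact epitope occurrences
#'
#' All occurrences are reported, overlapping matches included. Library
#' entries sharing an identical sequence collapse to one hit whose `names`
#' field lists every name (semicolon-separated).
#'
#' @param protein Amino-acid string.
#' @param library Epitope library tibble ([epitope_library()]); may be
#'   pre-filtered by class.
#' @param annotation Optional `protein_annotation`; when present each hit
#'   is labelled with the domain containing its start residue.
#' @return Tibble with `sequence`, `names`, `start`, `domain_label`.
#' @export
scan_epitopes <- function(protein, library = epitope_library(),
                          annotation = NULL) {
  if (nrow(library) == 0) stop("empty epitope library")
  protein <- toupper(trimws(protein))
  seqs <- unique(library$sequence)
  rows <- lapply(seqs, function(s) {
    st <- match_starts(protein, s)
    if (length(st) == 0) return(NULL)
    nm <- paste(library$name[library$sequence == s], collapse = ";")
    tibble::tibble(sequence = s, names = nm, start = st)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(sequence = character(), names = character(),
                          start = integer(), domain_label = character()))
  }
  out <- out[order(out$start, out$sequence), ]
  out$domain_label <- if (is.null(annotation)) NA_character_ else {
    vapply(out$start, function(p) domain_of_position(annotation, p),
           character(1))
  }
  out
}

#' Report near-miss epitope windows (Hamming distance exactly 1)
#'
#' Finds every window of the protein that differs from the epitope at
#' exactly one position; exact matches are excluded. Used to document
#' single-substitution epitope disruptions (e.g. a serine replacing the
#' eighth proline of an epitope).
#'
#' @param protein Amino-acid string.
#' @param epitope Epitope sequence (length >= 4).
#' @return Tibble with `start`, `position_in_epitope`, `observed_residue`,
#'   `expected_residue`.
#' @export
near_miss_report <- function(protein, epitope) {
  protein <- toupper(trimws(protein))
  epitope <- toupper(trimws(epitope))
  L <- nchar(epitope)
  if (L < 4) stop("epitope shorter than 4 residues")
  n <- nchar(protein)
  if (n < L) {
    return(tibble::tibble(start = integer(), position_in_epitope = integer(),
                          observed_residue = character(),
                          expected_residue = character()))
  }
  echars <- strsplit(epitope, "")[[1]]
  pchars <- strsplit(protein, "")[[1]]
  starts <- seq_len(n - L + 1L)
  # windows as an (n - L + 1) x L character matrix
  win <- vapply(seq_len(L), function(j) pchars[starts + j - 1L],
                character(length(starts)))
  if (length(starts) == 1L) win <- matrix(win, nrow = 1)
  mism <- win != matrix(echars, nrow = length(starts), ncol = L, byrow = TRUE)
  nm <- rowSums(mism)
  keep <- which(nm == 1L)
  pos <- vapply(keep, function(i) which(mism[i, ]), integer(1))
  tibble::tibble(
    start = starts[keep],
    position_in_epitope = pos,
    observed_residue = win[cbind(keep, pos)],
    expected_residue = echars[pos]
  )
}

#' Cysteine profile of a protein
#'
#' @param protein Amino-acid string.
#' @param annotation Optional `protein_annotation` for per-domain counts.
#' @param reference Optional reference protein; positions present in only
#'   one of the two sequences are reported as gained/lost (raw protein
#'   coordinates).
#' @return List with `total`, `positions`, `per_domain` (named integer
#'   vector, present when an annotation is supplied) and `diff` (when a
#'   reference is supplied).
#' @export
cysteine_profile <- function(protein, annotation = NULL, reference = NULL) {
  protein <- toupper(trimws(protein))
  positions <- match_starts(protein, "C")
  out <- list(total = length(positions), positions = as.integer(positions))
  if (!is.null(annotation)) {
    labs <- annotation$domains$label
    cnt <- stats::setNames(integer(length(labs)), labs)
    for (p in positions) {
      d <- domain_of_position(annotation, p)
      if (!is.na(d)) cnt[d] <- cnt[d] + 1L
    }
    out$per_domain <- cnt
  }
  if (!is.null(reference)) {
    ref_pos <- match_starts(toupper(reference), "C")
    out$diff <- list(gained = setdiff(positions, ref_pos),
                     lost = setdiff(ref_pos, positions))
  }
  out
}

expand_repeat_unit <- function(motif) {
  # the gamma repeat grammar PFPQ(1-2)(PQQ)(1-2) expands to four literals
  if (motif %in% c("PFPQ1-2(PQQ)1-2", "gamma_unit")) {
    c("PFPQPQQPQQ", "PFPQQPQQPQQ", "PFPQPQQ", "PFPQQPQQ")
  } else {
    motif
  }
}

#' Count repeat units in a protein region
#'
#' @param protein Amino-acid string.
#' @param motif A literal motif, a vector of literals, or the grammar token
#'   `"PFPQ1-2(PQQ)1-2"` which expands to its four literal units.
#' @param allow_overlap If `FALSE` (default) units are counted by a greedy
#'   left-to-right non-overlapping scan (longest unit preferred at each
#'   position); if `TRUE` every matching window is counted.
#' @return Integer count.
#' @export
count_repeat_units <- function(protein, motif, allow_overlap = FALSE) {
  protein <- toupper(trimws(protein))
  units <- expand_repeat_unit(motif)
  if (any(!nzchar(units))) stop("empty motif")
  if (allow_overlap) {
    return(sum(vapply(units, function(u) length(match_starts(protein, u)),
                      integer(1))))
  }
  units <- units[order(-nchar(units))]
  n <- nchar(protein)
  i <- 1L
  count <- 0L
  while (i <= n) {
    matched <- FALSE
    for (u in units) {
      L <- nchar(u)
      if (i + L - 1L <= n && substring(protein, i, i + L - 1L) == u) {
        count <- count + 1L
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  count
}

#' Q:P:F composition of a protein region
#'
#' @param protein_region Amino-acid string.
#' @return List with `fractions` (named Q/P/F fractions among Q+P+F
#'   residues) and `ratio` (nearest small-integer ratio, obtained by
#'   rounding eight times the fractions and reducing by their GCD).
#' @export
qpf_ratio <- function(protein_region) {
  protein_region <- toupper(trimws(protein_region))
  q <- length(match_starts(protein_region, "Q"))
  p <- length(match_starts(protein_region, "P"))
  f <- length(match_starts(protein_region, "F"))
  tot <- q + p + f
  if (tot == 0) stop("region contains no Q, P or F residues")
  fr <- c(Q = q, P = p, F = f) / tot
  ints <- round(8 * fr)
  nz <- ints[ints > 0]
  g <- Reduce(function(a, b) {
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    a
  }, nz)
  list(fractions = fr, ratio = as.integer(ints / g))
}

#' Classify an omega-gliadin by the first three mature residues
#'
#' ARQ or ARE prefixes give the ARQ/E type; KEL, SRL and TRQ give their
#' respective types. Any other prefix is called an ARQ/E-like variant when
#' the overall Q:P:F composition is within tolerance of the canonical
#' 4:3:1 (fractions 0.5/0.375/0.125), otherwise unknown.
#'
#' @param mature_protein Amino-acid string with the signal peptide removed.
#' @param tol Per-fraction tolerance for the composition rule.
#' @return One of `"ARQ/E"`, `"KEL"`, `"SRL"`, `"TRQ"`,
#'   `"ARQ/E-like variant"`, `"unknown"`.
#' @export
classify_omega <- function(mature_protein, tol = 0.05) {
  mature_protein <- toupper(trimws(mature_protein))
  if (nchar(mature_protein) < 3) stop("mature protein shorter than 3 residues")
  first3 <- substr(mature_protein, 1, 3)
  if (first3 %in% c("ARQ", "ARE")) return("ARQ/E")
  if (first3 %in% c("KEL", "SRL", "TRQ")) return(first3)
  if (!grepl("[QPF]", mature_protein)) return("unknown")
  fr <- qpf_ratio(mature_protein)$fractions
  target <- c(Q = 0.5, P = 0.375, F = 0.125)
  if (all(abs(fr - target) <= tol)) "ARQ/E-like variant" else "unknown"
}

#' Assign an alpha-gliadin to structural/epitope group I, II or III
#'
#' Group I: a Q-to-A point variant inside the QI tract together with the
#' DQ8-glia-alpha1 epitope. Group II: a Q-to-K point variant inside QII
#' together with both the DQ2.5-glia-alpha1a and DQ2.5-glia-alpha3
#' epitopes. Group III: pure-glutamine tracts and 3-4 distinct epitopes.
#' Anything else is unclassified.
#'
#' @param annotation Alpha `protein_annotation` (required).
#' @param epitope_hits Hit tibble from [scan_epitopes()].
#' @param qI_variants,qII_variants Character vectors of non-Q residues in
#'   the tracts; computed from the annotation via [polyq_variants()] when
#'   missing.
#' @return One of `"I"`, `"II"`, `"III"`, `"unclassified"`.
#' @export
classify_alpha_group <- function(annotation, epitope_hits,
                                 qI_variants = NULL, qII_variants = NULL) {
  if (is.null(annotation)) stop("annotation required")
  if (is.null(qI_variants) || is.null(qII_variants)) {
    v <- polyq_variants(annotation)
    if (is.null(qI_variants)) qI_variants <- v$qI
    if (is.null(qII_variants)) qII_variants <- v$qII
  }
  has <- function(seq) any(epitope_hits$sequence == seq)
  dq8a1 <- "QGSFQPSQQ"
  a1a <- "PFPQPQLPY"
  a3 <- "FRPQQPYPQ"
  if ("A" %in% qI_variants && has(dq8a1)) return("I")
  if ("K" %in% qII_variants && has(a1a) && has(a3)) return("II")
  n_distinct <- length(unique(epitope_hits$sequence))
  if (length(qI_variants) == 0 && length(qII_variants) == 0 &&
      n_distinct >= 3 && n_distinct <= 4) {
    return("III")
  }
  "unclassified"
}
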