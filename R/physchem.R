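# Theoretical molecular weight (average or monoisotopic) and isoelectric
# point by Henderson-Hasselbalch bisection. Average masses are the default
# because gel-scale MW values are averages over isotopologues.

AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
MONO_RESIDUE_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
WATER_AVG <- 18.0153
WATER_MONO <- 18.010565

# Bjellqvist pKa values (as used by the ExPASy tools), including the
# residue-specific N-terminal values; "emboss" offers the EMBOSS iep set.
PKA_SETS <- list(
  bjellqvist = list(
    nterm_default = 7.5,
    nterm = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.7),
    cterm_default = 3.55,
    cterm = c(D = 4.55, E = 4.75),
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  ),
  emboss = list(
    nterm_default = 8.6, nterm = c(),
    cterm_default = 3.6, cterm = c(),
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
)

protein_chars <- function(protein) {
  protein <- toupper(trimws(protein))
  if (!nzchar(protein)) stop("empty protein sequence")
  chars <- strsplit(protein, "")[[1]]
  bad <- !chars %in% names(AVERAGE_RESIDUE_MASS)
  if (any(bad)) {
    stop("non-standard residue(s): ", paste(unique(chars[bad]), collapse = ""))
  }
  chars
}

#' Theoretical molecular weight of a protein
#'
#' Sum of residue masses plus one water (peptide-bond condensation).
#'
#' @param protein Amino-acid string (20 standard residues).
#' @param monoisotopic Use monoisotopic masses instead of average masses.
#' @return Mass in daltons.
#' @export
molecular_weight <- function(protein, monoisotopic = FALSE) {
  chars <- protein_chars(protein)
  if (monoisotopic) {
    sum(MONO_RESIDUE_MASS[chars]) + WATER_MONO
  } else {
    sum(AVERAGE_RESIDUE_MASS[chars]) + WATER_AVG
  }
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch over the N-terminus, C-terminus and ionizable
#' side chains (K, R, H positive; D, E, C, Y negative). Strictly
#' decreasing in pH, so the isoelectric point is a unique root.
#'
#' @param protein Amino-acid string.
#' @param ph pH value(s).
#' @param pka_set `"bjellqvist"` (default) or `"emboss"`.
#' @return Net charge (vectorized over `ph`).
#' @export
net_charge <- function(protein, ph, pka_set = "bjellqvist") {
  chars <- protein_chars(protein)
  pk <- PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  first <- chars[1]
  last <- chars[length(chars)]
  nterm_pka <- if (first %in% names(pk$nterm)) pk$nterm[[first]] else
    pk$nterm_default
  cterm_pka <- if (last %in% names(pk$cterm)) pk$cterm[[last]] else
    pk$cterm_default
  counts <- table(chars)
  cnt <- function(r) if (r %in% names(counts)) as.numeric(counts[[r]]) else 0
  pos_pkas <- c(nterm_pka, rep(pk$positive, times = vapply(names(pk$positive),
                                                           cnt, numeric(1))))
  neg_pkas <- c(cterm_pka, rep(pk$negative, times = vapply(names(pk$negative),
                                                           cnt, numeric(1))))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pkas))) - sum(1 / (1 + 10^(neg_pkas - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' Bisection on pH in `[0, 14]` for the root of [net_charge()], to a pH
#' tolerance of 0.005.
#'
#' @inheritParams net_charge
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein, pka_set = "bjellqvist") {
  lo <- 0
  hi <- 14
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical table for a set of proteins
#'
#' @param proteins Named character vector (or tibble with `id`/`sequence`)
#'   of full predicted proteins.
#' @param mature_start Optional named integer vector; when `scope` is
#'   `"mature"` each sequence is trimmed to start there.
#' @param scope `"full"` (default, signal peptide included) or `"mature"`.
#' @param pka_set pKa set name, recorded in the output.
#' @return Tibble: `gene`, `mw_kd` (2 decimals), `pi` (2 decimals),
#'   `pka_set`, `sequence_scope`.
#' @export
physchem_table <- function(proteins, mature_start = NULL, scope = "full",
                           pka_set = "bjellqvist") {
  if (is.data.frame(proteins)) {
    proteins <- stats::setNames(proteins$sequence, proteins$id)
  }
  ids <- names(proteins)
  seqs <- as.character(proteins)
  if (scope == "mature" && !is.null(mature_start)) {
    seqs <- vapply(seq_along(seqs), function(i) {
      ms <- mature_start[[ids[i]]]
      substring(seqs[i], ms)
    }, character(1))
  }
  seqs <- gsub("[*X]", "", seqs)   # conceptual translations may carry stops
  tibble::tibble(
    gene = ids,
    mw_kd = round(vapply(seqs, molecular_weight, numeric(1)) / 1000, 2),
    pi = round(vapply(seqs, isoelectric_point, numeric(1),
                      pka_set = pka_set), 2),
    pka_set = pka_set,
    sequence_scope = scope
  )
}
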