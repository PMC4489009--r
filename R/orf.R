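# ORF classification: conceptual translation, internal stop detection,
# frameshift detection against a full-ORF homolog, and classification of
# each pseudogenizing event's mutational origin (the canonical event in
# Q-rich prolamin genes is a C-to-T transition turning a CAA/CAG glutamine
# codon, or rarely a CGA arginine codon, into a stop).

STOP_CODONS <- c("TAA", "TAG", "TGA")

split_codons <- function(nt) {
  n <- nchar(nt)
  k <- n %/% 3
  if (k == 0) return(character())
  substring(nt, seq(1, by = 3, length.out = k), seq(3, by = 3, length.out = k))
}

#' Translate a coding sequence
#'
#' Standard genetic code; internal stop codons are rendered as `*` so that
#' pseudogenes obtain a conceptual translation. Codons containing `N` (or
#' any unresolvable triplet) translate to `X`. The input is expected to
#' exclude the terminal stop codon (catalogue convention: fragment length
#' equals three times the predicted protein length).
#'
#' @param nt Nucleotide string, length divisible by 3.
#' @return Amino-acid string of length `nchar(nt) / 3`.
#' @export
translate_cds <- function(nt) {
  nt <- toupper(trimws(nt))
  if (!nzchar(nt)) stop("empty coding sequence")
  if (!grepl("^[ACGTN]+$", nt)) stop("illegal characters in coding sequence")
  if (nchar(nt) %% 3 != 0) {
    stop("CDS length not divisible by 3 (", nchar(nt),
         " bp); route the sequence to frameshift handling")
  }
  if (substr(nt, 1, 3) != "ATG") {
    warning("CDS does not start with ATG")
  }
  codons <- split_codons(nt)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find internal stop codons in an in-frame CDS
#'
#' @param nt In-frame nucleotide string (any trailing partial codon is
#'   ignored). The terminal stop codon is assumed absent per the catalogue
#'   convention; every stop found is reported.
#' @return Tibble of stop events sorted by `codon_index`, with
#'   `observed_codon` and `origin = "unexplained"` until
#'   [classify_stop_origin()] is applied.
#' @export
find_internal_stops <- function(nt) {
  nt <- toupper(trimws(nt))
  codons <- split_codons(nt)
  idx <- which(codons %in% STOP_CODONS)
  tibble::tibble(
    codon_index = as.integer(idx),
    observed_codon = codons[idx],
    reference_codon = NA_character_,
    origin = rep("unexplained", length(idx))
  )
}

#' Classify the mutational origin of an internal stop codon
#'
#' A stop is explained when a single C-to-T substitution at the first codon
#' position converts the aligned reference codon into the observed stop:
#' CAA to TAA, CAG to TAG, or CGA to TGA. A reference codon containing an
#' alignment gap marks the stop as frameshift-induced; anything else is
#' unexplained.
#'
#' @param observed_codon Observed stop triplet (TAA/TAG/TGA).
#' @param reference_codon Aligned codon from a full-ORF homolog (may
#'   contain `-` for gap columns).
#' @return Origin label, one of `"CAA->TAA"`, `"CAG->TAG"`, `"CGA->TGA"`,
#'   `"frameshift-induced"`, `"unexplained"`.
#' @export
classify_stop_origin <- function(observed_codon, reference_codon) {
  observed_codon <- toupper(observed_codon)
  if (!observed_codon %in% STOP_CODONS) {
    stop("observed codon is not a stop codon: ", observed_codon)
  }
  if (is.na(reference_codon)) return("unexplained")
  reference_codon <- toupper(reference_codon)
  if (grepl("-", reference_codon, fixed = TRUE)) return("frameshift-induced")
  ok <- reference_codon %in% c("CAA", "CAG", "CGA") &&
    substr(reference_codon, 2, 3) == substr(observed_codon, 2, 3)
  if (ok) paste0(reference_codon, "->", observed_codon) else "unexplained"
}

nt_sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

align_nt <- function(query, reference, gap_open = 5, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(reference),
    substitutionMatrix = nt_sub_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
}

# Left-normalize an indel: shift its reported reference position left while
# the preceding reference base equals the last base of the event (canonical
# placement inside homopolymer runs).
left_normalize_indel <- function(ref_chars, pos, event_base) {
  while (pos > 1 && ref_chars[pos - 1] == event_base) pos <- pos - 1
  pos
}

#' Detect frameshift indels against a full-ORF reference
#'
#' Globally aligns the query CDS to a full-ORF homolog and reports indels
#' whose length is not a multiple of 3. Positions are 1-based reference
#' (CDS) coordinates of the first affected base pair, left-normalized
#' within homopolymer runs.
#'
#' @param nt Query nucleotide string.
#' @param reference_nt Full-ORF homolog nucleotide string.
#' @param gap_open,gap_extend Positive gap penalties for the global
#'   alignment.
#' @param all_indels If `TRUE`, also report in-frame indels (length
#'   divisible by 3).
#' @return Tibble with columns `cds_position`, `kind`
#'   (`insertion`/`deletion`, relative to the reference), `length`.
#' @export
detect_frameshift <- function(nt, reference_nt = NULL, gap_open = 5,
                              gap_extend = 1, all_indels = FALSE) {
  nt <- toupper(trimws(nt))
  if (is.null(reference_nt)) {
    if (nchar(nt) %% 3 == 0) {
      return(tibble::tibble(cds_position = integer(), kind = character(),
                            length = integer()))
    }
    # no homolog to localize the event: frame is broken but position unknown
    return(tibble::tibble(cds_position = NA_integer_, kind = "unknown",
                          length = NA_integer_))
  }
  reference_nt <- toupper(trimws(reference_nt))
  if (nt == reference_nt) {
    return(tibble::tibble(cds_position = integer(), kind = character(),
                          length = integer()))
  }
  aln <- align_nt(nt, reference_nt, gap_open, gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(s != "-")
  ref_chars <- strsplit(reference_nt, "")[[1]]

  events <- list()
  i <- 1
  ncol <- length(p)
  while (i <= ncol) {
    if (p[i] == "-") {            # gap in query = deletion of reference bases
      j <- i
      while (j < ncol && p[j + 1] == "-") j <- j + 1
      pos <- ref_pos[i]
      len <- j - i + 1L
      pos <- left_normalize_indel(ref_chars, pos, ref_chars[pos + len - 1L])
      events[[length(events) + 1]] <- c(pos, 1L, len)
      i <- j + 1
    } else if (s[i] == "-") {     # gap in reference = insertion in query
      j <- i
      while (j < ncol && s[j + 1] == "-") j <- j + 1
      pos <- if (i == 1) 1L else ref_pos[i - 1] + 1L
      len <- j - i + 1L
      ins_base <- p[j]
      pos <- left_normalize_indel(ref_chars, pos, ins_base)
      events[[length(events) + 1]] <- c(pos, 2L, len)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(events) == 0) {
    return(tibble::tibble(cds_position = integer(), kind = character(),
                          length = integer()))
  }
  m <- do.call(rbind, events)
  out <- tibble::tibble(
    cds_position = as.integer(m[, 1]),
    kind = c("deletion", "insertion")[m[, 2]],
    length = as.integer(m[, 3])
  )
  if (!all_indels) out <- out[out$length %% 3 != 0, , drop = FALSE]
  out[order(out$cds_position), , drop = FALSE]
}

# Map each query codon to the reference characters aligned to its three
# bases ("-" where the reference has a gap).
aligned_reference_codons <- function(aln, codon_indices) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qcols <- which(p != "-")        # alignment column of each query base
  vapply(codon_indices, function(ci) {
    cols <- qcols[(3 * ci - 2):(3 * ci)]
    paste(s[cols], collapse = "")
  }, character(1))
}

percent_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    100 * mean(ca == cb)
  } else {
    Biostrings::pid(align_nt(a, b))
  }
}

#' Classify a gliadin CDS as full-ORF or pseudogene
#'
#' Translates the CDS, detects internal stops and (against the best
#' reference from a full-ORF panel) frameshift indels, and assigns each
#' internal stop its mutational origin. Reference selection: highest global
#' nucleotide identity, ties broken by longer reference then lexicographic
#' id. A gene is `pseudo_frameshift` when an indel of length not divisible
#' by 3 is found (or the frame is broken with no reference available);
#' otherwise any internal stop makes it `pseudo_stop`; otherwise
#' `full_orf`.
#'
#' @param nt Query CDS (terminal stop codon, if present, is trimmed with a
#'   warning).
#' @param reference_panel Named character vector of full-ORF CDS (may be
#'   empty or `NULL`).
#' @param gap_open,gap_extend Alignment gap penalties.
#' @return An object of class `orf_result`: list with `status`
#'   (`full_orf`/`pseudo_stop`/`pseudo_frameshift`), `protein` (conceptual
#'   translation, stops as `*`), `stop_events`, `frameshift_events`,
#'   `reference` (id used, or `NA`).
#' @export
classify_orf <- function(nt, reference_panel = NULL, gap_open = 5,
                         gap_extend = 1) {
  nt <- toupper(trimws(nt))
  if (!nzchar(nt)) stop("empty input sequence")
  # catalogue convention: CDS excludes the terminal stop
  if (nchar(nt) %% 3 == 0 && nchar(nt) >= 3) {
    last <- substr(nt, nchar(nt) - 2, nchar(nt))
    if (last %in% STOP_CODONS) {
      warning("trimming terminal stop codon")
      nt <- substr(nt, 1, nchar(nt) - 3)
    }
  }
  frame_rem <- nchar(nt) %% 3
  in_frame <- substr(nt, 1, nchar(nt) - frame_rem)
  protein <- translate_cds_quiet(in_frame)
  stops <- find_internal_stops(in_frame)

  ref_id <- NA_character_
  ref_nt <- NULL
  needs_ref <- nrow(stops) > 0 || frame_rem != 0
  if (needs_ref && length(reference_panel) > 0) {
    ids <- names(reference_panel)
    if (is.null(ids)) ids <- paste0("ref", seq_along(reference_panel))
    idsc <- as.character(reference_panel)
    pidv <- vapply(idsc, function(r) percent_identity(nt, r), numeric(1))
    ord <- order(-pidv, -nchar(idsc), ids)
    ref_id <- ids[ord[1]]
    ref_nt <- idsc[ord[1]]
  }

  # frameshift search only when the frame is actually broken; in-frame
  # indels between homologs (tract-length variation) are not frameshifts
  fs <- if (frame_rem != 0) {
    if (!is.null(ref_nt)) detect_frameshift(nt, ref_nt, gap_open, gap_extend)
    else detect_frameshift(nt, NULL)
  } else {
    tibble::tibble(cds_position = integer(), kind = character(),
                   length = integer())
  }

  if (nrow(stops) > 0 && !is.null(ref_nt)) {
    aln <- align_nt(nt, ref_nt, gap_open, gap_extend)
    refc <- aligned_reference_codons(aln, stops$codon_index)
    stops$reference_codon <- refc
    stops$origin <- vapply(seq_len(nrow(stops)), function(i) {
      classify_stop_origin(stops$observed_codon[i], stops$reference_codon[i])
    }, character(1))
  }

  status <- if (nrow(fs) > 0) {
    "pseudo_frameshift"
  } else if (nrow(stops) > 0) {
    "pseudo_stop"
  } else {
    "full_orf"
  }
  structure(
    list(status = status, protein = protein, stop_events = stops,
         frameshift_events = fs, reference = ref_id),
    class = "orf_result"
  )
}

# translate without the ATG warning (used on arbitrary frames internally)
translate_cds_quiet <- function(nt) {
  codons <- split_codons(nt)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Summarize ORF classifications as a per-gene table
#'
#' @param results Named list of `orf_result` objects.
#' @return Tibble: gene, status, n_internal_stops, stop codon indices,
#'   origins, frameshift positions (semicolon-separated).
#' @export
orf_summary <- function(results) {
  tibble::tibble(
    gene = names(results),
    status = vapply(results, function(r) r$status, character(1)),
    n_internal_stops = vapply(results, function(r) nrow(r$stop_events),
                              integer(1)),
    stop_positions = vapply(results, function(r) {
      paste(r$stop_events$codon_index, collapse = ";")
    }, character(1)),
    stop_origins = vapply(results, function(r) {
      paste(r$stop_events$origin, collapse = ";")
    }, character(1)),
    frameshift_positions = vapply(results, function(r) {
      paste(r$frameshift_events$cds_position, collapse = ";")
    }, character(1)),
    reference = vapply(results, function(r) r$reference, character(1))
  )
}
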