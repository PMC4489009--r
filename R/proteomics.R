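# In-silico chymotryptic digestion, sequence-level peptide matching and
# 2-DE spot assignment. Cleavage follows the extended chymotrypsin rule
# (C-terminal to F, Y, W, L, M, never before proline); matching is exact
# substring identity against the predicted proteins, so an ambiguous spot
# keeps its whole candidate group and its volume is never split.

#' In-silico chymotryptic digest
#'
#' @param protein Amino-acid string (standard residues).
#' @param max_missed Maximum missed cleavages retained (default 2).
#' @param min_len Minimum peptide length retained (default 5).
#' @param residues Cleavage residues; default extended specificity
#'   F/Y/W/L/M, switchable to high-specificity `c("F","Y","W")`.
#' @return Tibble: `sequence`, `start`, `end`, `missed_cleavages`,
#'   `monoisotopic_mass`.
#' @export
chymotryptic_digest <- function(protein, max_missed = 2, min_len = 5,
                                residues = c("F", "Y", "W", "L", "M")) {
  chars <- protein_chars(protein)
  n <- length(chars)
  sites <- which(chars[-n] %in% residues & chars[-1] != "P")
  bounds <- c(0L, sites, n)
  bounds <- unique(bounds)
  nseg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nseg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nseg) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      if (e - s + 1L < min_len) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        sequence = paste(chars[s:e], collapse = ""),
        start = s, end = e, missed_cleavages = m
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(sequence = character(), start = integer(),
                          end = integer(), missed_cleavages = integer(),
                          monoisotopic_mass = numeric()))
  }
  out$monoisotopic_mass <- vapply(out$sequence, molecular_weight, numeric(1),
                                  monoisotopic = TRUE)
  out
}

#' Match observed peptides to a predicted proteome
#'
#' Exact substring match of each peptide against each predicted protein.
#'
#' @param observed_peptides Character vector of peptide sequences.
#' @param proteome Named character vector of proteins, or a tibble with
#'   `id`/`sequence` columns.
#' @return Named list: peptide -> character vector of supporting gene ids
#'   (possibly empty).
#' @export
match_peptides <- function(observed_peptides, proteome) {
  if (is.data.frame(proteome)) {
    proteome <- stats::setNames(proteome$sequence, proteome$id)
  }
  if (length(proteome) == 0) stop("empty proteome")
  ids <- names(proteome)
  seqs <- toupper(as.character(proteome))
  out <- lapply(toupper(observed_peptides), function(p) {
    ids[vapply(seqs, function(s) grepl(p, s, fixed = TRUE), logical(1))]
  })
  stats::setNames(out, observed_peptides)
}

#' Assign a 2-DE spot to gene(s) from its identified peptides
#'
#' A spot is uniquely assigned when exactly one gene is supported by at
#' least one peptide found in no other protein; otherwise it is ambiguous
#' and keeps the list of genes supported by every peptide (intersection).
#' A spot whose peptides match nothing is unassigned.
#'
#' @param peptides Character vector of the spot's identified peptides.
#' @param proteome Named character vector of predicted proteins (or tibble
#'   `id`/`sequence`).
#' @param spot_id Spot identifier carried through.
#' @return Object of class `spot_assignment`: list with `spot_id`,
#'   `matched_genes`, `unique` (flag), `assigned_gene` (or `NA`),
#'   `supporting_peptides` (gene -> peptides), `unique_peptides`.
#' @export
assign_spot <- function(peptides, proteome, spot_id = NA_integer_) {
  if (length(peptides) == 0) stop("spot has no peptides")
  matches <- match_peptides(peptides, proteome)
  supported <- unique(unlist(matches))
  if (length(supported) == 0) {
    return(structure(list(spot_id = spot_id, matched_genes = character(),
                          unique = FALSE, assigned_gene = NA_character_,
                          supporting_peptides = list(),
                          unique_peptides = list()),
                     class = "spot_assignment"))
  }
  supporting <- lapply(stats::setNames(supported, supported), function(g) {
    names(matches)[vapply(matches, function(gs) g %in% gs, logical(1))]
  })
  uniq <- lapply(stats::setNames(supported, supported), function(g) {
    names(matches)[vapply(matches, function(gs) identical(gs, g), logical(1))]
  })
  genes_with_unique <- supported[vapply(uniq, length, integer(1)) > 0]
  if (length(genes_with_unique) == 1) {
    return(structure(list(spot_id = spot_id, matched_genes = supported,
                          unique = TRUE,
                          assigned_gene = genes_with_unique,
                          supporting_peptides = supporting,
                          unique_peptides = uniq),
                     class = "spot_assignment"))
  }
  # ambiguous: genes supported by every peptide that matched anything
  informative <- matches[vapply(matches, length, integer(1)) > 0]
  inter <- Reduce(intersect, informative)
  matched <- if (length(inter) > 0) inter else supported
  structure(list(spot_id = spot_id, matched_genes = matched, unique = FALSE,
                 assigned_gene = NA_character_,
                 supporting_peptides = supporting, unique_peptides = uniq),
            class = "spot_assignment")
}

spot_entity <- function(genes) {
  if (length(genes) == 0) "unassigned" else
    paste(sort(genes), collapse = "+")
}

gene_class <- function(gene) {
  # catalogue naming convention: type is encoded in the gene-name prefix
  if (grepl("^Gli-(\u03b1|alpha|a)-", gene)) return("alpha")
  if (grepl("^Gli-(\u03b3|gamma|g)-", gene)) return("gamma")
  if (grepl("^Gli-(\u03c9|omega|w|o)-", gene)) return("omega")
  NA_character_
}

#' Aggregate 2-DE percent volumes per gene/group and per gliadin class
#'
#' Uniquely assigned spots contribute to their gene; ambiguous spots are
#' attributed to their candidate group as a unit (never split). Class
#' totals sum every spot of that gliadin class.
#'
#' @param spot_table Long spot tibble from [read_spot_table()].
#' @param assignments Optional named list (by spot id) of
#'   `spot_assignment` objects; when absent, assignments derive from the
#'   table's `gene` column (one gene = unique, several = ambiguous group).
#' @return List with `per_gene` (tibble entity/genes/percent_volume),
#'   `per_class` (tibble class/percent_volume), `total` (all-spot sum).
#'   Warns when the total exceeds 100.5.
#' @export
aggregate_volumes <- function(spot_table, assignments = NULL) {
  spots <- unique(spot_table$spot_id)
  ent <- character(length(spots))
  genes <- vector("list", length(spots))
  vol <- numeric(length(spots))
  for (k in seq_along(spots)) {
    rows <- spot_table[spot_table$spot_id == spots[k], , drop = FALSE]
    vol[k] <- rows$percent_volume[1]
    g <- if (!is.null(assignments)) {
      a <- assignments[[as.character(spots[k])]]
      if (isTRUE(a$unique)) a$assigned_gene else a$matched_genes
    } else {
      # multi-gene spots: several table rows and/or semicolon-joined names
      unique(unlist(strsplit(rows$gene[!is.na(rows$gene)], ";", fixed = TRUE)))
    }
    genes[[k]] <- g
    ent[k] <- spot_entity(g)
  }
  per_gene <- tibble::tibble(entity = ent, percent_volume = vol) |>
    dplyr::group_by(.data$entity) |>
    dplyr::summarise(percent_volume = sum(.data$percent_volume),
                     .groups = "drop")
  cls <- vapply(genes, function(g) {
    if (length(g) == 0) return(NA_character_)
    gene_class(g[1])
  }, character(1))
  per_class <- tibble::tibble(class = cls, percent_volume = vol) |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(percent_volume = sum(.data$percent_volume),
                     .groups = "drop")
  total <- sum(vol)
  if (total > 100.5) warning("spot volumes sum to ", round(total, 2),
                             "% (> 100.5%)")
  list(per_gene = per_gene, per_class = per_class, total = total)
}

#' Check a spot's observed MW/pI against candidate gene predictions
#'
#' @param spot_mw_kd,spot_pi Observed spot coordinates.
#' @param predicted Tibble with `gene`, `mw_kd`, `pi` for the candidate
#'   genes ([physchem_table()] output).
#' @param tol_mw_kd,tol_pi Tolerances (defaults 3.0 kD and 0.5 pH units).
#' @return List with `consistent` (TRUE when at least one candidate is
#'   within both tolerances) and `deltas` (per-candidate tibble).
#' @export
spot_consistency <- function(spot_mw_kd, spot_pi, predicted,
                             tol_mw_kd = 3.0, tol_pi = 0.5) {
  if (nrow(predicted) == 0) stop("no candidate predictions supplied")
  deltas <- tibble::tibble(
    gene = predicted$gene,
    delta_mw_kd = spot_mw_kd - predicted$mw_kd,
    delta_pi = spot_pi - predicted$pi
  )
  ok <- abs(deltas$delta_mw_kd) <= tol_mw_kd & abs(deltas$delta_pi) <= tol_pi
  list(consistent = any(ok), deltas = deltas)
}
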