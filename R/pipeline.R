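# Pipeline entry points joining the modules into the three stages users
# actually run: sequence annotation, expression profiling and proteomic
# spot assignment. Each returns a list of tidy tables and optionally
# writes TSV/GFF3 outputs; given fixed inputs the outputs are
# byte-identical across runs.

type_from_name <- function(gene_name) {
  cls <- gene_class(gene_name)
  if (is.na(cls)) "unknown" else cls
}

#' Annotate a set of gliadin coding sequences
#'
#' For every input CDS: infer the gliadin type (from the gene-table name
#' prefix when a table is supplied, from the translated sequence
#' otherwise), classify the ORF against the set's own full-ORF genes,
#' segment the conceptual translation into structural domains, scan the
#' celiac epitope library, profile cysteines and compute MW/pI.
#'
#' @param fasta Path to a CDS FASTA file, or a tibble from [read_fasta()].
#' @param gene_table Optional catalogue tibble from [read_gene_table()].
#' @param config Configuration from [gliadin_config()].
#' @param out_dir Optional output directory for `catalogue.tsv`,
#'   `domains.gff3`, `epitopes.tsv`, `physchem.tsv`.
#' @return List with `catalogue` (one row per gene), `summary` (type and
#'   full-ORF totals), `orf`, `annotations`, `epitopes`, `physchem`.
#' @export
run_annotate <- function(fasta, gene_table = NULL,
                         config = gliadin_config(), out_dir = NULL) {
  records <- if (is.character(fasta)) {
    read_fasta(fasta, alphabet = "nt", allow_empty = TRUE)
  } else {
    fasta
  }
  if (nrow(records) == 0) {
    warning("no input sequences; emitting an empty catalogue")
    return(list(catalogue = tibble::tibble(), summary = list(n = 0),
                orf = list(), annotations = list(),
                epitopes = tibble::tibble(), physchem = tibble::tibble()))
  }
  lib <- epitope_library()

  # first pass: translations, provisional types, full-ORF panel
  prelim <- lapply(seq_len(nrow(records)), function(i) {
    nt <- records$sequence[i]
    frame_rem <- nchar(nt) %% 3
    protein <- translate_cds_quiet(substr(nt, 1, nchar(nt) - frame_rem))
    clean <- frame_rem == 0 && !grepl("*", protein, fixed = TRUE)
    type <- if (!is.null(gene_table) &&
                records$id[i] %in% gene_table$gene_name) {
      type_from_name(records$id[i])
    } else {
      infer_gliadin_type(protein, config)
    }
    list(id = records$id[i], nt = nt, protein = protein, clean = clean,
         type = type)
  })
  names(prelim) <- records$id
  panel_ids <- vapply(prelim, function(p) p$clean, logical(1))
  panel <- stats::setNames(
    vapply(prelim[panel_ids], function(p) p$nt, character(1)),
    names(prelim)[panel_ids])

  orf <- lapply(prelim, function(p) {
    same_type <- panel[vapply(names(panel), function(j) {
      prelim[[j]]$type == p$type
    }, logical(1))]
    same_type <- same_type[names(same_type) != p$id]
    classify_orf(p$nt, same_type, config$gap_open, config$gap_extend)
  })

  annotations <- list()
  epitope_rows <- list()
  cys <- list()
  for (p in prelim) {
    if (p$type == "unknown") next
    ann <- segment_domains(p$protein, p$type, config, gene_id = p$id)
    annotations[[p$id]] <- ann
    hits <- scan_epitopes(p$protein, lib[lib$class == p$type, ], ann)
    if (nrow(hits) > 0) {
      epitope_rows[[p$id]] <- dplyr::mutate(hits, gene = p$id,
                                            .before = 1)
    }
    cys[[p$id]] <- cysteine_profile(p$protein, ann)
  }
  epitopes <- dplyr::bind_rows(epitope_rows)

  proteins <- stats::setNames(
    vapply(prelim, function(p) p$protein, character(1)), names(prelim))
  pc <- physchem_table(proteins)

  catalogue <- tibble::tibble(
    gene_name = names(prelim),
    gliadin_type = vapply(prelim, function(p) p$type, character(1)),
    status = vapply(orf, function(r) r$status, character(1)),
    fragment_length = vapply(prelim, function(p) nchar(p$nt), integer(1)),
    predicted_aa_length = ifelse(
      vapply(orf, function(r) r$status, character(1)) == "full_orf",
      nchar(vapply(prelim, function(p) p$protein, character(1))),
      NA_integer_),
    cysteine_count = vapply(prelim, function(p) {
      length(match_starts(p$protein, "C"))
    }, integer(1)),
    n_internal_stops = vapply(orf, function(r) nrow(r$stop_events),
                              integer(1))
  )
  summary <- list(
    n = nrow(catalogue),
    by_type = table(catalogue$gliadin_type),
    full_orf_by_type = table(catalogue$gliadin_type[catalogue$status ==
                                                      "full_orf"])
  )
  out <- list(catalogue = catalogue, summary = summary, orf = orf,
              annotations = annotations, epitopes = epitopes, physchem = pc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(catalogue),
                       file.path(out_dir, "catalogue.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_domain_gff(annotations, file.path(out_dir, "domains.gff3"),
                     cysteines = cys)
    utils::write.table(as.data.frame(epitopes),
                       file.path(out_dir, "epitopes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(pc),
                       file.path(out_dir, "physchem.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run the expression stage
#'
#' @param counts Count matrix (genes x samples) or path to a count TSV.
#' @param samples Sample sheet tibble or path.
#' @param gene_lengths Named vector of gene lengths (bp), e.g. cloned
#'   fragment lengths from the catalogue.
#' @param config Configuration from [gliadin_config()].
#' @param out_dir Optional output directory (`rpkm.tsv`, `profiles.tsv`).
#' @return List with `rpkm` (`rpkm_matrix`), `stage_means`, `profiles`,
#'   `expressed`, `fold` (per-stage max/min fold among expressed genes).
#' @export
run_expression <- function(counts, samples, gene_lengths,
                           config = gliadin_config(), out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(samples)) samples <- read_samples(samples)
  x <- rpkm_matrix(counts, samples, gene_lengths)
  sm <- stage_means(x)
  expressed <- classify_expressed(x, config$expression_threshold)
  profiles <- characterize_profile(
    sm[, colnames(sm) %in% GRAIN_STAGES, drop = FALSE],
    threshold = config$expression_threshold,
    stability_fraction = config$stability_fraction)
  folds <- lapply(stats::setNames(nm = GRAIN_STAGES), function(st) {
    v <- sm[rownames(sm) %in% expressed, st]
    if (length(v) >= 2 && min(v) > 0) fold_summary(v) else NULL
  })
  out <- list(rpkm = x, stage_means = sm, profiles = profiles,
              expressed = expressed, fold = folds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene = rownames(sm), sm,
                                  check.names = FALSE),
                       file.path(out_dir, "rpkm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(profiles),
                       file.path(out_dir, "profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run the proteomic spot-assignment stage
#'
#' Spots carrying peptide lists are assigned by peptide matching against
#' the predicted proteome; spots without peptides fall back to the
#' table's gene column. Volumes are aggregated per gene/group and per
#' gliadin class, and observed spot coordinates are checked against the
#' predicted MW/pI.
#'
#' @param spot_table Long spot tibble from [read_spot_table()] (or path).
#' @param proteome Named character vector of predicted proteins (or
#'   tibble `id`/`sequence`); may be `NULL` when all spots carry gene
#'   assignments.
#' @param physchem Optional [physchem_table()] for consistency checks.
#' @param config Configuration from [gliadin_config()].
#' @param out_dir Optional output directory (`assignments.tsv`,
#'   `class_volumes.tsv`).
#' @return List with `assignments`, `volumes`, `consistency`.
#' @export
run_proteomics <- function(spot_table, proteome = NULL, physchem = NULL,
                           config = gliadin_config(), out_dir = NULL) {
  if (is.character(spot_table)) spot_table <- read_spot_table(spot_table)
  spots <- unique(spot_table$spot_id)
  have_peptides <- !all(is.na(spot_table$peptides))
  assignments <- NULL
  if (have_peptides && !is.null(proteome)) {
    assignments <- lapply(stats::setNames(nm = as.character(spots)),
                          function(s) {
      peps <- split_peptides(
        spot_table$peptides[spot_table$spot_id == as.integer(s)])
      assign_spot(peps, proteome, spot_id = as.integer(s))
    })
  }
  volumes <- aggregate_volumes(spot_table, assignments)
  consistency <- NULL
  if (!is.null(physchem)) {
    consistency <- lapply(stats::setNames(nm = as.character(spots)),
                          function(s) {
      rows <- spot_table[spot_table$spot_id == as.integer(s), ]
      cand <- if (!is.null(assignments)) {
        assignments[[s]]$matched_genes
      } else {
        unique(unlist(strsplit(rows$gene[!is.na(rows$gene)], ";",
                               fixed = TRUE)))
      }
      pred <- physchem[physchem$gene %in% cand, , drop = FALSE]
      if (nrow(pred) == 0) return(NULL)
      spot_consistency(rows$mw_kd[1], rows$pi[1], pred,
                       config$tol_mw_kd, config$tol_pi)
    })
  }
  out <- list(assignments = assignments, volumes = volumes,
              consistency = consistency)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(volumes$per_gene),
                       file.path(out_dir, "assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(volumes$per_class),
                       file.path(out_dir, "class_volumes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
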