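# Readers/writers for the external formats the pipeline touches: FASTA
# sequence sets, the gene-catalogue and 2-DE spot tables, count matrices,
# and GFF3 protein-coordinate domain annotations.

#' Read a FASTA file into a tibble of sequence records
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default), `"nt"` or `"aa"`. With `"auto"` the
#'   alphabet is inferred from the sequences: nucleotide files may contain
#'   `ACGTN`, amino-acid files the 20 standard residues plus `X` and `*`.
#' @param allow_empty If `TRUE` an empty file yields a zero-row tibble
#'   instead of an error.
#' @return A tibble with columns `id`, `description` and `sequence`
#'   (uppercased), one row per record, input order preserved.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nt", "aa"),
                       allow_empty = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    if (allow_empty) {
      return(tibble::tibble(id = character(), description = character(),
                            sequence = character()))
    }
    stop("empty FASTA file: ", path)
  }
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  description <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (any(!nzchar(id))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(id)) {
    stop("duplicate FASTA ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- toupper(unname(as.character(set)))
  if (alphabet == "auto") {
    alphabet <- if (all(grepl("^[ACGTN]*$", sequence))) "nt" else "aa"
  }
  pat <- switch(alphabet,
                nt = "^[ACGTN]+$",
                aa = "^[ACDEFGHIKLMNPQRSTVWYX*]+$")
  bad <- !grepl(pat, sequence)
  if (any(bad)) {
    stop("illegal characters for ", alphabet, " alphabet in record(s): ",
         paste(id[bad], collapse = ", "))
  }
  tibble::tibble(id = id, description = description, sequence = sequence)
}

#' Write sequence records to FASTA
#'
#' @param records A tibble/data.frame with columns `id`, `sequence` and
#'   optionally `description`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene-catalogue table
#'
#' Parses a TSV with the seven catalogue columns: gene name, GenBank id,
#' cDNA evidence (Y/N), draft-genome id (or NA), cloned fragment length
#' (bp), predicted amino-acid length (an integer, or the literal flag
#' `pseudo` for pseudogenes, case-insensitive) and cysteine count.
#'
#' @param path Path to the TSV (header required).
#' @return A tibble with typed columns `gene_name`, `genbank_id`,
#'   `cdna_evidence` (logical), `genome_id`, `fragment_length` (int),
#'   `predicted_aa_length` (int, `NA` for pseudogenes), `pseudo` (logical)
#'   and `cysteine_count` (int).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  expected <- c("gene_name", "genbank_id", "cdna_evidence", "genome_id",
                "fragment_length", "predicted_aa_length", "cysteine_count")
  if (!all(expected %in% names(raw))) {
    stop("gene table must contain columns: ", paste(expected, collapse = ", "))
  }
  raw <- raw[, expected]
  pseudo <- tolower(trimws(raw$predicted_aa_length)) == "pseudo"
  aa_chr <- trimws(raw$predicted_aa_length)
  aa_num <- suppressWarnings(as.integer(aa_chr))
  if (any(!pseudo & is.na(aa_num))) {
    stop("non-integer predicted_aa_length (other than the 'pseudo' flag) ",
         "in row(s): ",
         paste(which(!pseudo & is.na(aa_num)), collapse = ", "))
  }
  frag <- suppressWarnings(as.integer(trimws(raw$fragment_length)))
  if (any(is.na(frag)) || any(frag <= 0)) {
    stop("fragment_length must be a positive integer in every row")
  }
  cys <- suppressWarnings(as.integer(trimws(raw$cysteine_count)))
  if (any(is.na(cys)) || any(cys < 0)) {
    stop("cysteine_count must be a non-negative integer in every row")
  }
  cdna <- toupper(trimws(raw$cdna_evidence))
  if (!all(cdna %in% c("Y", "N"))) stop("cdna_evidence must be Y or N")
  tibble::tibble(
    gene_name = trimws(raw$gene_name),
    genbank_id = trimws(raw$genbank_id),
    cdna_evidence = cdna == "Y",
    genome_id = ifelse(toupper(trimws(raw$genome_id)) %in% c("NA", ""),
                       NA_character_, trimws(raw$genome_id)),
    fragment_length = frag,
    predicted_aa_length = ifelse(pseudo, NA_integer_, aa_num),
    pseudo = pseudo,
    cysteine_count = cys
  )
}

#' Write a gene-catalogue table (inverse of [read_gene_table()])
#' @param tab Tibble as returned by [read_gene_table()].
#' @param path Output TSV path.
#' @export
write_gene_table <- function(tab, path) {
  out <- data.frame(
    gene_name = tab$gene_name,
    genbank_id = tab$genbank_id,
    cdna_evidence = ifelse(tab$cdna_evidence, "Y", "N"),
    genome_id = ifelse(is.na(tab$genome_id), "NA", tab$genome_id),
    fragment_length = tab$fragment_length,
    predicted_aa_length = ifelse(tab$pseudo, "pseudo",
                                 as.character(tab$predicted_aa_length)),
    cysteine_count = tab$cysteine_count,
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a 2-DE spot table
#'
#' Long-format TSV, one row per (spot, candidate gene) pair: columns
#' `spot_id`, `percent_volume`, `gene` (may be NA for unassigned spots),
#' `mw_kd`, `pi` and optionally `peptides` (semicolon-separated amino-acid
#' strings). A spot assigned to several near-identical genes occupies
#' several rows sharing `spot_id` and `percent_volume`.
#'
#' @param path Path to the TSV.
#' @return A validated tibble in the same long format.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fileEncoding = "UTF-8",
                           colClasses = "character")
  need <- c("spot_id", "percent_volume", "gene", "mw_kd", "pi")
  if (!all(need %in% names(tab))) {
    stop("spot table must contain columns: ", paste(need, collapse = ", "))
  }
  out <- tibble::tibble(
    spot_id = as.integer(tab$spot_id),
    percent_volume = as.numeric(tab$percent_volume),
    gene = ifelse(tab$gene %in% c("", "NA"), NA_character_, tab$gene),
    mw_kd = as.numeric(tab$mw_kd),
    pi = as.numeric(tab$pi),
    peptides = if ("peptides" %in% names(tab)) {
      ifelse(tab$peptides %in% c("", "NA"), NA_character_, tab$peptides)
    } else NA_character_
  )
  if (any(out$percent_volume <= 0) || any(out$percent_volume > 100)) {
    stop("percent_volume must lie in (0, 100]")
  }
  if (any(out$mw_kd <= 0)) stop("mw_kd must be positive")
  if (any(out$pi <= 0 | out$pi >= 14)) stop("pi must lie in (0, 14)")
  out
}

#' Split a semicolon-separated peptide field
#' @param x Character scalar or vector (`"PEP1;PEP2"`); `NA` gives empty.
#' @return Character vector of peptides.
#' @export
split_peptides <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(character())
  unique(unlist(strsplit(x, ";", fixed = TRUE)))
}

#' Read a gene-by-sample count table
#' @param path TSV whose first column (`gene`) holds gene ids, remaining
#'   columns one sample each.
#' @return Integer matrix with genes as rownames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (names(tab)[1] != "gene") stop("first column of the count table must be 'gene'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("counts must be non-negative")
  rownames(m) <- tab$gene
  m
}

#' Read a sample sheet
#' @param path TSV with columns `sample`, `stage` (5/10/15/20/25/leaf),
#'   `replicate` and `library_size`.
#' @return Tibble with typed columns.
#' @export
read_samples <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fileEncoding = "UTF-8",
                           colClasses = "character")
  need <- c("sample", "stage", "replicate", "library_size")
  if (!all(need %in% names(tab))) {
    stop("sample sheet must contain columns: ", paste(need, collapse = ", "))
  }
  tibble::tibble(
    sample = tab$sample,
    stage = tab$stage,
    replicate = as.integer(tab$replicate),
    library_size = as.numeric(tab$library_size)
  )
}

#' Write domain/epitope/cysteine annotations as GFF3
#'
#' Emits one feature line per non-empty domain segment (plus optional
#' epitope hits and cysteine positions) in protein coordinates, 1-based
#' inclusive, via `rtracklayer`.
#'
#' @param annotations A list of protein annotations as produced by
#'   [segment_domains()].
#' @param path Output GFF3 path.
#' @param epitope_hits Optional named list (by gene id) of epitope hit
#'   tibbles from [scan_epitopes()].
#' @param cysteines Optional named list (by gene id) of cysteine profiles
#'   from [cysteine_profile()].
#' @export
write_domain_gff <- function(annotations, path, epitope_hits = NULL,
                             cysteines = NULL) {
  if (inherits(annotations, "protein_annotation")) {
    annotations <- list(annotations)
  }
  rows <- list()
  for (ann in annotations) {
    dom <- ann$domains[ann$domains$end >= ann$domains$start, , drop = FALSE]
    if (nrow(dom) > 1 && any(dom$start[-1] <= dom$end[-nrow(dom)])) {
      stop("overlapping domain features within protein ", ann$gene_id)
    }
    rows[[length(rows) + 1]] <- data.frame(
      seqid = ann$gene_id, type = "domain",
      start = dom$start, end = dom$end, name = dom$label
    )
    hits <- epitope_hits[[ann$gene_id]]
    if (!is.null(hits) && nrow(hits) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        seqid = ann$gene_id, type = "epitope",
        start = hits$start, end = hits$start + nchar(hits$sequence) - 1L,
        name = hits$names
      )
    }
    cp <- cysteines[[ann$gene_id]]
    if (!is.null(cp) && length(cp$positions) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        seqid = ann$gene_id, type = "cysteine",
        start = cp$positions, end = cp$positions, name = "C"
      )
    }
  }
  feats <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = feats$seqid,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end)
  )
  S4Vectors::mcols(gr)$source <- "gliadinR"
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$Name <- feats$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 protein-annotation file back into a tibble
#' @param path GFF3 path as written by [write_domain_gff()].
#' @return Tibble with columns `seqid`, `type`, `start`, `end`, `name`.
#' @export
read_domain_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = as.character(S4Vectors::mcols(gr)$Name)
  )
}
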