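# RPKM quantification from uniquely-mapped count tables and stage-profile
# characterization across grain development (5-25 days post-anthesis plus
# a flag-leaf control). Genes are called expressed when any grain-stage
# mean RPKM exceeds a threshold (default 1000); leaf samples never enter
# the criterion (endosperm specificity).

GRAIN_STAGES <- c("5", "10", "15", "20", "25")

#' Reads per kilobase per million mapped reads
#'
#' @param count Read count(s), uniquely aligned.
#' @param library_size Total mapped reads in the library.
#' @param gene_length Gene length in bp (here the cloned fragment length).
#' @return RPKM value(s): `count * 1e9 / (library_size * gene_length)`.
#' @export
rpkm <- function(count, library_size, gene_length) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  count * 1e9 / (library_size * gene_length)
}

#' Build an RPKM matrix from counts, a sample sheet and gene lengths
#'
#' @param counts Gene-by-sample numeric matrix (rownames = genes,
#'   colnames = samples).
#' @param samples Sample sheet tibble (`sample`, `stage`, `replicate`,
#'   `library_size`); must cover every count column.
#' @param gene_lengths Named vector of gene lengths (bp) covering every
#'   count row.
#' @return Object of class `rpkm_matrix`: list with `rpkm` (matrix),
#'   `counts`, `samples`, `gene_lengths`.
#' @export
rpkm_matrix <- function(counts, samples, gene_lengths) {
  if (!all(colnames(counts) %in% samples$sample)) {
    stop("sample sheet does not cover all count columns")
  }
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (any(samples$library_size < colSums(counts))) {
    stop("library sizes smaller than their column count sums")
  }
  gl <- gene_lengths[rownames(counts)]
  if (any(is.na(gl))) stop("gene_lengths missing for some genes")
  r <- sweep(counts, 2, samples$library_size, "/") * 1e9
  r <- sweep(r, 1, as.numeric(gl), "/")
  structure(list(rpkm = r, counts = counts, samples = samples,
                 gene_lengths = gl),
            class = "rpkm_matrix")
}

#' Per-stage mean (or median) RPKM over replicates
#'
#' @param x `rpkm_matrix` object.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return Gene-by-stage matrix; columns ordered 5, 10, 15, 20, 25, leaf
#'   (those present).
#' @export
stage_means <- function(x, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  fun <- if (aggregate == "mean") rowMeans else function(m) {
    apply(m, 1, stats::median)
  }
  stages <- unique(as.character(x$samples$stage))
  ordered <- c(GRAIN_STAGES[GRAIN_STAGES %in% stages],
               setdiff(stages, GRAIN_STAGES))
  out <- sapply(ordered, function(s) {
    cols <- x$samples$sample[as.character(x$samples$stage) == s]
    fun(x$rpkm[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(x$rpkm),
                                                       ordered))
  out
}

#' Classify genes as expressed from grain-stage RPKM
#'
#' A gene is expressed when any grain-stage (5-25 DPA) mean RPKM exceeds
#' the threshold; leaf samples are excluded from the criterion.
#'
#' @param x `rpkm_matrix` object.
#' @param threshold RPKM threshold (default 1000).
#' @param aggregate Replicate aggregation, `"mean"` or `"median"`.
#' @return Character vector of expressed gene ids.
#' @export
classify_expressed <- function(x, threshold = 1000,
                               aggregate = c("mean", "median")) {
  sm <- stage_means(x, match.arg(aggregate))
  grain <- sm[, colnames(sm) %in% GRAIN_STAGES, drop = FALSE]
  if (ncol(grain) == 0) stop("no grain-stage samples present")
  rownames(grain)[apply(grain, 1, function(v) any(v > threshold))]
}

#' Characterize a stage expression profile
#'
#' The peak stage maximizes the stage means; a profile is stable when the
#' 10- and 20-DPA means both exceed `stability_fraction` (default 0.70) of
#' the 15-DPA mean.
#'
#' @param stage_mean_row Named numeric vector of grain-stage means (must
#'   contain all five grain stages), or a gene-by-stage matrix.
#' @param threshold Expressed threshold applied to the stage means.
#' @param stability_fraction Flanking fraction of the 15-DPA level.
#' @param gene Gene id for the single-vector form.
#' @return Tibble: `gene`, `peak_stage`, `expressed`, `stable`.
#' @export
characterize_profile <- function(stage_mean_row, threshold = 1000,
                                 stability_fraction = 0.70, gene = "gene") {
  if (is.matrix(stage_mean_row)) {
    rows <- lapply(rownames(stage_mean_row), function(g) {
      characterize_profile(stage_mean_row[g, ], threshold,
                           stability_fraction, gene = g)
    })
    return(dplyr::bind_rows(rows))
  }
  v <- stage_mean_row[GRAIN_STAGES]
  if (any(is.na(v))) stop("all five grain stages (5-25 DPA) required")
  peak <- GRAIN_STAGES[which.max(v)]
  stable <- v[["10"]] > stability_fraction * v[["15"]] &&
    v[["20"]] > stability_fraction * v[["15"]]
  tibble::tibble(gene = gene, peak_stage = paste0(peak, " DPA"),
                 expressed = any(v > threshold), stable = stable)
}

#' Max/min fold summary at one stage among expressed genes
#'
#' @param x `rpkm_matrix` object, or a named numeric vector of stage
#'   values for the genes of interest.
#' @param stage Stage label (for the matrix form).
#' @param expressed Optional character vector restricting the genes
#'   considered; defaults to [classify_expressed()] for the matrix form.
#' @param threshold Expressed threshold used when `expressed` is missing.
#' @return List with `max_gene`, `min_gene`, `ratio` (2 decimals).
#' @export
fold_summary <- function(x, stage = NULL, expressed = NULL,
                         threshold = 1000) {
  if (inherits(x, "rpkm_matrix")) {
    if (is.null(expressed)) expressed <- classify_expressed(x, threshold)
    sm <- stage_means(x)
    v <- sm[rownames(sm) %in% expressed, as.character(stage)]
  } else {
    v <- x
  }
  if (length(v) < 2) stop("at least two expressed genes required")
  if (min(v) == 0) stop("minimum stage value is zero; fold undefined")
  list(
    max_gene = names(v)[which.max(v)],
    min_gene = names(v)[which.min(v)],
    ratio = round(max(v) / min(v), 2)
  )
}
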