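# Ground-truthed synthetic gliadin families. Genes are built domain by
# domain at the codon level so that nucleotide events (C-to-T transitions
# at glutamine codons, single-base deletions) are physically plantable,
# then pseudogenized as mutated copies of active family members — the way
# prolamin pseudogenes actually arise from recent duplicates. Expression
# count matrices and 2-DE spot tables derive from the same truth.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults reproduce the composition of the studied diploid wheat family:
#' 23 alpha, 3 gamma and 2 omega genes, 12/28 pseudogenes, QI tracts of
#' 9-33 residues (27-99 bp), stage-shaped expression (silent at 5 DPA,
#' peak at 15 DPA, decline to 25 DPA, leaf silent) and spots built from
#' the active proteins.
#'
#' @param n_alpha,n_gamma,n_omega Family sizes per type.
#' @param pseudogene_fraction Probability that a gene is pseudogenized.
#' @param qi_range,qii_range Polyglutamine tract length ranges (residues).
#' @param epitope_plant_rates Named plant probabilities for the alpha
#'   epitopes and peptides.
#' @param stop_rate_per_gene Range (1 to this) of planted stops per
#'   pseudogene.
#' @param cga_rate Probability that one stop arises from the planted CGA
#'   arginine codon (CGA to TGA) instead of a glutamine codon.
#' @param frameshift_rate Probability that a pseudogene carries a 1-bp
#'   deletion instead of point stops (about 1 in 12, as observed).
#' @param polyq_codon_weights CAA/CAG sampling weights inside tracts.
#' @param duplicate_fraction Fraction of active alpha genes generated as
#'   synonymous near-copies of another active gene (source of ambiguous
#'   spots).
#' @param stage_multipliers Expression shape over 5/10/15/20/25 DPA and
#'   leaf.
#' @param stable_fraction Fraction of active genes given a flat (stable)
#'   grain-filling profile.
#' @param peak_rpkm_meanlog,peak_rpkm_sdlog Log-normal peak RPKM model.
#' @param background_rpkm Background level for pseudogenes and leaf.
#' @param nb_size Negative-binomial size (inverse dispersion) for counts.
#' @param library_size_mean,library_size_sd Per-sample library sizes.
#' @param n_replicates Replicates per stage.
#' @param identity_merge Protein identity above which two active genes
#'   co-migrate as one ambiguous spot.
#' @param peptides_per_spot Peptides sampled per spot.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_alpha = 23, n_gamma = 3, n_omega = 2,
                       pseudogene_fraction = 12 / 28,
                       qi_range = c(9L, 33L), qii_range = c(8L, 24L),
                       epitope_plant_rates = c(
                         "DQ2.5-glia-a1a" = 0.6, "DQ2.5-glia-a3" = 0.8,
                         "DQ8-glia-a1" = 0.15, "p19" = 0.4, "p12" = 0.5),
                       stop_rate_per_gene = 3L, cga_rate = 0.08,
                       frameshift_rate = 1 / 12,
                       polyq_codon_weights = c(CAA = 0.6, CAG = 0.4),
                       duplicate_fraction = 0.3,
                       stage_multipliers = c("5" = 0.002, "10" = 0.5,
                                             "15" = 1, "20" = 0.5,
                                             "25" = 1 / 6, leaf = 0.0002),
                       stable_fraction = 5 / 16,
                       peak_rpkm_meanlog = log(15000),
                       peak_rpkm_sdlog = 0.5,
                       background_rpkm = 2,
                       nb_size = 300,
                       library_size_mean = 21.78e6, library_size_sd = 1e6,
                       n_replicates = 3L,
                       identity_merge = 0.98,
                       peptides_per_spot = c(6L, 12L),
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# ---- codon-level construction ---------------------------------------------

SYN_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

reverse_translate <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- SYN_CODONS[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

polyq_codons <- function(len, weights) {
  paste(sample(names(weights), len, replace = TRUE, prob = weights),
        collapse = "")
}

sample_len <- function(range) {
  if (range[1] >= range[2]) range[1] else
    sample(seq(range[1], range[2]), 1)
}

# fixed signal peptides (no Q runs, no cysteines)
SIGNAL_ALPHA <- "MKTFLILALLAIVATTATTA"   # 20 aa
SIGNAL_GAMMA <- "MKTLLILTILAMAITIGTAN"   # 20 aa
SIGNAL_OMEGA <- "MKTFLIFALLAMAMSIVTT"    # 19 aa

ALPHA_REP_UNITS <- c("PQPQPFPPQ", "QPYPQPQPF", "PQLPYPQPQ", "SPQPQPFLP")
ALPHA_REP_TERMINATOR <- "QPYPSPFLP"   # Q-free tail keeps the repetitive/QI boundary sharp
ALPHA_EPITOPES <- c("DQ2.5-glia-a1a" = "PFPQPQLPY",
                    "DQ2.5-glia-a3" = "FRPQQPYPQ",
                    "p19" = "LGQQQPFPPQQPYPQPQPF")
# unique-domain templates: 4 cysteines in UI, 2 in UII; one arginine of UI
# is encoded by CGA when that codon is drawn, enabling CGA->TGA events.
# mutate_template() may substitute residues other than C/Q/P/W, giving each
# gene private chymotryptic peptides while preserving the cysteine skeleton
# and tract boundaries (templates start and end with non-Q residues).
ALPHA_UI_CORE <- "SVNVLQQSTYQLLQELCCQHLWQIPEQSRCDVVLQQHNIAHACSSHE"
ALPHA_UII_CORE <- "SNVAGKSQVLQQSSYQLLQQLCNVNVPLGTTLLHILSGQGSCVNVE"

GAMMA_EPITOPES <- c("DQ2.5-glia-g5" = "QQPFPQQPQ",
                    "DQ2.5-glia-g2" = "IQPQQPAQL")
GAMMA_I <- "NIQVDPSGQVQW"                       # mature N-terminal stub
GAMMA_III_CYS <- paste0("IQPSLQQQLNPCKNILLQQCKPASLVSSLWSIIWPQSDCQVMRQQCC",
                        "QQLAQIPQQLQCAAIHSVVHSIIMH")   # six cysteines
GAMMA_V <- "VAGIGIIQPQQPAQLEAIRSLVLQTLPSMCNVYIPPYCSTIRAPFASIVAGIGGQ"

OMEGA_REP_POOL <- c("PFPQQPQQ", "PFPQPQQ", "QQQP", "QQFPQQ", "QQIPQQQ")
OMEGA_NTERM <- "ARQLNPSHE"       # mature start: ARQ type by default
OMEGA_CTERM <- "AIYSIAHGDSHE"    # no repeat units/Q runs; acidic residues
                                 # keep the pI in the gel's working range

mutate_template <- function(template, n_sub = 3) {
  # substitute a few non-critical residues so every gene's unique domains
  # carry private peptides; C, Q, P and W positions are left untouched
  chars <- strsplit(template, "")[[1]]
  mutable <- which(!chars %in% c("C", "Q", "P", "W", "*"))
  alphabet <- c("A", "S", "T", "V", "I", "L", "N", "D", "E", "G", "H", "K")
  if (length(mutable) == 0 || n_sub == 0) return(template)
  pick <- sample(mutable, min(n_sub, length(mutable)))
  for (p in pick) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

build_alpha_gene <- function(cfg) {
  rates <- cfg$epitope_plant_rates
  planted <- names(rates)[stats::runif(length(rates)) < rates]

  rep_units <- sample(ALPHA_REP_UNITS, sample(3:6, 1), replace = TRUE)
  for (e in intersect(planted, c("DQ2.5-glia-a1a", "DQ2.5-glia-a3", "p19"))) {
    at <- sample(seq_len(length(rep_units) + 1), 1)
    rep_units <- append(rep_units, ALPHA_EPITOPES[[e]], after = at - 1)
  }
  rep_units <- c(rep_units, ALPHA_REP_TERMINATOR)
  repetitive <- paste(rep_units, collapse = "")

  qi_len <- sample_len(cfg$qi_range)
  qii_len <- sample_len(cfg$qii_range)
  ui <- mutate_template(ALPHA_UI_CORE)
  uii <- mutate_template(ALPHA_UII_CORE)
  if ("p12" %in% planted) uii <- paste0("NVLLGQGSFRPSQQN", uii)
  if ("DQ8-glia-a1" %in% planted) uii <- paste0(uii, "QGSFQPSQQ")

  aa_parts <- list(signal = SIGNAL_ALPHA, repetitive = repetitive,
                   QI = strrep("Q", qi_len), UI = ui,
                   QII = strrep("Q", qii_len), UII = uii)
  lens <- vapply(aa_parts, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  boundaries <- tibble::tibble(label = names(aa_parts),
                               start = as.integer(starts),
                               end = as.integer(ends))
  nt <- paste0(
    reverse_translate(aa_parts$signal),
    reverse_translate(aa_parts$repetitive),
    polyq_codons(qi_len, cfg$polyq_codon_weights),
    reverse_translate(aa_parts$UI),
    polyq_codons(qii_len, cfg$polyq_codon_weights),
    reverse_translate(aa_parts$UII)
  )
  list(type = "alpha", nt = nt, protein = paste(unlist(aa_parts),
                                                collapse = ""),
       boundaries = boundaries, planted_epitopes = planted)
}

build_gamma_gene <- function(cfg) {
  n_units <- sample(6:9, 1)
  units <- sample(c("PFPQPQQ", "PFPQQPQQ", "PFPQPQQPQQ", "PFPQQPQQPQQ"),
                  n_units, replace = TRUE)
  planted <- character()
  if (stats::runif(1) < 0.5) {
    # plant a gamma epitope strictly inside the repetitive domain
    at <- sample(2:n_units, 1)
    units <- append(units, GAMMA_EPITOPES[["DQ2.5-glia-g5"]], after = at - 1)
    planted <- c(planted, "DQ2.5-glia-g5")
  }
  ii <- paste(units, collapse = "")
  iv_len <- sample(10:20, 1)
  iii <- mutate_template(GAMMA_III_CYS)
  v <- mutate_template(GAMMA_V)
  aa_parts <- list(signal = SIGNAL_GAMMA, I = GAMMA_I, II = ii,
                   III = iii, IV = strrep("Q", iv_len), V = v)
  lens <- vapply(aa_parts, nchar, integer(1))
  ends <- cumsum(lens)
  boundaries <- tibble::tibble(label = names(aa_parts),
                               start = as.integer(ends - lens + 1L),
                               end = as.integer(ends))
  nt <- paste0(
    reverse_translate(aa_parts$signal), reverse_translate(aa_parts$I),
    reverse_translate(aa_parts$II), reverse_translate(aa_parts$III),
    polyq_codons(iv_len, cfg$polyq_codon_weights),
    reverse_translate(aa_parts$V)
  )
  list(type = "gamma", nt = nt,
       protein = paste(unlist(aa_parts), collapse = ""),
       boundaries = boundaries, planted_epitopes = planted)
}

build_omega_gene <- function(cfg) {
  # weights keep the overall Q:P:F composition near the canonical 4:3:1
  units <- sample(OMEGA_REP_POOL, sample(18:28, 1), replace = TRUE,
                  prob = c(0.6, 0.2, 0.1, 0.05, 0.05))
  repetitive <- paste(units, collapse = "")
  aa_parts <- list(signal = SIGNAL_OMEGA, `N-terminal` = OMEGA_NTERM,
                   repetitive = repetitive, `C-terminal` = OMEGA_CTERM)
  lens <- vapply(aa_parts, nchar, integer(1))
  ends <- cumsum(lens)
  boundaries <- tibble::tibble(label = names(aa_parts),
                               start = as.integer(ends - lens + 1L),
                               end = as.integer(ends))
  nt <- paste(vapply(aa_parts, reverse_translate, character(1)),
              collapse = "")
  list(type = "omega", nt = nt,
       protein = paste(unlist(aa_parts), collapse = ""),
       boundaries = boundaries, planted_epitopes = character())
}

synonymous_copy <- function(nt, n_syn = 6) {
  # re-draw a handful of codons synonymously: identical protein, distinct CDS
  codons <- split_codons(nt)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  idx <- which(vapply(aa, function(a) length(SYN_CODONS[[a]]) > 1,
                      logical(1)))
  pick <- sample(idx, min(n_syn, length(idx)))
  for (i in pick) {
    alt <- setdiff(SYN_CODONS[[aa[i]]], codons[i])
    codons[i] <- alt[sample.int(length(alt), 1)]
  }
  paste(codons, collapse = "")
}

pseudogenize <- function(gene, cfg) {
  nt <- gene$nt
  codons <- split_codons(nt)
  if (stats::runif(1) < cfg$frameshift_rate) {
    # single-base deletion inside the gene body (after the signal peptide)
    pos <- sample(seq(63L, nchar(nt) - 30L), 1)
    ref_chars <- strsplit(nt, "")[[1]]
    norm <- left_normalize_indel(ref_chars, pos, ref_chars[pos])
    mutated <- paste0(substr(nt, 1, pos - 1), substring(nt, pos + 1))
    return(list(nt = mutated, kind = "frameshift",
                events = tibble::tibble(cds_position = as.integer(norm),
                                        kind = "deletion", length = 1L)))
  }
  n_stops <- sample(seq_len(cfg$stop_rate_per_gene), 1)
  qi <- gene$boundaries[gene$boundaries$label %in% c("QI", "IV"), ]
  q_codon_idx <- which(codons %in% c("CAA", "CAG"))
  q_codon_idx <- q_codon_idx[q_codon_idx > 20]   # never in the signal
  events <- list()
  chosen <- integer()
  for (k in seq_len(n_stops)) {
    pool <- setdiff(q_codon_idx, chosen)
    if (nrow(qi) == 1 && k == 1 && stats::runif(1) < 0.6) {
      in_qi <- pool[pool >= ceiling(qi$start) & pool <= qi$end]
      if (length(in_qi) > 0) pool <- in_qi
    }
    if (length(pool) == 0) break
    ci <- pool[sample.int(length(pool), 1)]
    chosen <- c(chosen, ci)
    ref_codon <- codons[ci]
    obs <- sub("^C", "T", ref_codon)
    codons[ci] <- obs
    events[[length(events) + 1]] <- tibble::tibble(
      codon_index = as.integer(ci), observed_codon = obs,
      reference_codon = ref_codon,
      origin = paste0(ref_codon, "->", obs))
  }
  # occasionally convert a CGA arginine codon instead
  if (stats::runif(1) < cfg$cga_rate) {
    cga <- which(codons == "CGA")
    if (length(cga) > 0) {
      ci <- cga[sample.int(length(cga), 1)]
      codons[ci] <- "TGA"
      events[[length(events) + 1]] <- tibble::tibble(
        codon_index = as.integer(ci), observed_codon = "TGA",
        reference_codon = "CGA", origin = "CGA->TGA")
    }
  }
  ev <- dplyr::bind_rows(events)
  ev <- ev[order(ev$codon_index), ]
  list(nt = paste(codons, collapse = ""), kind = "stop", events = ev)
}

#' Generate a synthetic gliadin gene family with full ground truth
#'
#' Active genes are constructed independently domain by domain (a fraction
#' of active alpha genes are synonymous copies of an earlier active gene,
#' giving near-identical proteins that later co-migrate on the gel).
#' Pseudogenes are mutated copies of active family members: 1-3 C-to-T
#' stops at glutamine codons (occasionally the planted CGA arginine
#' codon), or rarely a single-base deletion.
#'
#' @param config A [sim_config()] list.
#' @return List with `records` (tibble id/description/sequence of CDS) and
#'   `truth` (per-gene list: type, orf status, parent, domain boundaries,
#'   planted epitopes, stop/frameshift events, spot group).
#' @export
generate_family <- function(config = sim_config()) {
  with_seed(config$seed, {
    specs <- c(rep("alpha", config$n_alpha), rep("gamma", config$n_gamma),
               rep("omega", config$n_omega))
    counters <- c(alpha = 0L, gamma = 0L, omega = 0L)
    records <- list()
    truth <- list()
    active_by_type <- list(alpha = list(), gamma = list(), omega = list())

    is_pseudo <- stats::runif(length(specs)) < config$pseudogene_fraction
    # every represented type keeps at least one active gene, so each
    # pseudogene has a full-ORF relative to be compared against
    for (tp in unique(specs)) {
      idx <- which(specs == tp)
      if (all(is_pseudo[idx])) is_pseudo[idx[1]] <- FALSE
    }
    # build active genes first so pseudogenes can copy a real parent
    ord <- order(is_pseudo)
    for (k in ord) {
      type <- specs[k]
      counters[type] <- counters[type] + 1L
      id <- sprintf("Gli-%s-%d", type, counters[type])
      if (!is_pseudo[k]) {
        dup_pool <- active_by_type[[type]]
        if (type == "alpha" && length(dup_pool) > 0 &&
            stats::runif(1) < config$duplicate_fraction) {
          parent <- dup_pool[[sample.int(length(dup_pool), 1)]]
          gene <- parent
          gene$nt <- synonymous_copy(parent$nt)
          gene$copy_of <- parent$id
        } else {
          gene <- switch(type,
                         alpha = build_alpha_gene(config),
                         gamma = build_gamma_gene(config),
                         omega = build_omega_gene(config))
          gene$copy_of <- NA_character_
        }
        gene$id <- id
        active_by_type[[type]] <- c(active_by_type[[type]], list(gene))
        truth[[id]] <- list(
          id = id, type = type, status = "full_orf",
          parent = NA_character_, copy_of = gene$copy_of,
          boundaries = gene$boundaries,
          planted_epitopes = gene$planted_epitopes,
          stop_events = tibble::tibble(), frameshift_events = tibble::tibble()
        )
        records[[id]] <- gene
      } else {
        pool <- active_by_type[[type]]
        if (length(pool) > 0) {
          parent <- pool[[sample.int(length(pool), 1)]]
        } else {
          # no active relative in the family: derive from a hidden one
          parent <- switch(type,
                           alpha = build_alpha_gene(config),
                           gamma = build_gamma_gene(config),
                           omega = build_omega_gene(config))
          parent$id <- NA_character_
        }
        mut <- pseudogenize(parent, config)
        status <- if (mut$kind == "frameshift") "pseudo_frameshift" else
          "pseudo_stop"
        truth[[id]] <- list(
          id = id, type = type, status = status,
          parent = parent$id, copy_of = NA_character_,
          boundaries = parent$boundaries,
          planted_epitopes = parent$planted_epitopes,
          stop_events = if (mut$kind == "stop") mut$events else
            tibble::tibble(),
          frameshift_events = if (mut$kind == "frameshift") mut$events else
            tibble::tibble()
        )
        records[[id]] <- list(type = type, nt = mut$nt)
      }
    }
    # natural catalogue order: by type, then gene number
    ids <- names(truth)
    type_of <- vapply(truth, function(t) t$type, character(1))
    num_of <- as.integer(sub("^.*-", "", ids))
    ord_ids <- ids[order(match(type_of, c("alpha", "gamma", "omega")),
                         num_of)]
    truth <- truth[ord_ids]
    records <- records[ord_ids]
    recs <- tibble::tibble(
      id = ord_ids,
      description = vapply(ord_ids, function(i) {
        paste0("synthetic ", truth[[i]]$type, "-gliadin ", truth[[i]]$status)
      }, character(1)),
      sequence = unname(vapply(records, function(g) g$nt, character(1)))
    )
    list(records = recs, truth = truth, config = config)
  })
}

#' Generate a stage-resolved expression count matrix from family truth
#'
#' Active (full-ORF) genes follow the grain-filling shape: silent at
#' 5 DPA, rise at 10, peak at 15, decline through 20-25 DPA; flag leaf is
#' background only. Pseudogenes receive background counts everywhere.
#' Counts are negative-binomial around the RPKM-implied means.
#'
#' @param family Output of [generate_family()].
#' @param config The [sim_config()] used (defaults to the family's).
#' @param seed Optional seed overriding `config$seed + 1`.
#' @return List with `counts` (matrix), `samples` (sheet),
#'   `gene_lengths`, and truth columns `expressed`, `stable` per gene.
#' @export
generate_expression <- function(family, config = family$config,
                                seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 1L
  truth <- family$truth
  genes <- names(truth)
  gene_lengths <- stats::setNames(nchar(family$records$sequence),
                                  family$records$id)[genes]
  with_seed(seed, {
    stages <- names(config$stage_multipliers)
    samples <- tibble::tibble(
      sample = paste0(rep(stages, each = config$n_replicates), "_r",
                      rep(seq_len(config$n_replicates), length(stages))),
      stage = rep(stages, each = config$n_replicates),
      replicate = rep(seq_len(config$n_replicates), length(stages)),
      library_size = round(stats::rnorm(length(stages) * config$n_replicates,
                                        config$library_size_mean,
                                        config$library_size_sd))
    )
    active <- vapply(truth, function(t) t$status == "full_orf", logical(1))
    peak <- stats::setNames(numeric(length(genes)), genes)
    peak[active] <- stats::rlnorm(sum(active), config$peak_rpkm_meanlog,
                                  config$peak_rpkm_sdlog)
    stable <- stats::setNames(rep(FALSE, length(genes)), genes)
    act_ids <- genes[active]
    n_stable <- round(config$stable_fraction * length(act_ids))
    if (n_stable > 0) stable[sample(act_ids, n_stable)] <- TRUE

    counts <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (g in genes) {
      mult <- config$stage_multipliers
      if (stable[g]) mult[c("10", "20")] <- stats::runif(2, 0.85, 0.95)
      for (j in seq_len(nrow(samples))) {
        st <- samples$stage[j]
        target_rpkm <- if (active[g] && st != "leaf") {
          max(peak[g] * mult[[st]], config$background_rpkm)
        } else {
          config$background_rpkm
        }
        mu <- target_rpkm * samples$library_size[j] * gene_lengths[g] / 1e9
        counts[g, j] <- stats::rnbinom(1, size = config$nb_size, mu = mu)
      }
    }
    list(counts = counts, samples = samples, gene_lengths = gene_lengths,
         expressed = stats::setNames(active, genes), stable = stable)
  })
}

#' Generate a 2-DE spot table (with peptides) from family truth
#'
#' Each group of near-identical active proteins (pairwise identity above
#' `identity_merge`, which here means synonymous copies) yields one spot;
#' spot MW/pI are the predicted values with small jitter; the peptide list
#' is sampled from the chymotryptic digests of the member proteins.
#'
#' @param family Output of [generate_family()].
#' @param physchem Optional precomputed [physchem_table()] of the active
#'   proteins; computed when `NULL`.
#' @param digests Optional named list of digest tibbles; computed when
#'   `NULL`.
#' @param config The [sim_config()] used.
#' @param seed Optional seed overriding `config$seed + 2`.
#' @return List with `spot_table` (long tibble incl. peptides) and
#'   `truth_membership` (named list spot id -> member genes).
#' @export
generate_spots <- function(family, physchem = NULL, digests = NULL,
                           config = family$config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 2L
  truth <- family$truth
  active_ids <- names(truth)[vapply(truth, function(t)
    t$status == "full_orf", logical(1))]
  proteins <- stats::setNames(
    vapply(active_ids, function(i) {
      translate_cds_quiet(family$records$sequence[family$records$id == i])
    }, character(1)), active_ids)
  if (is.null(physchem)) physchem <- physchem_table(proteins)
  if (is.null(digests)) {
    digests <- lapply(proteins, chymotryptic_digest)
  }
  # cluster identical/near-identical proteins (synonymous copies)
  groups <- list()
  for (id in active_ids) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      rep_id <- groups[[gi]][1]
      pa <- proteins[[rep_id]]
      pb <- proteins[[id]]
      sim <- if (nchar(pa) == nchar(pb)) {
        mean(strsplit(pa, "")[[1]] == strsplit(pb, "")[[1]])
      } else 0
      if (sim >= config$identity_merge) {
        groups[[gi]] <- c(groups[[gi]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- id
  }
  with_seed(seed, {
    vols <- stats::rgamma(length(groups), shape = 1.2)
    vols <- pmax(round(100 * vols / sum(vols), 2), 0.01)
    big <- which.max(vols)
    vols[big] <- round(vols[big] + (100 - sum(vols)), 2)  # printed-sum scale
    rows <- list()
    membership <- list()
    for (k in seq_along(groups)) {
      members <- groups[[k]]
      membership[[as.character(k)]] <- members
      pc <- physchem[physchem$gene == members[1], ]
      pep_pool <- unique(unlist(lapply(members, function(m) {
        d <- digests[[m]]
        d$sequence[nchar(d$sequence) >= 7]
      })))
      n_pep <- sample_len(config$peptides_per_spot)
      peps <- sample(pep_pool, min(n_pep, length(pep_pool)))
      rows[[k]] <- tibble::tibble(
        spot_id = k, percent_volume = vols[k],
        gene = paste(members, collapse = ";"),
        mw_kd = round(pc$mw_kd + stats::rnorm(1, 0, 0.3), 2),
        pi = round(pmin(pmax(pc$pi + stats::rnorm(1, 0, 0.05), 0.1), 13.9),
                   2),
        peptides = paste(peps, collapse = ";")
      )
    }
    list(spot_table = dplyr::bind_rows(rows), truth_membership = membership)
  })
}

#' Write a complete simulated dataset to disk
#'
#' Emits `family.fasta`, `truth.json`, `counts.tsv`, `samples.tsv` and
#' `spots.tsv` into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fam <- generate_family(config)
  expr <- generate_expression(fam, config)
  spots <- generate_spots(fam, config = config)
  write_fasta(fam$records, file.path(out_dir, "family.fasta"))
  jsonlite::write_json(
    lapply(fam$truth, function(t) {
      t$boundaries <- as.data.frame(t$boundaries)
      t$stop_events <- as.data.frame(t$stop_events)
      t$frameshift_events <- as.data.frame(t$frameshift_events)
      t
    }),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  counts_out <- data.frame(gene = rownames(expr$counts), expr$counts,
                           check.names = FALSE)
  utils::write.table(counts_out, file.path(out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(expr$samples),
                     file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(spots$spot_table),
                     file.path(out_dir, "spots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(family = fam, expression = expr, spots = spots))
}
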