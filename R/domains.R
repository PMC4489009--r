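# Type inference and structural domain segmentation. Mature alpha-gliadins
# carry an N-terminal repetitive domain, two polyglutamine tracts (QI, QII)
# and two unique domains (UI, UII); gamma-gliadins the domains I-V with the
# polyglutamine region as domain IV; omega-gliadins an N-terminal region, a
# long repetitive region of hepta/octapeptide units and a C-terminal
# region. All coordinates are 1-based inclusive protein positions.

ALPHA_DOMAIN_LABELS <- c("signal", "repetitive", "QI", "UI", "QII", "UII")
GAMMA_DOMAIN_LABELS <- c("signal", "I", "II", "III", "IV", "V")
OMEGA_DOMAIN_LABELS <- c("signal", "N-terminal", "repetitive", "C-terminal")

GAMMA_REPEAT_UNITS <- c("PFPQPQQPQQ", "PFPQQPQQPQQ", "PFPQPQQ", "PFPQQPQQ")
# hepta/octapeptide units plus their common degenerate variants (QQQP
# tetrapeptides and the immunoreactive hexa/heptapeptides)
OMEGA_REPEAT_UNITS <- c("PFPQQPQQ", "PFPQPQQ", "QQQP", "QQFPQQ", "QQIPQQQ",
                        "QQFHQQQ", "QQLPQQQ")

#' Default analysis configuration
#'
#' @param signal_length Named list of fixed signal-peptide lengths per type
#'   (residues). The gamma value follows the described 20-residue signal;
#'   alpha defaults to the same length, omega to 19.
#' @param min_polyq Minimum polyglutamine tract length (residues).
#' @param polyq_q_fraction Minimum Q fraction within a tract.
#' @param polyq_merge_gap Merge tracts separated by at most this many
#'   residues.
#' @param repeat_coverage Minimum repeat-unit coverage for a repetitive
#'   domain.
#' @param expression_threshold RPKM above which a grain-stage mean marks a
#'   gene as expressed.
#' @param stability_fraction Flanking-stage fraction of the 15-DPA level
#'   required for a stable profile.
#' @param gap_open,gap_extend Alignment gap penalties (ORF module).
#' @param tol_mw_kd,tol_pi Spot-consistency tolerances.
#' @return Named list of configuration values.
#' @export
gliadin_config <- function(signal_length = list(alpha = 20L, gamma = 20L,
                                                omega = 19L),
                           min_polyq = 6L, polyq_q_fraction = 0.8,
                           polyq_merge_gap = 2L, repeat_coverage = 0.6,
                           expression_threshold = 1000,
                           stability_fraction = 0.70,
                           gap_open = 5, gap_extend = 1,
                           tol_mw_kd = 3.0, tol_pi = 0.5) {
  list(signal_length = signal_length, min_polyq = min_polyq,
       polyq_q_fraction = polyq_q_fraction, polyq_merge_gap = polyq_merge_gap,
       repeat_coverage = repeat_coverage,
       expression_threshold = expression_threshold,
       stability_fraction = stability_fraction,
       gap_open = gap_open, gap_extend = gap_extend,
       tol_mw_kd = tol_mw_kd, tol_pi = tol_pi)
}

#' Read a YAML configuration file, filling unspecified keys with defaults
#' @param path YAML file whose keys override [gliadin_config()] defaults.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- gliadin_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

#' Find polyglutamine tracts
#'
#' A tract is a maximal region that starts and ends with Q, has at least
#' `q_fraction` glutamine, and is at least `min_len` residues long;
#' glutamine runs separated by gaps of at most `merge_gap` non-Q residues
#' are merged when the merged region still meets the Q-fraction rule.
#'
#' @param protein Amino-acid string.
#' @param min_len,q_fraction,merge_gap Tract definition parameters.
#' @return Tibble with `start`, `end`, `length`, `n_q`.
#' @export
find_polyq_tracts <- function(protein, min_len = 6L, q_fraction = 0.8,
                              merge_gap = 2L) {
  chars <- strsplit(protein, "")[[1]]
  r <- rle(chars == "Q")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer(), n_q = integer()))
  }
  # merge neighbouring Q runs across short gaps while the Q fraction holds
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    gap <- runs$start[i] - merged$end[last] - 1L
    if (gap <= merge_gap) {
      cand_start <- merged$start[last]
      cand_end <- runs$end[i]
      nq <- sum(chars[cand_start:cand_end] == "Q")
      if (nq / (cand_end - cand_start + 1L) >= q_fraction) {
        merged$end[last] <- cand_end
        next
      }
    }
    merged <- rbind(merged, runs[i, ])
  }
  len <- merged$end - merged$start + 1L
  keep <- len >= min_len
  tibble::tibble(
    start = as.integer(merged$start[keep]),
    end = as.integer(merged$end[keep]),
    length = as.integer(len[keep]),
    n_q = vapply(which(keep), function(i) {
      sum(chars[merged$start[i]:merged$end[i]] == "Q")
    }, integer(1))
  )
}

count_pattern <- function(protein, pattern) {
  m <- gregexpr(pattern, protein, fixed = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

match_starts <- function(protein, pattern) {
  # all (overlapping) start positions of a literal pattern
  L <- nchar(pattern)
  n <- nchar(protein)
  if (L > n || L == 0) return(integer())
  starts <- seq_len(n - L + 1L)
  starts[substring(protein, starts, starts + L - 1L) == pattern]
}

unit_matches <- function(protein, units) {
  res <- lapply(units, function(u) {
    st <- match_starts(protein, u)
    if (length(st) == 0) NULL else data.frame(start = st,
                                              end = st + nchar(u) - 1L)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(start = integer(), end = integer()) else
    out[order(out$start, out$end), , drop = FALSE]
}

coverage_fraction <- function(matches, from, to) {
  if (to < from) return(0)
  cov <- rep(FALSE, to - from + 1L)
  for (i in seq_len(nrow(matches))) {
    a <- max(matches$start[i], from)
    b <- min(matches$end[i], to)
    if (a <= b) cov[(a - from + 1L):(b - from + 1L)] <- TRUE
  }
  mean(cov)
}

#' Infer the gliadin type of a predicted protein
#'
#' Decision is score-based: the cysteine census (about six conserved
#' cysteines in alpha, eight in gamma, none in omega), the presence of two
#' separated polyglutamine tracts (alpha), PFPQ(1-2)(PQQ)(1-2) repeat
#' content (gamma), and hepta/octapeptide repeat content (omega).
#'
#' @param protein Amino-acid string (conceptual translation; `*` allowed),
#'   at least 50 residues.
#' @param config Configuration list from [gliadin_config()].
#' @return One of `"alpha"`, `"gamma"`, `"omega"`, `"unknown"`.
#' @export
infer_gliadin_type <- function(protein, config = gliadin_config()) {
  protein <- toupper(trimws(protein))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", protein)) {
    stop("protein contains non-standard residues")
  }
  if (nchar(protein) < 50) stop("protein shorter than 50 residues")
  ncys <- count_pattern(protein, "C")
  tracts <- find_polyq_tracts(protein, config$min_polyq,
                              config$polyq_q_fraction, config$polyq_merge_gap)
  n_tracts <- nrow(tracts)
  gamma_units <- nrow(unit_matches(protein, GAMMA_REPEAT_UNITS))
  omega_units <- nrow(unit_matches(protein,
                                   c("PFPQPQQ", "PFPQQPQQ", "QQQP")))
  scores <- c(
    alpha = 2 * (ncys >= 5 && ncys <= 7) + (n_tracts >= 2),
    gamma = 2 * (ncys >= 8) + (gamma_units >= 3),
    omega = 3 * (ncys == 0) + (omega_units >= 2)
  )
  if (max(scores) < 2 || sum(scores == max(scores)) > 1) return("unknown")
  names(scores)[which.max(scores)]
}

empty_domain <- function(label, at) {
  data.frame(label = label, start = as.integer(at), end = as.integer(at - 1L))
}

#' Segment a gliadin protein into its type-specific ordered domains
#'
#' The signal peptide is a fixed-length prefix (configurable per type).
#' Alpha: the first polyglutamine tract after the signal is QI, the second
#' QII; the region before QI is the repetitive domain, between the tracts
#' UI, after QII UII. Gamma: the dominant (longest) tract is domain IV; the
#' maximal region covered by PFPQ(1-2)(PQQ)(1-2) units is the repetitive
#' domain II; remaining gaps become domains I, III and V. Omega: the
#' maximal region covered by hepta/octapeptide (and QQQP) units is the
#' repetitive region, its flanks the N- and C-terminal regions. Empty
#' domains are permitted (represented with `end = start - 1`).
#'
#' @param protein Amino-acid string.
#' @param gliadin_type `"alpha"`, `"gamma"` or `"omega"`.
#' @param config Configuration list; see [gliadin_config()].
#' @param gene_id Identifier carried into the annotation.
#' @param signal_length Optional per-gene override of the signal length.
#' @return Object of class `protein_annotation`: list with `gene_id`,
#'   `protein`, `gliadin_type`, `domains` (tibble label/start/end, a
#'   partition of 1..nchar(protein)), `mature_start`, `warning` (character,
#'   possibly empty).
#' @export
segment_domains <- function(protein, gliadin_type, config = gliadin_config(),
                            gene_id = "protein", signal_length = NULL) {
  protein <- toupper(trimws(protein))
  n <- nchar(protein)
  sig_len <- as.integer(
    if (!is.null(signal_length)) signal_length
    else config$signal_length[[gliadin_type]]
  )
  if (is.na(sig_len) || sig_len >= n) stop("signal length exceeds protein")
  warn <- character()
  sig_end <- sig_len
  tracts <- find_polyq_tracts(protein, config$min_polyq,
                              config$polyq_q_fraction, config$polyq_merge_gap)
  tracts <- tracts[tracts$start > sig_end, , drop = FALSE]

  if (gliadin_type == "alpha") {
    if (nrow(tracts) == 0) {
      warn <- c(warn, "no polyglutamine tract found; QI and QII empty")
      dom <- rbind(
        data.frame(label = "signal", start = 1L, end = sig_end),
        data.frame(label = "repetitive", start = sig_end + 1L, end = n),
        empty_domain("QI", n + 1L), empty_domain("UI", n + 1L),
        empty_domain("QII", n + 1L), empty_domain("UII", n + 1L)
      )
    } else if (nrow(tracts) == 1) {
      warn <- c(warn, "fewer than two polyglutamine tracts; QII empty")
      q1 <- tracts[1, ]
      dom <- rbind(
        data.frame(label = "signal", start = 1L, end = sig_end),
        data.frame(label = "repetitive", start = sig_end + 1L,
                   end = q1$start - 1L),
        data.frame(label = "QI", start = q1$start, end = q1$end),
        data.frame(label = "UI", start = q1$end + 1L, end = n),
        empty_domain("QII", n + 1L), empty_domain("UII", n + 1L)
      )
    } else {
      q1 <- tracts[1, ]
      q2 <- tracts[2, ]
      dom <- rbind(
        data.frame(label = "signal", start = 1L, end = sig_end),
        data.frame(label = "repetitive", start = sig_end + 1L,
                   end = q1$start - 1L),
        data.frame(label = "QI", start = q1$start, end = q1$end),
        data.frame(label = "UI", start = q1$end + 1L, end = q2$start - 1L),
        data.frame(label = "QII", start = q2$start, end = q2$end),
        data.frame(label = "UII", start = q2$end + 1L, end = n)
      )
    }
  } else if (gliadin_type == "gamma") {
    if (nrow(tracts) == 0) stop("no polyglutamine tract for gamma domain IV")
    iv <- tracts[which.max(tracts$length), ]       # dominant tract
    um <- unit_matches(protein, GAMMA_REPEAT_UNITS)
    um <- um[um$start > sig_end & um$end < iv$start, , drop = FALSE]
    if (nrow(um) == 0) {
      warn <- c(warn, "no repeat units found; domain II empty")
      ii_start <- sig_end + 1L; ii_end <- sig_end
    } else {
      # trim outermost matches until coverage of the spanned region holds
      while (nrow(um) > 1 &&
             coverage_fraction(um, min(um$start), max(um$end)) <
               config$repeat_coverage) {
        gaps_left <- um$start[2] - um$start[1]
        gaps_right <- um$end[nrow(um)] - um$end[nrow(um) - 1]
        if (gaps_left >= gaps_right) um <- um[-1, , drop = FALSE]
        else um <- um[-nrow(um), , drop = FALSE]
      }
      ii_start <- min(um$start); ii_end <- max(um$end)
    }
    dom <- rbind(
      data.frame(label = "signal", start = 1L, end = sig_end),
      data.frame(label = "I", start = sig_end + 1L, end = ii_start - 1L),
      data.frame(label = "II", start = ii_start, end = ii_end),
      data.frame(label = "III", start = ii_end + 1L, end = iv$start - 1L),
      data.frame(label = "IV", start = iv$start, end = iv$end),
      data.frame(label = "V", start = iv$end + 1L, end = n)
    )
  } else if (gliadin_type == "omega") {
    um <- unit_matches(protein, OMEGA_REPEAT_UNITS)
    um <- um[um$start > sig_end, , drop = FALSE]
    if (nrow(um) == 0) {
      warn <- c(warn, "no repeat units found; repetitive region empty")
      rep_start <- n + 1L; rep_end <- n
      dom <- rbind(
        data.frame(label = "signal", start = 1L, end = sig_end),
        data.frame(label = "N-terminal", start = sig_end + 1L, end = n),
        empty_domain("repetitive", n + 1L),
        empty_domain("C-terminal", n + 1L)
      )
    } else {
      rep_start <- min(um$start); rep_end <- max(um$end)
      dom <- rbind(
        data.frame(label = "signal", start = 1L, end = sig_end),
        data.frame(label = "N-terminal", start = sig_end + 1L,
                   end = rep_start - 1L),
        data.frame(label = "repetitive", start = rep_start, end = rep_end),
        data.frame(label = "C-terminal", start = rep_end + 1L, end = n)
      )
    }
  } else {
    stop("unknown gliadin type: ", gliadin_type)
  }

  dom <- tibble::as_tibble(dom)
  dom$start <- as.integer(dom$start); dom$end <- as.integer(dom$end)
  check_partition(dom, n, gene_id)
  structure(
    list(gene_id = gene_id, protein = protein, gliadin_type = gliadin_type,
         domains = dom, mature_start = sig_end + 1L, warning = warn),
    class = "protein_annotation"
  )
}

# every segmentation must partition 1..n (empty domains allowed)
check_partition <- function(dom, n, gene_id) {
  nonempty <- dom[dom$end >= dom$start, , drop = FALSE]
  lens <- nonempty$end - nonempty$start + 1L
  if (sum(lens) != n) {
    stop("domain segmentation of ", gene_id, " does not cover the protein (",
         sum(lens), " vs ", n, " residues)")
  }
  ord <- order(nonempty$start)
  if (any(nonempty$start[ord][-1] != nonempty$end[ord][-nrow(nonempty)] + 1L)) {
    stop("domain segmentation of ", gene_id, " has gaps or overlaps")
  }
  invisible(TRUE)
}

domain_of_position <- function(annotation, pos) {
  dom <- annotation$domains
  hit <- dom$label[dom$start <= pos & dom$end >= pos]
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Polyglutamine tract length profile for alpha annotations
#'
#' @param annotations List of alpha `protein_annotation` objects.
#' @return Tibble with per-gene QI/QII residue lengths and nucleotide
#'   extents (3 bp per residue); attributes `qi_nt_range` holds the
#'   min/max QI extent.
#' @export
polyq_length_profile <- function(annotations) {
  if (inherits(annotations, "protein_annotation")) {
    annotations <- list(annotations)
  }
  rows <- lapply(annotations, function(ann) {
    dom <- ann$domains
    qi <- dom[dom$label == "QI", ]
    qii <- dom[dom$label == "QII", ]
    qi_len <- max(0L, qi$end - qi$start + 1L)
    qii_len <- max(0L, qii$end - qii$start + 1L)
    tibble::tibble(gene_id = ann$gene_id, qi_len = qi_len, qii_len = qii_len,
                   qi_nt = 3L * qi_len, qii_nt = 3L * qii_len)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "qi_nt_range") <- if (nrow(out)) range(out$qi_nt) else c(NA, NA)
  out
}

#' Non-glutamine residues inside the QI/QII tracts of an alpha annotation
#' @param annotation Alpha `protein_annotation`.
#' @return List with character vectors `qI` and `qII` of non-Q residues.
#' @export
polyq_variants <- function(annotation) {
  chars <- strsplit(annotation$protein, "")[[1]]
  get <- function(lab) {
    d <- annotation$domains[annotation$domains$label == lab, ]
    if (nrow(d) == 0 || d$end < d$start) return(character())
    seg <- chars[d$start:d$end]
    seg[seg != "Q"]
  }
  list(qI = get("QI"), qII = get("QII"))
}
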