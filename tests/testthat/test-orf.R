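test_that("translation follows the standard code and the length arithmetic", {
  expect_equal(translate_cds("ATGGGT"), "MG")

  set.seed(42)
  prot <- random_protein(341, pool = names(ORACLE_AVG_MASS))
  cds <- paste0("ATG", vapply(strsplit(prot, "")[[1]], function(a) {
    cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    cods[1]
  }, character(1)) |> paste(collapse = ""))
  expect_equal(nchar(cds), 1026)             # 342 codons -> 342 residues
  expect_equal(nchar(translate_cds(cds)), 342)
  expect_equal(translate_cds(cds), paste0("M", prot))

  # codon-by-codon oracle via an independent translator
  set.seed(7)
  cds2 <- random_cds_stop_free(300)
  oracle <- paste(seqinr::translate(strsplit(tolower(cds2), "")[[1]]),
                  collapse = "")
  expect_equal(suppressWarnings(translate_cds(cds2)), oracle)

  expect_error(translate_cds("ATGG"), "divisible")
  expect_error(translate_cds("ATGXYZ"), "illegal")
  expect_warning(translate_cds("GGGAAA"), "ATG")
})

test_that("internal stops are found exactly where planted", {
  set.seed(11)
  cds <- paste0("ATG", random_cds_stop_free(99))
  expect_equal(nrow(find_internal_stops(cds)), 0)

  mutated <- paste0(substr(cds, 1, 147), "TAG", substring(cds, 151))
  ev <- find_internal_stops(mutated)
  expect_equal(ev$codon_index, 50L)
  expect_equal(ev$observed_codon, "TAG")
  expect_equal(ev$origin, "unexplained")
})

test_that("stop-codon origins follow the single C-to-T rule", {
  expect_equal(classify_stop_origin("TAG", "CAG"), "CAG->TAG")
  expect_equal(classify_stop_origin("TAA", "CAA"), "CAA->TAA")
  expect_equal(classify_stop_origin("TGA", "CGA"), "CGA->TGA")
  expect_equal(classify_stop_origin("TAA", "AAA"), "unexplained")
  expect_equal(classify_stop_origin("TAA", "CAG"), "unexplained")
  expect_equal(classify_stop_origin("TAG", "C-G"), "frameshift-induced")
  expect_error(classify_stop_origin("CAG", "CAG"), "not a stop")
})

test_that("frameshift deletions are localized against a reference", {
  set.seed(3)
  ref <- paste0("ATG", random_cds_stop_free(299))   # 900 bp
  # make bp 471 an unambiguous deletion target
  substr(ref, 470, 472) <- "ATG"
  q <- paste0(substr(ref, 1, 470), substring(ref, 472))
  ev <- detect_frameshift(q, ref)
  expect_equal(ev$cds_position, 471L)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$length, 1L)

  expect_equal(nrow(detect_frameshift(ref, ref)), 0)

  # no reference: position unknown but the broken frame is flagged
  unk <- detect_frameshift(substr(ref, 1, 899))
  expect_equal(unk$kind, "unknown")
})

test_that("planted 1-bp insertions are recovered at left-normalized positions", {
  set.seed(19)
  for (i in 1:15) {
    ref <- paste0("ATG", random_cds_stop_free(150))
    pos <- sample(30:420, 1)
    base <- sample(c("A", "C", "G", "T"), 1)
    q <- paste0(substr(ref, 1, pos - 1), base, substring(ref, pos))
    rc <- strsplit(ref, "")[[1]]
    truth <- pos
    while (truth > 1 && rc[truth - 1] == base) truth <- truth - 1
    ev <- detect_frameshift(q, ref)
    expect_equal(ev$kind, "insertion")
    expect_equal(ev$cds_position, as.integer(truth))
  }
})

test_that("ORF classification recovers generator ground truth completely", {
  fam <- generate_family(sim_config(seed = 13))
  rec <- measure_family_recovery(fam)
  expect_equal(rec$status[1], rec$status[2])   # 100% status recovery
  expect_equal(rec$origin[1], rec$origin[2])   # 100% origin recovery

  # a full-ORF panel classifies every clean gene as full_orf
  fam0 <- generate_family(sim_config(n_alpha = 12, n_gamma = 0, n_omega = 0,
                                     pseudogene_fraction = 0, seed = 4))
  panels <- family_panels(fam0)
  st <- vapply(names(fam0$truth), function(id) {
    classify_orf(fam0$records$sequence[fam0$records$id == id],
                 panels[[id]])$status
  }, character(1))
  expect_true(all(st == "full_orf"))
})

test_that("planted single mutants of a panel member are explained", {
  fam <- generate_family(sim_config(n_alpha = 3, n_gamma = 0, n_omega = 0,
                                    pseudogene_fraction = 0, seed = 8))
  nt <- fam$records$sequence[1]
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  cag <- which(codons == "CAG")
  ci <- cag[cag > 21][1]
  codons[ci] <- "TAG"
  mutant <- paste(codons, collapse = "")
  panel <- stats::setNames(fam$records$sequence, fam$records$id)
  res <- classify_orf(mutant, panel)
  expect_equal(res$status, "pseudo_stop")
  expect_equal(res$stop_events$codon_index, ci)
  expect_equal(res$stop_events$origin, "CAG->TAG")
  expect_equal(res$reference, fam$records$id[1])  # exact parent preferred
})

test_that("uniform C-to-T mutation creates stops preferentially at Q codons", {
  fam <- generate_family(sim_config(n_alpha = 1000, n_gamma = 0, n_omega = 0,
                                    pseudogene_fraction = 0, seed = 17))
  set.seed(99)
  stops_at_q <- 0; stops_total <- 0
  q_frac <- 0
  for (nt in fam$records$sequence) {
    chars <- strsplit(nt, "")[[1]]
    codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
    q_frac <- q_frac + mean(codons %in% c("CAA", "CAG"))
    cpos <- which(chars == "C")
    p <- sample(cpos, 1)
    chars[p] <- "T"
    mut_codons <- substring(paste(chars, collapse = ""),
                            seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
    new_stop <- which(mut_codons %in% c("TAA", "TAG", "TGA") &
                        !codons %in% c("TAA", "TAG", "TGA"))
    if (length(new_stop) > 0) {
      stops_total <- stops_total + 1
      if (codons[new_stop[1]] %in% c("CAA", "CAG")) {
        stops_at_q <- stops_at_q + 1
      }
    }
  }
  q_frac <- q_frac / nrow(fam$records)
  enrichment <- (stops_at_q / stops_total) / q_frac
  expect_gt(enrichment, 1)
})
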