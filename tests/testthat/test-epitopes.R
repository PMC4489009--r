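test_that("the shipped epitope library matches its declared structure", {
  lib <- epitope_library()
  expect_true(all(lib$length %in% c(4, 6, 7, 9, 12, 19)))
  expect_setequal(unique(lib$class), c("alpha", "gamma", "omega"))
  # deamidation-context pairs share one sequence
  expect_equal(sum(lib$sequence == "QQPQQPFPQ"), 2)
  expect_equal(sum(lib$sequence == "QQPQQPYPQ"), 2)
  expect_equal(sum(lib$sequence == "PQQSFPQQQ"), 2)
  # both reported omega hexapeptides are retained
  expect_true(all(c("QQPPQQ", "QQFPQQ") %in% lib$sequence))
})

test_that("epitope scanning reports every overlapping exact occurrence", {
  lib <- epitope_library()
  p <- paste0(strrep("A", 9), "FRPQQPYPQ", strrep("A", 10))
  hits <- scan_epitopes(p, lib)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 10L)
  expect_match(hits$names, "glia-α3")

  tetra <- lib[lib$sequence == "QQQP", ]
  hits2 <- scan_epitopes("QQQPQQQP", tetra)
  expect_equal(hits2$start, c(1L, 5L))

  # identical-sequence epitopes collapse into one named hit
  g4c <- scan_epitopes(paste0("AAA", "QQPQQPFPQ", "AAA"),
                       lib[lib$class == "gamma", ])
  expect_equal(nrow(g4c), 1)
  expect_match(g4c$names, "DQ2.5-glia-γ4c")
  expect_match(g4c$names, "DQ8-glia-γ1a")

  expect_error(scan_epitopes("QQQ", lib[0, ]), "empty")
})

test_that("epitope scanning equals the all-window oracle on random sequences", {
  lib <- epitope_library()
  set.seed(101)
  for (i in 1:20) {
    p <- random_protein(250)
    hits <- scan_epitopes(p, lib)
    oracle <- oracle_scan(p, lib$sequence)
    got <- hits[order(hits$sequence, hits$start), c("sequence", "start")]
    expect_equal(as.data.frame(got), oracle, ignore_attr = TRUE)
  }
})

test_that("hits are labelled with the domain containing their start", {
  fam <- generate_family(sim_config(n_alpha = 3, n_gamma = 0, n_omega = 0,
                                    pseudogene_fraction = 0, seed = 12))
  lib <- epitope_library()
  for (id in names(fam$truth)) {
    p <- family_proteins(fam)[[id]]
    ann <- segment_domains(p, "alpha", gene_id = id)
    hits <- scan_epitopes(p, lib[lib$class == "alpha", ], ann)
    for (k in seq_len(nrow(hits))) {
      d <- ann$domains
      lab <- d$label[d$start <= hits$start[k] & d$end >= hits$start[k]]
      expect_equal(hits$domain_label[k], lab)
    }
    # every planted epitope is found at least once
    for (e in fam$truth[[id]]$planted_epitopes) {
      seqs <- c("DQ2.5-glia-a1a" = "PFPQPQLPY", "DQ2.5-glia-a3" = "FRPQQPYPQ",
                "p19" = "LGQQQPFPPQQPYPQPQPF", "p12" = "LGQGSFRPSQQN",
                "DQ8-glia-a1" = "QGSFQPSQQ")
      expect_true(seqs[[e]] %in% hits$sequence)
    }
  }
})

test_that("near-miss windows are exactly Hamming distance one", {
  rep <- near_miss_report(paste0("AAA", "PQPQLPYSQ", "AAA"), "PQPQLPYPQ")
  expect_equal(rep$start, 4L)
  expect_equal(rep$position_in_epitope, 8L)
  expect_equal(rep$observed_residue, "S")
  expect_equal(rep$expected_residue, "P")

  # exact matches are excluded
  exact <- near_miss_report(paste0("AAA", "PQPQLPYPQ", "AAA"), "PQPQLPYPQ")
  expect_false(4L %in% exact$start)

  set.seed(55)
  for (i in 1:10) {
    p <- random_protein(120)
    got <- near_miss_report(p, "QQPQQPFPQ")
    expect_equal(got$start, oracle_near_miss(p, "QQPQQPFPQ")$start)
  }
  expect_error(near_miss_report("AAAA", "QQP"), "shorter")
})

test_that("cysteine skeletons match the type-specific architecture", {
  fam <- generate_family(sim_config(n_alpha = 1, n_gamma = 1, n_omega = 1,
                                    pseudogene_fraction = 0, seed = 15))
  prots <- family_proteins(fam)
  types <- vapply(fam$truth, function(t) t$type, character(1))

  g <- prots[[names(types)[types == "gamma"]]]
  ann_g <- segment_domains(g, "gamma")
  cp_g <- cysteine_profile(g, ann_g)
  expect_equal(cp_g$total, 8L)
  expect_equal(unname(cp_g$per_domain[c("III", "V")]), c(6L, 2L))

  a <- prots[[names(types)[types == "alpha"]]]
  cp_a <- cysteine_profile(a, segment_domains(a, "alpha"))
  expect_equal(cp_a$total, 6L)
  expect_equal(unname(cp_a$per_domain[c("UI", "UII")]), c(4L, 2L))

  w <- prots[[names(types)[types == "omega"]]]
  expect_equal(cysteine_profile(w)$total, 0L)

  cp <- cysteine_profile("ACCA")
  expect_equal(cp$total, 2L)
  expect_equal(cp$positions, c(2L, 3L))

  # positional differences against a reference protein
  d <- cysteine_profile("ACAAA", reference = "AAAAC")$diff
  expect_equal(d$gained, 2L)
  expect_equal(d$lost, 5L)
})

test_that("repeat units count greedily without overlap by default", {
  expect_equal(count_repeat_units("PFPQQPQQPFPQQPQQ", "PFPQQPQQ"), 2L)
  expect_equal(count_repeat_units("PFPQQPQQPFPQQPQQ", "PFPQQPQQ",
                                  allow_overlap = TRUE), 2L)
  # grammar token expands to its four literal units
  expect_equal(count_repeat_units("PFPQPQQPFPQQPQQPQQ", "PFPQ1-2(PQQ)1-2"),
               2L)
  expect_error(count_repeat_units("AAA", ""), "empty")

  set.seed(77)
  for (i in 1:10) {
    p <- random_protein(200)
    # overlapping count equals the window census
    n <- nchar(p); L <- 4
    census <- sum(vapply(seq_len(n - L + 1), function(j) {
      substr(p, j, j + L - 1) == "QQQP"
    }, logical(1)))
    expect_equal(count_repeat_units(p, "QQQP", allow_overlap = TRUE), census)
    expect_lte(count_repeat_units(p, "QQQP"),
               count_repeat_units(p, "QQQP", allow_overlap = TRUE))
  }
})

test_that("Q:P:F composition reduces to small-integer ratios", {
  r <- qpf_ratio("QQQQPPPF")
  expect_equal(r$ratio, c(4L, 3L, 1L))
  expect_equal(unname(r$fractions), c(0.5, 0.375, 0.125))
  expect_equal(qpf_ratio("QP")$ratio, c(1L, 1L, 0L))
  expect_error(qpf_ratio("AAA"), "no Q, P or F")

  fam <- generate_family(sim_config(n_alpha = 0, n_gamma = 0, n_omega = 6,
                                    pseudogene_fraction = 0, seed = 21))
  for (p in family_proteins(fam)) {
    mature <- substring(p, 20)
    fr <- qpf_ratio(mature)$fractions
    expect_true(all(abs(fr - c(0.5, 0.375, 0.125)) <= 0.05))
  }
})

test_that("omega typing uses the mature N-terminus then composition", {
  expect_equal(classify_omega("ARQLNPSHEQQQ"), "ARQ/E")
  expect_equal(classify_omega("ARELNPSHEQQQ"), "ARQ/E")
  expect_equal(classify_omega("KELNPSHEQQQ"), "KEL")
  expect_equal(classify_omega("SRLNPSHEQQQ"), "SRL")
  expect_equal(classify_omega("TRQLNPSHEQQQ"), "TRQ")
  # unknown start but canonical 4:3:1 composition -> ARQ/E-like variant
  expect_equal(classify_omega(paste0("ARH", strrep("QQQQPPPF", 10))),
               "ARQ/E-like variant")
  expect_equal(classify_omega("AHALALALAL"), "unknown")
  expect_error(classify_omega("AR"), "shorter")
})

test_that("alpha group classification follows the epitope/variant rules", {
  sig <- "MKTFLILALLAIVATTATTA"
  lib <- epitope_library()
  alib <- lib[lib$class == "alpha", ]
  mk <- function(qi, qii, uii_extra = "") {
    paste0(sig, "PFPQPQLPYFRPQQPYPQQPYPSPFLP", qi, "SVNVLSSTYLLNE", qii,
           "SNVAGKSVNVE", uii_extra)
  }
  # group I: Q-to-A variant in QI plus the DQ8 alpha epitope
  p1 <- mk(paste0(strrep("Q", 5), "A", strrep("Q", 5)), strrep("Q", 10),
           uii_extra = "QGSFQPSQQ")
  a1 <- segment_domains(p1, "alpha")
  expect_equal(classify_alpha_group(a1, scan_epitopes(p1, alib, a1)), "I")

  # group II: Q-to-K variant in QII plus both DQ2.5 alpha epitopes
  p2 <- mk(strrep("Q", 10), paste0(strrep("Q", 5), "K", strrep("Q", 5)))
  a2 <- segment_domains(p2, "alpha")
  expect_equal(classify_alpha_group(a2, scan_epitopes(p2, alib, a2)), "II")

  # group III: pure tracts, 3-4 distinct epitopes
  p3 <- mk(strrep("Q", 10), strrep("Q", 10), uii_extra = "LGQGSFRPSQQN")
  a3 <- segment_domains(p3, "alpha")
  expect_equal(classify_alpha_group(a3, scan_epitopes(p3, alib, a3)), "III")

  # one epitope, pure tracts: unclassified
  p4 <- paste0(sig, "FRPQQPYPQQPYPSPFLP", strrep("Q", 10), "SVNVLSSTYLLNE",
               strrep("Q", 10), "SNVAGKSVNVE")
  a4 <- segment_domains(p4, "alpha")
  expect_equal(classify_alpha_group(a4, scan_epitopes(p4, alib, a4)),
               "unclassified")
})
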