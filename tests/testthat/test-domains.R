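test_that("gliadin types are inferred from structural features", {
  fam <- generate_family(sim_config(n_alpha = 2, n_gamma = 2, n_omega = 2,
                                    pseudogene_fraction = 0, seed = 6))
  prots <- family_proteins(fam)
  for (id in names(prots)) {
    expect_equal(infer_gliadin_type(prots[[id]]), fam$truth[[id]]$type)
  }
  # invariant to trailing whitespace
  expect_equal(infer_gliadin_type(paste0(prots[[1]], "  \n")),
               infer_gliadin_type(prots[[1]]))
  expect_error(infer_gliadin_type("QPQ"), "shorter")
  expect_error(infer_gliadin_type(strrep("QB", 30)), "non-standard")
})

test_that("polyglutamine tracts are maximal, merged and thresholded", {
  p <- paste0(strrep("A", 10), strrep("Q", 8), "AA", strrep("Q", 5),
              strrep("A", 10))
  tr <- find_polyq_tracts(p)
  # 8 Qs + gap of 2 + 5 Qs merge (13/15 = 87% Q) into one tract
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 11L)
  expect_equal(tr$end, 25L)

  # short runs below min length are dropped
  expect_equal(nrow(find_polyq_tracts(paste0(strrep("A", 5), "QQQQQ",
                                             strrep("A", 5)))), 0)
})

test_that("alpha segmentation yields the six ordered domains", {
  fam <- generate_family(sim_config(n_alpha = 4, n_gamma = 0, n_omega = 0,
                                    pseudogene_fraction = 0, seed = 2))
  prots <- family_proteins(fam)
  for (id in names(prots)) {
    ann <- segment_domains(prots[[id]], "alpha", gene_id = id)
    expect_equal(ann$domains$label,
                 c("signal", "repetitive", "QI", "UI", "QII", "UII"))
    # partition: lengths sum to the protein length, no gaps
    nonempty <- ann$domains[ann$domains$end >= ann$domains$start, ]
    expect_equal(sum(nonempty$end - nonempty$start + 1L),
                 nchar(prots[[id]]))
    expect_equal(ann$mature_start, 21L)
  }
})

test_that("planted domain boundaries are recovered", {
  rec1 <- measure_family_recovery(generate_family(sim_config(seed = 23)))
  rec2 <- measure_family_recovery(generate_family(sim_config(seed = 31)))
  ok <- rec1$boundary[1] + rec2$boundary[1]
  tot <- rec1$boundary[2] + rec2$boundary[2]
  expect_gte(ok / tot, 0.95)
  expect_true(rec1$tract_exact && rec2$tract_exact)
})

test_that("the dominant gamma tract becomes domain IV", {
  fam <- generate_family(sim_config(n_alpha = 0, n_gamma = 2, n_omega = 0,
                                    pseudogene_fraction = 0, seed = 9))
  prots <- family_proteins(fam)
  for (id in names(prots)) {
    ann <- segment_domains(prots[[id]], "gamma", gene_id = id)
    expect_equal(ann$domains$label, c("signal", "I", "II", "III", "IV", "V"))
    tr <- fam$truth[[id]]$boundaries
    expect_equal(ann$domains$start[ann$domains$label == "IV"],
                 tr$start[tr$label == "IV"])
    expect_equal(ann$domains$end[ann$domains$label == "IV"],
                 tr$end[tr$label == "IV"])
  }
})

test_that("alpha proteins with fewer than two tracts keep an empty QII", {
  p <- paste0("MKTFLILALLAIVATTATTA",        # 20-residue signal
              "QPYPSPFLP", strrep("Q", 12), "SVNVLSSTYLLNE")
  ann <- segment_domains(p, "alpha")
  expect_length(ann$warning, 1)
  qii <- ann$domains[ann$domains$label == "QII", ]
  expect_true(qii$end < qii$start)            # empty domain
  expect_equal(ann$domains$label[1:6],
               c("signal", "repetitive", "QI", "UI", "QII", "UII"))
})

test_that("polyQ length profiles convert residues to nucleotide extents", {
  sig <- "MKTFLILALLAIVATTATTA"
  mk <- function(qi, qii) {
    paste0(sig, "QPYPSPFLP", strrep("Q", qi), "SVNVLSSTYLLNE",
           if (qii > 0) strrep("Q", qii) else "", "SNVAGKSVNVE")
  }
  a1 <- segment_domains(mk(9, 12), "alpha", gene_id = "a1")
  a2 <- segment_domains(mk(33, 12), "alpha", gene_id = "a2")
  a3 <- segment_domains(mk(9, 0), "alpha", gene_id = "a3")
  prof <- polyq_length_profile(list(a1, a2, a3))
  expect_equal(prof$qi_nt, c(27L, 99L, 27L))   # 9 and 33 residues
  expect_equal(prof$qii_nt[1], 36L)
  expect_equal(prof$qii_nt[3], 0L)             # empty QII -> 0 bp
  expect_equal(attr(prof, "qi_nt_range"), c(27L, 99L))
})
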