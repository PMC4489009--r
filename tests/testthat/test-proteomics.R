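test_that("chymotryptic cleavage respects the no-cut-before-proline rule", {
  d0 <- chymotryptic_digest("AAFGGYPKKW", max_missed = 0, min_len = 1)
  # cut after F3; no cut after Y6 (followed by P); W is the terminus
  expect_setequal(d0$sequence, c("AAF", "GGYPKKW"))

  # a peptide spanning an internal cut site (F before E) needs a missed
  # cleavage; here it is the C-terminal peptide of its protein
  prot <- paste0("AAAW", "QPQQLPQFEEIRN")
  d <- chymotryptic_digest(prot, max_missed = 2, min_len = 5)
  target <- d[d$sequence == "QPQQLPQFEEIRN", ]
  expect_gt(nrow(target), 0)
  expect_true(all(target$missed_cleavages >= 1))
  expect_false("QPQQLPQFEEIRN" %in%
                 chymotryptic_digest(prot, max_missed = 0,
                                     min_len = 5)$sequence)
})

test_that("digests tile the protein and match exhaustive enumeration", {
  set.seed(61)
  for (i in 1:10) {
    p <- random_protein(60)
    d0 <- chymotryptic_digest(p, max_missed = 0, min_len = 1)
    expect_equal(paste(d0$sequence, collapse = ""), p)
  }
  for (i in 1:50) {
    p <- random_protein(sample(30:80, 1))
    got <- sort(chymotryptic_digest(p, max_missed = 2, min_len = 5)$sequence)
    expect_equal(got, oracle_digest(p, max_missed = 2, min_len = 5))
  }
})

test_that("peptides match proteins by exact substring", {
  proteome <- c(g1 = "AAAWQPQQLPQFEEIRNWAAA", g2 = "AAAWLLLPQWAAA",
                g3 = "CCCWQPQQLPQFEEIRNWCCC")
  m <- match_peptides(c("QPQQLPQFEEIRN", "LLLPQ", "NOTPRESENT"), proteome)
  expect_setequal(m[["QPQQLPQFEEIRN"]], c("g1", "g3"))
  expect_equal(m[["LLLPQ"]], "g2")
  expect_length(m[["NOTPRESENT"]], 0)
  expect_error(match_peptides("AAA", character()), "empty proteome")
})

test_that("spot assignment distinguishes unique from ambiguous support", {
  shared <- "LPSMCNVYIPPYCSTIRAPF"
  protA <- paste0("AAAW", shared, "W", "QPQQLPQFEEIRN", "W")
  protB <- paste0("AAAW", shared, "W", "SSSSSSSS", "W")
  proteome <- c(A = protA, B = protB)

  # shared peptides plus one unique peptide: unique assignment
  a <- assign_spot(c(shared, "QPQQLPQFEEIRN"), proteome, spot_id = 1L)
  expect_true(a$unique)
  expect_equal(a$assigned_gene, "A")
  expect_setequal(a$matched_genes, c("A", "B"))

  # all peptides shared between two genes: ambiguous pair
  b <- assign_spot(shared, proteome, spot_id = 2L)
  expect_false(b$unique)
  expect_setequal(b$matched_genes, c("A", "B"))

  # one peptide, one protein: unique
  c1 <- assign_spot("QPQQLPQFEEIRN", proteome)
  expect_true(c1$unique)
  expect_equal(c1$assigned_gene, "A")

  # nothing matches: unassigned
  u <- assign_spot("KKKKKKKK", proteome)
  expect_length(u$matched_genes, 0)

  # stability: dropping any one shared peptide keeps the assignment
  peps <- c(shared, "QPQQLPQFEEIRN", "AAAW")
  full <- assign_spot(peps, proteome)
  for (k in which(peps != "QPQQLPQFEEIRN")) {
    red <- assign_spot(peps[-k], proteome)
    expect_equal(red$assigned_gene, full$assigned_gene)
  }
})

test_that("volume aggregation keeps ambiguous groups whole", {
  st <- read_spot_table(system.file("extdata", "spot_table.tsv",
                                    package = "gliadinR"))
  v <- aggregate_volumes(st)
  pg <- stats::setNames(v$per_gene$percent_volume, v$per_gene$entity)
  expect_equal(unname(pg[["Gli-γ-1"]]), 49.27)
  expect_equal(unname(pg[["Gli-α-10+Gli-α-11"]]), 18.79)
  pc <- stats::setNames(v$per_class$percent_volume, v$per_class$class)
  expect_equal(unname(pc[["gamma"]]), 53.39)
  expect_equal(v$total, 100.01, tolerance = 1e-9)

  single <- tibble::tibble(spot_id = 1L, percent_volume = 100,
                           gene = "Gli-α-1", mw_kd = 30, pi = 7,
                           peptides = NA_character_)
  expect_equal(aggregate_volumes(single)$per_gene$percent_volume, 100)

  over <- tibble::tibble(spot_id = 1:2, percent_volume = c(60, 50),
                         gene = c("Gli-α-1", "Gli-α-2"),
                         mw_kd = 30, pi = 7, peptides = NA_character_)
  expect_warning(aggregate_volumes(over), "100.5")
})

test_that("spot coordinates are checked against predicted physicochemistry", {
  pred <- tibble::tibble(gene = "Gli-α-8", mw_kd = 32.62, pi = 7.31)
  ok <- spot_consistency(32.6, 7.3, pred)
  expect_true(ok$consistent)
  bad <- spot_consistency(60.0, 5.0, pred)
  expect_false(bad$consistent)

  # generator round trip: synthetic spots match their source proteins
  fam <- generate_family(sim_config(seed = 47))
  spots <- generate_spots(fam)
  prots <- family_proteins(fam)
  pc <- physchem_table(prots)
  for (k in seq_len(nrow(spots$spot_table))) {
    row <- spots$spot_table[k, ]
    cand <- strsplit(row$gene, ";")[[1]]
    sc <- spot_consistency(row$mw_kd, row$pi, pc[pc$gene %in% cand, ])
    expect_true(sc$consistent)
  }
})
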