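test_that("generation is deterministic under a fixed seed", {
  a <- generate_family(sim_config(seed = 5))
  b <- generate_family(sim_config(seed = 5))
  expect_identical(a$records, b$records)
  expect_identical(generate_expression(a)$counts,
                   generate_expression(b)$counts)
  expect_identical(generate_spots(a)$spot_table,
                   generate_spots(b)$spot_table)
  c2 <- generate_family(sim_config(seed = 6))
  expect_false(identical(a$records$sequence, c2$records$sequence))
})

test_that("a zero pseudogene fraction yields only clean full ORFs", {
  fam <- generate_family(sim_config(pseudogene_fraction = 0, seed = 10))
  expect_true(all(vapply(fam$truth, function(t) t$status == "full_orf",
                         logical(1))))
  for (nt in fam$records$sequence) {
    expect_equal(nrow(find_internal_stops(nt)), 0)
    expect_equal(nchar(nt) %% 3, 0)
  }
})

test_that("the realized pseudogene fraction is binomial around the rate", {
  fam <- generate_family(sim_config(n_alpha = 1000, n_gamma = 0, n_omega = 0,
                                    pseudogene_fraction = 0.5, seed = 14))
  frac <- mean(vapply(fam$truth, function(t) t$status != "full_orf",
                      logical(1)))
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("planted stop counts equal detected stop counts per gene", {
  fam <- generate_family(sim_config(seed = 18))
  for (id in names(fam$truth)) {
    t <- fam$truth[[id]]
    if (t$status != "pseudo_stop") next
    nt <- fam$records$sequence[fam$records$id == id]
    expect_equal(nrow(find_internal_stops(nt)), nrow(t$stop_events))
    expect_equal(find_internal_stops(nt)$codon_index,
                 t$stop_events$codon_index)
  }
})

test_that("simulated counts drive expressed genes over the threshold", {
  fam <- generate_family(sim_config(seed = 25))
  ex <- generate_expression(fam)
  x <- rpkm_matrix(ex$counts, ex$samples, ex$gene_lengths)
  expect_setequal(classify_expressed(x),
                  names(ex$expressed)[ex$expressed])
  # pseudogenes never cross the threshold
  sm <- stage_means(x)
  pseudo <- names(ex$expressed)[!ex$expressed]
  expect_true(all(sm[pseudo, c("5", "10", "15", "20", "25")] < 1000))
})

test_that("synonymous copies co-migrate as one ambiguous spot", {
  fam <- generate_family(sim_config(n_alpha = 2, n_gamma = 0, n_omega = 0,
                                    pseudogene_fraction = 0,
                                    duplicate_fraction = 1, seed = 33))
  prots <- family_proteins(fam)
  expect_equal(unname(prots[[1]]), unname(prots[[2]]))  # identical proteins
  expect_false(fam$records$sequence[1] == fam$records$sequence[2])
  spots <- generate_spots(fam)
  expect_equal(nrow(spots$spot_table), 1)
  asg <- assign_spot(split_peptides(spots$spot_table$peptides[1]), prots,
                     spot_id = 1L)
  expect_false(asg$unique)
  expect_setequal(asg$matched_genes, names(prots))
})

test_that("spot membership is recovered from sampled peptides", {
  ok <- 0; tot <- 0
  for (seed in c(51, 52, 53)) {
    fam <- generate_family(sim_config(seed = seed))
    prots <- family_proteins(fam)
    spots <- generate_spots(fam)
    for (k in seq_len(nrow(spots$spot_table))) {
      row <- spots$spot_table[k, ]
      asg <- assign_spot(split_peptides(row$peptides), prots,
                         spot_id = row$spot_id)
      truth <- spots$truth_membership[[as.character(row$spot_id)]]
      tot <- tot + 1
      if (setequal(assigned_genes(asg), truth)) ok <- ok + 1
    }
  }
  expect_gte(ok / tot, 0.95)
})

test_that("simulate_dataset writes a complete readable bundle", {
  out <- withr::local_tempdir()
  simulate_dataset(sim_config(seed = 2), out)
  expect_true(all(file.exists(file.path(out, c(
    "family.fasta", "truth.json", "counts.tsv", "samples.tsv",
    "spots.tsv")))))
  fasta <- read_fasta(file.path(out, "family.fasta"))
  expect_equal(nrow(fasta), 28)
  counts <- read_counts(file.path(out, "counts.tsv"))
  samples <- read_samples(file.path(out, "samples.tsv"))
  expect_equal(ncol(counts), nrow(samples))
  spots <- read_spot_table(file.path(out, "spots.tsv"))
  expect_true(nrow(spots) > 0)
})
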