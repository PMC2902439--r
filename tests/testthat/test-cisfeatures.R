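# CNS validation, motif conservation, composite enumeration, counts.

cns_row <- function(id, gene, len = 150, ident = 0.9) {
  rbind(data.frame(cns_id = id, gene_id = gene, species = "rat",
                   chrom = "chr1", start = 1000, end = 1000 + len,
                   pct_identity = ident, stringsAsFactors = FALSE),
        data.frame(cns_id = id, gene_id = gene, species = "human",
                   chrom = "chr1", start = 5000, end = 5000 + len,
                   pct_identity = ident, stringsAsFactors = FALSE))
}

inst <- function(cns, species, fam, start = 10) {
  data.frame(cns_id = cns, species = species, family_id = fam,
             start = start, strand = "+", stringsAsFactors = FALSE)
}

test_that("CNS validity bounds are inclusive at 100 bp and 0.75 identity", {
  tab <- rbind(cns_row("c1", "g1", len = 99, ident = 0.80),
               cns_row("c2", "g1", len = 100, ident = 0.75),
               cns_row("c3", "g2", len = 300, ident = 0.60),
               cns_row("c4", "g2"))
  val <- validate_cns(tab)
  expect_setequal(unique(val$cns$cns_id), c("c2", "c4"))
  expect_setequal(unique(val$rejected$cns_id), c("c1", "c3"))
  expect_equal(val$summary$n_cns, 2)
  # a CNS missing one species track is rejected as a whole
  tab2 <- rbind(cns_row("c5", "g3"))[1, , drop = FALSE]
  val2 <- validate_cns(rbind(tab, tab2))
  expect_false("c5" %in% val2$cns$cns_id)
})

test_that("conservation requires both tracks; positions are irrelevant", {
  cns <- cns_row("c1", "g1")
  ins <- rbind(inst("c1", "human", "F", start = 10),
               inst("c1", "rat", "F", start = 120),
               inst("c1", "rat", "F", start = 40),
               inst("c1", "human", "G"))
  cons <- conserved_motifs(cns, ins)
  expect_equal(cons$family_id, "F")
  expect_equal(cons$n_rat, 2)         # two rat instances counted
  expect_equal(cons$n_human, 1)
  expect_false("G" %in% cons$family_id)  # human-only: not conserved
  expect_error(conserved_motifs(cns, inst("nope", "rat", "F")), "unknown")
})

test_that("composite enumeration: 2^m - 1 subsets capped at size 3", {
  cns <- rbind(cns_row("c1", "g1"))
  ins <- do.call(rbind, lapply(c("A", "B", "C"), function(f)
    rbind(inst("c1", "rat", f), inst("c1", "human", f))))
  cons <- conserved_motifs(cns, ins)
  ft <- enumerate_composites(cons, "g1")
  expect_equal(ncol(ft$presence), 7)  # 3 singles + 3 pairs + 1 triple
  expect_setequal(ft$composites$composite_id,
                  c("A", "B", "C", "A_B", "A_C", "B_C", "A_B_C"))
  # max_size 2 drops the triple
  ft2 <- enumerate_composites(cons, "g1", max_size = 2)
  expect_equal(ncol(ft2$presence), 6)
  # empty conserved set -> empty table
  ft0 <- enumerate_composites(cons[0, ], c("g1", "g2"))
  expect_equal(ncol(ft0$presence), 0)
})

test_that("gene-level composites respect the CNS boundary", {
  cns <- rbind(cns_row("c1", "g1"), cns_row("c2", "g1"))
  ins <- rbind(inst("c1", "rat", "A"), inst("c1", "human", "A"),
               inst("c1", "rat", "B"), inst("c1", "human", "B"),
               inst("c2", "rat", "B"), inst("c2", "human", "B"),
               inst("c2", "rat", "C"), inst("c2", "human", "C"))
  ft <- enumerate_composites(conserved_motifs(cns, ins), "g1")
  # A and C never share a CNS, so A_C is absent
  expect_setequal(ft$composites$composite_id,
                  c("A", "B", "C", "A_B", "B_C"))
})

test_that("downward closure holds on generated data", {
  b <- tiny_bundle(seed = 8, n_a = 250, n_b = 230)
  f <- build_cis_features(b$cns, b$motifs, b$truth$genes_A,
                          min_gene_support = 1)
  pres <- f$features$presence
  comp <- f$features$composites
  multi <- comp$composite_id[comp$size > 1]
  for (cid in sample(multi, min(25, length(multi)))) {
    members <- strsplit(cid, "_", fixed = TRUE)[[1]]
    carriers <- pres[, cid]
    for (mm in members)
      expect_true(all(pres[carriers, mm]))
  }
})

test_that("a CNS with m families yields sum(choose(m, 1:3)) composites", {
  cns <- cns_row("c1", "g1")
  ins <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(f)
    rbind(inst("c1", "rat", f), inst("c1", "human", f))))
  ft <- enumerate_composites(conserved_motifs(cns, ins), "g1")
  expect_equal(ncol(ft$presence), choose(4, 1) + choose(4, 2) + choose(4, 3))
})

test_that("counts sum rat-track instances over a gene's CNSs", {
  cns <- rbind(cns_row("c1", "g1"), cns_row("c2", "g1"))
  ins <- rbind(inst("c1", "rat", "SATB", 1), inst("c1", "rat", "SATB", 20),
               inst("c1", "rat", "SATB", 40), inst("c1", "human", "SATB"),
               inst("c2", "rat", "SATB", 1), inst("c2", "rat", "SATB", 20),
               inst("c2", "rat", "SATB", 40), inst("c2", "human", "SATB"),
               inst("c2", "rat", "LONE"))   # rat-only: not conserved
  cons <- conserved_motifs(cns, ins)
  ct <- count_features(cns, cons, c("g1", "g2"))
  expect_equal(unname(ct$motif_counts["g1", "SATB"]), 6)
  expect_false("LONE" %in% colnames(ct$motif_counts))
  # zero-CNS gene stays addressable with zero counts
  expect_equal(unname(ct$cns_count["g2"]), 0)
  expect_equal(unname(ct$motif_counts["g2", "SATB"]), 0)
  expect_equal(unname(ct$cns_count["g1"]), 2)
  # count species is configurable
  ct_h <- count_features(cns, cons, "g1", count_species = "human")
  expect_equal(unname(ct_h$motif_counts["g1", "SATB"]), 2)
})

test_that("support filter trims the feature universe and logs the drop", {
  b <- tiny_bundle(seed = 9, n_a = 250, n_b = 230)
  f1 <- build_cis_features(b$cns, b$motifs, b$truth$genes_A,
                           min_gene_support = 1)
  f5 <- build_cis_features(b$cns, b$motifs, b$truth$genes_A,
                           min_gene_support = 5)
  expect_lt(ncol(f5$features$presence), ncol(f1$features$presence))
  expect_true(all(f5$features$composites$n_genes >= 5))
  expect_gt(f5$features$n_dropped, 0)
})
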