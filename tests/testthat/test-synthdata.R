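# Synthetic paired-dataset generator: bookkeeping, exact low-rank
# construction, distributional properties, serialization.

test_that("matrix shapes, design and shared-gene bookkeeping are correct", {
  cfg <- synth_config(seed = 1, n_genes_A = 200, n_genes_B = 180,
                      frac_shared = 0.4)
  pe <- generate_paired_expression(cfg)
  expect_equal(dim(pe$expr_A$signal), c(200, 15))
  expect_equal(dim(pe$expr_B$signal), c(180, 30))
  # shared fraction applies to the smaller system
  expect_length(pe$truth$shared_genes, round(0.4 * 180))
  expect_true(all(pe$expr_A$calls == "P"))
  expect_equal(nrow(pe$expr_A$design), 15)
  expect_equal(length(unique(pe$expr_B$design$condition_id)), 10)
  expect_false(anyDuplicated(pe$expr_A$design$array_id) > 0)
})

test_that("noise-free construction is recovered exactly by SVD", {
  cfg <- synth_config(seed = 2, n_genes_A = 300, n_genes_B = 280,
                      noise_sd = 0, planted_sign_features = NULL,
                      planted_count_effect = NULL, antagonist_pair = NULL)
  pe <- generate_paired_expression(cfg)
  tr <- pe$truth
  expect_lt(max(abs(crossprod(tr$U_A) - diag(3))), 1e-10)
  expect_lt(max(abs(crossprod(tr$V_B) - diag(3))), 1e-10)
  lg <- log2(pe$expr_A$signal)
  des <- pe$expr_A$design
  cond <- des$condition_id[match(colnames(lg), des$array_id)]
  avg <- t(rowsum(t(lg), cond))[, unique(des$condition_id)] / 3
  sv <- svd(avg)
  expect_equal(sv$d[1:3], tr$s_A, tolerance = 1e-8)
  expect_gt(abs(cor(sv$u[, 2], tr$U_A[, 2])), 1 - 1e-8)
})

test_that("planted effects survive noise and SVD re-estimation", {
  for (seed in c(11, 12)) {
    b <- generate_paired_expression(
      synth_config(seed = seed, n_genes_A = 2000, n_genes_B = 1800))
    gem <- preprocess_system(b$expr_A, alpha = 1)
    ed <- eigen_decompose(gem)
    genes <- rownames(gem$expr)
    expect_gt(abs(cor(ed$U[, 2], b$truth$U_A[genes, 2])), 0.95)
    expect_gt(abs(cor(ed$U[, 3], b$truth$U_A[genes, 3])), 0.95)
  }
})

test_that("total CNS count follows the configured Poisson regime", {
  cfg <- synth_config(seed = 3, n_genes_A = 700, n_genes_B = 600,
                      frac_shared = 0.5, cns_per_gene_mean = 2)
  b <- simulate_bundle(cfg)
  n_union <- 700 + 600 - 300
  n_cns <- length(unique(b$cns$cns_id))
  band <- qpois(c(0.005, 0.995), lambda = 2 * n_union)
  expect_gte(n_cns, band[1])
  expect_lte(n_cns, band[2])
  # two species rows per CNS, BED half-open intervals of >= 100 bp
  expect_equal(nrow(b$cns), 2 * n_cns)
  expect_true(all(b$cns$end - b$cns$start >= 100))
  expect_true(all(b$cns$pct_identity >= 0.75))
})

test_that("odds-multiplier 1 leaves sign frequencies flat", {
  cfg <- synth_config(seed = 4, n_genes_A = 1500, n_genes_B = 1400,
                      planted_sign_features = list(
                        list(feature = "AP1F", odds = 1, eigensystem = 2,
                             systems = c("A", "B"))),
                      planted_count_effect = NULL, antagonist_pair = NULL)
  pe <- generate_paired_expression(cfg)
  tr <- pe$truth
  carriers <- unique(tr$assignments$gene_id[tr$assignments$family_id == "AP1F"])
  carr <- intersect(carriers, tr$genes_A)
  non <- setdiff(tr$genes_A, carriers)
  up_c <- mean(tr$U_A[carr, 2] > 0)
  up_n <- mean(tr$U_A[non, 2] > 0)
  pt <- prop.test(c(sum(tr$U_A[carr, 2] > 0), sum(tr$U_A[non, 2] > 0)),
                  c(length(carr), length(non)))
  expect_gt(pt$p.value, 0.001)
  expect_lt(abs(up_c - up_n), 0.1)
})

test_that("ground truth round-trips through JSON", {
  b <- tiny_bundle(seed = 5, n_a = 120, n_b = 110)
  path <- tempfile(fileext = ".json")
  write_truth_json(b$truth, path)
  tr <- read_truth_json(path)
  for (nm in c("genes_A", "genes_B", "shared_genes"))
    expect_identical(tr[[nm]], b$truth[[nm]])
  expect_equal(tr$U_A, b$truth$U_A, tolerance = 1e-12)
  expect_equal(tr$s_B, b$truth$s_B, tolerance = 1e-12)
  expect_equal(tr$baseline, b$truth$baseline, tolerance = 1e-12)
  expect_equal(tr$assignments$n_rat, b$truth$assignments$n_rat)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(k_shared = 5, n_conditions_A = 5,
                            singular_values = c(40, 30, 20, 10)),
               "k_shared")
  expect_error(synth_config(frac_shared = 1.5), "frac_shared")
  expect_error(synth_config(planted_sign_features = list(
    list(feature = c("AP1F", "CREB", "EGRF", "SATB"), odds = 2,
         eigensystem = 2, systems = "A"))), "size 1-3")
  expect_error(synth_config(singular_values = c(10, 40)), "descending")
})

test_that("decoy instances are single-track and never conserved", {
  b <- tiny_bundle(seed = 6, n_a = 400, n_b = 380, decoy_rate = 0.3)
  expect_gt(b$truth$n_decoy_instances, 0)
  val <- validate_cns(b$cns)
  cons <- conserved_motifs(val$cns, b$motifs)
  # every conserved (cns, family) pair must be in the planted assignments
  key_cons <- paste(cons$cns_id, cons$family_id)
  key_true <- paste(b$truth$assignments$cns_id,
                    b$truth$assignments$family_id)
  expect_true(all(key_cons %in% key_true))
  # and some instance rows are decoys, i.e. absent from the assignments
  key_inst <- paste(b$motifs$cns_id, b$motifs$family_id)
  expect_gt(sum(!(key_inst %in% key_true)), 0)
})

test_that("dual-probeset mode exercises averaging", {
  b <- generate_paired_expression(
    synth_config(seed = 7, n_genes_A = 400, n_genes_B = 380,
                 dual_probesets = TRUE))
  map <- b$expr_A$probeset_map
  expect_gt(nrow(map), 400)
  expect_true(all(table(map$gene_id) <= 2))
  avg <- average_to_genes(b$expr_A$signal, map)
  expect_equal(nrow(avg), 400)
})
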