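# End-to-end orchestration: preprocessing -> SVD -> eigenarray matching
# -> cis features -> Bayesian-network analysis (both directions, per
# conserved eigensystem) -> count regressions, with optional on-disk
# outputs and a checksum manifest.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full comparative cis-regulation pipeline
#'
#' @param bundle a data bundle as produced by [simulate_bundle()] (or an
#'   equivalently shaped list read from user tables): `expr_A`, `expr_B`,
#'   `cns`, `motifs`.
#' @param eigensystems indices (in system A) of the conserved
#'   eigensystems to analyse (default `c(2, 3)`).
#' @param alpha ANOVA threshold for preprocessing.
#' @param bn_cfg a [bde_config()].
#' @param regress_families motif families for the count regressions
#'   (default `c("AP1F", "SATB", "CREB")`, intersected with the families
#'   observed in the data).
#' @param path_family family used for the CNS/motif path analysis
#'   (default `"CREB"`).
#' @param k_max eigensystems to match (default 3).
#' @param min_gene_support feature-universe support filter.
#' @param out_dir optional output directory for TSV artifacts and a
#'   manifest.
#' @return a run report: list with `gem`, `eigen`, `match`, `features`,
#'   `bn` (per eigensystem), `regression` (per eigensystem), and
#'   `manifest` when `out_dir` is set.
#' @export
run_pipeline <- function(bundle, eigensystems = c(2, 3), alpha = 0.05,
                         bn_cfg = bde_config(),
                         regress_families = c("AP1F", "SATB", "CREB"),
                         path_family = "CREB",
                         k_max = 3, min_gene_support = 5,
                         out_dir = NULL) {
  for (need in c("expr_A", "expr_B", "cns", "motifs"))
    if (is.null(bundle[[need]])) stop("bundle lacks component '", need, "'")

  gem_a <- .stage("preprocess A", preprocess_system(bundle$expr_A, alpha))
  gem_b <- .stage("preprocess B", preprocess_system(bundle$expr_B, alpha))
  ed_a <- .stage("svd A", eigen_decompose(gem_a))
  ed_b <- .stage("svd B", eigen_decompose(gem_b))
  match <- .stage("match", match_eigenarrays(ed_a, ed_b, k_max = k_max))

  feats_a <- .stage("features A",
                    build_cis_features(bundle$cns, bundle$motifs,
                                       rownames(gem_a$expr),
                                       min_gene_support = min_gene_support))
  feats_b <- .stage("features B",
                    build_cis_features(bundle$cns, bundle$motifs,
                                       rownames(gem_b$expr),
                                       min_gene_support = min_gene_support))

  bn <- list()
  regression <- list()
  for (k in eigensystems) {
    row <- match$matches[match$matches$k_a == k, , drop = FALSE]
    if (nrow(row) == 0) stop("eigensystem ", k, " has no match")
    signs_a <- binarize_loadings(ed_a, k)
    signs_b <- binarize_loadings(ed_b, row$k_b, flip = row$sign_flip)
    bn[[paste0("es", k)]] <-
      .stage(paste0("bn es", k),
             bn_eigensystem_analysis(feats_a$features, signs_a,
                                     feats_b$features, signs_b, bn_cfg))
    fams <- intersect(regress_families, colnames(feats_a$counts$motif_counts))
    reg <- list()
    for (sys in c("a", "b")) {
      ed <- if (sys == "a") ed_a else ed_b
      kk <- if (sys == "a") k else row$k_b
      feats <- if (sys == "a") feats_a else feats_b
      u <- ed$U[, kk]
      if (sys == "b" && row$sign_flip) u <- -u
      lo <- setNames(u, ed$genes)
      cc <- feats$counts$cns_count
      per_fam <- lapply(fams, function(f)
        tryCatch(count_regression(lo, feats$counts$motif_counts[, f], cc),
                 error = function(e) NULL))
      names(per_fam) <- fams
      path <- if (path_family %in% fams)
        tryCatch(path_analysis(lo, cc,
                               feats$counts$motif_counts[, path_family]),
                 error = function(e) NULL) else NULL
      reg[[sys]] <- list(families = per_fam, path = path)
    }
    regression[[paste0("es", k)]] <- reg
  }

  report <- list(gem = list(a = gem_a, b = gem_b),
                 eigen = list(a = ed_a, b = ed_b),
                 match = match,
                 features = list(a = feats_a, b = feats_b),
                 bn = bn, regression = regression,
                 settings = list(eigensystems = eigensystems, alpha = alpha,
                                 bn_cfg = unclass(bn_cfg), k_max = k_max))
  if (!is.null(out_dir)) report$manifest <- write_run_outputs(report, out_dir)
  report
}

#' Write pipeline artifacts and a checksum manifest
#'
#' @param report a [run_pipeline()] report.
#' @param out_dir output directory (created if missing).
#' @return the manifest data.frame (file, md5), invisibly written as
#'   `manifest.tsv` alongside a `run_metadata.json`.
#' @export
write_run_outputs <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c()
  for (sys in c("a", "b")) {
    ed <- report$eigen[[sys]]
    paths <- c(paths,
      write_tsv(mat_to_df(ed$U, "gene_id"),
                file.path(out_dir, paste0("eigenarrays_", sys, ".tsv"))),
      write_tsv(mat_to_df(ed$V, "condition_id"),
                file.path(out_dir, paste0("eigengenes_", sys, ".tsv"))),
      write_tsv(data.frame(k = seq_along(ed$d), singular_value = ed$d),
                file.path(out_dir, paste0("singular_values_", sys, ".tsv"))))
  }
  m <- report$match$matches
  paths <- c(paths, write_tsv(m, file.path(out_dir, "match_report.tsv")))
  for (es in names(report$bn)) {
    bn <- report$bn[[es]]
    for (sys in c("a", "b")) {
      rep_ <- bn[[paste0("report_", sys)]]
      df <- as.data.frame(rep_[, c("feature", "n_parents",
                                   "log_bn_score", "q", "significant")])
      paths <- c(paths, write_tsv(head(df, 50),
        file.path(out_dir, paste0("bn_", es, "_", sys, ".tsv"))))
    }
    for (dir_ in c("test_a_on_b", "test_b_on_a"))
      paths <- c(paths, write_tsv(bn[[dir_]],
        file.path(out_dir, paste0("bn_", es, "_", dir_, ".tsv"))))
  }
  meta <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(report$settings, meta, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, meta)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
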