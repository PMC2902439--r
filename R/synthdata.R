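# Synthetic paired time-series expression + cis-regulatory tables with
# planted ground truth.  Emulates the data regime the pipeline expects:
# two systems sharing a fraction of genes, a handful of dominant shared
# eigensystems with system-specific eigengenes, and gene-level composite
# motif features that bias the sign or value of loadings.

# family alphabet; first entries are the names used by the default planted
# effects, extended with generic ids when more families are requested
.family_alphabet <- function(n) {
  base <- c("AP1F", "SATB", "CREB", "EGRF", "LHXF", "ZF5F",
            "AHRR", "PARF", "E4FF", "ZBPF", "NKXH", "SORY")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("MF%03d", seq_len(n - length(base))))
}

#' Configuration for the synthetic paired-dataset generator
#'
#' All randomness in the generator is drawn from one stream seeded with
#' `seed`, so a configuration reproduces its bundle bit-for-bit.
#'
#' @param seed integer seed for the generator stream.
#' @param n_genes_A,n_genes_B number of genes in each system.
#' @param frac_shared fraction (of the smaller system) of genes present in
#'   both systems.
#' @param n_conditions_A,n_conditions_B number of biological conditions.
#' @param n_replicates arrays per condition.
#' @param k_shared number of planted shared eigensystems, including the
#'   magnitude-like first eigensystem.
#' @param singular_values singular values of the planted non-constant
#'   eigensystems 2..`k_shared` (descending, positive).  The first
#'   eigensystem's singular value is implied by the baseline expression
#'   level.
#' @param noise_sd replicate-level Gaussian noise, log2 units.
#' @param baseline_log2,baseline_sd mean and SD of per-gene baseline log2
#'   expression (the constant row offset realising the magnitude
#'   eigensystem).
#' @param n_motif_families size of the motif-family alphabet.
#' @param cns_per_gene_mean Poisson mean of conserved non-coding sequences
#'   (CNSs) per gene; zero-CNS genes are allowed.
#' @param motifs_per_cns_mean Poisson mean of distinct motif families per
#'   CNS (truncated at the alphabet size).
#' @param instance_excess_mean Poisson mean of instances beyond the first
#'   for a family present in a CNS track.
#' @param decoy_rate fraction of conserved instances matched by decoy
#'   non-conserved instances (present in one species track only).
#' @param dual_probesets if `TRUE`, about 10% of genes get a second,
#'   correlated probeset to exercise probeset averaging.
#' @param planted_sign_features list of planted sign effects; each element
#'   is a list with `feature` (character vector of 1-3 family ids forming a
#'   composite motif), `odds` (odds multiplier for a positive loading sign
#'   among carrier genes), `eigensystem` (target component) and `systems`
#'   (subset of `c("A","B")`).  `NULL` plants nothing.
#' @param planted_count_effect list with `family`, `beta` (loading units
#'   per conserved rat-track instance) and `eigensystem`, or `NULL`.
#' @param antagonist_pair list with `effect`, `blocker` and `eigensystem`,
#'   or `NULL`.  Blocker carriers receive the inverse odds regardless of
#'   the effect motif, so the effect motif's sign bias is nullified in
#'   the blocker stratum while the blocker itself acts repressively.
#' @return a validated `eigencis_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_genes_A = 3000, n_genes_B = 3300,
                         frac_shared = 0.3,
                         n_conditions_A = 5, n_conditions_B = 10,
                         n_replicates = 3,
                         k_shared = 3,
                         singular_values = c(40, 28),
                         noise_sd = 0.2,
                         baseline_log2 = 8, baseline_sd = 1,
                         n_motif_families = 12,
                         cns_per_gene_mean = 2,
                         motifs_per_cns_mean = 3,
                         instance_excess_mean = 0.15,
                         decoy_rate = 0.2,
                         dual_probesets = FALSE,
                         planted_sign_features = list(
                           list(feature = "AP1F", odds = 3,
                                eigensystem = 2, systems = c("A", "B"))),
                         planted_count_effect = list(
                           family = "CREB", beta = 0.012, eigensystem = 3),
                         antagonist_pair = list(
                           effect = "AP1F", blocker = "SATB",
                           eigensystem = 2)) {
  cfg <- list(seed = as.integer(seed),
              n_genes_A = n_genes_A, n_genes_B = n_genes_B,
              frac_shared = frac_shared,
              n_conditions_A = n_conditions_A,
              n_conditions_B = n_conditions_B,
              n_replicates = n_replicates, k_shared = k_shared,
              singular_values = singular_values, noise_sd = noise_sd,
              baseline_log2 = baseline_log2, baseline_sd = baseline_sd,
              n_motif_families = n_motif_families,
              cns_per_gene_mean = cns_per_gene_mean,
              motifs_per_cns_mean = motifs_per_cns_mean,
              instance_excess_mean = instance_excess_mean,
              decoy_rate = decoy_rate, dual_probesets = dual_probesets,
              planted_sign_features = planted_sign_features,
              planted_count_effect = planted_count_effect,
              antagonist_pair = antagonist_pair)
  class(cfg) <- "eigencis_config"
  validate_synth_config(cfg)
  cfg
}

#' Validate a synthetic-data configuration
#'
#' @param cfg an `eigencis_config`.
#' @return `cfg`, invisibly; errors on an invalid configuration.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$frac_shared < 0 || cfg$frac_shared > 1)
    stop("frac_shared must lie in [0, 1]")
  if (cfg$frac_shared * min(cfg$n_genes_A, cfg$n_genes_B) < 1)
    stop("frac_shared * min(n_genes) must be >= 1")
  counts <- c(cfg$n_genes_A, cfg$n_genes_B, cfg$n_conditions_A,
              cfg$n_conditions_B, cfg$n_replicates, cfg$k_shared,
              cfg$n_motif_families)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$k_shared > min(cfg$n_conditions_A, cfg$n_conditions_B) - 1)
    stop("k_shared must not exceed min(n_conditions) - 1")
  sv <- cfg$singular_values
  if (length(sv) != cfg$k_shared - 1)
    stop("singular_values must have length k_shared - 1 ",
         "(the magnitude eigensystem is implied by the baseline)")
  if (any(sv <= 0) || is.unsorted(rev(sv)))
    stop("singular_values must be strictly positive and descending")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  fams <- .family_alphabet(cfg$n_motif_families)
  check_feat <- function(members, what) {
    if (length(members) < 1 || length(members) > 3)
      stop("planted composite motif in ", what, " must have size 1-3")
    if (!all(members %in% fams))
      stop(what, " references motif families outside the alphabet")
  }
  for (f in cfg$planted_sign_features)
    check_feat(f$feature, "planted_sign_features")
  if (!is.null(cfg$planted_count_effect)) {
    check_feat(cfg$planted_count_effect$family, "planted_count_effect")
    if (cfg$planted_count_effect$eigensystem > cfg$k_shared)
      stop("planted_count_effect eigensystem exceeds k_shared")
  }
  if (!is.null(cfg$antagonist_pair))
    check_feat(c(cfg$antagonist_pair$effect, cfg$antagonist_pair$blocker),
               "antagonist_pair")
  invisible(cfg)
}

# draw gene -> CNS -> motif-family assignments for the union gene set;
# returns the assignment table (one row per CNS x family, with conserved
# instance counts in both species tracks) and the CNS roster
.draw_cis_assignments <- function(genes, cfg) {
  fams <- .family_alphabet(cfg$n_motif_families)
  n_cns <- rpois(length(genes), cfg$cns_per_gene_mean)
  cns_gene <- rep(genes, n_cns)
  total <- length(cns_gene)
  cns_id <- sprintf("cns_%06d", seq_len(total))
  asg <- NULL
  if (total > 0) {
    nf <- cfg$n_motif_families
    m <- pmin(rpois(total, cfg$motifs_per_cns_mean), nf)
    # vectorised sampling-without-replacement: per CNS, the m families
    # with the smallest random keys are the ones present
    keys <- matrix(runif(total * nf), total, nf)
    rk <- matrix(0L, total, nf)
    for (i in which(m > 0)) rk[i, order(keys[i, ])[seq_len(m[i])]] <- 1L
    hit <- which(rk == 1L, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      asg <- data.frame(
        cns_id = cns_id[hit[, 1]], gene_id = cns_gene[hit[, 1]],
        family_id = fams[hit[, 2]],
        n_rat = 1L + rpois(nrow(hit), cfg$instance_excess_mean),
        n_human = 1L + rpois(nrow(hit), cfg$instance_excess_mean),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(asg))
    asg <- data.frame(cns_id = character(), gene_id = character(),
                      family_id = character(), n_rat = integer(),
                      n_human = integer(), stringsAsFactors = FALSE)
  cns_roster <- data.frame(cns_id = cns_id, gene_id = cns_gene,
                           stringsAsFactors = FALSE)
  list(assignments = asg, cns_roster = cns_roster)
}

# genes carrying a composite motif: >= 1 CNS holds all member families
.carriers <- function(members, assignments) {
  if (nrow(assignments) == 0) return(character())
  per <- lapply(members, function(f)
    unique(assignments$cns_id[assignments$family_id == f]))
  cns <- Reduce(intersect, per)
  unique(assignments$gene_id[assignments$cns_id %in% cns])
}

# per-gene conserved rat-track instance counts for one family
.family_counts <- function(family, genes, assignments) {
  cnt <- setNames(numeric(length(genes)), genes)
  sel <- assignments$family_id == family
  if (any(sel)) {
    s <- tapply(assignments$n_rat[sel], assignments$gene_id[sel], sum)
    cnt[names(s)] <- s
  }
  cnt
}

# remove the projection of w onto the columns of basis
.orth <- function(w, basis) {
  if (is.null(basis) || NCOL(basis) == 0) return(w)
  w - basis %*% crossprod(basis, w)
}

# per-system eigengene matrix: seeded smooth-ish random patterns,
# orthonormal, each column oriented so its largest-magnitude entry is
# positive (the same convention eigen_decompose() applies)
.make_eigengenes <- function(p, k) {
  v1 <- rep(1 / sqrt(p), p)
  V <- matrix(v1, p, 1)
  for (j in seq_len(k - 1)) {
    w <- .orth(rnorm(p), V)
    w <- w / sqrt(sum(w^2))
    V <- cbind(V, w)
  }
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# effective positive-sign odds per gene for one component of one system
.sign_odds <- function(genes, component, system, cfg, assignments) {
  odds <- setNames(rep(1, length(genes)), genes)
  feats <- cfg$planted_sign_features
  for (f in feats) {
    if (f$eigensystem != component) next
    if (!(system %in% f$systems)) next
    carr <- intersect(.carriers(f$feature, assignments), genes)
    odds[carr] <- odds[carr] * f$odds
    ant <- cfg$antagonist_pair
    if (!is.null(ant) && ant$eigensystem == component &&
        identical(sort(ant$effect), sort(unlist(f$feature)))) {
      # the blocker dominates: every blocker carrier gets the inverse
      # odds, so the effect motif's bias is nullified in that stratum
      # and the blocker itself represses
      blk <- intersect(.carriers(ant$blocker, assignments), genes)
      odds[blk] <- 1 / f$odds
    }
  }
  odds
}

# build the planted eigenarray matrix for one system
.make_loadings <- function(idx, genes_all, b, Z, Usig, counts_target, cfg,
                           system, assignments) {
  genes <- genes_all[idx]
  n <- length(genes)
  u1 <- b[idx] / sqrt(sum(b[idx]^2))
  U <- matrix(u1, n, 1)
  ce <- cfg$planted_count_effect
  for (k in 2:cfg$k_shared) {
    w <- Z[idx, k - 1]
    odds <- .sign_odds(genes, k, system, cfg, assignments)
    resamp <- odds != 1
    if (any(resamp)) {
      pos <- Usig[idx, k - 1][resamp] < odds[resamp] / (1 + odds[resamp])
      w[resamp] <- ifelse(pos, 1, -1) * abs(w[resamp])
    }
    if (!is.null(ce) && ce$eigensystem == k) {
      cc <- counts_target[idx]
      e <- ce$beta * (cc - mean(cc))
      e <- .orth(e, U)
      ne2 <- sum(e^2)
      if (ne2 >= 0.95^2)
        stop("planted count effect too large for unit-norm eigenarray ",
             "(beta or count spread too high)")
      z <- .orth(w, cbind(U, e / sqrt(ne2)))
      z <- z / sqrt(sum(z^2))
      u <- e + sqrt(1 - ne2) * z
    } else {
      u <- .orth(w, U)
      u <- u / sqrt(sum(u^2))
    }
    U <- cbind(U, u)
  }
  rownames(U) <- genes
  colnames(U) <- paste0("es", seq_len(ncol(U)))
  U
}

.make_design <- function(system, p, n_rep) {
  if (system == "A" && p == 5) {
    time_h <- c(0, 6, 12, 24, 48); treatment <- c("sham", rep("mcao", 4))
  } else if (system == "B" && p == 10) {
    time_h <- rep(c(1, 6, 24, 72, 240), 2)
    treatment <- rep(c("kainate", "saline"), each = 5)
  } else {
    time_h <- seq_len(p); treatment <- rep("treat", p)
  }
  cond <- sprintf("%s_c%02d", system, seq_len(p))
  data.frame(array_id = sprintf("%s_r%d", rep(cond, each = n_rep),
                                rep(seq_len(n_rep), p)),
             condition_id = rep(cond, each = n_rep),
             time_h = rep(time_h, each = n_rep),
             treatment = rep(treatment, each = n_rep),
             replicate = rep(seq_len(n_rep), p),
             stringsAsFactors = FALSE)
}

#' Generate a pair of synthetic probeset-level expression datasets
#'
#' Builds two systems whose replicate-averaged expression equals a planted
#' low-rank structure `U diag(s) V'` plus a constant per-gene row offset
#' (the magnitude eigensystem) plus i.i.d. Gaussian noise.  Shared genes
#' carry the same planted loadings in both systems (up to per-system
#' orthonormalisation and any system-specific planted effects).  Planted
#' sign and count effects act on the eigenarrays before expression
#' synthesis, so SVD re-estimation noise propagates into downstream
#' analyses honestly.
#'
#' @param cfg an [synth_config()] object.
#' @return a list with elements `expr_A`, `expr_B` (each holding `signal`
#'   and `calls` matrices on the linear scale, a `design` data.frame and a
#'   `probeset_map`), and `truth`, the planted ground truth.
#' @export
generate_paired_expression <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  m <- round(cfg$frac_shared * min(cfg$n_genes_A, cfg$n_genes_B))
  shared <- sprintf("gene_s%05d", seq_len(m))
  only_a <- sprintf("gene_a%05d", seq_len(cfg$n_genes_A - m))
  only_b <- sprintf("gene_b%05d", seq_len(cfg$n_genes_B - m))
  genes_all <- c(shared, only_a, only_b)
  idx_A <- c(seq_len(m), m + seq_along(only_a))
  idx_B <- c(seq_len(m), m + length(only_a) + seq_along(only_b))

  b <- pmax(rnorm(length(genes_all), cfg$baseline_log2, cfg$baseline_sd), 2)
  cis <- .draw_cis_assignments(genes_all, cfg)
  Z <- matrix(rnorm(length(genes_all) * (cfg$k_shared - 1)),
              ncol = cfg$k_shared - 1)
  Usig <- matrix(runif(length(genes_all) * (cfg$k_shared - 1)),
                 ncol = cfg$k_shared - 1)
  ce <- cfg$planted_count_effect
  counts_target <- if (is.null(ce)) rep(0, length(genes_all)) else
    .family_counts(ce$family, genes_all, cis$assignments)

  build <- function(system, idx, p) {
    genes <- genes_all[idx]
    U <- .make_loadings(idx, genes_all, b, Z, Usig, counts_target, cfg,
                        system, cis$assignments)
    V <- .make_eigengenes(p, cfg$k_shared)
    s <- c(sqrt(sum(b[idx]^2)) * sqrt(p), cfg$singular_values)
    Xbar <- U %*% (s * t(V))
    design <- .make_design(system, p, cfg$n_replicates)
    rep_cond <- match(design$condition_id,
                      sprintf("%s_c%02d", system, seq_len(p)))
    X <- Xbar[, rep_cond, drop = FALSE] +
      matrix(rnorm(length(genes) * nrow(design), 0, cfg$noise_sd),
             nrow = length(genes))
    colnames(X) <- design$array_id
    rownames(X) <- genes

    ps_id <- paste0("ps_", genes)
    map <- data.frame(probeset_id = ps_id, gene_id = genes,
                      stringsAsFactors = FALSE)
    signal <- 2^X
    rownames(signal) <- ps_id
    if (cfg$dual_probesets) {
      extra <- which(runif(length(genes)) < 0.1)
      if (length(extra) > 0) {
        dup <- 2^(X[extra, , drop = FALSE] +
                    matrix(rnorm(length(extra) * ncol(X), 0, 0.1),
                           nrow = length(extra)))
        rownames(dup) <- paste0("ps2_", genes[extra])
        signal <- rbind(signal, dup)
        map <- rbind(map, data.frame(probeset_id = rownames(dup),
                                     gene_id = genes[extra],
                                     stringsAsFactors = FALSE))
      }
    }
    calls <- matrix("P", nrow(signal), ncol(signal),
                    dimnames = dimnames(signal))
    dimnames(V) <- list(design$condition_id[!duplicated(design$condition_id)],
                        colnames(U))
    list(signal = signal, calls = calls, design = design,
         probeset_map = map, U = U, s = s, V = V)
  }

  A <- build("A", idx_A, cfg$n_conditions_A)
  B <- build("B", idx_B, cfg$n_conditions_B)

  truth <- list(genes_A = genes_all[idx_A], genes_B = genes_all[idx_B],
                shared_genes = shared,
                U_A = A$U, s_A = A$s, V_A = A$V,
                U_B = B$U, s_B = B$s, V_B = B$V,
                baseline = setNames(b, genes_all),
                counts_target = setNames(counts_target, genes_all),
                assignments = cis$assignments,
                cns_roster = cis$cns_roster,
                config = cfg)
  class(truth) <- "eigencis_truth"
  list(expr_A = A[c("signal", "calls", "design", "probeset_map")],
       expr_B = B[c("signal", "calls", "design", "probeset_map")],
       truth = truth)
}

#' Emit CNS and motif-instance tables for a generated gene set
#'
#' Formats the gene/CNS/motif assignments drawn during
#' [generate_paired_expression()] into BED-convention tables (0-based,
#' half-open) with one CNS row per species track and one motif-instance
#' row per instance.  Conserved instances appear in both tracks; decoy
#' instances (at rate `decoy_rate`) appear in one track only, for families
#' absent from the CNS, so they never create spurious conservation.
#'
#' @param cfg the [synth_config()] used to generate `truth`.
#' @param truth ground truth from [generate_paired_expression()].
#' @return list with `cns` and `motifs` data.frames and the updated
#'   `truth` (which records the decoy instances).
#' @export
generate_cis_tables <- function(cfg, truth) {
  roster <- truth$cns_roster
  asg <- truth$assignments
  n <- nrow(roster)
  len <- 100L + as.integer(round(rexp(n, 1 / 90)))
  ident <- runif(n, 0.75, 0.99)
  chrom_rat <- sprintf("chr%d", sample(20, n, replace = TRUE))
  chrom_hum <- sprintf("chr%d", sample(22, n, replace = TRUE))
  start_rat <- sample.int(1e8, n)
  start_hum <- sample.int(1e8, n)
  cns <- rbind(
    data.frame(cns_id = roster$cns_id, gene_id = roster$gene_id,
               species = "rat", chrom = chrom_rat, start = start_rat,
               end = start_rat + len, pct_identity = ident,
               stringsAsFactors = FALSE),
    data.frame(cns_id = roster$cns_id, gene_id = roster$gene_id,
               species = "human", chrom = chrom_hum, start = start_hum,
               end = start_hum + len, pct_identity = ident,
               stringsAsFactors = FALSE))
  len_of <- setNames(len, roster$cns_id)

  inst_block <- function(cns_ids, species, families) {
    k <- length(cns_ids)
    L <- len_of[cns_ids]
    data.frame(cns_id = cns_ids, species = species, family_id = families,
               start = as.integer(floor(runif(k) * pmax(L - 12L, 1L))),
               strand = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  motifs <- rbind(
    inst_block(rep(asg$cns_id, asg$n_rat), "rat",
               rep(asg$family_id, asg$n_rat)),
    inst_block(rep(asg$cns_id, asg$n_human), "human",
               rep(asg$family_id, asg$n_human)))

  # decoy non-conserved instances: a family absent from the chosen CNS,
  # emitted on a single species track (draws hitting a family already in
  # the CNS are discarded, so the realised rate is approximate)
  n_decoy <- round(cfg$decoy_rate * sum(asg$n_rat + asg$n_human))
  fams <- .family_alphabet(cfg$n_motif_families)
  n_kept <- 0L
  if (n_decoy > 0 && n > 0) {
    pick_cns <- sample(roster$cns_id, n_decoy, replace = TRUE)
    pick_sp <- sample(c("rat", "human"), n_decoy, replace = TRUE)
    pick_fam <- sample(fams, n_decoy, replace = TRUE)
    key <- paste(pick_cns, pick_fam)
    # never an assigned (CNS, family) pair, and never the same pair twice
    # (two draws on opposite tracks would fake conservation)
    ok <- !(key %in% paste(asg$cns_id, asg$family_id)) & !duplicated(key)
    n_kept <- sum(ok)
    if (n_kept > 0)
      motifs <- rbind(motifs, inst_block(pick_cns[ok], pick_sp[ok],
                                         pick_fam[ok]))
  }
  truth$n_decoy_instances <- n_kept
  list(cns = cns, motifs = motifs, truth = truth)
}

#' Generate a complete synthetic analysis bundle
#'
#' Runs [generate_paired_expression()] and [generate_cis_tables()] under
#' one seeded stream and optionally writes every table (and the ground
#' truth as JSON) to a directory.
#'
#' @param cfg an [synth_config()].
#' @param dir optional output directory; created if missing.
#' @return list with `expr_A`, `expr_B`, `cns`, `motifs`, `truth` and, if
#'   `dir` was given, `files` (named paths).
#' @export
simulate_bundle <- function(cfg, dir = NULL) {
  bundle <- generate_paired_expression(cfg)
  cis <- generate_cis_tables(cfg, bundle$truth)
  bundle$cns <- cis$cns
  bundle$motifs <- cis$motifs
  bundle$truth <- cis$truth
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c()
    for (sys in c("A", "B")) {
      ex <- bundle[[paste0("expr_", sys)]]
      files[paste0("signal_", sys)] <-
        write_tsv(mat_to_df(ex$signal, "probeset_id"),
                  file.path(dir, paste0("signal_", sys, ".tsv")))
      files[paste0("calls_", sys)] <-
        write_tsv(mat_to_df(ex$calls, "probeset_id"),
                  file.path(dir, paste0("calls_", sys, ".tsv")))
      files[paste0("design_", sys)] <-
        write_tsv(ex$design, file.path(dir, paste0("design_", sys, ".tsv")))
      files[paste0("probeset_map_", sys)] <-
        write_tsv(ex$probeset_map,
                  file.path(dir, paste0("probeset_map_", sys, ".tsv")))
    }
    files["cns"] <- write_tsv(bundle$cns, file.path(dir, "cns.tsv"))
    files["motifs"] <- write_tsv(bundle$motifs, file.path(dir, "motifs.tsv"))
    files["truth"] <- write_truth_json(bundle$truth,
                                       file.path(dir, "truth.json"))
    bundle$files <- files
  }
  bundle
}

#' Serialize ground truth to JSON
#'
#' @param truth an `eigencis_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  x$config <- unclass(x$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor", pretty = FALSE)
  invisible(path)
}

#' Reload ground truth from JSON
#'
#' Reconstitutes the matrices and named vectors written by
#' [write_truth_json()].
#'
#' @param path JSON path.
#' @return an `eigencis_truth`.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("U_A", "U_B", "V_A", "V_B")) {
    x[[nm]] <- as.matrix(x[[nm]])
    colnames(x[[nm]]) <- paste0("es", seq_len(ncol(x[[nm]])))
  }
  rownames(x$U_A) <- x$genes_A
  rownames(x$U_B) <- x$genes_B
  rownames(x$V_A) <- sprintf("A_c%02d", seq_len(nrow(x$V_A)))
  rownames(x$V_B) <- sprintf("B_c%02d", seq_len(nrow(x$V_B)))
  gene_union <- unique(c(x$genes_A, x$genes_B))
  x$baseline <- setNames(as.numeric(x$baseline), gene_union)
  x$counts_target <- setNames(as.numeric(x$counts_target), gene_union)
  for (df in c("assignments", "cns_roster"))
    x[[df]] <- as.data.frame(x[[df]], stringsAsFactors = FALSE)
  class(x$config) <- "eigencis_config"
  class(x) <- "eigencis_truth"
  x
}
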