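# Exact Bayesian parent-set selection over composite cis-regulatory
# motifs: BDe (BDeu) marginal likelihood, size-penalised structure prior,
# two-step exhaustive search, permutation q-values and cross-system
# validation.  The expression node is the binarized loading sign of one
# eigensystem; all edges point from motif features to that node, so
# acyclicity is trivial and the exhaustive subset search is exact.

#' Configuration for the Bayesian-network analysis
#'
#' @param ess equivalent sample size of the BDeu prior (default 1).
#' @param kappa structure-penalty base in (0,1); each parent contributes
#'   `kappa^size` to the structure prior, so larger composites are
#'   penalised more (default 0.5).
#' @param step1_pool_size number of composites retained by the first
#'   (singleton-scoring) step (default 120).
#' @param max_parents maximal parent-set size (default 3).
#' @param n_permutations label permutations for q-values (default 1000).
#' @param q_threshold significance threshold on q-values (default 0.05).
#' @param top_features_for_test training features carried into the
#'   cross-system test (default 10).
#' @param seed base seed; permutation `i` uses `seed + i`.
#' @return a `bde_config` list.
#' @export
bde_config <- function(ess = 1, kappa = 0.5, step1_pool_size = 120,
                       max_parents = 3, n_permutations = 1000,
                       q_threshold = 0.05, top_features_for_test = 10,
                       seed = 1) {
  stopifnot(ess > 0, kappa > 0, kappa < 1, step1_pool_size >= 1,
            max_parents >= 1, max_parents <= 3, n_permutations >= 1,
            q_threshold > 0, top_features_for_test >= 1)
  structure(list(ess = ess, kappa = kappa,
                 step1_pool_size = as.integer(step1_pool_size),
                 max_parents = as.integer(max_parents),
                 n_permutations = as.integer(n_permutations),
                 q_threshold = q_threshold,
                 top_features_for_test = as.integer(top_features_for_test),
                 seed = as.integer(seed)),
            class = "bde_config")
}

# align a GeneFeatureTable and SignedLoadings on their common genes
.align_bn_data <- function(features, signs) {
  genes <- intersect(features$genes, names(signs$loading))
  if (length(genes) < 1) stop("no labelled genes shared with features")
  X <- features$presence[genes, , drop = FALSE]
  storage.mode(X) <- "integer"
  y <- as.integer(signs$label[match(genes, names(signs$loading))] == "up")
  sizes <- features$composites$size[
    match(colnames(X), features$composites$composite_id)]
  list(genes = genes, X = X, y = y, sizes = as.integer(sizes))
}

#' BDe (BDeu) score of a parent set
#'
#' Log marginal likelihood of the binary target given binary parent
#' features, under a Dirichlet prior with pseudocounts `ess / (2q)` per
#' cell (`q = 2^k` parent configurations), plus the conditional
#' probability table with posterior-mean entries
#' `(N_j,up + a_j,up) / (N_j + a_j)`.
#'
#' @param y integer/logical vector (1 = positive loading sign).
#' @param parents matrix of binary gene-level features (columns are
#'   parents; may have zero columns for the empty set).
#' @param ess equivalent sample size.
#' @param max_parents guard on the parent count (default 3).
#' @return list with `log_ml` and `cpt` (data.frame: one row per parent
#'   configuration with the parent values, `n` genes and `p_up`).
#' @export
bde_score <- function(y, parents = NULL, ess = 1, max_parents = 3) {
  y <- as.integer(y)
  if (is.null(parents)) parents <- matrix(0L, length(y), 0)
  parents <- as.matrix(parents)
  k <- ncol(parents)
  if (k > max_parents) stop("more than max_parents parent features")
  if (k > 0 && nrow(parents) != length(y))
    stop("parents must be aligned to the same gene set as y")
  q <- 2^k
  code <- rep(0L, length(y))
  if (k > 0)
    for (b in seq_len(k)) code <- code + as.integer(parents[, b] != 0) *
      2L^(b - 1L)
  n1 <- as.vector(tapply(y, factor(code, levels = 0:(q - 1)), sum))
  n1[is.na(n1)] <- 0
  nj <- as.vector(table(factor(code, levels = 0:(q - 1))))
  n0 <- nj - n1
  aj <- ess / q
  ajc <- ess / (2 * q)
  log_ml <- sum(lgamma(aj) - lgamma(aj + nj) +
                  lgamma(ajc + n0) - lgamma(ajc) +
                  lgamma(ajc + n1) - lgamma(ajc))
  cfg_grid <- if (k > 0) {
    g <- expand.grid(rep(list(0:1), k))
    names(g) <- colnames(parents)
    g
  } else data.frame(row.names = "1")[, 0, drop = FALSE]
  cpt <- cbind(cfg_grid, n = nj, p_up = (n1 + ajc) / (nj + aj))
  rownames(cpt) <- NULL
  list(log_ml = log_ml, cpt = cpt)
}

#' Log structure prior of a parent set
#'
#' The prior over structures is proportional to a product of per-edge
#' penalties; a parent that is a size-`s` composite contributes
#' `kappa^s`, so the log prior is `sum(sizes) * log(kappa)` and the empty
#' set scores 0.
#'
#' @param sizes integer vector of composite sizes of the parents.
#' @param kappa penalty base in (0,1).
#' @return log prior (<= 0).
#' @export
structure_log_prior <- function(sizes, kappa = 0.5) {
  if (length(sizes) == 0) return(0)
  sum(sizes) * log(kappa)
}

#' Step 1: select promising composite motifs
#'
#' Scores every composite in the feature universe as a singleton parent
#' set (BDe marginal likelihood plus structure prior, relative to the
#' empty set) and retains the top `step1_pool_size` by score, ties broken
#' lexicographically on the composite id.
#'
#' @param features a `GeneFeatureTable`.
#' @param signs a `SignedLoadings`.
#' @param cfg a [bde_config()].
#' @return list with `pool` (composite ids, score order), `scores`
#'   (data.frame over the whole universe) and the aligned `data`.
#' @export
step1_select <- function(features, signs, cfg = bde_config()) {
  d <- .align_bn_data(features, signs)
  if (ncol(d$X) == 0)
    return(list(pool = character(), scores = data.frame(), data = d))
  res <- .bn_exhaustive_cpp(d$X, d$y, d$sizes, cfg$ess, log(cfg$kappa), 1L)
  ord <- order(-res$log_score, colnames(d$X))
  scores <- data.frame(composite_id = colnames(d$X)[ord],
                       size = d$sizes[ord],
                       log_bn_score = res$log_score[ord],
                       stringsAsFactors = FALSE)
  list(pool = head(scores$composite_id, cfg$step1_pool_size),
       scores = scores, data = d)
}

# deterministic label for a parent set
.set_label <- function(members) paste(sort(members), collapse = " + ")

#' Step 2: exhaustive exact search over parent sets from a pool
#'
#' Scores every subset of the candidate pool up to `max_parents` and
#' ranks non-empty sets by BN score (the posterior ratio to the empty
#' set).  The search is exhaustive, hence exact over the searched family.
#'
#' @param pool character vector of candidate composite ids.
#' @param features a `GeneFeatureTable`.
#' @param signs a `SignedLoadings`.
#' @param cfg a [bde_config()].
#' @return a `ScoredParentSets`: data.frame with `feature`, `members`
#'   (list-column), `n_parents`, `log_bn_score`, ranked descending (ties
#'   broken on the feature label), with the aligned data and config kept
#'   as attributes.
#' @export
step2_search <- function(pool, features, signs, cfg = bde_config()) {
  d <- .align_bn_data(features, signs)
  pool <- intersect(pool, colnames(d$X))
  p <- length(pool)
  n_subsets <- sum(choose(p, seq_len(min(cfg$max_parents, max(p, 1)))))
  if (n_subsets > 1e7)
    stop("pool of ", p, " features gives ", n_subsets,
         " subsets; reduce step1_pool_size or max_parents")
  if (p == 0) {
    out <- data.frame(feature = character(), n_parents = integer(),
                      log_bn_score = numeric())
    out$members <- list()
    attr(out, "data") <- d
    attr(out, "cfg") <- cfg
    class(out) <- c("ScoredParentSets", "data.frame")
    return(out)
  }
  X <- d$X[, pool, drop = FALSE]
  sizes <- d$sizes[match(pool, colnames(d$X))]
  res <- .bn_exhaustive_cpp(X, d$y, sizes, cfg$ess, log(cfg$kappa),
                            cfg$max_parents)
  members <- lapply(res$subsets, function(i) pool[i])
  lab <- vapply(members, .set_label, character(1))
  ord <- order(-res$log_score, lab)
  out <- data.frame(feature = lab[ord],
                    n_parents = lengths(members)[ord],
                    log_bn_score = res$log_score[ord],
                    stringsAsFactors = FALSE)
  out$members <- members[ord]
  attr(out, "data") <- d
  attr(out, "cfg") <- cfg
  class(out) <- c("ScoredParentSets", "data.frame")
  out
}

# permuted label matrix; permutation i is seeded with cfg$seed + i
.perm_labels <- function(y, cfg) {
  n <- length(y)
  ymat <- matrix(0L, n, cfg$n_permutations)
  for (i in seq_len(cfg$n_permutations)) {
    set.seed(cfg$seed + i)
    ymat[, i] <- y[sample.int(n)]
  }
  ymat
}

#' Permutation null of optimal BN scores
#'
#' For each permutation the gene labels are shuffled against the feature
#' table and the *full two-step search* is rerun: step-1 singleton
#' scoring over the whole feature universe, selection of the top
#' `step1_pool_size` composites, exhaustive step-2 search over that pool
#' (always augmented with `fixed_pool`, e.g. the other system's observed
#' step-1 selection, so a union-pool observed search has an exchangeable
#' null), and the best non-empty BN score is recorded.
#'
#' @param features a `GeneFeatureTable` (the whole universe).
#' @param signs a `SignedLoadings`.
#' @param cfg a [bde_config()].
#' @param fixed_pool composite ids always added to the per-permutation
#'   step-2 pool (default none).
#' @return a `PermutationNull`: list with `scores` (sorted descending),
#'   `n_permutations` and `scheme`.
#' @export
permutation_null <- function(features, signs, cfg = bde_config(),
                             fixed_pool = character()) {
  if (cfg$n_permutations < 100)
    warning("fewer than 100 permutations: q-value resolution is only 1/",
            cfg$n_permutations)
  d <- .align_bn_data(features, signs)
  fixed_idx <- match(intersect(fixed_pool, colnames(d$X)),
                     colnames(d$X)) - 1L
  ymat <- .perm_labels(d$y, cfg)
  best <- .bn_two_step_best_cpp(d$X, ymat, d$sizes, cfg$step1_pool_size,
                                as.integer(fixed_idx), cfg$ess,
                                log(cfg$kappa), cfg$max_parents)
  structure(list(scores = sort(best, decreasing = TRUE),
                 n_permutations = cfg$n_permutations,
                 scheme = "best nonempty set from a full two-step rerun per label permutation"),
            class = "PermutationNull")
}

# exceedance q-value of log-scores against a permutation null
.qvalue <- function(log_scores, null) {
  q <- vapply(log_scores, function(s) mean(null$scores >= s), numeric(1))
  cummax(q)  # monotone non-increasing in score for score-sorted input
}

#' Attach permutation q-values to ranked parent sets
#'
#' `q(s)` is the fraction of permutation-optimal scores at least `s`,
#' monotonized to be non-increasing in the score.
#'
#' @param ranked a `ScoredParentSets` from [step2_search()].
#' @param null a `PermutationNull` for the same system and pool.
#' @param cfg a [bde_config()].
#' @return a `FeatureReport`: the ranked non-empty sets with a `q` column
#'   and a `significant` flag at `cfg$q_threshold`.
#' @export
permutation_qvalues <- function(ranked, null, cfg = bde_config()) {
  rep_ <- ranked[ranked$n_parents > 0, , drop = FALSE]
  rep_$q <- .qvalue(rep_$log_bn_score, null)
  rep_$significant <- rep_$q < cfg$q_threshold
  attr(rep_, "null") <- null
  class(rep_) <- c("FeatureReport", "data.frame")
  rep_
}

# score one explicit parent set on given data; composites absent from the
# feature table enter as all-zero columns (flagged)
.score_set_on <- function(members, features, signs, cfg) {
  d <- .align_bn_data(features, signs)
  missing <- setdiff(members, colnames(d$X))
  X <- matrix(0L, length(d$genes), length(members),
              dimnames = list(d$genes, members))
  present <- intersect(members, colnames(d$X))
  X[, present] <- d$X[, present]
  sizes <- lengths(strsplit(members, "_", fixed = TRUE))
  sc <- bde_score(d$y, X, ess = cfg$ess, max_parents = cfg$max_parents)
  empty <- bde_score(d$y, NULL, ess = cfg$ess)
  list(log_bn_score = sc$log_ml +
         structure_log_prior(sizes, cfg$kappa) - empty$log_ml,
       cpt = sc$cpt, missing = missing)
}

#' Cross-system validation of top training features
#'
#' Takes the top training features (at most `top_features_for_test`, all
#' with training q below the threshold), scores each on the test system
#' and assigns test q-values from the test system's own permutation null.
#' A feature is cross-validated when both q-values fall below the
#' threshold.
#'
#' @param train_report a `FeatureReport` from the training system.
#' @param test_features test-system `GeneFeatureTable`.
#' @param test_signs test-system `SignedLoadings`.
#' @param test_null the test system's `PermutationNull`.
#' @param cfg a [bde_config()].
#' @return data.frame with per-feature train and test scores and
#'   q-values, `cross_validated` and `missing_in_test` flags.
#' @export
cross_validate <- function(train_report, test_features, test_signs,
                           test_null, cfg = bde_config()) {
  sel <- train_report[train_report$q < cfg$q_threshold, , drop = FALSE]
  sel <- head(sel, cfg$top_features_for_test)
  if (nrow(sel) == 0)
    return(data.frame(feature = character(), train_log_bn_score = numeric(),
                      train_q = numeric(), test_log_bn_score = numeric(),
                      test_q = numeric(), cross_validated = logical(),
                      missing_in_test = logical()))
  test_scores <- numeric(nrow(sel))
  missing <- logical(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    sc <- .score_set_on(sel$members[[i]], test_features, test_signs, cfg)
    test_scores[i] <- sc$log_bn_score
    missing[i] <- length(sc$missing) > 0
  }
  test_q <- vapply(test_scores, function(s)
    mean(test_null$scores >= s), numeric(1))
  data.frame(feature = sel$feature,
             train_log_bn_score = sel$log_bn_score, train_q = sel$q,
             test_log_bn_score = test_scores, test_q = test_q,
             cross_validated = sel$q < cfg$q_threshold &
               test_q < cfg$q_threshold,
             missing_in_test = missing,
             stringsAsFactors = FALSE)
}

#' Full two-system Bayesian-network analysis of one conserved eigensystem
#'
#' Step-1 pools are selected on each system and their union forms the
#' step-2 candidate pool on both systems (which makes the cross-system
#' scores comparable).  Each system gets an exhaustive step-2 ranking,
#' its own permutation null and q-values; the top training features are
#' then tested on the other system, in both directions.
#'
#' @param features_a,features_b `GeneFeatureTable`s.
#' @param signs_a,signs_b `SignedLoadings` of the matched eigensystem
#'   (system B already sign-flipped if the match required it).
#' @param cfg a [bde_config()].
#' @return list with `pool` (union), per-system `report_a`/`report_b`
#'   (FeatureReports), `null_a`/`null_b`, and `test_a_on_b`/`test_b_on_a`
#'   cross-validation tables.
#' @export
bn_eigensystem_analysis <- function(features_a, signs_a,
                                    features_b, signs_b,
                                    cfg = bde_config()) {
  s1a <- step1_select(features_a, signs_a, cfg)
  s1b <- step1_select(features_b, signs_b, cfg)
  pool <- sort(union(s1a$pool, s1b$pool))
  ranked_a <- step2_search(pool, features_a, signs_a, cfg)
  ranked_b <- step2_search(pool, features_b, signs_b, cfg)
  null_a <- permutation_null(features_a, signs_a, cfg, fixed_pool = s1b$pool)
  null_b <- permutation_null(features_b, signs_b, cfg, fixed_pool = s1a$pool)
  report_a <- permutation_qvalues(ranked_a, null_a, cfg)
  report_b <- permutation_qvalues(ranked_b, null_b, cfg)
  list(pool = pool,
       report_a = report_a, report_b = report_b,
       null_a = null_a, null_b = null_b,
       test_a_on_b = cross_validate(report_a, features_b, signs_b,
                                    null_b, cfg),
       test_b_on_a = cross_validate(report_b, features_a, signs_a,
                                    null_a, cfg))
}

#' Conditional probability table of a named parent set
#'
#' @param members character vector of composite ids.
#' @param features a `GeneFeatureTable`.
#' @param signs a `SignedLoadings`.
#' @param cfg a [bde_config()].
#' @return the CPT data.frame (parent configuration, gene count, P(up)).
#' @export
parent_set_cpt <- function(members, features, signs, cfg = bde_config()) {
  .score_set_on(members, features, signs, cfg)$cpt
}
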