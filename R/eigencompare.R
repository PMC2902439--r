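# Per-system SVD into eigensystems, cross-system eigenarray matching on
# common genes, the t-based correlation p-value, and sign-of-loading
# discretization.

#' Decompose a gene-expression matrix into eigensystems
#'
#' Thin SVD of the uncentred genes x conditions log2 matrix: columns of
#' `U` are eigenarrays (gene loadings), columns of `V` eigengenes.  A
#' deterministic sign convention orients each eigensystem so the eigengene
#' entry of largest magnitude is positive (ties broken by earliest
#' condition).
#'
#' @param gem a `GeneExpressionMatrix` (from [anova_filter()]) or a plain
#'   genes x conditions matrix.
#' @return an `EigenDecomposition`: list with `U`, `d` (singular values),
#'   `V`, `genes`, `conditions`.
#' @export
eigen_decompose <- function(gem) {
  X <- if (inherits(gem, "GeneExpressionMatrix")) gem$expr else gem
  if (!all(is.finite(X))) {
    bad <- rownames(X)[rowSums(!is.finite(X)) > 0]
    stop("non-finite expression for gene(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (nrow(X) < ncol(X))
    stop("need at least as many genes as conditions")
  sv <- svd(X)
  for (k in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, k]))
    if (sv$v[i, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  dimnames(sv$u) <- list(rownames(X), paste0("es", seq_along(sv$d)))
  dimnames(sv$v) <- list(colnames(X), paste0("es", seq_along(sv$d)))
  structure(list(U = sv$u, d = sv$d, V = sv$v,
                 genes = rownames(X), conditions = colnames(X)),
            class = "EigenDecomposition")
}

#' Two-sided p-value for a Pearson correlation
#'
#' The t statistic is `r * sqrt(d / (1 - r^2))` with `d = n - 2` degrees
#' of freedom; the two-sided p-value comes from the Student t
#' distribution, computed in log space so magnitudes far below the
#' double-precision underflow limit keep a meaningful power of ten.
#'
#' @param r Pearson correlation.
#' @param n number of paired observations (>= 3).
#' @return list with `t`, `df`, `p`, `log10_p` and `exponent`
#'   (`floor(log10_p)`, the power of ten of the p-value).  `|r| = 1`
#'   yields `p = 0` with `degenerate = TRUE`.
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| must be <= 1")
  d <- n - 2
  if (abs(r) == 1)
    return(list(t = Inf * sign(r), df = d, p = 0, log10_p = -Inf,
                exponent = -Inf, degenerate = TRUE))
  t <- r * sqrt(d / (1 - r^2))
  log10_p <- (log(2) + pt(-abs(t), df = d, log.p = TRUE)) / log(10)
  list(t = t, df = d, p = 10^log10_p, log10_p = log10_p,
       exponent = floor(log10_p), degenerate = FALSE)
}

#' Match eigenarrays between two systems on common genes
#'
#' Restricts each system's eigenarrays to the common gene set, computes
#' the full Pearson correlation grid, and matches greedily one-to-one on
#' `|r|` descending.  A negative correlation sets `sign_flip`, meaning
#' downstream consumers should negate system-B loadings for that
#' eigensystem.
#'
#' @param ed_a,ed_b `EigenDecomposition` objects.
#' @param k_max number of eigensystems to match (default 3).
#' @return list with `matches` (data.frame: k_a, k_b, r, n, df, t,
#'   log10_p, sign_flip) and `grid` (full correlation matrix), plus
#'   `common_genes`.
#' @export
match_eigenarrays <- function(ed_a, ed_b, k_max = 3) {
  common <- intersect(ed_a$genes, ed_b$genes)
  if (length(common) < 3)
    stop("need >= 3 common genes; found ", length(common))
  ka <- min(k_max, ncol(ed_a$U))
  kb <- min(k_max, ncol(ed_b$U))
  Ua <- ed_a$U[common, seq_len(ka), drop = FALSE]
  Ub <- ed_b$U[common, seq_len(kb), drop = FALSE]
  grid <- stats::cor(Ua, Ub)
  g <- abs(grid)
  rows <- list()
  while (length(rows) < min(ka, kb)) {
    i <- which(g == max(g), arr.ind = TRUE)[1, ]
    r <- grid[i[1], i[2]]
    pv <- correlation_pvalue(r, length(common))
    rows[[length(rows) + 1]] <-
      data.frame(k_a = i[1], k_b = i[2], r = r, n = length(common),
                 df = pv$df, t = pv$t, log10_p = pv$log10_p,
                 sign_flip = r < 0)
    g[i[1], ] <- -Inf
    g[, i[2]] <- -Inf
  }
  matches <- do.call(rbind, rows)
  matches <- matches[order(matches$k_a), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches, grid = grid, common_genes = common)
}

#' Binarize loadings of one eigensystem by sign
#'
#' @param ed an `EigenDecomposition`.
#' @param k eigensystem index.
#' @param flip negate loadings first (for matched system-B eigensystems
#'   with `sign_flip = TRUE`).
#' @return a `SignedLoadings`: list with `loading` (named numeric over
#'   genes with nonzero loading), `label` (`"up"`/`"down"`), `k`, and
#'   `n_zero` (count of excluded exact-zero loadings).
#' @export
binarize_loadings <- function(ed, k, flip = FALSE) {
  if (k > ncol(ed$U)) stop("k exceeds number of eigensystems")
  u <- ed$U[, k]
  if (flip) u <- -u
  nz <- u != 0
  structure(list(loading = u[nz],
                 label = ifelse(u[nz] > 0, "up", "down"),
                 k = k, n_zero = sum(!nz)),
            class = "SignedLoadings")
}

#' Robustness of eigenarrays to the ANOVA threshold
#'
#' Decomposes a loose- and a strict-threshold matrix and reports the
#' correlation between corresponding eigenarrays restricted to the shared
#' genes (which must be the strict gene set).
#'
#' @param gem_loose,gem_strict `GeneExpressionMatrix` objects; the strict
#'   gene set must be a subset of the loose one.
#' @param k_max number of eigensystems to compare.
#' @return data.frame with `k` and `r` (absolute correlation).
#' @export
robustness_check <- function(gem_loose, gem_strict, k_max = 3) {
  gl <- rownames(gem_loose$expr)
  gs <- rownames(gem_strict$expr)
  if (length(intersect(gl, gs)) == 0) stop("gene sets are disjoint")
  if (!all(gs %in% gl))
    stop("strict gene set must be a subset of the loose gene set")
  ed_l <- eigen_decompose(gem_loose)
  ed_s <- eigen_decompose(gem_strict)
  k <- min(k_max, ncol(ed_l$U), ncol(ed_s$U))
  r <- vapply(seq_len(k), function(j)
    abs(stats::cor(ed_l$U[gs, j], ed_s$U[gs, j])), numeric(1))
  data.frame(k = seq_len(k), r = r)
}
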