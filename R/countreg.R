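# Grouped weighted least-squares regression of eigensystem loadings on
# motif / CNS counts, heteroskedasticity and residual-normality checks,
# and the bivariate path analysis of CNS and motif counts.

#' Group loadings by integer count
#'
#' One group per exact count value (no binning).  In motif-regressor mode
#' only genes with at least one CNS are eligible; in CNS-regressor mode
#' all genes (including zero-CNS genes) are used.
#'
#' @param loadings named numeric vector of gene loadings.
#' @param counts named integer vector (same gene universe), or a
#'   two-column matrix/data.frame for bivariate grouping.
#' @param cns_count named integer vector of per-gene CNS counts, required
#'   for the eligibility rule.
#' @param mode `"motif"` (drop zero-CNS genes first) or `"cns"` (keep all
#'   genes).
#' @return a `CountGroups` data.frame: count column(s), `n`, `mean`,
#'   `sd` (`NA` for singleton groups).
#' @export
group_by_count <- function(loadings, counts, cns_count = NULL,
                           mode = c("motif", "cns")) {
  mode <- match.arg(mode)
  bivariate <- !is.null(dim(counts))
  cnt <- if (bivariate) as.data.frame(counts) else
    data.frame(count = counts)
  genes <- intersect(names(loadings),
                     if (bivariate) rownames(counts) else names(counts))
  if (mode == "motif") {
    if (is.null(cns_count)) stop("motif mode needs cns_count for eligibility")
    genes <- genes[cns_count[genes] >= 1]
  }
  if (length(genes) == 0) stop("no eligible genes")
  cnt <- cnt[match(genes, if (bivariate) rownames(counts) else
    names(counts)), , drop = FALSE]
  key <- do.call(paste, c(cnt, sep = ":"))
  y <- loadings[genes]
  agg <- unique(cnt)
  agg <- agg[do.call(order, as.list(agg)), , drop = FALSE]
  ukey <- do.call(paste, c(agg, sep = ":"))
  agg$n <- as.vector(table(key)[ukey])
  agg$mean <- as.vector(tapply(y, key, mean)[ukey])
  agg$sd <- as.vector(tapply(y, key, sd)[ukey])
  rownames(agg) <- NULL
  class(agg) <- c("CountGroups", "data.frame")
  agg
}

#' Weighted least-squares fit on count groups
#'
#' Regresses the group-mean loading on the count value(s) with weights
#' equal to the group gene counts, via `stats::lm`.  With weights equal
#' to group sizes this reproduces the gene-level ordinary least-squares
#' estimates of the same model.
#'
#' @param groups a `CountGroups` data.frame.
#' @return a `WLSFit`: list with `coefficients` (estimate, SE, t, p),
#'   `r_squared` (weighted), `residuals`, `weights`, `fit` (the lm
#'   object) and `df_residual`.
#' @export
wls_fit <- function(groups) {
  xcols <- setdiff(names(groups), c("n", "mean", "sd"))
  if (nrow(groups) < length(xcols) + 2)
    stop("need at least ", length(xcols) + 2, " groups")
  fml <- stats::as.formula(paste("mean ~", paste(xcols, collapse = " + ")))
  fit <- lm(fml, data = groups, weights = groups$n)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear regressors (rank deficiency): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p")
  w <- groups$n
  wm <- sum(w * groups$mean) / sum(w)
  ssr <- sum(w * residuals(fit)^2)
  sst <- sum(w * (groups$mean - wm)^2)
  structure(list(coefficients = coefs,
                 r_squared = 1 - ssr / sst,
                 residuals = residuals(fit), weights = w,
                 fitted = fitted(fit), fit = fit,
                 df_residual = fit$df.residual),
            class = "WLSFit")
}

#' Goldfeld-Quandt test for heteroskedasticity
#'
#' Orders the observations by the regressor, omits the central fraction
#' (default: the middle third), fits the model separately on the lower
#' and upper segments and compares their residual variances with an F
#' ratio (upper over lower).  Delegates to [lmtest::gqtest()].
#'
#' @param x regressor (ordering variable).
#' @param y response.
#' @param middle_frac central fraction omitted (default 1/3).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `GQResult`: list with `statistic`, `p`, `split` and the
#'   underlying htest object.
#' @export
gq_test <- function(x, y, middle_frac = 1/3,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(y)
  n_seg <- floor(n * (1 - middle_frac) / 2)
  if (n_seg < 3) stop("fewer than 3 observations per segment")
  ht <- lmtest::gqtest(y ~ x, point = 0.5, fraction = middle_frac,
                       order.by = x, alternative = alternative)
  structure(list(statistic = unname(ht$statistic), p = ht$p.value,
                 split = list(n = n, per_segment = n_seg,
                              middle_frac = middle_frac),
                 htest = ht),
            class = "GQResult")
}

#' Shapiro-Wilk normality check of weighted residuals
#'
#' Applied to `sqrt(weight) * residual` of a weighted fit.  Reported for
#' inspection only, never used as an automatic gate.  Degenerate
#' (constant) residuals are flagged and the p-value omitted.
#'
#' @param fit a `WLSFit`.
#' @return list with `W`, `p` and `degenerate`.
#' @export
residual_normality <- function(fit) {
  r <- sqrt(fit$weights) * fit$residuals
  if (length(r) < 3) stop("need >= 3 residuals")
  if (sd(r) < 1e-12 * (abs(mean(r)) + 1))
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  ht <- shapiro.test(r)
  list(W = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Univariate grouped WLS of loadings on a count
#'
#' Convenience wrapper: group, fit, Goldfeld-Quandt and normality checks
#' in one call.
#'
#' @param loadings named loadings.
#' @param counts named integer counts.
#' @param cns_count named CNS counts (eligibility).
#' @param mode eligibility mode, see [group_by_count()].
#' @return list with `groups`, `fit`, `slope` (estimate, se, t, p), `gq`,
#'   `normality`.
#' @export
count_regression <- function(loadings, counts, cns_count,
                             mode = c("motif", "cns")) {
  mode <- match.arg(mode)
  groups <- group_by_count(loadings, counts, cns_count, mode = mode)
  fit <- wls_fit(groups)
  genes <- intersect(names(loadings), names(counts))
  if (mode == "motif") genes <- genes[cns_count[genes] >= 1]
  gq <- tryCatch(gq_test(counts[genes], loadings[genes]),
                 error = function(e) NULL)
  list(groups = groups, fit = fit,
       slope = fit$coefficients[2, , drop = FALSE],
       gq = gq, normality = residual_normality(fit))
}

#' Path analysis of CNS count, motif count and loading
#'
#' Five grouped weighted regressions: (1) loading ~ CNS count over all
#' genes, (2) loading ~ motif count over genes with >= 1 CNS, (3) motif
#' count ~ CNS count over genes with >= 1 CNS, and the bivariate
#' (4) loading ~ CNS count + motif count giving the two partial edges.
#'
#' @param loadings named loadings.
#' @param cns_count named per-gene CNS counts.
#' @param motif_counts named per-gene counts of the motif of interest.
#' @return a `PathGraph`: data.frame of edges with `from`, `to`, `alpha`
#'   (directional coefficient) and `p`, plus the fits as an attribute.
#' @export
path_analysis <- function(loadings, cns_count, motif_counts) {
  e1 <- wls_fit(group_by_count(loadings, cns_count, cns_count,
                               mode = "cns"))
  e2 <- wls_fit(group_by_count(loadings, motif_counts, cns_count,
                               mode = "motif"))
  genes <- intersect(names(cns_count), names(motif_counts))
  genes <- genes[cns_count[genes] >= 1]
  mg <- group_by_count(setNames(as.numeric(motif_counts[genes]), genes),
                       cns_count[genes], cns_count, mode = "cns")
  e3 <- wls_fit(mg)
  both <- cbind(cns = cns_count, motif = motif_counts[names(cns_count)])
  rownames(both) <- names(cns_count)
  bg <- group_by_count(loadings, both, cns_count, mode = "cns")
  e45 <- wls_fit(bg)
  edge <- function(fit, row, from, to)
    data.frame(edge = NA_integer_, from = from, to = to,
               alpha = fit$coefficients[row, "estimate"],
               p = fit$coefficients[row, "p"], stringsAsFactors = FALSE)
  edges <- rbind(edge(e1, 2, "cns_count", "loading"),
                 edge(e2, 2, "motif_count", "loading"),
                 edge(e3, 2, "cns_count", "motif_count"),
                 edge(e45, "cns", "cns_count", "loading"),
                 edge(e45, "motif", "motif_count", "loading"))
  edges$edge <- seq_len(5)
  edges$type <- c("univariate", "univariate", "univariate",
                  "bivariate", "bivariate")
  attr(edges, "fits") <- list(e1 = e1, e2 = e2, e3 = e3, e45 = e45)
  class(edges) <- c("PathGraph", "data.frame")
  edges
}

#' Scan a count effect across all eigensystems
#'
#' Repeats the univariate grouped WLS of loadings on a motif count for
#' every eigensystem of a decomposition (specificity check).
#'
#' @param ed an `EigenDecomposition`.
#' @param counts named integer counts.
#' @param cns_count named CNS counts.
#' @param mode eligibility mode.
#' @return data.frame with `k`, `slope`, `se`, `p`, `r_squared`.
#' @export
count_effect_scan <- function(ed, counts, cns_count,
                              mode = c("motif", "cns")) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(ncol(ed$U)), function(k) {
    lo <- setNames(ed$U[, k], ed$genes)
    fit <- wls_fit(group_by_count(lo, counts, cns_count, mode = mode))
    data.frame(k = k, slope = fit$coefficients[2, "estimate"],
               se = fit$coefficients[2, "se"],
               p = fit$coefficients[2, "p"],
               r_squared = fit$r_squared)
  })
  do.call(rbind, rows)
}
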