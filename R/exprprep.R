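# Probeset-level signal tables -> ANOVA-filtered, replicate-averaged log2
# gene-expression matrices.

.check_design <- function(arrays, design) {
  if (anyDuplicated(design$array_id))
    stop("array_ids in the design are not unique")
  missing <- setdiff(arrays, design$array_id)
  if (length(missing) > 0)
    stop("arrays absent from the design: ",
         paste(head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

#' Filter probesets on detection calls
#'
#' Retains exactly the probesets detected (call `P` or `M`) on *all*
#' arrays of at least one condition.
#'
#' @param signal probesets x arrays matrix of linear-scale signals.
#' @param calls matching matrix of detection calls in `{P, M, A}`.
#' @param design array-design data.frame with `array_id` and
#'   `condition_id` columns.
#' @return list with the filtered `signal` and `calls` matrices.
#' @export
detection_filter <- function(signal, calls, design) {
  stopifnot(identical(dim(signal), dim(calls)))
  .check_design(colnames(signal), design)
  cond <- design$condition_id[match(colnames(signal), design$array_id)]
  ok <- calls == "P" | calls == "M"
  keep <- rep(FALSE, nrow(signal))
  for (cc in unique(cond)) {
    cols <- which(cond == cc)
    keep <- keep | rowSums(ok[, cols, drop = FALSE]) == length(cols)
  }
  list(signal = signal[keep, , drop = FALSE],
       calls = calls[keep, , drop = FALSE])
}

#' Average probeset signals to gene level
#'
#' Per gene, the arithmetic mean of its probesets' linear-scale signals on
#' each array; the log2 transform is applied afterwards, downstream.
#' Probesets without a mapping are dropped.  A probeset mapped to more
#' than one gene is an error in strict mode, or dropped (with a message)
#' in lenient mode.
#'
#' @param signal probesets x arrays linear signal matrix.
#' @param map data.frame with `probeset_id` and `gene_id`.
#' @param strict if `TRUE` (default), ambiguous probesets raise an error.
#' @return genes x arrays matrix of mean linear signals.
#' @export
average_to_genes <- function(signal, map, strict = TRUE) {
  dup <- unique(map$probeset_id[duplicated(map$probeset_id)])
  if (length(dup) > 0) {
    if (strict)
      stop("probesets mapped to more than one gene: ",
           paste(head(dup, 5), collapse = ", "))
    message("dropping ", length(dup), " ambiguously mapped probesets")
    map <- map[!(map$probeset_id %in% dup), , drop = FALSE]
  }
  keep <- rownames(signal) %in% map$probeset_id
  signal <- signal[keep, , drop = FALSE]
  gene <- map$gene_id[match(rownames(signal), map$probeset_id)]
  sums <- rowsum(signal, gene)
  n <- as.vector(table(gene)[rownames(sums)])
  sums / n
}

#' Log2-transform a gene-level signal matrix
#'
#' Signals at or below zero are floored at `eps` before the transform;
#' the number of floored values is reported as an attribute.
#'
#' @param gene_signal genes x arrays linear signal matrix.
#' @param eps positive floor (default `2^-10`).
#' @return log2 matrix with attribute `n_floored`.
#' @export
log2_signal <- function(gene_signal, eps = 2^-10) {
  n_floored <- sum(gene_signal <= 0)
  out <- log2(pmax(gene_signal, eps))
  attr(out, "n_floored") <- n_floored
  out
}

# vectorised one-way fixed-effects ANOVA across condition groups;
# returns F and p per row (cross-checked against stats::aov in the tests)
.row_anova <- function(x, groups) {
  groups <- as.factor(groups)
  n <- ncol(x)
  k <- nlevels(groups)
  counts <- as.vector(table(groups))
  gm <- rowMeans(x)
  cm <- t(rowsum(t(x), groups)) / rep(counts, each = nrow(x))
  ss_between <- rowSums(sweep(cm, 2, counts, "*") * cm) - n * gm^2
  ss_total <- rowSums(x^2) - n * gm^2
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  # no variability at all: F is 0/0; report p = 1 (no evidence of signal)
  degen <- ss_total < 1e-24
  p[degen] <- 1
  f[degen] <- 0
  # perfect separation: zero within-group variance with unequal means
  zero_within <- !degen & ss_within < 1e-24 & ss_between > 1e-24
  if (any(zero_within)) {
    warning(sum(zero_within),
            " gene(s) with zero within-group variance; p reported as 0")
    p[zero_within] <- 0
    f[zero_within] <- Inf
  }
  list(f = f, p = p)
}

#' ANOVA filtering and replicate averaging
#'
#' Per gene, a one-way fixed-effects ANOVA of log2 replicate values
#' across all conditions; genes with p < `alpha` are retained and their
#' replicate means per condition returned.  Condition order follows the
#' order of first appearance in the design.
#'
#' @param log_matrix genes x arrays log2 expression matrix.
#' @param design array-design data.frame.
#' @param alpha retention threshold on the ANOVA p-value (default 0.05;
#'   `alpha = 1` retains every gene).
#' @return a `GeneExpressionMatrix`: list with `expr` (genes x conditions
#'   means), `pvalue` (named, all tested genes) and `alpha`.
#' @export
anova_filter <- function(log_matrix, design, alpha = 0.05) {
  .check_design(colnames(log_matrix), design)
  cond <- design$condition_id[match(colnames(log_matrix), design$array_id)]
  cond_levels <- unique(design$condition_id)
  if (length(cond_levels) < 2) stop("need >= 2 conditions for ANOVA")
  if (any(table(cond) < 2)) stop("every condition needs >= 2 replicates")
  if (!all(is.finite(log_matrix)))
    stop("non-finite log2 values for gene(s): ",
         paste(head(rownames(log_matrix)[!complete.cases(log_matrix) |
             rowSums(!is.finite(log_matrix)) > 0], 5), collapse = ", "))
  a <- .row_anova(log_matrix, factor(cond, levels = cond_levels))
  # alpha = 1 is the "keep everything" path of the robustness analysis
  keep <- if (alpha >= 1) rep(TRUE, nrow(log_matrix)) else a$p < alpha
  means <- t(rowsum(t(log_matrix), factor(cond, levels = cond_levels))) /
    rep(as.vector(table(factor(cond, levels = cond_levels))),
        each = nrow(log_matrix))
  colnames(means) <- cond_levels
  structure(list(expr = means[keep, , drop = FALSE],
                 pvalue = setNames(a$p, rownames(log_matrix)),
                 alpha = alpha),
            class = "GeneExpressionMatrix")
}

#' Full preprocessing of one system
#'
#' Detection filter, probeset-to-gene averaging on the linear scale, log2
#' transform, then ANOVA filtering with replicate averaging.
#'
#' @param expr list with `signal`, `calls`, `design`, `probeset_map`
#'   (as produced by [generate_paired_expression()] or read from TSVs).
#' @param alpha ANOVA threshold.
#' @param strict ambiguity handling for [average_to_genes()].
#' @return a `GeneExpressionMatrix`.
#' @export
preprocess_system <- function(expr, alpha = 0.05, strict = TRUE) {
  det <- detection_filter(expr$signal, expr$calls, expr$design)
  gene_signal <- average_to_genes(det$signal, expr$probeset_map,
                                  strict = strict)
  lg <- log2_signal(gene_signal)
  anova_filter(lg, expr$design, alpha = alpha)
}
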