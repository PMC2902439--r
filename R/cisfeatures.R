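# CNS and motif-instance tables -> conserved motifs, composite-motif
# enumeration, gene-level binary feature tables and motif/CNS counts.
# Coordinates are BED-style 0-based half-open.

#' Validate CNS records
#'
#' A CNS is valid when both species tracks are present, each interval is
#' at least `min_length` bp (inclusive) and the identity fraction is at
#' least `min_identity` (inclusive).  Rejected rows are returned in a log.
#'
#' @param cns data.frame with columns `cns_id`, `gene_id`, `species`,
#'   `chrom`, `start`, `end`, `pct_identity`.
#' @param min_length minimum length in bp (default 100).
#' @param min_identity minimum identity fraction (default 0.75).
#' @return list with `cns` (valid rows), `rejected` (invalid rows with a
#'   `reason` column) and `summary` (CNS count, mean/SD length of valid
#'   CNSs).
#' @export
validate_cns <- function(cns, min_length = 100, min_identity = 0.75) {
  need <- c("cns_id", "gene_id", "species", "chrom", "start", "end",
            "pct_identity")
  if (!all(need %in% names(cns)))
    stop("CNS table must have columns: ", paste(need, collapse = ", "))
  len <- cns$end - cns$start
  reason <- rep(NA_character_, nrow(cns))
  reason[cns$end <= cns$start] <- "end <= start"
  reason[is.na(reason) & len < min_length] <- "too short"
  reason[is.na(reason) & cns$pct_identity < min_identity] <- "low identity"
  # a CNS is rejected as a whole if any of its species rows fails,
  # or if it lacks one of the two tracks
  bad_ids <- unique(cns$cns_id[!is.na(reason)])
  two_tracks <- tapply(cns$species, cns$cns_id,
                       function(s) length(unique(s)) == 2)
  bad_ids <- union(bad_ids, names(two_tracks)[!two_tracks])
  bad <- cns$cns_id %in% bad_ids
  reason[bad & is.na(reason)] <- "partner track rejected or missing"
  valid <- cns[!bad, , drop = FALSE]
  vlen <- valid$end - valid$start
  list(cns = valid,
       rejected = cbind(cns[bad, , drop = FALSE],
                        reason = reason[bad])[seq_len(sum(bad)), ,
                                              drop = FALSE],
       summary = list(n_cns = length(unique(valid$cns_id)),
                      mean_length = if (length(vlen)) mean(vlen) else NA,
                      sd_length = if (length(vlen) > 1) sd(vlen) else NA))
}

#' Conserved motifs per CNS
#'
#' A motif family is conserved in a CNS when both species tracks of that
#' CNS contain at least one instance of the family; aligned positions are
#' irrelevant.
#'
#' @param cns valid CNS table (as returned in `validate_cns()$cns`).
#' @param instances motif-instance data.frame with `cns_id`, `species`,
#'   `family_id`, `start`, `strand`.
#' @return data.frame with `cns_id`, `gene_id`, `family_id` and the
#'   per-track instance counts `n_rat`... (one column per species,
#'   named `n_<species>`).
#' @export
conserved_motifs <- function(cns, instances) {
  unknown <- setdiff(unique(instances$cns_id), unique(cns$cns_id))
  if (length(unknown) > 0)
    stop("motif instances reference unknown cns_ids: ",
         paste(head(unknown, 5), collapse = ", "))
  species <- sort(unique(instances$species))
  if (length(species) == 0)
    return(data.frame(cns_id = character(), gene_id = character(),
                      family_id = character(), stringsAsFactors = FALSE))
  key <- paste(instances$cns_id, instances$family_id)
  tab <- table(key, factor(instances$species, levels = species))
  conserved <- rownames(tab)[rowSums(tab > 0) == length(species)]
  if (length(conserved) == 0)
    return(data.frame(cns_id = character(), gene_id = character(),
                      family_id = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(conserved, " ", fixed = TRUE))
  out <- data.frame(cns_id = parts[, 1], family_id = parts[, 2],
                    stringsAsFactors = FALSE)
  gene_of <- cns$gene_id[match(out$cns_id, cns$cns_id)]
  out$gene_id <- gene_of
  counts <- as.data.frame.matrix(tab[conserved, , drop = FALSE])
  names(counts) <- paste0("n_", species)
  cbind(out[, c("cns_id", "gene_id", "family_id")], counts)
}

# canonical composite id: sorted families joined by "_"
composite_id <- function(members) paste(sort(members), collapse = "_")

#' Enumerate composite motifs and build the gene feature table
#'
#' Per CNS with `m` distinct conserved families, every non-empty family
#' subset of size at most `max_size` is a composite-motif instance;
#' gene-level presence is the union over the gene's CNSs.  Composites
#' carried by fewer than `min_gene_support` genes can be dropped from the
#' feature universe (used before network learning to avoid degenerate
#' contingency tables).
#'
#' @param conserved output of [conserved_motifs()].
#' @param genes character vector of addressable gene ids (genes without
#'   any CNS get all-zero rows).
#' @param max_size maximal composite size (1-3, default 3).
#' @param min_gene_support minimal number of carrier genes (default 1,
#'   i.e. no filtering).
#' @return a `GeneFeatureTable`: list with `presence` (genes x composites
#'   logical matrix), `composites` (data.frame: composite_id, size,
#'   n_genes) and `genes`.
#' @export
enumerate_composites <- function(conserved, genes, max_size = 3,
                                 min_gene_support = 1) {
  if (!(max_size %in% 1:3)) stop("max_size must be 1, 2 or 3")
  gene_acc <- character(0)
  id_acc <- character(0)
  size_acc <- integer(0)
  if (nrow(conserved) > 0) {
    fam_by_cns <- split(conserved$family_id, conserved$cns_id)
    gene_by_cns <- conserved$gene_id[!duplicated(conserved$cns_id)]
    names(gene_by_cns) <- conserved$cns_id[!duplicated(conserved$cns_id)]
    # combn index matrices cached per distinct family count
    idx2 <- list(); idx3 <- list()
    acc <- vector("list", length(fam_by_cns))
    for (i in seq_along(fam_by_cns)) {
      fams <- sort(unique(fam_by_cns[[i]]))
      mm <- length(fams)
      ids <- fams
      sizes <- rep(1L, mm)
      if (max_size >= 2 && mm >= 2) {
        if (is.null(idx2[[paste0(mm)]])) idx2[[paste0(mm)]] <- combn(mm, 2)
        cb <- idx2[[paste0(mm)]]
        ids <- c(ids, paste(fams[cb[1, ]], fams[cb[2, ]], sep = "_"))
        sizes <- c(sizes, rep(2L, ncol(cb)))
      }
      if (max_size >= 3 && mm >= 3) {
        if (is.null(idx3[[paste0(mm)]])) idx3[[paste0(mm)]] <- combn(mm, 3)
        cb <- idx3[[paste0(mm)]]
        ids <- c(ids, paste(fams[cb[1, ]], fams[cb[2, ]], fams[cb[3, ]],
                            sep = "_"))
        sizes <- c(sizes, rep(3L, ncol(cb)))
      }
      acc[[i]] <- list(ids, sizes)
    }
    id_acc <- unlist(lapply(acc, `[[`, 1), use.names = FALSE)
    size_acc <- unlist(lapply(acc, `[[`, 2), use.names = FALSE)
    gene_acc <- rep(gene_by_cns[names(fam_by_cns)],
                    vapply(acc, function(a) length(a[[1]]), integer(1)))
  }
  gc_tab <- data.frame(gene_id = gene_acc, composite_id = id_acc,
                       size = size_acc, stringsAsFactors = FALSE)
  gc_tab <- gc_tab[!duplicated(paste(gc_tab$gene_id, gc_tab$composite_id)), ,
                   drop = FALSE]
  comp_ids <- sort(unique(gc_tab$composite_id))
  presence <- matrix(FALSE, length(genes), length(comp_ids),
                     dimnames = list(genes, comp_ids))
  if (nrow(gc_tab) > 0) {
    keep <- gc_tab$gene_id %in% genes
    presence[cbind(match(gc_tab$gene_id[keep], genes),
                   match(gc_tab$composite_id[keep], comp_ids))] <- TRUE
  }
  size_of <- gc_tab$size[match(comp_ids, gc_tab$composite_id)]
  n_genes <- colSums(presence)
  ok <- n_genes >= min_gene_support
  structure(list(presence = presence[, ok, drop = FALSE],
                 composites = data.frame(composite_id = comp_ids[ok],
                                         size = size_of[ok],
                                         n_genes = n_genes[ok],
                                         stringsAsFactors = FALSE,
                                         row.names = NULL),
                 genes = genes,
                 n_dropped = sum(!ok)),
            class = "GeneFeatureTable")
}

#' Per-gene motif and CNS counts
#'
#' Counts instances of conserved motif families on the designated count
#' species track (default rat), summed over each gene's valid CNSs, plus
#' the number of valid CNSs per gene.  Genes with no CNS stay addressable
#' with zero counts.
#'
#' @param cns valid CNS table.
#' @param conserved output of [conserved_motifs()].
#' @param genes addressable gene ids.
#' @param families families to count (default: all conserved families).
#' @param count_species species track whose instances are counted
#'   (default `"rat"`).
#' @return list with `cns_count` (named integer) and `motif_counts`
#'   (genes x families matrix).
#' @export
count_features <- function(cns, conserved, genes, families = NULL,
                           count_species = "rat") {
  col <- paste0("n_", count_species)
  if (nrow(conserved) > 0 && !(col %in% names(conserved)))
    stop("no instance counts for species '", count_species, "'")
  if (is.null(families)) families <- sort(unique(conserved$family_id))
  cns_count <- setNames(integer(length(genes)), genes)
  per_gene <- table(unique(cns[, c("cns_id", "gene_id")])$gene_id)
  cns_count[names(per_gene)] <- as.integer(per_gene)
  mc <- matrix(0L, length(genes), length(families),
               dimnames = list(genes, families))
  if (nrow(conserved) > 0 && length(families) > 0) {
    sel <- conserved$family_id %in% families & conserved$gene_id %in% genes
    if (any(sel)) {
      agg <- tapply(conserved[[col]][sel],
                    list(conserved$gene_id[sel], conserved$family_id[sel]),
                    sum)
      mc[rownames(agg), colnames(agg)] <-
        ifelse(is.na(agg), 0L, as.integer(agg))
    }
  }
  list(cns_count = cns_count, motif_counts = mc)
}

#' Build all cis-regulatory features for a gene universe
#'
#' Convenience wrapper: CNS validation, motif conservation, composite
#' enumeration and count extraction in one call.
#'
#' @param cns raw CNS table.
#' @param motifs raw motif-instance table.
#' @param genes addressable gene ids.
#' @param max_size,min_gene_support passed to [enumerate_composites()].
#' @param count_species passed to [count_features()].
#' @return list with `features` (a `GeneFeatureTable`), `counts`,
#'   `conserved`, and the `validation` log.
#' @export
build_cis_features <- function(cns, motifs, genes, max_size = 3,
                               min_gene_support = 5,
                               count_species = "rat") {
  val <- validate_cns(cns)
  cons <- conserved_motifs(val$cns, motifs)
  feats <- enumerate_composites(cons, genes, max_size = max_size,
                                min_gene_support = min_gene_support)
  cts <- count_features(val$cns, cons, genes,
                        count_species = count_species)
  list(features = feats, counts = cts, conserved = cons, validation = val)
}
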