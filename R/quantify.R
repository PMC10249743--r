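# CPM normalisation, the two-stage abundance filter, sequence- and
# feature-level log2 fold changes, and composition summaries.

#' Counts-per-million normalisation
#'
#' `value = count * 1e6 / column_total`. The column total is computed over
#' all rows of the supplied matrix — for the standard workflow that is the
#' stage-1 survivors, before any biotype exclusion, so rRNA-derived
#' sequences still contribute to depth even though they are excluded from
#' downstream displays.
#'
#' @param counts sequence x sample count matrix.
#' @return CPM matrix of the same shape.
#' @export
cpm_normalize <- function(counts) {
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("zero column total for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Two-stage abundance filter
#'
#' Stage 1 (on raw counts) drops sequences whose length is outside
#' `size`, sequences with fewer than `min_count` counts in fewer than
#' `ceiling(min_count_frac * n_samples)` samples, and (when
#' `require_genome_match`) sequences with origin `unmapped`. CPM is then
#' computed on the stage-1 survivors, and stage 2 drops sequences below
#' `min_cpm` CPM in fewer than `ceiling(min_cpm_frac * n_samples)` samples.
#' All thresholds are inclusive.
#'
#' @param table an `scount_table`.
#' @param anno matching annotation table (required when
#'   `require_genome_match`).
#' @param size inclusive length window in nt.
#' @param min_count,min_count_frac stage-1 prevalence rule.
#' @param min_cpm,min_cpm_frac stage-2 prevalence rule (CPM scale).
#' @param require_genome_match drop sequences that match neither genome.
#' @return list: `table` (filtered `scount_table`), `cpm` (CPM matrix of
#'   stage-2 survivors, depth from stage-1 survivors), `report` (sequences
#'   dropped per rule, in order of application).
#' @export
apply_filters <- function(table, anno = NULL, size = c(18, 50),
                          min_count = 10, min_count_frac = 0.60,
                          min_cpm = 20, min_cpm_frac = 0.25,
                          require_genome_match = TRUE) {
  stopifnot(inherits(table, "scount_table"))
  for (fr in c(min_count_frac, min_cpm_frac)) {
    if (!is.numeric(fr) || fr <= 0 || fr > 1) {
      stop("prevalence fractions must be in (0, 1]")
    }
  }
  if (require_genome_match && is.null(anno)) {
    stop("'anno' is required when require_genome_match = TRUE")
  }
  counts <- table$counts
  n_samples <- ncol(counts)
  report <- list()

  len <- nchar(rownames(counts))
  keep <- len >= size[1] & len <= size[2]
  report$dropped_size <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]

  need <- ceiling(min_count_frac * n_samples)
  keep <- rowSums(counts >= min_count) >= need
  report$dropped_min_count <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]

  if (require_genome_match) {
    origin <- anno$origin[match(rownames(counts), anno$sequence)]
    keep <- !is.na(origin) & origin != "unmapped"
    report$dropped_unmapped <- sum(!keep)
    counts <- counts[keep, , drop = FALSE]
  } else {
    report$dropped_unmapped <- 0L
  }

  cpm1 <- cpm_normalize(counts)
  need2 <- ceiling(min_cpm_frac * n_samples)
  keep <- rowSums(cpm1 >= min_cpm) >= need2
  report$dropped_min_cpm <- sum(!keep)

  out <- table
  out$counts <- counts[keep, , drop = FALSE]
  out$stage1_counts <- counts
  list(table = out, cpm = cpm1[keep, , drop = FALSE],
       report = unlist(report))
}

#' Log2 fold change between two groups
#'
#' `log2fc = log2((mean_a + pseudocount) / (mean_b + pseudocount))` on mean
#' CPM per group. The standard error follows the per-individual convention:
#' the SEM over samples `i` of group a of
#' `log2((cpm[a, i] + pseudocount) / (mean_b + pseudocount))`.
#'
#' @param mat feature x sample CPM (or aggregated feature CPM) matrix.
#' @param pheno sample sheet with `sample` and `group` columns matching the
#'   matrix columns.
#' @param group_a,group_b numerator and denominator group labels.
#' @param pseudocount added to both means (and per-sample values in the SEM)
#'   to stabilise zeros.
#' @return data frame (class `fc_table`): feature, mean_a, mean_b, log2fc,
#'   sem_log2fc, direction (up/down/zero).
#' @export
log2fc <- function(mat, pheno, group_a, group_b, pseudocount = 1.0) {
  for (g in c(group_a, group_b)) {
    if (!g %in% pheno$group) stop("unknown group: ", g)
  }
  sa <- pheno$sample[pheno$group == group_a]
  sb <- pheno$sample[pheno$group == group_b]
  ma <- rowMeans(mat[, sa, drop = FALSE])
  mb <- rowMeans(mat[, sb, drop = FALSE])
  lfc <- log2((ma + pseudocount) / (mb + pseudocount))
  per_ind <- log2(sweep(mat[, sa, drop = FALSE] + pseudocount, 1,
                        mb + pseudocount, "/"))
  sem <- apply(per_ind, 1, stats::sd) / sqrt(length(sa))
  out <- data.frame(feature = rownames(mat), mean_a = ma, mean_b = mb,
                    log2fc = lfc, sem_log2fc = sem,
                    direction = ifelse(lfc > 0, "up",
                                       ifelse(lfc < 0, "down", "zero")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- c(a = group_a, b = group_b)
  class(out) <- c("fc_table", "data.frame")
  out
}

#' Fold-change summary by biotype and genome origin
#'
#' For each biotype split by origin: number of transcripts, mean and median
#' log2 fold change, and the percentage up- (log2fc > 0) and down-regulated
#' (< 0); exact zeros are counted separately. Empty cells are emitted with
#' `n = 0` and `NA` summaries.
#'
#' @param fc a sequence-level [log2fc()] table.
#' @param anno matching annotation table.
#' @param include_excluded keep biotypes flagged excluded (rRNA)?
#' @return data frame: biotype, origin, n, mean_log2fc, median_log2fc,
#'   pct_up, pct_down, n_zero.
#' @export
origin_fc_summary <- function(fc, anno, include_excluded = FALSE) {
  m <- match(fc$feature, anno$sequence)
  df <- data.frame(biotype = anno$biotype[m], origin = anno$origin[m],
                   excluded = anno$excluded[m], log2fc = fc$log2fc,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$biotype), , drop = FALSE]
  if (!include_excluded) df <- df[!df$excluded, , drop = FALSE]
  biotypes <- unique(anno$biotype[if (include_excluded) TRUE else !anno$excluded])
  origins <- unique(anno$origin)
  grid <- expand.grid(biotype = biotypes, origin = origins,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- df$log2fc[df$biotype == grid$biotype[i] & df$origin == grid$origin[i]]
    n <- length(x)
    data.frame(biotype = grid$biotype[i], origin = grid$origin[i], n = n,
               mean_log2fc = if (n) mean(x) else NA_real_,
               median_log2fc = if (n) stats::median(x) else NA_real_,
               pct_up = if (n) 100 * sum(x > 0) / n else NA_real_,
               pct_down = if (n) 100 * sum(x < 0) / n else NA_real_,
               n_zero = sum(x == 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$biotype, out$origin), , drop = FALSE]
}

#' Size distribution of mean CPM by biotype
#'
#' Per group and read length, the summed mean CPM per biotype. Excluded
#' biotypes (rRNA-derived reads) are omitted; lncRNA, piRNA, protein-coding
#' and unannotated sequences can be grouped as "other".
#'
#' @param cpm_mat sequence x sample CPM matrix.
#' @param anno matching annotation table.
#' @param pheno sample sheet.
#' @param groups groups to tabulate (default: all).
#' @param lengths length range of the table.
#' @param collapse_other collapse minor biotypes into "other".
#' @return long data frame: group, length, biotype, mean_cpm.
#' @export
size_distribution <- function(cpm_mat, anno, pheno,
                              groups = unique(pheno$group),
                              lengths = 18:50, collapse_other = TRUE) {
  m <- match(rownames(cpm_mat), anno$sequence)
  biotype <- anno$biotype[m]
  excluded <- anno$excluded[m]
  if (collapse_other) {
    biotype[biotype %in% c("lncRNA", "piRNA", "protein_coding", "no_anno")] <- "other"
  }
  len <- nchar(rownames(cpm_mat))
  keep <- !excluded & len %in% lengths
  rows <- list()
  for (g in groups) {
    samples <- pheno$sample[pheno$group == g]
    mu <- rowMeans(cpm_mat[, samples, drop = FALSE])
    for (bt in unique(biotype[keep])) {
      for (l in lengths) {
        idx <- keep & biotype == bt & len == l
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, length = l, biotype = bt, mean_cpm = sum(mu[idx]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
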