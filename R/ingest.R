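# Adapter trimming and read collapsing into a unique-sequence count table.
# Only reads with an adapter present are kept; unique sequences must show
# evidence in at least `min_samples` separate samples.

#' Read a FASTQ file
#'
#' @param path FASTQ file (optionally gzipped). Qualities are not used
#'   downstream and are dropped.
#' @return character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Trim the 3' adapter from reads
#'
#' For each read, the leftmost occurrence of the full adapter is located;
#' failing that, the longest adapter prefix of length `>= min_overlap` that
#' is a suffix of the read (a read window that ended inside the adapter).
#' The insert 5' of the match is emitted. Reads with no qualifying match
#' are discarded and counted, as are zero-length inserts.
#'
#' @param reads character vector of read sequences.
#' @param adapter adapter sequence over ACGT.
#' @param min_overlap minimum adapter prefix length for a truncated match.
#' @return list: `insert` (character, `NA` where discarded), `status`
#'   (factor: kept / no_adapter / empty_insert), `counters` (named integer:
#'   input, kept, no_adapter, empty_insert).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L) {
  if (!is.character(adapter) || length(adapter) != 1L || nchar(adapter) == 0L ||
      grepl("[^ACGT]", adapter)) {
    stop("adapter must be a non-empty string over ACGT")
  }
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  n <- length(reads)
  insert <- rep(NA_character_, n)
  status <- rep("no_adapter", n)
  if (n > 0L) {
    pos <- regexpr(adapter, reads, fixed = TRUE)
    full <- pos > 0L
    insert[full] <- substr(reads[full], 1L, pos[full] - 1L)
    pending <- which(!full)
    kmax <- min(nchar(adapter) - 1L, if (length(pending)) max(nchar(reads[pending])) else 0L)
    if (kmax >= min_overlap) {
      for (k in kmax:min_overlap) {     # longest truncated prefix wins
        if (length(pending) == 0L) break
        hit <- endsWith(reads[pending], substr(adapter, 1L, k))
        idx <- pending[hit]
        insert[idx] <- substr(reads[idx], 1L, nchar(reads[idx]) - k)
        pending <- pending[!hit]
      }
    }
    matched <- !is.na(insert)
    status[matched & nchar(insert) > 0L] <- "kept"
    status[matched & nchar(insert) == 0L] <- "empty_insert"
    insert[status != "kept"] <- NA_character_
  }
  status <- factor(status, levels = c("kept", "no_adapter", "empty_insert"))
  counters <- c(input = n, kept = sum(status == "kept"),
                no_adapter = sum(status == "no_adapter"),
                empty_insert = sum(status == "empty_insert"))
  list(insert = insert, status = status, counters = counters)
}

#' Collapse trimmed reads into a unique-sequence count table
#'
#' Tallies exact sequences per sample and drops sequences lacking evidence
#' of at least `min_count` counts in at least `min_samples` distinct
#' samples. Sequences containing `N` are dropped (and counted) before the
#' evidence rule. Rows are ordered by descending total count, ties broken
#' lexicographically, so output is byte-reproducible.
#'
#' @param sample_inserts named list (one element per sample) of trimmed
#'   insert sequences.
#' @param min_count minimum per-sample count for the evidence rule.
#' @param min_samples minimum number of samples meeting `min_count`.
#' @param pheno optional sample sheet (data frame with at least a `sample`
#'   column) attached to the result.
#' @return object of class `scount_table`: `counts` (sequence x sample
#'   integer matrix), `pheno`, `report` (per-sample reads dropped by the
#'   evidence rule, N-containing reads, reads retained).
#' @export
collapse_reads <- function(sample_inserts, min_count = 1L, min_samples = 2L,
                           pheno = NULL) {
  if (length(sample_inserts) < 1L) stop("at least one sample is required")
  if (is.null(names(sample_inserts)) || anyDuplicated(names(sample_inserts))) {
    stop("sample_inserts must have unique names")
  }
  samples <- names(sample_inserts)
  n_with_n <- integer(length(samples))
  tallies <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    x <- sample_inserts[[s]]
    x <- x[!is.na(x)]
    has_n <- grepl("N", x, fixed = TRUE)
    n_with_n[s] <- sum(has_n)
    tallies[[s]] <- table(x[!has_n])
  }
  all_seqs <- sort(unique(unlist(lapply(tallies, names), use.names = FALSE)))
  counts <- matrix(0L, length(all_seqs), length(samples),
                   dimnames = list(all_seqs, samples))
  for (s in seq_along(samples)) {
    t <- tallies[[s]]
    counts[names(t), s] <- as.integer(t)
  }
  keep <- rowSums(counts >= min_count) >= min_samples
  dropped_reads <- colSums(counts[!keep, , drop = FALSE])
  counts <- counts[keep, , drop = FALSE]
  ord <- order(-rowSums(counts), rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  report <- data.frame(sample = samples,
                       retained_reads = colSums(counts),
                       dropped_by_evidence = as.integer(dropped_reads),
                       dropped_n_containing = n_with_n,
                       stringsAsFactors = FALSE)
  structure(list(counts = counts, pheno = pheno, report = report),
            class = "scount_table")
}

#' Trim and collapse a set of FASTQ samples
#'
#' Convenience wrapper: reads each sample's FASTQ, trims the adapter and
#' collapses to a [collapse_reads()] table, keeping per-sample trimming
#' counters.
#'
#' @param fastq named character vector of FASTQ paths (names = sample ids),
#'   or a named list of in-memory read vectors.
#' @param adapter,min_overlap passed to [trim_adapter()].
#' @param min_count,min_samples passed to [collapse_reads()].
#' @param pheno optional sample sheet.
#' @return an `scount_table` whose `trim_report` element holds the
#'   per-sample trimming counters.
#' @export
ingest_samples <- function(fastq, adapter = NEB_ADAPTER, min_overlap = 3L,
                           min_count = 1L, min_samples = 2L, pheno = NULL) {
  samples <- names(fastq)
  if (is.null(samples)) stop("'fastq' must be named by sample id")
  inserts <- vector("list", length(samples))
  names(inserts) <- samples
  counters <- matrix(0L, length(samples), 4L,
                     dimnames = list(samples, c("input", "kept", "no_adapter",
                                                "empty_insert")))
  for (s in samples) {
    reads <- if (is.character(fastq[[s]]) && length(fastq[[s]]) == 1L &&
                 file.exists(fastq[[s]])) read_fastq(fastq[[s]]) else fastq[[s]]
    tr <- trim_adapter(unname(reads), adapter, min_overlap)
    inserts[[s]] <- tr$insert[tr$status == "kept"]
    counters[s, ] <- tr$counters
  }
  tab <- collapse_reads(inserts, min_count = min_count,
                        min_samples = min_samples, pheno = pheno)
  tab$trim_report <- as.data.frame(counters)
  tab$trim_report$sample <- samples
  tab
}

#' @export
print.scount_table <- function(x, ...) {
  cat(sprintf("unique-sequence count table: %d sequences x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
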