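# Exact-match (no mismatch) mapping of unique sequences against hierarchical
# biotype references and the nuclear/mitochondrial genomes; hierarchical
# biotype assignment and genome-origin classification.

#' Exact-match search of a query against a reference collection
#'
#' Finds all perfect (no mismatch) occurrences of `query` in every
#' reference sequence; with `strands = "both"` also of its reverse
#' complement, reported on the minus strand with plus-strand coordinates.
#' Hits are ordered by reference id, then start (sense hits first).
#'
#' @param query single DNA string over ACGT.
#' @param reference a `DNAStringSet` (or named character vector).
#' @param strands `"sense"` or `"both"`.
#' @return data frame: ref, start, end, strand (1-based inclusive).
#' @export
map_exact <- function(query, reference, strands = c("sense", "both")) {
  strands <- match.arg(strands)
  query <- as.character(query)
  stopifnot(length(query) == 1L, nchar(query) >= 1L)
  if (inherits(reference, "DNAStringSet")) {
    reference <- structure(as.character(reference), names = names(reference))
  }
  scan <- function(q, strand) {
    m <- gregexpr(q, reference, fixed = TRUE)
    rows <- lapply(seq_along(reference), function(i) {
      st <- m[[i]]
      if (st[1] == -1L) return(NULL)
      data.frame(ref = names(reference)[i], start = as.integer(st),
                 end = as.integer(st) + nchar(q) - 1L,
                 strand = strand, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(ref = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
    }
    out
  }
  hits <- scan(query, "+")
  if (strands == "both") {
    hits <- rbind(hits, scan(revcomp(query), "-"))
  }
  hits <- hits[order(match(hits$strand, c("+", "-")), hits$ref, hits$start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

serialize_hits <- function(hits) {
  if (nrow(hits) == 0L) return("")
  paste(sprintf("%s:%d-%d:%s", hits$ref, hits$start, hits$end, hits$strand),
        collapse = ";")
}

#' Parse a serialized hits string back into a data frame
#'
#' Inverse of the `ref:start-end:strand;...` serialization used in
#' annotation tables.
#'
#' @param x a single serialized hits string.
#' @return data frame: ref, start, end, strand.
#' @export
parse_hits <- function(x) {
  if (is.na(x) || x == "") {
    return(data.frame(ref = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  se <- vapply(parts, function(p) {
    as.integer(strsplit(p[2], "-", fixed = TRUE)[[1]])
  }, integer(2))
  data.frame(ref = vapply(parts, `[`, character(1), 1L),
             start = se[1, ], end = se[2, ],
             strand = vapply(parts, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Hierarchical biotype assignment
#'
#' Walks the fixed hierarchy (rRNA, mt-tRNA, tRNA, miRNA, lncRNA, piRNA,
#' protein coding) and stops at the first level with at least one perfect
#' sense-strand hit, recording all hits at that level only. Sequences with
#' no hit anywhere are `no_anno`.
#'
#' @param sequence single DNA string.
#' @param refset a `reference_set`.
#' @return list: biotype, features (reference ids hit), hits (data frame),
#'   multimap_count.
#' @export
assign_biotype <- function(sequence, refset) {
  for (bt in names(refset$biotype_refs)) {
    refs <- refset$biotype_refs[[bt]]
    if (length(refs) == 0L) next
    hits <- map_exact(sequence, refs, strands = "sense")
    if (nrow(hits) > 0L) {
      return(list(biotype = bt, features = unique(hits$ref), hits = hits,
                  multimap_count = length(unique(hits$ref))))
    }
  }
  list(biotype = "no_anno", features = character(0),
       hits = data.frame(ref = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         stringsAsFactors = FALSE),
       multimap_count = 0L)
}

#' Genome-origin classification
#'
#' A sequence is `nuclear`, `mito` or `both` by perfect match (either
#' strand) against each genome, else `unmapped`. Mature tRNA fragments that
#' carry the non-templated 3' CCA match the biotype reference but not the
#' genome; such sequences are rescued to the origin implied by their
#' biotype (mt-tRNA to mito, tRNA to nuclear) and flagged.
#'
#' @param sequence single DNA string.
#' @param refset a `reference_set`.
#' @param biotype the sequence's assigned biotype (for the CCA rescue).
#' @return list: origin, rescued (logical).
#' @export
genome_origin <- function(sequence, refset, biotype = NA_character_) {
  in_nuc <- nrow(map_exact(sequence, refset$nuclear_genome, "both")) > 0L
  in_mit <- nrow(map_exact(sequence, refset$mito_genome, "both")) > 0L
  origin <- if (in_nuc && in_mit) "both" else if (in_nuc) "nuclear" else
    if (in_mit) "mito" else "unmapped"
  rescued <- FALSE
  if (origin == "unmapped" && !is.na(biotype)) {
    if (biotype == "mt-tRNA") { origin <- "mito"; rescued <- TRUE }
    else if (biotype == "tRNA") { origin <- "nuclear"; rescued <- TRUE }
  }
  list(origin = origin, rescued = rescued)
}

#' Annotate unique sequences
#'
#' Applies [assign_biotype()] and [genome_origin()] to every sequence and
#' returns one annotation row per sequence. rRNA-assigned sequences are
#' flagged `excluded` (rRNA-derived reads are excluded from downstream
#' summaries and displays, never deleted).
#'
#' @param sequences character vector of unique sequences (or an
#'   `scount_table`, whose rownames are used).
#' @param refset a `reference_set`.
#' @param exclude_biotypes biotypes flagged as excluded downstream.
#' @return data frame (class `annotation_table`): sequence, length,
#'   biotype, origin, feature, multimap_count, hits, rescued, excluded.
#' @export
annotate_sequences <- function(sequences, refset,
                               exclude_biotypes = "rRNA") {
  if (inherits(sequences, "scount_table")) {
    sequences <- rownames(sequences$counts)
  }
  # convert references to plain character once, up front
  as_chr <- function(x) {
    if (inherits(x, "DNAStringSet")) structure(as.character(x), names = names(x))
    else x
  }
  refset$biotype_refs <- lapply(refset$biotype_refs, as_chr)
  refset$nuclear_genome <- as_chr(refset$nuclear_genome)
  refset$mito_genome <- as_chr(refset$mito_genome)
  n <- length(sequences)
  biotype <- character(n); origin <- character(n)
  feature <- character(n); hits <- character(n)
  multimap <- integer(n); rescued <- logical(n)
  for (i in seq_len(n)) {
    ab <- assign_biotype(sequences[i], refset)
    go <- genome_origin(sequences[i], refset, ab$biotype)
    biotype[i] <- ab$biotype
    origin[i] <- go$origin
    feature[i] <- paste(ab$features, collapse = ";")
    hits[i] <- serialize_hits(ab$hits)
    multimap[i] <- ab$multimap_count
    rescued[i] <- go$rescued
  }
  out <- data.frame(sequence = sequences, length = nchar(sequences),
                    biotype = biotype, origin = origin, feature = feature,
                    multimap_count = multimap, hits = hits,
                    rescued = rescued,
                    excluded = biotype %in% exclude_biotypes,
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_table", "data.frame")
  out
}
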