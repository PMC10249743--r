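# tRNA secondary structures and tRNA-derived fragment (tsRNA) analytics:
# parsing tRNAscan-SE ss records, anticodon-loop derivation, cut-site
# subtype classification, coverage profiles and feature aggregation.

#' Construct a tRNA structure record
#'
#' @param id isoacceptor/isodecoder identifier (e.g. `tRNA-Gly-TCC-1-1`).
#' @param mature_seq mature sequence including the 3' CCA.
#' @param structure string over `>`, `<`, `.` aligned to `mature_seq`.
#' @param anticodon anticodon triplet.
#' @param ac_start,ac_end 1-based anticodon interval on `mature_seq`.
#' @param aa amino acid label (optional).
#' @param cca_appended whether the CCA was appended to a genomic record.
#' @return object of class `trna_structure` with a derived `loop` interval
#'   (the maximal contiguous unpaired run containing the anticodon).
#' @export
new_trna_structure <- function(id, mature_seq, structure, anticodon,
                               ac_start, ac_end, aa = NA_character_,
                               cca_appended = FALSE) {
  if (nchar(mature_seq) != nchar(structure)) {
    stop("structure/sequence length mismatch for tRNA '", id, "'")
  }
  if (ac_end - ac_start != 2L || ac_start < 1L || ac_end > nchar(mature_seq)) {
    stop("anticodon interval must be a triplet within the sequence ('", id, "')")
  }
  if (substr(mature_seq, ac_start, ac_end) != anticodon) {
    stop("annotated anticodon does not match the sequence for tRNA '", id, "'")
  }
  loop <- derive_loop(structure, ac_start, ac_end, id = id)
  structure(list(id = id, mature_seq = mature_seq, structure = structure,
                 anticodon = anticodon, ac_start = as.integer(ac_start),
                 ac_end = as.integer(ac_end), loop = loop, aa = aa,
                 cca_appended = isTRUE(cca_appended)),
            class = "trna_structure")
}

#' Derive the anticodon loop from a structure string
#'
#' The loop is the maximal contiguous run of unpaired positions (`.`)
#' containing the annotated anticodon interval. It is an error for any
#' anticodon position to be paired.
#'
#' @param structure string over `>`, `<`, `.`.
#' @param ac_start,ac_end anticodon interval (1-based inclusive).
#' @param id used in error messages.
#' @return integer vector `c(loop_start, loop_end)`.
#' @export
derive_loop <- function(structure, ac_start, ac_end, id = "?") {
  ch <- strsplit(structure, "")[[1]]
  if (!all(ch %in% c(">", "<", "."))) {
    stop("structure string for tRNA '", id, "' contains characters other than >, <, .")
  }
  unpaired <- ch == "."
  if (!all(unpaired[ac_start:ac_end])) {
    stop("anticodon positions are not all unpaired in tRNA '", id, "'")
  }
  a <- ac_start
  while (a > 1L && unpaired[a - 1L]) a <- a - 1L
  b <- ac_end
  while (b < length(ch) && unpaired[b + 1L]) b <- b + 1L
  c(a, b)
}

#' Parse tRNAscan-SE style ss records
#'
#' Accepts the ss output dialect: a header line
#' `<id> (<start>-<end>)  Length: <n> bp`, a
#' `Type: <aa>  Anticodon: <nnn> at <a>-<b> (...)` line, then `Seq:` and
#' `Str:` lines; records separated by blank lines. When the genomic
#' sequence does not end in CCA, the non-templated CCA is appended to form
#' the mature sequence (with unpaired structure).
#'
#' @param x a file path or a character vector of lines.
#' @return named list of [new_trna_structure()] records.
#' @export
parse_ss <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- sub("\r$", "", lines)
  blank <- grepl("^\\s*$", lines)
  recs <- split(lines[!blank], cumsum(blank)[!blank])
  out <- list()
  for (rec in recs) {
    id <- sub("^(\\S+).*", "\\1", rec[1])
    m <- regmatches(rec, regexec(
      "Anticodon:\\s+(\\S+)\\s+at\\s+(\\d+)-(\\d+)", rec))
    aci <- which(vapply(m, length, integer(1)) > 0)
    if (length(aci) == 0L) stop("no anticodon annotation in record '", id, "'")
    anticodon <- m[[aci[1]]][2]
    ac_start <- as.integer(m[[aci[1]]][3])
    ac_end <- as.integer(m[[aci[1]]][4])
    aa <- sub(".*Type:\\s+(\\S+).*", "\\1",
              rec[grep("Type:", rec)[1]] %||% NA_character_)
    seq_line <- rec[grep("^Seq:", rec)[1]]
    str_line <- rec[grep("^Str:", rec)[1]]
    if (is.na(seq_line) || is.na(str_line)) {
      stop("record '", id, "' lacks Seq:/Str: lines")
    }
    seq <- toupper(gsub("\\s", "", sub("^Seq:\\s*", "", seq_line)))
    str <- gsub("\\s", "", sub("^Str:\\s*", "", str_line))
    if (nchar(seq) != nchar(str)) {
      stop("Seq/Str length mismatch in record '", id, "' (",
           nchar(seq), " vs ", nchar(str), ")")
    }
    cca_appended <- FALSE
    if (!endsWith(seq, "CCA")) {
      seq <- paste0(seq, "CCA")
      str <- paste0(str, "...")
      cca_appended <- TRUE
    }
    out[[id]] <- new_trna_structure(id, seq, str, anticodon, ac_start,
                                    ac_end, aa = aa,
                                    cca_appended = cca_appended)
  }
  out
}

#' Write tRNA structures as ss records
#'
#' Inverse of [parse_ss()]: emits the genomic (CCA-free when the CCA was
#' appended) sequence and structure.
#'
#' @param structures list of `trna_structure` records.
#' @param path output file.
#' @param coords optional data frame with `id`, `start`, `end` genomic
#'   coordinates for headers; defaults to `1-L`.
#' @return `path`, invisibly.
#' @export
write_ss <- function(structures, path, coords = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (st in structures) {
    seq <- st$mature_seq
    str <- st$structure
    if (st$cca_appended) {
      seq <- substr(seq, 1L, nchar(seq) - 3L)
      str <- substr(str, 1L, nchar(str) - 3L)
    }
    g1 <- 1L; g2 <- nchar(seq)
    if (!is.null(coords)) {
      i <- match(st$id, coords$id)
      if (!is.na(i)) { g1 <- coords$start[i]; g2 <- coords$end[i] }
    }
    writeLines(c(
      sprintf("%s (%d-%d)\tLength: %d bp", st$id, g1, g2, nchar(seq)),
      sprintf("Type: %s\tAnticodon: %s at %d-%d (%d-%d)\tScore: 60.00",
              st$aa, st$anticodon, st$ac_start, st$ac_end,
              g1 + st$ac_start - 1L, g1 + st$ac_end - 1L),
      paste0("Seq: ", seq),
      paste0("Str: ", str),
      ""), con)
  }
  invisible(path)
}

#' Classify tRNA fragments into the five cut-site subtypes
#'
#' With loop `[a, b]` on the mature sequence of length `L`, a fragment
#' touching the 5' end that ends inside (or beyond) the anticodon loop is a
#' 5'-half; one ending before the loop is a 5'-tsRNA. Mirror rules apply at
#' the 3' end (3'-half starts inside or before the loop; 3'-tsRNA starts
#' after it). Fragments touching neither end are internal (i'-tsRNA); a
#' fragment touching both ends is labelled `whole_tRNA` and excluded from
#' the five-subtype tallies.
#'
#' @param start,end 1-based inclusive coordinates on the mature sequence
#'   (vectorised).
#' @param struct a `trna_structure`.
#' @param end_tolerance nt of slack when testing contact with either end.
#' @return factor with levels [TSRNA_SUBTYPES_ALL].
#' @export
classify_fragment <- function(start, end, struct, end_tolerance = 0L) {
  stopifnot(inherits(struct, "trna_structure"))
  L <- nchar(struct$mature_seq)
  a <- struct$loop[1]; b <- struct$loop[2]
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L | end > L | start > end)) {
    stop("fragment coordinates out of range for tRNA '", struct$id, "'")
  }
  t5 <- start <= 1L + end_tolerance
  t3 <- end >= L - end_tolerance
  out <- rep("i_tsRNA", length(start))
  out[t5 & !t3 & end < a] <- "five_tsRNA"
  out[t5 & !t3 & end >= a] <- "five_half"
  out[!t5 & t3 & start > b] <- "three_tsRNA"
  out[!t5 & t3 & start <= b] <- "three_half"
  out[t5 & t3] <- "whole_tRNA"
  factor(out, levels = TSRNA_SUBTYPES_ALL)
}

#' Per-fragment subtype table for tRNA-mapped sequences
#'
#' Expands every tRNA/mt-tRNA biotype hit of every annotated sequence into
#' one row with its alignment interval and cut-site subtype.
#'
#' @param anno annotation table from [annotate_sequences()].
#' @param structures named list of `trna_structure` records.
#' @param end_tolerance passed to [classify_fragment()].
#' @return data frame: sequence, trna_id, origin, start, end, subtype.
#' @export
classify_table <- function(anno, structures, end_tolerance = 0L) {
  idx <- which(anno$biotype %in% c("tRNA", "mt-tRNA"))
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    h <- parse_hits(anno$hits[i])
    h <- h[h$ref %in% names(structures), , drop = FALSE]
    if (nrow(h) == 0L) next
    sub <- character(nrow(h))
    for (r in seq_len(nrow(h))) {
      sub[r] <- as.character(classify_fragment(h$start[r], h$end[r],
                                               structures[[h$ref[r]]],
                                               end_tolerance))
    }
    rows[[j]] <- data.frame(sequence = anno$sequence[i], trna_id = h$ref,
                            origin = anno$origin[i], start = h$start,
                            end = h$end, subtype = sub,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence = character(0), trna_id = character(0),
                      origin = character(0), start = integer(0),
                      end = integer(0), subtype = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Positional coverage profile of one mature tRNA
#'
#' For each position of the mature sequence, the mean (over a group's
#' samples) of summed CPM of all fragments covering that position.
#'
#' @param cpm_mat sequence x sample CPM matrix (rownames are sequences).
#' @param anno annotation table.
#' @param struct a `trna_structure`.
#' @param pheno sample sheet with `sample` and `group` columns.
#' @param group group label.
#' @return numeric vector of length `nchar(struct$mature_seq)`.
#' @export
coverage_profile <- function(cpm_mat, anno, struct, pheno, group) {
  if (!group %in% pheno$group) stop("unknown group: ", group)
  samples <- pheno$sample[pheno$group == group]
  L <- nchar(struct$mature_seq)
  cov <- matrix(0, L, length(samples))
  idx <- which(anno$biotype %in% c("tRNA", "mt-tRNA"))
  for (i in idx) {
    h <- parse_hits(anno$hits[i])
    h <- h[h$ref == struct$id, , drop = FALSE]
    if (nrow(h) == 0L) next
    if (!anno$sequence[i] %in% rownames(cpm_mat)) next
    v <- cpm_mat[anno$sequence[i], samples]
    for (r in seq_len(nrow(h))) {
      pos <- h$start[r]:h$end[r]
      cov[pos, ] <- cov[pos, ] + matrix(rep(v, each = length(pos)),
                                        nrow = length(pos))
    }
  }
  rowMeans(cov)
}

#' Aggregate sequence counts to features
#'
#' Sums member-sequence counts per feature. Multimapping is not resolved:
#' a sequence hitting k > 1 features contributes its full count to each,
#' and the fraction of each feature's counts that came from multimapping
#' sequences is reported.
#'
#' @param counts sequence x sample count (or CPM) matrix.
#' @param anno annotation table aligned by sequence name.
#' @param level `"mature_tRNA"` (tRNA and mt-tRNA isodecoders),
#'   `"miRNA"` (mature miRNA ids; 5' and 3' arms are distinct features), or
#'   `"trna_subtype"` (`<trna_id>|<subtype>`, needs `structures`).
#' @param structures required for `level = "trna_subtype"`.
#' @param end_tolerance passed to [classify_fragment()].
#' @return list with `counts` (feature x sample matrix) and
#'   `multimap_fraction` (named vector).
#' @export
aggregate_features <- function(counts, anno,
                               level = c("mature_tRNA", "miRNA",
                                         "trna_subtype"),
                               structures = NULL, end_tolerance = 0L) {
  level <- match.arg(level)
  anno <- anno[anno$sequence %in% rownames(counts), , drop = FALSE]
  memb <- list()   # feature -> character vector of member sequences
  add <- function(feature, sequence) {
    memb[[feature]] <<- c(memb[[feature]], sequence)
  }
  if (level == "miRNA") {
    sel <- anno[anno$biotype == "miRNA", , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      for (f in strsplit(sel$feature[i], ";", fixed = TRUE)[[1]]) {
        add(f, sel$sequence[i])
      }
    }
  } else {
    if (level == "trna_subtype" && is.null(structures)) {
      stop("'structures' is required for level = 'trna_subtype'")
    }
    sel <- anno[anno$biotype %in% c("tRNA", "mt-tRNA"), , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      h <- parse_hits(sel$hits[i])
      feats <- unique(h$ref)
      if (level == "trna_subtype") {
        feats <- unique(vapply(seq_len(nrow(h)), function(r) {
          paste0(h$ref[r], "|",
                 as.character(classify_fragment(h$start[r], h$end[r],
                                                structures[[h$ref[r]]],
                                                end_tolerance)))
        }, character(1)))
      }
      for (f in feats) add(f, sel$sequence[i])
    }
  }
  feats <- sort(names(memb))
  if (length(feats) == 0L) {
    return(list(counts = matrix(0, 0, ncol(counts),
                                dimnames = list(NULL, colnames(counts))),
                multimap_fraction = numeric(0)))
  }
  # how many features each sequence belongs to, at this level
  seq_k <- table(unlist(memb, use.names = FALSE))
  out <- matrix(0, length(feats), ncol(counts),
                dimnames = list(feats, colnames(counts)))
  mmf <- numeric(length(feats))
  names(mmf) <- feats
  for (f in feats) {
    sqs <- unique(memb[[f]])
    sub <- counts[sqs, , drop = FALSE]
    out[f, ] <- colSums(sub)
    tot <- sum(sub)
    mm <- sum(sub[seq_k[sqs] > 1L, , drop = FALSE])
    mmf[f] <- if (tot > 0) mm / tot else 0
  }
  list(counts = out, multimap_fraction = mmf)
}

#' @export
print.trna_structure <- function(x, ...) {
  cat(sprintf("tRNA %s (%d nt mature%s), anticodon %s at %d-%d, loop %d-%d\n",
              x$id, nchar(x$mature_seq),
              if (x$cca_appended) ", CCA appended" else "",
              x$anticodon, x$ac_start, x$ac_end, x$loop[1], x$loop[2]))
  invisible(x)
}
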