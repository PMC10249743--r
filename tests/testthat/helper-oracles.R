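# Independent oracles, written directly from the plain-language rules and
# deliberately sharing no code with the package implementation.

# Subtype of a tRNA fragment, literal restatement of the rule: a fragment
# touching the 5' end that ends inside or past the anticodon loop is a
# 5'-half; ending before the loop, a 5'-tsRNA. Mirrored at the 3' end.
# Touching neither end: internal. Touching both: whole tRNA.
oracle_subtype <- function(start, end, L, loop_start, loop_end) {
  touches5 <- start == 1
  touches3 <- end == L
  if (touches5 && touches3) return("whole_tRNA")
  if (touches5) {
    if (end >= loop_start) return("five_half") else return("five_tsRNA")
  }
  if (touches3) {
    if (start <= loop_end) return("three_half") else return("three_tsRNA")
  }
  "i_tsRNA"
}

# naive position-by-position exact substring scan
oracle_scan <- function(query, subject) {
  nq <- nchar(query); ns <- nchar(subject)
  hits <- integer(0)
  if (nq <= ns) {
    for (i in seq_len(ns - nq + 1L)) {
      if (substr(subject, i, i + nq - 1L) == query) hits <- c(hits, i)
    }
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# repeated-measures correlation by dense least squares on the dummy-coded
# design matrix (subject indicators + common slope), solved with qr.solve
oracle_rmcorr <- function(subject, x, y) {
  subject <- as.factor(subject)
  D <- stats::model.matrix(~ 0 + subject)
  Xf <- cbind(D, x = x)
  bf <- qr.solve(Xf, y)
  rf <- y - Xf %*% bf
  br <- qr.solve(D, y)
  rr <- y - D %*% br
  rss_f <- sum(rf^2); rss_r <- sum(rr^2)
  ssx <- rss_r - rss_f
  df <- length(y) - nlevels(subject) - 1L
  r <- sign(bf[["x"]]) * sqrt(max(ssx, 0) / (ssx + rss_f))
  p <- stats::pf(ssx / (rss_f / df), 1, df, lower.tail = FALSE)
  list(r = r, df = df, p_value = p, slope = bf[["x"]])
}

# brute-force recount of the two-stage filter, looping over sequences and
# re-deriving every rule from scratch
oracle_filter <- function(counts, origin, size = c(18, 50), min_count = 10,
                          min_count_frac = 0.60, min_cpm = 20,
                          min_cpm_frac = 0.25) {
  n <- ncol(counts)
  stage1 <- character(0)
  for (s in rownames(counts)) {
    len <- nchar(s)
    if (len < size[1] || len > size[2]) next
    n_ok <- 0L
    for (j in seq_len(n)) if (counts[s, j] >= min_count) n_ok <- n_ok + 1L
    if (n_ok < ceiling(min_count_frac * n)) next
    if (origin[[s]] == "unmapped") next
    stage1 <- c(stage1, s)
  }
  totals <- colSums(counts[stage1, , drop = FALSE])
  stage2 <- character(0)
  for (s in stage1) {
    n_ok <- 0L
    for (j in seq_len(n)) {
      if (counts[s, j] / totals[j] * 1e6 >= min_cpm) n_ok <- n_ok + 1L
    }
    if (n_ok >= ceiling(min_cpm_frac * n)) stage2 <- c(stage2, s)
  }
  list(stage1 = stage1, stage2 = stage2)
}

# a random unique-sequence count table as produced by collapsing
random_scount_table <- function(n_seq = 60, n_samples = 6) {
  seqs <- unique(vapply(sample(15:55, n_seq, replace = TRUE), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1)))
  counts <- matrix(stats::rnbinom(length(seqs) * n_samples, mu = 15, size = 0.7),
                   nrow = length(seqs),
                   dimnames = list(seqs, paste0("s", seq_len(n_samples))))
  origin <- stats::setNames(sample(c("nuclear", "mito", "unmapped"),
                                   length(seqs), replace = TRUE,
                                   prob = c(0.6, 0.2, 0.2)), seqs)
  list(table = structure(list(counts = counts), class = "scount_table"),
       origin = origin,
       anno = data.frame(sequence = seqs, origin = unname(origin),
                         stringsAsFactors = FALSE))
}

# a small synthetic configuration that keeps unit tests fast
small_config <- function(...) {
  args <- list(n_nuclear_trna = 4, n_mito_trna = 2, n_mirna = 4, n_rrna = 2,
               n_other = 2, reads_per_sample = 4000,
               n_samples_per_group = 3, seed = 101L)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# a handmade canonical structure: 73-nt gene cloverleaf + CCA (76 nt mature),
# anticodon GCC at 34-36, loop 32-38
demo_structure <- function() {
  str73 <- paste0(strrep(">", 7), strrep(".", 2), strrep(">", 4),
                  strrep(".", 8), strrep("<", 4), ".", strrep(">", 5),
                  strrep(".", 7), strrep("<", 5), strrep(".", 5),
                  strrep(">", 5), strrep(".", 7), strrep("<", 5),
                  strrep("<", 7), ".")
  set.seed(4242)
  seq <- paste(sample(c("A", "C", "G", "T"), 73, replace = TRUE),
               collapse = "")
  substr(seq, 34, 36) <- "GCC"
  new_trna_structure("tRNA-Ala-GCC-1-1", paste0(seq, "CCA"),
                     paste0(str73, "..."), "GCC", 34, 36, aa = "Ala",
                     cca_appended = TRUE)
}
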