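test_that("a canonical 76-nt cloverleaf has loop [32, 38]", {
  st <- demo_structure()
  expect_equal(st$loop, c(32L, 38L))
  # brute-force unpaired-run scan oracle
  ch <- strsplit(st$structure, "")[[1]]
  runs <- rle(ch == ".")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  i <- which(runs$values & starts <= 34 & ends >= 36)
  expect_equal(st$loop, c(starts[i], ends[i]))
})

test_that("structure records are validated", {
  st <- demo_structure()
  expect_error(new_trna_structure("x", st$mature_seq,
                                  substr(st$structure, 1, 75),
                                  "GCC", 34, 36), "length mismatch")
  expect_error(new_trna_structure("x", st$mature_seq, st$structure,
                                  "AAA", 34, 36), "anticodon")
  # paired anticodon positions are rejected
  bad <- st$structure
  substr(bad, 34, 34) <- ">"
  expect_error(new_trna_structure("x", st$mature_seq, bad, "GCC", 34, 36),
               "not all unpaired")
})

test_that("a malformed ss record errors naming the tRNA id", {
  st <- demo_structure()
  lines <- c(
    sprintf("%s (1-73)\tLength: 73 bp", st$id),
    sprintf("Type: Ala\tAnticodon: GCC at 34-36 (34-36)\tScore: 60.00"),
    paste0("Seq: ", substr(st$mature_seq, 1, 73)),
    paste0("Str: ", substr(st$structure, 1, 72)))  # 1 nt short
  expect_error(parse_ss(lines), "tRNA-Ala-GCC-1-1")
})

test_that("parse_ss appends the non-templated CCA to genomic records", {
  st <- demo_structure()
  f <- tempfile(fileext = ".ss")
  write_ss(list(st), f)
  back <- parse_ss(f)[[1]]
  expect_true(back$cca_appended)
  expect_identical(back$mature_seq, st$mature_seq)
  expect_identical(back$structure, st$structure)
  expect_equal(back, st)
  unlink(f)
})

test_that("canonical fragment coordinates classify by the cut-site rules", {
  st <- demo_structure()  # L = 76, loop [32, 38]
  expect_identical(as.character(classify_fragment(1, 34, st)), "five_half")
  expect_identical(as.character(classify_fragment(1, 30, st)), "five_tsRNA")
  expect_identical(as.character(classify_fragment(20, 50, st)), "i_tsRNA")
  expect_identical(as.character(classify_fragment(35, 76, st)), "three_half")
  expect_identical(as.character(classify_fragment(45, 76, st)), "three_tsRNA")
  expect_identical(as.character(classify_fragment(1, 76, st)), "whole_tRNA")
  expect_error(classify_fragment(0, 20, st), "out of range")
  expect_error(classify_fragment(10, 77, st), "out of range")
})

test_that("end tolerance relaxes the end-contact rule", {
  st <- demo_structure()
  expect_identical(as.character(classify_fragment(2, 34, st)), "i_tsRNA")
  expect_identical(as.character(classify_fragment(2, 34, st, end_tolerance = 1)),
                   "five_half")
  expect_identical(as.character(classify_fragment(45, 75, st, end_tolerance = 1)),
                   "three_tsRNA")
})

test_that("coverage is additive over overlapping fragments", {
  st <- demo_structure()
  seq1 <- substr(st$mature_seq, 1, 30)
  seq2 <- substr(st$mature_seq, 20, 50)
  anno <- data.frame(
    sequence = c(seq1, seq2), biotype = "tRNA", origin = "nuclear",
    hits = c(sprintf("%s:1-30:+", st$id), sprintf("%s:20-50:+", st$id)),
    stringsAsFactors = FALSE)
  cpm <- matrix(100, 2, 2, dimnames = list(c(seq1, seq2), c("s1", "s2")))
  pheno <- data.frame(sample = c("s1", "s2"), group = "g")
  v <- coverage_profile(cpm, anno, st, pheno, "g")
  expect_equal(v[1:19], rep(100, 19))
  expect_equal(v[20:30], rep(200, 11))
  expect_equal(v[31:50], rep(100, 20))
  expect_equal(v[51:76], rep(0, 26))
})

test_that("single-fragment coverage equals its CPM on the covered interval", {
  st <- demo_structure()
  s <- substr(st$mature_seq, 1, 30)
  anno <- data.frame(sequence = s, biotype = "tRNA", origin = "nuclear",
                     hits = sprintf("%s:1-30:+", st$id),
                     stringsAsFactors = FALSE)
  cpm <- matrix(100, 1, 1, dimnames = list(s, "s1"))
  v <- coverage_profile(cpm, anno, st,
                        data.frame(sample = "s1", group = "g"), "g")
  expect_equal(v, c(rep(100, 30), rep(0, 46)))
})

test_that("feature aggregation sums members and reports multimapping", {
  counts <- matrix(c(10, 5, 8), 3, 1,
                   dimnames = list(c("AAA", "CCC", "GGG"), "s1"))
  anno <- data.frame(
    sequence = c("AAA", "CCC", "GGG"),
    biotype = c("tRNA", "tRNA", "tRNA"),
    feature = c("tRNA-Gly-TCC-1-1", "tRNA-Gly-TCC-1-1",
                "tRNA-Gly-TCC-1-1;tRNA-Gly-TCC-1-2"),
    hits = c("tRNA-Gly-TCC-1-1:1-20:+", "tRNA-Gly-TCC-1-1:30-50:+",
             "tRNA-Gly-TCC-1-1:1-25:+;tRNA-Gly-TCC-1-2:1-25:+"),
    stringsAsFactors = FALSE)
  ag <- aggregate_features(counts, anno, "mature_tRNA")
  expect_equal(unname(ag$counts["tRNA-Gly-TCC-1-1", 1]), 23)
  expect_equal(unname(ag$counts["tRNA-Gly-TCC-1-2", 1]), 8)
  expect_equal(unname(ag$multimap_fraction["tRNA-Gly-TCC-1-1"]), 8 / 23)
  expect_equal(unname(ag$multimap_fraction["tRNA-Gly-TCC-1-2"]), 1)
})

test_that("5' and 3' miRNA arms aggregate to distinct features", {
  counts <- matrix(c(4, 6), 2, 1, dimnames = list(c("AAAA", "TTTT"), "s1"))
  anno <- data.frame(sequence = c("AAAA", "TTTT"), biotype = "miRNA",
                     feature = c("miR-10a", "miR-10b"),
                     hits = c("miR-10a:1-4:+", "miR-10b:1-4:+"),
                     stringsAsFactors = FALSE)
  ag <- aggregate_features(counts, anno, "miRNA")
  expect_setequal(rownames(ag$counts), c("miR-10a", "miR-10b"))
  expect_equal(unname(ag$counts["miR-10a", 1]), 4)
  expect_true(all(ag$multimap_fraction == 0))
})

test_that("classify_table matches per-fragment classification on synthetic truth", {
  cfg <- small_config()
  built <- build_reference_set(cfg)
  frag <- built$truth$fragments
  frag <- frag[frag$biotype %in% c("tRNA", "mt-tRNA"), ]
  anno <- data.frame(sequence = frag$sequence, biotype = frag$biotype,
                     origin = frag$origin,
                     hits = sprintf("%s:%d-%d:+", frag$transcript_id,
                                    frag$start, frag$end),
                     stringsAsFactors = FALSE)
  cls <- classify_table(anno, built$refset$trna_structures)
  m <- match(paste(cls$trna_id, cls$start, cls$end),
             paste(frag$transcript_id, frag$start, frag$end))
  expect_false(anyNA(m))
  expect_identical(cls$subtype, frag$subtype[m])
})
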