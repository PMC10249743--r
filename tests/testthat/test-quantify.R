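test_that("CPM arithmetic and scale invariance", {
  m <- matrix(c(10, 999990, 5, 15), 2, 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  cp <- cpm_normalize(m)
  expect_equal(unname(cp["A", "s1"]), 10)
  expect_equal(cpm_normalize(m * c(2, 2)), cp)
  m0 <- m; m0[, 2] <- 0
  expect_error(cpm_normalize(m0), "s2")
})

test_that("stage-1 boundaries are inclusive and 17-nt sequences are dropped", {
  seqs <- c(strrep("A", 17), strrep("C", 18), strrep("G", 50), strrep("T", 51))
  counts <- matrix(1000L, 4, 5, dimnames = list(seqs, paste0("s", 1:5)))
  tab <- structure(list(counts = counts), class = "scount_table")
  anno <- data.frame(sequence = seqs, origin = "nuclear",
                     stringsAsFactors = FALSE)
  f <- apply_filters(tab, anno)
  expect_setequal(rownames(f$table$counts), seqs[2:3])
  expect_equal(unname(f$report["dropped_size"]), 2)
})

test_that("exactly 10 counts in exactly 60% of samples is retained", {
  s <- c(strrep("A", 20), strrep("C", 20))
  counts <- matrix(0L, 2, 5, dimnames = list(s, paste0("s", 1:5)))
  counts[1, ] <- c(10L, 10L, 10L, 9L, 9L)  # >= 10 in 3 of 5 = 60%, threshold
  counts[2, 1:2] <- 500L                   # >= 10 in only 2 samples
  anno <- data.frame(sequence = s, origin = "nuclear", stringsAsFactors = FALSE)
  f <- apply_filters(structure(list(counts = counts), class = "scount_table"),
                     anno, min_cpm_frac = 0.25, min_cpm = 0.001)
  expect_identical(rownames(f$table$counts), s[1])
  expect_equal(unname(f$report["dropped_min_count"]), 1)
})

test_that("stage 2 needs min CPM in at least ceil(frac * n) samples", {
  # 10 samples, 25 CPM in 2 samples, 0 elsewhere: 2 < ceil(0.25*10) = 3
  s1 <- strrep("A", 20); s2 <- strrep("C", 20)
  counts <- matrix(0L, 2, 10, dimnames = list(c(s1, s2), paste0("s", 1:10)))
  counts[1, ] <- 40000L
  counts[2, 1:2] <- 1L    # 1/40001 * 1e6 ~ 25 CPM in 2 samples
  counts[1, ] <- counts[1, ] + c(0L, 0L, rep(1L, 8))  # keep depth comparable
  anno <- data.frame(sequence = c(s1, s2), origin = "nuclear",
                     stringsAsFactors = FALSE)
  f <- apply_filters(structure(list(counts = counts), class = "scount_table"),
                     anno, min_count = 1, min_count_frac = 0.1)
  expect_identical(rownames(f$table$counts), s1)
  expect_equal(unname(f$report["dropped_min_cpm"]), 1)
})

test_that("filter survivors match the brute-force oracle on random tables", {
  set.seed(21)
  for (i in 1:25) {
    rt <- random_scount_table()
    got <- apply_filters(rt$table, rt$anno)
    want <- oracle_filter(rt$table$counts, rt$origin)
    expect_setequal(rownames(got$table$stage1_counts), want$stage1)
    expect_setequal(rownames(got$table$counts), want$stage2)
  }
})

test_that("relaxing thresholds only grows the survivor set", {
  set.seed(22)
  rt <- random_scount_table(n_seq = 120)
  strict <- apply_filters(rt$table, rt$anno)
  loose <- apply_filters(rt$table, rt$anno, size = c(15, 55), min_count = 2,
                         min_count_frac = 0.3, min_cpm = 2,
                         min_cpm_frac = 0.1)
  expect_true(all(rownames(strict$table$counts) %in%
                    rownames(loose$table$counts)))
})

test_that("log2fc follows the stated arithmetic and SEM convention", {
  m <- matrix(c(99, 99, 24, 24,   40, 40, 40, 40), 2, 4, byrow = TRUE,
              dimnames = list(c("x", "y"),
                              c("a1", "a2", "b1", "b2")))
  pheno <- data.frame(sample = colnames(m), group = c("A", "A", "B", "B"))
  fc <- log2fc(m, pheno, "A", "B", pseudocount = 1)
  expect_equal(fc$log2fc[fc$feature == "x"], log2(100 / 25))
  expect_equal(fc$log2fc[fc$feature == "y"], 0)
  expect_identical(fc$direction, c("up", "zero"))
  # SEM: sd over group-A samples of per-individual log ratios / sqrt(nA)
  m2 <- m; m2["x", c("a1", "a2")] <- c(90, 108)
  fc2 <- log2fc(m2, pheno, "A", "B")
  per_ind <- log2((c(90, 108) + 1) / 25)
  expect_equal(fc2$sem_log2fc[1], sd(per_ind) / sqrt(2))
})

test_that("planted +1 log2 effects are recovered by log2fc on average", {
  est <- vapply(1:10, function(s) {
    cfg <- small_config(reads_per_sample = 20000, seed = 500 + s)
    built <- build_reference_set(cfg)
    sim <- simulate_reads(built$refset, built$truth, cfg)
    cpm <- cpm_normalize(sim$realized_counts)
    fc <- log2fc(cpm, sim$pheno, cfg$groups[2], cfg$groups[1],
                 pseudocount = 0.5)
    mito <- built$truth$fragments$origin == "mito"
    mean(fc$log2fc[mito])
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.3)
})

test_that("origin summary emits NA rows for empty cells and tracks sign counts", {
  fc <- data.frame(feature = c("A", "B", "C", "D"),
                   log2fc = c(1, -1, 2, 0), stringsAsFactors = FALSE)
  anno <- data.frame(sequence = c("A", "B", "C", "D", "E"),
                     biotype = c("tRNA", "tRNA", "miRNA", "miRNA", "piRNA"),
                     origin = c("nuclear", "nuclear", "nuclear", "nuclear",
                                "mito"),
                     excluded = FALSE, stringsAsFactors = FALSE)
  s <- origin_fc_summary(fc, anno)
  tn <- s[s$biotype == "tRNA" & s$origin == "nuclear", ]
  expect_equal(tn$n, 2)
  expect_equal(tn$pct_up, 50)
  expect_equal(tn$pct_down, 50)
  mn <- s[s$biotype == "miRNA" & s$origin == "nuclear", ]
  expect_equal(mn$n_zero, 1)
  empty <- s[s$biotype == "piRNA" & s$origin == "mito", ]
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_log2fc))
})

test_that("size distribution conserves non-excluded mean CPM", {
  set.seed(31)
  seqs <- vapply(sample(18:50, 30, replace = TRUE), function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  seqs <- unique(seqs)
  cpm <- matrix(runif(length(seqs) * 4, 0, 100), length(seqs), 4,
                dimnames = list(seqs, paste0("s", 1:4)))
  anno <- data.frame(sequence = seqs,
                     biotype = sample(c("tRNA", "miRNA", "rRNA", "piRNA"),
                                      length(seqs), replace = TRUE),
                     stringsAsFactors = FALSE)
  anno$excluded <- anno$biotype == "rRNA"
  pheno <- data.frame(sample = paste0("s", 1:4),
                      group = c("g1", "g1", "g2", "g2"))
  sd_tab <- size_distribution(cpm, anno, pheno)
  for (g in c("g1", "g2")) {
    mu <- rowMeans(cpm[, pheno$sample[pheno$group == g]])
    expect_equal(sum(sd_tab$mean_cpm[sd_tab$group == g]),
                 sum(mu[!anno$excluded]))
  }
})
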