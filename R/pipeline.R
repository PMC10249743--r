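# One-command orchestration: synthesis (or user FASTQ) -> trimming and
# collapsing -> annotation -> filtering and CPM -> fold changes, subtype and
# origin summaries, clustering, coverage, NB-GLM tests and repeated-measures
# correlations, emitted as a machine-readable report bundle.

#' Load a reference set written by [write_reference_set()]
#'
#' @param dir directory with per-biotype FASTA files, genome FASTAs and a
#'   `trna_structures.ss` file.
#' @return a `reference_set`.
#' @export
load_reference_set <- function(dir) {
  refs <- lapply(BIOTYPE_HIERARCHY, function(bt) {
    fn <- file.path(dir, paste0(gsub("-", "_", bt), ".fasta"))
    if (file.exists(fn)) Biostrings::readDNAStringSet(fn)
    else Biostrings::DNAStringSet()
  })
  names(refs) <- BIOTYPE_HIERARCHY
  ssfile <- file.path(dir, "trna_structures.ss")
  structure(list(
    biotype_refs = refs,
    nuclear_genome = Biostrings::readDNAStringSet(
      file.path(dir, "genome_nuclear.fasta")),
    mito_genome = Biostrings::readDNAStringSet(
      file.path(dir, "genome_mito.fasta")),
    trna_structures = if (file.exists(ssfile)) parse_ss(ssfile) else list()
  ), class = "reference_set")
}

#' Pipeline configuration
#'
#' @param synth a [synthetic_config()] (synthetic mode), or NULL to run on
#'   user FASTQ files.
#' @param fastq named vector of FASTQ paths (user mode).
#' @param pheno sample sheet with sample, group, subject and phenotype
#'   columns (user mode; generated in synthetic mode).
#' @param refdir reference directory for [load_reference_set()] (user mode).
#' @param contrasts list of `c(group_a, group_b)` pairs (numerator first);
#'   default: second configured group versus the first. May be empty, in
#'   which case only composition tables are produced.
#' @param filter_params list of [apply_filters()] arguments.
#' @param coverage_trnas tRNA ids for coverage profiles; default: all
#'   mitochondrial tRNAs.
#' @param phenotype_cols phenotype columns for repeated-measures
#'   correlation against per-sample mean mitochondrial CPM.
#' @param out_dir bundle directory (NULL keeps everything in memory).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(), fastq = NULL,
                            pheno = NULL, refdir = NULL, contrasts = NULL,
                            filter_params = list(),
                            coverage_trnas = NULL,
                            phenotype_cols = NULL, out_dir = NULL) {
  if (is.null(synth) && (is.null(fastq) || is.null(pheno) || is.null(refdir))) {
    stop("without a synthetic config, 'fastq', 'pheno' and 'refdir' are required")
  }
  if (is.null(contrasts)) {
    groups <- if (!is.null(synth)) synth$groups else unique(pheno$group)
    contrasts <- if (length(groups) >= 2L) list(c(groups[2], groups[1]))
      else list()
  }
  if (is.null(phenotype_cols) && !is.null(synth)) {
    phenotype_cols <- names(synth$phenotype_assoc)
  }
  structure(list(synth = synth, fastq = fastq, pheno = pheno,
                 refdir = refdir, contrasts = contrasts,
                 filter_params = filter_params,
                 coverage_trnas = coverage_trnas,
                 phenotype_cols = phenotype_cols, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed [E_%s]: %s", name,
                 toupper(name), conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full small RNA pipeline
#'
#' Executes synthesis (or FASTQ loading), adapter trimming, collapsing with
#' the cross-sample evidence rule, hierarchical annotation, two-stage
#' filtering with CPM, and — per contrast — sequence-level fold changes,
#' biotype/origin summaries, miRNA feature aggregation with NB-GLM tests,
#' mature-tRNA clustering (k = 4, Euclidean, complete linkage), tsRNA
#' subtype distributions by origin, coverage profiles, and repeated-measures
#' correlations of phenotypes with mitochondrial small RNA levels.
#' Re-running with the same configuration and seed reproduces the bundle
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return the report bundle (named list of data frames and tables); when
#'   `config$out_dir` is set the bundle is also written as TSV + JSON and
#'   the paths recorded in `bundle$files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  synthetic <- !is.null(config$synth)

  if (synthetic) {
    built <- run_stage("synth", build_reference_set(config$synth))
    refset <- built$refset
    fq_dir <- if (!is.null(config$out_dir)) file.path(config$out_dir, "fastq")
    sim <- run_stage("synth", simulate_reads(refset, built$truth,
                                             config$synth, out_dir = fq_dir))
    pheno <- sim$pheno
    read_source <- sim$reads
    adapter <- config$synth$adapter
    min_overlap <- config$synth$adapter_min_overlap
    input_files <- sim$fastq
  } else {
    refset <- run_stage("load", load_reference_set(config$refdir))
    pheno <- config$pheno
    read_source <- config$fastq
    adapter <- NEB_ADAPTER
    min_overlap <- 3L
    input_files <- config$fastq
    sim <- NULL
  }

  tab <- run_stage("ingest", ingest_samples(read_source, adapter = adapter,
                                            min_overlap = min_overlap,
                                            pheno = pheno))
  anno <- run_stage("annotate", annotate_sequences(tab, refset))
  filt <- run_stage("quantify", do.call(apply_filters,
                                        c(list(table = tab, anno = anno),
                                          config$filter_params)))
  cpm <- filt$cpm
  anno_f <- anno[match(rownames(cpm), anno$sequence), , drop = FALSE]
  lib_sizes <- colSums(filt$table$stage1_counts)

  # biotype composition: percent of mean CPM per group (rRNA included here,
  # since composition is reported before the rRNA display exclusion)
  composition <- do.call(rbind, lapply(unique(pheno$group), function(g) {
    mu <- rowMeans(cpm[, pheno$sample[pheno$group == g], drop = FALSE])
    tot <- sum(mu)
    agg <- tapply(mu, anno_f$biotype, sum)
    data.frame(group = g, biotype = names(agg),
               pct_cpm = 100 * as.numeric(agg) / tot,
               stringsAsFactors = FALSE)
  }))

  sizes <- run_stage("quantify",
                     size_distribution(cpm, anno, pheno))

  structures <- refset$trna_structures
  cls <- run_stage("tsrna", classify_table(anno_f, structures))

  bundle <- list(
    pheno = pheno,
    composition = composition,
    size_distribution = sizes,
    filter_report = data.frame(rule = names(filt$report),
                               dropped = as.integer(filt$report),
                               stringsAsFactors = FALSE),
    trim_report = tab$trim_report,
    collapse_report = tab$report
  )

  # mature-tRNA feature matrix, row-standardised, k = 4 Euclidean clusters
  trna_feats <- run_stage("tsrna",
                          aggregate_features(cpm, anno_f, "mature_tRNA"))
  if (nrow(trna_feats$counts) >= 4L) {
    m <- trna_feats$counts
    mscaled <- t(scale(t(m)))
    mscaled[is.nan(mscaled)] <- 0
    hc <- hcluster(mscaled, metric = "euclidean", k = 4)
    bundle$trna_clusters <- data.frame(
      feature = rownames(m), cluster = as.integer(hc$labels),
      dendrogram_position = order(hc$order),
      multimap_fraction = as.numeric(trna_feats$multimap_fraction),
      stringsAsFactors = FALSE)
  }

  # tsRNA subtype distribution by origin (percent of tRNA-mapped mean CPM
  # over the five subtypes; whole-tRNA reads are excluded from the tally)
  if (nrow(cls) > 0L) {
    subtype_rows <- list()
    for (g in unique(pheno$group)) {
      mu <- rowMeans(cpm[, pheno$sample[pheno$group == g], drop = FALSE])
      x <- cls[cls$subtype != "whole_tRNA", , drop = FALSE]
      w <- mu[x$sequence]
      for (o in unique(x$origin)) {
        sel <- x$origin == o
        tot <- sum(w[sel])
        for (st in TSRNA_SUBTYPES) {
          subtype_rows[[length(subtype_rows) + 1L]] <- data.frame(
            group = g, origin = o, subtype = st,
            pct_cpm = if (tot > 0) 100 * sum(w[sel & x$subtype == st]) / tot
                      else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
    bundle$subtype_distribution <- do.call(rbind, subtype_rows)
  }

  # coverage profiles
  cov_ids <- config$coverage_trnas
  if (is.null(cov_ids)) {
    cov_ids <- names(structures)[vapply(structures, function(s)
      grepl("^mt-", s$id), logical(1))]
  }
  cov_rows <- list()
  for (id in intersect(cov_ids, names(structures))) {
    for (g in unique(pheno$group)) {
      v <- coverage_profile(cpm, anno_f, structures[[id]], pheno, g)
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        trna = id, group = g, position = seq_along(v), mean_cpm = v,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cov_rows)) bundle$coverage <- do.call(rbind, cov_rows)

  # per-contrast analytics
  for (ct in config$contrasts) {
    ga <- ct[1]; gb <- ct[2]
    key <- paste0(ga, "_vs_", gb)
    fc <- run_stage("quantify", log2fc(cpm, pheno, ga, gb))
    bundle[[paste0("seq_fc_", key)]] <- fc
    bundle[[paste0("origin_summary_", key)]] <-
      run_stage("quantify", origin_fc_summary(fc, anno_f))

    mirna <- run_stage("tsrna",
                       aggregate_features(filt$table$counts, anno_f, "miRNA"))
    if (nrow(mirna$counts) > 0L) {
      mirna_cpm <- aggregate_features(cpm, anno_f, "miRNA")$counts
      mfc <- log2fc(mirna_cpm, pheno, ga, gb)
      nb <- run_stage("stats", nb_glm_table(mirna$counts, pheno, ga, gb,
                                            lib_sizes = lib_sizes))
      m <- match(mfc$feature, nb$feature)
      mfc$p_value <- nb$p_value[m]
      mfc$nb_coefficient <- nb$coefficient[m]
      mfc$theta <- nb$theta[m]
      mfc$converged <- nb$converged[m]
      bundle[[paste0("mirna_features_", key)]] <- mfc
    }
  }

  # repeated-measures correlation of phenotypes with mito sRNA level
  if (!is.null(config$phenotype_cols) && length(config$phenotype_cols)) {
    mito_seqs <- anno_f$sequence[anno_f$origin == "mito"]
    if (length(mito_seqs) > 0L && "subject" %in% names(pheno)) {
      mito_level <- colMeans(cpm[mito_seqs, , drop = FALSE])
      rows <- lapply(intersect(config$phenotype_cols, names(pheno)),
                     function(p) {
        res <- rm_corr(pheno$subject, mito_level[pheno$sample], pheno[[p]])
        data.frame(phenotype = p, r = res$r, df = res$df,
                   p_value = res$p_value, slope = res$slope,
                   stringsAsFactors = FALSE)
      })
      if (length(rows)) bundle$rmcorr <- do.call(rbind, rows)
    }
  }

  # provenance (no timestamps: the bundle must be reproducible byte for byte)
  bundle$provenance <- list(
    package = "srnafrag",
    version = as.character(utils::packageVersion("srnafrag")),
    mode = if (synthetic) "synthetic" else "fastq",
    seed = if (synthetic) config$synth$seed else NA,
    contrasts = lapply(config$contrasts, function(ct)
      list(a = ct[1], b = ct[2])),
    filter_params = config$filter_params,
    n_sequences_retained = nrow(cpm),
    input_md5 = if (!is.null(input_files)) {
      fp <- unlist(input_files)
      # key hashes by file name, not path, so bundles stay byte-identical
      # across output directories
      as.list(stats::setNames(unname(tools::md5sum(fp)), basename(fp)))
    } else NULL
  )

  if (synthetic) bundle$truth <- sim$truth

  if (!is.null(config$out_dir)) {
    bundle$files <- write_bundle(bundle, config$out_dir)
  }
  invisible(bundle)
}

#' Write a report bundle as TSV + JSON
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory.
#' @return named vector of written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    if (is.data.frame(x)) {
      fn <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, fn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files[nm] <- fn
    } else if (identical(nm, "provenance")) {
      fn <- file.path(dir, "provenance.json")
      jsonlite::write_json(x, fn, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
      files[nm] <- fn
    }
  }
  files
}
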