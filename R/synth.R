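# Synthetic sperm-like small RNA library generator: reference sets with
# known composition, tRNAscan-SE style secondary structures, and
# adapter-bearing FASTQ reads with planted group effects and
# negative-binomial sample noise.

# amino acid / anticodon combinations used to label generated tRNA genes
TRNA_ANTICODONS <- data.frame(
  aa = c("Gly", "Ile", "Met", "Ala", "Glu", "Lys", "Val", "Leu", "Ser",
         "Arg", "Asp", "Phe", "His", "Pro", "Thr", "Asn", "Cys", "Trp",
         "Tyr", "Gln"),
  anticodon = c("TCC", "GAT", "CAT", "AGC", "TTC", "CTT", "AAC", "TAA",
                "GCT", "ACG", "GTC", "GAA", "GTG", "TGG", "AGT", "GTT",
                "GCA", "CCA", "GTA", "TTG"),
  stringsAsFactors = FALSE
)

#' Cloverleaf structure string for a generated tRNA gene
#'
#' Canonical layout: 7 bp acceptor stem, 4 bp D-stem with an 8 nt D-loop,
#' 5 bp anticodon stem with a 7 nt anticodon loop (positions 32-38,
#' anticodon at 34-36), a variable region of `len - 68` nt, 5 bp T-stem
#' with a 7 nt T-loop, and a single discriminator base. Characters follow
#' the tRNAscan-SE convention: `>` / `<` paired, `.` unpaired.
#'
#' @param len gene length in nt; must be >= 68.
#' @return a structure string of length `len`.
#' @keywords internal
cloverleaf_structure <- function(len) {
  v <- len - 68L
  if (v < 0L) stop("tRNA gene length must be >= 68 for the cloverleaf layout")
  paste0(strrep(">", 7), strrep(".", 2), strrep(">", 4), strrep(".", 8),
         strrep("<", 4), ".", strrep(">", 5), strrep(".", 7), strrep("<", 5),
         strrep(".", v), strrep(">", 5), strrep(".", 7), strrep("<", 5),
         strrep("<", 7), ".")
}

#' Default planted group effects
#'
#' A global +1 log2 up-shift of all mitochondrial transcripts and a single
#' up-regulated miRNA (+1.5 log2) in the second group, mirroring a high- vs
#' low-sugar contrast in which mitochondrial small RNA rise globally and one
#' miRNA responds.
#'
#' @param groups group labels; effects are planted in `groups[2]`.
#' @return list of effect specifications.
#' @export
default_effects <- function(groups) {
  if (length(groups) < 2L) return(list())
  list(
    list(selector = "origin:mito", group = groups[2], log2fc = 1),
    list(selector = "transcript:miRNA-01", group = groups[2], log2fc = 1.5)
  )
}

#' Configuration for the synthetic library generator
#'
#' Defaults emulate a sperm small RNA library: rRNA-derived fragments
#' dominate, tsRNA exceed miRNA, nuclear tsRNA are mostly 5'-halves while
#' mitochondrial tsRNA are mostly internal fragments, and miRNA reads peak
#' at 21-23 nt. Two diet groups of five samples each are simulated with
#' negative-binomial noise (size `dispersion`) and the planted effects of
#' [default_effects()].
#'
#' @param n_nuclear_trna,n_mito_trna,n_mirna,n_rrna,n_other number of genes
#'   per biotype (`n_other` applies to each of lncRNA, piRNA and
#'   protein-coding).
#' @param genome_pad nt of random spacer between genes in the synthetic
#'   genomes.
#' @param groups group labels.
#' @param n_samples_per_group samples per group; sample `j` of every group
#'   shares subject `j` (paired design).
#' @param reads_per_sample total reads per sample, including adapter-free
#'   reads.
#' @param dispersion negative-binomial size parameter theta (> 0);
#'   per-fragment abundances are Gamma(theta) mixed before multinomial read
#'   sampling, giving NB-distributed fragment counts.
#' @param adapter 3' adapter appended to every informative read.
#' @param adapter_free_fraction fraction of reads carrying no adapter
#'   (discarded by trimming).
#' @param adapter_min_overlap minimum adapter prefix length used both when
#'   rejection-sampling adapter-free reads and as the trimming default.
#' @param read_length sequencing window; the adapter is truncated when the
#'   window ends early.
#' @param trna_length,mito_trna_length gene lengths (mature tRNA adds a
#'   non-templated 3' CCA, so mature length is 3 nt longer).
#' @param biotype_mix expected read-mass fractions per biotype class.
#' @param cut_sites_nuclear,cut_sites_mito tsRNA subtype probabilities for
#'   nuclear and mitochondrial tRNA fragments.
#' @param fragments_per_subtype distinct fragments drawn per tRNA subtype.
#' @param rrna_fragments,other_fragments distinct fragments per rRNA and per
#'   lncRNA/protein-coding gene.
#' @param effects list of planted effects, each
#'   `list(selector=, group=, log2fc=)` with selector one of
#'   `"origin:<nuclear|mito>"`, `"biotype:<name>"`, `"transcript:<id>"`.
#' @param phenotype_assoc named slopes linking per-sample mitochondrial read
#'   fraction to generated phenotype columns.
#' @param seed integer seed; config + seed fully determine all outputs.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_nuclear_trna = 20, n_mito_trna = 5,
                             n_mirna = 20, n_rrna = 5, n_other = 10,
                             genome_pad = 50,
                             groups = c("sugar30", "sugar300"),
                             n_samples_per_group = 5,
                             reads_per_sample = 50000,
                             dispersion = 10,
                             adapter = NEB_ADAPTER,
                             adapter_free_fraction = 0.1,
                             adapter_min_overlap = 3,
                             read_length = 75,
                             trna_length = 73, mito_trna_length = 69,
                             biotype_mix = c(rRNA = 0.70, tsRNA = 0.15,
                                             miRNA = 0.05, mt_tsRNA = 0.03,
                                             other = 0.07),
                             cut_sites_nuclear = c(five_half = 0.50,
                                                   five_tsRNA = 0.15,
                                                   i_tsRNA = 0.10,
                                                   three_tsRNA = 0.10,
                                                   three_half = 0.15),
                             cut_sites_mito = c(five_half = 0.10,
                                                five_tsRNA = 0.10,
                                                i_tsRNA = 0.60,
                                                three_tsRNA = 0.10,
                                                three_half = 0.10),
                             fragments_per_subtype = 2,
                             rrna_fragments = 20,
                             other_fragments = 6,
                             effects = default_effects(groups),
                             phenotype_assoc = c(motility = 400,
                                                 sperm_count = 250),
                             seed = 1L) {
  for (nm in c("n_nuclear_trna", "n_mito_trna", "n_mirna", "n_rrna",
               "n_other")) {
    stopifnot_scalar_count(get(nm), nm, min = 0L)
  }
  stopifnot_scalar_count(reads_per_sample, "reads_per_sample", min = 0L)
  stopifnot_scalar_count(n_samples_per_group, "n_samples_per_group", min = 1L)
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("'dispersion' (NB size theta) must be > 0")
  }
  if (adapter_free_fraction < 0 || adapter_free_fraction >= 1) {
    stop("'adapter_free_fraction' must be in [0, 1)")
  }
  if (grepl("[^ACGT]", adapter)) stop("adapter must be over ACGT")
  if (length(groups) < 1L || anyDuplicated(groups)) {
    stop("'groups' must be non-empty and unique")
  }
  if (trna_length < 68 || mito_trna_length < 68) {
    stop("tRNA gene lengths must be >= 68")
  }
  if (abs(sum(biotype_mix) - 1) > 1e-8) biotype_mix <- biotype_mix / sum(biotype_mix)
  for (cs in list(cut_sites_nuclear, cut_sites_mito)) {
    if (!all(TSRNA_SUBTYPES %in% names(cs))) {
      stop("cut-site models must name all five tsRNA subtypes")
    }
  }
  cfg <- list(
    n_nuclear_trna = as.integer(n_nuclear_trna),
    n_mito_trna = as.integer(n_mito_trna),
    n_mirna = as.integer(n_mirna), n_rrna = as.integer(n_rrna),
    n_other = as.integer(n_other), genome_pad = as.integer(genome_pad),
    groups = groups, n_samples_per_group = as.integer(n_samples_per_group),
    reads_per_sample = as.integer(reads_per_sample),
    dispersion = dispersion, adapter = adapter,
    adapter_free_fraction = adapter_free_fraction,
    adapter_min_overlap = as.integer(adapter_min_overlap),
    read_length = as.integer(read_length),
    trna_length = as.integer(trna_length),
    mito_trna_length = as.integer(mito_trna_length),
    biotype_mix = biotype_mix,
    cut_sites_nuclear = cut_sites_nuclear[TSRNA_SUBTYPES] /
      sum(cut_sites_nuclear[TSRNA_SUBTYPES]),
    cut_sites_mito = cut_sites_mito[TSRNA_SUBTYPES] /
      sum(cut_sites_mito[TSRNA_SUBTYPES]),
    fragments_per_subtype = as.integer(fragments_per_subtype),
    rrna_fragments = as.integer(rrna_fragments),
    other_fragments = as.integer(other_fragments),
    effects = effects, phenotype_assoc = phenotype_assoc,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# draw one gene sequence that is pairwise non-substring with the pool
draw_unique_gene <- function(len, pool, max_tries = 200L, no_cca_end = FALSE) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(1, len)
    if (no_cca_end && endsWith(s, "CCA")) next
    if (!has_substring_conflict(s, pool)) return(s)
  }
  stop("could not generate a pairwise non-substring gene of length ", len,
       " after ", max_tries, " attempts; increase gene length")
}

# fragment catalogue for one tRNA (coordinates on the mature, CCA-bearing seq)
trna_fragment_catalog <- function(struct, cut_sites, k) {
  L <- nchar(struct$mature_seq)
  a <- struct$loop[1]; b <- struct$loop[2]
  draw <- function(subtype) {
    switch(subtype,
      five_half   = c(1L, sample(a:b, 1L)),
      five_tsRNA  = c(1L, sample(18:(a - 1L), 1L)),
      i_tsRNA     = {
        st <- sample(3:12, 1L)
        en <- min(st + sample(18:28, 1L) - 1L, L - 2L)
        c(st, en)
      },
      three_tsRNA = c(sample((b + 1L):(L - 17L), 1L), L),
      three_half  = c(sample(a:b, 1L), L)
    )
  }
  out <- list()
  for (subtype in TSRNA_SUBTYPES) {
    got <- 0L; tries <- 0L
    while (got < k && tries < 100L) {
      tries <- tries + 1L
      se <- draw(subtype)
      key <- paste(se, collapse = "-")
      if (is.null(out[[key]])) {
        out[[key]] <- data.frame(start = se[1], end = se[2],
                                 subtype = subtype,
                                 weight = cut_sites[[subtype]] / k,
                                 stringsAsFactors = FALSE)
        got <- got + 1L
      }
    }
  }
  do.call(rbind, unname(out))
}

#' Build a synthetic reference set with ground truth
#'
#' Generates per-biotype reference FASTA collections, a nuclear and a
#' mitochondrial genome (genes concatenated with random spacers, strands
#' randomised), tRNAscan-SE style secondary structures for every tRNA gene,
#' and a fragment catalogue with expected abundance weights. Mature tRNA
#' sequences carry a 3' CCA that is absent from the genome copy, so 3'
#' tRNA fragments match the biotype reference but not the genome.
#' Transcript sequences are rejection-sampled to be pairwise non-substring
#' so biotype assignment on synthetic data is unambiguous.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `refset` (class `reference_set`: ordered
#'   `biotype_refs`, `nuclear_genome`, `mito_genome`, `trna_structures`) and
#'   `truth` (class `simulation_truth`: `transcripts`, `fragments`,
#'   `effect_multipliers`, `config`).
#' @export
build_reference_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  pool <- character(0)
  transcripts <- list()
  structures <- list()
  add_transcript <- function(id, biotype, origin, seq) {
    transcripts[[length(transcripts) + 1L]] <<- data.frame(
      id = id, biotype = biotype, origin = origin, length = nchar(seq),
      sequence = seq, stringsAsFactors = FALSE)
    pool <<- c(pool, seq)
  }

  make_trnas <- function(n, len, prefix, origin) {
    if (n == 0L) return(invisible(NULL))
    str <- cloverleaf_structure(len)
    for (i in seq_len(n)) {
      ac <- TRNA_ANTICODONS[((i - 1L) %% nrow(TRNA_ANTICODONS)) + 1L, ]
      copy <- ((i - 1L) %/% nrow(TRNA_ANTICODONS)) + 1L
      id <- sprintf("%s-%s-%s-%d-1", prefix, ac$aa, ac$anticodon, copy)
      gene <- draw_unique_gene(len, pool, no_cca_end = TRUE)
      substr(gene, 34, 36) <- ac$anticodon
      if (endsWith(gene, "CCA") || has_substring_conflict(gene, pool)) {
        # anticodon substitution may rarely reintroduce a conflict; redraw
        repeat {
          gene <- draw_unique_gene(len, pool, no_cca_end = TRUE)
          substr(gene, 34, 36) <- ac$anticodon
          if (!endsWith(gene, "CCA") && !has_substring_conflict(gene, pool)) break
        }
      }
      mature <- paste0(gene, "CCA")
      biotype <- if (origin == "mito") "mt-tRNA" else "tRNA"
      add_transcript(id, biotype, origin, mature)
      structures[[id]] <<- new_trna_structure(
        id = id, mature_seq = mature, structure = paste0(str, "..."),
        anticodon = ac$anticodon, ac_start = 34L, ac_end = 36L,
        aa = ac$aa, cca_appended = TRUE)
    }
  }

  # hierarchy order: rRNA, mt-tRNA, tRNA, miRNA, lncRNA, piRNA, protein-coding
  if (config$n_rrna > 0L) {
    for (i in seq_len(config$n_rrna)) {
      add_transcript(sprintf("rRNA-%02d", i), "rRNA", "nuclear",
                     draw_unique_gene(sample(120:200, 1L), pool))
    }
  }
  make_trnas(config$n_mito_trna, config$mito_trna_length, "mt-tRNA", "mito")
  make_trnas(config$n_nuclear_trna, config$trna_length, "tRNA", "nuclear")
  if (config$n_mirna > 0L) {
    for (i in seq_len(config$n_mirna)) {
      add_transcript(sprintf("miRNA-%02d", i), "miRNA", "nuclear",
                     draw_unique_gene(sample(21:23, 1L), pool))
    }
  }
  if (config$n_other > 0L) {
    for (i in seq_len(config$n_other)) {
      add_transcript(sprintf("lncRNA-%02d", i), "lncRNA", "nuclear",
                     draw_unique_gene(sample(150:250, 1L), pool))
    }
    for (i in seq_len(config$n_other)) {
      add_transcript(sprintf("piRNA-%02d", i), "piRNA", "nuclear",
                     draw_unique_gene(sample(26:31, 1L), pool))
    }
    for (i in seq_len(config$n_other)) {
      add_transcript(sprintf("protein_coding-%02d", i), "protein_coding",
                     "nuclear", draw_unique_gene(sample(150:250, 1L), pool))
    }
  }
  transcripts <- do.call(rbind, transcripts)
  if (is.null(transcripts)) stop("config generates no transcripts")

  # genomes: genes with random spacers; tRNA genomic copies lack the CCA
  build_genome <- function(tx) {
    pieces <- character(0)
    pos <- 0L
    rows <- list()
    if (config$genome_pad > 0L) {
      sp <- random_dna(1, config$genome_pad)
      pieces <- c(pieces, sp); pos <- pos + nchar(sp)
    }
    if (nrow(tx) > 0L) {
      strands <- sample(c("+", "-"), nrow(tx), replace = TRUE)
      for (i in seq_len(nrow(tx))) {
        gseq <- tx$sequence[i]
        if (tx$biotype[i] %in% c("tRNA", "mt-tRNA")) {
          gseq <- substr(gseq, 1L, nchar(gseq) - 3L)  # drop non-templated CCA
        }
        emb <- if (strands[i] == "-") revcomp(gseq) else gseq
        pieces <- c(pieces, emb)
        rows[[i]] <- data.frame(
          id = tx$id[i], start = pos + 1L, end = pos + nchar(emb),
          strand = strands[i], stringsAsFactors = FALSE)
        pos <- pos + nchar(emb)
        if (config$genome_pad > 0L) {
          sp <- random_dna(1, config$genome_pad)
          pieces <- c(pieces, sp); pos <- pos + nchar(sp)
        }
      }
    }
    coords <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(0), start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    list(seq = paste(pieces, collapse = ""), coords = coords)
  }
  nuc <- build_genome(transcripts[transcripts$origin == "nuclear", ])
  mit <- build_genome(transcripts[transcripts$origin == "mito", ])

  transcripts$genome <- ifelse(transcripts$origin == "mito", "chrM", "chrN")
  coords <- rbind(nuc$coords, mit$coords)
  m <- match(transcripts$id, coords$id)
  transcripts$start <- coords$start[m]
  transcripts$end <- coords$end[m]
  transcripts$strand <- coords$strand[m]

  # fragment catalogue
  frags <- list()
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    cat_i <- switch(tx$biotype,
      "tRNA" = , "mt-tRNA" = {
        cs <- if (tx$origin == "mito") config$cut_sites_mito else config$cut_sites_nuclear
        trna_fragment_catalog(structures[[tx$id]], cs,
                              config$fragments_per_subtype)
      },
      "miRNA" = , "piRNA" = data.frame(start = 1L, end = tx$length,
                                       subtype = NA_character_, weight = 1),
      "rRNA" = {
        n <- config$rrna_fragments
        len <- sample(18:50, n, replace = TRUE)
        st <- vapply(len, function(l) sample(seq_len(tx$length - l + 1L), 1L),
                     integer(1))
        w <- stats::rgamma(n, shape = 1.5)
        data.frame(start = st, end = st + len - 1L, subtype = NA_character_,
                   weight = w / sum(w))
      },
      {
        n <- config$other_fragments
        len <- sample(18:40, n, replace = TRUE)
        st <- vapply(len, function(l) sample(seq_len(tx$length - l + 1L), 1L),
                     integer(1))
        w <- stats::rgamma(n, shape = 1.5)
        data.frame(start = st, end = st + len - 1L, subtype = NA_character_,
                   weight = w / sum(w))
      })
    cat_i <- cat_i[!duplicated(cat_i[, c("start", "end")]), , drop = FALSE]
    cat_i$weight <- cat_i$weight / sum(cat_i$weight)
    cat_i$transcript_id <- tx$id
    cat_i$biotype <- tx$biotype
    cat_i$origin <- tx$origin
    cat_i$sequence <- substr(rep(tx$sequence, nrow(cat_i)), cat_i$start,
                             cat_i$end)
    frags[[i]] <- cat_i
  }
  fragments <- do.call(rbind, frags)
  fragments <- fragments[, c("transcript_id", "biotype", "origin", "start",
                             "end", "subtype", "sequence", "weight")]

  # biotype masses, renormalised over biotypes that are present
  class_of <- c("rRNA" = "rRNA", "mt-tRNA" = "mt_tsRNA", "tRNA" = "tsRNA",
                "miRNA" = "miRNA", "lncRNA" = "other", "piRNA" = "other",
                "protein_coding" = "other")
  present <- unique(transcripts$biotype)
  mass <- config$biotype_mix
  n_other_types <- sum(c("lncRNA", "piRNA", "protein_coding") %in% present)
  bt_mass <- vapply(present, function(bt) {
    cl <- class_of[[bt]]
    if (cl == "other") mass[["other"]] / n_other_types else mass[[cl]]
  }, numeric(1))
  names(bt_mass) <- present
  bt_mass <- bt_mass / sum(bt_mass)

  # transcript weights within biotype ~ Gamma(2), then fragment weights
  tw <- stats::rgamma(nrow(transcripts), shape = 2)
  for (bt in present) {
    idx <- transcripts$biotype == bt
    tw[idx] <- tw[idx] / sum(tw[idx]) * bt_mass[[bt]]
  }
  names(tw) <- transcripts$id
  fragments$weight <- fragments$weight * tw[fragments$transcript_id]
  fragments$weight <- fragments$weight / sum(fragments$weight)
  fragments$fragment_id <- sprintf("%s:%d-%d", fragments$transcript_id,
                                   fragments$start, fragments$end)
  rownames(fragments) <- NULL

  # sanity: no transcript may occur in the other genome (either strand)
  other_genome <- function(origin) if (origin == "mito") nuc$seq else mit$seq
  for (i in seq_len(nrow(transcripts))) {
    g <- other_genome(transcripts$origin[i])
    s <- transcripts$sequence[i]
    if (nchar(g) >= nchar(s) &&
        (grepl(s, g, fixed = TRUE) || grepl(revcomp(s), g, fixed = TRUE))) {
      stop("transcript ", transcripts$id[i],
           " collides with the opposite genome; uniqueness unattainable")
    }
  }

  biotype_refs <- lapply(BIOTYPE_HIERARCHY, function(bt) {
    tx <- transcripts[transcripts$biotype == bt, ]
    Biostrings::DNAStringSet(structure(tx$sequence, names = tx$id))
  })
  names(biotype_refs) <- BIOTYPE_HIERARCHY

  refset <- structure(list(
    biotype_refs = biotype_refs,
    nuclear_genome = Biostrings::DNAStringSet(c(chrN = nuc$seq)),
    mito_genome = Biostrings::DNAStringSet(c(chrM = mit$seq)),
    trna_structures = structures
  ), class = "reference_set")

  truth <- structure(list(
    transcripts = transcripts[, c("id", "biotype", "origin", "genome",
                                  "start", "end", "strand", "length",
                                  "sequence")],
    fragments = fragments,
    effect_multipliers = resolve_effects(fragments, config),
    config = config
  ), class = "simulation_truth")

  list(refset = refset, truth = truth)
}

# fragment x group matrix of 2^log2fc multipliers; errors on empty selectors
resolve_effects <- function(fragments, config) {
  mult <- matrix(1, nrow = nrow(fragments), ncol = length(config$groups),
                 dimnames = list(fragments$fragment_id, config$groups))
  for (eff in config$effects) {
    if (!eff$group %in% config$groups) {
      stop("effect group '", eff$group, "' is not a configured group")
    }
    parts <- strsplit(eff$selector, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad effect selector: ", eff$selector)
    idx <- switch(parts[1],
      origin = fragments$origin == parts[2],
      biotype = fragments$biotype == parts[2],
      transcript = fragments$transcript_id == parts[2],
      stop("unknown effect selector type: ", parts[1]))
    if (!any(idx)) {
      stop("effect selector '", eff$selector, "' matches no transcript")
    }
    mult[idx, eff$group] <- mult[idx, eff$group] * 2^eff$log2fc
  }
  mult
}

# adapter-free reads: rejection-sample so no full adapter occurs and no
# adapter prefix of length >= min_overlap is a read suffix (these reads must
# be discarded by trimming, deterministically)
draw_adapter_free <- function(n, read_length, adapter, min_overlap) {
  if (n == 0L) return(character(0))
  ok <- function(x) {
    if (grepl(adapter, x, fixed = TRUE)) return(FALSE)
    kmax <- min(nchar(adapter), nchar(x))
    for (k in min_overlap:kmax) {
      if (endsWith(x, substr(adapter, 1L, k))) return(FALSE)
    }
    TRUE
  }
  reads <- random_dna(n, read_length)
  for (i in seq_len(n)) {
    while (!ok(reads[i])) reads[i] <- random_dna(1, read_length)
  }
  reads
}

#' Simulate per-sample FASTQ reads
#'
#' For each sample, per-fragment proportions are formed from catalogue
#' weights times the group's planted effect multipliers times independent
#' Gamma(theta) noise, and `reads_per_sample` reads are drawn: a binomial
#' share of adapter-free reads plus a multinomial draw over fragments.
#' Marginally this yields negative-binomial fragment counts with size
#' theta. Each informative read is the fragment sequence followed by the 3'
#' adapter, truncated at `read_length`; qualities are constant.
#'
#' @param refset,truth output of [build_reference_set()].
#' @param config the same [synthetic_config()].
#' @param out_dir if non-NULL, one FASTQ file per sample is written there.
#' @return class `srna_simulation`: `pheno` (sample, group, subject,
#'   phenotype columns), `reads` (named list of character vectors),
#'   `fastq` (paths or NULL), `realized_counts` and `expected_counts`
#'   (fragment x sample matrices), `truth`.
#' @export
simulate_reads <- function(refset, truth, config, out_dir = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(config$seed + 1L)
  frag <- truth$fragments
  mult <- truth$effect_multipliers
  groups <- rep(config$groups, each = config$n_samples_per_group)
  subj_idx <- rep(seq_len(config$n_samples_per_group), length(config$groups))
  samples <- sprintf("%s_rep%d", groups, subj_idx)
  subjects <- sprintf("subj%02d", subj_idx)
  n_subj <- config$n_samples_per_group
  subj_eff <- lapply(names(config$phenotype_assoc), function(p) {
    stats::rnorm(n_subj, 0, 2)
  })
  names(subj_eff) <- names(config$phenotype_assoc)

  N <- config$reads_per_sample
  f <- config$adapter_free_fraction
  nfrag <- nrow(frag)
  realized <- matrix(0L, nfrag, length(samples),
                     dimnames = list(frag$fragment_id, samples))
  expected <- matrix(0, nfrag, length(samples),
                     dimnames = list(frag$fragment_id, samples))
  reads <- vector("list", length(samples))
  names(reads) <- samples
  read_ids <- vector("list", length(samples))
  pheno_extra <- matrix(0, length(samples), length(config$phenotype_assoc),
                        dimnames = list(samples, names(config$phenotype_assoc)))

  for (s in seq_along(samples)) {
    g <- groups[s]
    w <- frag$weight * mult[, g]
    expected[, s] <- N * (1 - f) * w / sum(w)
    if (N == 0L) {
      reads[[s]] <- character(0); read_ids[[s]] <- character(0)
    } else {
      gam <- stats::rgamma(nfrag, shape = config$dispersion,
                           rate = config$dispersion)
      p <- w * gam
      n_af <- stats::rbinom(1L, N, f)
      cts <- as.integer(stats::rmultinom(1L, N - n_af, p))
      realized[, s] <- cts
      ins <- rep(frag$sequence, cts)
      full <- paste0(ins, config$adapter)
      frag_reads <- substr(full, 1L, pmin(nchar(full), config$read_length))
      af_reads <- draw_adapter_free(n_af, config$read_length, config$adapter,
                                    config$adapter_min_overlap)
      src <- c(rep(frag$fragment_id, cts), rep("adapter_free", n_af))
      all_reads <- c(frag_reads, af_reads)
      ord <- sample(length(all_reads))
      reads[[s]] <- all_reads[ord]
      read_ids[[s]] <- sprintf("%s:%07d %s", samples[s],
                               seq_along(ord), src[ord])
    }
    mito_frac <- if (sum(realized[, s]) > 0) {
      sum(realized[frag$origin == "mito", s]) / sum(realized[, s])
    } else 0
    for (p in names(config$phenotype_assoc)) {
      pheno_extra[s, p] <- 40 + config$phenotype_assoc[[p]] * mito_frac +
        subj_eff[[p]][subj_idx[s]] + stats::rnorm(1, 0, 0.5)
    }
  }

  pheno <- data.frame(sample = samples, group = groups, subject = subjects,
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(pheno_extra))
  rownames(pheno) <- samples

  fastq <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fastq <- file.path(out_dir, paste0(samples, ".fastq"))
    for (s in seq_along(samples)) {
      x <- Biostrings::DNAStringSet(reads[[s]])
      names(x) <- read_ids[[s]]
      Biostrings::writeXStringSet(
        x, fastq[s], format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", nchar(reads[[s]]))))
    }
    names(fastq) <- samples
  }

  structure(list(pheno = pheno, reads = reads, read_ids = read_ids,
                 fastq = fastq, realized_counts = realized,
                 expected_counts = expected, truth = truth),
            class = "srna_simulation")
}

#' Write a reference set to a directory
#'
#' Emits per-biotype FASTA files, the two genome FASTAs, a tRNAscan-SE
#' style `.ss` file for all tRNA structures, and TSV truth tables.
#'
#' @param built output of [build_reference_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(built, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rs <- built$refset
  for (bt in names(rs$biotype_refs)) {
    fn <- file.path(dir, paste0(gsub("-", "_", bt), ".fasta"))
    Biostrings::writeXStringSet(rs$biotype_refs[[bt]], fn)
  }
  Biostrings::writeXStringSet(rs$nuclear_genome,
                              file.path(dir, "genome_nuclear.fasta"))
  Biostrings::writeXStringSet(rs$mito_genome,
                              file.path(dir, "genome_mito.fasta"))
  write_ss(rs$trna_structures, file.path(dir, "trna_structures.ss"),
           coords = built$truth$transcripts)
  utils::write.table(built$truth$transcripts,
                     file.path(dir, "truth_transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(built$truth$fragments,
                     file.path(dir, "truth_fragments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic small RNA library config\n")
  cat(sprintf("  genes: %d nuclear tRNA, %d mito tRNA, %d miRNA, %d rRNA, %d per other biotype\n",
              x$n_nuclear_trna, x$n_mito_trna, x$n_mirna, x$n_rrna, x$n_other))
  cat(sprintf("  samples: %s x %d; %d reads/sample; theta = %g; seed = %d\n",
              paste(x$groups, collapse = "/"), x$n_samples_per_group,
              x$reads_per_sample, x$dispersion, x$seed))
  invisible(x)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation truth: %d transcripts, %d fragments, %d planted effects\n",
              nrow(x$transcripts), nrow(x$fragments), length(x$config$effects)))
  invisible(x)
}
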