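#' Configuration for the synthetic alignment generator
#'
#' The generator emulates the alignment-level structure of droplet scRNA-seq
#' over a repetitive annotation: barcoded, UMI-tagged reads; PCR duplicates
#' sharing CB+UMI; multimapped reads whose extra candidate loci ("decoys")
#' come from the same subfamily with alignment scores reduced by a few units
#' (mirroring aligners that report suboptimal hits within a small score
#' range); reads also counted by a canonical-gene quantifier (GX tag); and
#' background reads aligning outside the annotation. Simulation starts at
#' the alignment level -- no sequences or error model -- because alignments
#' are the tool's input.
#'
#' Defaults describe a modest but realistic droplet experiment: 100 cells,
#' ~300 captured molecules per cell over 50 loci in 5 subfamilies, 40% of
#' reads ambiguous with up to 3 same-subfamily decoys, an expected 0.43
#' extra PCR copies per molecule (`duplication_rate` 0.3 as the geometric
#' parameter), 12-base UMIs (10x v3 chemistry), 10% of TE reads also tagged
#' by the gene quantifier, and 5% background molecules.
#'
#' @param n_loci,n_subfamilies annotation size (loci are assigned to
#'   subfamilies round-robin).
#' @param n_cells number of cells.
#' @param n_pools number of ground-truth abundance pools; cells are assigned
#'   round-robin and each pool draws its own abundance vector.
#' @param pi_truth optional matrix (pools x loci, rows summing to 1) of true
#'   abundances; drawn from a flat Dirichlet when `NULL`.
#' @param mean_fragments_per_cell expected captured molecules per cell
#'   (Poisson).
#' @param ambiguous_fraction probability a read gains decoy alignments.
#' @param max_decoys_per_read maximum decoys per ambiguous read.
#' @param score_gap_range integer range of alignment-score reduction for
#'   decoys (AS units).
#' @param duplication_rate geometric parameter: each molecule emits
#'   `1 + rgeom(1 - duplication_rate)` reads; 0 means no duplicates.
#' @param umi_length UMI length in bases (collisions possible at short
#'   lengths, exercising multi-component deduplication).
#' @param gx_rate fraction of TE molecules whose reads carry a GX tag.
#' @param no_feature_rate fraction of molecules that are background
#'   (non-TE), aligned outside the annotation.
#' @param read_length read length in bases.
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return a `te_sim_config` list.
#' @export
sim_config <- function(n_loci = 50, n_subfamilies = 5, n_cells = 100,
                       n_pools = 1, pi_truth = NULL,
                       mean_fragments_per_cell = 300,
                       ambiguous_fraction = 0.4, max_decoys_per_read = 3,
                       score_gap_range = c(0L, 5L), duplication_rate = 0.3,
                       umi_length = 12, gx_rate = 0.1, no_feature_rate = 0.05,
                       read_length = 90, seed = 1) {
  stopifnot(
    n_loci >= n_subfamilies, n_subfamilies >= 1, n_cells >= 1, n_pools >= 1,
    ambiguous_fraction >= 0, ambiguous_fraction <= 1,
    duplication_rate >= 0, duplication_rate < 1,
    gx_rate >= 0, gx_rate <= 1, no_feature_rate >= 0, no_feature_rate <= 1,
    max_decoys_per_read >= 1, umi_length >= 1
  )
  if (!is.null(pi_truth)) {
    pi_truth <- rbind(pi_truth)
    stopifnot(nrow(pi_truth) == n_pools, ncol(pi_truth) == n_loci,
              all(abs(rowSums(pi_truth) - 1) < 1e-8))
  }
  cfg <- as.list(environment())
  class(cfg) <- "te_sim_config"
  cfg
}

rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

random_seqs <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Simulate a TE annotation
#'
#' Loci of 1 kb are tiled 10 kb apart along synthetic chromosomes (at most
#' 25 loci per chromosome) and assigned to subfamilies round-robin, so decoy
#' alignments drawn within a subfamily land on well-separated loci.
#'
#' @param config a `te_sim_config`.
#' @return a `te_annotation`.
#' @export
simulate_annotation <- function(config) {
  withr::local_seed(config$seed)
  n <- config$n_loci
  per_chrom <- 25L
  chrom_i <- (seq_len(n) - 1L) %/% per_chrom + 1L
  pos_i <- (seq_len(n) - 1L) %% per_chrom
  start <- pos_i * 10000L + 1001L
  loci <- data.frame(
    locus_id = sprintf("TE_%04d", seq_len(n)),
    subfamily = sprintf("SF%02d", (seq_len(n) - 1L) %% config$n_subfamilies + 1L),
    chrom = sprintf("chrS%d", chrom_i),
    strand = rep(c("+", "-"), length.out = n),
    stringsAsFactors = FALSE
  )
  gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start, start + 999L), strand = loci$strand
  )
  gr$locus_id <- loci$locus_id
  new_te_annotation(loci, gr)
}

#' Simulate barcoded, UMI-tagged alignment records with ground truth
#'
#' See [sim_config()] for the generative model. Every emitted read's
#' candidate set contains its true locus; decoys are drawn from the read's
#' subfamily. Background molecules map uniquely to a chromosome absent from
#' the annotation.
#'
#' @param config a `te_sim_config`.
#' @param annotation annotation from [simulate_annotation()] (regenerated
#'   from the config when `NULL`).
#' @return list with `records` (alignment data.frame as from
#'   [read_alignments()], plus `true_locus` and `molecule` columns),
#'   `truth` (list: `molecules` data.frame of cell/umi/locus, `true_counts`
#'   sparse loci x cells matrix, `pi_truth`, `pools` label per cell) and
#'   `annotation`.
#' @export
simulate_reads <- function(config, annotation = NULL) {
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  withr::local_seed((config$seed + 104729L) %% .Machine$integer.max)

  n_loci <- config$n_loci
  loci <- annotation$loci$locus_id
  cells <- paste0(random_seqs(config$n_cells, 16L), "-1")
  pool_of <- sprintf("pool%d", (seq_len(config$n_cells) - 1L) %% config$n_pools + 1L)
  pi_truth <- config$pi_truth
  if (is.null(pi_truth)) {
    pi_truth <- t(vapply(seq_len(config$n_pools),
                         function(i) rdirichlet1(n_loci), numeric(n_loci)))
  }
  rownames(pi_truth) <- sprintf("pool%d", seq_len(config$n_pools))
  colnames(pi_truth) <- loci

  # molecules per cell
  n_mol <- rpois(config$n_cells, config$mean_fragments_per_cell)
  cell_idx <- rep(seq_len(config$n_cells), n_mol)
  n_total <- sum(n_mol)
  if (n_total == 0L) stop("simulation produced zero molecules")
  is_bg <- runif(n_total) < config$no_feature_rate
  mol_locus <- rep(NA_integer_, n_total)
  for (p in seq_len(config$n_pools)) {
    sel <- !is_bg & pool_of[cell_idx] == sprintf("pool%d", p)
    mol_locus[sel] <- sample.int(n_loci, sum(sel), replace = TRUE,
                                 prob = pi_truth[p, ])
  }
  umi <- random_seqs(n_total, config$umi_length)
  mol_gx <- !is_bg & runif(n_total) < config$gx_rate

  # reads per molecule: 1 + geometric duplicates
  n_reads <- 1L + rgeom(n_total, prob = 1 - config$duplication_rate)
  mol_of_read <- rep(seq_len(n_total), n_reads)
  n_read_total <- length(mol_of_read)
  read_name <- sprintf("read%08d", seq_len(n_read_total))

  # per-read decoys within subfamily (vectorized; the only loop samples
  # without replacement from each ambiguous read's small subfamily pool)
  fam <- annotation$loci$subfamily
  fam_members <- split(seq_len(n_loci), fam)
  fam_excl <- lapply(seq_len(n_loci),
                     function(l) setdiff(fam_members[[fam[l]]], l))
  gr <- annotation$ranges
  locus_chrom <- annotation$loci$chrom
  locus_start <- GenomicRanges::start(gr)[match(loci, gr$locus_id)]
  locus_end <- GenomicRanges::end(gr)[match(loci, gr$locus_id)]
  rl <- config$read_length
  gap_lo <- as.integer(config$score_gap_range[1L])
  gap_hi <- as.integer(config$score_gap_range[2L])
  base_as <- rl

  read_mol <- mol_of_read
  read_bg <- is_bg[read_mol]
  read_locus <- ifelse(read_bg, NA_integer_, mol_locus[read_mol])
  amb <- !read_bg & runif(n_read_total) < config$ambiguous_fraction
  nd <- integer(n_read_total)
  if (any(amb)) {
    nd[amb] <- sample.int(config$max_decoys_per_read, sum(amb), replace = TRUE)
    avail <- lengths(fam_excl)[read_locus[amb]]
    nd[amb] <- pmin(nd[amb], avail)
  }
  n_cand <- 1L + nd
  idx_amb <- which(nd > 0L)
  decoys <- lapply(idx_amb, function(r) {
    pool <- fam_excl[[read_locus[r]]]
    pool[sample.int(length(pool), nd[r])]
  })

  n_aln <- sum(n_cand)
  aln_read <- rep(seq_len(n_read_total), n_cand)
  pos1 <- cumsum(n_cand) - n_cand + 1L
  cand_locus <- integer(n_aln)
  cand_locus[pos1] <- ifelse(read_bg, 0L, read_locus)
  if (length(idx_amb)) cand_locus[-pos1] <- unlist(decoys)
  is_primary <- logical(n_aln)
  is_primary[pos1] <- TRUE

  score <- integer(n_aln)
  score[pos1] <- base_as
  if (n_aln > n_read_total) {
    score[-pos1] <- base_as -
      sample(gap_lo:gap_hi, n_aln - n_read_total, replace = TRUE)
  }
  start <- integer(n_aln)
  te_aln <- cand_locus > 0L
  span <- locus_end[cand_locus[te_aln]] - locus_start[cand_locus[te_aln]] - rl + 2L
  start[te_aln] <- locus_start[cand_locus[te_aln]] +
    as.integer(floor(runif(sum(te_aln)) * span))
  n_bg_aln <- sum(!te_aln)
  if (n_bg_aln) start[!te_aln] <- 1000L + sample.int(100000L, n_bg_aln, replace = TRUE)

  records <- data.frame(
    read_name = read_name[aln_read],
    chrom = ifelse(te_aln, locus_chrom[pmax(cand_locus, 1L)], "chrBG"),
    start = start, end = start + rl - 1L, score = score,
    cb = cells[cell_idx[read_mol[aln_read]]],
    umi = umi[read_mol[aln_read]],
    gx = mol_gx[read_mol[aln_read]],
    nh = n_cand[aln_read],
    true_locus = loci[read_locus[aln_read]],   # NA for background reads
    molecule = read_mol[aln_read],
    stringsAsFactors = FALSE
  )

  te_mol <- which(!is_bg)
  true_counts <- Matrix::sparseMatrix(
    i = mol_locus[te_mol], j = cell_idx[te_mol], x = 1,
    dims = c(n_loci, config$n_cells), dimnames = list(loci, cells)
  )
  molecules <- data.frame(
    molecule = seq_len(n_total), cell = cells[cell_idx], umi = umi,
    locus = loci[mol_locus],   # NA for background molecules
    gx = mol_gx, stringsAsFactors = FALSE
  )
  list(
    records = records,
    truth = list(molecules = molecules, true_counts = true_counts,
                 pi_truth = pi_truth,
                 pools = setNames(pool_of, cells)),
    annotation = annotation,
    cells = cells
  )
}

#' Serialize simulated alignment records as SAM text
#'
#' Emits a valid SAM file with `@SQ` header lines for every chromosome
#' (annotation chromosomes plus the background contig) and one record per
#' alignment carrying `NH`, `AS`, `CB`, `UB` and optional `GX` tags.
#' Secondary alignments of a multimapped read are flagged 0x100.
#'
#' @param records alignment data.frame from [simulate_reads()].
#' @param path output `.sam` path.
#' @param annotation the `te_annotation` used for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, annotation) {
  chroms <- unique(c(annotation$loci$chrom, records$chrom))
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", chroms, 500000L)
  )
  first <- !duplicated(records$read_name)
  flag <- ifelse(first, 0L, 256L)
  mapq <- ifelse(records$nh == 1L, 255L, 3L)
  gx_tag <- ifelse(records$gx, "\tGX:Z:GENE0001", "")
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d\tAS:i:%d\tCB:Z:%s\tUB:Z:%s%s",
    records$read_name, flag, records$chrom, records$start, mapq,
    records$end - records$start + 1L, records$nh, records$score,
    records$cb, records$umi, gx_tag
  )
  writeLines(c(header, body), path)
  invisible(path)
}
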