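#' Run the full quantification pipeline from files
#'
#' Orchestrates ingest, multimapper-aware UMI deduplication, pooled EM model
#' fitting, reassignment, counting, canonical-gene correction and MTX
#' serialization. Artifacts written to `out_dir`: the corrected count matrix
#' (`matrix.mtx`, `features.tsv`, `barcodes.tsv`), the uncorrected matrix
#' under `uncorrected/`, `fit_report.tsv`, `dedup_report.tsv`,
#' `run_report.tsv`, `te_load.tsv` and a JSON `manifest.json` capturing the
#' configuration.
#'
#' @param alignments path to a SAM or BAM file with CB/UB/AS/NH (and
#'   optional GX) tags.
#' @param gtf path to the locus-level TE annotation (GTF).
#' @param whitelist path to the passing-barcode list (one per line) or a
#'   character vector of barcodes.
#' @param out_dir output directory.
#' @param labels optional path to a two-column TSV (barcode, label) or a
#'   named vector; required for `pooling = "celltype"`.
#' @param pooling `"pseudobulk"` (default), `"individual"` or `"celltype"`.
#' @param reassign_mode `"best_exclude"` (default), `"best_random"` or
#'   `"average"`.
#' @param min_overlap minimum alignment/locus overlap fraction (default
#'   0.2).
#' @param pi_prior,theta_prior Dirichlet pseudocounts for the M-step
#'   (defaults 0 and 200000).
#' @param max_iter,em_tol EM iteration cap and parameter-change tolerance
#'   (defaults 500 and 1e-7).
#' @param tie_tol posterior tie tolerance for `best_exclude` (default
#'   1e-12).
#' @param cg_totals optional named per-cell totals from a canonical-gene
#'   matrix, used for the TE-load denominator. When absent, the denominator
#'   is the corrected TE total plus the number of deduplicated GX-tagged
#'   molecules observed in the alignments (a proxy for CG counts).
#' @param seed integer seed for any stochastic reassignment strategy.
#' @return (invisibly) list with `counts` (corrected), `raw_counts`,
#'   `correction`, `fit`, `dedup_report`, `ingest_report`, `assignments`,
#'   `te_load`, `out_dir`.
#' @export
run_pipeline <- function(alignments, gtf, whitelist, out_dir,
                         labels = NULL,
                         pooling = c("pseudobulk", "individual", "celltype"),
                         reassign_mode = "best_exclude",
                         min_overlap = 0.2, pi_prior = 0,
                         theta_prior = 200000, max_iter = 500,
                         em_tol = 1e-7, tie_tol = 1e-12,
                         cg_totals = NULL, seed = 1) {
  pooling <- match.arg(pooling)
  for (p in c(alignments, gtf)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (pooling == "celltype" && is.null(labels)) {
    stop("celltype pooling requires a cell label table")
  }
  if (!is.null(labels) && is.character(labels) && length(labels) == 1L) {
    if (!file.exists(labels)) stop("input file not found: ", labels)
    lab_df <- read.delim(labels, header = FALSE, stringsAsFactors = FALSE)
    labels <- setNames(as.character(lab_df[[2L]]), as.character(lab_df[[1L]]))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  annotation <- load_te_annotation(gtf)
  index <- build_interval_index(annotation)
  records <- read_alignments(alignments)
  filt <- filter_alignments(records, whitelist)
  wm <- build_weight_matrix(filt$records, index, min_overlap = min_overlap)

  dd <- deduplicate(wm)
  wm_dd <- dd$matrix

  barcodes <- if (length(whitelist) == 1L && file.exists(whitelist)) {
    readLines(whitelist)
  } else whitelist
  barcodes <- barcodes[nzchar(barcodes)]
  pools <- assign_pools(barcodes, mode = pooling, labels = labels)

  fit <- fit_em(wm_dd, pools, pi_prior = pi_prior, theta_prior = theta_prior,
                max_iter = max_iter, tol = em_tol)
  asn <- reassign(fit$posterior, wm_dd, strategy = reassign_mode,
                  tie_tol = tie_tol)
  raw_counts <- count_umis(asn, barcodes, annotation$loci$locus_id)
  correction <- build_correction_matrix(asn, barcodes, annotation$loci$locus_id)
  counts <- apply_correction(raw_counts, correction)

  te_per_cell <- Matrix::colSums(counts)
  if (is.null(cg_totals)) {
    # proxy CG totals: deduplicated GX-tagged molecules per cell
    gx_mol <- unique(wm_dd$fragments[wm_dd$fragments$gx, c("cb", "umi")])
    cg <- table(factor(gx_mol$cb, levels = barcodes))
    totals <- te_per_cell + as.numeric(cg)
  } else {
    totals <- te_per_cell + as.numeric(cg_totals[barcodes])
  }
  names(totals) <- barcodes
  load_frac <- suppressWarnings(te_load(te_per_cell, totals))

  feats <- annotation_features(annotation)
  write_mtx(counts, out_dir, feature_table = feats)
  write_mtx(raw_counts, file.path(out_dir, "uncorrected"), feature_table = feats)
  write.table(fit_report(fit), file.path(out_dir, "fit_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(metric = names(dd$report$totals),
               value = as.integer(dd$report$totals)),
    file.path(out_dir, "dedup_report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  ingest <- c(filt$report, wm$report[-1L])
  write.table(data.frame(metric = names(ingest), value = as.integer(ingest)),
              file.path(out_dir, "run_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(barcode = names(load_frac),
               te_umis = as.numeric(te_per_cell[names(load_frac)]),
               total_umis = as.numeric(totals[names(load_frac)]),
               load_pct = 100 * as.numeric(load_frac)),
    file.path(out_dir, "te_load.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "scTElocus",
    version = as.character(utils::packageVersion("scTElocus")),
    pooling = pooling, reassign_mode = reassign_mode,
    min_overlap = min_overlap, pi_prior = pi_prior,
    theta_prior = theta_prior, max_iter = max_iter, em_tol = em_tol,
    tie_tol = tie_tol, seed = seed,
    inputs = list(alignments = alignments, gtf = gtf)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    counts = counts, raw_counts = raw_counts, correction = correction,
    fit = fit, dedup_report = dd$report, ingest_report = ingest,
    assignments = asn, te_load = load_frac, annotation = annotation,
    out_dir = out_dir
  ))
}

#' Compute and evaluate UMI count bounds from files
#'
#' @inheritParams run_pipeline
#' @param scope `"cell"`, `"sample"` or `"locus"`.
#' @param estimates optional named numeric vector of estimated counts (or a
#'   matrix, see [evaluate_estimates()]); when supplied an evaluation table
#'   and summary are written alongside the bounds.
#' @return (invisibly) list with `bounds` and, when estimates were given,
#'   `evaluation`.
#' @export
run_bounds <- function(alignments, gtf, whitelist, out_dir,
                       min_overlap = 0.2, scope = "cell", estimates = NULL) {
  for (p in c(alignments, gtf)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  annotation <- load_te_annotation(gtf)
  index <- build_interval_index(annotation)
  filt <- filter_alignments(read_alignments(alignments), whitelist)
  bounds <- compute_bounds(filt$records, index, min_overlap = min_overlap,
                           scope = scope)
  write.table(bounds, file.path(out_dir, "bounds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  out <- list(bounds = bounds)
  if (!is.null(estimates)) {
    ev <- evaluate_estimates(estimates, bounds)
    write.table(ev$table, file.path(out_dir, "evaluation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(ev$summary),
                         file.path(out_dir, "bounds_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$evaluation <- ev
  }
  invisible(out)
}

#' Generate a simulated fixture set on disk
#'
#' Writes `reads.sam`, `te_annotation.gtf`, `whitelist.txt`, `labels.tsv`,
#' the true count matrix under `truth_counts/` (MTX triple) and
#' `truth_molecules.tsv`.
#'
#' @param config a `te_sim_config` (see [sim_config()]).
#' @param out_dir output directory.
#' @return (invisibly) list of the simulation object plus file paths.
#' @export
run_simulate <- function(config, out_dir) {
  if (config$n_cells < 1) stop("n_cells must be at least 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_reads(config)
  paths <- list(
    sam = file.path(out_dir, "reads.sam"),
    gtf = file.path(out_dir, "te_annotation.gtf"),
    whitelist = file.path(out_dir, "whitelist.txt"),
    labels = file.path(out_dir, "labels.tsv"),
    truth_counts = file.path(out_dir, "truth_counts"),
    truth_molecules = file.path(out_dir, "truth_molecules.tsv")
  )
  write_sam(sim$records, paths$sam, sim$annotation)
  write_te_annotation(sim$annotation, paths$gtf)
  writeLines(sim$cells, paths$whitelist)
  write.table(
    data.frame(barcode = sim$cells, label = unname(sim$truth$pools)),
    paths$labels, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_mtx(sim$truth$true_counts, paths$truth_counts)
  write.table(sim$truth$molecules, paths$truth_molecules,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sim, paths = list(paths)))
}
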