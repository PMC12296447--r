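#' Read barcoded alignments from SAM or BAM
#'
#' Reads every alignment record (including secondary alignments) together with
#' the auxiliary tags used downstream: `CB` (error-corrected cell barcode),
#' `UB` (error-corrected UMI), `AS` (alignment score), `NH` (number of
#' reported hits) and `GX` (gene assigned by the canonical-gene quantifier,
#' optional). SAM input is converted to BAM on the fly with
#' [Rsamtools::asBam()].
#'
#' @param path SAM or BAM file (extension decides).
#' @return data.frame with one row per alignment record: `read_name`,
#'   `chrom`, `start`, `end` (1-based closed reference span from the CIGAR),
#'   `score`, `cb`, `umi`, `gx` (logical), `nh`. Unmapped records are
#'   excluded.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- path
  }
  param <- Rsamtools::ScanBamParam(
    tag = c("CB", "UB", "AS", "NH", "GX"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = TRUE)
  tg <- S4Vectors::mcols(ga)
  data.frame(
    read_name = names(ga),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    score = if (is.null(tg$AS)) rep(0L, length(ga)) else as.integer(tg$AS),
    cb = if (is.null(tg$CB)) rep(NA_character_, length(ga)) else as.character(tg$CB),
    umi = if (is.null(tg$UB)) rep(NA_character_, length(ga)) else as.character(tg$UB),
    gx = if (is.null(tg$GX)) rep(FALSE, length(ga)) else !is.na(tg$GX),
    nh = if (is.null(tg$NH)) rep(1L, length(ga)) else as.integer(tg$NH),
    stringsAsFactors = FALSE
  )
}

#' Filter alignments to passing cells and group by read name
#'
#' Keeps only records whose cell barcode belongs to the whitelist of passing
#' cells; records lacking a `CB` or `UB` tag are dropped and tallied. The
#' result is sorted by read name so that all alignments of one fragment are
#' contiguous, mirroring a name-sorted BAM.
#'
#' @param records data.frame from [read_alignments()].
#' @param barcode_whitelist character vector of passing cell barcodes, or the
#'   path of a one-barcode-per-line text file.
#' @return list with `records` (filtered, name-sorted data.frame) and
#'   `report` (named integer tallies: `records_read`, `dropped_no_cb`,
#'   `dropped_no_ub`, `dropped_not_whitelisted`, `records_retained`).
#' @export
filter_alignments <- function(records, barcode_whitelist) {
  if (length(barcode_whitelist) == 1L && file.exists(barcode_whitelist)) {
    barcode_whitelist <- readLines(barcode_whitelist)
  }
  barcode_whitelist <- barcode_whitelist[nzchar(barcode_whitelist)]
  if (length(barcode_whitelist) == 0L) stop("empty barcode whitelist")

  no_cb <- is.na(records$cb) | !nzchar(records$cb)
  no_ub <- !no_cb & (is.na(records$umi) | !nzchar(records$umi))
  off_list <- !no_cb & !no_ub & !(records$cb %in% barcode_whitelist)
  keep <- !(no_cb | no_ub | off_list)
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$read_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  list(
    records = out,
    report = c(
      records_read = nrow(records),
      dropped_no_cb = sum(no_cb),
      dropped_no_ub = sum(no_ub),
      dropped_not_whitelisted = sum(off_list),
      records_retained = nrow(out)
    )
  )
}

#' Fraction of an alignment covered by a locus
#'
#' Overlap is measured against the union of the locus's (merged) intervals
#' and reported as a fraction of the alignment's reference span. Coordinates
#' are 1-based closed.
#'
#' @param chrom,start,end alignment reference span.
#' @param annotation a `te_annotation`.
#' @param locus_id locus to compare against.
#' @return numeric fraction in \[0, 1\].
#' @export
overlap_fraction <- function(chrom, start, end, annotation, locus_id) {
  gr <- annotation$ranges
  sel <- gr$locus_id == locus_id &
    as.character(GenomicRanges::seqnames(gr)) == chrom
  if (!any(sel)) return(0)
  ir <- IRanges::ranges(gr[sel])
  ov <- IRanges::intersect(IRanges::IRanges(start, end), ir)
  sum(IRanges::width(ov)) / (end - start + 1)
}

#' Build the initial fragment-by-feature weight matrix
#'
#' Alignments of each fragment (read name) are assigned to every TE locus
#' they overlap by at least `min_overlap` of their reference span; alignments
#' meeting no locus load on the no-feature column (mixture component j = 0).
#' Per-candidate weights are a softmax numerator over alignment scores,
#' `q = exp((AS - AS_best) / score_scale)`, so the fragment's best alignment
#' always has weight 1. When several alignments of one fragment hit the same
#' locus only the best-scoring one is kept. Fragments whose only candidate is
#' the no-feature column carry no TE information and are excluded from the
#' matrix (but tallied).
#'
#' @param records name-sorted, whitelist-filtered alignment data.frame (from
#'   [filter_alignments()]).
#' @param index a `te_interval_index`.
#' @param min_overlap minimum overlap fraction (default 0.2).
#' @param score_scale softmax temperature in alignment-score units.
#' @return a `te_weight_matrix`: list with `weights` (sparse `dgCMatrix`,
#'   fragments x (no-feature + K loci)), `fragments` (data.frame `read_name`,
#'   `cb`, `umi`, `y` ambiguity indicator, `gx`, `best_score`), `features`
#'   (locus ids, matrix column order minus the leading no-feature column) and
#'   `report` tallies.
#' @export
build_weight_matrix <- function(records, index, min_overlap = 0.2,
                                score_scale = 1.0) {
  if (nrow(records) == 0L) stop("no alignment records supplied")
  ann_gr <- index$ranges

  aln <- data.table::as.data.table(records)
  aln[, aln_id := .I]
  gr <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(aln$start, aln$end))
  hits <- GenomicRanges::findOverlaps(gr, ann_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ovw <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[qh], IRanges::ranges(ann_gr)[sh]
  ))
  hit_dt <- data.table::data.table(
    aln_id = qh, locus = ann_gr$locus_id[sh], ov = ovw
  )
  # union of a locus's merged (disjoint) intervals: overlap bases add up
  hit_dt <- hit_dt[, .(ov = sum(ov)), by = c("aln_id", "locus")]
  hit_dt[, frac := ov / (aln$end[aln_id] - aln$start[aln_id] + 1)]
  hit_dt <- hit_dt[frac >= min_overlap & frac > 0]

  cand <- merge(
    aln[, .(aln_id, read_name, cb, umi, score, gx)],
    hit_dt[, .(aln_id, locus)],
    by = "aln_id", all.x = TRUE
  )
  cand[is.na(locus), locus := NO_FEATURE]
  # one candidate per (fragment, feature): keep the best score
  cand <- cand[, .(score = max(score), gx = any(gx)),
               by = c("read_name", "cb", "umi", "locus")]

  frag <- cand[, .(
    best_score = max(score),
    n_locus = sum(locus != NO_FEATURE),
    gx = any(gx)
  ), by = c("read_name", "cb", "umi")]
  data.table::setkey(frag, read_name)

  nofeat_only <- frag[n_locus == 0L]
  frag <- frag[n_locus > 0L]
  frag[, row := .I]
  frag[, y := as.integer(n_locus >= 2L)]

  cand <- cand[read_name %in% frag$read_name]
  cand[, row := frag[data.table::data.table(read_name = cand$read_name),
                     on = "read_name", row]]
  cand[, q := exp((score - frag$best_score[row]) / score_scale)]

  # full annotation feature set as columns (not just observed loci), so that
  # matrices line up with the annotation across samples
  features <- sort(unique(index$annotation$loci$locus_id))
  col_of <- setNames(seq_along(features) + 1L, features)
  cand[, col := ifelse(locus == NO_FEATURE, 1L, col_of[locus])]

  w <- Matrix::sparseMatrix(
    i = cand$row, j = cand$col, x = cand$q,
    dims = c(nrow(frag), length(features) + 1L),
    dimnames = list(frag$read_name, c(NO_FEATURE, features))
  )
  wm <- list(
    weights = w,
    fragments = data.frame(
      read_name = frag$read_name, cb = frag$cb, umi = frag$umi,
      y = frag$y, gx = frag$gx, best_score = frag$best_score,
      stringsAsFactors = FALSE
    ),
    features = features,
    report = c(
      records_read = nrow(records),
      fragments_total = nrow(frag) + nrow(nofeat_only),
      fragments_te = nrow(frag),
      fragments_no_feature_only = nrow(nofeat_only)
    )
  )
  class(wm) <- "te_weight_matrix"
  validate_weight_matrix(wm)
  wm
}

#' Construct a `te_weight_matrix` from parts
#'
#' Mainly for tests and programmatic use; validates the container invariants
#' (every row has an entry, row maxima equal 1, the ambiguity flag matches
#' the number of locus candidates).
#'
#' @param weights sparse or dense matrix, columns `c(no-feature, loci...)`.
#'   Column names are required; the first column must be the no-feature
#'   column.
#' @param fragments data.frame with `read_name`, `cb`, `umi` and optionally
#'   `gx`, `best_score` (`y` is derived).
#' @return a `te_weight_matrix`.
#' @export
weight_matrix <- function(weights, fragments) {
  w <- methods::as(Matrix::Matrix(weights, sparse = TRUE) * 1, "CsparseMatrix")
  if (is.null(colnames(w))) stop("weights must have column names")
  if (colnames(w)[1L] != NO_FEATURE) {
    w <- cbind(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                    dims = c(nrow(w), 1L),
                                    dimnames = list(NULL, NO_FEATURE)), w)
  }
  n_locus <- Matrix::rowSums(w[, -1L, drop = FALSE] != 0)
  fragments$y <- as.integer(n_locus >= 2L)
  if (is.null(fragments$gx)) fragments$gx <- FALSE
  if (is.null(fragments$best_score)) fragments$best_score <- 0
  rownames(w) <- fragments$read_name
  wm <- list(
    weights = w, fragments = fragments, features = colnames(w)[-1L],
    report = c(records_read = NA_integer_, fragments_total = nrow(fragments),
               fragments_te = nrow(fragments), fragments_no_feature_only = 0L)
  )
  class(wm) <- "te_weight_matrix"
  validate_weight_matrix(wm)
  wm
}

validate_weight_matrix <- function(wm) {
  w <- wm$weights
  stopifnot(nrow(w) == nrow(wm$fragments))
  if (nrow(w) == 0L) return(invisible(wm))
  nz <- Matrix::rowSums(w != 0)
  if (any(nz == 0L)) stop("weight matrix has empty rows")
  rmax <- rowmax_sparse(w)
  if (any(abs(rmax - 1) > 1e-9)) stop("row maxima must equal 1")
  n_locus <- Matrix::rowSums(w[, -1L, drop = FALSE] != 0)
  if (!all(wm$fragments$y == as.integer(n_locus >= 2L))) {
    stop("ambiguity flags inconsistent with candidate sets")
  }
  invisible(wm)
}

rowmax_sparse <- function(w) {
  s <- Matrix::summary(w)
  out <- rep(-Inf, nrow(w))
  agg <- tapply(s$x, s$i, max)
  out[as.integer(names(agg))] <- agg
  out
}

#' @exportS3Method base::print
print.te_weight_matrix <- function(x, ...) {
  cat("te_weight_matrix: ", nrow(x$weights), " fragments x ",
      length(x$features), " loci (+ no-feature); ",
      sum(x$fragments$y), " ambiguous\n", sep = "")
  invisible(x)
}

# subset rows of a weight matrix, preserving class and reports
subset_weight_matrix <- function(wm, rows) {
  wm$weights <- wm$weights[rows, , drop = FALSE]
  wm$fragments <- wm$fragments[rows, , drop = FALSE]
  rownames(wm$fragments) <- NULL
  wm
}
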