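#' Reassign fragments from posterior membership weights
#'
#' The normative `best_exclude` strategy keeps, per fragment, the single
#' feature with the highest posterior probability; when two or more
#' candidates tie for the maximum (within `tie_tol`), the fragment is
#' excluded. `best_random` breaks such ties uniformly at random, and
#' `average` assigns each candidate its fractional posterior weight.
#'
#' @param posterior sparse posterior matrix (rows normalized), typically
#'   `fit$posterior`; column names must include the no-feature column first.
#' @param wm the `te_weight_matrix` the posterior was computed from (carries
#'   barcodes, UMIs and GX flags).
#' @param strategy `"best_exclude"` (default), `"best_random"` or
#'   `"average"`.
#' @param tie_tol absolute tolerance within which posteriors count as tied
#'   (default 1e-12); floating-point equality alone is unreliable.
#' @return a `te_assignments` object: data.frame with `row` (fragment row
#'   index), `read_name`, `cb`, `feature` (locus id, the no-feature label,
#'   or `NA` for excluded fragments), `posterior`, `weight` (1 for best-hit
#'   strategies; the fractional posterior for `average`, one row per
#'   candidate) and `gx`.
#' @export
reassign <- function(posterior, wm, strategy = "best_exclude",
                     tie_tol = 1e-12) {
  supported <- c("best_exclude", "best_random", "average")
  if (!strategy %in% supported) {
    stop("unknown reassignment strategy '", strategy, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  s <- Matrix::summary(posterior)
  dt <- data.table::data.table(i = s$i, j = s$j, x = s$x)
  frag <- wm$fragments
  feat_names <- colnames(posterior)

  if (strategy == "average") {
    out <- data.frame(
      row = dt$i, read_name = frag$read_name[dt$i], cb = frag$cb[dt$i],
      feature = feat_names[dt$j], posterior = dt$x, weight = dt$x,
      gx = frag$gx[dt$i], stringsAsFactors = FALSE
    )
  } else {
    mx <- dt[, .(best = max(x), n_tied = sum(x >= max(x) - tie_tol),
                 jbest = j[which.max(x)]), by = "i"]
    if (strategy == "best_random" && any(mx$n_tied > 1L)) {
      tied_rows <- mx$i[mx$n_tied > 1L]
      pick <- dt[i %in% tied_rows][
        , .(jbest = {
          cand <- j[x >= max(x) - tie_tol]
          cand[sample.int(length(cand), 1L)]
        }), by = "i"]
      mx[match(pick$i, mx$i), jbest := pick$jbest]
      mx[, n_tied := 1L]
    }
    excluded <- mx$n_tied > 1L
    out <- data.frame(
      row = mx$i, read_name = frag$read_name[mx$i], cb = frag$cb[mx$i],
      feature = ifelse(excluded, NA_character_, feat_names[mx$jbest]),
      posterior = mx$best,
      weight = ifelse(excluded, 0, 1),
      gx = frag$gx[mx$i], stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$row), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("te_assignments", "data.frame")
  attr(out, "strategy") <- strategy
  out
}

#' Count UMIs per locus and cell
#'
#' Tallies assigned fragments into a features x cells sparse count matrix.
#' Excluded fragments and fragments assigned to the no-feature column
#' contribute nothing. Input fragments are assumed deduplicated, so each
#' counted fragment is one molecule (UMI).
#'
#' @param assignments a `te_assignments`.
#' @param barcodes column order (all expected cell barcodes).
#' @param feature_order row order (locus ids).
#' @return sparse `dgCMatrix` features x cells with dimnames.
#' @export
count_umis <- function(assignments, barcodes, feature_order) {
  keep <- !is.na(assignments$feature) &
    assignments$feature %in% feature_order & assignments$weight > 0
  a <- assignments[keep, , drop = FALSE]
  Matrix::sparseMatrix(
    i = match(a$feature, feature_order),
    j = match(a$cb, barcodes),
    x = a$weight,
    dims = c(length(feature_order), length(barcodes)),
    dimnames = list(feature_order, barcodes)
  )
}

#' Correction matrix for canonical-gene double counting
#'
#' When a UMI was also counted by the canonical-gene (CG) quantifier --
#' detected via the `GX` tag on its alignment records -- adding the TE
#' matrix to the CG matrix would count the molecule twice. This tallies,
#' per (feature, cell), the assigned fragments whose GX flag is set.
#'
#' @inheritParams count_umis
#' @return sparse `dgCMatrix`, same shape as [count_umis()] output.
#' @export
build_correction_matrix <- function(assignments, barcodes, feature_order) {
  a <- assignments
  a$weight <- a$weight * as.numeric(a$gx)
  count_umis(a, barcodes, feature_order)
}

#' Subtract the CG correction from a TE count matrix
#'
#' Entrywise difference, floored at zero (with a warning when flooring
#' triggers, which indicates inconsistent inputs).
#'
#' @param te_counts,correction sparse matrices of identical shape and
#'   dimnames.
#' @return corrected sparse count matrix.
#' @export
apply_correction <- function(te_counts, correction) {
  if (!identical(dim(te_counts), dim(correction)) ||
      !identical(dimnames(te_counts), dimnames(correction))) {
    stop("count and correction matrices must have identical shape and names")
  }
  out <- te_counts - correction
  if (any(out@x < 0)) {
    warning("correction exceeded counts for ", sum(out@x < 0),
            " entries; flooring at 0")
    out@x[out@x < 0] <- 0
  }
  Matrix::drop0(out)
}

#' Aggregate locus counts to subfamily level
#'
#' Sums member-locus rows per subfamily; per-cell totals are preserved
#' exactly.
#'
#' @param counts features x cells sparse matrix (rownames are locus ids).
#' @param annotation a `te_annotation` supplying the locus-to-subfamily map.
#' @return subfamilies x cells sparse matrix.
#' @export
aggregate_by_subfamily <- function(counts, annotation) {
  sub <- subfamily_of(annotation)
  missing <- setdiff(rownames(counts), names(sub))
  if (length(missing)) {
    stop("loci missing from the subfamily map: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  fam <- sub[rownames(counts)]
  fams <- sort(unique(unname(fam)))
  agg <- Matrix::sparseMatrix(
    i = match(unname(fam), fams), j = seq_along(fam), x = 1,
    dims = c(length(fams), nrow(counts)), dimnames = list(fams, rownames(counts))
  )
  agg %*% counts
}

#' Per-cell TE load
#'
#' Fraction of a cell's feature-assigned UMIs that derive from TE loci:
#' `te / total`. Cells with zero total are omitted with a warning.
#'
#' @param te_counts_per_cell named numeric vector of TE UMIs per cell (or a
#'   features x cells matrix, which is column-summed).
#' @param total_counts_per_cell named numeric vector of total feature UMIs
#'   per cell (TE + canonical genes).
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
te_load <- function(te_counts_per_cell, total_counts_per_cell) {
  if (is.matrix(te_counts_per_cell) || methods::is(te_counts_per_cell, "Matrix")) {
    te_counts_per_cell <- Matrix::colSums(te_counts_per_cell)
  }
  cells <- names(total_counts_per_cell)
  te <- te_counts_per_cell[cells]
  te[is.na(te)] <- 0
  zero <- total_counts_per_cell == 0
  if (any(zero)) {
    warning("TE load undefined for ", sum(zero), " cell(s) with zero total; omitted")
  }
  setNames(as.numeric(te[!zero] / total_counts_per_cell[!zero]), cells[!zero])
}

#' Write a count matrix in 10x-style MTX layout
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format, 1-based indices;
#' field `integer` when all entries are whole numbers, else `real`),
#' `features.tsv` and `barcodes.tsv` into `out_dir`. The round-trip through
#' [read_mtx()] is lossless.
#'
#' @param counts features x cells sparse matrix with dimnames.
#' @param out_dir output directory (created if needed).
#' @param feature_table optional data.frame of feature annotations (first
#'   column must match `rownames(counts)`); defaults to the ids alone.
#' @return `out_dir`, invisibly.
#' @export
write_mtx <- function(counts, out_dir, feature_table = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  counts <- methods::as(counts, "CsparseMatrix")
  s <- Matrix::summary(counts)
  o <- order(s$j, s$i)
  s <- s[o, , drop = FALSE]
  integral <- nrow(s) == 0L || all(s$x == round(s$x))
  field <- if (integral) "integer" else "real"
  vals <- if (integral) format(as.integer(round(s$x))) else
    format(s$x, digits = 15, scientific = FALSE, trim = TRUE)
  con <- file.path(out_dir, "matrix.mtx")
  writeLines(c(
    sprintf("%%%%MatrixMarket matrix coordinate %s general", field),
    sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(s)),
    if (nrow(s)) sprintf("%d %d %s", s$i, s$j, trimws(vals))
  ), con)
  if (is.null(feature_table)) {
    feature_table <- data.frame(id = rownames(counts), name = rownames(counts),
                                type = "TE", stringsAsFactors = FALSE)
  }
  write.table(feature_table, file.path(out_dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(out_dir, "barcodes.tsv"))
  invisible(out_dir)
}

#' Read a 10x-style MTX triple back into a sparse matrix
#'
#' @param dir directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return sparse `dgCMatrix` with dimnames.
#' @export
read_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  m <- m * 1
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(feats[[1L]], bcs)
  m
}
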