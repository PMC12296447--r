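#' Feasibility bounds on true UMI counts
#'
#' Because ground truth is unknowable for empirical data, true UMI counts can
#' still be bracketed from the alignments alone. The upper bound is the
#' number of distinct (cell barcode, UMI) pairs having at least one alignment
#' that overlaps a TE locus at the configured criterion; the lower bound
#' applies the same criterion but only to fragments that are uniquely aligned
#' (a single reported alignment, NH = 1). Any quantifier run on the same
#' alignments should fall inside `[lower, upper]`.
#'
#' At `locus` scope a multimapped UMI is attributed to every locus it could
#' overlap (upper) and to none (lower), generalizing the sample-level
#' definition. Distinctness is always keyed on (CB, UMI): UMIs recur across
#' cells by design.
#'
#' @param records whitelist-filtered alignment data.frame (from
#'   [filter_alignments()]).
#' @param index a `te_interval_index`.
#' @param min_overlap overlap fraction criterion, matching the ingest
#'   setting (default 0.2).
#' @param scope `"cell"`, `"sample"` or `"locus"`.
#' @return a `te_bounds` data.frame with columns `key`, `lower`, `upper`
#'   (`key` is the barcode, `"sample"`, or the locus id).
#' @export
compute_bounds <- function(records, index, min_overlap = 0.2,
                           scope = c("cell", "sample", "locus")) {
  scope <- match.arg(scope)
  aln <- data.table::as.data.table(records)
  if (nrow(aln) == 0L) {
    out <- data.frame(key = character(0), lower = integer(0), upper = integer(0))
    class(out) <- c("te_bounds", "data.frame")
    attr(out, "scope") <- scope
    return(out)
  }
  aln[, aln_id := .I]
  gr <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(aln$start, aln$end))
  hits <- GenomicRanges::findOverlaps(gr, index$ranges, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ovw <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr)[qh], IRanges::ranges(index$ranges)[sh]))
  hd <- data.table::data.table(aln_id = qh, locus = index$ranges$locus_id[sh],
                               ov = ovw)
  hd <- hd[, .(ov = sum(ov)), by = c("aln_id", "locus")]
  hd[, frac := ov / (aln$end[aln_id] - aln$start[aln_id] + 1)]
  hd <- hd[frac >= min_overlap & frac > 0]

  # a fragment is uniquely aligned when it has exactly one reported alignment
  n_aln <- aln[, .(n = .N), by = "read_name"]
  aln[, unique_aln := n_aln[data.table::data.table(read_name = aln$read_name),
                            on = "read_name", n] == 1L]

  te <- merge(hd, aln[, .(aln_id, read_name, cb, umi, unique_aln)],
              by = "aln_id")
  if (scope == "locus") {
    upper_dt <- te[, .(upper = data.table::uniqueN(paste(cb, umi))), by = "locus"]
    lower_dt <- te[unique_aln == TRUE,
                   .(lower = data.table::uniqueN(paste(cb, umi))), by = "locus"]
    out <- merge(upper_dt, lower_dt, by = "locus", all.x = TRUE)
    out[is.na(lower), lower := 0L]
    res <- data.frame(key = out$locus, lower = out$lower, upper = out$upper,
                      stringsAsFactors = FALSE)
  } else {
    grp <- if (scope == "cell") "cb" else NULL
    if (scope == "cell") {
      upper_dt <- te[, .(upper = data.table::uniqueN(paste(cb, umi))), by = "cb"]
      lower_dt <- te[unique_aln == TRUE,
                     .(lower = data.table::uniqueN(paste(cb, umi))), by = "cb"]
      out <- merge(upper_dt, lower_dt, by = "cb", all.x = TRUE)
      out[is.na(lower), lower := 0L]
      res <- data.frame(key = out$cb, lower = out$lower, upper = out$upper,
                        stringsAsFactors = FALSE)
    } else {
      res <- data.frame(
        key = "sample",
        lower = te[unique_aln == TRUE, data.table::uniqueN(paste(cb, umi))],
        upper = te[, data.table::uniqueN(paste(cb, umi))],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- res[order(res$key), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("te_bounds", "data.frame")
  attr(res, "scope") <- scope
  res
}

#' Classify estimates against UMI count bounds
#'
#' @param estimates named numeric vector of estimated UMI counts (names
#'   matching the bounds keys), or a features x cells matrix when the bounds
#'   are per cell (column sums are used) or per locus (row sums).
#' @param bounds a `te_bounds` from [compute_bounds()].
#' @return list with `table` (data.frame `key`, `estimate`, `lower`,
#'   `upper`, `label`) and `summary` (named fractions `below`, `within`,
#'   `above`). Keys present in the estimates but absent from the bounds are
#'   given (0, 0) bounds with a warning.
#' @export
evaluate_estimates <- function(estimates, bounds) {
  scope <- attr(bounds, "scope")
  if (methods::is(estimates, "Matrix") || is.matrix(estimates)) {
    estimates <- if (identical(scope, "locus")) {
      Matrix::rowSums(estimates)
    } else {
      Matrix::colSums(estimates)
    }
  }
  if (is.null(names(estimates))) stop("estimates must be named")
  b <- setNames(Map(c, bounds$lower, bounds$upper), bounds$key)
  missing <- setdiff(names(estimates), bounds$key)
  if (length(missing)) {
    warning(length(missing), " key(s) absent from bounds; assuming (0, 0)")
  }
  lower <- vapply(names(estimates),
                  function(k) if (k %in% names(b)) b[[k]][1L] else 0, numeric(1))
  upper <- vapply(names(estimates),
                  function(k) if (k %in% names(b)) b[[k]][2L] else 0, numeric(1))
  label <- ifelse(estimates < lower, "below",
                  ifelse(estimates > upper, "above", "within"))
  tab <- data.frame(key = names(estimates), estimate = as.numeric(estimates),
                    lower = lower, upper = upper, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  n <- nrow(tab)
  summ <- c(below = sum(label == "below") / n,
            within = sum(label == "within") / n,
            above = sum(label == "above") / n)
  if (n == 0L) summ <- c(below = 0, within = 0, above = 0)
  list(table = tab, summary = summ)
}
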