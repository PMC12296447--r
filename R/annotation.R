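#' Load a locus-level TE annotation from GTF
#'
#' Parses a GTF file in which every row belongs to a TE locus identified by a
#' grouping attribute (default `"locus"`, falling back to `"gene_id"` when the
#' primary attribute is absent from the first data row). Rows sharing the same
#' attribute value are merged into a single locus whose intervals are sorted
#' and overlap-merged, so multi-exon TE gene models collapse to one feature.
#'
#' Coordinates are 1-based closed as in GTF; intervals are stored as a
#' `GRanges` and all overlap arithmetic is done with `IRanges`, which uses the
#' same convention, so no off-by-one conversion is required.
#'
#' @param gtf_file path to a GTF file (tab-separated, 9 columns).
#' @param feature_attribute attribute key used to group rows into loci.
#' @param subfamily_attribute attribute key carrying the subfamily (model)
#'   name; loci missing it fall back to their own locus id.
#' @return A `te_annotation` object: list with `loci` (data.frame of
#'   `locus_id`, `subfamily`, `chrom`, `strand`), `ranges` (`GRanges`, one row
#'   per merged interval, metadata column `locus_id`), and `K` (locus count).
#' @export
load_te_annotation <- function(gtf_file, feature_attribute = "locus",
                               subfamily_attribute = "subfamily") {
  lines <- readLines(gtf_file)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no features parsed from ", gtf_file)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GTF row at line ", lineno[which(nf < 9L)[1L]],
         ": expected 9 tab-separated columns, found ", nf[which(nf < 9L)[1L]])
  }
  chrom  <- vapply(fields, `[[`, "", 1L)
  start  <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end    <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs  <- vapply(fields, `[[`, "", 9L)
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad)) {
    stop("malformed GTF row at line ", lineno[bad[1L]], ": bad coordinates")
  }
  strand[!strand %in% c("+", "-")] <- "."

  locus_id <- gtf_attribute(attrs, feature_attribute)
  if (all(is.na(locus_id)) && feature_attribute != "gene_id") {
    locus_id <- gtf_attribute(attrs, "gene_id")
  }
  if (anyNA(locus_id)) {
    stop("malformed GTF row at line ", lineno[which(is.na(locus_id))[1L]],
         ": missing attribute '", feature_attribute, "' (and 'gene_id')")
  }
  subfamily <- gtf_attribute(attrs, subfamily_attribute)
  subfamily[is.na(subfamily)] <- locus_id[is.na(subfamily)]

  # a locus must live on a single chromosome
  by_locus <- split(seq_along(locus_id), locus_id)
  multi_chrom <- vapply(by_locus, function(i) length(unique(chrom[i])) > 1L,
                        logical(1L))
  if (any(multi_chrom)) {
    stop("locus '", names(by_locus)[multi_chrom][1L],
         "' appears on multiple chromosomes")
  }
  sub_conflict <- vapply(by_locus, function(i) length(unique(subfamily[i])) > 1L,
                         logical(1L))
  if (any(sub_conflict)) {
    stop("locus '", names(by_locus)[sub_conflict][1L],
         "' has conflicting subfamily assignments")
  }

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  gr$locus_id <- locus_id
  # merge intervals within each locus; reduce() also sorts them
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, gr$locus_id))
  merged <- unlist(grl, use.names = FALSE)
  merged$locus_id <- rep(names(grl), lengths(grl))

  ids <- names(by_locus)
  loci <- data.frame(
    locus_id  = ids,
    subfamily = vapply(by_locus, function(i) subfamily[i[1L]], ""),
    chrom     = vapply(by_locus, function(i) chrom[i[1L]], ""),
    strand    = vapply(by_locus, function(i) {
      s <- unique(strand[i]); if (length(s) == 1L) s else "."
    }, ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
  new_te_annotation(loci, merged)
}

new_te_annotation <- function(loci, ranges) {
  stopifnot(is.data.frame(loci), !anyDuplicated(loci$locus_id))
  ann <- list(loci = loci, ranges = ranges, K = nrow(loci))
  class(ann) <- "te_annotation"
  ann
}

gtf_attribute <- function(attrs, key) {
  pat <- paste0('(^|; ?)', key, ' +"([^"]*)"')
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
}

#' @exportS3Method base::print
print.te_annotation <- function(x, ...) {
  cat("te_annotation: ", x$K, " loci, ",
      length(unique(x$loci$subfamily)), " subfamilies, ",
      length(x$ranges), " intervals\n", sep = "")
  invisible(x)
}

#' Subfamily membership of an annotation
#'
#' @param annotation a `te_annotation`.
#' @param subfamily subfamily name.
#' @return character vector of locus ids in the subfamily (possibly empty).
#' @export
subfamily_members <- function(annotation, subfamily) {
  annotation$loci$locus_id[annotation$loci$subfamily == subfamily]
}

#' Mapping from locus id to subfamily
#' @param annotation a `te_annotation`.
#' @return named character vector, names are locus ids.
#' @export
subfamily_of <- function(annotation) {
  setNames(annotation$loci$subfamily, annotation$loci$locus_id)
}

#' Build a genomic interval index over TE loci
#'
#' Thin wrapper around the annotation's `GRanges` enabling overlap queries.
#' Strand is ignored: droplet protocols are quantified unstranded here.
#' Overlapping loci are tolerated; queries report every hit.
#'
#' @param annotation a `te_annotation`.
#' @return a `te_interval_index`.
#' @export
build_interval_index <- function(annotation) {
  idx <- list(ranges = annotation$ranges, annotation = annotation)
  class(idx) <- "te_interval_index"
  idx
}

#' Query an interval index
#'
#' @param index a `te_interval_index`.
#' @param chrom chromosome name.
#' @param start,end 1-based closed query coordinates.
#' @return character vector of locus ids intersecting the query (unique,
#'   sorted); empty when the chromosome is absent from the annotation.
#' @export
query_index <- function(index, chrom, start, end) {
  if (!chrom %in% GenomeInfoDb::seqlevels(index$ranges)) {
    return(character(0))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, index$ranges, ignore.strand = TRUE)
  sort(unique(index$ranges$locus_id[S4Vectors::subjectHits(hits)]))
}

#' Write a TE annotation back to GTF
#'
#' One `exon` row per merged interval; attributes carry the locus id (key
#' `locus`), `gene_id` (same value, for generic consumers) and `subfamily`.
#' Reloading the file reproduces the annotation.
#'
#' @param annotation a `te_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_te_annotation <- function(annotation, path) {
  gr <- annotation$ranges
  sub <- subfamily_of(annotation)
  loci <- annotation$loci
  str <- setNames(loci$strand, loci$locus_id)
  lines <- sprintf(
    "%s\tscTElocus\texon\t%d\t%d\t.\t%s\t.\tlocus \"%s\"; gene_id \"%s\"; subfamily \"%s\";",
    as.character(GenomicRanges::seqnames(gr)),
    GenomicRanges::start(gr), GenomicRanges::end(gr),
    str[gr$locus_id], gr$locus_id, gr$locus_id, sub[gr$locus_id]
  )
  writeLines(lines, path)
  invisible(path)
}

#' Feature table of an annotation
#'
#' @param annotation a `te_annotation`.
#' @return data.frame with `locus_id`, `subfamily`, `chrom`, `span`
#'   (`start-end` of the locus footprint), used for MTX feature files.
#' @export
annotation_features <- function(annotation) {
  gr <- annotation$ranges
  dt <- data.table::data.table(
    locus_id = gr$locus_id,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  span <- dt[, .(start = min(start), end = max(end)), by = "locus_id"]
  m <- merge(
    data.table::as.data.table(annotation$loci), span,
    by = "locus_id", sort = FALSE
  )
  data.frame(
    locus_id = m$locus_id, subfamily = m$subfamily, chrom = m$chrom,
    span = sprintf("%s:%d-%d", m$chrom, m$start, m$end),
    stringsAsFactors = FALSE
  )
}
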