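#' Group fragments by (cell barcode, UMI)
#'
#' Fragments sharing an error-corrected barcode and UMI are candidate PCR
#' duplicates of one captured molecule. Singleton groups are allowed.
#'
#' @param wm a `te_weight_matrix`.
#' @return list of integer vectors of row indices, named `"<cb>|<umi>"`.
#' @export
group_by_barcode_umi <- function(wm) {
  if (nrow(wm$fragments) == 0L) return(list())
  key <- paste(wm$fragments$cb, wm$fragments$umi, sep = "|")
  split(seq_len(nrow(wm$fragments)), key)
}

#' Build the duplicate graph for one UMI group
#'
#' Nodes are fragments; an undirected edge joins two fragments when their
#' candidate locus sets intersect (the no-feature column never creates
#' edges). Edge weight is the number of shared loci. Fragments with no
#' mapping location in common can still fall in one connected component
#' through a third fragment that shares a locus with each.
#'
#' @param rows integer row indices of the group's fragments.
#' @param wm a `te_weight_matrix`.
#' @return an `igraph` undirected graph whose vertex names are the row
#'   indices (as characters).
#' @export
build_umi_graph <- function(rows, wm) {
  sub <- wm$weights[rows, -1L, drop = FALSE]   # drop no-feature column
  # shared-locus counts between fragments: pattern product
  pat <- sub != 0
  shared <- Matrix::tcrossprod(pat * 1)
  adj <- as.matrix(shared)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- as.character(rows)
  g
}

#' Connected components and representative fragments
#'
#' Each connected component of the duplicate graph is taken to be one
#' molecule; a group whose graph has several components is retained as
#' several molecules (the same UMI labelled distinct molecules). The "most
#' informative" fragment represents each component: highest best-alignment
#' score, then fewest candidate loci (least ambiguous), then smallest read
#' name — a deterministic tie-break.
#'
#' @param graph graph from [build_umi_graph()].
#' @param wm a `te_weight_matrix`.
#' @return data.frame with one row per component: `representative` (row
#'   index), `size` (fragments in the component), `members` (list column of
#'   row indices).
#' @export
components_and_representatives <- function(graph, wm) {
  comp <- igraph::components(graph)
  rows <- as.integer(igraph::V(graph)$name)
  member_split <- split(rows, comp$membership)
  n_cand <- Matrix::rowSums(wm$weights[, -1L, drop = FALSE] != 0)
  reps <- vapply(member_split, function(m) {
    o <- order(-wm$fragments$best_score[m], n_cand[m],
               wm$fragments$read_name[m], method = "radix")
    m[o[1L]]
  }, integer(1L))
  data.frame(
    representative = unname(reps),
    size = lengths(member_split),
    members = I(unname(member_split)),
    stringsAsFactors = FALSE
  )
}

#' Multimapper-aware UMI deduplication
#'
#' Removes PCR duplicates from a weight matrix: within each (barcode, UMI)
#' group, fragments whose candidate locus sets intersect -- directly or
#' transitively -- are collapsed to the most informative representative.
#' Implemented as a single union-find pass over (group, locus) buckets,
#' equivalent to connected components of the per-group duplicate graphs.
#'
#' @param wm a `te_weight_matrix`.
#' @return list with `matrix` (deduplicated `te_weight_matrix`, rows in the
#'   original order) and `report`: totals (`fragments_in`, `groups`,
#'   `components`, `duplicates_removed`, `fragments_out`) plus `histogram`,
#'   a data.frame of group size vs component count.
#' @export
deduplicate <- function(wm) {
  n <- nrow(wm$fragments)
  if (n == 0L) {
    return(list(matrix = wm, report = list(
      totals = c(fragments_in = 0L, groups = 0L, components = 0L,
                 duplicates_removed = 0L, fragments_out = 0L),
      histogram = data.frame(group_size = integer(0), components = integer(0),
                             n_groups = integer(0)))))
  }
  key <- paste(wm$fragments$cb, wm$fragments$umi, sep = "|")
  s <- Matrix::summary(wm$weights)
  s <- s[s$j > 1L, , drop = FALSE]           # locus candidates only
  bucket <- paste(key[s$i], s$j, sep = "|")  # same group + same locus

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (rows in split(s$i, bucket)) {
    if (length(rows) > 1L) {
      r0 <- find(rows[1L])
      for (r in rows[-1L]) {
        rr <- find(r)
        if (rr != r0) parent[rr] <- r0
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  # fragments in different groups can never be duplicates; fragments with no
  # locus candidates stay their own component within their group
  comp_id <- paste(key, root, sep = "@")

  comp_split <- split(seq_len(n), comp_id)
  n_cand <- Matrix::rowSums(wm$weights[, -1L, drop = FALSE] != 0)
  reps <- vapply(comp_split, function(m) {
    if (length(m) == 1L) return(m)
    o <- order(-wm$fragments$best_score[m], n_cand[m],
               wm$fragments$read_name[m], method = "radix")
    m[o[1L]]
  }, integer(1L))
  keep <- sort(unname(reps))

  group_sizes <- table(key)
  comp_per_group <- table(sub("@.*$", "", names(comp_split)))
  hist_dt <- data.table::data.table(
    group_size = as.integer(group_sizes[names(comp_per_group)]),
    components = as.integer(comp_per_group)
  )[, .(n_groups = .N), by = c("group_size", "components")]
  data.table::setorder(hist_dt, group_size, components)

  list(
    matrix = subset_weight_matrix(wm, keep),
    report = list(
      totals = c(
        fragments_in = n,
        groups = length(group_sizes),
        components = length(comp_split),
        duplicates_removed = n - length(keep),
        fragments_out = length(keep)
      ),
      histogram = as.data.frame(hist_dt)
    )
  )
}
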