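# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, brute force) and never call the code paths they check.

gtf_line <- function(chrom, start, end, locus, subfamily = locus,
                     strand = "+") {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tlocus "%s"; subfamily "%s";',
          chrom, start, end, strand, locus, subfamily)
}

write_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

# annotation with three loci in two subfamilies on one chromosome
toy_annotation <- function() {
  load_te_annotation(write_gtf(c(
    gtf_line("chr1", 1001, 2000, "L1", "HERVH"),
    gtf_line("chr1", 5001, 6000, "L2", "HERVH"),
    gtf_line("chr1", 9001, 10000, "L3", "MER4")
  )))
}

# build a te_weight_matrix from a list of fragments; each fragment is
# list(q = named weights, cb = , umi = , gx = , score = )
make_wm <- function(frags, features) {
  m <- matrix(0, length(frags), length(features) + 1L,
              dimnames = list(NULL, c(NO_FEATURE_LABEL, features)))
  meta <- data.frame(
    read_name = sprintf("r%03d", seq_along(frags)),
    cb = rep("CELL1", length(frags)),
    umi = sprintf("U%03d", seq_along(frags)),
    gx = rep(FALSE, length(frags)), best_score = rep(0, length(frags)),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(frags)) {
    f <- frags[[k]]
    m[k, names(f$q)] <- f$q
    if (!is.null(f$cb)) meta$cb[k] <- f$cb
    if (!is.null(f$umi)) meta$umi[k] <- f$umi
    if (!is.null(f$gx)) meta$gx[k] <- f$gx
    if (!is.null(f$score)) meta$best_score[k] <- f$score
    if (!is.null(f$name)) meta$read_name[k] <- f$name
  }
  weight_matrix(m, meta)
}

# random weight matrix for property tests
rand_wm <- function(n_frag, n_feat, n_cells = 3, nofeat_p = 0.2) {
  feats <- paste0("F", seq_len(n_feat))
  m <- matrix(0, n_frag, n_feat + 1L,
              dimnames = list(NULL, c(NO_FEATURE_LABEL, feats)))
  for (k in seq_len(n_frag)) {
    nc <- sample(seq_len(min(4L, n_feat)), 1L)
    js <- sample(feats, nc)
    w <- exp(-runif(nc, 0, 5))
    w[1L] <- 1
    m[k, js] <- w
    if (runif(1) < nofeat_p) m[k, 1L] <- runif(1, 0.1, 1)
  }
  weight_matrix(m, data.frame(
    read_name = sprintf("r%03d", seq_len(n_frag)),
    cb = paste0("C", sample.int(n_cells, n_frag, replace = TRUE)),
    umi = sprintf("U%03d", seq_len(n_frag)),
    gx = runif(n_frag) < 0.2, best_score = 0,
    stringsAsFactors = FALSE
  ))
}

# --- oracles ---------------------------------------------------------------

# brute-force overlap: count bases one by one
oracle_overlap_fraction <- function(r_start, r_end, intervals) {
  bases <- r_start:r_end
  hit <- vapply(bases, function(b) {
    any(vapply(intervals, function(iv) b >= iv[1] && b <= iv[2], logical(1)))
  }, logical(1))
  sum(hit) / length(bases)
}

# transitive closure of pairwise candidate-set intersection; returns a
# membership vector (component label per set)
oracle_components <- function(sets) {
  n <- length(sets)
  if (n == 0L) return(integer(0))
  adj <- diag(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (length(intersect(sets[[a]], sets[[b]])) > 0L) adj[a, b] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  apply(adj, 1L, function(r) min(which(r)))
}

# per-row posterior by direct normalization of pi * theta^y * q
oracle_estep <- function(pi_vec, theta_vec, q_row, y) {
  w <- pi_vec[names(q_row)] * (if (y == 1) theta_vec[names(q_row)] else 1) * q_row
  w / sum(w)
}

# per-term accumulation of the complete-data log-likelihood
oracle_lnl <- function(pi_mat, theta_mat, post, wm, pool_of_row) {
  tot <- 0
  for (i in seq_len(nrow(post))) {
    for (j in seq_len(ncol(post))) {
      x <- post[i, j]
      if (x > 0) {
        term <- pi_mat[pool_of_row[i], j] *
          (if (wm$fragments$y[i] == 1) theta_mat[pool_of_row[i], j] else 1) *
          wm$weights[i, j]
        tot <- tot + x * log(term)
      }
    }
  }
  tot
}

# simple deterministic simulated dataset used by several test files
quick_sim <- function(seed = 11, ...) {
  simulate_reads(sim_config(n_cells = 12, mean_fragments_per_cell = 60,
                            n_loci = 20, n_subfamilies = 4, seed = seed, ...))
}
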