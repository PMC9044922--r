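.aln_matrix <- function(aligned) {
  seqs <- .named_chr(aligned)
  ids <- names(seqs)
  if (is.null(ids)) stop("aligned sequences must be named")
  if (length(seqs) < 3) stop("at least 3 taxa are required")
  w <- nchar(seqs)
  if (length(unique(w)) != 1) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- ids
  m
}

#' Pairwise-deletion p-distance matrix
#'
#' Proportion of differing sites per pair, with sites where either sequence
#' has a gap (`-`) excluded for that pair.  A pair with no comparable sites
#' is an error.
#'
#' @param aligned named character vector or `AAStringSet` of equal-length
#'   aligned sequences (>= 3 taxa).
#' @param model `"p"` for the raw p-distance (default) or `"poisson"` for
#'   the Poisson correction `-log(1 - p)`.
#' @return Symmetric numeric matrix of distances with taxa dimnames.
#' @export
p_distance <- function(aligned, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- .aln_matrix(aligned)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(comp))
        stop("no comparable sites between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'")
      p <- mean(m[i, comp] != m[j, comp])
      if (model == "poisson") {
        if (p >= 1) stop("p-distance of 1 cannot be Poisson-corrected")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q-criterion.
#' Ties in the Q minimisation are broken by the lexicographically smallest
#' index pair of the current matrix, which makes the topology deterministic
#' across platforms.  Negative branch lengths are clamped to zero.  For an
#' additive input matrix the output path distances reproduce the input
#' exactly.
#'
#' @param d symmetric distance matrix with taxa dimnames (n >= 3).
#' @return An unrooted [ape] `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("at least 3 taxa are required")
  if (is.null(rownames(d))) stop("distance matrix must have taxa names")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  node <- labels                    # growing newick fragments
  D <- d
  clamp <- function(x) pmax(x, 0)
  while (length(node) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best - 1e-12) { best <- q; bi <- i; bj <- j }
      }
    }
    la <- clamp(D[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (m - 2)))
    lb <- clamp(D[bi, bj] - la)
    new_node <- sprintf("(%s:%.17g,%s:%.17g)", node[bi], la, node[bj], lb)
    dn <- (D[bi, ] + D[bj, ] - D[bi, bj]) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    D <- D2
    node <- c(node[keep], new_node)
  }
  dxy <- D[1, 2]; dxz <- D[1, 3]; dyz <- D[2, 3]
  lx <- clamp((dxy + dxz - dyz) / 2)
  ly <- clamp((dxy + dyz - dxz) / 2)
  lz <- clamp((dxz + dyz - dxy) / 2)
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 node[1], lx, node[2], ly, node[3], lz)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and reports, for every internal edge of the point-estimate
#' tree, the percentage of replicates containing the same bipartition.
#' Replicates where some pair loses all comparable sites are skipped and
#' logged.  Column resampling is indexed by site, so supports do not depend
#' on taxon input order.
#'
#' @inheritParams p_distance
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed (required, for reproducibility).
#' @return List with `tree` (point-estimate `phylo`, node labels set to
#'   support percentages), `support` (numeric per internal node, `NA` for
#'   the root-trifurcation node) and `n_replicates_used`.
#' @export
bootstrap_support <- function(aligned, n_reps = 1000, seed,
                              model = c("p", "poisson")) {
  model <- match.arg(model)
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_reps >= 1)
  m <- .aln_matrix(aligned)
  base <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  ref <- neighbor_joining(p_distance(base, model))
  L <- ncol(m)
  set.seed(seed)
  boots <- vector("list", n_reps)
  used <- 0L
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    mb <- m[, idx, drop = FALSE]
    sb <- setNames(apply(mb, 1, paste, collapse = ""), rownames(m))
    tb <- tryCatch(neighbor_joining(p_distance(sb, model)),
                   error = function(e) NULL)
    if (is.null(tb)) { gf_log("bootstrap replicate %d skipped", b); next }
    used <- used + 1L
    boots[[used]] <- tb
  }
  if (used == 0) stop("all bootstrap replicates degenerate")
  boots <- boots[seq_len(used)]
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  support <- 100 * counts / used
  ref$node.label <- ifelse(is.na(support), "",
                           formatC(support, format = "f", digits = 1))
  gf_log("bootstrap_support: %d/%d replicates used", used, n_reps)
  list(tree = ref, support = support, n_replicates_used = used)
}

#' Write a tree to Newick
#'
#' @param tree an [ape] `phylo` object (support values, if any, are carried
#'   as internal node labels).
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
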