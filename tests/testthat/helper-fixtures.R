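options(gfam.verbose = FALSE)

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_peptide <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force global alignment oracle for tiny strings, matching the
# Biostrings gap convention: a gap run of length k costs open + k * extend.
# Enumerates every monotone alignment path recursively.
brute_force_align_score <- function(a, b, score_fun, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, sc, last) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recurse(i + 1, j + 1, sc + score_fun(a[i], b[j]), "M")
    if (i <= length(a))
      recurse(i + 1, j,
              sc - extend - if (last == "D") 0 else open, "D")
    if (j <= length(b))
      recurse(i, j + 1,
              sc - extend - if (last == "I") 0 else open, "I")
  }
  recurse(1, 1, 0, "S")
  best
}

blosum62_score <- local({
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  function(x, y) e$BLOSUM62[x, y]
})

# Random additive distance matrix from a random binary tree topology with
# positive branch lengths; returns the matrix and the source phylo tree.
random_additive_matrix <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.5, 3))
  d <- ape::cophenetic.phylo(tree)
  taxa <- sort(rownames(d))
  list(tree = tree, d = d[taxa, taxa])
}

# Net-charge grid oracle for the pI bisection.
grid_pi <- function(seq, step = 0.001) {
  ph <- seq(0, 14, by = step)
  q <- gfam::net_charge(seq, ph)
  ph[which.min(abs(q))]
}
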