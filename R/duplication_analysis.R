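.blosum62 <- function() {
  if (is.null(.gfam_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .gfam_env$BLOSUM62 <- e$BLOSUM62
  }
  .gfam_env$BLOSUM62
}

#' Global pairwise protein alignment (BLOSUM62, affine gaps)
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with the BLOSUM62 substitution matrix.  Gap parameters follow the usual
#' BLOSUM62 conventions (open 10, extend 0.5) and are configurable.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties.
#' @return List with the two gapped aligned strings `a` and `b` and the
#'   alignment `score`.
#' @export
global_align <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = .blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Identity, similarity and coverage of an aligned pair
#'
#' All three percentages are normalised by the length of the *longer*
#' ungapped sequence.  Identity counts identical aligned positions;
#' similarity counts positions with a positive BLOSUM62 score (identities
#' included); coverage is the fraction of the longer sequence inside the
#' aligned region, terminal gaps excluded.
#'
#' @param alignment list from [global_align()].
#' @param id_a,id_b identifiers recorded in the result.
#' @return One-row `data.frame`: `id_a`, `id_b`, `identity_pct`,
#'   `similarity_pct`, `coverage_pct`.
#' @export
identity_similarity <- function(alignment, id_a = "a", id_b = "b") {
  a <- strsplit(alignment$a, "")[[1]]
  b <- strsplit(alignment$b, "")[[1]]
  stopifnot(length(a) == length(b))
  len_a <- sum(a != "-"); len_b <- sum(b != "-")
  longer <- max(len_a, len_b)
  both <- a != "-" & b != "-"
  ident <- sum(both & a == b)
  bl <- .blosum62()
  sim <- ident
  mism <- which(both & a != b)
  if (length(mism))
    sim <- sim + sum(bl[cbind(a[mism], b[mism])] > 0)
  idxs <- which(both)
  cov <- if (length(idxs)) {
    span <- idxs[1]:idxs[length(idxs)]
    longer_chars <- if (len_a >= len_b) a else b
    sum(longer_chars[span] != "-")
  } else 0L
  data.frame(id_a = id_a, id_b = id_b,
             identity_pct = 100 * ident / longer,
             similarity_pct = 100 * sim / longer,
             coverage_pct = 100 * cov / longer,
             stringsAsFactors = FALSE)
}

#' All-vs-all pair scores within a protein set
#'
#' Computes [global_align()] + [identity_similarity()] for every unordered
#' pair.  Intended for within-family comparisons (quadratic in the number
#' of sequences).
#'
#' @param proteins named `AAStringSet` or named character vector.
#' @param gap_open,gap_extend gap penalties passed to [global_align()].
#' @return `data.frame` of pair scores, one row per unordered pair.
#' @export
pair_scores <- function(proteins, gap_open = 10, gap_extend = 0.5) {
  seqs <- .named_chr(proteins)
  ids <- names(seqs)
  if (is.null(ids)) stop("proteins must be named")
  n <- length(seqs)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(seqs[[i]], seqs[[j]], gap_open, gap_extend)
      out[[length(out) + 1L]] <- identity_similarity(aln, ids[i], ids[j])
    }
  }
  res <- do.call(rbind, out)
  gf_log("pair_scores: %d sequences -> %d pairs", n, nrow(res))
  res
}

#' Segmental duplication calls
#'
#' A pair is called segmental when the alignment covers more than
#' `min_coverage` percent of the longer gene *and* identity exceeds
#' `min_identity` percent (strict inequalities, i.e. the ">90%/>90%" rule).
#'
#' @param scores pair-score `data.frame` from [pair_scores()].
#' @param min_coverage,min_identity thresholds in percent.
#' @return The qualifying rows with an added `call = "SEGMENTAL"` column.
#' @export
call_segmental <- function(scores, min_coverage = 90, min_identity = 90) {
  keep <- scores$coverage_pct > min_coverage &
    scores$identity_pct > min_identity
  out <- scores[keep, , drop = FALSE]
  if (nrow(out)) out$call <- "SEGMENTAL"
  else out$call <- character(0)
  rownames(out) <- NULL
  gf_log("call_segmental: %d of %d pairs called", nrow(out), nrow(scores))
  out
}

#' Tandem duplication calls among segmental pairs
#'
#' A segmental pair is upgraded to tandem when both genes lie on the same
#' chromosome, one following the other (no other gene of the set between
#' them), with at most `max_gap` bp between their nearer ends.  Tandem
#' calls are therefore always a subset of segmental calls.
#'
#' @param segmental `data.frame` from [call_segmental()].
#' @param loci loci `data.frame` (0-based half-open, as from
#'   [read_gff3_genes()]); pairs with a missing locus stay segmental with
#'   a warning.
#' @param max_gap maximum gap between nearer gene ends, in bp.
#' @return `segmental` with `call` upgraded to `"TANDEM"` where the rule
#'   holds and a `distance_bp` column (gap between nearer ends for
#'   same-chromosome pairs, otherwise `NA`).
#' @export
call_tandem <- function(segmental, loci, max_gap = 100000) {
  out <- segmental
  out$distance_bp <- rep(NA_real_, nrow(out))
  if (!nrow(out)) return(out)
  # start-order rank per chromosome defines "one following the other"
  ord <- order(loci$chromosome, loci$start)
  rank_in_chr <- integer(nrow(loci))
  rank_in_chr[ord] <- ave(seq_along(ord), loci$chromosome[ord],
                          FUN = seq_along)
  for (k in seq_len(nrow(out))) {
    ia <- match(out$id_a[k], loci$gene_id)
    ib <- match(out$id_b[k], loci$gene_id)
    if (is.na(ia) || is.na(ib)) {
      gf_warn("no locus for pair (%s, %s); kept as SEGMENTAL",
              out$id_a[k], out$id_b[k])
      next
    }
    if (loci$chromosome[ia] != loci$chromosome[ib]) next
    gap <- max(loci$start[ia], loci$start[ib]) -
      min(loci$end[ia], loci$end[ib])
    out$distance_bp[k] <- max(gap, 0)
    adjacent <- abs(rank_in_chr[ia] - rank_in_chr[ib]) == 1
    if (adjacent && out$distance_bp[k] <= max_gap)
      out$call[k] <- "TANDEM"
  }
  gf_log("call_tandem: %d of %d segmental pairs upgraded",
         sum(out$call == "TANDEM"), nrow(out))
  out
}

#' Duplication analysis of a gene family
#'
#' Convenience wrapper: all-vs-all pair scores, segmental calling and --
#' when loci are supplied -- tandem refinement.
#'
#' @inheritParams pair_scores
#' @param loci optional loci `data.frame` for tandem calling.
#' @param min_coverage,min_identity segmental thresholds (percent).
#' @param max_gap tandem distance threshold in bp.
#' @return `data.frame` of called duplication pairs.
#' @export
find_duplications <- function(proteins, loci = NULL,
                              min_coverage = 90, min_identity = 90,
                              max_gap = 100000,
                              gap_open = 10, gap_extend = 0.5) {
  scores <- pair_scores(proteins, gap_open, gap_extend)
  seg <- call_segmental(scores, min_coverage, min_identity)
  if (!is.null(loci)) seg <- call_tandem(seg, loci, max_gap)
  seg
}
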