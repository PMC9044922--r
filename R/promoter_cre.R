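#' Read a cis-regulatory element catalog
#'
#' The catalog is a TSV with columns `name`, `consensus` (IUPAC nucleotide
#' string, length >= 4) and `group` (one of the seven functional groups:
#' light-responsive, hormone-responsive, environmental-stress, development,
#' promoter-related, site-binding, other).  A default catalog of
#' literature-standard consensi ships with the package and is explicitly
#' user-replaceable; two elements whose definitions are not public
#' (`STRE`, `Unnamed-4`) are placeholders flagged in the `non_canonical`
#' column.
#'
#' @param path catalog TSV path; default uses the bundled catalog.
#' @return Data frame with `name`, `consensus`, `group` (and any extra
#'   columns present in the file).
#' @export
read_cre_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cre_catalog.tsv", package = "gfam")
  cat_df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("name", "consensus", "group") %in% names(cat_df)))
    stop("catalog must have columns name, consensus, group")
  if (any(nchar(cat_df$consensus) < 4))
    stop("catalog consensus strings must be at least 4 nt")
  bad <- setdiff(cat_df$group, CRE_GROUPS)
  if (length(bad))
    stop("unknown CRE group(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(cat_df$name))
    stop("duplicate motif names in catalog")
  cat_df$consensus <- toupper(cat_df$consensus)
  cat_df
}

#' Scan promoters for cis-regulatory elements
#'
#' Reports every position where a catalog consensus matches under IUPAC
#' semantics, on both strands (a minus-strand hit is a match of the
#' reverse complement, reported at its forward-strand offset).
#' Overlapping matches are all reported; `N` in the promoter never
#' matches.
#'
#' @param promoters named `DNAStringSet` or named character vector of
#'   A/C/G/T/N promoter sequences.
#' @param catalog catalog data frame from [read_cre_catalog()].
#' @return `data.frame` with `gene_id`, `motif`, `position` (0-based
#'   offset of the match start in the promoter), `strand` (`+`/`-`),
#'   ordered by gene, position, motif, strand.
#' @export
scan_promoters <- function(promoters, catalog = read_cre_catalog()) {
  if (is.null(catalog) || nrow(catalog) == 0) stop("empty CRE catalog")
  proms <- if (methods::is(promoters, "DNAStringSet")) promoters
           else {
    nm <- names(promoters)
    ps <- Biostrings::DNAStringSet(toupper(unlist(promoters)))
    names(ps) <- nm
    ps
  }
  if (is.null(names(proms))) stop("promoters must be named")
  out <- list()
  for (k in seq_len(nrow(catalog))) {
    pat <- Biostrings::DNAString(catalog$consensus[k])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      mm <- Biostrings::vmatchPattern(p, proms, fixed = "subject")
      st <- BiocGenerics::start(mm)
      ln <- lengths(st)
      if (sum(ln) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        gene_id = rep(names(proms), ln),
        motif = catalog$name[k],
        position = unlist(st, use.names = FALSE) - 1L,
        strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$position, res$motif, res$strand), ]
  rownames(res) <- NULL
  gf_log("scan_promoters: %d promoters, %d hits", length(proms), nrow(res))
  res
}

#' @rdname scan_promoters
#' @param promoter a single promoter sequence (string).
#' @param gene_id identifier used in the result.
#' @export
scan_promoter <- function(promoter, catalog = read_cre_catalog(),
                          gene_id = "promoter") {
  scan_promoters(setNames(as.character(promoter), gene_id), catalog)
}

#' Summarise CRE hits by motif and functional group
#'
#' @param hits hit `data.frame` from [scan_promoters()].
#' @param catalog catalog used for the scan (supplies motif -> group).
#' @return List with `per_motif` (all catalog motifs, zero-filled),
#'   `per_group` (all seven groups, zero-filled), `per_gene` totals,
#'   a gene x motif `presence` matrix, and `n_hits`.  Count conservation
#'   holds: motif counts, group counts and `n_hits` agree.
#' @export
summarize_cre <- function(hits, catalog = read_cre_catalog()) {
  unknown <- setdiff(unique(hits$motif), catalog$name)
  if (length(unknown))
    stop("hit(s) name motif(s) absent from catalog: ",
         paste(unknown, collapse = ", "))
  per_motif <- data.frame(
    motif = catalog$name, group = catalog$group,
    count = as.integer(table(factor(hits$motif,
                                    levels = catalog$name))),
    stringsAsFactors = FALSE)
  grp <- tapply(per_motif$count, factor(per_motif$group,
                                        levels = CRE_GROUPS), sum)
  per_group <- data.frame(group = CRE_GROUPS,
                          count = as.integer(ifelse(is.na(grp), 0, grp)),
                          stringsAsFactors = FALSE)
  genes <- sort(unique(hits$gene_id))
  per_gene <- data.frame(
    gene_id = genes,
    count = as.integer(table(factor(hits$gene_id, levels = genes))),
    stringsAsFactors = FALSE)
  presence <- matrix(FALSE, nrow = length(genes), ncol = nrow(catalog),
                     dimnames = list(genes, catalog$name))
  if (nrow(hits))
    presence[cbind(hits$gene_id, hits$motif)] <- TRUE
  list(per_motif = per_motif, per_group = per_group, per_gene = per_gene,
       presence = presence, n_hits = nrow(hits))
}
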