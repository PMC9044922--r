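#' Read a FASTA file of protein or nucleotide sequences
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()] that enforces the package's record
#' contract: identifiers are the first whitespace-delimited token of the
#' header, sequences are uppercased, and identifiers must be unique within
#' the file.
#'
#' @param path path to a FASTA file.
#' @param type `"AA"` for proteins (default) or `"DNA"` for promoters.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet] named
#'   by record identifier.  An empty file yields an empty set with a warning.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.info(path)$size == 0) {
    gf_warn("FASTA file '%s' is empty", path)
    return(if (type == "AA") Biostrings::AAStringSet()
           else Biostrings::DNAStringSet())
  }
  set <- tryCatch(
    if (type == "AA") Biostrings::readAAStringSet(path)
    else Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0) {
    gf_warn("FASTA file '%s' contains no records", path)
    return(set)
  }
  names(set) <- sub("\\s.*$", "", names(set))
  dup <- names(set)[duplicated(names(set))]
  if (length(dup))
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  up <- toupper(as.character(set))
  set <- if (type == "AA") Biostrings::AAStringSet(up)
         else Biostrings::DNAStringSet(up)
  names(set) <- names(up)
  gf_log("read_fasta: %d %s records from %s", length(set), type, path)
  set
}

#' Write sequences to FASTA
#'
#' @param x a named `XStringSet` or named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `invisible(path)`.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    x <- Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

.normalize_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))

#' Read gene loci from a GFF3 annotation
#'
#' Builds one locus per mRNA (or transcript) feature with its child exons.
#' External GFF3 coordinates are 1-based inclusive; the returned loci use
#' 0-based half-open coordinates -- all internal arithmetic in the package
#' uses that convention and conversion happens only at this I/O boundary.
#'
#' @param path path to a GFF3 file with gene/mRNA/exon features.
#' @return A `data.frame` with columns `gene_id`, `chromosome`, `start`,
#'   `end` (0-based half-open), `strand` and a list-column `exons` of
#'   two-column matrices (`start`, `end`, 0-based half-open, sorted,
#'   non-overlapping).  Exons lying outside their parent span are an error;
#'   exons without a `Parent` attribute are skipped with a warning.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- tolower(as.character(gr$type))
  mrna <- gr[type %in% c("mrna", "transcript")]
  ex <- gr[type == "exon"]
  if (length(mrna) == 0) stop("no mRNA/transcript features in '", path, "'")

  parents <- if (!is.null(ex$Parent)) ex$Parent else
    S4Vectors::mcols(ex)[["Parent"]]
  orphan <- lengths(parents) == 0
  if (any(orphan)) {
    gf_warn("%d exon(s) without a Parent attribute skipped", sum(orphan))
    ex <- ex[!orphan]
    parents <- parents[!orphan]
  }
  ex <- rep(ex, lengths(parents))
  parent_id <- unlist(parents, use.names = FALSE)

  ids <- as.character(mrna$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("mRNA feature without ID attribute in '", path, "'")
  if (anyDuplicated(ids))
    stop("duplicate mRNA ID(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  loci <- data.frame(
    gene_id = ids,
    chromosome = .normalize_chrom(GenomicRanges::seqnames(mrna)),
    start = BiocGenerics::start(mrna) - 1L,
    end = BiocGenerics::end(mrna),
    strand = as.character(BiocGenerics::strand(mrna)),
    stringsAsFactors = FALSE)
  loci$strand[!loci$strand %in% c("+", "-")] <- "+"

  exlist <- vector("list", nrow(loci))
  es <- BiocGenerics::start(ex) - 1L
  ee <- BiocGenerics::end(ex)
  for (k in seq_len(nrow(loci))) {
    sel <- parent_id == ids[k]
    if (!any(sel)) stop("mRNA '", ids[k], "' has no exons")
    m <- cbind(start = es[sel], end = ee[sel])
    m <- m[order(m[, "start"]), , drop = FALSE]
    if (any(m[, "start"] < loci$start[k]) || any(m[, "end"] > loci$end[k]))
      stop("exon outside parent span for mRNA '", ids[k], "'")
    if (nrow(m) > 1 && any(m[-1, "start"] < m[-nrow(m), "end"]))
      stop("overlapping exons for mRNA '", ids[k], "'")
    exlist[[k]] <- m
  }
  loci$exons <- exlist
  gf_log("read_gff3_genes: %d loci from %s", nrow(loci), path)
  loci
}

#' Write gene loci back to GFF3
#'
#' Inverse of [read_gff3_genes()]: converts the internal 0-based half-open
#' representation back to 1-based inclusive GFF3 via [rtracklayer::export()].
#'
#' @param loci a loci `data.frame` as returned by [read_gff3_genes()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_gff3_genes <- function(loci, path) {
  n_ex <- vapply(loci$exons, nrow, integer(1))
  mk <- function(type, start0, end0, chrom, strand, id, parent) {
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = strand)
    gr$type <- type
    gr$ID <- id
    gr$Parent <- parent
    gr
  }
  mrna <- mk("mRNA", loci$start, loci$end, loci$chromosome, loci$strand,
             loci$gene_id,
             IRanges::CharacterList(rep(list(character(0)), nrow(loci))))
  exs <- mk("exon",
            unlist(lapply(loci$exons, function(m) m[, "start"])),
            unlist(lapply(loci$exons, function(m) m[, "end"])),
            rep(loci$chromosome, n_ex),
            rep(loci$strand, n_ex),
            NA_character_,
            IRanges::CharacterList(as.list(rep(loci$gene_id, n_ex))))
  rtracklayer::export(c(mrna, exs), path, format = "gff3")
  invisible(path)
}

#' Exon/intron structure summary per gene
#'
#' @param loci a loci `data.frame` as returned by [read_gff3_genes()].
#' @return A `data.frame` with `gene_id`, `n_exons`, `n_introns`
#'   (`n_exons - 1`) and the `intronless` flag used to tally single-exon
#'   genes per family.
#' @export
gene_structure_summary <- function(loci) {
  n_ex <- vapply(loci$exons, nrow, integer(1))
  if (any(n_ex == 0)) stop("locus with zero exons: ",
                           loci$gene_id[which(n_ex == 0)[1]])
  data.frame(gene_id = loci$gene_id,
             n_exons = n_ex,
             n_introns = n_ex - 1L,
             intronless = n_ex == 1L,
             stringsAsFactors = FALSE)
}

#' Chromosome and sub-genome distribution of gene loci
#'
#' Hexaploid wheat chromosome labels are `1A`..`7D`; the sub-genome (A, B
#' or D) is the trailing letter.  Unplaced or unparseable labels are counted
#' under `"Un"` (with a warning for the latter).
#'
#' @param loci a loci `data.frame` (only `chromosome` is used).
#' @return A list with `chromosome` and `subgenome` count data frames and
#'   the total `n`; counts always sum to the number of input loci.
#' @export
chromosome_distribution <- function(loci) {
  labs <- as.character(loci$chromosome)
  if (length(labs) == 0)
    return(list(chromosome = data.frame(chromosome = character(0),
                                        count = integer(0)),
                subgenome = data.frame(subgenome = character(0),
                                       count = integer(0)),
                n = 0L))
  ok <- grepl("^[1-7][ABD]$", labs)
  bad <- !ok & labs != "Un"
  if (any(bad)) {
    gf_warn("%d unparseable chromosome label(s) counted as 'Un': %s",
            sum(bad), paste(unique(labs[bad]), collapse = ", "))
    labs[bad] <- "Un"
  }
  chrom <- as.data.frame(table(chromosome = labs), stringsAsFactors = FALSE)
  names(chrom)[2] <- "count"
  sub <- ifelse(labs == "Un", "Un", substring(labs, 2, 2))
  subg <- as.data.frame(table(subgenome = sub), stringsAsFactors = FALSE)
  names(subg)[2] <- "count"
  list(chromosome = chrom, subgenome = subg, n = length(labs))
}
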