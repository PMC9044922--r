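# Average residue masses (Da), peptide-bond convention: the mass of a
# protein is the sum of residue masses plus one water.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy indices.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.residues <- function(sequence, caller) {
  res <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (length(res) == 0) stop(caller, ": empty sequence")
  bad <- which(!res %in% AA_ORDER)
  if (length(bad))
    stop(caller, ": non-canonical residue '", res[bad[1]],
         "' at position ", bad[1])
  res
}

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water, matching the kDa values
#' reported by standard protein-analysis services.
#'
#' @param sequence amino-acid string of canonical residues.
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(sequence) {
  res <- .residues(sequence, "molecular_weight")
  sum(AA_MASS[res]) + WATER_MASS
}

#' Bundled pKa table (Bjellqvist values)
#'
#' The table ships as a TSV under `extdata` so an alternative set (e.g.
#' EMBOSS) can be swapped in.
#'
#' @param path optional path to a pKa TSV (`site`, `pka`, `charge` columns).
#' @return Data frame with one row per ionisable site.
#' @export
load_pka_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pka_bjellqvist.tsv", package = "gfam")
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch over the N- and C-termini and the ionisable side
#' chains (D, E, C, Y, H, K, R).  Monotone decreasing in pH.
#'
#' @param sequence amino-acid string.
#' @param pH pH value (vectorised).
#' @param pka pKa table from [load_pka_table()].
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(sequence, pH, pka = load_pka_table()) {
  res <- .residues(sequence, "net_charge")
  counts <- table(factor(res, levels = AA_ORDER))
  vapply(pH, function(p) {
    pos <- 0; neg <- 0
    for (k in seq_len(nrow(pka))) {
      site <- pka$site[k]
      n <- if (site == "Nterm" || site == "Cterm") 1 else counts[[site]]
      if (n == 0) next
      if (pka$charge[k] == "pos")
        pos <- pos + n / (1 + 10^(p - pka$pka[k]))
      else
        neg <- neg + n / (1 + 10^(pka$pka[k] - p))
    }
    pos - neg
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge crosses zero, found by bisection on
#' `[0, 14]` to `|charge| < 1e-4` or a bracket narrower than `1e-3`.
#'
#' @inheritParams net_charge
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = load_pka_table()) {
  lo <- 0; hi <- 14
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-3) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle indices over all residues; bounded by
#' the table extremes `[-4.5, 4.5]`.
#'
#' @param sequence amino-acid string.
#' @return GRAVY value.
#' @export
gravy <- function(sequence) {
  res <- .residues(sequence, "gravy")
  mean(KD_HYDROPATHY[res])
}

#' Biochemical property table for a set of proteins
#'
#' @param proteins named `AAStringSet` or named character vector.
#' @return Data frame with `protein_id`, `length`, `mol_weight` (Da),
#'   `pI`, `gravy`.
#' @export
protein_properties <- function(proteins) {
  seqs <- .named_chr(proteins)
  ids <- names(seqs)
  if (is.null(ids)) stop("proteins must be named")
  pka <- load_pka_table()
  out <- data.frame(
    protein_id = ids,
    length = nchar(seqs),
    mol_weight = vapply(seqs, molecular_weight, numeric(1)),
    pI = vapply(seqs, isoelectric_point, numeric(1), pka = pka),
    gravy = vapply(seqs, gravy, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  gf_log("protein_properties: %d proteins", nrow(out))
  out
}
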