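#' Build a position-specific domain scoring profile
#'
#' A profile is the package's lightweight stand-in for an HMM domain model:
#' one score vector per alignment column (log-odds-style units), a score
#' threshold playing the role of the usual E-value gate, and metadata
#' recording which columns carry the sub-family diagnostic residues
#' (positions 14 and 19 of the AP2 domain alignment) and the conserved
#' WLG residue triple.
#'
#' The default scoring is `match_score` for the consensus residue of a
#' column and `mismatch_score` otherwise; users can substitute profiles
#' derived from a real domain alignment via [read_profile_tsv()].
#'
#' @param name domain name, `"AP2"` or `"B3"` (free-form allowed).
#' @param consensus consensus amino-acid string, one letter per column
#'   (length >= 10; >= 19 when `res14_col`/`res19_col` are set).
#' @param match_score,mismatch_score per-column scores.
#' @param gap_open,gap_extend affine gap penalties of the local scan
#'   (first gapped position costs `gap_open`, each further `gap_extend`).
#' @param score_threshold minimum hit score; defaults to
#'   `match_score * length / 2`, half the perfect-match score.
#' @param res14_col,res19_col 1-based profile columns of the sub-family
#'   diagnostic residues (`NA` for profiles without them, e.g. B3).
#' @param wlg_cols integer vector of the three profile columns holding the
#'   WLG triple (`NULL` if absent).
#' @return An object of class `domain_profile`.
#' @export
build_domain_profile <- function(name, consensus,
                                 match_score = 2, mismatch_score = -1,
                                 gap_open = 4, gap_extend = 1,
                                 score_threshold = NULL,
                                 res14_col = NA_integer_,
                                 res19_col = NA_integer_,
                                 wlg_cols = NULL) {
  cons <- strsplit(toupper(consensus), "")[[1]]
  L <- length(cons)
  if (L < 10) stop("profile length must be >= 10")
  if (!all(cons %in% AA_ORDER)) stop("consensus contains non-canonical residues")
  if (!is.na(res14_col) || !is.na(res19_col)) {
    if (L < 19) stop("profiles carrying positions 14 and 19 need length >= 19")
  }
  scores <- matrix(mismatch_score, nrow = L, ncol = 20,
                   dimnames = list(NULL, AA_ORDER))
  scores[cbind(seq_len(L), match(cons, AA_ORDER))] <- match_score
  if (is.null(score_threshold)) score_threshold <- match_score * L / 2
  if (!is.finite(score_threshold)) stop("score threshold must be finite")
  structure(list(name = name, length = L, scores = scores,
                 consensus = paste(cons, collapse = ""),
                 gap_open = gap_open, gap_extend = gap_extend,
                 score_threshold = score_threshold,
                 res14_col = as.integer(res14_col),
                 res19_col = as.integer(res19_col),
                 wlg_cols = if (is.null(wlg_cols)) integer(0)
                            else as.integer(wlg_cols)),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("domain_profile '%s': %d columns, threshold %.1f\n",
              x$name, x$length, x$score_threshold))
  invisible(x)
}

# 60-column AP2-like consensus used by the bundled default profile and the
# synthetic proteome generator.  Column 14 = V, column 19 = E (the DREB
# diagnostic pair), WLG triple at columns 30-32.
AP2_CONSENSUS <- "SGSKYRGVRQRPWVKWAAEIRDPKKGVRVWLGTFDTAEEAARAYDEAALRFRGNKAKTNF"

# 50-column B3-like consensus (co-occurrence with AP2 defines RAV).
B3_CONSENSUS <- "FFKVLTPSDVSKRMRIPEKFARNLDGKIPETVTLKVPSGAEWPVELTKRD"

#' Bundled default AP2 and B3 profiles
#'
#' @return Named list with elements `AP2` and `B3`.
#' @export
default_profiles <- function() {
  list(AP2 = build_domain_profile("AP2", AP2_CONSENSUS,
                                  res14_col = 14L, res19_col = 19L,
                                  wlg_cols = 30:32),
       B3 = build_domain_profile("B3", B3_CONSENSUS))
}

#' Write / read a profile as a versioned TSV
#'
#' The on-disk format is one header line
#' `#gfam-profile v1 name=... threshold=... gap_open=... gap_extend=...
#' res14_col=... res19_col=... wlg_cols=...` followed by a TSV with columns
#' `column`, `consensus` and the 20 residue scores.
#'
#' @param profile a `domain_profile`.
#' @param path file path.
#' @return `write_profile_tsv` returns `invisible(path)`;
#'   `read_profile_tsv` returns a `domain_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  hdr <- sprintf(
    "#gfam-profile v1 name=%s threshold=%g gap_open=%g gap_extend=%g res14_col=%s res19_col=%s wlg_cols=%s",
    profile$name, profile$score_threshold, profile$gap_open,
    profile$gap_extend,
    ifelse(is.na(profile$res14_col), "NA", profile$res14_col),
    ifelse(is.na(profile$res19_col), "NA", profile$res19_col),
    if (length(profile$wlg_cols)) paste(profile$wlg_cols, collapse = ",")
    else "NA")
  df <- data.frame(column = seq_len(profile$length),
                   consensus = strsplit(profile$consensus, "")[[1]],
                   profile$scores, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!startsWith(hdr, "#gfam-profile v1"))
    stop("'", path, "' is not a v1 gfam profile file")
  kv <- regmatches(hdr, gregexpr("[a-z0-9_]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  df <- read.delim(path, skip = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  scores <- as.matrix(df[, AA_ORDER])
  dimnames(scores) <- list(NULL, AA_ORDER)
  wlg <- meta[["wlg_cols"]]
  prof <- structure(list(
    name = meta[["name"]],
    length = nrow(df),
    scores = scores,
    consensus = paste(df$consensus, collapse = ""),
    gap_open = as.numeric(meta[["gap_open"]]),
    gap_extend = as.numeric(meta[["gap_extend"]]),
    score_threshold = as.numeric(meta[["threshold"]]),
    res14_col = suppressWarnings(as.integer(meta[["res14_col"]])),
    res19_col = suppressWarnings(as.integer(meta[["res19_col"]])),
    wlg_cols = if (identical(wlg, "NA")) integer(0)
               else as.integer(strsplit(wlg, ",")[[1]])),
    class = "domain_profile")
  if (prof$length < 10) stop("profile length must be >= 10")
  prof
}
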