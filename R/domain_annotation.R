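#' Scan a protein for domain hits against scoring profiles
#'
#' Iterated best-hit Smith-Waterman of the protein against each
#' position-specific profile: the best local hit above the profile's score
#' threshold is reported, its residues are masked, and scanning repeats
#' until no hit clears the threshold or `max_hits` is reached.  Hits from
#' different profiles are then reduced to a non-overlapping set greedily,
#' best score first (leftmost on ties), so the reported architecture is
#' deterministic.
#'
#' @param sequence amino-acid string (or length-1 `AAStringSet` element).
#' @param profiles list of `domain_profile` objects (see
#'   [default_profiles()]).
#' @param max_hits maximum hits per profile.
#' @param protein_id identifier recorded in the result.
#' @return A `data.frame` with one row per hit: `protein_id`, `domain`,
#'   `start`/`end` (0-based half-open protein offsets), `score`,
#'   `domain_sequence`, and a list-column `profile_residues` holding, for
#'   each profile column, the aligned residue (`"-"` for a gap or an
#'   unaligned column).  Proteins shorter than half the profile length give
#'   no hits for that profile.
#' @export
scan_domains <- function(sequence, profiles = default_profiles(),
                         max_hits = 4L, protein_id = "protein") {
  seq_chr <- toupper(as.character(sequence))
  res <- strsplit(seq_chr, "")[[1]]
  idx <- match(res, AA_ORDER)          # NA / X -> 0 (never matches)
  idx[is.na(idx)] <- 0L
  n <- length(idx)

  hits <- list()
  for (prof in profiles) {
    if (n < prof$length / 2) next
    mask <- rep(FALSE, n)
    for (h in seq_len(max_hits)) {
      al <- .profile_local_align(idx, prof$scores, prof$gap_open,
                                 prof$gap_extend, mask)
      if (!isTRUE(al$found) || al$score < prof$score_threshold) break
      pr <- rep("-", prof$length)
      aligned <- al$col_res > 0
      pr[aligned] <- AA_ORDER[al$col_res[aligned]]
      hits[[length(hits) + 1L]] <- list(
        domain = prof$name,
        start = al$prot_start - 1L,
        end = al$prot_end,
        score = al$score,
        profile_residues = pr)
      mask[al$prot_start:al$prot_end] <- TRUE
    }
  }
  if (!length(hits)) return(.empty_hits(protein_id))

  df <- data.frame(
    protein_id = protein_id,
    domain = vapply(hits, `[[`, "", "domain"),
    start = vapply(hits, `[[`, 0L, "start"),
    end = vapply(hits, `[[`, 0L, "end"),
    score = vapply(hits, `[[`, 0, "score"),
    stringsAsFactors = FALSE)
  df$domain_sequence <- substring(seq_chr, df$start + 1L, df$end)
  df$profile_residues <- lapply(hits, `[[`, "profile_residues")

  # greedy non-overlap selection across profiles: best score, then leftmost
  df <- df[order(-df$score, df$start), ]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    keep[i] <- !any(keep & df$start < df$end[i] & df$end > df$start[i])
  }
  df <- df[keep, ]
  df <- df[order(df$start), ]
  rownames(df) <- NULL
  df
}

.empty_hits <- function(protein_id) {
  df <- data.frame(protein_id = character(0), domain = character(0),
                   start = integer(0), end = integer(0),
                   score = numeric(0), domain_sequence = character(0),
                   stringsAsFactors = FALSE)
  df$profile_residues <- list()
  df
}

#' Family classification from domain architecture
#'
#' One AP2 domain and no B3 gives `ERF_DREB`, two AP2 domains `AP2`, one
#' AP2 plus one B3 `RAV`.  Proteins without a well-defined AP2 domain are
#' `DISCARDED`, as are unexpected architectures (with a warning).
#'
#' @param hits hit `data.frame` from [scan_domains()] for one protein.
#' @return One of `"ERF_DREB"`, `"AP2"`, `"RAV"`, `"DISCARDED"`.
#' @export
classify_family <- function(hits) {
  n_ap2 <- sum(hits$domain == "AP2")
  n_b3 <- sum(hits$domain == "B3")
  if (n_ap2 == 1 && n_b3 == 0) return("ERF_DREB")
  if (n_ap2 == 2 && n_b3 == 0) return("AP2")
  if (n_ap2 == 1 && n_b3 == 1) return("RAV")
  if (n_ap2 == 0) return("DISCARDED")
  gf_warn("unexpected domain architecture (%d AP2, %d B3) discarded",
          n_ap2, n_b3)
  "DISCARDED"
}

.hit_residue <- function(hit, col) {
  if (is.na(col) || col < 1) return(NA_character_)
  hit$profile_residues[[1]][col]
}

#' DREB/ERF sub-family assignment from AP2-domain positions 14 and 19
#'
#' Valine at column 14 and glutamate at column 19 are evidence for DREB;
#' alanine at 14 and aspartate at 19 for ERF.  A sub-family is assigned
#' when its evidence count strictly exceeds the other's and is at least 1;
#' ties -- including the 0-0 case and the one-residue-each conflict -- fall
#' into `OTHER`.
#'
#' @param hit one-row hit `data.frame` (an AP2 hit) from [scan_domains()].
#' @param profile the `domain_profile` the hit was scanned with (supplies
#'   the diagnostic column indices).
#' @return One of `"DREB"`, `"ERF"`, `"OTHER"`, plus attributes
#'   `residue14`/`residue19`.
#' @export
classify_subfamily <- function(hit, profile = default_profiles()$AP2) {
  stopifnot(nrow(hit) == 1, hit$domain == "AP2")
  r14 <- .hit_residue(hit, profile$res14_col)
  r19 <- .hit_residue(hit, profile$res19_col)
  if (identical(r14, "-") && identical(r19, "-"))
    gf_warn("gap at both diagnostic columns 14 and 19 for '%s'",
            hit$protein_id)
  dreb <- sum(identical(r14, "V"), identical(r19, "E"))
  erf <- sum(identical(r14, "A"), identical(r19, "D"))
  out <- if (dreb > erf && dreb >= 1) "DREB"
         else if (erf > dreb && erf >= 1) "ERF"
         else "OTHER"
  attr(out, "residue14") <- r14
  attr(out, "residue19") <- r19
  out
}

#' WLG-motif variant of an AP2 hit
#'
#' Returns the residues aligned to the profile's conserved WLG columns
#' (canonically tryptophan-leucine-glycine); gaps render as `"-"`.
#'
#' @inheritParams classify_subfamily
#' @return Three-character string, e.g. `"WLG"`, `"WIG"`, `"W-G"`.
#' @export
wlg_variant <- function(hit, profile = default_profiles()$AP2) {
  stopifnot(nrow(hit) == 1, hit$domain == "AP2")
  if (length(profile$wlg_cols) != 3) return(NA_character_)
  paste(hit$profile_residues[[1]][profile$wlg_cols], collapse = "")
}

#' Classify a whole proteome
#'
#' Runs [scan_domains()] on every protein and applies the family and
#' sub-family rules, producing the per-protein classification table that
#' drives the rest of the pipeline.  Every protein gets exactly one family
#' label (including `DISCARDED`), so label counts always sum to the input
#' size.
#'
#' @param proteins named `AAStringSet` or named character vector.
#' @param profiles list of `domain_profile`s; the element named `"AP2"`
#'   supplies the sub-family diagnostic columns.
#' @param max_hits per-profile hit cap passed to [scan_domains()].
#' @return A `data.frame` with one row per protein: `protein_id`, `family`,
#'   `subfamily` (`NA` unless family is `ERF_DREB`), `residue14`,
#'   `residue19`, `wlg`, `n_AP2`, `n_B3`, `best_score`.
#' @export
classify_proteome <- function(proteins, profiles = default_profiles(),
                              max_hits = 4L) {
  seqs <- .named_chr(proteins)
  ids <- names(seqs)
  if (is.null(ids)) stop("proteins must be named")
  ap2_prof <- profiles[["AP2"]]
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    hits <- scan_domains(seqs[[i]], profiles, max_hits = max_hits,
                         protein_id = ids[[i]])
    fam <- classify_family(hits)
    sub <- NA_character_; r14 <- NA_character_; r19 <- NA_character_
    wlg <- NA_character_
    ap2_hits <- hits[hits$domain == "AP2", ]
    if (fam == "ERF_DREB") {
      sub <- classify_subfamily(ap2_hits[1, ], ap2_prof)
      r14 <- attr(sub, "residue14"); r19 <- attr(sub, "residue19")
      sub <- as.character(sub)
      wlg <- wlg_variant(ap2_hits[1, ], ap2_prof)
    } else if (nrow(ap2_hits)) {
      wlg <- wlg_variant(ap2_hits[1, ], ap2_prof)
    }
    out[[i]] <- data.frame(
      protein_id = ids[[i]], family = fam, subfamily = sub,
      residue14 = r14, residue19 = r19, wlg = wlg,
      n_AP2 = sum(hits$domain == "AP2"),
      n_B3 = sum(hits$domain == "B3"),
      best_score = if (nrow(hits)) max(hits$score) else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  gf_log("classify_proteome: %d proteins -> %d ERF_DREB, %d AP2, %d RAV, %d discarded",
         nrow(res), sum(res$family == "ERF_DREB"), sum(res$family == "AP2"),
         sum(res$family == "RAV"), sum(res$family == "DISCARDED"))
  res
}
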