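.CT_COLS <- c("genotype", "class", "treatment", "replicate", "gene", "ct")

#' Read a qPCR Ct table
#'
#' TSV with columns `genotype`, `class` (`TOLERANT`/`SUSCEPTIBLE`),
#' `treatment` (`CONTROL`/`HEAT`), `replicate`, `gene`, `ct`.  Technical
#' repeats (duplicate rows for the same genotype/treatment/replicate/gene)
#' are averaged into one Ct before analysis.
#'
#' @param path TSV path.
#' @param reference_gene housekeeping gene (e.g. beta-actin); must be
#'   measured in every (genotype, treatment, replicate) cell.
#' @return Validated Ct `data.frame`.
#' @export
read_ct_table <- function(path, reference_gene) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(ct, reference_gene)
}

#' @rdname read_ct_table
#' @param ct a Ct `data.frame` in memory.
#' @export
validate_ct_table <- function(ct, reference_gene) {
  missing_cols <- setdiff(.CT_COLS, names(ct))
  if (length(missing_cols))
    stop("Ct table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ct$class <- toupper(ct$class)
  ct$treatment <- toupper(ct$treatment)
  if (!all(ct$class %in% c("TOLERANT", "SUSCEPTIBLE")))
    stop("class must be TOLERANT or SUSCEPTIBLE")
  if (!all(ct$treatment %in% c("CONTROL", "HEAT")))
    stop("treatment must be CONTROL or HEAT")
  if (!all(is.finite(ct$ct))) stop("non-finite Ct value(s)")
  # technical repeats -> one Ct
  key <- interaction(ct$genotype, ct$treatment, ct$replicate, ct$gene,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    gf_log("averaging technical repeats (%d rows -> %d)",
           nrow(ct), length(unique(key)))
    ct <- aggregate(ct["ct"],
                    ct[c("genotype", "class", "treatment", "replicate",
                         "gene")], mean)
  }
  # reference gene must cover every sample cell
  cells <- unique(ct[c("genotype", "treatment", "replicate")])
  ref <- ct[ct$gene == reference_gene, ]
  got <- interaction(ref$genotype, ref$treatment, ref$replicate, drop = TRUE)
  want <- interaction(cells$genotype, cells$treatment, cells$replicate,
                      drop = TRUE)
  miss <- !as.character(want) %in% as.character(got)
  if (any(miss))
    stop("reference gene '", reference_gene, "' missing in sample cell(s): ",
         paste(utils::head(as.character(want)[miss], 3), collapse = "; "))
  for (g in unique(ct$genotype)) {
    trt <- ct$treatment[ct$genotype == g]
    if (!all(c("CONTROL", "HEAT") %in% trt))
      stop("genotype '", g, "' lacks a control or heat replicate")
  }
  ct
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_gene - Ct_reference`.  Per genotype and gene, the
#' baseline is the mean control-replicate dCt (replicates are not paired in
#' the design).  Each heat replicate then yields
#' `ratio = 2^-(dCt_heat - baseline)`.
#'
#' @param ct validated Ct table ([validate_ct_table()] is applied).
#' @param reference_gene housekeeping gene name.
#' @return `data.frame` with one row per (gene, genotype, heat replicate):
#'   `gene`, `genotype`, `class`, `replicate`, `ratio`, `log2_ratio`.
#' @export
relative_expression <- function(ct, reference_gene) {
  ct <- validate_ct_table(ct, reference_gene)
  ref <- ct[ct$gene == reference_gene,
            c("genotype", "treatment", "replicate", "ct")]
  names(ref)[4] <- "ref_ct"
  tg <- ct[ct$gene != reference_gene, ]
  if (!nrow(tg)) stop("no target genes in Ct table")
  tg <- merge(tg, ref, by = c("genotype", "treatment", "replicate"))
  tg$dct <- tg$ct - tg$ref_ct
  ctrl <- tg[tg$treatment == "CONTROL", ]
  base <- aggregate(ctrl["dct"], ctrl[c("gene", "genotype")], mean)
  names(base)[3] <- "base_dct"
  heat <- merge(tg[tg$treatment == "HEAT", ], base,
                by = c("gene", "genotype"))
  heat$log2_ratio <- -(heat$dct - heat$base_dct)
  heat$ratio <- 2^heat$log2_ratio
  out <- heat[order(heat$gene, heat$genotype, heat$replicate),
              c("gene", "genotype", "class", "replicate", "ratio",
                "log2_ratio")]
  rownames(out) <- NULL
  out
}

#' Per-class fold change and Log2FC
#'
#' Per genotype, FC is the arithmetic mean of replicate ratios; the class
#' FC is the mean of its genotype FCs.  The class Log2FC is the mean of
#' per-replicate log2 ratios over all genotypes and replicates of the
#' class -- so `FC` and `2^Log2FC` differ whenever replicates vary
#' (AM >= GM), which is the convention the bundled reference panel follows.
#'
#' @param ratios `data.frame` from [relative_expression()].
#' @return `data.frame` with one row per (gene, class): `gene`, `class`,
#'   `fc`, `log2fc`.
#' @export
class_fold_change <- function(ratios) {
  if (any(ratios$ratio <= 0))
    stop("non-positive expression ratio: corrupt input")
  geno <- aggregate(ratios["ratio"],
                    ratios[c("gene", "class", "genotype")], mean)
  fc <- aggregate(geno["ratio"], geno[c("gene", "class")], mean)
  names(fc)[3] <- "fc"
  lg <- aggregate(ratios["log2_ratio"], ratios[c("gene", "class")], mean)
  names(lg)[3] <- "log2fc"
  out <- merge(fc, lg, by = c("gene", "class"))
  out[order(out$gene, out$class), ]
}

#' Significance call from Log2FC
#'
#' `UP` when Log2FC >= 1, `DOWN` when <= -1 (boundaries inclusive),
#' `NS` otherwise.
#'
#' @param log2fc numeric vector.
#' @return Character vector of `"UP"`, `"DOWN"`, `"NS"`.
#' @export
significance <- function(log2fc) {
  stopifnot(all(is.finite(log2fc)))
  ifelse(log2fc >= 1, "UP", ifelse(log2fc <= -1, "DOWN", "NS"))
}

#' Regulation-pattern group (sign based)
#'
#' Group 1: up in tolerant, down in susceptible; Group 2: up in both;
#' Group 3: up in susceptible, down in tolerant; Group 4: down in both.
#' A Log2FC of exactly zero counts as up.
#'
#' @param log2fc_tol,log2fc_sus class Log2FC values (vectorised).
#' @return Integer vector in 1..4.
#' @export
classify_group <- function(log2fc_tol, log2fc_sus) {
  stopifnot(all(is.finite(log2fc_tol)), all(is.finite(log2fc_sus)))
  up_t <- log2fc_tol >= 0
  up_s <- log2fc_sus >= 0
  ifelse(up_t & !up_s, 1L,
         ifelse(up_t & up_s, 2L,
                ifelse(!up_t & up_s, 3L, 4L)))
}

.trait_one <- function(tol, sus) {
  tol_up <- tol >= 1; sus_down <- sus <= -1     # tolerance evidence
  tol_down <- tol <= -1; sus_up <- sus >= 1     # susceptibility evidence
  tol_ev <- tol_up + sus_down
  sus_ev <- tol_down + sus_up
  if (tol_ev > 0 && sus_ev > 0) return("neutral")
  if (tol_ev == 2) return("highly heat-tolerant")
  if (tol_ev == 1) {
    if (tol_up) return(if (sus < 0) "moderately highly heat-tolerant"
                       else "heat-tolerant")
    return("heat-tolerant")                     # via susceptible-DOWN
  }
  if (sus_ev == 2) return("highly heat-susceptible")
  if (sus_ev == 1) {
    if (tol_down) return(if (sus > 0) "moderately highly heat-susceptible"
                         else "heat-susceptible")
    return("heat-susceptible")                  # via susceptible-UP
  }
  "not-DE"
}

#' Heat-tolerance trait category from the Log2FC pair
#'
#' Categorises each gene by the strength and direction of the evidence in
#' the two genotype classes: significant up-regulation in the tolerant
#' class and significant down-regulation in the susceptible class each
#' count as tolerance evidence (mirrored for susceptibility).  Two pieces
#' of evidence give the "highly" category, one gives "moderately highly"
#' or plain depending on the other class's sign, conflicting evidence is
#' "neutral", and no evidence is "not-DE".  The rule is total over the
#' real plane.
#'
#' @inheritParams classify_group
#' @return Character vector of trait labels (see `TRAIT_LEVELS`).
#' @export
classify_trait <- function(log2fc_tol, log2fc_sus) {
  stopifnot(all(is.finite(log2fc_tol)), all(is.finite(log2fc_sus)))
  mapply(.trait_one, log2fc_tol, log2fc_sus, USE.NAMES = FALSE)
}

#' Full expression calls from a Log2FC table
#'
#' Adds significance, group and trait columns to a table of per-gene class
#' Log2FC values (and optional FC values) -- the entry point for desk
#' analysis of a published fold-change panel.
#'
#' @param df `data.frame` with columns `gene`, `log2fc_tolerant`,
#'   `log2fc_susceptible` (optionally `fc_tolerant`, `fc_susceptible`).
#' @return `df` with added `sig_tolerant`, `sig_susceptible`, `group`,
#'   `trait`.
#' @export
expression_calls <- function(df) {
  need <- c("gene", "log2fc_tolerant", "log2fc_susceptible")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  df$sig_tolerant <- significance(df$log2fc_tolerant)
  df$sig_susceptible <- significance(df$log2fc_susceptible)
  df$group <- classify_group(df$log2fc_tolerant, df$log2fc_susceptible)
  df$trait <- classify_trait(df$log2fc_tolerant, df$log2fc_susceptible)
  df
}

#' End-to-end qPCR expression analysis
#'
#' Ct table to trait categorisation: relative expression per replicate,
#' class fold changes, significance, group and trait per gene.
#'
#' @inheritParams relative_expression
#' @return `data.frame` with one row per gene: `gene`, `fc_tolerant`,
#'   `fc_susceptible`, `log2fc_tolerant`, `log2fc_susceptible`,
#'   `sig_tolerant`, `sig_susceptible`, `group`, `trait`.
#' @export
analyze_expression <- function(ct, reference_gene) {
  rel <- relative_expression(ct, reference_gene)
  cfc <- class_fold_change(rel)
  tol <- cfc[cfc$class == "TOLERANT", c("gene", "fc", "log2fc")]
  sus <- cfc[cfc$class == "SUSCEPTIBLE", c("gene", "fc", "log2fc")]
  names(tol)[2:3] <- c("fc_tolerant", "log2fc_tolerant")
  names(sus)[2:3] <- c("fc_susceptible", "log2fc_susceptible")
  res <- merge(tol, sus, by = "gene")
  res <- expression_calls(res)
  res <- res[order(res$gene), ]
  rownames(res) <- NULL
  gf_log("analyze_expression: %d genes", nrow(res))
  res
}

#' Regulation summary counts
#'
#' Per-class up/down/total counts, the union of differentially expressed
#' genes across classes, and per-trait tallies.
#'
#' @param results `data.frame` from [analyze_expression()] or
#'   [expression_calls()].
#' @return List with `up_tolerant`, `down_tolerant`, `total_tolerant`,
#'   `up_susceptible`, `down_susceptible`, `total_susceptible`, `n_deg`
#'   (union), `n_genes` and `trait_counts` (named vector over all trait
#'   levels).
#' @export
summarize_regulation <- function(results) {
  if (!nrow(results)) stop("no expression results to summarise")
  st <- results$sig_tolerant; ss <- results$sig_susceptible
  trait_counts <- table(factor(results$trait, levels = TRAIT_LEVELS))
  list(up_tolerant = sum(st == "UP"),
       down_tolerant = sum(st == "DOWN"),
       total_tolerant = sum(st != "NS"),
       up_susceptible = sum(ss == "UP"),
       down_susceptible = sum(ss == "DOWN"),
       total_susceptible = sum(ss != "NS"),
       n_deg = sum(st != "NS" | ss != "NS"),
       n_genes = nrow(results),
       trait_counts = trait_counts)
}

#' Bundled reference qPCR fold-change panel
#'
#' 18 differentially expressed wheat AP2/ERF genes measured in contrasting
#' heat-tolerant vs heat-susceptible genotypes, with the published mean FC,
#' Log2FC, trait category and regulation-pattern group.  Used in examples
#' and to validate [classify_trait()]/[classify_group()] against the
#' published calls.
#'
#' @param path optional path to an alternative panel TSV.
#' @return `data.frame` with columns `gene`, `family`, `fc_tolerant`,
#'   `fc_susceptible`, `log2fc_tolerant`, `log2fc_susceptible`, `trait`,
#'   `published_group`.
#' @export
read_reference_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "qpcr_heat_panel.tsv", package = "gfam")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
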