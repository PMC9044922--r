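.PHENO_COLS <- c("genotype", "class", "treatment", "replicate", "root_depth")

#' Read a root-depth phenotype table
#'
#' TSV with columns `genotype`, `class` (`TOLERANT`/`SUSCEPTIBLE`),
#' `treatment` (`CONTROL`/`HEAT`), `replicate`, `root_depth` (mm, >= 0).
#'
#' @param path TSV path.
#' @return Validated phenotype `data.frame`.
#' @export
read_phenotype_table <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  validate_phenotype(rec)
}

#' @rdname read_phenotype_table
#' @param records phenotype `data.frame` in memory.
#' @export
validate_phenotype <- function(records) {
  miss <- setdiff(.PHENO_COLS, names(records))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  records$class <- toupper(records$class)
  records$treatment <- toupper(records$treatment)
  if (!all(records$class %in% c("TOLERANT", "SUSCEPTIBLE")))
    stop("class must be TOLERANT or SUSCEPTIBLE")
  if (!all(records$treatment %in% c("CONTROL", "HEAT")))
    stop("treatment must be CONTROL or HEAT")
  if (any(records$root_depth < 0)) stop("negative root depth")
  for (g in unique(records$genotype)) {
    trt <- records$treatment[records$genotype == g]
    if (!all(c("CONTROL", "HEAT") %in% trt))
      stop("genotype '", g, "' lacks a control or heat replicate")
  }
  records
}

#' Heat damage index per genotype and per class
#'
#' Defined here as the relative root-depth reduction under heat:
#' `HDI = 100 * (mean control depth - mean heat depth) / mean control
#' depth`, averaged over member genotypes for the class value.  The index
#' is unitless, so rescaling all depths leaves it unchanged.
#'
#' @param records phenotype `data.frame` (validated on entry).
#' @return List with `genotype` (`genotype`, `class`, `hdi`) and `class`
#'   (`class`, `hdi`) data frames.
#' @export
heat_damage_index <- function(records) {
  records <- validate_phenotype(records)
  mean_depth <- aggregate(records["root_depth"],
                          records[c("genotype", "class", "treatment")],
                          mean)
  ctrl <- mean_depth[mean_depth$treatment == "CONTROL", ]
  heat <- mean_depth[mean_depth$treatment == "HEAT", ]
  names(ctrl)[4] <- "ctrl"; names(heat)[4] <- "heat"
  per_gen <- merge(ctrl[c("genotype", "class", "ctrl")],
                   heat[c("genotype", "class", "heat")],
                   by = c("genotype", "class"))
  if (any(per_gen$ctrl == 0))
    stop("zero mean control depth for genotype '",
         per_gen$genotype[per_gen$ctrl == 0][1], "'")
  per_gen$hdi <- 100 * (per_gen$ctrl - per_gen$heat) / per_gen$ctrl
  per_class <- aggregate(per_gen["hdi"], per_gen["class"], mean)
  list(genotype = per_gen[c("genotype", "class", "hdi")],
       class = per_class)
}

#' Replicate-level heat damage index values
#'
#' One HDI value per heat replicate (against the genotype's mean control
#' depth), the unit of observation for the class comparison.
#'
#' @inheritParams heat_damage_index
#' @return `data.frame` with `genotype`, `class`, `replicate`, `hdi`.
#' @export
hdi_replicates <- function(records) {
  records <- validate_phenotype(records)
  ctrl <- aggregate(records[records$treatment == "CONTROL", "root_depth",
                            drop = FALSE],
                    records[records$treatment == "CONTROL",
                            c("genotype"), drop = FALSE], mean)
  names(ctrl)[2] <- "ctrl"
  if (any(ctrl$ctrl == 0))
    stop("zero mean control depth for genotype '",
         ctrl$genotype[ctrl$ctrl == 0][1], "'")
  heat <- records[records$treatment == "HEAT", ]
  heat <- merge(heat, ctrl, by = "genotype")
  heat$hdi <- 100 * (heat$ctrl - heat$root_depth) / heat$ctrl
  out <- heat[order(heat$genotype, heat$replicate),
              c("genotype", "class", "replicate", "hdi")]
  rownames(out) <- NULL
  out
}

#' Welch comparison of HDI between tolerance classes
#'
#' Two-sided Welch t-test (Satterthwaite degrees of freedom) of HDI values
#' between the tolerant and susceptible classes.  When both classes have
#' zero variance the p-value is 1 for equal means and 0 otherwise.
#'
#' @param hdi `data.frame` with columns `class` and `hdi` (e.g. from
#'   [hdi_replicates()]); each class needs >= 2 values.
#' @return List with `difference` (susceptible minus tolerant mean),
#'   `statistic`, `df`, `p_value`.
#' @export
compare_classes <- function(hdi) {
  x <- hdi$hdi[toupper(hdi$class) == "SUSCEPTIBLE"]
  y <- hdi$hdi[toupper(hdi$class) == "TOLERANT"]
  if (length(x) < 2 || length(y) < 2)
    stop("each class needs at least 2 values")
  diff <- mean(x) - mean(y)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(difference = diff, statistic = NA_real_, df = NA_real_,
                p_value = if (diff == 0) 1 else 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(difference = diff,
       statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value)
}
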