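#' Derive a named RNG substream seed
#'
#' A single root seed fans out to one deterministic seed per generator, so
#' adding a generator never perturbs the fixtures of another.  Derived
#' seeds stay below 2^31.
#'
#' @param seed root integer seed.
#' @param stream generator name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1000003 * 1009 + h) %% 2147483647)
}

.random_aa <- function(n) paste(sample(AA_ORDER, n, replace = TRUE),
                                collapse = "")

#' Plant residue overrides into a domain consensus
#'
#' Returns the consensus with positions 14/19 and the WLG triple replaced,
#' used to synthesise DREB-like (V14/E19), ERF-like (A14/D19) and
#' non-canonical domain copies.
#'
#' @param consensus domain consensus string.
#' @param r14,r19 residues for columns 14 and 19 (`NULL` keeps consensus).
#' @param wlg 3-character replacement for the WLG triple (`NULL` keeps).
#' @param wlg_cols columns of the WLG triple.
#' @return Modified domain string.
#' @export
plant_domain <- function(consensus, r14 = NULL, r19 = NULL, wlg = NULL,
                         wlg_cols = 30:32) {
  s <- strsplit(consensus, "")[[1]]
  if (!is.null(r14)) s[14] <- r14
  if (!is.null(r19)) s[19] <- r19
  if (!is.null(wlg)) s[wlg_cols] <- strsplit(wlg, "")[[1]]
  paste(s, collapse = "")
}

# background flank that triggers no domain hit at the default thresholds
.clean_flank <- function(n, profiles) {
  for (try in 1:50) {
    fl <- .random_aa(n)
    hits <- scan_domains(fl, profiles)
    if (nrow(hits) == 0) return(fl)
  }
  stop("could not generate a domain-free background flank")
}

#' Generate a synthetic proteome with planted domains
#'
#' Builds proteins from random background flanks plus planted domain
#' copies: DREB members carry an AP2 domain with V14/E19, ERF members
#' A14/D19, "other" members a non-diagnostic pair (G14/G19), AP2-family
#' members two AP2 copies, RAV members one AP2 plus one B3, and decoys no
#' domain at all.  Backgrounds are rejection-sampled to be free of
#' accidental domain hits, so zero-noise recovery by the classifier is
#' exact rather than probabilistic.
#'
#' @param n_per_family named counts: `DREB`, `ERF`, `AP2`, `RAV`, `other`,
#'   `decoy` (missing names count as 0).
#' @param seed root seed.
#' @param flank_range min/max background flank length (aa).
#' @param wlg_pool WLG triples sampled for ERF_DREB members (default the
#'   canonical `"WLG"`; supply variants such as `"WIG"` to plant them).
#' @param profiles profiles used for the rejection scan (and the expected
#'   downstream classifier).
#' @return List with `proteins` (`AAStringSet`) and `truth`, a list of
#'   `families` (expected classification per protein) and `domains`
#'   (planted (protein, domain, offset, r14, r19, wlg) records).
#' @export
generate_proteome <- function(n_per_family = c(DREB = 5, ERF = 5, AP2 = 2,
                                               RAV = 2, other = 1,
                                               decoy = 5),
                              seed = 1, flank_range = c(40, 80),
                              wlg_pool = "WLG",
                              profiles = default_profiles()) {
  set.seed(derive_seed(seed, "proteome"))
  get_n <- function(k) if (k %in% names(n_per_family)) n_per_family[[k]] else 0
  plan <- c(rep("DREB", get_n("DREB")), rep("ERF", get_n("ERF")),
            rep("AP2", get_n("AP2")), rep("RAV", get_n("RAV")),
            rep("other", get_n("other")), rep("decoy", get_n("decoy")))
  proteins <- character(length(plan))
  fam_rows <- vector("list", length(plan))
  dom_rows <- list()
  flank <- function() sample(flank_range[1]:flank_range[2], 1)
  for (i in seq_along(plan)) {
    id <- sprintf("SYNP%04d", i)
    kind <- plan[i]
    parts <- .clean_flank(flank(), profiles)
    doms <- list()
    add_dom <- function(domain, seqs, r14, r19, wlg) {
      offset <- nchar(paste(seqs, collapse = ""))
      list(domain = domain, offset = offset, r14 = r14, r19 = r19,
           wlg = wlg)
    }
    if (kind %in% c("DREB", "ERF", "other")) {
      rr <- switch(kind, DREB = c("V", "E"), ERF = c("A", "D"),
                   other = c("G", "G"))
      wlg <- if (kind == "other") "WLG" else sample(wlg_pool, 1)
      doms[[1]] <- add_dom("AP2", parts, rr[1], rr[2], wlg)
      parts <- c(parts, plant_domain(AP2_CONSENSUS, rr[1], rr[2], wlg),
                 .clean_flank(flank(), profiles))
    } else if (kind == "AP2") {
      for (cpy in 1:2) {
        doms[[cpy]] <- add_dom("AP2", parts, "V", "E", "WLG")
        parts <- c(parts, AP2_CONSENSUS, .clean_flank(flank(), profiles))
      }
    } else if (kind == "RAV") {
      doms[[1]] <- add_dom("AP2", parts, "V", "E", "WLG")
      parts <- c(parts, AP2_CONSENSUS, .clean_flank(flank(), profiles))
      doms[[2]] <- add_dom("B3", parts, NA, NA, NA)
      parts <- c(parts, B3_CONSENSUS, .clean_flank(flank(), profiles))
    }
    prot <- paste(parts, collapse = "")
    # closed-loop rejection: the scan must recover exactly the planted set
    hits <- scan_domains(prot, profiles, protein_id = id)
    planted_ok <- nrow(hits) == length(doms) &&
      (length(doms) == 0 ||
         all(hits$domain == vapply(doms, `[[`, "", "domain")) &&
         all(hits$start == vapply(doms, `[[`, 0, "offset")))
    if (!planted_ok) stop("planted-domain self-check failed for ", id)
    proteins[i] <- prot
    family <- switch(kind, DREB = "ERF_DREB", ERF = "ERF_DREB",
                     other = "ERF_DREB", AP2 = "AP2", RAV = "RAV",
                     decoy = "DISCARDED")
    subfam <- switch(kind, DREB = "DREB", ERF = "ERF", other = "OTHER",
                     NA_character_)
    fam_rows[[i]] <- data.frame(protein_id = id, family = family,
                                subfamily = subfam, stringsAsFactors = FALSE)
    for (d in doms)
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        protein_id = id, domain = d$domain, offset = d$offset,
        r14 = d$r14, r19 = d$r19, wlg = d$wlg, stringsAsFactors = FALSE)
  }
  names(proteins) <- sprintf("SYNP%04d", seq_along(plan))
  truth <- list(
    families = if (length(fam_rows)) do.call(rbind, fam_rows)
               else data.frame(),
    domains = if (length(dom_rows)) do.call(rbind, dom_rows)
              else data.frame())
  gf_log("generate_proteome: %d proteins (%d with domains)",
         length(proteins), nrow(truth$domains))
  list(proteins = Biostrings::AAStringSet(proteins), truth = truth)
}

.mutate_protein <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  k <- round(rate * length(s))
  if (k == 0) return(seq)
  pos <- sample(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(AA_ORDER, s[p]), 1)
  paste(s, collapse = "")
}

WHEAT_CHROMOSOMES <- paste0(rep(1:7, each = 3), c("A", "B", "D"))

#' Generate gene loci with planted duplicate pairs
#'
#' Duplicate pairs are sequence copies with `round(rate * length)` distinct
#' substituted sites, so pairwise identity is `100 * (1 - rate)` percent by
#' construction.  Tandem pairs sit consecutively on one chromosome with a
#' gap below 100 kb; other segmental pairs are split across chromosomes.
#' Remaining genes are unrelated singletons.  Genes are laid out with wide
#' spacing so no third gene falls between a tandem pair.
#'
#' @param n_singletons unrelated background genes.
#' @param n_segmental total duplicate pairs (including tandem ones).
#' @param n_tandem tandem pairs (`<= n_segmental`).
#' @param mutation_rate per-site substitution fraction within a pair.
#' @param seed root seed.
#' @param protein_length length of the synthetic proteins (aa).
#' @param tandem_gap fixed tandem gap in bp, or `NULL` to draw one from
#'   1-80 kb.
#' @return List with `proteins` (`AAStringSet`), `loci` (data frame in the
#'   internal 0-based convention) and `truth` (`pairs` data frame with
#'   `id_a`, `id_b`, `type`, `mutation_rate`, `distance_bp`).
#' @export
generate_loci_with_duplicates <- function(n_singletons = 8,
                                          n_segmental = 3, n_tandem = 1,
                                          mutation_rate = 0.05, seed = 1,
                                          protein_length = 300,
                                          tandem_gap = NULL) {
  if (n_tandem > n_segmental) stop("n_tandem must be <= n_segmental")
  set.seed(derive_seed(seed, "duplicates"))
  ids <- character(0); seqs <- character(0)
  chrom <- character(0); starts <- numeric(0); ends <- numeric(0)
  cursor <- setNames(rep(1e5, 21), WHEAT_CHROMOSOMES)
  gene_len <- 3 * protein_length
  pairs <- list()
  chr_cycle <- rep(WHEAT_CHROMOSOMES, length.out = max(n_segmental * 2, 1))
  ci <- 1
  next_chr <- function() { ch <- chr_cycle[ci]; ci <<- ci + 1; ch }
  add_gene <- function(id, seq, chr, start) {
    ids <<- c(ids, id); seqs <<- c(seqs, seq)
    chrom <<- c(chrom, chr); starts <<- c(starts, start)
    ends <<- c(ends, start + gene_len)
    cursor[chr] <<- max(cursor[chr], start + gene_len) + 250000
  }
  for (k in seq_len(n_segmental)) {
    a <- .random_aa(protein_length)
    b <- .mutate_protein(a, mutation_rate)
    ida <- sprintf("DUP%02dA", k); idb <- sprintf("DUP%02dB", k)
    if (k <= n_tandem) {
      ch <- next_chr()
      gap <- if (is.null(tandem_gap)) sample(1000:80000, 1) else tandem_gap
      s1 <- cursor[[ch]]
      add_gene(ida, a, ch, s1)
      add_gene(idb, b, ch, s1 + gene_len + gap)
      pairs[[k]] <- data.frame(id_a = ida, id_b = idb, type = "TANDEM",
                               mutation_rate = mutation_rate,
                               distance_bp = gap, stringsAsFactors = FALSE)
    } else {
      ch1 <- next_chr(); ch2 <- next_chr()
      if (ch2 == ch1) ch2 <- next_chr()
      add_gene(ida, a, ch1, cursor[[ch1]])
      add_gene(idb, b, ch2, cursor[[ch2]])
      pairs[[k]] <- data.frame(id_a = ida, id_b = idb, type = "SEGMENTAL",
                               mutation_rate = mutation_rate,
                               distance_bp = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(n_singletons)) {
    ch <- sample(WHEAT_CHROMOSOMES, 1)
    add_gene(sprintf("SGL%03d", k), .random_aa(protein_length), ch,
             cursor[[ch]])
  }
  loci <- data.frame(gene_id = ids, chromosome = chrom, start = starts,
                     end = ends, strand = "+", stringsAsFactors = FALSE)
  loci$exons <- lapply(seq_len(nrow(loci)), function(i)
    cbind(start = loci$start[i], end = loci$end[i]))
  truth <- list(pairs = if (length(pairs)) do.call(rbind, pairs)
                        else data.frame())
  gf_log("generate_loci_with_duplicates: %d genes, %d pairs (%d tandem)",
         nrow(loci), n_segmental, n_tandem)
  list(proteins = Biostrings::AAStringSet(setNames(seqs, ids)),
       loci = loci, truth = truth)
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

.instantiate_iupac <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]],
               function(cc) {
                 set <- IUPAC_SETS[[cc]]
                 if (is.null(set)) stop("bad IUPAC code: ", cc)
                 if (length(set) == 1) set else sample(set, 1)
               }, character(1)), collapse = "")
}

#' Generate promoters with planted motif occurrences
#'
#' 2-kb promoters with a requested number of occurrences per catalog
#' motif.  The background is iteratively repaired until the catalog scan
#' reports no hit outside a planted instance, so planted counts are
#' recovered exactly by [scan_promoters()] (palindromic consensi yield one
#' hit per strand at the planted offset; the truth table records final
#' attributable hit counts).
#'
#' @param n number of promoters.
#' @param motif_plan named integer vector: occurrences per motif planted
#'   in *each* promoter.
#' @param seed root seed.
#' @param width promoter length in bp.
#' @param catalog CRE catalog used for planting and cleaning.
#' @param max_iter repair iterations before giving up.
#' @return List with `promoters` (`DNAStringSet`) and `truth`: `counts`
#'   (promoter, motif, expected hit count) and `placements` (promoter,
#'   motif, offset, instance).
#' @export
generate_promoters <- function(n = 4, motif_plan = c(`CAAT-box` = 2),
                               seed = 1, width = 2000,
                               catalog = read_cre_catalog(),
                               max_iter = 100) {
  set.seed(derive_seed(seed, "promoters"))
  motif_plan <- motif_plan[motif_plan > 0]
  unknown <- setdiff(names(motif_plan), catalog$name)
  if (length(unknown)) stop("plan names unknown motif(s): ",
                            paste(unknown, collapse = ", "))
  margin <- max(c(4, nchar(catalog$consensus)))
  proms <- character(n)
  placements <- list()
  count_rows <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("PROM%03d", i)
    x <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    intervals <- matrix(numeric(0), ncol = 2)   # 0-based half-open
    # plant instances
    for (m in names(motif_plan)) {
      cons <- catalog$consensus[catalog$name == m]
      ml <- nchar(cons)
      for (r in seq_len(motif_plan[[m]])) {
        placed <- FALSE
        for (try in 1:2000) {
          off <- sample.int(width - ml + 1, 1) - 1L
          if (nrow(intervals) == 0 ||
              all(off >= intervals[, 2] + margin |
                  off + ml <= intervals[, 1] - margin)) {
            inst <- .instantiate_iupac(cons)
            x[(off + 1):(off + ml)] <- strsplit(inst, "")[[1]]
            intervals <- rbind(intervals, c(off, off + ml))
            placements[[length(placements) + 1L]] <- data.frame(
              promoter = pid, motif = m, offset = off, instance = inst,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("cannot place requested motifs without overlap")
      }
    }
    # repair background until every scan hit is inside a planted instance
    planted_pos <- if (nrow(intervals))
      unlist(lapply(seq_len(nrow(intervals)),
                    function(k) (intervals[k, 1] + 1):intervals[k, 2]))
    else integer(0)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      hits <- scan_promoter(paste(x, collapse = ""), catalog, gene_id = pid)
      hl <- nchar(catalog$consensus)[match(hits$motif, catalog$name)]
      inside <- vapply(seq_len(nrow(hits)), function(k) {
        nrow(intervals) > 0 &&
          any(hits$position[k] >= intervals[, 1] &
              hits$position[k] + hl[k] <= intervals[, 2])
      }, logical(1))
      if (all(inside)) { ok <- TRUE; break }
      bad <- which(!inside)
      for (k in bad) {
        span <- (hits$position[k] + 1):(hits$position[k] + hl[k])
        span <- setdiff(span, planted_pos)
        x[span] <- sample(c("A", "C", "G", "T"), length(span),
                          replace = TRUE)
      }
    }
    if (!ok) stop("promoter background repair did not converge")
    proms[i] <- paste(x, collapse = "")
    cnt <- table(hits$motif)
    if (length(cnt))
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        promoter = pid, motif = names(cnt), count = as.integer(cnt),
        stringsAsFactors = FALSE)
  }
  names(proms) <- sprintf("PROM%03d", seq_len(n))
  truth <- list(
    counts = if (length(count_rows)) do.call(rbind, count_rows)
             else data.frame(promoter = character(0), motif = character(0),
                             count = integer(0)),
    placements = if (length(placements)) do.call(rbind, placements)
                 else data.frame())
  gf_log("generate_promoters: %d promoters of %d bp", n, width)
  list(promoters = Biostrings::DNAStringSet(proms), truth = truth)
}

#' Generate a qPCR Ct table with planted class effects
#'
#' Emulates the contrasting-genotype heat-stress design: 2 tolerant + 2
#' susceptible genotypes x 2 treatments x `n_reps` replicates.  The
#' reference gene is constant at `reference_ct`; per gene and genotype a
#' control dCt is drawn once, and each heat replicate's dCt equals the
#' control dCt minus the planted class Log2FC plus `Normal(0, noise_sd)`.
#' At zero noise the analysis recovers the planted Log2FC exactly.
#'
#' @param effects `data.frame` with `gene`, `log2fc_tolerant`,
#'   `log2fc_susceptible`.
#' @param noise_sd replicate noise on heat dCt, in cycles.
#' @param seed root seed.
#' @param genotypes named character vector mapping genotype name to class.
#' @param n_reps biological replicates per treatment.
#' @param reference_gene,reference_ct housekeeping gene name and its Ct.
#' @return List with `ct` (Ct `data.frame`) and `truth` (the `effects`).
#' @export
generate_ct_table <- function(effects, noise_sd = 0, seed = 1,
                              genotypes = c(Perenjori = "TOLERANT",
                                            W156 = "TOLERANT",
                                            Brazil32 = "SUSCEPTIBLE",
                                            Yitpi = "SUSCEPTIBLE"),
                              n_reps = 3,
                              reference_gene = "beta_actin",
                              reference_ct = 20) {
  stopifnot(all(c("gene", "log2fc_tolerant", "log2fc_susceptible") %in%
                  names(effects)))
  set.seed(derive_seed(seed, "ct_table"))
  rows <- list()
  for (g in names(genotypes)) {
    cls <- genotypes[[g]]
    for (gene_i in seq_len(nrow(effects))) {
      gene <- effects$gene[gene_i]
      eff <- if (cls == "TOLERANT") effects$log2fc_tolerant[gene_i]
             else effects$log2fc_susceptible[gene_i]
      ctrl_dct <- runif(1, 2, 8)
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, class = cls, treatment = "CONTROL", replicate = r,
          gene = gene, ct = reference_ct + ctrl_dct,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, class = cls, treatment = "HEAT", replicate = r,
          gene = gene,
          ct = reference_ct + ctrl_dct - eff + rnorm(1, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    # reference gene rows for every cell
    for (trt in c("CONTROL", "HEAT")) {
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, class = cls, treatment = trt, replicate = r,
          gene = reference_gene, ct = reference_ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  ct <- do.call(rbind, rows)
  gf_log("generate_ct_table: %d rows, %d genes", nrow(ct), nrow(effects))
  list(ct = ct, truth = effects)
}

#' Generate root-depth phenotype records with planted class HDI
#'
#' Control depths centre on `control_depth` (100 mm by default); heat
#' depths are scaled by `1 - HDI/100` for the genotype's class, plus
#' replicate noise.  At zero noise [heat_damage_index()] recovers the
#' planted class values exactly.
#'
#' @param class_hdi named vector (`TOLERANT`, `SUSCEPTIBLE`) of heat
#'   damage indices in `[0, 100)`.
#' @param noise_sd replicate noise in mm.
#' @param seed root seed.
#' @param n_genotypes_per_class,n_reps design size.
#' @param control_depth mean control root depth in mm.
#' @return List with `records` (phenotype `data.frame`) and `truth`.
#' @export
generate_root_depths <- function(class_hdi = c(TOLERANT = 30,
                                               SUSCEPTIBLE = 65),
                                 noise_sd = 0, seed = 1,
                                 n_genotypes_per_class = 2, n_reps = 3,
                                 control_depth = 100) {
  stopifnot(all(class_hdi >= 0 & class_hdi < 100))
  set.seed(derive_seed(seed, "root_depths"))
  rows <- list()
  for (cls in names(class_hdi)) {
    for (g in seq_len(n_genotypes_per_class)) {
      gid <- sprintf("%s%d", substr(cls, 1, 3), g)
      for (r in seq_len(n_reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = gid, class = cls, treatment = "CONTROL",
          replicate = r,
          root_depth = control_depth + rnorm(1, 0, noise_sd),
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = gid, class = cls, treatment = "HEAT", replicate = r,
          root_depth = control_depth * (1 - class_hdi[[cls]] / 100) +
            rnorm(1, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- do.call(rbind, rows)
  gf_log("generate_root_depths: %d records", nrow(rec))
  list(records = rec, truth = data.frame(class = names(class_hdi),
                                         hdi = unname(class_hdi)))
}
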