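profiles <- default_profiles()
ap2 <- gfam:::AP2_CONSENSUS
b3 <- gfam:::B3_CONSENSUS

test_that("profile scan recovers planted domains at exact offsets", {
  set.seed(101)
  # null case: random sequence, no planted domain
  expect_equal(nrow(scan_domains(random_peptide(200), profiles)), 0L)

  flank <- random_peptide(50)
  hit <- scan_domains(paste0(flank, ap2, random_peptide(50)), profiles)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$domain, "AP2")
  expect_equal(hit$start, 50L)
  expect_equal(hit$end, 50L + nchar(ap2))
  expect_equal(hit$domain_sequence, ap2)

  two <- scan_domains(paste0(random_peptide(40), ap2, random_peptide(30),
                             b3, random_peptide(40)), profiles)
  expect_equal(two$domain, c("AP2", "B3"))
  expect_equal(two$start, c(40L, 40L + nchar(ap2) + 30L))

  # too-short protein: empty result, no error
  expect_equal(nrow(scan_domains(random_peptide(20), profiles)), 0L)
})

test_that("raising the score threshold never increases hit count", {
  set.seed(77)
  seqs <- replicate(10, paste0(random_peptide(30),
                               plant_domain(ap2, sample(AA20, 1),
                                            sample(AA20, 1)),
                               random_peptide(30)))
  for (thr in list(c(20, 60), c(60, 100), c(100, 130))) {
    lo <- build_domain_profile("AP2", ap2, score_threshold = thr[1],
                               res14_col = 14, res19_col = 19,
                               wlg_cols = 30:32)
    hi <- build_domain_profile("AP2", ap2, score_threshold = thr[2],
                               res14_col = 14, res19_col = 19,
                               wlg_cols = 30:32)
    n_lo <- sum(vapply(seqs, function(s)
      nrow(scan_domains(s, list(AP2 = lo))), numeric(1)))
    n_hi <- sum(vapply(seqs, function(s)
      nrow(scan_domains(s, list(AP2 = hi))), numeric(1)))
    expect_gte(n_lo, n_hi)
  }
})

test_that("family rule maps domain architecture per the classification flowchart", {
  mk <- function(domains) data.frame(domain = domains)
  expect_equal(classify_family(mk("AP2")), "ERF_DREB")
  expect_equal(classify_family(mk(c("AP2", "AP2"))), "AP2")
  expect_equal(classify_family(mk(c("AP2", "B3"))), "RAV")
  expect_equal(classify_family(mk(character(0))), "DISCARDED")
  expect_equal(classify_family(mk("B3")), "DISCARDED")
  expect_warning(out <- classify_family(mk(c("AP2", "AP2", "B3"))),
                 "architecture")
  expect_equal(out, "DISCARDED")
})

subfam_of <- function(r14, r19) {
  hit <- scan_domains(plant_domain(ap2, r14, r19), profiles)
  expect_equal(nrow(hit), 1L)
  as.character(classify_subfamily(hit[1, ], profiles$AP2))
}

test_that("sub-family rule is total and deterministic over all residue pairs", {
  # canonical assignments
  expect_equal(subfam_of("V", "E"), "DREB")
  expect_equal(subfam_of("A", "D"), "ERF")
  expect_equal(subfam_of("G", "G"), "OTHER")
  expect_equal(subfam_of("A", "E"), "OTHER")  # one residue each: conflict
  expect_equal(subfam_of("V", "D"), "OTHER")
  # single-evidence cases
  expect_equal(subfam_of("V", "G"), "DREB")
  expect_equal(subfam_of("G", "E"), "DREB")
  expect_equal(subfam_of("A", "G"), "ERF")
  expect_equal(subfam_of("G", "D"), "ERF")
  # exhaustive: exactly one label per ordered pair, consistent with the rule
  for (r14 in AA20) {
    for (r19 in AA20) {
      dreb <- (r14 == "V") + (r19 == "E")
      erf <- (r14 == "A") + (r19 == "D")
      want <- if (dreb > erf) "DREB" else if (erf > dreb) "ERF" else "OTHER"
      hit <- data.frame(protein_id = "x", domain = "AP2", start = 0L,
                        end = 60L, score = 120)
      pr <- rep("-", 60); pr[14] <- r14; pr[19] <- r19
      hit$profile_residues <- list(pr)
      expect_equal(as.character(classify_subfamily(hit, profiles$AP2)), want)
    }
  }
})

test_that("WLG variants and gaps are reported from the profile columns", {
  hit <- scan_domains(ap2, profiles)
  expect_equal(wlg_variant(hit[1, ], profiles$AP2), "WLG")
  hit2 <- scan_domains(plant_domain(ap2, wlg = "WIG"), profiles)
  expect_equal(wlg_variant(hit2[1, ], profiles$AP2), "WIG")
  # gap rendering: construct a hit with the middle WLG column unaligned
  hit3 <- hit[1, ]
  pr <- hit3$profile_residues[[1]]
  pr[31] <- "-"
  hit3$profile_residues <- list(pr)
  expect_equal(wlg_variant(hit3, profiles$AP2), "W-G")
})

test_that("proteome classification partitions every protein exactly once", {
  g <- generate_proteome(c(DREB = 4, ERF = 4, AP2 = 2, RAV = 2, other = 2,
                           decoy = 4), seed = 19)
  cls <- classify_proteome(g$proteins)
  expect_equal(nrow(cls), length(g$proteins))
  expect_true(all(cls$family %in% c("ERF_DREB", "AP2", "RAV", "DISCARDED")))
  expect_equal(sum(table(cls$family)), length(g$proteins))
  # planted-truth recovery, including sub-family and WLG
  expect_equal(cls$family, g$truth$families$family)
  expect_equal(cls$subfamily, g$truth$families$subfamily)
  erf_dreb <- cls$family == "ERF_DREB"
  expect_true(all(cls$wlg[erf_dreb] == "WLG"))
  expect_equal(cls$n_AP2[cls$family == "AP2"], c(2L, 2L))
  expect_equal(cls$n_B3[cls$family == "RAV"], c(1L, 1L))
})

test_that("profile TSV round-trips through write/read", {
  f <- tempfile(fileext = ".tsv")
  write_profile_tsv(profiles$AP2, f)
  back <- read_profile_tsv(f)
  expect_equal(back$name, "AP2")
  expect_equal(back$length, profiles$AP2$length)
  expect_equal(back$consensus, profiles$AP2$consensus)
  expect_equal(back$scores, profiles$AP2$scores)
  expect_equal(back$score_threshold, profiles$AP2$score_threshold)
  expect_equal(back$wlg_cols, 30:32)
  expect_error(read_profile_tsv(write_tmp(c("not a profile", "x"))), "v1")
})
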