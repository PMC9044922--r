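test_that("FASTA reading handles single, wrapped and duplicate records", {
  f <- write_tmp(c(">g1", "MKV"), ".fa")
  recs <- read_fasta(f)
  expect_equal(length(recs), 1L)
  expect_equal(names(recs), "g1")
  expect_equal(as.character(recs[["g1"]]), "MKV")

  f2 <- write_tmp(c(">g1 descr", "MK", "VR", "ND", ">g2", "arnd"), ".fa")
  recs2 <- read_fasta(f2)
  expect_equal(length(recs2), 2L)
  expect_equal(as.character(recs2[["g1"]]), "MKVRND")
  expect_equal(as.character(recs2[["g2"]]), "ARND")  # uppercased

  f3 <- write_tmp(c(">g1", "MKV", ">g1", "MKT"), ".fa")
  expect_error(read_fasta(f3), "g1")

  f4 <- tempfile(fileext = ".fa")
  file.create(f4)
  expect_warning(recs4 <- read_fasta(f4), "empty")
  expect_equal(length(recs4), 0L)
})

test_that("FASTA round-trip preserves ids and sequences", {
  set.seed(11)
  seqs <- setNames(vapply(1:5, function(i) random_peptide(30 + i),
                          character(1)),
                   paste0("p", 1:5))
  f <- tempfile(fileext = ".fa")
  write_fasta(seqs, f, width = 17)  # force wrapping
  back <- read_fasta(f)
  expect_equal(names(back), names(seqs))
  expect_equal(as.character(back), seqs)
})

gff_lines <- function(rows) {
  c("##gff-version 3", rows)
}

test_that("GFF3 loci are built from mRNA + exons with boundary conversion", {
  f <- write_tmp(gff_lines(c(
    "1A\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=m1",
    "1A\tsrc\texon\t100\t200\t.\t+\t.\tParent=m1",
    "1A\tsrc\texon\t300\t400\t.\t+\t.\tParent=m1",
    "3B\tsrc\tmRNA\t50\t80\t.\t-\t.\tID=m2",
    "3B\tsrc\texon\t50\t80\t.\t-\t.\tParent=m2")), ".gff3")
  loci <- read_gff3_genes(f)
  expect_equal(nrow(loci), 2L)
  m1 <- loci[loci$gene_id == "m1", ]
  expect_equal(m1$start, 99)        # 0-based half-open internally
  expect_equal(m1$end, 400)
  expect_equal(nrow(m1$exons[[1]]), 2L)
  expect_equal(unname(m1$exons[[1]][1, ]), c(99, 200))
  m2 <- loci[loci$gene_id == "m2", ]
  expect_equal(nrow(m2$exons[[1]]), 1L)
  expect_equal(m2$strand, "-")
})

test_that("GFF3 errors on exon outside parent and warns on orphan exons", {
  f <- write_tmp(gff_lines(c(
    "1A\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=m1",
    "1A\tsrc\texon\t500\t600\t.\t+\t.\tParent=m1")), ".gff3")
  expect_error(read_gff3_genes(f), "outside parent")

  f2 <- write_tmp(gff_lines(c(
    "1A\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=m1",
    "1A\tsrc\texon\t100\t400\t.\t+\t.\tParent=m1",
    "1A\tsrc\texon\t150\t220\t.\t+\t.\tID=orphan")), ".gff3")
  expect_warning(loci <- read_gff3_genes(f2), "Parent")
  expect_equal(nrow(loci$exons[[1]]), 1L)
})

test_that("GFF3 coordinate round-trip is the identity", {
  f <- write_tmp(gff_lines(c(
    "2D\tsrc\tmRNA\t1000\t2500\t.\t+\t.\tID=mA",
    "2D\tsrc\texon\t1000\t1400\t.\t+\t.\tParent=mA",
    "2D\tsrc\texon\t1800\t2500\t.\t+\t.\tParent=mA",
    "5B\tsrc\tmRNA\t7\t99\t.\t-\t.\tID=mB",
    "5B\tsrc\texon\t7\t99\t.\t-\t.\tParent=mB")), ".gff3")
  loci <- read_gff3_genes(f)
  out <- tempfile(fileext = ".gff3")
  write_gff3_genes(loci, out)
  back <- read_gff3_genes(out)
  back <- back[match(loci$gene_id, back$gene_id), ]
  expect_equal(back$start, loci$start)
  expect_equal(back$end, loci$end)
  expect_equal(back$chromosome, loci$chromosome)
  expect_equal(unname(back$exons[[1]]), unname(loci$exons[[1]]))
})

test_that("gene structure summary counts exons and introns", {
  mk_locus <- function(id, exons) {
    data.frame(gene_id = id, chromosome = "1A",
               start = min(exons[, 1]), end = max(exons[, 2]),
               strand = "+") |>
      (\(df) { df$exons <- list(exons); df })()
  }
  one <- mk_locus("a", cbind(start = 0, end = 100))
  expect_equal(gene_structure_summary(one)[, c("n_exons", "n_introns",
                                               "intronless")],
               data.frame(n_exons = 1L, n_introns = 0L, intronless = TRUE))
  four <- mk_locus("b", cbind(start = c(0, 20, 40, 60),
                              end = c(10, 30, 50, 70)))
  s4 <- gene_structure_summary(four)
  expect_equal(s4$n_introns, 3L)
  expect_false(s4$intronless)
  eleven <- mk_locus("c", cbind(start = seq(0, 200, 20),
                                end = seq(10, 210, 20)))
  s11 <- gene_structure_summary(eleven)
  expect_equal(s11$n_exons, 11L)
  expect_equal(s11$n_introns, 10L)   # matches the deepest intron count seen
})

test_that("chromosome distribution tallies per chromosome and sub-genome", {
  loci <- data.frame(chromosome = c("1A", "1A", "3B", "Un"))
  d <- chromosome_distribution(loci)
  expect_equal(d$chromosome$count[d$chromosome$chromosome == "1A"], 2L)
  expect_equal(d$subgenome$count[d$subgenome$subgenome == "A"], 2L)
  expect_equal(d$subgenome$count[d$subgenome$subgenome == "Un"], 1L)

  expect_equal(chromosome_distribution(data.frame(chromosome = character(0)))$n,
               0L)

  set.seed(5)
  labs <- c(sample(paste0(1:7, "A"), 4, TRUE), sample(paste0(1:7, "B"), 3, TRUE),
            sample(paste0(1:7, "D"), 3, TRUE))
  d2 <- chromosome_distribution(data.frame(chromosome = labs))
  expect_equal(d2$subgenome$count[match(c("A", "B", "D"),
                                        d2$subgenome$subgenome)],
               c(4L, 3L, 3L))
  expect_equal(sum(d2$chromosome$count), 10L)  # conservation

  expect_warning(d3 <- chromosome_distribution(data.frame(
    chromosome = c("1A", "chrX"))), "Un")
  expect_equal(sum(d3$chromosome$count), 2L)
})
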