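test_that("bed decoding matches bytes frozen from the 2-bit format", {
  # 2 subjects x 3 SNPs, SNP-major, lowest bits = first subject.
  # SNP1: subj1 hom A1 (00), subj2 hom A2 (11)      -> byte 0x0C
  # SNP2: both het (10)                             -> byte 0x0A
  # SNP3: subj1 missing (01), subj2 hom A1 (00)     -> byte 0x01
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "frozen")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x0c, 0x0a, 0x01)),
           paste0(prefix, ".bed"))
  writeLines(c("s1\ts1\t0\t0\t0\t-9", "s2\ts2\t0\t0\t0\t-9"),
             paste0(prefix, ".fam"))
  writeLines(c("1\trs1\t0\t100\tA\tG",
               "1\trs2\t0\t200\tC\tT",
               "2\trs3\t0\t300\tG\tA"), paste0(prefix, ".bim"))
  raw <- read_plink(prefix)
  expect_equal(unname(raw$g), rbind(c(2L, 1L, NA), c(0L, 1L, 2L)))
  expect_equal(raw$subject_ids, c("s1", "s2"))
  expect_equal(raw$variants$a1, c("A", "C", "G"))
})

test_that("PLINK write/read round trip is exact, including missing calls", {
  withr::local_seed(31)
  dir <- withr::local_tempdir()
  for (n in c(3L, 4L, 7L)) {  # exercise byte padding at n %% 4 = 3, 0, 3
    m <- 23L
    g <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), nrow = n)
    variants <- data.frame(snp_id = paste0("v", 1:m), chrom = "1",
                           pos = 1:m * 10L, a1 = "A", a2 = "G",
                           stringsAsFactors = FALSE)
    prefix <- file.path(dir, paste0("rt", n))
    write_plink(g, paste0("s", 1:n), variants, prefix)
    back <- read_plink(prefix)
    expect_identical(unname(back$g), g)
  }
})

test_that("corrupt PLINK inputs are rejected", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  writeLines("s1\ts1\t0\t0\t0\t-9", paste0(prefix, ".fam"))
  writeLines("1\trs1\t0\t100\tA\tG", paste0(prefix, ".bim"))
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")

  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "corrupt")

  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00)), paste0(prefix, ".bed"))
  writeLines(character(0), paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "empty|no lines")

  expect_error(read_plink(file.path(dir, "nothere")), "missing PLINK")
})

test_that("VCF genotypes parse to REF-allele counts with missing preserved", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0|0",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t1/1",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t0/1/1\t0/0",
    "1\t400\trs4\tT\tC,G\t.\tPASS\t.\tGT\t0/1\t0/0"
  ), path)
  expect_warning(raw <- read_vcf(path), "non-diploid")
  expect_equal(raw$variants$snp_id, c("rs1", "rs2", "rs3"))  # rs4 multiallelic
  expect_equal(unname(raw$g), rbind(c(1L, NA, NA), c(2L, 0L, 2L)))
})

test_that("harmonization resolves swaps and strand flips and drops ambiguity", {
  panel <- tiny_panel()  # pairs: A/G, C/T, G/A, T/C
  # input variants: rs1 swapped (G,A); rs2 strand-flipped (G,A -> comp C,T);
  # rs3 exact; rs4 strand+swap (G,A -> comp C,T -> swap of T,C); rs9 unmatched
  variants <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs9"),
    chrom = c("1", "1", "2", "4", "9"),
    pos = c(100L, 200L, 300L, 400L, 900L),
    a1 = c("G", "G", "G", "G", "A"),
    a2 = c("A", "A", "A", "A", "G"),
    stringsAsFactors = FALSE
  )
  g <- rbind(c(0L, 1L, 2L, NA, 1L),
             c(2L, NA, 0L, 1L, 0L))
  out <- harmonize_to_panel(list(g = g, subject_ids = c("s1", "s2"),
                                 variants = variants), panel)
  expect_equal(out$report$n_matched, 1L)        # rs3
  expect_equal(out$report$n_flipped, 1L)        # rs1
  expect_equal(out$report$n_strand_flipped, 2L) # rs2, rs4
  expect_equal(out$report$n_dropped_unmatched, 1L)
  expect_equal(out$report$n_dropped_ambiguous, 0L)
  G <- out$genotypes$g
  expect_equal(unname(G[, "rs1"]), c(2L, 0L))   # swap: 2 - g
  expect_equal(unname(G[, "rs2"]), c(1L, NA))   # strand only: g kept
  expect_equal(unname(G[, "rs3"]), c(2L, 0L))   # exact
  expect_equal(unname(G[, "rs4"]), c(NA_integer_, 1L))  # strand + swap
  expect_equal(out$genotypes$S_prime, c(3L, 3L))
})

test_that("strand-ambiguous SNPs are dropped by default but can be kept", {
  snps <- data.frame(snp_id = c("a1", "a2"), chrom = "1", pos = c(1L, 2L),
                     ref = c("A", "C"), alt = c("T", "G"),
                     stringsAsFactors = FALSE)
  p <- matrix(0.5, 2, 5)
  panel <- make_panel(snps, p, p[, 1:3])
  raw <- list(g = rbind(c(1L, 2L)), subject_ids = "s1",
              variants = data.frame(snp_id = c("a1", "a2"), chrom = "1",
                                    pos = c(1L, 2L), a1 = c("A", "C"),
                                    a2 = c("T", "G"), stringsAsFactors = FALSE))
  out <- harmonize_to_panel(raw, panel)
  expect_equal(out$report$n_dropped_ambiguous, 2L)
  expect_equal(out$genotypes$S_prime, 0L)

  kept <- harmonize_to_panel(raw, panel, drop_ambiguous = FALSE)
  expect_equal(kept$report$n_matched, 2L)
  expect_equal(unname(kept$genotypes$g[1, ]), c(1L, 2L))
})

test_that("harmonization counts partition the input variants", {
  panel <- tiny_panel()
  variants <- data.frame(snp_id = c("rs1", "rs2", "zz"), chrom = "1",
                         pos = c(100L, 200L, 999L),
                         a1 = c("A", "T", "A"), a2 = c("G", "G", "C"),
                         stringsAsFactors = FALSE)
  raw <- list(g = rbind(c(1L, 1L, 1L)), subject_ids = "s1",
              variants = variants)
  out <- harmonize_to_panel(raw, panel)
  # rs2 alleles (T,G) cannot be reconciled with panel (C,T): unmatched
  expect_equal(sum(unlist(out$report)), nrow(variants))
  expect_equal(out$report$n_dropped_unmatched, 2L)
})

test_that("position fallback matches variants with unknown ids", {
  panel <- tiny_panel()
  variants <- data.frame(snp_id = "unknown", chrom = "2", pos = 200L,
                         a1 = "C", a2 = "T", stringsAsFactors = FALSE)
  raw <- list(g = rbind(2L), subject_ids = "s1", variants = variants)
  miss <- harmonize_to_panel(raw, panel, match_by_position = FALSE)
  expect_equal(miss$report$n_dropped_unmatched, 1L)
  hit <- harmonize_to_panel(raw, panel, match_by_position = TRUE)
  expect_equal(hit$report$n_matched, 1L)
  expect_equal(unname(hit$genotypes$g[1, "rs2"]), 2L)
})

test_that("VCF and PLINK writers round trip through harmonization", {
  sc <- small_scene()
  sub <- genotype_set(sc$gset$g[1:5, ], sc$gset$subject_ids[1:5],
                      sc$gset$snp_ids)
  dir <- withr::local_tempdir()

  prefix <- file.path(dir, "rt")
  write_plink_genotypes(sub, sc$panel, prefix)
  out_p <- harmonize_to_panel(read_plink(prefix), sc$panel)
  expect_identical(out_p$genotypes$g, sub$g)

  vcf <- file.path(dir, "rt.vcf")
  write_vcf_genotypes(sub, sc$panel, vcf)
  out_v <- harmonize_to_panel(read_vcf(vcf), sc$panel)
  expect_identical(out_v$genotypes$g, sub$g)

  rep_path <- file.path(dir, "report.tsv")
  write_harmonization_report(out_v$report, rep_path)
  expect_true(file.exists(rep_path))
})
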