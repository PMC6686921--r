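MISSING_GT <- NA_integer_

#' Construct a genotype set aligned to a reference panel
#'
#' @param g n x S integer matrix of panel-reference-allele counts in
#'   \{0, 1, 2\} with `NA` for missing; columns in panel SNP order.
#' @param subject_ids character vector of length n.
#' @param snp_ids character vector of length S (the panel's SNP ids).
#' @return object of class `triadmix_genotypes` with elements `g`,
#'   `subject_ids`, `snp_ids`, and `S_prime` (per-subject genotyped counts).
#' @export
genotype_set <- function(g, subject_ids, snp_ids) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  stopifnot(nrow(g) == length(subject_ids), ncol(g) == length(snp_ids))
  bad <- !is.na(g) & !(g %in% c(0L, 1L, 2L))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA")
  dimnames(g) <- list(as.character(subject_ids), as.character(snp_ids))
  structure(
    list(g = g,
         subject_ids = as.character(subject_ids),
         snp_ids = as.character(snp_ids),
         S_prime = as.integer(rowSums(!is.na(g)))),
    class = "triadmix_genotypes"
  )
}

#' @export
print.triadmix_genotypes <- function(x, ...) {
  cat("genotype set:", length(x$subject_ids), "subjects x",
      length(x$snp_ids), "SNPs; mean genotyped per subject:",
      round(mean(x$S_prime), 1), "\n")
  invisible(x)
}

# ---- PLINK 1 bed/bim/fam ----------------------------------------------------

# 2-bit codes in a PLINK 1 SNP-major .bed, per byte, lowest bits = first
# sample: 00 hom A1, 01 missing, 10 het, 11 hom A2. We decode to the count of
# the A1 allele (2, NA, 1, 0 respectively).
PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK 1 binary fileset
#'
#' Decodes the SNP-major 2-bit .bed encoding. Genotypes are returned as counts
#' of the A1 allele of the .bim file; the PLINK missing code is mapped to `NA`
#' and never imputed.
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim` and `prefix.fam`
#'   must exist.
#' @return list with `g` (subjects x variants integer matrix of A1 counts),
#'   `subject_ids`, and `variants` (data.frame: snp_id, chrom, pos, a1, a2).
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stop("missing PLINK file(s): ", paste(miss, collapse = ", "))

  fam <- utils::read.table(paths[3], header = FALSE, colClasses = "character")
  if (nrow(fam) == 0L) stop("empty .fam: cohort has no subjects")
  subject_ids <- fam[[2]]
  bim <- utils::read.table(paths[2], header = FALSE, colClasses = "character")
  if (ncol(bim) < 6L) stop("malformed .bim: expected 6 columns")
  variants <- data.frame(snp_id = bim[[2]], chrom = bim[[1]],
                         pos = as.integer(bim[[4]]),
                         a1 = toupper(bim[[5]]), a2 = toupper(bim[[6]]),
                         stringsAsFactors = FALSE)

  n <- length(subject_ids)
  m <- nrow(variants)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(paths[1], what = "raw", n = 3 + m * bytes_per_snp + 1)
  if (length(raw) < 3 || !identical(raw[1:2], PLINK_MAGIC[1:2])) {
    stop("bad .bed magic bytes: not a PLINK 1 binary file")
  }
  if (raw[3] != PLINK_MAGIC[3]) {
    stop("unsupported .bed mode: only SNP-major (0x01) is supported")
  }
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp) {
    stop("corrupt .bed: size does not match .bim x .fam dimensions")
  }
  # split each byte into 4 two-bit codes, lowest bits first
  idx <- as.integer(body)
  codes <- rbind(idx %% 4L,
                 (idx %/% 4L) %% 4L,
                 (idx %/% 16L) %% 4L,
                 idx %/% 64L)
  codes <- matrix(codes, nrow = 4L * bytes_per_snp, ncol = m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(2L, NA_integer_, 1L, 0L)  # code 0,1,2,3 -> A1 count
  g <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  dimnames(g) <- list(subject_ids, variants$snp_id)
  list(g = g, subject_ids = subject_ids, variants = variants)
}

#' Write genotypes to a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: `g` holds counts of the A1 allele of `variants`.
#'
#' @param g subjects x variants integer matrix (`NA` = missing).
#' @param subject_ids character vector.
#' @param variants data.frame with snp_id, chrom, pos, a1, a2.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, subject_ids, variants, prefix) {
  g <- as.matrix(g)
  n <- length(subject_ids)
  m <- nrow(variants)
  stopifnot(nrow(g) == n, ncol(g) == m)
  fam <- data.frame(variants = subject_ids, iid = subject_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  names(fam)[1] <- "fid"
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = variants$chrom, snp_id = variants$snp_id,
                    cm = 0L, pos = variants$pos,
                    a1 = variants$a1, a2 = variants$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  code_of <- function(x) {  # A1 count -> 2-bit code
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 2L] <- 0L
    out[!is.na(x) & x == 1L] <- 2L
    out[!is.na(x) & x == 0L] <- 3L
    out
  }
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4L * bytes_per_snp - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    codes <- c(code_of(g[, j]), rep(0L, pad))
    quads <- matrix(codes, nrow = 4L)
    writeBin(as.raw(colSums(quads * mult)), con)
  }
  invisible(prefix)
}

#' Write a panel-aligned genotype set as PLINK (A1 = panel ref)
#'
#' @param gset a `triadmix_genotypes` aligned to `panel`.
#' @param panel the `triadmix_panel` supplying alleles and positions.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_genotypes <- function(gset, panel, prefix) {
  stopifnot(inherits(gset, "triadmix_genotypes"),
            identical(gset$snp_ids, panel$snps$snp_id))
  variants <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                         pos = panel$snps$pos,
                         a1 = panel$snps$ref, a2 = panel$snps$alt,
                         stringsAsFactors = FALSE)
  write_plink(gset$g, gset$subject_ids, variants, prefix)
}

# ---- VCF --------------------------------------------------------------------

#' Read genotypes from a VCF
#'
#' Parses diploid GT fields to counts of the VCF REF allele. Half calls,
#' `./.`, and non-diploid GTs become missing (non-diploid sites are counted
#' and reported with a warning). Multiallelic sites are dropped.
#'
#' @param path path to a VCF (uncompressed or gzipped).
#' @return list with `g` (subjects x variants REF-allele counts),
#'   `subject_ids`, `variants` (snp_id, chrom, pos, a1 = REF, a2 = ALT).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    toupper(fix$REF) %in% c("A", "C", "G", "T") &
    toupper(fix$ALT) %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1L)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
  variants <- data.frame(snp_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         a1 = toupper(fix$REF), a2 = toupper(fix$ALT),
                         stringsAsFactors = FALSE)

  alleles <- gsub("[|]", "/", gt)
  parts <- strsplit(alleles, "/", fixed = TRUE)
  nallele <- lengths(parts)
  flat <- unlist(lapply(parts, function(x) {
    if (length(x) != 2L || any(!x %in% c("0", "1"))) return(NA_integer_)
    sum(x == "0")  # count of REF allele
  }))
  g <- matrix(flat, nrow = nrow(gt), ncol = ncol(gt))
  n_nondiploid <- sum(nallele != 2L & !is.na(gt))
  if (n_nondiploid > 0L) {
    warning(n_nondiploid, " non-diploid GT call(s) set to missing")
  }
  g <- t(g)  # subjects x variants
  dimnames(g) <- list(colnames(gt), variants$snp_id)
  storage.mode(g) <- "integer"
  list(g = g, subject_ids = colnames(gt), variants = variants)
}

# ---- harmonization ----------------------------------------------------------

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align raw genotypes onto a panel's reference/alternate orientation
#'
#' Variants are matched to the panel by `snp_id` (optionally falling back to
#' `chrom:pos`). For each match the allele pair is reconciled: an exact
#' (a1, a2) = (ref, alt) match keeps the genotype; swapped alleles complement
#' it (g becomes 2 - g); a reverse-strand pair is complemented to the panel
#' strand first. Strand-ambiguous A/T and C/G SNPs are dropped by default
#' because their orientation cannot be resolved reliably at the high minor
#' allele frequencies typical of fingerprint panels. Missing calls are carried
#' through untouched — no imputation, ever.
#'
#' @param raw list as returned by [read_plink()] or [read_vcf()]; `raw$g`
#'   counts the a1 allele.
#' @param panel a `triadmix_panel`.
#' @param drop_ambiguous drop A/T and C/G SNPs (default `TRUE`).
#' @param match_by_position also try matching unmatched variants by
#'   `chrom:pos` (default `FALSE`).
#' @return list with `genotypes` (a `triadmix_genotypes` over the full panel,
#'   `NA` at panel SNPs absent from the input) and `report` (counts:
#'   n_matched, n_flipped, n_strand_flipped, n_dropped_ambiguous,
#'   n_dropped_unmatched).
#' @export
harmonize_to_panel <- function(raw, panel, drop_ambiguous = TRUE,
                               match_by_position = FALSE) {
  stopifnot(inherits(panel, "triadmix_panel"))
  v <- raw$variants
  n <- length(raw$subject_ids)
  S <- panel$S

  panel_idx <- match(v$snp_id, panel$snps$snp_id)
  if (match_by_position) {
    key_panel <- paste(panel$snps$chrom, panel$snps$pos, sep = ":")
    key_raw <- paste(v$chrom, v$pos, sep = ":")
    fallback <- match(key_raw, key_panel)
    panel_idx[is.na(panel_idx)] <- fallback[is.na(panel_idx)]
  }
  # a later duplicate hit on the same panel SNP counts as unmatched
  panel_idx[duplicated(panel_idx, incomparables = NA)] <- NA

  report <- c(n_matched = 0L, n_flipped = 0L, n_strand_flipped = 0L,
              n_dropped_ambiguous = 0L, n_dropped_unmatched = 0L)
  G <- matrix(NA_integer_, nrow = n, ncol = S,
              dimnames = list(raw$subject_ids, panel$snps$snp_id))

  hit <- which(!is.na(panel_idx))
  report["n_dropped_unmatched"] <- nrow(v) - length(hit)
  if (length(hit)) {
    pi <- panel_idx[hit]
    a1 <- v$a1[hit]; a2 <- v$a2[hit]
    pref <- panel$snps$ref[pi]; palt <- panel$snps$alt[pi]
    ambiguous <- is_strand_ambiguous(pref, palt) | is_strand_ambiguous(a1, a2)
    ca1 <- unname(DNA_COMPLEMENT[a1]); ca2 <- unname(DNA_COMPLEMENT[a2])

    exact <- a1 == pref & a2 == palt
    swap <- a1 == palt & a2 == pref
    strand <- !is.na(ca1) & !is.na(ca2) & ca1 == pref & ca2 == palt
    strand_swap <- !is.na(ca1) & !is.na(ca2) & ca1 == palt & ca2 == pref
    exact[is.na(exact)] <- FALSE
    swap[is.na(swap)] <- FALSE

    if (drop_ambiguous) {
      drop_amb <- ambiguous
    } else {
      # without the ambiguity filter, an A/T or C/G pair is taken at face
      # value: strand categories collapse onto exact/swap for these SNPs
      drop_amb <- rep(FALSE, length(hit))
    }
    use_exact <- exact & !drop_amb
    use_swap <- swap & !use_exact & !drop_amb
    use_strand <- (strand | strand_swap) & !use_exact & !use_swap & !drop_amb
    unmatched_alleles <- !(use_exact | use_swap | use_strand | drop_amb)

    report["n_dropped_ambiguous"] <- sum(drop_amb)
    report["n_dropped_unmatched"] <- report["n_dropped_unmatched"] +
      sum(unmatched_alleles)
    report["n_matched"] <- sum(use_exact)
    report["n_flipped"] <- sum(use_swap)
    report["n_strand_flipped"] <- sum(use_strand)

    keep_cols <- which(use_exact)
    for (k in keep_cols) G[, pi[k]] <- raw$g[, hit[k]]
    for (k in which(use_swap)) G[, pi[k]] <- 2L - raw$g[, hit[k]]
    for (k in which(use_strand)) {
      if (strand[k]) G[, pi[k]] <- raw$g[, hit[k]]          # same allele order
      else G[, pi[k]] <- 2L - raw$g[, hit[k]]               # flipped order too
    }
  }
  list(genotypes = genotype_set(G, raw$subject_ids, panel$snps$snp_id),
       report = as.list(report))
}

#' Write a harmonization report as TSV
#'
#' @param report the `report` element from [harmonize_to_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_report <- function(report, path) {
  df <- data.frame(metric = names(report),
                   count = unlist(report, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
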