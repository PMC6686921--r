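# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds derived from one master seed.
split_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

DEFAULT_FST <- c(eur = 0.15, afr = 0.15, eas = 0.15, sas = 0.12, lat = 0.15)

#' Simulate a reference allele-frequency panel
#'
#' Draws an ancestral reference-allele frequency per SNP uniformly on
#' \code{[maf_floor, 1 - maf_floor]} (fingerprint panels are selected for high
#' minor allele frequency), then draws each population's frequency from a
#' Balding-Nichols distribution around the ancestral value,
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)}, with a per-population drift parameter
#' F. Drift defaults are set above genome-wide averages because fingerprint
#' SNPs are chosen to be ancestry-informative, and the three anchor
#' populations get equal drift: a panel selected to resolve all continental
#' pairs is balanced by construction, and a symmetric reference configuration
#' keeps the shared heterozygosity offset of admixed subjects orthogonal to
#' the triangle plane (it surfaces in the out-of-plane score instead of
#' biasing ancestry proportions). Anchor-group frequencies equal
#' the corresponding reference-population frequencies (European, African, East
#' Asian), optionally perturbed with independent Balding-Nichols noise.
#'
#' @param S number of SNPs (default 10000).
#' @param fst named length-5 vector of drift parameters for
#'   `eur`, `afr`, `eas`, `sas`, `lat`.
#' @param maf_floor minimum ancestral minor allele frequency (default 0.15).
#' @param anchor_perturb drift of anchor groups around their reference
#'   populations (0 = identical, the default).
#' @param epsilon frequency clamp bound.
#' @param seed integer seed; the same seed always yields the same panel.
#' @return a `triadmix_panel`.
#' @export
simulate_panel <- function(S = 10000L, fst = DEFAULT_FST, maf_floor = 0.15,
                           anchor_perturb = 0, epsilon = 1e-6, seed = 1L) {
  stopifnot(S >= 3L, length(fst) == 5L, all(fst > 0), all(fst < 1),
            maf_floor >= 0, maf_floor < 0.5, anchor_perturb >= 0,
            anchor_perturb < 1)
  with_seed(split_seed(seed, 1L), {
    p0 <- stats::runif(S, maf_floor, 1 - maf_floor)
    bn <- function(center, F) {
      stats::rbeta(length(center), center * (1 - F) / F,
                   (1 - center) * (1 - F) / F)
    }
    p <- vapply(fst, function(F) bn(p0, F), numeric(S))
    colnames(p) <- REF_POPS
    u <- p[, 1:3, drop = FALSE]
    if (anchor_perturb > 0) {
      u <- vapply(1:3, function(j) bn(p[, j], anchor_perturb), numeric(S))
    }
    colnames(u) <- ANCHOR_GROUPS

    # non-ambiguous allele pairs only, so harmonization keeps every SNP
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pick <- sample.int(4L, S, replace = TRUE)
    snps <- data.frame(
      snp_id = sprintf("snp%06d", seq_len(S)),
      chrom = as.character(rep_len(1:22, S)),
      pos = 10000L + 100L * seq_len(S),
      ref = pairs[pick, 1], alt = pairs[pick, 2],
      stringsAsFactors = FALSE
    )
    make_panel(snps, p, u, epsilon = epsilon)
  })
}

#' Simulate subject genotypes from a panel
#'
#' Each cohort group is a list with `n` (subjects) and `alpha`, either a
#' length-3 ancestry-proportion vector over the anchor groups (E, F, A) or a
#' length-5 vector over the reference populations. A subject's allele
#' frequency at SNP l is the alpha-weighted mixture of the group frequencies,
#' and the genotype is Binomial(2, frequency), independent across SNPs —
#' the random-mating single-SNP model the distance method assumes.
#'
#' @param panel a `triadmix_panel`.
#' @param cohort list of groups, e.g.
#'   `list(list(n = 100, alpha = c(1, 0, 0), label = "E"))`.
#' @param seed integer seed.
#' @return a `triadmix_genotypes` with an added `group` element giving each
#'   subject's cohort label.
#' @export
simulate_subjects <- function(panel, cohort, seed = 1L) {
  stopifnot(inherits(panel, "triadmix_panel"), is.list(cohort))
  freqs <- lapply(cohort, function(grp) {
    a <- grp$alpha
    stopifnot(is.numeric(a), length(a) %in% c(3L, 5L), all(a >= -1e-12))
    if (abs(sum(a) - 1) > 1e-9) stop("group proportions must sum to 1")
    if (length(a) == 3L) as.vector(panel$u %*% a) else as.vector(panel$p %*% a)
  })
  labels <- vapply(seq_along(cohort), function(k) {
    if (!is.null(cohort[[k]]$label)) as.character(cohort[[k]]$label)
    else paste0("group", k)
  }, character(1))
  ns <- vapply(cohort, function(grp) as.integer(grp$n), integer(1))
  stopifnot(all(ns >= 1L))

  with_seed(split_seed(seed, 2L), {
    G <- matrix(NA_integer_, nrow = sum(ns), ncol = panel$S)
    row0 <- 0L
    for (k in seq_along(cohort)) {
      f <- freqs[[k]]
      draws <- stats::rbinom(ns[k] * panel$S, size = 2L,
                             prob = rep(f, each = ns[k]))
      G[row0 + seq_len(ns[k]), ] <- matrix(draws, nrow = ns[k])
      row0 <- row0 + ns[k]
    }
    ids <- paste0(rep(labels, ns), "_", unlist(lapply(ns, seq_len)))
    gset <- genotype_set(G, ids, panel$snps$snp_id)
    gset$group <- rep(labels, ns)
    gset
  })
}

#' Impose a missingness pattern on a genotype set
#'
#' Two regimes mirror how genotypes go missing in merged multi-study data:
#' `mcar` sets each call missing independently with probability `rate`
#' (missing completely at random), and `platform` retains one seeded SNP
#' subset of size `fraction * S` shared by all subjects — the structured,
#' non-random pattern produced when a study genotypes on a single array.
#'
#' @param gset a `triadmix_genotypes`.
#' @param mode one of `"none"`, `"mcar"`, `"platform"`.
#' @param rate per-call missing probability for `mcar`.
#' @param fraction retained SNP fraction for `platform`.
#' @param seed integer seed.
#' @return a `triadmix_genotypes` with calls masked; existing missing calls
#'   stay missing.
#' @export
apply_missingness <- function(gset, mode = c("none", "mcar", "platform"),
                              rate = 0, fraction = 1, seed = 1L) {
  stopifnot(inherits(gset, "triadmix_genotypes"))
  mode <- match.arg(mode)
  if (mode == "none") return(gset)
  G <- gset$g
  with_seed(split_seed(seed, 3L), {
    if (mode == "mcar") {
      stopifnot(rate >= 0, rate <= 1)
      if (rate >= 1) warning("missingness rate of 1 leaves no genotypes")
      drop <- matrix(stats::runif(length(G)) < rate, nrow = nrow(G))
      G[drop] <- NA_integer_
    } else {
      stopifnot(fraction > 0, fraction <= 1)
      keep_n <- ceiling(fraction * ncol(G))
      keep <- sort(sample.int(ncol(G), keep_n))
      G[, -keep] <- NA_integer_
    }
  })
  out <- genotype_set(G, gset$subject_ids, gset$snp_ids)
  out$group <- gset$group
  out
}

#' Write the small deterministic fixture cohort used by the test suite
#'
#' Emits a 60-SNP panel TSV, a PLINK fileset and a VCF for a 12-subject
#' cohort (4 each pure E/F/A) with a sprinkling of missing calls.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named list of the paths written.
#' @export
write_fixture_cohort <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(S = 60L, seed = seed)
  gset <- simulate_subjects(panel, list(
    list(n = 4L, alpha = c(1, 0, 0), label = "E"),
    list(n = 4L, alpha = c(0, 1, 0), label = "F"),
    list(n = 4L, alpha = c(0, 0, 1), label = "A")
  ), seed = seed)
  gset <- apply_missingness(gset, "mcar", rate = 0.05, seed = seed)

  panel_path <- file.path(dir, "panel.tsv")
  write_panel(panel, panel_path)
  plink_prefix <- file.path(dir, "cohort")
  write_plink_genotypes(gset, panel, plink_prefix)
  vcf_path <- file.path(dir, "cohort.vcf")
  write_vcf_genotypes(gset, panel, vcf_path)
  list(panel = panel_path, plink = plink_prefix, vcf = vcf_path)
}

#' Write a panel-aligned genotype set as a minimal VCF
#'
#' @param gset a `triadmix_genotypes` aligned to `panel`.
#' @param panel the `triadmix_panel` supplying alleles and positions.
#' @param path output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gset, panel, path) {
  stopifnot(inherits(gset, "triadmix_genotypes"),
            identical(gset$snp_ids, panel$snps$snp_id))
  gt_of <- function(g) {
    out <- rep("./.", length(g))
    out[!is.na(g) & g == 2L] <- "0/0"
    out[!is.na(g) & g == 1L] <- "0/1"
    out[!is.na(g) & g == 0L] <- "1/1"
    out
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gset$subject_ids), collapse = "\t"))
  body <- vapply(seq_len(panel$S), function(l) {
    paste(c(panel$snps$chrom[l], panel$snps$pos[l], panel$snps$snp_id[l],
            panel$snps$ref[l], panel$snps$alt[l], ".", "PASS", ".", "GT",
            gt_of(gset$g[, l])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
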