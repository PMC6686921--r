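SCORE_COLS <- c("subject_id", "S_prime", "D1", "D2", "D3", "D4", "D5",
                "GD1", "GD2", "GD3", "GD4",
                "lambda_e", "lambda_f", "lambda_a",
                "P_e", "P_f", "P_a", "flags")

#' Build the full-panel reference triangle frame
#'
#' Places each anchor group at its expected-distance triple over the full
#' panel and planarizes the resulting triangle under the fixed frame
#' convention. This frame is the common coordinate system onto which every
#' subject's scores are normalized, so cohorts with arbitrary missingness
#' patterns remain comparable.
#'
#' @param panel a `triadmix_panel`.
#' @param table optional precomputed [expected_contribution_table()].
#' @return a `triadmix_frame` (the reference triangle).
#' @export
build_reference_frame <- function(panel, table = NULL) {
  if (is.null(table)) table <- expected_contribution_table(panel)
  tri <- build_triangle(expected_triple(table, "E"),
                        expected_triple(table, "F"),
                        expected_triple(table, "A"))
  planarize(tri)
}

#' Compute normalized ancestry scores for a cohort
#'
#' Per subject: (i) genetic distances D1..D5 to the five reference populations
#' over the genotyped SNPs; (ii) the subject-specific expected triangle over
#' the same SNP subset; (iii) rigid projection of the subject point with that
#' triangle onto the z = 0 plane; (iv) barycentric coordinates and clamped
#' ancestry proportions with respect to the subset triangle; (v) re-expression
#' of the barycentric coordinates on the full-panel reference triangle, giving
#' the normalized in-plane scores GD1, GD2. GD3 is the out-of-plane coordinate
#' in the subset-triangle frame and GD4 = D5 - D4 (distance to Mexican/Latino
#' minus distance to South Asian). Subjects are scored independently: adding
#' or removing subjects never changes another subject's row.
#'
#' Flags: `no_genotypes` (S' = 0, scores withheld), `unstable_frame` (subset
#' triangle too close to degenerate; proportions withheld), `low_snps`
#' (S' below `min_snps_warn`), `strong` (S' at or above `strong_snps`).
#'
#' @param gset a `triadmix_genotypes` aligned to `panel`.
#' @param panel a `triadmix_panel`.
#' @param table optional precomputed contribution table.
#' @param frame0 optional precomputed reference frame.
#' @param min_snps_warn warn threshold on genotyped SNP count (default 1000).
#' @param strong_snps strong-confidence threshold (default 4000).
#' @return data.frame with one row per subject, columns `subject_id`,
#'   `S_prime`, `D1..D5`, `GD1..GD4`, `lambda_e/f/a`, `P_e/f/a`, `flags`.
#' @export
compute_cohort_scores <- function(gset, panel, table = NULL, frame0 = NULL,
                                  min_snps_warn = 1000L, strong_snps = 4000L) {
  stopifnot(inherits(gset, "triadmix_genotypes"),
            inherits(panel, "triadmix_panel"),
            identical(gset$snp_ids, panel$snps$snp_id))
  if (is.null(table)) table <- expected_contribution_table(panel)
  if (is.null(frame0)) frame0 <- build_reference_frame(panel, table)

  n <- length(gset$subject_ids)
  dist <- cohort_distance_matrix(gset$g, panel)
  D <- dist$D
  Sp <- dist$S_prime

  # expected subset-triangle vertices: masked means of the contribution table,
  # accumulated per subject (keeps rows bit-identical across cohort shapes)
  ctab <- unclass(table)
  Etrip <- matrix(NA_real_, n, 9L, dimnames = list(NULL, colnames(ctab)))
  for (i in seq_len(n)) {
    if (Sp[i] == 0L) next
    idx <- which(!is.na(gset$g[i, ]))
    Etrip[i, ] <- colSums(ctab[idx, , drop = FALSE]) / Sp[i]
  }

  out <- data.frame(subject_id = gset$subject_ids, S_prime = Sp,
                    D1 = D[, 1], D2 = D[, 2], D3 = D[, 3],
                    D4 = D[, 4], D5 = D[, 5],
                    GD1 = NA_real_, GD2 = NA_real_, GD3 = NA_real_,
                    GD4 = D[, 5] - D[, 4],
                    lambda_e = NA_real_, lambda_f = NA_real_,
                    lambda_a = NA_real_,
                    P_e = NA_real_, P_f = NA_real_, P_a = NA_real_,
                    flags = "", stringsAsFactors = FALSE)
  rownames(out) <- NULL

  flags <- vector("list", n)
  for (i in seq_len(n)) {
    fl <- character(0)
    if (Sp[i] == 0L) {
      flags[[i]] <- "no_genotypes"
      next
    }
    if (Sp[i] < min_snps_warn) fl <- c(fl, "low_snps")
    if (Sp[i] >= strong_snps) fl <- c(fl, "strong")

    tri <- tryCatch(
      build_triangle(Etrip[i, c("E1", "E2", "E3")],
                     Etrip[i, c("F1", "F2", "F3")],
                     Etrip[i, c("A1", "A2", "A3")]),
      error = function(e) NULL
    )
    if (is.null(tri)) {
      flags[[i]] <- c(fl, "unstable_frame")
      next
    }
    fr <- planarize(tri, points = D[i, 1:3])
    q <- fr$points[1, ]
    out$GD3[i] <- q["z"]
    if (frame_unstable(fr)) {
      flags[[i]] <- c(fl, "unstable_frame")
      next
    }
    lam <- barycentric(fr, q[c("x", "y")])
    out$lambda_e[i] <- lam[1, 1]
    out$lambda_f[i] <- lam[1, 2]
    out$lambda_a[i] <- lam[1, 3]
    P <- ancestry_proportions(lam)
    out$P_e[i] <- P[1, 1]; out$P_f[i] <- P[1, 2]; out$P_a[i] <- P[1, 3]
    xy0 <- barycentric_to_cartesian(lam, frame0)
    out$GD1[i] <- xy0[1, 1]
    out$GD2[i] <- xy0[1, 2]
    flags[[i]] <- fl
  }
  out$flags <- vapply(flags, function(f) paste(f, collapse = ";"), character(1))
  attr(out, "frame0") <- frame0
  out
}

#' Compute ancestry scores for a single subject
#'
#' @param g integer genotype vector over the panel SNPs (`NA` = missing).
#' @param panel a `triadmix_panel`.
#' @param subject_id label for the output row.
#' @param ... passed to [compute_cohort_scores()].
#' @return one-row data.frame as in [compute_cohort_scores()].
#' @export
compute_subject_scores <- function(g, panel, subject_id = "subject", ...) {
  gset <- genotype_set(matrix(as.integer(g), nrow = 1L), subject_id,
                       panel$snps$snp_id)
  compute_cohort_scores(gset, panel, ...)
}

#' Write a score table as TSV (fixed column order, 6-decimal floats)
#'
#' @param scores data.frame from [compute_cohort_scores()] (possibly with
#'   classification columns appended).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  cols <- c(SCORE_COLS, setdiff(names(scores), SCORE_COLS))
  cols <- intersect(cols, names(scores))
  out <- scores[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  for (cn in names(out)[num]) {
    out[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                        formatC(out[[cn]], format = "f", digits = 6))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_scores <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "", comment.char = "",
                    colClasses = NA)
}
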