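PANEL_FREQ_COLS <- c("p_eur", "p_afr", "p_eas", "p_sas", "p_lat",
                     "u_E", "u_F", "u_A")
PANEL_COLS <- c("snp_id", "chrom", "pos", "ref", "alt", PANEL_FREQ_COLS)

REF_POPS <- c("eur", "afr", "eas", "sas", "lat")
ANCHOR_GROUPS <- c("E", "F", "A")

#' Clamp allele frequencies away from 0 and 1
#'
#' The distance model takes logs of both allele frequencies, so frequencies of
#' exactly 0 or 1 would contribute infinite per-SNP distances. Clamping into
#' \code{[epsilon, 1 - epsilon]} bounds any single-SNP contribution to roughly
#' \code{-2 log(epsilon)} nats.
#'
#' @param x numeric vector or matrix of frequencies.
#' @param epsilon clamp bound; default \code{1e-6}.
#' @return `x` with all values forced into \code{[epsilon, 1 - epsilon]}.
#' @export
clamp_freq <- function(x, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            epsilon > 0, epsilon < 0.5)
  pmin(pmax(x, epsilon), 1 - epsilon)
}

new_panel <- function(snps, p, u, epsilon, n_dropped = 0L) {
  structure(
    list(snps = snps, p = p, u = u, S = nrow(snps),
         epsilon = epsilon, n_dropped = as.integer(n_dropped)),
    class = "triadmix_panel"
  )
}

#' Construct a reference allele-frequency panel from in-memory tables
#'
#' Validates SNP metadata and frequencies, clamps all frequencies into
#' \code{[epsilon, 1 - epsilon]}, and returns the panel object used by all
#' downstream distance computations. Rows with any frequency outside
#' \code{[0, 1]} or non-finite are dropped (counted in `n_dropped`).
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param p numeric matrix, one column per reference population
#'   (`eur`, `afr`, `eas`, `sas`, `lat`): reference-allele frequencies.
#' @param u numeric matrix, one column per anchor group (`E`, `F`, `A`):
#'   reference-allele frequencies in the anchor subject groups.
#' @param epsilon frequency clamp bound.
#' @return an object of class `triadmix_panel` with elements `snps`, `p`, `u`,
#'   `S` (SNP count), `epsilon`, and `n_dropped`.
#' @export
make_panel <- function(snps, p, u, epsilon = 1e-6) {
  p <- as.matrix(p); u <- as.matrix(u)
  storage.mode(p) <- "double"; storage.mode(u) <- "double"
  stopifnot(ncol(p) == 5L, ncol(u) == 3L,
            nrow(p) == nrow(snps), nrow(u) == nrow(snps))
  colnames(p) <- REF_POPS
  colnames(u) <- ANCHOR_GROUPS
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snps))) {
    stop("panel metadata must have columns: ", paste(need, collapse = ", "))
  }
  snps <- as.data.frame(snps)[, need]
  snps$snp_id <- as.character(snps$snp_id)
  snps$ref <- toupper(as.character(snps$ref))
  snps$alt <- toupper(as.character(snps$alt))

  ok_freq <- function(m) {
    apply(m, 1L, function(r) all(is.finite(r) & r >= 0 & r <= 1))
  }
  keep <- ok_freq(p) & ok_freq(u) &
    snps$ref %in% c("A", "C", "G", "T") &
    snps$alt %in% c("A", "C", "G", "T") &
    snps$ref != snps$alt
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("dropping ", n_dropped, " panel SNP(s) with unusable rows")
    snps <- snps[keep, , drop = FALSE]
    p <- p[keep, , drop = FALSE]
    u <- u[keep, , drop = FALSE]
  }
  if (nrow(snps) == 0L) stop("no usable SNPs in panel")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in panel")
  rownames(snps) <- NULL

  new_panel(snps, clamp_freq(p, epsilon), clamp_freq(u, epsilon),
            epsilon, n_dropped)
}

#' Load a reference panel from a tab-separated file
#'
#' The file must have a header with columns `snp_id`, `chrom`, `pos`, `ref`,
#' `alt`, the five reference-population frequency columns `p_eur`, `p_afr`,
#' `p_eas`, `p_sas`, `p_lat`, and the three anchor-group columns `u_E`, `u_F`,
#' `u_A`. Frequencies are reference-allele frequencies in \code{[0, 1]}; rows
#' that fail to parse are dropped with a message.
#'
#' @param path path to the panel TSV.
#' @param epsilon frequency clamp bound applied after parsing.
#' @return a `triadmix_panel`; see [make_panel()].
#' @export
load_panel <- function(path, epsilon = 1e-6) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "")
  missing_cols <- setdiff(PANEL_COLS, names(tab))
  if (length(missing_cols)) {
    stop("panel file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  freq <- suppressWarnings(
    vapply(PANEL_FREQ_COLS, function(cn) as.numeric(tab[[cn]]),
           numeric(nrow(tab)))
  )
  if (nrow(tab) == 1L) freq <- matrix(freq, nrow = 1L,
                                      dimnames = list(NULL, PANEL_FREQ_COLS))
  snps <- data.frame(snp_id = tab$snp_id, chrom = tab$chrom,
                     pos = suppressWarnings(as.integer(tab$pos)),
                     ref = tab$ref, alt = tab$alt,
                     stringsAsFactors = FALSE)
  make_panel(snps, freq[, 1:5, drop = FALSE], freq[, 6:8, drop = FALSE],
             epsilon = epsilon)
}

#' Write a reference panel to a tab-separated file
#'
#' @param panel a `triadmix_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "triadmix_panel"))
  out <- cbind(panel$snps,
               as.data.frame(panel$p), as.data.frame(panel$u))
  names(out) <- PANEL_COLS
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.triadmix_panel <- function(x, ...) {
  cat("reference panel:", x$S, "SNPs,",
      "5 reference populations, 3 anchor groups",
      sprintf("(clamp epsilon = %g", x$epsilon),
      paste0("dropped rows = ", x$n_dropped, ")\n"))
  invisible(x)
}

#' Per-SNP expected distance contributions for anchor groups
#'
#' For each SNP l, anchor group r in {E, F, A} and reference population
#' j in {1, 2, 3}, computes the expected negative log genotype probability of
#' a Hardy-Weinberg subject from group r scored against population j's
#' frequencies:
#' \deqn{c_{rjl} = -[u^2 \ln(p^2) + 2uv \ln(2pq) + v^2 \ln(q^2)]}
#' Averaging these contributions over any SNP subset gives the expected
#' distance from group r to population j over that subset, which is the basis
#' of the missingness normalization: per-subject expected triangles reduce to
#' a masked mean of this precomputed table.
#'
#' @param panel a `triadmix_panel` (frequencies already clamped).
#' @return an S x 9 matrix of class `triadmix_ctable`, columns named
#'   `E1, E2, E3, F1, F2, F3, A1, A2, A3` (anchor group x reference
#'   population).
#' @export
expected_contribution_table <- function(panel) {
  stopifnot(inherits(panel, "triadmix_panel"))
  p <- panel$p[, 1:3, drop = FALSE]
  q <- 1 - p
  out <- matrix(NA_real_, nrow = panel$S, ncol = 9L)
  cols <- as.vector(outer(1:3, ANCHOR_GROUPS,
                          function(j, r) paste0(r, j)))
  colnames(out) <- cols
  for (r in seq_along(ANCHOR_GROUPS)) {
    ur <- panel$u[, r]
    vr <- 1 - ur
    for (j in 1:3) {
      out[, paste0(ANCHOR_GROUPS[r], j)] <-
        -(ur^2 * log(p[, j]^2) +
            2 * ur * vr * log(2 * p[, j] * q[, j]) +
            vr^2 * log(q[, j]^2))
    }
  }
  structure(out, class = c("triadmix_ctable", "matrix", "array"))
}

#' Expected distance from an anchor group to a reference population
#'
#' Mean of the precomputed per-SNP contributions over a SNP subset. With the
#' full panel this is the full-set expected distance used to place the
#' reference triangle; with a subject's genotyped subset it gives the vertex
#' of that subject's subset triangle.
#'
#' @param table output of [expected_contribution_table()].
#' @param group anchor group, one of `"E"`, `"F"`, `"A"`.
#' @param refpop reference population index in 1..3.
#' @param subset integer vector of SNP indices; default all SNPs.
#' @return expected distance in nats per SNP.
#' @export
expected_distances <- function(table, group, refpop,
                               subset = seq_len(nrow(table))) {
  stopifnot(inherits(table, "triadmix_ctable"))
  group <- match.arg(group, ANCHOR_GROUPS)
  stopifnot(refpop %in% 1:3)
  if (length(subset) == 0L) stop("SNP subset is empty")
  mean(table[subset, paste0(group, refpop)])
}

# Expected-distance triple (to reference populations 1..3) for one anchor
# group over a subset; used to build triangle vertices.
expected_triple <- function(table, group, subset = seq_len(nrow(table))) {
  vapply(1:3, function(j) expected_distances(table, group, j, subset),
         numeric(1))
}
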