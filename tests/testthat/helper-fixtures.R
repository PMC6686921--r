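# Small handcrafted panel: 4 SNPs with fixed frequencies, anchor groups equal
# to the first three reference populations.
tiny_panel <- function(epsilon = 1e-6) {
  snps <- data.frame(
    snp_id = paste0("rs", 1:4),
    chrom = c("1", "2", "3", "4"),
    pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"),
    alt = c("G", "T", "A", "C"),
    stringsAsFactors = FALSE
  )
  p <- cbind(eur = c(0.5, 0.8, 0.3, 0.6),
             afr = c(0.2, 0.4, 0.7, 0.9),
             eas = c(0.7, 0.3, 0.5, 0.2),
             sas = c(0.5, 0.7, 0.4, 0.5),
             lat = c(0.4, 0.6, 0.6, 0.4))
  make_panel(snps, p, p[, 1:3], epsilon = epsilon)
}

# One-population-column panel builder used by the distance worked examples:
# all five populations share the given frequency vector.
flat_panel <- function(p1, epsilon = 1e-6) {
  S <- length(p1)
  snps <- data.frame(snp_id = paste0("s", seq_len(S)),
                     chrom = rep("1", S), pos = seq_len(S) * 100L,
                     ref = rep("A", S), alt = rep("G", S),
                     stringsAsFactors = FALSE)
  p <- matrix(rep(p1, 5), ncol = 5)
  make_panel(snps, p, p[, 1:3, drop = FALSE], epsilon = epsilon)
}

# Cached small simulated scene shared by several test files (built once per
# test run).
.fixture_env <- new.env(parent = emptyenv())

small_scene <- function() {
  if (is.null(.fixture_env$scene)) {
    panel <- simulate_panel(S = 600L, seed = 301L)
    table <- expected_contribution_table(panel)
    frame0 <- build_reference_frame(panel, table)
    gset <- simulate_subjects(panel, list(
      list(n = 30L, alpha = c(1, 0, 0), label = "E"),
      list(n = 30L, alpha = c(0, 1, 0), label = "F"),
      list(n = 30L, alpha = c(0, 0, 1), label = "A")
    ), seed = 302L)
    .fixture_env$scene <- list(panel = panel, table = table,
                               frame0 = frame0, gset = gset)
  }
  .fixture_env$scene
}

# Random non-degenerate 3-space triangle.
random_triangle <- function() {
  repeat {
    V <- matrix(stats::runif(9, -2, 2), nrow = 3)
    tri <- tryCatch(build_triangle(V[1, ], V[2, ], V[3, ]),
                    error = function(e) NULL)
    if (!is.null(tri)) return(tri)
  }
}

# Independent linear-system oracle for barycentric coordinates: solve
# Q = sum(lambda * V), sum(lambda) = 1 directly.
bary_solve_oracle <- function(frame, q) {
  V <- frame$vertices2d
  A <- rbind(c(1, 1, 1), t(V))
  as.numeric(solve(A, c(1, q)))
}

random_rigid_motion <- function() {
  M <- matrix(stats::rnorm(9), 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3))
}
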