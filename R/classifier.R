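POP_LABELS <- c("European", "African", "East Asian", "African American",
                "Latin American 1", "Latin American 2",
                "Asian-Pacific Islander", "South Asian", "Other")

#' The nine population labels, indexed by PopID
#'
#' @return character vector of length 9; element k is the label for PopID k.
#' @export
population_labels <- function() POP_LABELS

#' Default classification cutoffs
#'
#' Ancestry-proportion thresholds and the two GD1/GD4 separating curves used
#' to assign the nine population IDs. All constants are configurable because
#' the cutoffs are a suggested standard: users analysing their own cohorts are
#' expected to inspect the score scatter and may prefer their own boundaries.
#'
#' @param residual_popid PopID (7 or 9) assigned in the South/East-Asian
#'   region when GD4 >= 0 but neither separating curve is satisfied. The
#'   default 7 reflects that this middle sub-cluster adjoins the
#'   Asian-Pacific Islander cluster.
#' @return named list of cutoff constants.
#' @export
default_cutoffs <- function(residual_popid = 7L) {
  stopifnot(residual_popid %in% c(7L, 9L))
  list(
    p_e_european = 0.87,         # PopID 1: P_e >= this
    p_f_african = 0.95,          # PopID 2: P_f >= this
    p_a_east_asian = 0.95,       # PopID 3: P_a >= this
    p_f_afram_min = 0.40,        # PopID 4: this <= P_f < p_f_african
    p_minor = 0.13,              # the "small proportion" bound (P_a, P_f)
    # PopID 8 (South Asian): GD4 > sas_a * (GD1 - sas_x0)^2 + sas_c
    sas_a = 5, sas_x0 = 1.69, sas_c = 0.042,
    # PopID 7 (Asian-Pacific Islander): GD1 > api_a * GD4^2 + api_c
    api_a = 30, api_c = 1.73,
    residual_popid = as.integer(residual_popid)
  )
}

#' Assign nine-way population IDs from ancestry scores
#'
#' Proportion rules are evaluated in a fixed order: European (P_e >= 0.87),
#' African (P_f >= 0.95), East Asian (P_a >= 0.95), African American
#' (0.40 <= P_f < 0.95 and P_a < 0.13), Latin American 1 (P_f < 0.40,
#' P_e < 0.87, P_a < 0.13, P_f >= P_a), then the South/East-Asian region
#' (P_a < 0.95, P_e < 0.87, P_f < 0.13, P_f < P_a) which is resolved on the
#' (GD1, GD4) plane: South Asian when GD4 lies above the parabola
#' 5 (GD1 - 1.69)^2 + 0.042, else Asian-Pacific Islander when
#' GD1 > 30 GD4^2 + 1.73, else Latin American 2 when GD4 < 0, else the
#' configured residual PopID. Anything remaining with P_a >= 0.13 and
#' P_f >= 0.13 is Other. Subjects with missing proportions (no genotypes or
#' an unstable subset triangle) are left Unassigned (`pop_id` NA).
#'
#' @param scores data.frame from [compute_cohort_scores()], or any data.frame
#'   with columns `P_e`, `P_f`, `P_a`, `GD1`, `GD4` (and optionally `flags`).
#' @param cutoffs list from [default_cutoffs()].
#' @return `scores` with columns `pop_id` (integer, NA when unassigned),
#'   `pop_label`, and `rule_fired` appended.
#' @export
assign_population <- function(scores, cutoffs = default_cutoffs()) {
  need <- c("P_e", "P_f", "P_a", "GD1", "GD4")
  stopifnot(all(need %in% names(scores)))
  ct <- cutoffs
  n <- nrow(scores)
  pop <- rep(NA_integer_, n)
  rule <- rep("unassigned", n)

  pe <- scores$P_e; pf <- scores$P_f; pa <- scores$P_a
  gd1 <- scores$GD1; gd4 <- scores$GD4
  ok <- !is.na(pe) & !is.na(pf) & !is.na(pa)
  if (any(ok & abs(pe + pf + pa - 1) > 1e-6)) {
    stop("ancestry proportions must sum to 1")
  }

  set_if <- function(cond, id, rname) {
    cond <- ok & is.na(pop) & !is.na(cond) & cond
    pop[cond] <<- id
    rule[cond] <<- rname
  }
  set_if(pe >= ct$p_e_european, 1L, "prop_european")
  set_if(pf >= ct$p_f_african, 2L, "prop_african")
  set_if(pa >= ct$p_a_east_asian, 3L, "prop_east_asian")
  set_if(pf >= ct$p_f_afram_min & pf < ct$p_f_african & pa < ct$p_minor,
         4L, "prop_african_american")
  set_if(pf < ct$p_f_afram_min & pe < ct$p_e_european & pa < ct$p_minor &
           pf >= pa, 5L, "prop_latin_american_1")

  region <- ok & is.na(pop) & pa < ct$p_a_east_asian & pe < ct$p_e_european &
    pf < ct$p_minor & pf < pa
  in_region <- region & !is.na(gd1) & !is.na(gd4)
  set_if(in_region & gd4 > ct$sas_a * (gd1 - ct$sas_x0)^2 + ct$sas_c,
         8L, "curve_south_asian")
  set_if(in_region & gd1 > ct$api_a * gd4^2 + ct$api_c,
         7L, "curve_asian_pacific")
  set_if(in_region & gd4 < 0, 6L, "curve_latin_american_2")
  set_if(in_region, ct$residual_popid, "region_residual")

  set_if(pa >= ct$p_minor & pf >= ct$p_minor, 9L, "prop_other")

  scores$pop_id <- pop
  scores$pop_label <- ifelse(is.na(pop), "Unassigned", POP_LABELS[pop])
  scores$rule_fired <- rule
  scores
}

#' Write a cutoff configuration as a key = value file
#'
#' @param cutoffs list from [default_cutoffs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  writeLines(paste(names(cutoffs), unlist(cutoffs), sep = " = "), path)
  invisible(path)
}

#' Read a cutoff configuration written by [write_cutoffs()]
#'
#' @param path path to the key = value file.
#' @return named list merging the file's values over the defaults.
#' @export
read_cutoffs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- default_cutoffs()
  for (pair in kv) {
    if (length(pair) != 2L) stop("malformed cutoff line: ", paste(pair, collapse = "="))
    key <- trimws(pair[1]); val <- as.numeric(trimws(pair[2]))
    if (!key %in% names(out)) stop("unknown cutoff key: ", key)
    out[[key]] <- if (key == "residual_popid") as.integer(val) else val
  }
  stopifnot(out$residual_popid %in% c(7L, 9L))
  out
}
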