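# Drug-gene interaction scoring from CPP dose series.
#
# For each culture and each CPP, the departure from the reference strain is
# decomposed into a dose-independent 'shift' (K_0, the mutant-vs-reference
# difference without drug) and a dose-dependent interaction: K_i = Y_i -
# R_i, L_i = K_i - K_0, least-squares line L_i = A + B*D_i, and INT = A +
# B*D_max. INT values are standardized against the replicate reference
# cultures (z-scores); knockdown strains are standardized against their own
# stratum. Enhancers/suppressors are called at |z| >= 2 on L and K.

.CPPS <- c("K", "r", "L")

#' Per-dose reference statistics and Y_i-max values
#'
#' For each dose and CPP: the reference mean `R` and SD over the replicate
#' reference cultures that grew, and `ymax`, the maximum observed value of
#' that CPP among all cultures (mutant or reference) whose carrying
#' capacity lies within `k_sd_window` reference SDs below the reference
#' mean at that dose. `ymax` caps the L parameter of barely-growing
#' cultures, whose time-to-half-K diverges.
#'
#' @param cpp_table CPP table from [fit_cpp_table()].
#' @param drug drug name to restrict to.
#' @param k_sd_window how many reference K SDs below the reference K mean a
#'   culture may lie and still qualify for the Y_i-max pool.
#' @return list with `drug`, `doses`, `per_dose` (data.table: dose, cpp, R,
#'   ref_sd, n_ref, ymax) and `degenerate` (TRUE when any reference SD is 0).
#' @export
compute_reference_stats <- function(cpp_table, drug, k_sd_window = 2) {
  dg <- drug
  cpp <- data.table::as.data.table(cpp_table)
  cpp <- cpp[drug == dg]
  if (!nrow(cpp)) stop("no rows for drug ", dg)
  long <- data.table::melt(
    cpp, measure.vars = .CPPS, variable.name = "cpp", value.name = "value",
    variable.factor = FALSE)

  refs <- long[strain_class == "reference" & no_growth == FALSE]
  nref <- refs[cpp == "K", .N, by = dose]
  short <- nref[N < 2]
  doses <- sort(unique(cpp$dose))
  missing_dose <- setdiff(doses, nref$dose)
  if (nrow(short) || length(missing_dose))
    stop("fewer than 2 grown reference cultures at dose(s): ",
         paste(sort(c(short$dose, missing_dose)), collapse = ", "))

  per_dose <- refs[, .(R = mean(value), ref_sd = stats::sd(value), n_ref = .N),
                   by = .(dose, cpp)]

  # Y_i max: max observed value among cultures with K within k_sd_window
  # reference SDs (below the mean) at that dose
  kstat <- per_dose[cpp == "K", .(dose, Kbar = R, Ksd = ref_sd)]
  cand <- kstat[long, on = "dose"]
  cand <- cand[!is.na(value)]
  qual <- cand[cpp == "K" &
                 value >= Kbar - k_sd_window * Ksd - 1e-8 * (abs(Kbar) + 1),
               .(dose, plate, row, col, strain)]
  cand <- cand[qual, on = c("dose", "plate", "row", "col", "strain")]
  ymax <- cand[, .(ymax = max(value)), by = .(dose, cpp)]
  per_dose <- ymax[per_dose, on = c("dose", "cpp")]
  data.table::setcolorder(per_dose, c("dose", "cpp", "R", "ref_sd", "n_ref",
                                      "ymax"))
  data.table::setorder(per_dose, cpp, dose)
  list(drug = drug, doses = doses, per_dose = per_dose[],
       degenerate = any(per_dose$ref_sd == 0))
}

#' Apply the no-growth and Y_i-max value rules to one dose profile
#'
#' For the K and r CPPs, no-growth cultures take the value 0. For L: a
#' culture that grew without drug but not at dose `D_i` takes `ymax(L,
#' D_i)`, and an observed L above `ymax` is replaced by `ymax` (the
#' outlier rule). A culture that did not grow at dose 0 is left untouched
#' and flagged by the caller (its interaction is undefined; downstream a
#' sentinel score marks it).
#'
#' @param profile data.table for one culture with columns `dose`, `cpp`,
#'   `value`, `no_growth`.
#' @param stats output of [compute_reference_stats()] for the same drug.
#' @return the profile with substituted `value`s and a logical
#'   `substituted` column.
#' @export
substitute_ymax <- function(profile, stats) {
  p <- data.table::copy(data.table::as.data.table(profile))
  p[stats$per_dose, ymax := i.ymax, on = c("dose", "cpp")]
  grew_d0 <- !any(p[dose == 0]$no_growth)
  p[, substituted := FALSE]
  p[cpp %in% c("K", "r") & no_growth == TRUE,
    `:=`(value = 0, substituted = TRUE)]
  if (grew_d0) {
    need <- p[cpp == "L" &
                ((no_growth == TRUE) |
                   (!is.na(value) & !is.na(ymax) & value > ymax))]
    if (nrow(need[is.na(ymax)]))
      stop("Y_i max undefined at dose(s) ",
           paste(unique(need[is.na(ymax)]$dose), collapse = ", "),
           " but substitution is required")
    p[cpp == "L" & ((no_growth == TRUE) | (!is.na(value) & value > ymax)),
      `:=`(value = ymax, substituted = TRUE)]
  }
  p[, ymax := NULL]
  p[]
}

#' Score one dose series: shift, regression and INT
#'
#' The elementary interaction computation for a single culture and CPP:
#' `K_i = Y_i - R_i`; shift `K_0 = K_i` at dose 0; `L_i = K_i - K_0`
#' (zero at dose 0 by construction); ordinary least squares `L_i = A +
#' B*D_i` over all doses including dose 0; `INT = A + B * max(D)`.
#'
#' @param doses dose vector including 0.
#' @param values observed CPP values `Y_i`, aligned with `doses`.
#' @param ref_means reference means `R_i`, aligned with `doses` (default 0,
#'   in which case `values` are interpreted as already reference-corrected).
#' @return list with `K_i`, `shift`, `L_i`, `A`, `B`, `INT`, `n_used`.
#' @export
score_interaction <- function(doses, values, ref_means = 0) {
  stopifnot(length(doses) == length(values))
  if (doses[1] != 0) stop("dose series must include D_0 = 0 first")
  K_i <- values - ref_means
  shift <- K_i[1]
  L_i <- K_i - shift
  use <- !is.na(L_i)
  if (sum(use) < 3)
    return(list(K_i = K_i, shift = shift, L_i = L_i, A = NA_real_,
                B = NA_real_, INT = NA_real_, n_used = sum(use)))
  d <- doses[use]; l <- L_i[use]
  B <- sum((d - mean(d)) * (l - mean(l))) / sum((d - mean(d))^2)
  A <- mean(l) - B * mean(d)
  list(K_i = K_i, shift = shift, L_i = L_i, A = A, B = B,
       INT = A + B * max(doses), n_used = sum(use))
}

#' Standardize an interaction value against a stratum
#'
#' @param int interaction value(s).
#' @param stratum_mean,stratum_sd mean and SD of INT in the standardizing
#'   stratum (replicate reference cultures for knockouts; the knockdown
#'   stratum for knockdown strains).
#' @param stratum label used in the error message when the SD is zero.
#' @return z-score(s).
#' @export
standardize_scores <- function(int, stratum_mean, stratum_sd,
                               stratum = "reference") {
  if (is.na(stratum_sd) || stratum_sd <= 0) {
    # degenerate noise-free stratum: scores identical to the stratum mean
    # standardize to exactly 0; anything else is undefined
    if (all(abs(int - stratum_mean) <= 1e-12)) return(rep(0, length(int)))
    stop("interaction SD is zero or undefined in stratum '", stratum,
         "'; z-scores are not defined")
  }
  (int - stratum_mean) / stratum_sd
}

#' Classify enhancer / suppressor calls from L and K z-scores
#'
#' Deletion enhancers of cytotoxicity satisfy `z_L >= threshold` or
#' `z_K <= -threshold` (growth further delayed / capacity further reduced
#' by drug in the mutant); deletion suppressors satisfy `z_L <= -threshold`
#' or `z_K >= threshold`. If both rules fire the call is `"conflict"`,
#' flagged for manual review. Thresholds are inclusive.
#'
#' @param z_L,z_K z-score vectors for the L and K CPPs.
#' @param threshold classification threshold (default 2).
#' @return character vector in
#'   `{"enhancer","suppressor","conflict","none"}`, `NA` where both
#'   z-scores are missing.
#' @export
classify_interaction <- function(z_L, z_K, threshold = 2) {
  enh <- (!is.na(z_L) & z_L >= threshold) | (!is.na(z_K) & z_K <= -threshold)
  sup <- (!is.na(z_L) & z_L <= -threshold) | (!is.na(z_K) & z_K >= threshold)
  out <- data.table::fcase(enh & sup, "conflict",
                           enh, "enhancer",
                           sup, "suppressor",
                           default = "none")
  out[is.na(z_L) & is.na(z_K)] <- NA_character_
  out
}

#' Score drug-gene interaction for every culture of a drug
#'
#' Runs the full scoring pipeline on a CPP table: reference statistics,
#' no-growth / Y_i-max value rules, shift correction, dose regression, INT,
#' z-scores and enhancer/suppressor classification. Reference cultures are
#' scored like mutants (their z-scores have mean 0, SD 1 by construction)
#' and define the standardizing distribution for knockout strains;
#' knockdown strains are standardized against the knockdown stratum.
#' Cultures that did not grow at dose 0 have undefined interaction and are
#' flagged (`no_growth_d0`); the conventional sentinel score 0.0001 is
#' applied when profiles are assembled for clustering (see
#' [profile_matrix()]).
#'
#' @param cpp_table CPP table from [fit_cpp_table()].
#' @param drug drug name.
#' @param threshold classification threshold on z (default 2).
#' @param k_sd_window see [compute_reference_stats()].
#' @return data.table: `strain, strain_class, drug, cpp, plate, row, col,
#'   shift, A, B, INT, z, class, n_used, no_growth_d0`. One row per culture
#'   per CPP; `class` is the per-drug call combining the L and K z-scores.
#' @export
score_interactions <- function(cpp_table, drug, threshold = 2,
                               k_sd_window = 2) {
  dg <- drug
  stats <- compute_reference_stats(cpp_table, dg,
                                   k_sd_window = k_sd_window)
  cpp <- data.table::as.data.table(cpp_table)
  cpp <- cpp[drug == dg]
  long <- data.table::melt(
    cpp, measure.vars = .CPPS, variable.name = "cpp", value.name = "value",
    variable.factor = FALSE)
  long <- long[, .(strain, strain_class, plate, row, col, dose, cpp, value,
                   no_growth)]

  # value rules, vectorized (same semantics as substitute_ymax per culture)
  long[stats$per_dose, ymax := i.ymax, on = c("dose", "cpp")]
  ng0 <- unique(long[dose == 0 & no_growth == TRUE,
                     .(strain, plate, row, col)])
  long[, no_growth_d0 := FALSE]
  long[ng0, no_growth_d0 := TRUE, on = c("strain", "plate", "row", "col")]
  long[cpp %in% c("K", "r") & no_growth == TRUE, value := 0]
  need_undef <- long[no_growth_d0 == FALSE & cpp == "L" & is.na(ymax) &
                       (no_growth == TRUE | value > ymax)]
  if (nrow(need_undef))
    stop("Y_i max undefined at dose(s) ",
         paste(unique(need_undef$dose), collapse = ", "),
         " but substitution is required")
  long[no_growth_d0 == FALSE & cpp == "L" &
         (no_growth == TRUE | (!is.na(value) & value > ymax)),
       value := ymax]

  # K_i, shift, L_i
  long[stats$per_dose, R := i.R, on = c("dose", "cpp")]
  long[, K_i := value - R]
  long[, shift := K_i[dose == 0][1], by = .(strain, plate, row, col, cpp)]
  long[, L_i := K_i - shift]

  # least squares over doses (including dose 0) and INT at max dose
  dmax <- max(stats$doses)
  res <- long[, {
    use <- !is.na(L_i)
    if (no_growth_d0[1] || sum(use) < 3) {
      list(shift = shift[1], A = NA_real_, B = NA_real_, INT = NA_real_,
           n_used = sum(use), no_growth_d0 = no_growth_d0[1])
    } else {
      d <- dose[use]; l <- L_i[use]
      B <- sum((d - mean(d)) * (l - mean(l))) / sum((d - mean(d))^2)
      A <- mean(l) - B * mean(d)
      list(shift = shift[1], A = A, B = B, INT = A + B * dmax,
           n_used = sum(use), no_growth_d0 = no_growth_d0[1])
    }
  }, by = .(strain, strain_class, plate, row, col, cpp)]

  # stratum statistics and z-scores
  ref_int <- res[strain_class == "reference",
                 .(m = mean(INT, na.rm = TRUE),
                   s = stats::sd(INT[!is.na(INT)])), by = cpp]
  kd_int <- res[strain_class == "knockdown",
                .(m = mean(INT, na.rm = TRUE),
                  s = stats::sd(INT[!is.na(INT)])), by = cpp]
  # tolerate a noise-free degenerate stratum (SD 0): INT values equal to
  # the stratum mean standardize to 0, others have no defined z
  safe_z <- function(int, m, s, stratum) {
    if (is.na(s) || s <= 0) {
      z <- ifelse(abs(int - m) <= 1e-12, 0, NA_real_)
      if (anyNA(z))
        warning("interaction SD is zero in stratum '", stratum,
                "'; z undefined for values off the stratum mean")
      return(z)
    }
    (int - m) / s
  }
  res[, z := NA_real_]
  for (cp in .CPPS) {
    rs <- ref_int[cpp == cp]
    res[cpp == cp & strain_class %in% c("reference", "knockout") &
          !is.na(INT),
        z := safe_z(INT, rs$m, rs$s, "reference")]
    if (nrow(kd_int)) {
      ks <- kd_int[cpp == cp]
      res[cpp == cp & strain_class == "knockdown" & !is.na(INT),
          z := safe_z(INT, ks$m, ks$s, "knockdown")]
    }
  }

  # per-culture class from the L and K z-scores
  zw <- data.table::dcast(res, strain + strain_class + plate + row + col ~
                            cpp, value.var = "z")
  zw[, class := classify_interaction(L, K, threshold = threshold)]
  res[zw, class := i.class,
      on = c("strain", "strain_class", "plate", "row", "col")]
  res[, drug := dg]
  data.table::setcolorder(res, c("strain", "strain_class", "drug", "cpp",
                                 "plate", "row", "col", "shift", "A", "B",
                                 "INT", "z", "class", "n_used",
                                 "no_growth_d0"))
  data.table::setorder(res, strain, cpp)
  res[]
}

#' Assemble a clustering profile matrix from interaction results
#'
#' Pivots per-strain interaction results for one or more drugs into the
#' matrix clustered by REMc: one row per mutant strain, z-score columns
#' `z_<drug>_<cpp>` for the K and L CPPs, and carried-along
#' `shift_<drug>_<cpp>` columns that are excluded from clustering but kept
#' for display. Strains that did not grow without drug have no defined
#' interaction; their z columns carry the conventional sentinel 0.0001 and
#' are flagged in the `sentinel` column.
#'
#' @param results list of (or single) interaction tables from
#'   [score_interactions()], one per drug.
#' @param sentinel value marking interaction scores of cultures that did
#'   not grow in the absence of drug (default 0.0001).
#' @return data.table keyed by `strain`, with z and shift columns per
#'   (drug, CPP in K, L) and a logical `sentinel` column.
#' @export
profile_matrix <- function(results, sentinel = 1e-4) {
  if (data.table::is.data.table(results) || is.data.frame(results))
    results <- list(results)
  all <- data.table::rbindlist(lapply(results, data.table::as.data.table))
  all <- all[strain_class %in% c("knockout", "knockdown") & cpp %in% c("K", "L")]
  wz <- data.table::dcast(all, strain ~ drug + cpp, value.var = "z",
                          sep = "_")
  zcols <- setdiff(names(wz), "strain")
  data.table::setnames(wz, zcols, paste0("z_", zcols))
  ws <- data.table::dcast(all, strain ~ drug + cpp, value.var = "shift",
                          sep = "_")
  data.table::setnames(ws, setdiff(names(ws), "strain"),
                       paste0("shift_", setdiff(names(ws), "strain")))
  out <- ws[wz, on = "strain"]
  out[, sentinel := FALSE]
  for (zc in grep("^z_", names(out), value = TRUE)) {
    nas <- is.na(out[[zc]])
    if (any(nas)) {
      data.table::set(out, which(nas), zc, sentinel)
      out[nas, sentinel := TRUE]
    }
  }
  data.table::setkey(out, strain)
  out[]
}
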