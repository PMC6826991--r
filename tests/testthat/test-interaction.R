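# helper: build a one-dose-level CPP table row
cpp_row <- function(strain, cls, dose, K, L, drug = "gem", r = K / 500,
                    plate = "p1", row = "A", col = 1, ng = FALSE) {
  data.table::data.table(strain = strain, strain_class = cls, drug = drug,
                         dose = dose, plate = plate, row = row, col = col,
                         K = K, r = r, L = L, rss = 0, converged = TRUE,
                         no_growth = ng)
}

test_that("reference stats and Y_i max follow the 2-SD qualification rule", {
  # reference K values 95/100/105: mean 100, sample SD 5; cultures with K
  # below 90 are excluded from the Y_i-max pool, so ymax(L) = 25
  tab <- data.table::rbindlist(list(
    cpp_row("ref", "reference", 10, 95, 20, col = 1),
    cpp_row("ref", "reference", 10, 100, 20, col = 2),
    cpp_row("ref", "reference", 10, 105, 20, col = 3),
    cpp_row("yko_a", "knockout", 10, 95, 20, col = 4),
    cpp_row("yko_b", "knockout", 10, 99, 25, col = 5),
    cpp_row("yko_c", "knockout", 10, 70, 40, col = 6),
    # dose 0 layer so the dose grid is complete
    cpp_row("ref", "reference", 0, 95, 9, col = 1),
    cpp_row("ref", "reference", 0, 100, 10, col = 2),
    cpp_row("ref", "reference", 0, 105, 11, col = 3),
    cpp_row("yko_a", "knockout", 0, 100, 10, col = 4),
    cpp_row("yko_b", "knockout", 0, 100, 10, col = 5),
    cpp_row("yko_c", "knockout", 0, 100, 10, col = 6)))
  st <- compute_reference_stats(tab, "gem")
  d10 <- st$per_dose[dose == 10]
  expect_equal(d10[cpp == "K"]$R, 100)
  expect_equal(d10[cpp == "K"]$ref_sd, 5)
  expect_equal(d10[cpp == "L"]$ymax, 25)
  expect_true(st$degenerate)  # the constant reference L at dose 10 flags it
})

test_that("identical reference cultures are flagged degenerate", {
  tab <- data.table::rbindlist(lapply(1:3, function(i)
    rbind(cpp_row("ref", "reference", 0, 100, 10, col = i),
          cpp_row("ref", "reference", 5, 90, 12, col = i))))
  st <- compute_reference_stats(tab, "gem")
  expect_true(st$degenerate)
  expect_equal(st$per_dose[dose == 5 & cpp == "K"]$R, 90)
})

test_that("a dose with fewer than 2 reference cultures errors by name", {
  tab <- rbind(cpp_row("ref", "reference", 0, 100, 10, col = 1),
               cpp_row("ref", "reference", 0, 100, 10, col = 2),
               cpp_row("ref", "reference", 5, 90, 12, col = 1))
  expect_error(compute_reference_stats(tab, "gem"), "dose\\(s\\): 5")
})

test_that("Y_i-max substitution implements the three quoted cases", {
  stats <- list(per_dose = data.table::data.table(
    dose = rep(c(0, 5, 10), each = 3),
    cpp = rep(c("K", "r", "L"), 3),
    R = 0, ref_sd = 1, n_ref = 8,
    ymax = rep(c(110, 0.5, 40), 3)))
  prof <- data.table::data.table(
    dose = rep(c(0, 5, 10), each = 3),
    cpp = rep(c("K", "r", "L"), 3),
    value = c(100, 0.3, 10, 100, 0.3, 20, NA, 0, NA),
    no_growth = rep(c(FALSE, FALSE, TRUE), each = 3))

  out <- substitute_ymax(prof, stats)
  # grew at dose 0, not at dose 10: L takes ymax, K and r take 0
  expect_equal(out[dose == 10 & cpp == "L"]$value, 40)
  expect_equal(out[dose == 10 & cpp == "K"]$value, 0)
  expect_equal(out[dose == 10 & cpp == "r"]$value, 0)
  # observed values below ymax are untouched
  expect_equal(out[dose == 5 & cpp == "L"]$value, 20)
  expect_equal(out[dose == 0 & cpp == "K"]$value, 100)

  # observed L above ymax is clipped to ymax
  prof2 <- data.table::copy(prof)
  prof2[dose == 5 & cpp == "L", value := 55]
  out2 <- substitute_ymax(prof2, stats)
  expect_equal(out2[dose == 5 & cpp == "L"]$value, 40)

  # all observed and below ymax: identity
  prof3 <- data.table::data.table(
    dose = rep(c(0, 5, 10), each = 3), cpp = rep(c("K", "r", "L"), 3),
    value = rep(c(100, 0.3, 12), 3), no_growth = FALSE)
  out3 <- substitute_ymax(prof3, stats)
  expect_equal(out3$value, prof3$value)

  # substitution required but ymax undefined: error
  stats_na <- list(per_dose = data.table::copy(stats$per_dose)[
    dose == 10 & cpp == "L", ymax := NA])
  expect_error(substitute_ymax(prof, stats_na), "undefined")
})

test_that("score_interaction matches the hand-solved normal equations", {
  d <- c(0, 5, 10, 20, 30)
  res <- score_interaction(d, c(0, 1, 2, 4, 6))
  expect_equal(res$A, 0, tolerance = 1e-12)
  expect_equal(res$B, 0.2, tolerance = 1e-12)
  expect_equal(res$INT, 6.0, tolerance = 1e-12)
  # independent oracle on an unstructured series
  y <- c(0, 0.8, 2.4, 3.1, 7.2)
  res2 <- score_interaction(d, y)
  ab <- ols_oracle(d, y)
  expect_equal(c(res2$A, res2$B), ab, tolerance = 1e-12)
  expect_equal(res2$INT, ab[1] + ab[2] * 30, tolerance = 1e-12)
})

test_that("pure shift cancels: INT = 0 for a dose-independent offset", {
  d <- c(0, 5, 10, 20, 30)
  ref <- c(10, 12, 14, 18, 22)
  res <- score_interaction(d, ref + 5, ref_means = ref)
  expect_equal(res$shift, 5)
  expect_equal(res$L_i, rep(0, 5))
  expect_equal(res$INT, 0)
  # identity case
  res0 <- score_interaction(d, ref, ref_means = ref)
  expect_equal(res0$shift, 0)
  expect_equal(res0$INT, 0)
})

test_that("standardization arithmetic and strict zero-SD contract", {
  expect_equal(standardize_scores(6, 0, 1.5), 4)
  expect_equal(standardize_scores(3.7, 3.7, 2), 0)
  expect_error(standardize_scores(1, 0, 0, "knockdown"), "knockdown")
  # degenerate stratum with all values at the mean standardizes to zero
  expect_equal(standardize_scores(c(2, 2), 2, 0), c(0, 0))
})

test_that("classification reproduces printed enhancer/suppressor calls", {
  pub <- published_scores()
  for (dg in c("gem", "cyt")) {
    zk <- setNames(pub[[paste0(dg, "_K")]], pub$gene)
    zl <- setNames(pub[[paste0(dg, "_L")]], pub$gene)
    expect_equal(unname(classify_interaction(zl["PMR1"], zk["PMR1"])),
                 "enhancer")
    expect_equal(unname(classify_interaction(zl["CPR3"], zk["CPR3"])),
                 "suppressor")
  }
  expect_equal(classify_interaction(0, 0), "none")
  expect_equal(classify_interaction(2, 0), "enhancer")    # inclusive
  expect_equal(classify_interaction(-2, 0), "suppressor")
  expect_equal(classify_interaction(3, 3), "conflict")
  expect_true(is.na(classify_interaction(NA, NA)))
  expect_equal(classify_interaction(NA, -2.5), "enhancer")
})

test_that("reference cultures self-standardize to mean 0, SD 1 exactly", {
  sim <- generate_plate_experiment(tiny_config(n_mut = 3, n_ref = 12,
                                               noise = 4, seed = 3))
  cpp <- fit_cpp_table(sim$timeseries)
  res <- score_interactions(cpp, "gemcitabine")
  for (cp in c("K", "L")) {
    z <- res[strain_class == "reference" & cpp == cp]$z
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
})

test_that("shift invariance: a constant CPP offset never changes INT or z", {
  slopes <- data.frame(strain = "yko_0001", drug = "gemcitabine",
                       cpp = "L", value = 0.2)
  base <- NULL
  for (sh in c(0, 3, -2)) {
    planted <- list(
      slopes = slopes,
      shifts = if (sh != 0) data.frame(strain = "yko_0001", cpp = "L",
                                       value = sh) else NULL)
    sim <- generate_plate_experiment(tiny_config(planted = planted))
    # noise-free: the degenerate-stratum warning (z undefined) is expected
    res <- suppressWarnings(
      score_interactions(fit_cpp_table(sim$timeseries), "gemcitabine"))
    row <- res[strain == "yko_0001" & cpp == "L"]
    expect_equal(row$shift, sh, tolerance = 1e-6)
    if (is.null(base)) base <- row$INT
    expect_equal(row$INT, base, tolerance = 1e-6)
  }
})

test_that("linearity: doubling a planted slope doubles INT (noise-free)", {
  ints <- vapply(c(0.1, 0.2), function(b) {
    planted <- list(slopes = data.frame(strain = "yko_0001",
                                        drug = "gemcitabine",
                                        cpp = "L", value = b))
    sim <- generate_plate_experiment(tiny_config(planted = planted))
    res <- suppressWarnings(
      score_interactions(fit_cpp_table(sim$timeseries), "gemcitabine"))
    res[strain == "yko_0001" & cpp == "L"]$INT
  }, numeric(1))
  expect_equal(ints[2], 2 * ints[1], tolerance = 1e-6)
  expect_equal(ints[2], 6.0, tolerance = 1e-6)
})

test_that("knockdown strains standardize against their own stratum", {
  sim <- generate_plate_experiment(
    tiny_config(n_mut = 3, n_ref = 10, noise = 4, seed = 9,
                n_knockdown_strains = 6))
  res <- score_interactions(fit_cpp_table(sim$timeseries), "gemcitabine")
  kd <- res[strain_class == "knockdown" & cpp == "L"]
  expect_equal(mean(kd$z), 0, tolerance = 1e-10)
  expect_equal(sd(kd$z), 1, tolerance = 1e-10)
})

test_that("strains without drug-free growth get the sentinel profile", {
  sim <- generate_plate_experiment(tiny_config(n_mut = 6, n_ref = 8,
                                               noise = 0,
                                               no_growth_fraction = 0.5,
                                               seed = 4))
  cpp <- fit_cpp_table(sim$timeseries)
  res <- lapply(c("gemcitabine", "cytarabine"), function(d)
    score_interactions(cpp, d))
  ng <- sim$truth[no_growth == TRUE]$strain
  expect_true(all(res[[1]][strain %in% ng]$no_growth_d0))
  expect_true(all(is.na(res[[1]][strain %in% ng]$z)))
  prof <- profile_matrix(res)
  expect_true(all(prof[strain %in% ng]$sentinel))
  zc <- grep("^z_", names(prof), value = TRUE)
  for (col in zc) expect_true(all(prof[strain %in% ng][[col]] == 1e-4))
  expect_true(all(!prof[!strain %in% ng]$sentinel))
})
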