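# small labelled pharmaco dataset with planted UES/OES/null genes
planted_pharmaco <- function(seed = 1, n_lines = 200, effect = 0.8) {
  hg <- sprintf("H%03d", 1:30)
  planted <- data.frame(
    gene = hg[1:10],
    direction = rep(c("UES", "OES"), each = 5),
    effect_size = effect)
  pd <- generate_pharmaco_dataset(n_lines, hg, planted = planted,
                                  drug = "gemcitabine", seed = seed)
  list(pd = pd, genes = hg, planted = planted)
}

test_that("perfect anticorrelation gives coefficient -1 with p ~ 0", {
  lines <- sprintf("CL%02d", 1:30)
  sens <- data.table::data.table(cell_line = lines, drug = "gem",
                                 value = seq(0.1, 0.9, length.out = 30))
  expr <- rbind(anti = -sens$value, pro = sens$value)
  colnames(expr) <- lines
  tis <- data.table::data.table(cell_line = lines, tissue = "HaL")
  res <- associate_expression(expr, sens, tis, "all", "gem")
  expect_equal(res[gene == "anti"]$standardized_coefficient, -1,
               tolerance = 1e-10)
  expect_equal(res[gene == "pro"]$standardized_coefficient, 1,
               tolerance = 1e-10)
  expect_lt(res[gene == "anti"]$p_value, 1e-20)
})

test_that("stratum filtering and the minimum-lines guard work", {
  x <- planted_pharmaco()
  res_all <- associate_expression(x$pd$expression, x$pd$sensitivity,
                                  x$pd$tissues, "all", "gemcitabine")
  res_hal <- associate_expression(x$pd$expression, x$pd$sensitivity,
                                  x$pd$tissues, "HaL", "gemcitabine")
  expect_equal(unique(res_hal$tissue), "HaL")
  expect_lt(res_hal$n[1], res_all$n[1])
  expect_error(associate_expression(x$pd$expression, x$pd$sensitivity,
                                    x$pd$tissues, "nonexistent",
                                    "gemcitabine"),
               "need >= 10")
})

test_that("constant-expression genes are skipped with a log entry", {
  x <- planted_pharmaco()
  expr <- x$pd$expression
  expr["H030", ] <- 5
  expect_message(
    res <- associate_expression(expr, x$pd$sensitivity, x$pd$tissues,
                                "all", "gemcitabine"),
    "constant")
  expect_false("H030" %in% res$gene)
  expect_equal(attr(res, "skipped"), "H030")
})

test_that("planted directions are recovered and nulls stay calibrated", {
  # type-I calibration on a larger null-only panel
  hg <- sprintf("N%03d", 1:400)
  pd0 <- generate_pharmaco_dataset(200, hg, seed = 31)
  r0 <- associate_expression(pd0$expression, pd0$sensitivity, pd0$tissues,
                             "all", "gemcitabine")
  expect_gt(mean(r0$p_value < 0.05), 0.02)
  expect_lt(mean(r0$p_value < 0.05), 0.09)

  x <- planted_pharmaco()
  res <- associate_expression(x$pd$expression, x$pd$sensitivity,
                              x$pd$tissues, "all", "gemcitabine")
  ues <- res[gene %in% x$planted$gene[x$planted$direction == "UES"]]
  oes <- res[gene %in% x$planted$gene[x$planted$direction == "OES"]]
  expect_true(all(ues$standardized_coefficient < 0 & ues$p_value < 0.05))
  expect_true(all(oes$standardized_coefficient > 0 & oes$p_value < 0.05))
})

test_that("call_hits applies the UES/OES logic and filter contracts", {
  yr <- data.table::data.table(
    strain = c("PMR1", "CPR3", "NEUT"), drug = "gemcitabine",
    class = c("enhancer", "suppressor", "none"))
  hm <- data.table::data.table(
    yeast = c("PMR1", "CPR3", "NEUT"),
    human = c("ATP2C1s", "PPIAs", "NONEs"),  # synthetic homolog stand-ins
    class = "one-to-one")
  assoc <- data.table::data.table(
    gene = c("ATP2C1s", "PPIAs", "NONEs"), drug = "gemcitabine",
    tissue = "HaL",
    standardized_coefficient = c(-0.5, 0.4, -0.6),
    p_value = c(0.001, 0.01, 0.001))
  hits <- call_hits(yr, hm, assoc)
  expect_equal(hits[yeast == "PMR1"]$direction, "UES")
  expect_equal(hits[yeast == "CPR3"]$direction, "OES")
  expect_false("NEUT" %in% hits$yeast)       # class none: never a hit
  # non-significant association: no hit regardless of yeast class
  assoc2 <- data.table::copy(assoc)[, p_value := 0.5]
  expect_equal(nrow(call_hits(yr, hm, assoc2)), 0)
  # wrong sign for the class: no hit
  assoc3 <- data.table::copy(assoc)[gene == "ATP2C1s",
                                    standardized_coefficient := 0.5]
  expect_false("PMR1" %in% call_hits(yr, hm, assoc3)$yeast)
})

test_that("hits are invariant to row order and duplicated homolog rows", {
  yr <- data.table::data.table(strain = c("y1", "y2"), drug = "gem",
                               class = c("enhancer", "suppressor"))
  hm <- data.table::data.table(yeast = c("y1", "y2"), human = c("h1", "h2"),
                               class = "one-to-one")
  assoc <- data.table::data.table(
    gene = c("h1", "h2"), drug = "gem", tissue = "all",
    standardized_coefficient = c(-0.4, 0.4), p_value = 0.001)
  h1 <- call_hits(yr, hm, assoc)
  h2 <- call_hits(yr[2:1], rbind(hm, hm)[sample(4, 4)], assoc[2:1])
  expect_identical(h1, h2)
  # unknown yeast genes in the map warn and are skipped
  expect_warning(h3 <- call_hits(yr, rbind(
    hm, data.table::data.table(yeast = "ghost", human = "h9",
                               class = "one-to-one")), assoc),
    "ghost")
  expect_identical(h1, h3)
})

test_that("flipping the sensitivity sign swaps UES and OES exactly", {
  x <- planted_pharmaco()
  yr <- data.table::data.table(
    strain = paste0("y_", x$genes), drug = "gemcitabine",
    class = rep(c("enhancer", "suppressor", "none"), c(5, 5, 20)))
  hm <- data.table::data.table(yeast = paste0("y_", x$genes),
                               human = x$genes, class = "one-to-one")
  assoc <- associate_expression(x$pd$expression, x$pd$sensitivity,
                                x$pd$tissues, "all", "gemcitabine")
  sens_flipped <- data.table::copy(x$pd$sensitivity)[, value := -value]
  assoc_f <- associate_expression(x$pd$expression, sens_flipped,
                                  x$pd$tissues, "all", "gemcitabine")
  yr_swapped <- data.table::copy(yr)[, class := data.table::fcase(
    class == "enhancer", "suppressor", class == "suppressor", "enhancer",
    default = "none")]
  h <- call_hits(yr, hm, assoc)
  hf <- call_hits(yr_swapped, hm, assoc_f)
  expect_setequal(h[direction == "UES"]$human, hf[direction == "OES"]$human)
  expect_setequal(h[direction == "OES"]$human, hf[direction == "UES"]$human)
})

test_that("the hit set shrinks monotonically as alpha decreases", {
  x <- planted_pharmaco(effect = 0.3)
  yr <- data.table::data.table(
    strain = paste0("y_", x$genes), drug = "gemcitabine",
    class = rep(c("enhancer", "suppressor", "none"), c(5, 5, 20)))
  hm <- data.table::data.table(yeast = paste0("y_", x$genes),
                               human = x$genes, class = "one-to-one")
  assoc <- associate_expression(x$pd$expression, x$pd$sensitivity,
                                x$pd$tissues, "all", "gemcitabine")
  sizes <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a)
    nrow(call_hits(yr, hm, assoc, alpha = a)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("conservation summary counts concordant homolog calls", {
  yr <- data.table::data.table(strain = c("y1", "y2", "y3"), drug = "gem",
                               class = c("enhancer", "enhancer",
                                         "suppressor"))
  empty <- call_hits(yr,
                     data.table::data.table(yeast = "y1", human = "h1",
                                            class = "one-to-one"),
                     data.table::data.table(
                       gene = "h1", drug = "gem", tissue = "all",
                       standardized_coefficient = -0.5, p_value = 0.9))
  cs0 <- summarize_conservation(empty, yr)
  expect_true(all(cs0$fraction == 0))

  hits <- data.table::data.table(
    yeast = c("y1", "y3"), human = c("h1", "h3"),
    homology_class = "one-to-one", drug = "gem", tissue = "all",
    direction = c("UES", "OES"), standardized_coefficient = c(-0.5, 0.5),
    p_value = 0.01, yeast_class = c("enhancer", "suppressor"))
  cs <- summarize_conservation(hits, yr)
  expect_equal(cs[direction == "UES"]$fraction, 0.5)  # y1 of y1, y2
  expect_equal(cs[direction == "OES"]$fraction, 1)
})
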