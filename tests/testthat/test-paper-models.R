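# anchor points: the published mono-objective optima (value then the six
# factor levels in equation letter order A..F) for each rootstock/response
t8_anchor <- list(
  Pyrodwarf.PR  = list(c(1.5637, 1.188, 1.7548, 3.2834, 2.0792, 0.1311), 13.00432),
  Pyrodwarf.SL  = list(c(1.8265, 0.5115, 1.7393, 2.6042, 0.5947, 0.1599), 4.9999),
  Pyrodwarf.QI  = list(c(0.8855, 0.5, 2.5, 3.9999, 0.5001, 0.05), 4.9886),
  OHF.PR        = list(c(1.9996, 1.1895, 0.6188, 2.1306, 1.5938, 0.1721), 9.4209),
  OHF.SL        = list(c(0.8990, 1.3538, 2.0435, 3.4533, 1.8080, 0.0976), 4.9923),
  OHF.QI        = list(c(0.9914, 0.533, 1.8578, 2.1212, 2.5860, 0.1800), 4.8365))

test_that("the catalog is complete and immutable", {
  for (rs in c("OHF", "Pyrodwarf")) for (o in c("PR", "SL", "QI", "STN", "Vitri")) {
    g <- get_model(rs, o, "GEP")
    expect_s3_class(g, "model_expression")
    m <- get_model(rs, o, "M5")
    expect_s3_class(m, "m5_ruleset")
    expect_identical(get_model(rs, o, "GEP"), g)
  }
  expect_error(get_model("OHF", "PR", "bogus-kind"))
  expect_error(get_model("Rootstock-X", "PR", "GEP"))
})

test_that("GEP fixtures reproduce their published optima", {
  # the printed optimum inputs carry four decimals, so agreement is bounded
  # by gradient x input rounding; the proliferation and shoot-length
  # equations (the steepest-graded anchors) hold at 1e-3 relative, the
  # quality-index pair at 2.5e-3
  tol <- c(Pyrodwarf.PR = 1e-3, Pyrodwarf.SL = 1e-3, Pyrodwarf.QI = 2.5e-3,
           OHF.PR = 1e-3, OHF.SL = 1e-3, OHF.QI = 2.5e-3)
  for (k in names(t8_anchor)) {
    rs <- sub("[.].*", "", k); o <- sub(".*[.]", "", k)
    m <- get_model(rs, o, "GEP")
    v <- evaluate_expression(m, setNames(t8_anchor[[k]][[1]], LETTERS[1:6]))
    expect_equal(v, t8_anchor[[k]][[2]], tolerance = tol[[k]],
                 label = paste("fixture", k))
  }
})

test_that("every GEP fixture is finite across the experimental region", {
  # 7 points per axis; the C grid avoids C = 1 exactly, where the OHF
  # quality reading has a removable protected-log sentinel (ln C = 0)
  grid <- as.matrix(expand.grid(A = seq(0.5, 2, length.out = 7),
                                B = seq(0.5, 2, length.out = 7),
                                C = seq(0.5, 2.5, length.out = 7),
                                D = seq(0.5, 4, length.out = 7),
                                E = seq(0.5, 3, length.out = 7),
                                F = seq(0.05, 0.2, length.out = 7)))
  for (rs in c("OHF", "Pyrodwarf")) for (o in c("PR", "SL", "QI", "STN", "Vitri")) {
    v <- evaluate_expression(get_model(rs, o, "GEP"), grid)
    expect_true(all(is.finite(v)), label = paste(rs, o))
  }
})

test_that("five-response prediction applies the per-table letter mappings", {
  med <- c(NH4NO3 = 1.00, KNO3 = 0.50, Mesos = 2.32, Micros = 2.32,
           BA = 2.10, IBA = 0.20)
  p <- predict_media_response("OHF", med, "GEP")
  expect_named(p, c("PR", "SL", "QI", "STN", "Vitri"))
  # same medium, evaluated by hand with the equation-letter order
  m <- get_model("OHF", "PR", "GEP")
  expect_equal(unname(p["PR"]),
               evaluate_expression(m, c(A = 1.00, B = 0.50, C = 2.32,
                                        D = 2.32, E = 2.10, F = 0.20)))
  # the M5 table letters swap KNO3 and NH4NO3
  pm <- predict_media_response("OHF", med, "M5")
  rm_ <- get_model("OHF", "PR", "M5")
  expect_equal(unname(pm["PR"]),
               predict_m5(rm_, c(A = 0.50, B = 1.00, C = 2.32, D = 2.32,
                                 E = 2.10, F = 0.20)))
})

test_that("necrosis and hyperhydricity are reported clamped at zero", {
  med <- c(NH4NO3 = 1.00, KNO3 = 0.50, Mesos = 2.32, Micros = 2.32,
           BA = 2.10, IBA = 0.20)
  p <- predict_media_response("OHF", med, "GEP")
  expect_identical(unname(p["STN"]), 0)
  raw <- evaluate_expression(get_model("OHF", "STN", "GEP"),
                             c(A = 1, B = 0.5, C = 2.32, D = 2.32,
                               E = 2.1, F = 0.2))
  expect_lt(raw, 0)
})

test_that("fixtures round-trip through the canonical text format", {
  for (rs in c("OHF", "Pyrodwarf")) for (o in c("PR", "SL")) {
    m <- get_model(rs, o, "GEP")
    expect_identical(str2lang(render_expression_text(m)), m$expr)
  }
})
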