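test_that("figure tables reproduce the expected asymptotics", {
  f3 <- figure_tables(3)
  late <- f3[f3$t_bar == 10, ]
  expect_equal(late$c_bar, 1 - late$x_bar, tolerance = 1e-9)
  f4 <- figure_tables(4)
  expect_equal(f4$c_bar[f4$t_bar == 10 & f4$x_bar == 1], 0.5, tolerance = 1e-9)
  expect_error(figure_tables(7), "which")
})

test_that("response curves in the comparison figure order by sensitivity", {
  f5 <- figure_tables(5, t_bar = seq(0.05, 3, by = 0.05))
  wide <- tidyr::pivot_wider(f5, names_from = "sensor", values_from = "m_bar")
  m <- as.matrix(wide[, c("concentration (Neumann)", "robin (alpha_bar = 0.2)",
                          "robin (alpha_bar = 1)", "robin (alpha_bar = 5)",
                          "ideal flux (Dirichlet)")])
  expect_true(all(diff(t(m)) >= -1e-12))   # nondecreasing across columns
})

test_that("response_curve carries steady states in the right units", {
  skin <- skin_kskin(C0 = mg_per_dl_to_mol_per_cm3(100, ETHANOL_MW_TEST))
  rc <- response_curve("ideal_flux", t_bar = c(0, 1), skin = skin)
  expect_equal(attr(rc, "steady_state"), steady_state_flux(skin))
  expect_match(attr(rc, "steady_state_units"), "cm\\^-2")
  cc <- response_curve("concentration", t_bar = c(0, 1), skin = skin)
  expect_equal(attr(cc, "steady_state"), skin$C0)
  rr <- response_curve("robin", t_bar = c(0, 1), alpha_bar = 1, skin = skin)
  expect_equal(attr(rr, "steady_state"),
               robin_steady_state(skin, permeability(skin)))
  expect_error(response_curve("robin", t_bar = 1), "alpha_bar")
})

test_that("autoplot builds ggplots for curves and profiles", {
  p1 <- ggplot2::autoplot(response_curves(seq(0, 1, 0.1)))
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(profile_curve("concentration", t_bar = c(0.1, 1)))
  expect_s3_class(p2, "ggplot")
})

test_that("run_config drives the pipeline end to end", {
  out <- withr::local_tempdir()
  cfg <- file.path(out, "cfg.yaml")
  writeLines(c(
    "skin:",
    "  D_cm2_per_s: 3.0e-11",
    "  L_cm: 1.5e-3",
    "sensor:",
    "  kind: robin",
    "  alpha_cm_per_s: 2.45e-7",
    "figures: [5]",
    "response_t_bar: [0.0, 0.1, 0.5, 1.0]"
  ), cfg)
  rep <- run_config(cfg, out_dir = out, quiet = TRUE)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "figure5.csv")))
  expect_true(file.exists(file.path(out, "responses.csv")))
  # the ethanol-timescale skin yields the published response times
  expect_equal(rep$timescales$tau_conc_s / 3600, 8.4, tolerance = 0.1 / 8.4)
  expect_equal(rep$timescales$tau_flux_s / 3600, 2.1, tolerance = 0.05 / 2.1)
  expect_equal(rep$sensor$classification, "ideal-flux-like")
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$timescales$tau_ratio, 4, tolerance = 1e-12)
})

test_that("identical configs give byte-identical CSV outputs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- file.path(out1, "cfg.yaml")
  writeLines(c("skin:", "  D_cm2_per_s: 5.0e-10", "  L_cm: 1.5e-3",
               "figures: [2]"), cfg)
  run_config(cfg, out_dir = out1, quiet = TRUE)
  run_config(cfg, out_dir = out2, quiet = TRUE)
  expect_identical(readLines(file.path(out1, "figure2.csv")),
                   readLines(file.path(out2, "figure2.csv")))
})

test_that("config validation rejects malformed inputs", {
  out <- withr::local_tempdir()
  empty <- file.path(out, "empty.yaml")
  writeLines("", empty)
  expect_error(run_config(empty, out_dir = out, quiet = TRUE), "empty|skin")
  bad <- file.path(out, "bad.yaml")
  writeLines(c("skin:", "  D_cm2_per_s: 1.0e-10"), bad)
  expect_error(run_config(bad, out_dir = out, quiet = TRUE), "L_cm")
  badsensor <- file.path(out, "badsensor.yaml")
  writeLines(c("skin:", "  D_cm2_per_s: 1.0e-10", "  L_cm: 1.0e-3",
               "sensor:", "  kind: sorption"), badsensor)
  expect_error(run_config(badsensor, out_dir = out, quiet = TRUE), "kind")
  expect_error(run_config(file.path(out, "nope.yaml")), "not found")
})

test_that("bundled preset configs parse and run", {
  for (preset in c("ethanol-timescale", "ethanol-kskin")) {
    cfg <- system.file("extdata", paste0(preset, ".yaml"), package = "dermadiff")
    expect_true(nzchar(cfg))
    out <- withr::local_tempdir()
    rep <- run_config(cfg, out_dir = out, quiet = TRUE)
    expect_true(rep$skin$k_skin_cm_per_s > 0)
  }
})
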