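# Per-solvent configuration comparison.

campaign_fixture <- function(seed = 91, gen_lib = "pi_complex",
                             solvents = "ACN") {
  design <- study_design(solvents, sprintf("BA%02d", 1:15), 2)
  mats <- make_campaign_matrices(design, seed = seed)
  truth <- setNames(lapply(solvents, function(s)
    list(configuration = gen_lib, subset = c("x3", "x7", "x9"),
         coef = c(2, -1, 0.5), noise_sd = 0.05)), solvents)
  out <- gen_outcomes(design, truth, mats, replicate_sd = 0.02,
                      seed = seed + 1)
  list(design = design, mats = mats, outcomes = out)
}

test_that("the generating configuration ranks first in a planted campaign", {
  fx <- campaign_fixture(seed = 91, gen_lib = "pi_complex")
  rep <- run_campaign(fx$mats, fx$outcomes, design = fx$design,
                      settings = campaign_settings(kfold_top = 0, seed = 2))
  bc <- best_configurations(rep)
  expect_equal(bc$configuration[bc$solvent == "ACN" & bc$response == "log_dr"],
               "pi_complex")
  # the winning model recovers the planted subset
  best <- rep$cells[["ACN"]][["log_dr"]][["pi_complex"]]$best
  expect_setequal(best$labels, c("x3", "x7", "x9"))
})

test_that("identical responses for two solvents give identical per-solvent
           results", {
  fx <- campaign_fixture(seed = 92, solvents = c("s1", "s2"))
  # force both solvents to carry the same outcome values
  o <- fx$outcomes
  for (col in c("dr_anti", "dr_syn", "er_major", "er_minor", "yield_pct"))
    o[[col]][o$solvent == "s2"] <- o[[col]][o$solvent == "s1"]
  rep <- run_campaign(fx$mats, o, design = fx$design,
                      settings = campaign_settings(kfold_top = 0, seed = 2))
  s1 <- rep$summary[rep$summary$solvent == "s1", -1]
  s2 <- rep$summary[rep$summary$solvent == "s2", -1]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("a failing library is marked failed and the rest are unaffected", {
  fx <- campaign_fixture(seed = 93)
  mats <- fx$mats
  # make one library unassemblable: a config library with no specs usable
  lib_bad <- gen_toy_structures("H", label = "enamine_adduct",
                                modifier_ids = "BA01")
  mats$enamine_adduct <- lib_bad  # 1 structure, cannot cover 15 modifiers
  rep <- run_campaign(mats, fx$outcomes, design = fx$design,
                      specs = list(descriptor_spec("charge", 1)),
                      settings = campaign_settings(kfold_top = 0, seed = 2))
  sm <- rep$summary
  expect_true(all(sm$status[sm$configuration == "enamine_adduct"] == "failed"))
  expect_true(all(sm$status[sm$configuration != "enamine_adduct"] == "ok"))

  # cell independence: dropping a library leaves the others' best models
  rep2 <- run_campaign(fx$mats[c("free_acid", "pi_complex", "hbond_complex",
                                 "proline_adduct")],
                       fx$outcomes, design = fx$design,
                       settings = campaign_settings(kfold_top = 0, seed = 2))
  for (lib in c("free_acid", "pi_complex", "hbond_complex", "proline_adduct")) {
    a <- rep$summary[rep$summary$configuration == lib &
                     rep$summary$status == "ok", c("best_model", "q2_loo")]
    b <- rep2$summary[rep2$summary$configuration == lib, c("best_model", "q2_loo")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("near-tie flagging follows the tolerance strictly", {
  fake_rank <- function(q2s) {
    data.frame(solvent = "s", response = "log_dr",
               rank = seq_along(q2s),
               configuration = configuration_labels()[seq_along(q2s)],
               q2_loo = q2s, stringsAsFactors = FALSE)
  }
  rep <- structure(list(rankings = fake_rank(c(0.90, 0.89, 0.60))),
                   class = "qssr_comparison_report")
  fl <- near_tie_flags(rep, tolerance = 0.05)
  expect_equal(nrow(fl), 1L)
  expect_setequal(c(fl$config_a, fl$config_b),
                  configuration_labels()[1:2])
  expect_equal(nrow(near_tie_flags(rep, tolerance = 0.005)), 0L)
  expect_equal(nrow(near_tie_flags(rep, tolerance = 0)), 0L)
  rep2 <- structure(list(rankings = fake_rank(c(0.9, 0.9))),
                    class = "qssr_comparison_report")
  expect_equal(nrow(near_tie_flags(rep2, tolerance = 0)), 0L)  # strict <
  expect_equal(nrow(near_tie_flags(rep2, tolerance = 1e-9)), 1L)
})

test_that("narrow responses are skipped with a flag, not modeled", {
  design <- study_design("hexane", sprintf("BA%02d", 1:15), 2)
  mats <- make_campaign_matrices(design, seed = 94)
  truth <- list(hexane = list(configuration = "free_acid", subset = "x1",
                              coef = 0.01, noise_sd = 0))
  out <- gen_outcomes(design, truth, mats, replicate_sd = 0.001, seed = 95)
  rep <- run_campaign(mats, out, design = design,
                      settings = campaign_settings(kfold_top = 0, seed = 2))
  expect_true(all(c("log_dr", "ddg") %in% rep$skipped$response))
  expect_equal(nrow(rep$summary), 0L)
})

test_that("the report bundle writes JSON, per-cell tables and a narrative", {
  fx <- campaign_fixture(seed = 96)
  rep <- run_campaign(fx$mats, fx$outcomes, design = fx$design,
                      settings = campaign_settings(kfold_top = 1,
                                                   kfold_iterations = 20,
                                                   seed = 2))
  dir <- withr::local_tempdir()
  write_report_bundle(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "narrative.txt")))
  csvs <- list.files(dir, pattern = "^models_.*csv$")
  expect_equal(length(csvs), sum(rep$summary$status == "ok"))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_named(js, c("settings", "summary", "rankings", "skipped",
                     "near_ties"), ignore.order = TRUE)
  first <- readLines(file.path(dir, csvs[1]), n = 1)
  expect_match(first, "^# seed: 2$")
})
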