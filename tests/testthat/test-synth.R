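test_that("a noiseless basal register beats at exactly the configured mean", {
  cfg <- synth_config(rr_noise_sd = 0, rsa_amplitude = c(Relax = 0, Basal = 0,
                                                         Stress = 0))
  reg <- generate_register(synth_schedule(c(Basal = 60)), cfg, seed = 1)
  expect_true(all(reg$rr_beats$rr == 0.80))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  r1 <- generate_register(synth_schedule(), seed = 23)
  r2 <- generate_register(synth_schedule(), seed = 23)
  expect_identical(r1$eda, r2$eda)
  expect_identical(r1$rr_beats, r2$rr_beats)
})

test_that("state separations follow the configuration", {
  cfg <- synth_config()
  expect_equal(cfg$rr_mean[["Relax"]] - cfg$rr_mean[["Stress"]], 0.38)
  reg <- generate_register(synth_schedule(c(Relax = 120, Stress = 120)),
                           synth_config(rr_noise_sd = 0.005), seed = 29)
  in_state <- function(st) {
    seg <- reg$meta$schedule[reg$meta$schedule$state == st, ]
    idx <- reg$rr_beats$beat_time >= seg$t_start & reg$rr_beats$beat_time < seg$t_end
    mean(reg$rr_beats$rr[idx])
  }
  expect_equal(in_state("Relax") - in_state("Stress"), 0.38, tolerance = 0.03)
})

test_that("separation scaling interpolates toward identical states", {
  cfg <- synth_config()
  none <- scale_separation(cfg, 0)
  expect_equal(diff(range(none$rr_mean)), 0)
  expect_equal(diff(range(none$eda_tonic_slope)), 0)
  half <- scale_separation(cfg, 0.5)
  expect_equal(diff(range(half$rr_mean)), diff(range(cfg$rr_mean)) / 2)
  expect_identical(scale_separation(cfg, 1)$rr_mean, cfg$rr_mean)
})

test_that("a schedule register yields a labelled 51-feature table", {
  reg <- generate_register(
    synth_schedule(c(Basal = 100, Stress = 100, Relax = 100)), seed = 31)
  tab <- build_feature_table(reg)
  expect_equal(length(feature_columns(tab)), 51)
  expect_true(all(c("RR_Band", "label") %in% names(tab)))
  expect_equal(nlevels(droplevels(tab$label)), 3)
  counts <- table(droplevels(tab$label))
  expect_true(all(counts >= 3))  # balanced-ish
  expect_true(all(tab$RR_Band %in% 1:3))
})

test_that("RR_Band recovers the scheduled state for most windows", {
  reg <- generate_register(synth_schedule(), seed = 7)
  tab <- build_feature_table(reg)
  code <- c("Relax-RResp" = 1, "Basal-RResp" = 2,
            "Stress-RResp" = 3)[as.character(tab$label)]
  expect_gte(mean(tab$RR_Band == code), 0.9)
})

test_that("round-tripping a register through CSV preserves it", {
  reg <- generate_register(synth_schedule(c(Basal = 60, Stress = 60)), seed = 37)
  dir <- withr::local_tempdir()
  paths <- write_register(reg, dir)
  back <- read_register(paths[["eda"]], paths[["rr"]], paths[["annotations"]],
                        subject_id = reg$subject_id)
  expect_equal(back$eda$eda, reg$eda$eda, tolerance = 1e-9)
  expect_equal(back$rr_beats$rr, reg$rr_beats$rr, tolerance = 1e-9)
  expect_equal(as.character(back$annotations$label),
               as.character(reg$annotations$label))
})
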