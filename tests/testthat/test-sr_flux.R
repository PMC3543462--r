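series_from_conc <- function(conc, volume = 500, days = 14, area = 0.66,
                             trap = "T1") {
  trap_series(tibble::tibble(
    trap_id = trap,
    bottle_id = sprintf("B%02d", seq_along(conc)),
    duration_days = days, volume_ml = volume, sr_ug_per_ml = conc
  ), collection_area = area)
}

test_that("background is the mean and sample sd of sub-cutoff bottles", {
  bg <- suppressWarnings(estimate_background(series_from_conc(c(8, 8, 8, 20))))
  expect_equal(bg$mean, 8)
  expect_equal(bg$sd, 0)
  expect_equal(bg$n_bottles_used, 3L)

  bg2 <- estimate_background(series_from_conc(c(7, 8, 9.5)))
  expect_equal(bg2$mean, 7.5)
  expect_equal(bg2$sd, sqrt(0.5), tolerance = 1e-12) # sample sd of {7, 8}
  expect_equal(bg2$n_bottles_used, 2L)

  expect_error(estimate_background(series_from_conc(c(9.2, 10, 11))),
               "cannot-estimate-background")
  # a zero-sd background degenerates the threshold and warns
  expect_warning(estimate_background(series_from_conc(c(8, 8, 8))), "sd is 0")
})

test_that("significance is strictly above mean + 2 sd, reproducibly", {
  s <- series_from_conc(c(7.9, 8.0, 8.1, 20))
  bg <- estimate_background(s)
  expect_equal(flag_significant(s, bg), c(FALSE, FALSE, FALSE, TRUE))

  # a bottle sitting exactly at mean + 2 sd is not significant
  s2 <- series_from_conc(c(7.5, 8.5, 8 + 2 * sd(c(7.5, 8.5))))
  bg2 <- estimate_background(s2)
  expect_false(flag_significant(s2, bg2)[3])

  # constructed spike: elevation 2 ug/mL >> 2 sd -> exactly that bottle flagged
  sim <- simulate_trap_series(trap_sim_config(seed = 4, background_sd = 0.2,
                                              spikes = list(c(7, 1000))))
  bg3 <- estimate_background(sim$series)
  flags <- flag_significant(sim$series, bg3)
  expect_identical(which(flags), 7L)
  # decisions depend only on the series: re-running is identical
  expect_identical(flags, flag_significant(sim$series, bg3))
})

test_that("flux and uncertainty follow the volume/area/period arithmetic", {
  bg0 <- structure(list(mean = 8, sd = 0, n_bottles_used = 3, cutoff = 9),
                   class = "background_estimate")
  f <- compute_flux(10, 500, 14, bg0, 0.66)
  expect_equal(f$sr_flux, 1 / (0.66 * 14), tolerance = 1e-12) # ~0.10823
  expect_equal(f$sr_flux_sd, 0.1 * 0.5 / (0.66 * 14), tolerance = 1e-12)

  # concentration equal to background: zero flux
  expect_equal(compute_flux(8, 500, 14, bg0, 0.66)$sr_flux, 0)

  # quadrature with a background sd
  bg5 <- structure(list(mean = 8, sd = 0.05, n_bottles_used = 3, cutoff = 9),
                   class = "background_estimate")
  f5 <- compute_flux(10, 500, 14, bg5, 0.66)
  expect_equal(f5$sr_flux_sd, sqrt(0.1^2 + 0.05^2) * 0.5 / 9.24,
               tolerance = 1e-12)

  # unit coherence: linear in volume, inverse in area and duration
  expect_equal(compute_flux(10, 1000, 14, bg0, 0.66)$sr_flux, 2 * f$sr_flux)
  expect_equal(compute_flux(10, 500, 28, bg0, 0.66)$sr_flux, f$sr_flux / 2)
  expect_equal(compute_flux(10, 500, 14, bg0, 1.32)$sr_flux, f$sr_flux / 2)
})

test_that("carbon conversion, POC share and carbonate bound are exact", {
  cc <- estimate_carbon(c(0.13, 0.23), 0)
  expect_equal(cc$c_flux, c(0.0156, 0.0276), tolerance = 1e-12)
  # with zero Sr-flux sd the relative error is the ratio's own
  expect_equal(cc$c_flux_sd / cc$c_flux, rep(0.022 / 0.120, 2),
               tolerance = 1e-12)
  z <- estimate_carbon(0, 0)
  expect_equal(z$c_flux, 0)
  expect_equal(z$c_flux_sd, 0)

  expect_equal(poc_contribution(3.1, 100), 3.1)
  expect_equal(poc_contribution(0, 5), 0)
  expect_equal(poc_contribution(0.05, 2.5), 2)
  # scale invariance under joint rescaling
  expect_equal(poc_contribution(0.05, 2.5), poc_contribution(5, 250))
  expect_error(poc_contribution(1, 0), "positive")

  expect_equal(carbonate_sr_bound(300, 1), 0.3)
  expect_equal(carbonate_sr_bound(0), 0)
  expect_equal(carbonate_sr_bound(100, 2), 0.2)
  expect_error(carbonate_sr_bound(-1), "non-negative")
})

test_that("trap series round-trip through CSV and full analysis runs", {
  sim <- simulate_trap_series(trap_sim_config(seed = 10))
  csv <- tempfile(fileext = ".csv")
  write_trap_series(sim, csv)
  back <- read_trap_series(csv)
  expect_length(back, 1L)
  expect_equal(back[[1]]$sr_ug_per_ml, sim$series$sr_ug_per_ml,
               tolerance = 1e-12)

  poc <- data.frame(bottle_id = sim$truth$bottle_id, total_poc_flux = 50)
  res <- analyze_trap_series(sim$series, poc_table = poc)
  expect_equal(nrow(res), 21L)
  expect_true(all(sim$truth$bottle_id %in% res$bottle_id[res$significant]))
  sig <- res[res$significant, ]
  expect_true(all(sig$sr_flux > 0))
  expect_equal(sig$c_flux, sig$sr_flux * 0.120, tolerance = 1e-12)
  got_poc <- sig[sig$bottle_id %in% poc$bottle_id, ]
  expect_equal(got_poc$poc_contribution_pct, 100 * got_poc$c_flux / 50,
               tolerance = 1e-12)
  # non-significant bottles carry no fluxes
  expect_true(all(is.na(res$sr_flux[!res$significant])))
})

test_that("report truncation mirrors printed precision, toward zero", {
  tbl <- tibble::tibble(trap_id = "T", bottle_id = "B",
                        sr_ug_per_ml = 10, significant = TRUE,
                        sr_flux = 0.2289, sr_flux_sd = 0.0199,
                        c_flux = 0.0276, c_flux_sd = 0.00599,
                        poc_contribution_pct = 3.19)
  out <- format_flux_report(tbl)
  expect_equal(out$sr_flux, 0.22)
  expect_equal(out$c_flux, 0.027)
  expect_equal(out$c_flux_sd, 0.005)
  expect_equal(out$poc_contribution_pct, 3.1)
})
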