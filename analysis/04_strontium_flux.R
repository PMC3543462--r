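#!/usr/bin/env Rscript

# Stage 4: sediment-trap strontium flux analysis.
#
# (a) Full analysis of the simulated trap series from stage 1: background
#     estimation, mean+2sd significance flagging, fluxes with propagated
#     uncertainty, C:Sr carbon conversion and percent-of-POC contribution.
# (b) The worked arithmetic on the published subtropical flux endpoints and
#     the carbonate sanity bound.
# (c) A 200-replicate spike-recovery study of the significance screen.

library(cystflux)

dir.create("results", showWarnings = FALSE)

## (a) simulated series -------------------------------------------------------
trap_csv <- "scratch/simdata/trap.csv"
stopifnot(file.exists(trap_csv))
series <- read_trap_series(trap_csv)[[1]]
truth <- read.csv("scratch/simdata/trap_truth.csv")

# a constant plausible bathypelagic POC flux so the percent contribution has
# a denominator (total POC is measured independently of this pipeline)
poc <- data.frame(bottle_id = series$bottle_id, total_poc_flux = 30)

res <- analyze_trap_series(series, poc_table = poc)
bg <- attr(res, "background")
cat(sprintf("background: %.3f +/- %.3f ug/mL over %d bottles (< %g ug/mL)\n",
            bg$mean, bg$sd, bg$n_bottles_used, bg$cutoff))
sig <- res[res$significant, ]
cat(sprintf("%d of %d bottles significant (> mean + 2 sd)\n",
            nrow(sig), nrow(res)))
cat("\nsignificant bottles (full precision):\n")
print(as.data.frame(sig), digits = 4)
m <- match(sig$bottle_id, truth$bottle_id)
hit <- !is.na(m)
cat(sprintf("\nspiked bottles recovered: %d/%d; |flux error| <= 2 sd: %s\n",
            sum(hit), nrow(truth),
            paste(abs(sig$sr_flux[hit] - truth$truth_flux[m[hit]]) <=
                    2 * sig$sr_flux_sd[hit], collapse = ", ")))
write.csv(format_flux_report(res), "results/04_flux_table.csv",
          row.names = FALSE)

## (b) worked arithmetic on published endpoint fluxes -------------------------
cc <- estimate_carbon(c(0.13, 0.23), 0, c_sr_ratio(0.120, 0.022))
endpoints <- data.frame(
  sr_flux_mg_m2_d = c(0.13, 0.23),
  c_flux_mg_m2_d = cystflux:::truncate_decimals(cc$c_flux, 3),
  c_flux_sd_mg_m2_d = round(cc$c_flux_sd, 4)
)
cat("\nC:Sr conversion of the subtropical endpoint Sr fluxes:\n")
print(endpoints)
cat(sprintf("carbonate Sr bound for a 300 ug/mL Ca elevation: %.1f ug/mL\n",
            carbonate_sr_bound(300)))
write.csv(endpoints, "results/04_csr_endpoints.csv", row.names = FALSE)

## (c) spike-recovery replicate study -----------------------------------------
n_rep <- 200L
detected <- logical(n_rep); any_fp <- logical(n_rep); covered <- c()
for (r in seq_len(n_rep)) {
  simt <- simulate_trap_series(trap_sim_config(seed = 1000L + r))
  rr <- analyze_trap_series(simt$series)
  spiked <- rr$bottle_id %in% simt$truth$bottle_id
  detected[r] <- all(rr$significant[spiked])
  any_fp[r] <- any(rr$significant[!spiked])
  tm <- match(rr$bottle_id[spiked], simt$truth$bottle_id)
  covered <- c(covered, abs(rr$sr_flux[spiked] - simt$truth$truth_flux[tm]) <=
                 2 * rr$sr_flux_sd[spiked])
}
rep_summary <- data.frame(
  n_replicates = n_rep,
  spike_detection_pct = 100 * mean(detected),
  false_positive_replicate_pct = 100 * mean(any_fp),
  coverage_within_2sd_pct = 100 * mean(covered)
)
cat("\nreplicate study of the significance screen:\n")
print(rep_summary)
cat("note: with ~18 Gaussian background bottles per series, a mean+2sd rule\n",
    "flags at least one unspiked bottle in roughly a third of series; this\n",
    "is the expected per-bottle ~2% upper-tail rate, not an implementation\n",
    "artifact.\n", sep = "")
write.csv(rep_summary, "results/04_replicate_summary.csv", row.names = FALSE)
cat("wrote results/04_flux_table.csv, results/04_csr_endpoints.csv, ",
    "results/04_replicate_summary.csv\n", sep = "")
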