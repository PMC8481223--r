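#!/usr/bin/env Rscript

# Step 6 -- spatially explicit capture-recapture density and abundance.
#
# Simulates identified-individual capture histories at desk scale
# (49-detector grid, 50 daily occasions, true density 0.14 animals/km2,
# half-normal detection g0 = 0.05, sigma = 2000 m), fits the three
# detection functions by conditional maximum likelihood, ranks them by
# AICc, and derives density and abundance with lognormal intervals.

suppressPackageStartupMessages(library(ctdemog))

det <- detector_grid(49, 2000, core_n = 0)
cen <- simulate_centres(det, density = 0.14, buffer = 8000, seed = 42)
simd <- simulate_detections(cen, det, list(kind = "HN", g0 = 0.05, sigma = 2000),
                            n_occasions = 50, seed = 43)
cat(sprintf("True population: %d centres; detected: %d individuals, %d detections\n",
            nrow(cen), dim(simd$ch$y)[1], sum(simd$ch$y)))
write_capture_histories(simd$ch, "results/capture_histories.csv")

mask <- make_mask(det, buffer = 8000, spacing = 1000)
print(mask)

fits <- lapply(c("HN", "EX", "HR"), function(k) fit_secr(simd$ch, mask, k))
rank <- rank_models(fits)
utils::write.csv(rank, "results/secr_model_ranking.csv", row.names = FALSE)
print(as.data.frame(rank))

best <- fits[[match(rank$kind[1], vapply(fits, `[[`, "", "kind"))]]
print(best)
de <- derive_density(best)
utils::write.csv(de, "results/density.csv", row.names = FALSE)
cat(sprintf("Density %.3f /km2 (95%% CI %.3f-%.3f); N over %.0f km2: %.0f (%.0f-%.0f)\n",
            de$D, de$D_lcl, de$D_ucl, de$area_km2,
            de$N_hat, de$N_lcl, de$N_ucl))
cat(sprintf("True density 0.140 /km2 %s the interval\n",
            if (de$D_lcl <= 0.14 && 0.14 <= de$D_ucl) "inside" else "outside"))

# abundance arithmetic at the published survey's printed density and mask
cat(sprintf("Published-scale check: 0.138 /km2 x 1413 km2 = %.0f animals\n",
            abundance_from_density(0.138, 1413)))
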