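#!/usr/bin/env Rscript
# Builds the bundled SYNTHETIC UK-like life-table fixture
# (inst/extdata/life_table_synthetic_uk.csv).
#
# The model's mortality input is the general-population annual death
# probability by age. This fixture approximates a recent UK national life
# table (unisex) from the anchor values below, log-linearly interpolated
# between anchor ages and log-linearly extrapolated from the last segment up
# to age 110 (capped at 1). It is synthetic: anchor values are rounded
# approximations of published national figures, not a copy of any table.
# Run from the repository root: Rscript scripts/make_fixture_life_table.R

anchors <- data.frame(
  age = c(0, 1, 10, 20, 30, 40, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100),
  qx  = c(0.0040, 0.0003, 0.0001, 0.0004, 0.0006, 0.0012, 0.0030, 0.0045,
          0.0070, 0.0110, 0.0170, 0.0280, 0.0480, 0.0850, 0.1500, 0.2400,
          0.3500)
)

ages <- 0:110
logq <- approx(anchors$age, log(anchors$qx), xout = pmin(ages, 100))$y
# extend beyond the last anchor with the final segment's log slope
slope <- (log(0.35) - log(0.24)) / 5
beyond <- ages > 100
logq[beyond] <- log(0.35) + slope * (ages[beyond] - 100)
qx <- pmin(1, exp(logq))

out <- file.path("inst", "extdata", "life_table_synthetic_uk.csv")
write.csv(data.frame(age = ages, qx = signif(qx, 6)), out,
          row.names = FALSE, quote = FALSE)
cat("wrote", out, "\n")
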