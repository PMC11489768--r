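#!/usr/bin/env Rscript
# The normality-gated statistical battery applied the way the result
# tables use it: Shapiro-Wilk gate, then Welch t / Wilcoxon / one-sample t
# / Kruskal-Wallis with Holm-corrected follow-ups, plus a two-way mixed
# ANOVA on a dose-response design.

library(nicocircuit)

set.seed(800)

# two-sample comparison (skewed data routes to Wilcoxon)
a <- rexp(18)^1.5 * 10
b <- rexp(18)^1.5 * 14
r2 <- suppressWarnings(normality_gated_compare(list(a, b), "two_sample"))
cat("two-sample battery (skewed data):\n")
print(r2[, c("test", "statistic", "value", "p")], row.names = FALSE)

# one-sample CPP-style comparison against zero
scores <- rnorm(16, 40, 60)
r1 <- normality_gated_compare(scores, "one_sample_vs_zero")
cat("\nCPP-style one-sample test vs 0:\n")
print(r1[, c("test", "statistic", "value", "p")], row.names = FALSE)

# four-group comparison with Holm-corrected pairwise follow-ups
g <- list(sac_sal = rexp(12)^2 * 8, sac_nic = rexp(12)^2 * 4,
          nic_sal = rexp(12)^2 * 8, nic_nic = rexp(12)^2 * 8)
rk <- suppressWarnings(normality_gated_compare(g, "k_sample"))
cat("\nfour-group battery with Holm follow-ups:\n")
print(rk[, c("test", "factor", "p", "p_adjusted")], row.names = FALSE)

# two-way mixed ANOVA: treatment (between) x concentration (within)
df <- expand.grid(subject = sprintf("s%02d", 1:16),
                  within = c("c10", "c50", "c100"))
df$between <- rep(c("SAC", "NIC"), each = 8)[
  as.integer(sub("s", "", df$subject))]
set.seed(801)
df$response <- 50 + 10 * (df$within == "c50") + 15 * (df$within == "c100") +
  8 * (df$between == "NIC") + rnorm(nrow(df), sd = 6)
ma <- mixed_anova(df, "subject", "between", "within", "response")
cat("\ntwo-way mixed ANOVA (treatment x concentration):\n")
print(round(ma, 4))

utils::write.csv(rbind(
  cbind(design = "two_sample", r2[, c("test", "factor", "value", "p",
                                      "p_adjusted")]),
  cbind(design = "one_sample", r1[, c("test", "factor", "value", "p",
                                      "p_adjusted")]),
  cbind(design = "k_sample", rk[, c("test", "factor", "value", "p",
                                    "p_adjusted")])
), "results/stats_battery.csv", row.names = FALSE)
utils::write.csv(cbind(effect = rownames(ma), ma),
                 "results/stats_mixed_anova.csv", row.names = FALSE)
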