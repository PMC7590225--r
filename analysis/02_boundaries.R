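#!/usr/bin/env Rscript
# Construct the six community-activity-space boundary schemes and account
# for how much of the region each one covers, echoing the study-area
# accounting: most of an agricultural region belongs to no sub-county
# boundary, and the combined place/urban-area scheme is the candidate
# community activity space.

suppressPackageStartupMessages(library(communitygreen))

cfg <- world_config(seed = 1)
world <- generate_region(cfg)
schemes <- c("county", "h1ha", "h10ha", "place", "urban_area", "combined")
boundaries <- lapply(schemes, function(s) build_boundary(world, s))
names(boundaries) <- schemes

for (b in boundaries) {
  n_empty <- sum(vapply(b$geoms, gs_is_empty, logical(1)))
  cat(sprintf("scheme %-10s: %d counties without qualifying area\n", b$scheme, n_empty))
}

cov <- coverage_stats(boundaries, world)
dir.create("results", showWarnings = FALSE)
write.csv(cov$schemes, "results/coverage_schemes.csv", row.names = FALSE)
write.csv(as.data.frame(cov$overlap), "results/coverage_overlap.csv")

sub <- coverage_stats(boundaries[setdiff(schemes, "county")], world)
cat(sprintf("\n%.2f%% of the region lies inside at least one sub-county boundary\n",
            sub$union$pct_of_region))
cat(sprintf("the combined place/urban-area scheme covers %.2f%%\n",
            cov$schemes$pct_of_region[cov$schemes$scheme == "combined"]))
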