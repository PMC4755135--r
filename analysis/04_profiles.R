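#!/usr/bin/env Rscript
# Stage 4: column connectivity profiles and column comparisons.
#
# Per subject: mean connection probability from each column's retained
# voxels to every target surviving the P < 0.0003 removal, and each
# column's relative share of the across-column total per target. Sides are
# averaged within subject, then every column pair is compared per target
# (paired t-tests, Bonferroni-corrected over the 6 pairs) and as a whole
# profile (within-subject sign-flip permutation test, 10,000 permutations).

suppressPackageStartupMessages(library(pagseg))

state <- readRDS("scratch/cohort.rds")
tracking <- readRDS("scratch/tracking.rds")
clusters <- tryCatch(readRDS("scratch/clusters.rds"),
                     error = function(e) stop("run analysis/03_cluster.R first"))
seed <- state$cfg$rng_seed

profile_list <- lapply(seq_along(state$cohort), function(i) {
  out <- list()
  for (sd in c("left", "right")) {
    cm <- tracking[[paste0("s", i, "_", sd)]]
    cl <- clusters[[paste0("s", i, "_", sd)]]
    tot <- total_seed_connectivity(cm)
    prof <- tryCatch(column_profiles(cl, cm, tot$target[!tot$removed]),
                     error = function(e) NULL)
    if (!is.null(prof)) out[[sd]] <- prof
  }
  out
})
profiles <- cohort_profiles(profile_list)
write.table(profiles, "results/column_profiles.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

tests <- pairwise_column_tests(profiles, n_perm = 10000L,
                               rng_seed = derive_seed(seed, "profiles"))
write.table(tests$pairwise, "results/pairwise_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(tests$multivariate, "results/multivariate_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# radial diagram of the cohort-average relative profiles
avg <- aggregate(relative ~ column + target, data = profiles, FUN = mean)
radial_profile_plot(avg, file = "scratch/radial_profiles.png")

cat("Cohort-average relative connectivity (column x target):\n")
print(round(xtabs(relative ~ column + target, avg), 3))
cat("\nMultivariate permutation tests per column pair:\n")
print(tests$multivariate, digits = 3)
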