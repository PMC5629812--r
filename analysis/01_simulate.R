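#!/usr/bin/env Rscript
# Build the study's synthetic inputs: a clustered three-class resistance
# landscape (costs 10 / 100 / 1000 at 100 m cells) and microsatellite
# genotypes for two "species" sampled at sites across it, with genetic
# divergence driven by landscape effective resistance.

source("analysis/00_config.R")

lspec <- landscape_spec(60, 60, habitat_fraction = 0.45, clustering = 4,
                        seed = SEED)
landscape <- generate_landscape(lspec)
write_ascii_grid(landscape, file.path(DATA_DIR, "resistance.asc"))
cat(sprintf("landscape: %d x %d cells, %.0f%% habitat (cost 10)\n",
            nrow(landscape$values), ncol(landscape$values),
            100 * mean(landscape$values == 10)))

# two species with their own sites and sampling depths, sharing the landscape
all_tabs <- list()
for (sp in c("north_sp", "south_sp")) {
  off <- if (sp == "north_sp") 0L else 50L
  sites <- place_sites(landscape,
                       sim_spec(n_sites = 12, min_site_separation_m = 400,
                                seed = SEED + 1L + off))
  spc <- sim_spec(n_sites = 12, n_loci = 10, alleles_per_locus = 7,
                  n_per_site = withr::with_seed(SEED + 2L + off,
                                                sample(10:30, 12, TRUE)),
                  drift_scale = 1e-3, missing_rate = 0.05,
                  min_site_separation_m = 400, seed = SEED + 3L + off)
  tab <- simulate_genotypes(landscape, sites, spc)
  tab$sites$species <- sp
  tab$sites$site_id <- paste0(sp, "_", tab$sites$site_id)
  tab$individuals$site_id <- paste0(sp, "_", tab$individuals$site_id)
  tab$individuals$individual_id <- paste0(sp, "_", tab$individuals$individual_id)
  all_tabs[[sp]] <- tab
  cat(sprintf("%s: %d individuals at %d sites, %.1f%% missing calls\n",
              sp, nrow(tab$individuals), nrow(tab$sites),
              100 * mean(tab$calls == 0L)))
}

merged <- genotype_table(
  individuals = rbind(all_tabs[[1]]$individuals, all_tabs[[2]]$individuals),
  loci = all_tabs[[1]]$loci,
  calls = rbind(all_tabs[[1]]$calls, all_tabs[[2]]$calls),
  sites = rbind(all_tabs[[1]]$sites, all_tabs[[2]]$sites))
write_genotypes_csv(merged, file.path(DATA_DIR, "genotypes.csv"))
cat(sprintf("wrote %s and %s\n", file.path(DATA_DIR, "genotypes.csv"),
            file.path(DATA_DIR, "resistance.asc")))
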