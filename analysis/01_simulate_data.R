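#!/usr/bin/env Rscript
# Generate the default synthetic dataset: 2000 abundance time series from
# 400 species across the six monitored vertebrate classes, with known
# class-level trends (amphibians declining; birds, mammals and reptiles
# increasing), species random intercepts, and the database's survey-length
# structure. Writes the long-format data, the generating truth, and
# synthetic phylogenies and occurrence clouds used by later steps.

suppressMessages(library(popchange))
dir.create("results", showWarnings = FALSE)

seed <- 20260928
cfg <- sim_config()  # 2000 series, 400 species, defaults documented there
out <- simulate_dataset(cfg, seed = seed)

write_lpd_long(out$data, "results/synthetic_long.csv")
readr::write_csv(out$truth$series, "results/truth_series.csv")
readr::write_csv(out$truth$species, "results/truth_species.csv")

# ten candidate trees for the phylogenetic step (one class's species)
amph <- out$truth$species$species[out$truth$species$taxon_class == "Amphibia"]
tree <- simulate_tree(length(amph), seed = seed + 1)
tree$tip.label <- gsub(" ", "_", amph)
trees <- lapply(1:100, function(i) {
  t_i <- simulate_tree(length(amph), seed = seed + 1 + i)
  t_i$tip.label <- gsub(" ", "_", amph)
  t_i
})
class(trees) <- "multiPhylo"
ape::write.tree(trees, "results/synthetic_trees.nwk")

# occurrence clouds with 10% dirty records for a handful of species
occ <- dplyr::bind_rows(lapply(seq_len(20), function(i) {
  simulate_occurrences(center = c(runif(1, -50, 60), runif(1, -150, 150)),
                       spread = runif(1, 0.5, 4), n = 300,
                       dirty_fraction = 0.1, seed = seed + 100 + i,
                       species = out$truth$species$species[i])
}))
readr::write_csv(occ, "results/synthetic_occurrences.csv")

cat(sprintf("wrote %d series (%d observations), %d trees, %d occurrence records\n",
            nrow(out$data$meta), nrow(out$data$obs), length(trees),
            nrow(occ)))
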