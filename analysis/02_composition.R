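#!/usr/bin/env Rscript
# Stage 2: broad-scale composition.
#
# Forbes F' and Simpson dissimilarities over all site pairs, Ward
# clustering matched against biome labels across a range of cut sizes,
# PCoA and rotated NMDS, and permutation-tested climate vectors on both
# ordinations after collinearity filtering.

library(wetlanddiv)

dat <- "results/data"; out <- "results/composition"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

community <- read_community_table(file.path(dat, "community.csv"))
metadata <- read_site_metadata(file.path(dat, "metadata.csv"),
                               community = community)
labels <- setNames(metadata$biome, metadata$site_id)

d_forbes <- dissimilarity_matrix(community, "forbes")
d_simpson <- dissimilarity_matrix(community, "simpson")
r <- matrix_correlation(d_forbes, d_simpson)$r
cat(sprintf("Forbes-Simpson matrix correlation: r = %.3f\n", r))
write.csv(unclass(d_forbes), file.path(out, "dissimilarity_forbes.csv"))

# Ward clustering under both variants; mismatch across cut sizes
for (variant in c("D2", "D")) {
  tree <- ward_cluster(d_forbes, variant = variant)
  sel <- select_k(tree, labels, k_range = 2:8)
  rows <- do.call(rbind, lapply(2:8, function(k) {
    cm <- cut_and_match(tree, k, labels)
    data.frame(variant = variant, k = k,
               ari = sel$scores$ari[sel$scores$k == k],
               mismatch_pct = 100 * cm$mismatch_rate)
  }))
  cat(sprintf("Ward (%s): best k = %d, mismatch at best k = %.1f%%\n",
              variant, sel$best_k,
              rows$mismatch_pct[rows$k == sel$best_k]))
  write.csv(rows, file.path(out, sprintf("cluster_path_%s.csv", variant)),
            row.names = FALSE)
  if (variant == "D2")
    write.csv(cut_and_match(tree, sel$best_k, labels)$assignments,
              file.path(out, "assignments_bestk.csv"), row.names = FALSE)
}

ordp <- pcoa(d_forbes)
cat(sprintf("PCoA: axes 1-2 explain %.1f%% and %.1f%% (positive-eigenvalue convention)\n",
            100 * ordp$prop_explained[1], 100 * ordp$prop_explained[2]))
cat(sprintf("      (all-eigenvalue convention: %.1f%% and %.1f%%)\n",
            100 * ordp$prop_all_eigenvalues[1],
            100 * ordp$prop_all_eigenvalues[2]))
ordn <- suppressWarnings(nmds(d_forbes, n_dims = 2, n_starts = 20,
                              seed = 71001))
ordn <- rotate_to_reference(ordn, ordp$points[, 1])
cat(sprintf("NMDS: stress = %.3f (converged: %s)\n", ordn$stress,
            ordn$converged))

clim <- as.data.frame(metadata)[c("mat", "map_mm", "p_seasonality",
                                  "t_seasonality", "dry_months")]
keep <- decorrelate_variables(clim, threshold = 0.7)
cat("Climate variables retained after r > 0.7 filter:",
    paste(keep$retained, collapse = ", "), "\n")
vec_p <- fit_climate_vectors(ordp, clim[keep$retained], n_perm = 999,
                             seed = 71002)
vec_n <- fit_climate_vectors(ordn, clim[keep$retained], n_perm = 999,
                             seed = 71002)
vecs <- rbind(cbind(ordination = "pcoa", vec_p),
              cbind(ordination = "nmds", vec_n))
print(vecs[vecs$significant, c("ordination", "variable", "r2", "p")])
write.csv(vecs, file.path(out, "fitted_vectors.csv"), row.names = FALSE)
write.csv(data.frame(site_id = rownames(ordp$points), ordp$points,
                     ordn$points),
          file.path(out, "ordination_coordinates.csv"), row.names = FALSE)
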