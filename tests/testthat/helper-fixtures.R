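# Shared fixtures: all synthetic, built in code.

# small, fast 3-biome metacommunity for structural tests
small_config <- function(seed = 101, sites = c(8L, 8L, 8L),
                         overlap = 0.2, stems = 400) {
  metacommunity_config(n_biomes = 3, site_counts = sites,
                       pool_sizes = c(300L, 300L, 300L),
                       pairwise_overlap = overlap,
                       stems_meanlog = rep(log(stems), 3),
                       stems_sdlog = 0.3, seed = seed)
}

# long-format table from a site x species abundance matrix
table_from_matrix <- function(m) {
  df <- data.frame(site_id = rep(rownames(m), ncol(m)),
                   species_name = rep(colnames(m), each = nrow(m)),
                   abundance = as.vector(m))
  community_table(df[df$abundance > 0, ], normalize = FALSE)
}

# random community of n_sites sites over a shared species universe
random_table <- function(n_sites = 6, n_species = 40, seed = 1,
                         fill = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(n_sites * n_species, 5, fill), n_sites,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              sprintf("Genus%02d sp%02d",
                                      seq_len(n_species), seq_len(n_species))))
  # guarantee non-empty sites
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  table_from_matrix(m)
}

trivial_metadata <- function(table, biomes = NULL) {
  sites <- unique(table$site_id)
  if (is.null(biomes)) biomes <- rep("A", length(sites))
  site_metadata(data.frame(site_id = sites, biome = biomes,
                           stringsAsFactors = FALSE))
}
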