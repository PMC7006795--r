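# Small in-code fixtures shared across tests.

# One plot's records. `species` is a character vector; covers, woody and
# alien flags recycle against it.
make_plot <- function(plot_id, species, cover, woody = TRUE, alien = FALSE,
                      continent = "ContA", tree_layer_cover = 60,
                      area = 200, latitude = 45, longitude = 10) {
  n <- length(species)
  data.frame(plot_id = plot_id, latitude = latitude, longitude = longitude,
             area_m2 = area, tree_layer_cover = tree_layer_cover,
             continent = continent, species_id = species,
             cover = rep_len(cover, n), woody = rep_len(woody, n),
             alien_here = rep_len(alien, n))
}

# Trait table from log-trait values (so tests can state ln traits directly).
traits_from_log <- function(species, ln_sla, ln_height = ln_sla,
                            ln_sm = ln_sla, ln_wd = ln_sla) {
  data.frame(species_id = species, sla_cm2_g = exp(ln_sla),
             height_m = exp(ln_height), seed_mass_mg = exp(ln_sm),
             wood_density_g_cm3 = exp(ln_wd))
}

# Random trait table for n species, seeded by the caller.
random_traits <- function(species) {
  n <- length(species)
  data.frame(species_id = species,
             sla_cm2_g = exp(rnorm(n, log(100), 0.5)),
             height_m = exp(rnorm(n, log(15), 0.6)),
             seed_mass_mg = exp(rnorm(n, log(50), 1)),
             wood_density_g_cm3 = exp(rnorm(n, log(0.55), 0.2)))
}

# Independent brute-force metric computations (naive per-species loops),
# used as oracles against the vectorised implementations.
naive_cwm <- function(weights, trait_table) {
  lt <- log(as.matrix(trait_table[match(names(weights),
                                        trait_table$species_id),
                                  c("sla_cm2_g", "height_m", "seed_mass_mg",
                                    "wood_density_g_cm3")]))
  out <- numeric(4L)
  for (t in 1:4) {
    s <- 0
    for (k in seq_along(weights)) s <- s + weights[k] * lt[k, t]
    out[t] <- s
  }
  out
}

naive_gower <- function(f, c, r) {
  s <- 0
  for (t in seq_along(f)) s <- s + abs(f[t] - c[t]) / r[t]
  unname(s) / length(f)
}

# Null-model rows for the range mixed model: species and plot intercepts,
# no range effect.
gen_range_null <- function(n_species = 15, n_plots = 120, rows_per_plot = 2,
                           sd_species = 0.3, sd_plot = 0.3, sd_eps = 0.5,
                           range_effect = 0) {
  a <- rnorm(n_species, 0, sd_species)
  u <- rnorm(n_plots, 0, sd_plot)
  pl <- rep(seq_len(n_plots), each = rows_per_plot)
  sp <- as.vector(vapply(seq_len(n_plots), function(p)
    sample.int(n_species, rows_per_plot), integer(rows_per_plot)))
  alien <- rbinom(length(sp), 1L, 0.3)
  y <- 0.3 + a[sp] + u[pl] + range_effect * alien +
    rnorm(length(sp), 0, sd_eps)
  data.frame(focal_species = sprintf("s%02d", sp),
             plot_id = sprintf("p%03d", pl),
             range = ifelse(alien == 1L, "alien", "native"),
             rel_abund = pmin(pmax(plogis(y), 1e-6), 1))
}
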