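# shared helpers: all fixtures are built in code or shipped as plain text

table1_path <- function() {
  system.file("extdata", "table1_districts.csv", package = "reinpast")
}

# small synthetic district set for fast unit tests
tiny_ds <- function(n = 6, seed = 42, noise_sd = 0, ...) {
  generate_district_set(synthetic_config(n_districts = n, seed = seed,
                                         noise_sd = noise_sd, ...))
}

# constant herd-series data frame for one district, used where the drivers
# must be fully controlled
flat_herd <- function(id = "X1", years = 1995:2007, calves = 250,
                      females = 550, males = 200) {
  data.frame(district_id = id, year = years,
             calves_alive = calves, females_alive = females,
             males_alive = males, calves_slaughtered = 100,
             females_slaughtered = 40, males_slaughtered = 20,
             traffic_deaths = 5, predation_reported = 10)
}

# one hand-built district row
one_district <- function(rotation = FALSE, feeding = 0, area = 50000,
                         a_q = 0, q = 0, z1995 = 400, z2008 = 300,
                         g = 0.8, hm = 0, infra = 0) {
  data.frame(district_id = "X1", rotation = rotation, feeding = feeding,
             area_lichen = area, area_arboreal = a_q, arboreal_avail = q,
             z_1995 = z1995, z_2008 = z2008, growth_rel = g,
             heavy_metal_pct = hm, infra_pct = infra)
}
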