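# Shared fixtures, built once per test run and cached. The "standard
# phantom" is the desk-scale study condition used throughout: a 25 mm disk,
# gray-matter-like background, one 4 mm inclusion with +0.005 mM HbO2 at
# (0, 12), 16 co-located sources/detectors on a ring, 750/850 nm.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

standard_spec <- function() {
  phantom_spec(radius = 25, edge_length = 2.5,
               inclusions = list(list(center = c(0, 12), radius = 4,
                                      delta_c1 = 0.005)))
}

standard_phantom <- function() {
  fixture("standard_phantom", function() make_phantom(standard_spec()))
}

standard_clean_measurements <- function() {
  fixture("standard_clean", function() simulate_experiment(standard_phantom()))
}

standard_background <- function() standard_spec()$background[[1]]

standard_scatter_prior <- function() {
  bg <- standard_background()
  list(amplitude = bg$scatter_amplitude, power = bg$scatter_power)
}

standard_c0 <- function() {
  bg <- standard_background()
  c(bg$c1, bg$c2)
}

# linearized first-iteration problem on the standard phantom (shared by the
# L-curve and solver behaviour tests)
standard_problem <- function() {
  fixture("standard_problem", function() {
    st <- recon_settings(solver = solver_settings("fista"), lambda = 1,
                         c0 = standard_c0())
    scdot:::first_iteration_problem(standard_clean_measurements(),
                                    standard_phantom()$mesh,
                                    standard_phantom()$optodes,
                                    default_extinction_table(),
                                    standard_scatter_prior(), st)
  })
}

# small coarse mesh + optodes for Jacobian-level tests
coarse_setup <- function() {
  fixture("coarse_setup", function() {
    mesh <- build_disk_mesh(15, 3)
    field <- optical_field(0.01, 1.0, 750, nrow(mesh$nodes))
    optodes <- position_optodes(mesh, 8, 8, "ring")
    list(mesh = mesh, field = field, optodes = optodes)
  })
}

# Table of published head-tissue scattering amplitude/power pairs and the
# reduced scattering they must reproduce at 750 and 850 nm
head_tissue_scatter <- function() {
  data.frame(
    tissue = c("scalp", "skull", "csf", "gray", "white"),
    amplitude = c(0.53, 0.7258, 0.3, 0.5040, 0.8176),
    power = c(1.1599, 0.8987, 0.9e-6, 1.7757, 1.3048),
    musp750 = c(0.74, 0.94, 0.3, 0.84, 1.19),
    musp850 = c(0.64, 0.84, 0.3, 0.6726, 1.0107))
}

# round computed values to the decimal precision of the printed reference
round_to_printed <- function(x, printed) {
  dec <- vapply(printed, function(p) {
    s <- sub("0+$", "", sprintf("%.10f", p))
    nchar(sub("^[^.]*\\.", "", s))
  }, 0L)
  round(x, dec)
}

head_tissue_concentrations <- function() {
  data.frame(
    tissue = c("scalp", "skull", "csf", "gray", "white"),
    c1 = c(0.0575, 0.0438, 0.011, 0.0548, 0.0683),
    c2 = c(0.0313, 0.0209, 0.0083, 0.0354, 0.0273),
    mua750 = c(0.017, 0.012, 0.004, 0.018, 0.017),
    mua850 = c(0.019, 0.014, 0.004, 0.019, 0.021))
}
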