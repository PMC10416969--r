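# Shared fixtures: all synthetic, built in code at test time.

# Canonical Clarke zone polygons on [0, 450]^2 (x = reference, y = estimate),
# derived independently from the published zone geometry by intersecting the
# zone half-planes; used as a point-in-polygon oracle against the ordered
# rule set. The seven polygons are pairwise disjoint (up to shared edges);
# zone B is the remainder of the plane.
clarke_zone_polygons <- function(lim = 450) {
  list(
    A  = list(zone = "A",
              x = c(0, 70, 70, lim, lim, lim / 1.2, 70, 175 / 3, 0),
              y = c(0, 0, 56, 0.8 * lim, lim, lim, 84, 70, 70)),
    E1 = list(zone = "E", x = c(180, lim, lim, 180), y = c(0, 0, 70, 70)),
    E2 = list(zone = "E", x = c(0, 70, 70, 0), y = c(180, 180, lim, lim)),
    C1 = list(zone = "C", x = c(70, 290, 290, 70), y = c(180, 400, lim, lim)),
    C2 = list(zone = "C", x = c(130, 180, 180), y = c(0, 0, 70)),
    D1 = list(zone = "D", x = c(240, lim, lim, 240), y = c(70, 70, 180, 180)),
    D2 = list(zone = "D", x = c(0, 175 / 3, 70, 70, 0),
              y = c(70, 70, 84, 180, 180)))
}

# Returns list(zone = character, hits = integer): hits counts how many of
# the disjoint polygons contain each point (0 => zone B).
clarke_polygon_oracle <- function(references, estimates) {
  polys <- clarke_zone_polygons()
  memb <- vapply(polys, function(p)
    pracma::inpolygon(references, estimates, p$x, p$y, boundary = TRUE),
    logical(length(references)))
  memb <- matrix(memb, nrow = length(references))
  hits <- rowSums(memb)
  zone <- vapply(seq_along(references), function(i) {
    w <- which(memb[i, ])
    if (!length(w)) "B" else polys[[w[1]]]$zone
  }, "")
  list(zone = zone, hits = hits)
}

# Minimal valid paired-readings frame with fixed plausible covariates.
make_readings <- function(g_m, g_r = g_m, patient_id = "p1") {
  n <- length(g_m)
  data.frame(patient_id = patient_id,
             timestamp = as.POSIXct("2023-01-01 08:00:00", tz = "UTC") +
               300 * seq_len(n),
             g_m = g_m, g_r = g_r,
             x2 = rep_len(c(0.1, 0.3, 0.2), n),
             x3 = rep_len(c(0.5, 0.7), n),
             x4 = rep_len(c(-10, 20, 5), n),
             x5 = rep_len(c(70, 85, 62), n),
             x6 = rep_len(c(14, 18), n),
             x7 = rep_len(c(33, 34.5), n),
             x8 = rep_len(c(0, 450, 120), n),
             stringsAsFactors = FALSE)
}

# One cluster's readings with error d = d_fun(features); covariates random
# but reproducible.
make_cluster_readings <- function(n, g_r_range, d_fun, seed = 1) {
  set.seed(seed)
  g_r <- runif(n, g_r_range[1], g_r_range[2])
  r <- data.frame(patient_id = "p1",
                  timestamp = as.POSIXct("2023-01-01", tz = "UTC") +
                    300 * seq_len(n),
                  g_m = g_r,  # placeholder
                  g_r = g_r,
                  x2 = runif(n, 0, 1), x3 = runif(n, 0, 2),
                  x4 = runif(n, -90, 90), x5 = runif(n, 50, 160),
                  x6 = runif(n, 8, 30), x7 = runif(n, 30, 38),
                  x8 = runif(n, 0, 1200), stringsAsFactors = FALSE)
  r$g_m <- r$g_r + d_fun(r)
  r
}

# Small MLP grid (8 candidates) used for recovery and selection tests.
reduced_mlp_grid <- function() {
  hyperparameter_grid(hidden_layer_options = list(20, c(10, 10)),
                      learning_rates = 0.05,
                      learning_types = "constant",
                      activations = c("relu", "tanh"),
                      solvers = c("lbfgs", "adam"),
                      iteration_counts = 500,
                      momenta = 0.9)
}

# Study-scale cohort configs (~1026 paired readings over 9 patients).
noiseless_cohort_config <- function(seed = 11) {
  cohort_config(duration_days = 19,
                error_model = error_model_spec(noise_sd = 0,
                                               patient_offset_sd = 0),
                seed = seed)
}

noisy_cohort_config <- function(seed, noise_sd = 10) {
  cohort_config(duration_days = 19,
                error_model = error_model_spec(noise_sd = noise_sd,
                                               patient_offset_sd = 0),
                seed = seed)
}

# Held-out before/after MARD of a grid-search selection, pooled over
# clusters (cluster membership by reference value).
heldout_before_after <- function(cohort, selection) {
  parts <- partition_readings(cohort$readings, selection$ensemble$scheme,
                              assign_by = "reference")
  h <- do.call(rbind, lapply(1:6, function(k) {
    r <- selection$results[[k]]
    if (is.null(r)) return(NULL)
    m <- r$best_model
    sub <- parts[[k]]
    data.frame(g_m = sub$g_m[m$heldout$index],
               g_r = sub$g_r[m$heldout$index],
               g_p = m$heldout$g_p)
  }))
  c(pre = mard(h$g_m, h$g_r), post = mard(h$g_p, h$g_r))
}
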