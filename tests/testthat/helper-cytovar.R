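# Shared fixtures for the test suite.

# A minimal 3-marker panel whose hierarchy exercises auto and fixed
# thresholds, binary and tri-level relations, without the size of the
# built-in panels.
tiny_panel <- function() {
  cyto_panel(
    name = "tiny",
    markers = data.frame(
      marker = c("CD45", "CD11b", "Ly6C"),
      channel = c("VioGreen", "APC", "FITC"),
      role = "surface",
      stringsAsFactors = FALSE))
}

tiny_hierarchy <- function() {
  gating_hierarchy(
    gate_node("intact", list(gate_condition("FSC", "positive", 10000)),
      children = list(
        gate_node("Leukocytes", list(gate_condition("CD45", "positive")),
          reported = TRUE,
          children = list(
            gate_node("Myeloid", list(gate_condition("CD11b", "positive")),
              reported = TRUE,
              children = list(
                gate_node("Ly6C_high",
                          list(gate_condition("Ly6C", "high")),
                          reported = TRUE),
                gate_node("Ly6C_low",
                          list(gate_condition("Ly6C", "low")),
                          reported = TRUE))))))),
    panel_name = "tiny", leukocyte_node = "Leukocytes")
}

tiny_populations <- function(panel) {
  list(
    population_spec("lymphocytes", 1000,
                    full_signature(panel, c(CD45 = "high"))),
    population_spec("myeloid_high", 300,
                    full_signature(panel, c(CD45 = "high", CD11b = "high",
                                            Ly6C = "high"))),
    population_spec("myeloid_low", 200,
                    full_signature(panel, c(CD45 = "high", CD11b = "high",
                                            Ly6C = "low"))),
    population_spec("myeloid_mid", 100,
                    full_signature(panel, c(CD45 = "high", CD11b = "high",
                                            Ly6C = "intermediate"))),
    population_spec("debris", 60,
                    full_signature(panel, c(CD45 = "negative"))))
}

tiny_config <- function(..., seed = 123) {
  panel <- tiny_panel()
  sim_config(list(panel = panel, hierarchy = tiny_hierarchy()),
             populations = tiny_populations(panel), seed = seed, ...)
}

# Brute-force two-factor sums of squares by explicit deviation sums,
# an independent oracle for anova_components().
brute_force_ss <- function(m) {
  a <- nrow(m); b <- ncol(m)
  grand <- mean(m)
  ss_animal <- 0; ss_time <- 0; ss_resid <- 0; ss_total <- 0
  for (i in seq_len(a)) for (j in seq_len(b)) {
    ri <- mean(m[i, ]); cj <- mean(m[, j])
    ss_animal <- ss_animal + (ri - grand)^2
    ss_time <- ss_time + (cj - grand)^2
    ss_resid <- ss_resid + (m[i, j] - ri - cj + grand)^2
    ss_total <- ss_total + (m[i, j] - grand)^2
  }
  list(SS_animal = ss_animal, SS_time = ss_time, SS_residual = ss_resid,
       SS_total = ss_total)
}
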