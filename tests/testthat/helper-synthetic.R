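# Shared fixtures, built in code at test time.

default_config <- species_config()

# tiny well-formed time-point data frame
tiny_timepoints_df <- function() {
  data.frame(
    species = c("human", "chimpanzee", "human"),
    event_id = c("ev1", "ev1", "ev2"),
    event_type = c("brain_growth", "brain_growth", "life_history"),
    age_value = c(100, 90, 12),
    age_frame = c("days_post_conception", "days_post_conception",
                  "years_postnatal"),
    sex = "pooled", population = "test", environment = "captive",
    provenance = "individual", stringsAsFactors = FALSE)
}

# small linear (gamma = 0) two-species parameter set with a known
# log-log warp alpha = beta_b / beta_a, intercept_b = alpha * intercept_a
two_species_params <- function(alpha = 1.2, a_A = 4, b_A = 5) {
  data.frame(species = c("sp_a", "sp_b"),
             alpha = c(a_A, alpha * a_A),
             beta = c(b_A, alpha * b_A), stringsAsFactors = FALSE)
}

# completed pipeline on a generated table; returns everything
run_synthetic_fit <- function(spec) {
  gen <- gen_event_table(spec)
  comp <- impute_missing(gen$table)
  sc <- compute_event_scale(comp)
  list(gen = gen, table = comp, scale = sc,
       fit = fit_translating_time(comp, sc))
}
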