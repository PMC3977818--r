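# Shared fixtures: toy models with closed-form behaviour, and a cache for
# the (expensive) default model steady state so test files can share it.

.cache <- new.env(parent = emptyenv())

cached_default_model <- function() {
  if (is.null(.cache$model)) .cache$model <- build_default_model()
  .cache$model
}

cached_steady_state <- function() {
  if (is.null(.cache$ss)) .cache$ss <- steady_state(cached_default_model())
  .cache$ss
}

cached_stimulated_run <- function() {
  if (is.null(.cache$run))
    .cache$run <- run_ode(cached_default_model(), schedule(),
                          state0 = cached_steady_state())
  .cache$run
}

# birth-death: 0 -> A at 1/s, A -> 0 at 0.01/s; stationary mean 100
birth_death_model <- function() {
  iir_model(c(A = 0),
            list(reaction("birth", numeric(0), c(A = 1),
                          "prot_unreg_transl_r", 2),
                 reaction("death", c(A = 1), numeric(0), "gene_inact_r", 1)))
}

# one gene copy toggled by a large constant TF pool; active fraction
# kon*TF / (kon*TF + koff) = 0.5 at the chosen rates
telegraph_model <- function() {
  iir_model(
    data.frame(name = c("G_X", "G_X_a", "TF"), compartment = "nucleus",
               role = c("gene-free", "gene-bound", "protein-active"),
               initial_count = c(1, 0, 1000), stringsAsFactors = FALSE),
    list(reaction("act_gene_X", c(TF = 1, G_X = 1), c(G_X_a = 1),
                  "gene_act_r", 100),
         reaction("inact_gene_X", c(G_X_a = 1), c(G_X = 1, TF = 1),
                  "gene_inact_r", 1)))
}

# schedule helper for models without a dsRNA species
toy_schedule <- function(horizon, output_grid, species = "A", count = 0) {
  schedule(equilibration_start = -1, stimulus_species = species,
           stimulus_count = count, horizon = horizon,
           output_grid = output_grid)
}
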