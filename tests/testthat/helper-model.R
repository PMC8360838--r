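# Full-scale reduced-network experiment, trained once and shared by the
# acceptance tests: a 2,000-record synthetic cohort at prevalence 0.10,
# patient-level 75/25 split, quarter-channel network, 5 epochs with the
# default augmentation probability.
acceptance_experiment <- function() {
  if (!is.null(.test_cache$exp)) return(.test_cache$exp)
  co <- synth_cohort(2000, prevalence = 0.10, seed = 101)
  x <- preprocess_cohort(co$records)
  y <- co$manifest$label
  pat <- co$manifest$patient_id
  pats <- unique(pat)
  val_p <- with_seed(1, sample(pats, length(pats) %/% 4))
  te <- pat %in% val_p
  mod <- train_model(x[!te, ], y[!te], x[te, ], y[te],
                     config = model_config(reduced = TRUE),
                     train_cfg = train_config(epochs = 5, seed = 7),
                     augment_cfg = augment_config(probability = 0.5))
  .test_cache$exp <- list(mod = mod, x = x, y = y, te = te)
  .test_cache$exp
}
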